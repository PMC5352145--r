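trait	analysis	source	df	ms	f	variance
ma549	pooled	Sex	1	477.59	39.56	0.30
ma549	pooled	Line	187	102.77	6.62	0.10
ma549	pooled	SexLine	186	15.57	12.52	1.24
ma549	pooled	Error	55216	1.24	NA	NA
ma549	females	Line	187	52.06	56.55	0.33
ma549	females	Error	28852	0.92	NA	0.92
ma549	males	Line	186	67.68	42.37	0.47
ma549	males	Error	26364	1.6	NA	1.60
pa14	pooled	Sex	1	370.74	8	2.86
pa14	pooled	Line	80	623.17	10.98	0.53
pa14	pooled	SexLine	80	56.78	12.46	4.56
pa14	pooled	Error	16219	4.56	NA	NA
pa14	females	Line	80	304.05	62.2	3.03
pa14	females	Error	7984	4.89	NA	4.89
pa14	males	Line	80	385.48	90.95	3.75
pa14	males	Error	8235	4.24	NA	4.24
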