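---
title: "Methods: survival phenotypes and quantitative genetics for inbred line panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival phenotypes and quantitative genetics for inbred line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelsurv)
```

# The problem

Panels of fully inbred, fully sequenced lines — the Drosophila Genetic
Reference Panel (DGRP) being the canonical example — let one dissect natural
variation in a complex trait such as pathogen resistance at three levels at
once: the trait mean (do lines differ in how long flies survive infection?),
the micro-environmental variance (do genetically identical flies of some
lines scatter more around their line mean than others?), and individual
polymorphisms (which markers associate with either?). `panelsurv` implements
this analysis stack end-to-end for time-to-death bioassays scored on a fixed
observation grid, together with a synthetic-data generator that produces
panels with known architecture for parameter-recovery testing.

# Survival phenotypes

The raw unit is one fly: line, sex, replicate tube, observation time in
hours, and death/censor status. Mortality checks happen on a scoring grid
(12 h by default), so observed times are interval-censored at the grid; the
package treats the recorded grid time as the death time and never
interpolates.

**LT50.** Each tube's survival curve is the Kaplan–Meier product-limit
estimate with Greenwood standard errors. The tube LT50 is the first event
time at which $S(t) \le 0.5$ — on a 12-h grid, interpolated medians would be
pseudo-precision. A line's LT50 is the arithmetic mean of its tube LT50s
(`mean_of_replicates`, the default, matching how replicate bioassays are
usually summarized) or the pooled-curve median. Under heavy right-censoring
(e.g. a 14-day assay horizon) a curve can stay above 0.5; the median is then
flagged undefined rather than invented.

**Micro-environmental plasticity.** Within-line spread is quantified by
$\sigma_E$, the root mean squared error of an intercept-only fit to the
uncensored death times — identically the ordinary $n-1$ standard deviation
(the suite asserts equality of the two routes) — plus $\ln\sigma_E$ and the
coefficient of environmental variation $CV_E = \sigma_E/\text{mean}$,
reported as a fraction. Censored flies contribute to curves but not to
means or $\sigma_E$; exclusions are counted. A published alternative
computes line SDs from Kaplan–Meier standard errors; the curve-level
Greenwood SEs are available on every `survival_curve`, but the plasticity
pipeline uses the root-MSE definition because it is the one the
variance-level heritability model is defined on.

# Variance partitioning and heritability

The pooled-sex mixed model is

$$Y = \mu + S + L + S{\times}L + \varepsilon,$$

with sex fixed and line and sex-by-line random. The ANOVA table uses Type
III sums of squares; the F ratios respect the mixed-model expected mean
squares — line and sex are tested over the sex-by-line mean square, and
sex-by-line over error. Components come from method-of-moments equating of
observed to expected mean squares rather than REML: the published tables
this pipeline mirrors are MS-based, and method of moments is reproducible in
closed form (on balanced designs the estimates equal the closed-form EMS
solutions exactly, which the suite asserts). Unbalanced designs use the
harmonic mean of cell counts in the EMS coefficients (the classical
unweighted-means approximation). Negative component estimates are truncated
at zero and flagged so that

$$H^2 = \frac{\sigma_L^2 + \sigma_{SL}^2}{\sigma_L^2 + \sigma_{SL}^2 + \sigma_E^2}
\quad\text{(pooled)},\qquad
H^2 = \frac{\sigma_L^2}{\sigma_L^2 + \sigma_E^2}
\quad\text{(single sex)}$$

stays in $[0,1]$.

Variance-level heritability treats each replicate tube's $\ln\hat\sigma_E$
as one observation of a one-way random-effects model $Y = \mu + L +
\varepsilon$; the same single-sex ratio applied to its components measures
how heritable the within-line spread itself is. Replicate-tube granularity
is fixed by the estimation design: $\sigma_E$ is estimated separately per
line and replicate, so each tube contributes one point and the residual
variance of the model is the sampling noise of $\ln\hat\sigma_E$ (about
$1/(2(n-1)) \approx 0.026$ at 20 flies per tube).

Heterogeneity of within-line variance can be screened with Levene's test
(one-way ANOVA on absolute deviations from the group mean; the
Brown–Forsythe median variant is selectable). A factorial model with line
nested in a line-level infection status ($Y = \mu + S + I + S{\times}I +
L(I) + S{\times}L(I) + \varepsilon$) tests symbiont effects such as
Wolbachia; the infection main effect is tested over the line-within-status
mean square. It is implemented by sequential sums of squares that honor the
nesting (status fitted before line), which coincides with Type III on
balanced designs.

# Association scans

Association observations are covariate-adjusted **line means**, not per-fly
records: phenotypes are first residualized on the Wolbachia indicator and
the five major cosmopolitan inversions by least squares (a two-step
"adjust, then scan" design), then each marker is tested by OLS of adjusted
values on minor-allele dosage over that marker's complete cases. This
replaces the mixed-model machinery of the reference-panel web pipeline with
plain OLS on adjusted means — an approximation we document rather than hide;
no kinship or genomic-control correction is applied, because inbred panel
lines are treated as exchangeable. Four phenotype variants are scanned:
male, female, sex-average and sex-difference, for the mean trait (LT50) or
the plasticity trait ($CV_E$ default, $\ln\sigma_E$ selectable).

Inbred lines are homozygous, so dosages are 0 or 2; residual heterozygous
calls become missing (with a logged count) instead of fractional dosages.
The reported effect is the model-implied difference between homozygote
classes, signed so that a **negative effect means minor-allele homozygotes
survive longer** — the convention used when reporting that resistance
alleles are predominantly rare. Markers with fewer than 4 minor-allele
lines are skipped by default (and the count is always reported, since hits
carried by ≤5 lines are fragile). Nominal P-values are reported against
fixed discovery thresholds ($10^{-5}$, $10^{-6}$) rather than FDR, matching
the discovery-oriented design. Downstream summaries cover the MAF ×
effect-size spectrum (fraction of hits below MAF 0.2, sign counts), the
per-line minor-allele load with optional susceptible/resistant split
correlations (which reproduces the U-shaped-placement logic: overall $r
\approx 0$ with opposite-signed split correlations), and hit overlap
between scans at marker and gene level.

# Site classification and enrichment

A polymorphism is *genic* if it falls in a gene model or within 1 kb
(inclusive of the 1000th base) upstream or downstream of one. Classes are
resolved by a fixed precedence — coding (non-synonymous > synonymous) >
UTR > intron > 1-kb flank > intergenic — because no published rule resolves
multi-feature hits; overlapping genes are all reported while a single class
is kept. Synonymy requires codon context (reference codon, position in
codon, strand) carried with the gene models; a coding site without context
is classified `exon_other` with a warning, never guessed. Enrichment
against genome composition (genic 48.2%, exonic 18.3%, intronic 30%,
intergenic 51.8% for the fly genome — shipped as overridable constants,
since they are inputs, not code) uses the two-cell 1-df goodness-of-fit
chi-square without continuity correction. The pipeline reports the
enrichment for both the genic fraction and the "functional" fraction
(introns + UTRs + non-synonymous), since the two are easily conflated when
only one statistic is printed.

# Correlations and kinetics

Cross-trait analysis computes Pearson correlations (Spearman selectable)
between line means with pairwise-complete deletion — public panel traits
cover different line subsets, so per-pair $n$ is recorded — and controls
the family-wise error with the Holm–Bonferroni step-down over the declared
family of pairs. Within-host kinetics are summarized from CFU time courses:
the per-line mean trajectory over sampled flies, its first strict crossing
of a load threshold (strict reading of "> 10 CFU"), and Pearson
correlations of crossing times with LT50. A Welch t-test from summary
statistics (means, SEs, $n$) supports comparisons where only published
summaries exist.

# The synthetic-data generator

`simulate_panel()`/`simulate_survival()` generate what the analysis
assumes, with recorded ground truth:

* **Genotypes** — biallelic markers with MAF drawn from a rare-skewed Beta
  spectrum ($0.5\,\mathrm{Beta}(0.5, 1.5)$, floored at 0.02), independent
  across lines; optional linkage blocks copy a latent haplotype with
  probability 0.9. Wolbachia (rate 0.5) and five inversion indicators
  (rate 0.15) are Bernoulli per line — unremarkable mid-range rates for a
  wild-derived panel.
* **Death times** — $t = \mu + \text{sex} + \text{line} +
  \text{sex{\times}line} + \sum_j(-e_j)\,d_j/2 + \sigma_\ell z$, with $z$ a
  standardized (mean 0, SD 1) log-normal residual by default: positive
  support and a clean separation of location from scale, with the family
  pluggable (no distributional form is claimed for real death times; the
  log-normal is a modeling choice). $\sigma_\ell = \sigma_0 \prod_k
  m_k^{d_k/2} e^{\eta_\ell}$, $\eta_\ell \sim N(0, s^2)$, so
  $\ln\sigma_E$ is linear in the variance-effect dosages — matching the
  scale the plasticity analysis works on. Times are rounded **up** to the
  scoring grid (discovery at the next tube check; minimum one grid step)
  and times past the horizon become censored records at the horizon.
* **Defaults are the assay's design**: 188 lines, two sexes, 3 tubes × 20
  flies, 12-h grid, mean death time 5.3 days (127.2 h), and mean-level
  components $\sigma_L^2 = 0.33$, $\sigma_E^2 = 0.92$ on the day scale
  (converted to hours², the generator's working unit; $H^2$ is
  scale-invariant, so the implied heritability 0.264 is unchanged). The
  line-level dispersion default $s = 0.16$ makes the variance-level
  heritability of $\ln\sigma_E$ come out near one half at 20 flies per
  tube, the magnitude reported for micro-environmental plasticity of
  infection survival. A stored mean effect $e_j$ is applied as
  $-e_j d_j/2$ so the scan recovers it in the reporting convention.
* **CFU curves** — per-fly logistic growth with the lag tied to line
  resistance (LT50 − 36 h, the window in which loads climb before death)
  and multiplicative log-normal noise; threshold crossings are positively
  coupled to LT50 by construction.

What the generator does **not** emulate: linkage maps and recombination,
genuine kinship structure among lines, batch/day effects across replicates,
tolerance-vs-resistance mechanisms, or any within-host dynamics beyond the
phenomenological logistic curve. Passing recovery tests therefore shows the
estimators are consistent under the stated model, not that real data meet
that model.

# Numerical choices and edge cases

* Grid rounding adds roughly $\mathrm{grid}^2/12$ (≈12 h² at a 12-h grid) to
  the within-line variance, attenuating mean-level $H^2$ recovery from
  0.264 to about 0.260 at the default design — inside the recovery
  tolerance and intrinsic to grid-scored data.
* $\sigma_E = 0$ (all deaths identical) flags $\ln\sigma_E$ missing;
  lines with fewer than two deaths flag $\sigma_E$ itself.
* Negative variance components truncate to zero with a flag; all-zero
  components make $H^2$ undefined (flagged, not an error).
* Zero residual variance in a marker regression flags the P-value as a
  boundary case instead of reporting zero.
* Heterozygous or half-missing genotype calls become missing; multi-allelic
  VCF records are skipped with a warning count; per-marker complete-case
  analysis drops missing lines marker-by-marker, not panel-wide.
* Ties in Holm–Bonferroni follow sort order; the procedure stops at the
  first failure, and flags map back to input order.
* Writers emit fixed column order, 6 significant digits, "." decimals and
  newline termination so outputs diff cleanly; rerunning a pipeline with
  the same seed reproduces result tables byte-for-byte.

# Problem sizes used by the test suite

Recovery and calibration checks run at the assay's design size where that
is what is being claimed (188 lines × 3 × 20 over 20 seeds for mean-level
recovery; 150 lines for variance-level recovery and the 2000-marker
permutation-null calibration) and at reduced sizes for module-level
behavior checks (e.g. 30-line designs for the infection-ANOVA null
calibration, 400 simulations for the family-wise error check). The
variance-level "truth = 0.5" condition is constructed by calibrating the
line-level dispersion against the measured replicate-level sampling noise
of $\ln\hat\sigma_E$, so the designed ratio $s^2/(s^2+v_{rep})$ is exactly
one half before estimation begins.

# Known limitations

OLS on adjusted line means ignores differing line-mean precision and any
residual relatedness; no mixed-model GWAS, epistasis, imputation or
gene-based burden testing is provided. The LT50 convention is
deliberately grid-coarse. Variance components are method-of-moments, not
REML (a REML cross-check is possible in tests but not part of the API).
Site classification does not predict variant effects beyond synonymy.
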