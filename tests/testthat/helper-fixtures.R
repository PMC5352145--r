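## Shared in-code fixtures for the suite. Everything is built
## programmatically; no binary data.

make_events <- function(times, status = "dead", line = "L1", sex = "M",
                        rep_id = "R1", treatment = "pathogen", grid = NULL) {
  n <- length(times)
  event_table(data.frame(
    line_id = rep_len(line, n), sex = rep_len(sex, n),
    replicate_id = rep_len(rep_id, n), time_h = times,
    status = rep_len(status, n), treatment = rep_len(treatment, n),
    stringsAsFactors = FALSE), scoring_grid_hours = grid)
}

## Small two-gene model set (one gene per strand) with codon context on
## the plus-strand CDS; coordinates 0-based half-open.
toy_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = c("2L", "2L"),
    strand = c("+", "-"),
    start = c(1000L, 8000L), end = c(3000L, 9500L))
  features <- data.frame(
    gene_id = c("gA", "gA", "gA", "gB"),
    type = c("utr5", "exon_cds", "utr3", "exon_cds"),
    start = c(1000L, 1200L, 2700L, 8200L),
    end = c(1200L, 2700L, 3000L, 9000L))
  codon <- data.frame(
    chrom = "2L",
    pos = c(1203L, 1201L, 8500L),          # 1-based genomic positions
    ref_codon = c("GGA", "GGA", "GGA"),
    codon_pos = c(3L, 1L, 1L))
  gene_model_set(genes, features, codon_context = codon)
}

## Balanced pooled-sex design with known effects, for EMS checks.
balanced_pooled_data <- function(n_lines = 6, n_per_cell = 5, sd_line = 2,
                                 sd_sexline = 1, sd_error = 1.5, seed = 1) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  le <- stats::rnorm(n_lines, 0, sd_line)
  grid <- expand.grid(line_id = lines, sex = c("F", "M"),
                      stringsAsFactors = FALSE)
  sle <- stats::rnorm(nrow(grid), 0, sd_sexline)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(value = 100 + le[match(grid$line_id[i], lines)] + sle[i] +
                 (grid$sex[i] == "M") * 3 +
                 stats::rnorm(n_per_cell, 0, sd_error),
               line_id = grid$line_id[i], sex = grid$sex[i],
               stringsAsFactors = FALSE)
  }))
}
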