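## Single-marker association on line-level phenotypes. Line means (not
## per-fly records) are the observations; covariates (Wolbachia status and
## the five major inversions) are removed first by least squares, then each
## marker is tested by OLS of the adjusted values on minor-allele dosage
## with per-marker complete cases. Inbred panel lines are treated as
## exchangeable (no kinship correction) -- a stated limitation.

#' Adjust line phenotypes for Wolbachia and inversion covariates
#'
#' Least-squares regression of line values on the infection indicator and
#' the five inversion indicators; returns residuals recentered at the
#' grand mean, plus each covariate's marginal t-test P-value (to support
#' inversion-effect reporting). Collinear or constant covariate columns
#' are dropped with a warning. Lines without covariates are dropped and
#' counted.
#'
#' @param values named numeric vector of line phenotypes (names = line ids).
#' @param covariates a `covariate_table`.
#' @return list `adjusted` (named numeric), `covariate_tests` (data frame
#'   `covariate`, `estimate`, `p`), `n_dropped_lines`, `dropped_covariates`.
#' @export
adjust_phenotype <- function(values, covariates) {
  stopifnot(!is.null(names(values)))
  values <- values[!is.na(values)]
  cov <- as.data.frame(covariates)
  common <- intersect(names(values), cov$line_id)
  n_dropped <- length(values) - length(common)
  if (n_dropped > 0)
    warning(sprintf("dropping %d line(s) without covariates", n_dropped))
  y <- values[common]
  X <- as.matrix(cov[match(common, cov$line_id), c("wolbachia", INVERSION_NAMES)])
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  dropped_cov <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) > 0) {
    q <- qr(cbind(1, X))
    indep <- q$pivot[seq_len(q$rank)]
    redundant <- setdiff(seq_len(ncol(X) + 1), indep) - 1L
    redundant <- redundant[redundant > 0]
    if (length(redundant) > 0) {
      dropped_cov <- c(dropped_cov, colnames(X)[redundant])
      X <- X[, -redundant, drop = FALSE]
    }
  }
  if (length(dropped_cov) > 0)
    warning(sprintf("dropping constant/collinear covariate(s): %s",
                    paste(dropped_cov, collapse = ", ")))
  if (ncol(X) == 0) {
    adjusted <- y
    tests <- data.frame(covariate = character(0), estimate = numeric(0),
                        p = numeric(0))
  } else {
    dat <- data.frame(.y = y, X, check.names = FALSE)
    fit <- stats::lm(.y ~ ., data = dat)
    co <- summary(fit)$coefficients
    tests <- data.frame(covariate = rownames(co)[-1], estimate = co[-1, 1],
                        p = co[-1, 4], row.names = NULL)
    adjusted <- stats::setNames(stats::residuals(fit) + mean(y), common)
  }
  list(adjusted = adjusted, covariate_tests = tests,
       n_dropped_lines = n_dropped, dropped_covariates = dropped_cov)
}

#' Single-marker association scan on adjusted line values
#'
#' Per marker, ordinary least squares of the adjusted line values on
#' minor-allele dosage over that marker's complete cases. The reported
#' effect is the model-implied difference between the homozygote classes,
#' signed so that a *negative* effect means minor-allele homozygotes
#' survive longer; two-sided t-based P. Markers whose complete-case
#' minor-allele line count falls below `min_minor_lines` are skipped with
#' a counted reason.
#'
#' @param adjusted named numeric vector of adjusted line values.
#' @param panel a `genotype_panel`.
#' @param min_minor_lines minimum lines carrying the minor allele
#'   (default 4).
#' @param pheno_variant label stored with the records (e.g. `"male"`,
#'   `"average"`).
#' @return an `association_records` data frame `chrom`, `pos`, `ref`,
#'   `alt`, `pheno_variant`, `effect`, `se`, `p`, `maf`, `minor_lines`,
#'   `n`, `flag`; attribute `skipped` tabulates skip reasons.
#' @export
marker_scan <- function(adjusted, panel, min_minor_lines = 4,
                        pheno_variant = "pheno") {
  stopifnot(inherits(panel, "genotype_panel"), !is.null(names(adjusted)))
  lines <- intersect(panel$line_ids, names(adjusted))
  if (length(lines) < 3) stop_format("insufficient-data error: < 3 usable lines")
  y <- adjusted[lines]
  M <- minor_dosage(panel)[, lines, drop = FALSE]

  W <- !is.na(M)
  M0 <- M; M0[!W] <- 0
  n <- as.numeric(W %*% rep(1, length(y)))
  sx <- rowSums(M0)
  sy <- as.numeric(W %*% y)
  sxy <- as.numeric(M0 %*% y)
  sxx <- rowSums(M0 * M0)
  syy <- as.numeric(W %*% (y * y))
  Sxx <- sxx - sx^2 / n
  Sxy <- sxy - sx * sy / n
  Syy <- syy - sy^2 / n
  minor_lines_cc <- rowSums(M0 == 2 & W)
  major_lines_cc <- rowSums(M0 == 0 & W)
  maf_cc <- minor_lines_cc / pmax(n, 1)

  testable <- minor_lines_cc >= min_minor_lines & major_lines_cc >= 1 &
    Sxx > 0 & n >= 3
  skipped <- c(below_minor_line_threshold =
                 sum(minor_lines_cc < min_minor_lines | Sxx <= 0),
               too_few_lines = sum(n < 3 & minor_lines_cc >= min_minor_lines))

  b <- Sxy / Sxx
  rss <- Syy - b * Sxy
  dfree <- n - 2
  s2 <- rss / dfree
  boundary <- testable & s2 <= .Machine$double.eps * pmax(Syy, 1)
  se_b <- sqrt(pmax(s2, 0) / Sxx)
  tstat <- b / se_b
  p <- 2 * stats::pt(-abs(tstat), dfree)
  p[boundary] <- NA_real_

  idx <- which(testable)
  rec <- data.frame(
    chrom = panel$markers$chrom[idx], pos = panel$markers$pos[idx],
    ref = panel$markers$ref[idx], alt = panel$markers$alt[idx],
    pheno_variant = rep(pheno_variant, length(idx)),
    effect = -2 * b[idx],             # negative <=> minor homozygotes live longer
    se = 2 * se_b[idx], p = p[idx],
    maf = maf_cc[idx], minor_lines = as.integer(minor_lines_cc[idx]),
    n = as.integer(n[idx]),
    flag = ifelse(boundary[idx], "boundary", ""),
    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  structure(rec, class = c("association_records", "data.frame"),
            skipped = skipped)
}

#' Line-level phenotype variants for association scans
#'
#' Builds the four phenotype variants the assay design supports -- male,
#' female, sex-average and male-minus-female difference -- for either the
#' mean-level trait (LT50) or the plasticity trait (CV_E by default,
#' ln(sigma_E) selectable).
#'
#' @param summaries a `line_summary`.
#' @param trait `"lt50"` (uses `lt50_h`), `"cv_e"` or `"ln_sigma_e"`.
#' @return named list of four named numeric vectors
#'   (`male`, `female`, `average`, `difference`).
#' @export
phenotype_variants <- function(summaries, trait = c("lt50", "cv_e", "ln_sigma_e")) {
  trait <- match.arg(trait)
  col <- c(lt50 = "lt50_h", cv_e = "cv_e", ln_sigma_e = "ln_sigma_e")[[trait]]
  df <- as.data.frame(summaries)
  m <- stats::setNames(df[[col]][df$sex == "M"], df$line_id[df$sex == "M"])
  f <- stats::setNames(df[[col]][df$sex == "F"], df$line_id[df$sex == "F"])
  both <- intersect(names(m), names(f))
  list(male = m, female = f,
       average = (m[both] + f[both]) / 2,
       difference = m[both] - f[both])
}

#' Minor-allele frequency / effect-size spectrum of significant hits
#'
#' @param records an `association_records` data frame.
#' @param p_threshold discovery threshold (e.g. `1e-5`).
#' @param maf_breaks bin boundaries for the MAF x |effect| table.
#' @return list `n_sig`, `frac_maf_below_0.2`, `n_negative`, `n_positive`,
#'   `bins` (data frame `maf_bin`, `n`, `mean_abs_effect`).
#' @export
maf_effect_spectrum <- function(records, p_threshold = 1e-5,
                                maf_breaks = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  sig <- records[!is.na(records$p) & records$p < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0)
    return(list(n_sig = 0L, frac_maf_below_0.2 = NA_real_, n_negative = 0L,
                n_positive = 0L,
                bins = data.frame(maf_bin = character(0), n = integer(0),
                                  mean_abs_effect = numeric(0))))
  bin <- cut(sig$maf, maf_breaks, include.lowest = TRUE)
  bins <- data.frame(maf_bin = levels(bin),
                     n = as.integer(table(bin)),
                     mean_abs_effect = as.numeric(tapply(abs(sig$effect), bin, mean)))
  list(n_sig = nrow(sig),
       frac_maf_below_0.2 = mean(sig$maf < 0.2),
       n_negative = sum(sig$effect < 0),
       n_positive = sum(sig$effect > 0),
       bins = bins)
}

#' Minor-allele load per line versus phenotype
#'
#' Counts, per line, the trait-associated markers at which the line is
#' homozygous for the minor allele, and correlates this load with the line
#' phenotype -- overall and, when `split_at` is given, separately below
#' and above the split (the susceptible/resistant partition).
#'
#' @param panel a `genotype_panel`.
#' @param markers indices (or logical mask) of the significant markers.
#' @param phenotype named numeric vector of line phenotypes.
#' @param split_at optional phenotype value partitioning the lines.
#' @return list `load` (named integer), `overall` (`r`, `p`, `n`), and when
#'   split, `below`/`above` with the same shape; `defined = FALSE` flags an
#'   undefined correlation (constant load).
#' @export
minor_allele_load <- function(panel, markers, phenotype, split_at = NULL) {
  if (length(phenotype) < 3 || is.null(names(phenotype)))
    stop_format("insufficient-data error: need >= 3 named line phenotypes")
  md <- minor_dosage(panel)[markers, , drop = FALSE]
  if (nrow(md) < 1) stop_format("need >= 1 significant marker")
  load <- colSums(md == 2, na.rm = TRUE)
  lines <- intersect(names(phenotype), names(load))
  lo <- load[lines]; ph <- phenotype[lines]
  corr <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::var(x) == 0 || stats::var(y) == 0)
      return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x), defined = TRUE)
  }
  out <- list(load = lo, overall = corr(lo, ph))
  if (!is.null(split_at)) {
    out$below <- corr(lo[ph < split_at], ph[ph < split_at])
    out$above <- corr(lo[ph > split_at], ph[ph > split_at])
  }
  out
}

#' Overlap of significant hits between two scans
#'
#' Marker-level intersection of records significant in both scans, and
#' the gene-level intersection given a marker-to-gene map.
#'
#' @param records_a,records_b `association_records`.
#' @param p_threshold discovery threshold applied to both.
#' @param marker_genes optional data frame `marker_id`, `gene_id`
#'   (`marker_id` in `chrom:pos:ref:alt` form).
#' @return list `shared_markers`, `n_sig_a`, `n_sig_b`, `shared_genes`
#'   (NULL without a map).
#' @export
overlap_hits <- function(records_a, records_b, p_threshold,
                         marker_genes = NULL) {
  ids_a <- marker_ids(records_a); ids_b <- marker_ids(records_b)
  if (length(intersect(ids_a, ids_b)) == 0)
    warning("disjoint marker universes: overlap is 0 of 0")
  sig_a <- ids_a[!is.na(records_a$p) & records_a$p < p_threshold]
  sig_b <- ids_b[!is.na(records_b$p) & records_b$p < p_threshold]
  shared <- intersect(sig_a, sig_b)
  shared_genes <- NULL
  if (!is.null(marker_genes)) {
    g_a <- unique(marker_genes$gene_id[marker_genes$marker_id %in% sig_a])
    g_b <- unique(marker_genes$gene_id[marker_genes$marker_id %in% sig_b])
    shared_genes <- intersect(g_a, g_b)
  }
  list(shared_markers = shared, n_sig_a = length(sig_a),
       n_sig_b = length(sig_b), shared_genes = shared_genes)
}

#' Write association records as TSV
#'
#' @param records an `association_records`.
#' @param path output path.
#' @export
write_association_records <- function(records, path) {
  write_result_table(as.data.frame(records), path, sep = "\t")
}
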