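make_panel <- function(dosage_rows, line_ids = NULL) {
  m <- do.call(rbind, dosage_rows)
  storage.mode(m) <- "integer"
  colnames(m) <- line_ids %||% sprintf("L%02d", seq_len(ncol(m)))
  genotype_panel(data.frame(chrom = "2L", pos = 100L * seq_len(nrow(m)),
                            ref = "A", alt = "T"), m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_covariates <- function(line_ids, wolbachia = NULL) {
  n <- length(line_ids)
  df <- data.frame(line_id = line_ids, wolbachia = wolbachia %||% rep(0, n))
  for (inv in c("In2Lt", "In2RNS", "In3RP", "In3RK", "In3RMo")) df[[inv]] <- 0
  covariate_table(df)
}

test_that("adjustment is a projection: constant covariates, removal, idempotence", {
  lines <- sprintf("L%02d", 1:30)
  y <- stats::setNames(stats::rnorm(30, 120, 10), lines)

  ## all-constant covariates: values returned unchanged
  expect_warning(adj <- adjust_phenotype(y, toy_covariates(lines)),
                 "constant/collinear")
  expect_equal(adj$adjusted, y)

  ## an injected +10 h Wolbachia shift is removed exactly by least squares
  set.seed(41)
  for (s in 1:20) {
    wol <- c(0, 1, stats::rbinom(28, 1, 0.5))
    yy <- stats::setNames(stats::rnorm(30, 120, 5) + 10 * wol, lines)
    suppressWarnings(adj <- adjust_phenotype(yy, toy_covariates(lines, wol)))
    tt <- stats::t.test(adj$adjusted[wol == 1], adj$adjusted[wol == 0])
    expect_gt(tt$p.value, 0.05)
  }

  ## idempotence
  wol <- rep(c(0, 1), 15)
  yy <- stats::setNames(stats::rnorm(30) + 5 * wol, lines)
  suppressWarnings(a1 <- adjust_phenotype(yy, toy_covariates(lines, wol)))
  suppressWarnings(a2 <- adjust_phenotype(a1$adjusted, toy_covariates(lines, wol)))
  expect_equal(a2$adjusted, a1$adjusted, tolerance = 1e-10)
})

test_that("adjustment reports marginal covariate tests and dropped lines", {
  lines <- sprintf("L%02d", 1:20)
  wol <- rep(c(0, 1), 10)
  y <- stats::setNames(stats::rnorm(20) + 3 * wol, lines)
  suppressWarnings(adj <- adjust_phenotype(y, toy_covariates(lines, wol)))
  expect_true("wolbachia" %in% adj$covariate_tests$covariate)
  expect_lt(adj$covariate_tests$p[adj$covariate_tests$covariate == "wolbachia"],
            0.01)
  y2 <- c(y, orphan = 1)
  expect_warning(adj2 <- adjust_phenotype(y2, toy_covariates(lines, wol)),
                 "without covariates")
  expect_equal(adj2$n_dropped_lines, 1)
})

test_that("marker scan matches the per-marker least-squares oracle", {
  p <- make_panel(list(c(0L, 0L, 2L, 2L)))
  y <- stats::setNames(c(1, 2, 3, 4), p$line_ids)
  rec <- marker_scan(y, p, min_minor_lines = 2)
  ## homozygote classes {1,2} vs {3,4}: difference 2; minor (alt) class
  ## lives longer so the reported effect is negative
  expect_equal(rec$effect, -2)
  expect_equal(abs(rec$effect), 2)
  fit <- summary(stats::lm(y ~ c(0, 0, 2, 2)))
  expect_equal(rec$se, 2 * fit$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(rec$p, fit$coefficients[2, 4], tolerance = 1e-10)
  expect_equal(rec$p, 2 * stats::pt(-sqrt(8), 2), tolerance = 1e-10)

  set.seed(43)
  p2 <- simulate_panel(architecture_spec(n_lines = 40, n_markers = 25,
                                         maf = 0.3, seed = 6))$panel
  y2 <- stats::setNames(stats::rnorm(40), p2$line_ids)
  recs <- marker_scan(y2, p2, min_minor_lines = 2)
  md <- minor_dosage(p2)
  for (k in sample(nrow(recs), 5)) {
    i <- which(p2$markers$pos == recs$pos[k])
    fit <- summary(stats::lm(y2 ~ md[i, ]))
    expect_equal(recs$effect[k], -2 * fit$coefficients[2, 1], tolerance = 1e-9)
    expect_equal(recs$p[k], fit$coefficients[2, 4], tolerance = 1e-9)
  }
})

test_that("markers below the minor-line threshold are skipped with reasons", {
  p <- make_panel(list(c(0L, 0L, 2L, 2L), c(0L, 0L, 0L, 0L)))
  y <- stats::setNames(c(1, 2, 3, 4), p$line_ids)
  rec <- marker_scan(y, p, min_minor_lines = 4)
  expect_equal(nrow(rec), 0)
  expect_equal(unname(attr(rec, "skipped")["below_minor_line_threshold"]), 2)
  rec2 <- marker_scan(y, p, min_minor_lines = 2)
  expect_equal(nrow(rec2), 1)          # monomorphic marker still skipped
})

test_that("effects are equivariant and the scan is line-order invariant", {
  set.seed(44)
  p <- simulate_panel(architecture_spec(n_lines = 30, n_markers = 15,
                                        maf = 0.4, seed = 2))$panel
  y <- stats::setNames(stats::rnorm(30), p$line_ids)
  r1 <- marker_scan(y, p, min_minor_lines = 2)
  r2 <- marker_scan(y * 3, p, min_minor_lines = 2)
  expect_equal(r2$effect, 3 * r1$effect, tolerance = 1e-10)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)
  r3 <- marker_scan(y[sample(names(y))], p, min_minor_lines = 2)
  expect_equal(r3, r1, ignore_attr = TRUE)
})

test_that("P-values are uniform under a permutation null", {
  spec <- architecture_spec(n_lines = 150, n_markers = 500, seed = 52)
  p <- simulate_panel(spec)$panel
  set.seed(52)
  y <- stats::setNames(stats::rnorm(150), sample(p$line_ids))
  rec <- marker_scan(y, p)
  expect_gt(stats::ks.test(rec$p, "punif")$p.value, 0.01)
})

test_that("an injected large-effect marker ranks first", {
  hits <- vapply(1:20, function(s) {
    spec <- architecture_spec(n_lines = 150, n_markers = 300, seed = 100 + s)
    p <- simulate_panel(spec)$panel
    set.seed(200 + s)
    y <- stats::rnorm(150)
    md <- minor_dosage(p)
    cand <- which(p$minor_lines >= 15)
    mk <- cand[sample(length(cand), 1)]
    y <- y + (md[mk, ] / 2) * 1.5 * stats::sd(y)
    names(y) <- p$line_ids
    rec <- marker_scan(y, p)
    rec$pos[which.min(rec$p)] == p$markers$pos[mk]
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("phenotype variants cover male, female, average and difference", {
  ls <- data.frame(line_id = rep(c("L1", "L2", "L3"), each = 2),
                   sex = rep(c("M", "F"), 3),
                   lt50_h = c(100, 90, 120, 100, 110, 115),
                   cv_e = c(.1, .2, .15, .25, .2, .3))
  v <- phenotype_variants(ls, "lt50")
  expect_equal(unname(v$average["L1"]), 95)
  expect_equal(unname(v$difference["L1"]), 10)
  vc <- phenotype_variants(ls, "cv_e")
  expect_equal(unname(vc$male["L2"]), .15)
})

test_that("MAF/effect spectrum summarizes significant hits", {
  rec <- data.frame(chrom = "2L", pos = 1:6, ref = "A", alt = "T",
                    pheno_variant = "male",
                    effect = c(-3, -2, -1, 2, 1, -5),
                    se = 1, p = c(1e-7, 1e-6, 1e-8, 1e-9, 0.5, 1e-6),
                    maf = c(.05, .1, .15, .05, .4, .3),
                    minor_lines = 5L, n = 100L, flag = "")
  sp <- maf_effect_spectrum(rec, 1e-5)
  expect_equal(sp$n_sig, 5)
  expect_equal(sp$frac_maf_below_0.2, 4 / 5)
  expect_equal(sp$n_negative, 4)
  expect_equal(sp$n_positive, 1)
  ## sign symmetry: negating the phenotype swaps the counts
  rec2 <- rec; rec2$effect <- -rec2$effect
  sp2 <- maf_effect_spectrum(rec2, 1e-5)
  expect_equal(sp2$n_negative, sp$n_positive)
  expect_equal(sp2$n_positive, sp$n_negative)
  ## all hits rare
  rec3 <- rec; rec3$maf <- 0.05
  expect_equal(maf_effect_spectrum(rec3, 1e-5)$frac_maf_below_0.2, 1)
})

test_that("rare causal alleles with larger effects enrich the low-MAF bin", {
  diffs <- vapply(1:10, function(s) {
    set.seed(300 + s)
    n <- 120
    rare <- pmax(stats::runif(40, 0.02, 0.15), 0.02)
    common <- stats::runif(40, 0.25, 0.5)
    maf <- c(rare, common)
    dos <- t(vapply(maf, function(q) 2L * stats::rbinom(n, 1, q), integer(n)))
    colnames(dos) <- sprintf("L%03d", 1:n)
    p <- genotype_panel(data.frame(chrom = "2L", pos = 100L * (1:80),
                                   ref = "A", alt = "T"), dos)
    beta <- c(rep(2, 40), rep(1, 40))            # rare effects 2x common
    y <- as.numeric(crossprod(dos / 2, beta)) + stats::rnorm(n, 0, 0.5)
    names(y) <- colnames(dos)
    rec <- marker_scan(y, p, min_minor_lines = 2)
    sig <- rec[rec$p < 1e-3, ]
    mean(abs(sig$effect[sig$maf < 0.2])) - mean(abs(sig$effect[sig$maf >= 0.2]))
  }, numeric(1))
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})

test_that("minor-allele load correlates with phenotype by construction", {
  set.seed(61)
  n <- 60
  lines <- sprintf("L%03d", 1:n)
  ph <- stats::setNames(sort(stats::rnorm(n, 120, 15)), lines)
  ## minor alleles concentrated in the most resistant (high-LT50) lines
  prob <- ifelse(seq_len(n) > n / 2, 0.5, 0.05)
  dos <- t(vapply(1:30, function(i) 2L * stats::rbinom(n, 1, prob), integer(n)))
  colnames(dos) <- lines
  p <- genotype_panel(data.frame(chrom = "2L", pos = 100L * (1:30),
                                 ref = "A", alt = "T"), dos)
  res <- minor_allele_load(p, 1:30, ph)
  expect_true(res$overall$defined)
  expect_gt(res$overall$r, 0.4)

  ## constant loads flagged undefined
  dos2 <- matrix(2L, 3, n, dimnames = list(NULL, lines))
  p2 <- genotype_panel(data.frame(chrom = "2L", pos = 1:3, ref = "A",
                                  alt = "T"), dos2)
  expect_false(minor_allele_load(p2, 1:3, ph)$overall$defined)
})

test_that("U-shaped allele placement yields opposite split correlations", {
  set.seed(62)
  n <- 80
  lines <- sprintf("L%03d", 1:n)
  ph <- stats::setNames(sort(stats::rnorm(n, 96, 20)), lines)
  rank <- seq_len(n)
  prob <- ifelse(rank <= n / 4 | rank > 3 * n / 4, 0.5, 0.05)
  dos <- t(vapply(1:40, function(i) 2L * stats::rbinom(n, 1, prob), integer(n)))
  colnames(dos) <- lines
  p <- genotype_panel(data.frame(chrom = "2L", pos = 100L * (1:40),
                                 ref = "A", alt = "T"), dos)
  res <- minor_allele_load(p, 1:40, ph, split_at = stats::median(ph))
  expect_lt(abs(res$overall$r), 0.25)
  expect_lt(res$below$r, -0.3)
  expect_gt(res$above$r, 0.3)
})

test_that("hit overlap behaves on identical, disjoint and empty-threshold inputs", {
  rec <- data.frame(chrom = "2L", pos = 1:5, ref = "A", alt = "T",
                    pheno_variant = "male", effect = 1, se = 1,
                    p = c(1e-7, 1e-6, 1e-3, 0.5, 1e-8),
                    maf = .1, minor_lines = 5L, n = 50L, flag = "")
  ov <- overlap_hits(rec, rec, 1e-5)
  expect_equal(sort(ov$shared_markers), sort(marker_ids(rec)[rec$p < 1e-5]))
  expect_equal(length(overlap_hits(rec, rec, 0)$shared_markers), 0)
  rec2 <- rec; rec2$pos <- rec2$pos + 1000
  expect_warning(ov2 <- overlap_hits(rec, rec2, 1e-5), "disjoint")
  expect_equal(length(ov2$shared_markers), 0)
  ## gene-level intersection through a marker-gene map
  map <- data.frame(marker_id = marker_ids(rec), gene_id = c("g1", "g1", "g2", "g3", "g4"))
  ov3 <- overlap_hits(rec, rec, 1e-5, marker_genes = map)
  expect_setequal(ov3$shared_genes, c("g1", "g4"))
})
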