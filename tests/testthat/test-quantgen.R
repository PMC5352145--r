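test_that("single-sex ANOVA matches closed-form EMS on a balanced toy", {
  df <- data.frame(value = c(1, 2, 3, 5, 6, 7),
                   line_id = rep(c("A", "B"), each = 3))
  vc <- anova_mixed(df, model = "single_sex")
  expect_equal(vc$table$MS, c(24, 1))
  expect_equal(unname(vc$components["error"]), 1)
  expect_equal(unname(vc$components["line"]), (24 - 1) / 3)
  expect_equal(vc$n_h, 3)
})

test_that("pooled-sex components equal closed-form EMS on balanced designs", {
  df <- balanced_pooled_data(n_lines = 6, n_per_cell = 5, seed = 3)
  vc <- anova_mixed(df, model = "pooled_sex")

  ## independent closed-form EMS route from cell means
  n <- 5; s <- 2; l <- 6
  cell <- tapply(df$value, list(df$line_id, df$sex), mean)
  line_m <- rowMeans(cell); sex_m <- colMeans(cell); gm <- mean(df$value)
  ms_line <- n * s * sum((line_m - gm)^2) / (l - 1)
  ms_sex <- n * l * sum((sex_m - gm)^2) / (s - 1)
  inter <- sweep(sweep(cell, 1, line_m), 2, sex_m) + gm
  ms_sl <- n * sum(inter^2) / ((l - 1) * (s - 1))
  fitted_cell <- cell[cbind(df$line_id, df$sex)]
  ms_e <- sum((df$value - fitted_cell)^2) / (l * s * (n - 1))

  expect_equal(vc$table$MS, c(ms_sex, ms_line, ms_sl, ms_e), tolerance = 1e-10)
  expect_equal(unname(vc$components["error"]), ms_e, tolerance = 1e-10)
  expect_equal(unname(vc$components["sex_line"]),
               max((ms_sl - ms_e) / n, 0), tolerance = 1e-10)
  expect_equal(unname(vc$components["line"]),
               max((ms_line - ms_sl) / (s * n), 0), tolerance = 1e-10)
  ## F for line is over the sex-by-line mean square, never over error
  expect_equal(vc$table$F[vc$table$Source == "Line"], ms_line / ms_sl,
               tolerance = 1e-10)
})

test_that("heritability follows the model-matched formula and is scale invariant", {
  vc1 <- variance_components(line = 0.47, error = 1.6, model = "single_sex")
  expect_equal(as.numeric(broad_sense_heritability(vc1)), 0.47 / 2.07)
  vc2 <- variance_components(line = 2, sex_line = 1, error = 3,
                             model = "pooled_sex")
  expect_equal(as.numeric(broad_sense_heritability(vc2)), 3 / 6)
  expect_equal(as.numeric(broad_sense_heritability(
    variance_components(line = 0, error = 1))), 0)

  df <- balanced_pooled_data(seed = 11)
  h1 <- as.numeric(broad_sense_heritability(anova_mixed(df, "pooled_sex")))
  df2 <- df; df2$value <- df$value * 7.3
  h2 <- as.numeric(broad_sense_heritability(anova_mixed(df2, "pooled_sex")))
  expect_equal(h1, h2, tolerance = 1e-10)
})

test_that("shuffling line labels collapses the line component", {
  df <- balanced_pooled_data(n_lines = 10, n_per_cell = 6, sd_line = 3,
                             seed = 21)
  orig <- anova_mixed(df, "single_sex")$components[["line"]]
  set.seed(9)
  shuf <- vapply(1:20, function(i) {
    d <- df
    d$line_id <- sample(d$line_id)
    anova_mixed(d, "single_sex")$components[["line"]]
  }, numeric(1))
  expect_lt(mean(shuf), 0.15 * orig)
})

test_that("degenerate ANOVA inputs are rejected", {
  expect_error(anova_mixed(data.frame(value = rep(1, 10),
                                      line_id = rep(c("A", "B"), 5)),
                           "single_sex"), "zero-variance")
  expect_warning(
    anova_mixed(data.frame(value = c(1, 2, 3, 4, 9),
                           line_id = c("A", "A", "B", "B", "C")),
                "single_sex"),
    "single observation")
})

test_that("infection-status ANOVA detects an injected line-level shift", {
  set.seed(14)
  n_lines <- 100
  lines <- sprintf("L%03d", 1:n_lines)
  infection <- stats::rbinom(n_lines, 1, 0.5)
  le <- stats::rnorm(n_lines, 0, 1)
  df <- do.call(rbind, lapply(1:n_lines, function(i)
    data.frame(value = 120 + le[i] + 24 * infection[i] +
                 stats::rnorm(8, 0, 1.5),
               sex = rep(c("M", "F"), each = 4),
               line_id = lines[i], infection = infection[i])))
  res <- covariate_anova(df)
  expect_lt(res$p_infection, 0.001)

  ## permuting infection labels destroys the shift
  set.seed(15)
  perm_p <- vapply(1:20, function(i) {
    d <- df
    map <- sample(infection)
    d$infection <- map[match(d$line_id, lines)]
    covariate_anova(d)$p_infection
  }, numeric(1))
  expect_gt(stats::median(perm_p), 0.1)
})

test_that("infection-status P is uniform under the null", {
  set.seed(16)
  ps <- vapply(1:200, function(i) {
    n_lines <- 30
    lines <- sprintf("L%02d", 1:n_lines)
    infection <- c(0, 1, stats::rbinom(n_lines - 2, 1, 0.5))
    le <- stats::rnorm(n_lines, 0, 1)
    df <- do.call(rbind, lapply(1:n_lines, function(j)
      data.frame(value = le[j] + stats::rnorm(6, 0, 1),
                 sex = rep(c("M", "F"), each = 3),
                 line_id = lines[j], infection = infection[j])))
    covariate_anova(df)$p_infection
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Levene's test behaves at the null, under power, and vs brute force", {
  ## identical spread profiles -> statistic exactly 0
  v <- c(1, 3, 5, 11, 13, 15)
  g <- rep(c("A", "B"), each = 3)
  res <- levene_test(v, g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)

  set.seed(20)
  v <- c(stats::rnorm(50, 0, 1), stats::rnorm(50, 0, 10))
  g <- rep(c("A", "B"), each = 50)
  expect_lt(levene_test(v, g)$p, 0.001)

  ## brute-force oracle: one-way ANOVA on |y - group mean|
  for (i in 1:5) {
    v <- stats::rnorm(60, 0, sample(1:3, 1))
    g <- sample(c("A", "B", "C"), 60, replace = TRUE)
    res <- levene_test(v, g)
    dev <- abs(v - stats::ave(v, g))
    a <- stats::anova(stats::lm(dev ~ factor(g)))
    expect_equal(res$statistic, a$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p, a$`Pr(>F)`[1], tolerance = 1e-10)
  }

  expect_warning(levene_test(c(1, 2, 3, 4, 9), c("A", "A", "B", "B", "C")),
                 "dropping")
})

test_that("variance-level heritability is near zero without line dispersion", {
  h2s <- vapply(1:5, function(s) {
    spec <- architecture_spec(n_lines = 80, n_markers = 5, n_causal_mean = 0,
                              n_causal_var = 0, sigma_ln_sigma = 0,
                              sigma2_sexline = 0, seed = s)
    pan <- simulate_panel(spec)
    ev <- simulate_survival(pan$panel, pan$covariates, spec)$events
    rs <- replicate_summaries(ev)
    variance_level_heritability(rs[rs$sex == "M", ])$h2
  }, numeric(1))
  expect_lt(mean(h2s), 0.15)
})

test_that("more line-level dispersion raises the variance-level estimate", {
  h2_at <- function(s_ln) {
    mean(vapply(1:5, function(s) {
      spec <- architecture_spec(n_lines = 60, n_markers = 5,
                                n_causal_mean = 0, n_causal_var = 0,
                                sigma_ln_sigma = s_ln, sigma2_sexline = 0,
                                seed = s)
      pan <- simulate_panel(spec)
      ev <- simulate_survival(pan$panel, pan$covariates, spec)$events
      rs <- replicate_summaries(ev)
      variance_level_heritability(rs[rs$sex == "M", ])$h2
    }, numeric(1)))
  }
  expect_gt(h2_at(0.32), h2_at(0.16))
})

test_that("cross-sex correlation handles identity, nulls and missing sexes", {
  ls <- data.frame(line_id = rep(sprintf("L%02d", 1:10), each = 2),
                   sex = rep(c("M", "F"), 10),
                   lt50_h = rep(seq(100, 145, 5), each = 2))
  res <- cross_sex_correlation(ls)
  expect_equal(res$r, 1)
  expect_equal(res$n, 10)

  set.seed(33)
  n <- 100
  ls2 <- data.frame(line_id = rep(sprintf("L%03d", 1:n), 2),
                    sex = rep(c("M", "F"), each = n),
                    lt50_h = stats::rnorm(2 * n))
  expect_lt(abs(cross_sex_correlation(ls2)$r), 3 / sqrt(n - 3))

  ls3 <- ls[-1, ]                  # L01 lacks its male record
  res3 <- cross_sex_correlation(ls3)
  expect_equal(res3$n, 9)
  expect_equal(res3$n_dropped, 1)
  expect_error(cross_sex_correlation(ls[1:4, ]), "insufficient")
})
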