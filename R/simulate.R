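## Synthetic panel generator. Emulates a DGRP-style infection bioassay:
## ~190 near-homozygous inbred lines, two sexes, three replicate tubes of
## ~20 flies, mortality scored on a 12-h grid, with genetic effects on both
## the mean death time and the within-line residual scale. All generators
## are pure functions of (spec, seed) and record the ground truth needed
## for parameter-recovery tests.

#' Simulation architecture specification
#'
#' Defaults reproduce the design of the fungal-challenge assay that the
#' analysis stack was built around: 188 lines, 3 replicate tubes x 20 flies
#' per sex, 12-hour scoring, mean death time near 5.3 days, and mean-level
#' variance components (hours squared) equal to the day-scale components
#' 0.33 / 0.92 of the single-sex survival-time ANOVA converted to hours
#' (x 24^2). The within-line scale sigma_line is log-normal across lines
#' with `sigma_ln_sigma = 0.16`, chosen so that at 20 flies per replicate
#' the variance-level heritability of ln(sigma_E) is near one half.
#'
#' @param n_lines number of inbred lines.
#' @param n_markers number of biallelic markers.
#' @param maf either a single minor-allele frequency applied to every
#'   marker, or a list `list(shape1, shape2, min)` describing a rare-skewed
#'   Beta spectrum: MAF = max(min, 0.5 * Beta(shape1, shape2)).
#' @param block_size markers per linkage block (1 = independent markers).
#' @param block_r probability that a marker copies its block's latent
#'   haplotype rather than drawing independently.
#' @param p_wolbachia,p_inversion Bernoulli rates for line-level infection
#'   status and each of the 5 inversion covariates.
#' @param n_causal_mean,mean_effects_h number of mean-effect causal markers
#'   and their signed effects in hours. A negative stored effect means
#'   minor-allele homozygotes survive *longer* (the sign convention of the
#'   association records). `NULL` draws magnitudes 6 + |N(0, 6)| hours with
#'   a 70% negative-sign rate.
#' @param n_causal_var,var_multipliers number of variance-effect causal
#'   markers and their multiplicative effects on sigma_line (default 1.3).
#' @param sex_effect_h fixed male-minus-female difference in mean death
#'   time (hours); males get `+sex_effect_h/2`, females `-sex_effect_h/2`.
#' @param sigma2_line,sigma2_sexline,sigma2_error mean-level variance
#'   components in hours^2: polygenic line variance (beyond the explicit
#'   causal markers), sex-by-line interaction variance, and the mean
#'   within-line residual variance sigma_0^2.
#' @param sigma_ln_sigma SD of the line-level log-normal noise on
#'   sigma_line; with it the log within-line SD is linear in the
#'   variance-effect dosages plus Gaussian noise.
#' @param reps_per_line,flies_per_rep replicate tubes per line x sex and
#'   flies per tube.
#' @param scoring_grid_h scoring interval (hours); death times are rounded
#'   *up* to this grid (interval-censored discovery at tube checks).
#'   `NULL` keeps continuous times.
#' @param horizon_h optional right-censoring horizon (hours); flies alive
#'   past it are recorded as censored at the horizon.
#' @param baseline_family residual shape, `"lognormal"` (right-skewed,
#'   standardized to mean 0 / SD 1, shape `lognormal_sdlog`) or
#'   `"normal"`.
#' @param lognormal_sdlog shape of the standardized log-normal residual.
#' @param mu_h baseline mean death time (hours).
#' @param seed integer seed; every generator is deterministic given it.
#' @return an `architecture_spec` list.
#' @export
architecture_spec <- function(n_lines = 188, n_markers = 2000,
                              maf = list(shape1 = 0.5, shape2 = 1.5, min = 0.02),
                              block_size = 1, block_r = 0.9,
                              p_wolbachia = 0.5, p_inversion = 0.15,
                              n_causal_mean = 10, mean_effects_h = NULL,
                              n_causal_var = 5, var_multipliers = NULL,
                              sex_effect_h = 4.8,
                              sigma2_line = 0.33 * 24^2,
                              sigma2_sexline = 0.04 * 24^2,
                              sigma2_error = 0.92 * 24^2,
                              sigma_ln_sigma = 0.16,
                              reps_per_line = 3, flies_per_rep = 20,
                              scoring_grid_h = 12, horizon_h = NULL,
                              baseline_family = c("lognormal", "normal"),
                              lognormal_sdlog = 0.3,
                              mu_h = 5.3 * 24, seed = 1L) {
  baseline_family <- match.arg(baseline_family)
  if (n_lines < 2 || n_markers < 1)
    stop_format("configuration error: need n_lines >= 2 and n_markers >= 1")
  if (any(c(sigma2_line, sigma2_sexline, sigma2_error) < 0) || sigma_ln_sigma < 0)
    stop_format("configuration error: variances must be non-negative")
  if (sigma2_error <= 0 && baseline_family == "lognormal" && sigma_ln_sigma > 0)
    stop_format("configuration error: non-positive baseline scale")
  if (n_causal_mean > n_markers || n_causal_var > n_markers)
    stop_format("configuration error: causal marker count exceeds n_markers")
  spec <- list(n_lines = n_lines, n_markers = n_markers, maf = maf,
               block_size = block_size, block_r = block_r,
               p_wolbachia = p_wolbachia, p_inversion = p_inversion,
               n_causal_mean = n_causal_mean, mean_effects_h = mean_effects_h,
               n_causal_var = n_causal_var, var_multipliers = var_multipliers,
               sex_effect_h = sex_effect_h, sigma2_line = sigma2_line,
               sigma2_sexline = sigma2_sexline, sigma2_error = sigma2_error,
               sigma_ln_sigma = sigma_ln_sigma, reps_per_line = reps_per_line,
               flies_per_rep = flies_per_rep, scoring_grid_h = scoring_grid_h,
               horizon_h = horizon_h, baseline_family = baseline_family,
               lognormal_sdlog = lognormal_sdlog, mu_h = mu_h,
               seed = as.integer(seed))
  class(spec) <- "architecture_spec"
  spec
}

#' Mean-level heritability implied by an architecture specification
#'
#' The single-sex ratio sigma_L^2 / (sigma_L^2 + sigma_E^2) of the
#' polygenic line variance against the mean residual variance; explicit
#' causal-marker effects add genetic variance on top of this.
#'
#' @param spec an `architecture_spec`.
#' @return implied heritability in `[0, 1)`.
#' @export
implied_h2 <- function(spec) {
  spec$sigma2_line / (spec$sigma2_line + spec$sigma2_error)
}

#' Simulate a homozygous genotype panel and line covariates
#'
#' Dosages are sampled per marker from the MAF spectrum, independently
#' across lines; markers inside a linkage block copy a shared latent
#' haplotype with probability `block_r`. Wolbachia and inversion states
#' are Bernoulli per line. The alt allele is always the generated minor
#' allele, so MAF <= 0.5 by construction.
#'
#' @param spec an `architecture_spec`.
#' @return `list(panel = genotype_panel, covariates = covariate_table)`.
#' @export
simulate_panel <- function(spec) {
  set.seed(spec$seed)
  m <- spec$n_markers; n <- spec$n_lines
  maf <- if (is.numeric(spec$maf)) rep(spec$maf, m)
         else pmax(spec$maf$min, 0.5 * stats::rbeta(m, spec$maf$shape1, spec$maf$shape2))
  line_ids <- sprintf("L%04d", seq_len(n))
  block <- ((seq_len(m) - 1) %/% spec$block_size) + 1
  dos <- matrix(0L, m, n, dimnames = list(NULL, line_ids))
  for (b in unique(block)) {
    idx <- which(block == b)
    u_block <- stats::runif(n)               # latent haplotype per line
    for (j in idx) {
      use_block <- stats::runif(n) < spec$block_r
      u <- ifelse(use_block & length(idx) > 1, u_block, stats::runif(n))
      dos[j, ] <- ifelse(u < maf[j], 2L, 0L)
    }
  }
  chroms <- c("2L", "2R", "3L", "3R", "X")
  markers <- data.frame(chrom = chroms[(block - 1) %% length(chroms) + 1],
                        pos = 1000L + 100L * seq_len(m),
                        ref = "A", alt = "T", stringsAsFactors = FALSE)
  cov <- data.frame(line_id = line_ids,
                    wolbachia = stats::rbinom(n, 1, spec$p_wolbachia))
  for (inv in INVERSION_NAMES)
    cov[[inv]] <- stats::rbinom(n, 1, spec$p_inversion)
  list(panel = genotype_panel(markers, dos), covariates = covariate_table(cov))
}

## Standardized residual draw: mean 0, SD 1, family-shaped.
baseline_residual <- function(n, family, sdlog) {
  if (family == "normal") return(stats::rnorm(n))
  s2 <- sdlog^2
  (stats::rlnorm(n, 0, sdlog) - exp(s2 / 2)) / sqrt((exp(s2) - 1) * exp(s2))
}

#' Simulate per-fly survival events with recorded ground truth
#'
#' Death time = mu + sex + line + sex-by-line + causal mean effects +
#' sigma_line * standardized residual, where
#' sigma_line = sigma_0 * prod(variance multipliers ^ (minor dosage / 2)) *
#' exp(N(0, sigma_ln_sigma^2)), so ln(sigma_E) is linear in the
#' variance-effect dosages. Times are rounded up to the scoring grid
#' (minimum one grid step) and times past the horizon become censored
#' records at the horizon.
#'
#' @param panel,covariates output of [simulate_panel()] (covariates are
#'   carried for downstream stages; they do not influence death times).
#' @param spec the `architecture_spec` used for the panel.
#' @return `list(events = event_table, truth = sim_truth)`; `truth` holds
#'   the realized line effects, sex-by-line effects, per-line sigma, causal
#'   marker ids/effects and realized variance components.
#' @export
simulate_survival <- function(panel, covariates, spec) {
  if (length(panel$line_ids) != spec$n_lines)
    stop_format("configuration error: panel lines do not match spec")
  if (spec$sigma2_error < 0)
    stop_format("configuration error: non-positive baseline scale")
  set.seed(spec$seed + 1L)
  n <- spec$n_lines
  line_ids <- panel$line_ids
  md <- minor_dosage(panel)

  causal_mean <- integer(0); eff <- numeric(0)
  if (spec$n_causal_mean > 0) {
    causal_mean <- sort(sample.int(spec$n_markers, spec$n_causal_mean))
    eff <- spec$mean_effects_h %||%
      ((6 + abs(stats::rnorm(spec$n_causal_mean, 0, 6))) *
         ifelse(stats::runif(spec$n_causal_mean) < 0.7, -1, 1))
    if (length(eff) != spec$n_causal_mean)
      stop_format("configuration error: mean_effects_h length != n_causal_mean")
  }
  causal_var <- integer(0); mult <- numeric(0)
  if (spec$n_causal_var > 0) {
    pool <- setdiff(seq_len(spec$n_markers), causal_mean)
    causal_var <- sort(sample(pool, min(spec$n_causal_var, length(pool))))
    mult <- spec$var_multipliers %||% rep(1.3, length(causal_var))
    if (length(mult) != length(causal_var))
      stop_format("configuration error: var_multipliers length != n_causal_var")
  }

  ## line-level genetic values: negative stored effect => minor carriers
  ## live longer, hence the applied shift is -effect * dosage / 2
  g_causal <- if (length(causal_mean))
    as.numeric(crossprod(md[causal_mean, , drop = FALSE] / 2, -eff)) else rep(0, n)
  line_eff <- stats::rnorm(n, 0, sqrt(spec$sigma2_line)) + g_causal
  sl_eff <- matrix(stats::rnorm(2 * n, 0, sqrt(spec$sigma2_sexline)), n, 2,
                   dimnames = list(line_ids, c("F", "M")))
  log_mult <- if (length(causal_var))
    as.numeric(crossprod(md[causal_var, , drop = FALSE] / 2, log(mult))) else rep(0, n)
  sigma_line <- sqrt(spec$sigma2_error) * exp(log_mult) *
    exp(stats::rnorm(n, 0, spec$sigma_ln_sigma))

  sexes <- c("F", "M")
  sex_shift <- c(F = -spec$sex_effect_h / 2, M = spec$sex_effect_h / 2)
  nfly <- spec$reps_per_line * spec$flies_per_rep
  rows <- vector("list", 2L * n)
  k <- 0L
  for (s in sexes) for (i in seq_len(n)) {
    mu <- spec$mu_h + sex_shift[[s]] + line_eff[i] + sl_eff[i, s]
    t_raw <- mu + sigma_line[i] * baseline_residual(nfly, spec$baseline_family,
                                                    spec$lognormal_sdlog)
    if (!is.null(spec$scoring_grid_h)) {
      g <- spec$scoring_grid_h
      t_obs <- pmax(ceiling(t_raw / g), 1) * g   # round UP; minimum one step
    } else t_obs <- pmax(t_raw, .Machine$double.eps)
    status <- rep("dead", nfly)
    if (!is.null(spec$horizon_h)) {
      over <- t_obs > spec$horizon_h
      t_obs[over] <- spec$horizon_h
      status[over] <- "censored"
    }
    k <- k + 1L
    rows[[k]] <- data.frame(
      line_id = line_ids[i], sex = s,
      replicate_id = rep(sprintf("R%d", seq_len(spec$reps_per_line)),
                         each = spec$flies_per_rep),
      time_h = t_obs, status = status, treatment = "pathogen",
      stringsAsFactors = FALSE)
  }
  events <- event_table(do.call(rbind, rows),
                        scoring_grid_hours = spec$scoring_grid_h)
  truth <- structure(list(
    line_ids = line_ids,
    line_effects = stats::setNames(line_eff, line_ids),
    sexline_effects = sl_eff,
    sigma_line = stats::setNames(sigma_line, line_ids),
    causal_mean = data.frame(marker = causal_mean, effect_h = eff),
    causal_var = data.frame(marker = causal_var, multiplier = mult),
    realized = c(var_line = stats::var(line_eff),
                 var_sexline = stats::var(as.numeric(sl_eff)),
                 mean_sigma2 = mean(sigma_line^2),
                 var_ln_sigma = stats::var(log(sigma_line)))),
    class = "sim_truth")
  list(events = events, truth = truth)
}

#' Simulate within-host CFU time courses
#'
#' Per-fly logistic growth curves sampled on a 12-h grid, with the growth
#' lag proportional to line resistance (expected LT50 minus 36 h, the
#' window in which loads climb before death) and multiplicative log-normal
#' count noise; threshold-crossing times are positively associated with
#' LT50 by construction.
#'
#' @param line_lt50_h named vector of expected LT50s (hours), one per line.
#' @param n_flies flies sampled per line and time point.
#' @param K,rate logistic carrying capacity (CFU) and growth rate (per h).
#' @param lag_offset_h time from (LT50 - 36 h) to the logistic midpoint.
#' @param noise_sdlog SD of the log-normal multiplicative count noise
#'   (0 = deterministic curves).
#' @param grid_h sampling interval in hours.
#' @param seed integer seed.
#' @return a `cfu_series` data frame: `line_id`, `fly_id`, `time_h`, `cfu`.
#' @export
simulate_cfu <- function(line_lt50_h, n_flies = 10, K = 5e4, rate = 0.25,
                         lag_offset_h = 24, noise_sdlog = 0.5, grid_h = 12,
                         seed = 1L) {
  if (any(line_lt50_h <= 0)) stop_format("configuration error: negative resistance score")
  if (noise_sdlog < 0 || K <= 0 || rate <= 0)
    stop_format("configuration error: invalid CFU parameters")
  set.seed(seed)
  out <- lapply(names(line_lt50_h), function(ln) {
    lag <- line_lt50_h[[ln]] - 36
    t_mid <- lag + lag_offset_h
    times <- seq(0, ceiling((line_lt50_h[[ln]] + 48) / grid_h) * grid_h, by = grid_h)
    do.call(rbind, lapply(seq_len(n_flies), function(f) {
      mu <- K / (1 + exp(-rate * (times - t_mid)))
      noise <- if (noise_sdlog > 0) stats::rlnorm(length(times), 0, noise_sdlog) else 1
      data.frame(line_id = ln, fly_id = sprintf("fly%02d", f), time_h = times,
                 cfu = round(mu * noise), stringsAsFactors = FALSE)
    }))
  })
  structure(do.call(rbind, out), class = c("cfu_series", "data.frame"))
}
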