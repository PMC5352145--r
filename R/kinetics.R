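## Within-host pathogen kinetics: colony-forming-unit (CFU) time courses
## summarized per line and related to survival phenotypes. Crossing of a
## load threshold is read strictly ("> threshold") on the mean trajectory
## over flies, since counts are averaged across sampled flies per time
## point.

#' First time the mean CFU trajectory exceeds a threshold
#'
#' @param series a `cfu_series` data frame (`line_id`, `fly_id`, `time_h`,
#'   `cfu`).
#' @param threshold load threshold (strictly exceeded).
#' @return data frame `line_id`, `crossing_h` (`NA` when never crossed),
#'   `crossed`.
#' @export
threshold_crossing_time <- function(series, threshold) {
  if (nrow(series) == 0) stop_format("empty-input error: no CFU records")
  if (threshold < 0) stop_format("configuration error: negative threshold")
  out <- lapply(split(series, series$line_id), function(g) {
    mean_traj <- tapply(g$cfu, g$time_h, mean)
    times <- as.numeric(names(mean_traj))
    ord <- order(times)
    hit <- which(mean_traj[ord] > threshold)
    data.frame(line_id = g$line_id[1],
               crossing_h = if (length(hit)) times[ord][hit[1]] else NA_real_,
               crossed = length(hit) > 0, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation between load-threshold crossing times and line LT50s
#'
#' Pearson correlation with a two-sided P; never-crossed lines are
#' excluded with a count.
#'
#' @param crossings output of [threshold_crossing_time()].
#' @param lt50_h named numeric vector of line LT50s (hours).
#' @return list `r`, `p`, `n`, `n_never_crossed`.
#' @export
kinetics_phenotype_correlation <- function(crossings, lt50_h) {
  df <- crossings[crossings$crossed, , drop = FALSE]
  n_never <- sum(!crossings$crossed)
  common <- intersect(df$line_id, names(lt50_h))
  x <- df$crossing_h[match(common, df$line_id)]
  y <- lt50_h[common]
  if (length(common) < 3)
    stop_format("insufficient-data error: < 3 lines with both quantities")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common),
       n_never_crossed = n_never)
}

#' Welch t-test from summary statistics
#'
#' Two-group comparison from means, standard errors and sample sizes (SD
#' recovered as SE * sqrt(n)); Welch-Satterthwaite degrees of freedom;
#' two-sided P. Used for published-style comparisons such as spore
#' production between resistant and susceptible line sets.
#'
#' @param mean1,se1,n1,mean2,se2,n2 group summaries.
#' @return list `t`, `df`, `p`.
#' @export
two_group_summary_t <- function(mean1, se1, n1, mean2, se2, n2) {
  if (se1 <= 0 || se2 <= 0) stop_format("degenerate-input error: zero SE")
  if (n1 < 2 || n2 < 2) stop_format("need n >= 2 in each group")
  v1 <- se1^2; v2 <- se2^2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Write a CFU series as CSV
#'
#' @param series a `cfu_series`.
#' @param path output path.
#' @export
write_cfu_series <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("line_id", "fly_id", "time_h", "cfu")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CFU series CSV (`line_id,fly_id,time_h,cfu`)
#'
#' @param path input path.
#' @return a `cfu_series` data frame.
#' @export
read_cfu_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "fly_id", "time_h", "cfu")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_format("CFU format error: missing column(s) %s",
                paste(miss, collapse = ", "))
  if (any(df$cfu < 0)) stop_format("CFU validation error: negative counts")
  structure(df[, need], class = c("cfu_series", "data.frame"))
}
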