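## Replicate- and line-level survival phenotypes. LT50 follows the
## product-limit convention: the first event time at which the estimated
## survival fraction drops to one half or below, with no interpolation
## (the 12-h scoring grid would make interpolated precision illusory).

#' Kaplan-Meier survival curve for one group of flies
#'
#' Product-limit estimate with Greenwood standard errors; tied deaths are
#' handled as simultaneous events at the shared time.
#'
#' @param events an `event_table` (or any data frame with `time_h` and
#'   `status`) holding one group.
#' @return a `survival_curve` data frame: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `se` (Greenwood SE of S(t)).
#' @export
kaplan_meier <- function(events) {
  if (nrow(events) == 0) stop_format("empty-input error: no records in group")
  fit <- survival::survfit(
    survival::Surv(events$time_h, events$status == "dead") ~ 1,
    conf.type = "none")
  s <- summary(fit, censored = TRUE)
  curve <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                      n_censor = s$n.censor, surv = s$surv,
                      se = ifelse(is.na(s$std.err), 0, s$std.err))
  structure(curve, class = c("survival_curve", "data.frame"))
}

#' Median survival time (LT50) from a survival curve
#'
#' The smallest event time at which S(t) <= 0.5. Under heavy censoring the
#' curve may never reach one half; the median is then undefined and `NA`
#' is returned with attribute `defined = FALSE` (a flagged outcome, not an
#' error).
#'
#' @param curve a `survival_curve`.
#' @return numeric LT50 in hours (or `NA`), with attribute `defined`.
#' @export
median_survival <- function(curve) {
  if (nrow(curve) == 0) stop_format("empty-input error: empty curve")
  hit <- curve$n_event > 0 & curve$surv <= 0.5 + 1e-12
  if (!any(hit)) return(structure(NA_real_, defined = FALSE))
  structure(curve$time[which(hit)[1]], defined = TRUE)
}

#' Per-replicate survival summaries
#'
#' One row per line x sex x replicate tube: fly counts, the tube's
#' Kaplan-Meier LT50, and the within-tube standard deviation of uncensored
#' death times with its natural log (the observation unit of the
#' variance-level heritability analysis).
#'
#' @param events an `event_table`.
#' @param treatment treatment arm to summarize (default `"pathogen"`).
#' @return data frame `line_id`, `sex`, `replicate_id`, `n`, `n_dead`,
#'   `lt50_h`, `sigma`, `ln_sigma`.
#' @export
replicate_summaries <- function(events, treatment = "pathogen") {
  ev <- events[events$treatment == treatment, , drop = FALSE]
  key <- interaction(ev$line_id, ev$sex, ev$replicate_id, drop = TRUE)
  out <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    g <- ev[idx, , drop = FALSE]
    deaths <- g$time_h[g$status == "dead"]
    sig <- if (length(deaths) >= 2) stats::sd(deaths) else NA_real_
    data.frame(line_id = g$line_id[1], sex = g$sex[1],
               replicate_id = g$replicate_id[1],
               n = nrow(g), n_dead = length(deaths),
               lt50_h = as.numeric(median_survival(kaplan_meier(g))),
               sigma = sig,
               ln_sigma = ifelse(!is.na(sig) && sig > 0, log(sig), NA_real_),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$line_id, res$sex, res$replicate_id), , drop = FALSE]
}

#' Line-level survival phenotypes
#'
#' For every line x sex: the LT50 (arithmetic mean of replicate-tube LT50s
#' by default, or the pooled-curve median), the mean uncensored death time,
#' the within-line standard deviation sigma_E (root mean squared error of
#' an intercept-only fit to the uncensored death times, i.e. the ordinary
#' n-1 standard deviation), its natural log, and the coefficient of
#' environmental variation CV_E = sigma_E / mean (a fraction). Censored
#' flies contribute to the Kaplan-Meier curves only; their exclusion from
#' mean/sigma is counted. Control-treatment records are excluded by
#' default.
#'
#' @param events an `event_table`.
#' @param aggregation `"mean_of_replicates"` (default) or `"pooled"`.
#' @param treatment treatment arm to summarize.
#' @return a `line_summary` data frame: `line_id`, `sex`, `n`, `lt50_h`,
#'   `mean_h`, `sigma_e`, `ln_sigma_e`, `cv_e`, `n_censored`, `flags`
#'   (comma-joined reason codes, `""` when clean).
#' @export
line_summaries <- function(events,
                           aggregation = c("mean_of_replicates", "pooled"),
                           treatment = "pathogen") {
  aggregation <- match.arg(aggregation)
  ev <- events[events$treatment == treatment, , drop = FALSE]
  if (nrow(ev) == 0) stop_format("empty-input error: no %s records", treatment)
  key <- interaction(ev$line_id, ev$sex, drop = TRUE)
  out <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    g <- ev[idx, , drop = FALSE]
    deaths <- g$time_h[g$status == "dead"]
    flags <- character(0)
    if (aggregation == "mean_of_replicates") {
      reps <- split(seq_len(nrow(g)), g$replicate_id)
      rep_lt50 <- vapply(reps, function(ri)
        as.numeric(median_survival(kaplan_meier(g[ri, , drop = FALSE]))),
        numeric(1))
      if (anyNA(rep_lt50)) flags <- c(flags, "rep_lt50_undefined")
      lt50 <- if (all(is.na(rep_lt50))) NA_real_ else mean(rep_lt50, na.rm = TRUE)
    } else {
      lt50 <- as.numeric(median_survival(kaplan_meier(g)))
      if (is.na(lt50)) flags <- c(flags, "lt50_undefined")
    }
    mean_h <- if (length(deaths)) mean(deaths) else NA_real_
    if (length(deaths) < 2) {
      sigma <- NA_real_; flags <- c(flags, "lt2_deaths")
    } else sigma <- stats::sd(deaths)
    ln_sigma <- NA_real_
    if (!is.na(sigma)) {
      if (sigma == 0) flags <- c(flags, "sigma_zero") else ln_sigma <- log(sigma)
    }
    data.frame(line_id = g$line_id[1], sex = g$sex[1], n = nrow(g),
               lt50_h = lt50, mean_h = mean_h, sigma_e = sigma,
               ln_sigma_e = ln_sigma,
               cv_e = ifelse(is.na(sigma) || is.na(mean_h), NA_real_, sigma / mean_h),
               n_censored = sum(g$status == "censored"),
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$line_id, res$sex), , drop = FALSE]
  structure(res, class = c("line_summary", "data.frame"))
}

#' Write a line-summary table as TSV
#'
#' @param summaries a `line_summary`.
#' @param path output path.
#' @export
write_line_summaries <- function(summaries, path) {
  write_result_table(as.data.frame(summaries), path, sep = "\t")
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square with hypergeometric expectations at
#' each distinct death time; used to compare mutant lines against their
#' co-isogenic controls.
#'
#' @param events_a,events_b `event_table`s (or data frames with `time_h`,
#'   `status`) for the two groups.
#' @return list `statistic`, `p`, `defined` (`FALSE`, with `NA`s, when
#'   neither group has any deaths).
#' @export
log_rank <- function(events_a, events_b) {
  if (nrow(events_a) == 0 || nrow(events_b) == 0)
    stop_format("empty-input error: both groups must be non-empty")
  df <- rbind(data.frame(time_h = events_a$time_h, status = events_a$status,
                         grp = "A", stringsAsFactors = FALSE),
              data.frame(time_h = events_b$time_h, status = events_b$status,
                         grp = "B", stringsAsFactors = FALSE))
  if (all(df$status != "dead"))
    return(list(statistic = NA_real_, p = NA_real_, defined = FALSE))
  sd <- survival::survdiff(survival::Surv(time_h, status == "dead") ~ grp,
                           data = df)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       defined = TRUE)
}
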