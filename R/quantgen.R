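## Variance partitioning and broad-sense heritability. The pooled model is
## Y = mu + S + L + SxL + e with sex fixed and line / sex-by-line random;
## line and sex are tested over the sex-by-line mean square, sex-by-line
## over error. Components come from method-of-moments equating of observed
## to expected mean squares; unbalanced designs use the harmonic mean of
## cell counts in the EMS coefficients (unweighted-means approximation).
## Negative component estimates are truncated at zero and flagged so
## heritabilities stay in [0, 1].

new_variance_components <- function(model, table, components, n_h,
                                    truncated = character(0), extra = list()) {
  structure(c(list(model = model, table = table, components = components,
                   n_h = n_h, truncated = truncated), extra),
            class = "variance_components")
}

#' Assemble variance components from known values
#'
#' Convenience constructor for worked examples where the components are
#' given directly (e.g. from a published ANOVA table) rather than
#' estimated from raw data.
#'
#' @param line,error,sex_line variance components (sex_line only for the
#'   pooled model).
#' @param model `"single_sex"` or `"pooled_sex"`.
#' @return a `variance_components` object.
#' @export
variance_components <- function(line, error, sex_line = NULL,
                                model = c("single_sex", "pooled_sex")) {
  model <- match.arg(model)
  comp <- c(line = line,
            sex_line = if (model == "pooled_sex") sex_line %||% 0 else NA_real_,
            error = error)
  if (any(comp[!is.na(comp)] < 0))
    stop_format("variance components must be non-negative")
  new_variance_components(model, table = NULL, components = comp, n_h = NA_real_)
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components (%s model)\n", x$model))
  if (!is.null(x$table)) print(x$table, row.names = FALSE, digits = 4)
  cat("components:",
      paste(sprintf("%s = %.4g", names(x$components), x$components),
            collapse = ", "), "\n")
  if (length(x$truncated))
    cat("negative estimates truncated to 0:", paste(x$truncated, collapse = ", "), "\n")
  invisible(x)
}

one_way_anova <- function(value, group) {
  group <- factor(group)
  n_i <- tabulate(group)
  k <- nlevels(group)
  m_i <- tapply(value, group, mean)
  gm <- mean(value)
  ss_b <- sum(n_i * (m_i - gm)^2)
  ss_w <- sum((value - m_i[group])^2)
  df_b <- k - 1; df_w <- length(value) - k
  ms_b <- ss_b / df_b; ms_w <- ss_w / df_w
  list(k = k, n_i = n_i, ms_between = ms_b, ms_within = ms_w,
       df_between = df_b, df_within = df_w,
       f = ms_b / ms_w,
       p = stats::pf(ms_b / ms_w, df_b, df_w, lower.tail = FALSE))
}

#' Mixed-model ANOVA of per-fly death times
#'
#' Pooled-sex model: Y = mu + S + L + SxL + e (sex fixed; line and
#' sex-by-line random; Type III sums of squares; F for line and sex over
#' the sex-by-line mean square, sex-by-line over error). Single-sex model
#' reduces to the one-way Y = mu + L + e. Uncensored pathogen deaths only.
#'
#' @param data either an `event_table` (uncensored pathogen deaths are
#'   used) or a data frame with columns `value`, `line_id` and (for the
#'   pooled model) `sex`.
#' @param model `"pooled_sex"` or `"single_sex"`.
#' @return a `variance_components` with the ANOVA table (Source, df, MS,
#'   F, P), component estimates, heritability inputs and truncation flags.
#' @export
anova_mixed <- function(data, model = c("pooled_sex", "single_sex")) {
  model <- match.arg(model)
  df <- as_phenotype_frame(data)
  if (stats::var(df$value) == 0)
    stop_format("zero-variance error: all responses identical")

  if (model == "single_sex") {
    cnt <- table(df$line_id)
    single <- names(cnt)[cnt < 2]
    if (length(single) > 0) {
      warning(sprintf("dropping %d line(s) with a single observation", length(single)))
      df <- df[!df$line_id %in% single, , drop = FALSE]
    }
    if (length(unique(df$line_id)) < 2)
      stop_format("need >= 2 lines with >= 2 observations")
    a <- one_way_anova(df$value, df$line_id)
    n_h <- harmonic_mean(a$n_i)
    sigma_e <- a$ms_within
    sigma_l_raw <- (a$ms_between - a$ms_within) / n_h
    truncated <- if (sigma_l_raw < 0) "line" else character(0)
    comp <- c(line = max(sigma_l_raw, 0), sex_line = NA_real_, error = sigma_e)
    tab <- data.frame(
      Source = c("Line", "Error"),
      df = c(a$df_between, a$df_within),
      MS = c(a$ms_between, a$ms_within),
      F = c(a$f, NA), P = c(a$p, NA))
    return(new_variance_components("single_sex", tab, comp, n_h, truncated))
  }

  if (is.null(df$sex)) stop_format("pooled_sex model needs a sex column")
  cell <- table(df$line_id, df$sex)
  complete <- rownames(cell)[apply(cell > 0, 1, all)]
  if (length(complete) < 2)
    stop_format("pooled_sex model needs both sexes for >= 2 lines")
  if (length(complete) < nrow(cell)) {
    warning(sprintf("dropping %d line(s) missing a sex",
                    nrow(cell) - length(complete)))
    df <- df[df$line_id %in% complete, , drop = FALSE]
  }
  df$line_id <- factor(df$line_id); df$sex <- factor(df$sex)
  fit <- stats::lm(value ~ sex * line_id, data = df,
                   contrasts = list(sex = "contr.sum", line_id = "contr.sum"))
  a3 <- car::Anova(fit, type = 3, singular.ok = TRUE)
  ss <- a3[c("sex", "line_id", "sex:line_id", "Residuals"), ]
  ms <- ss$`Sum Sq` / ss$Df
  names(ms) <- c("sex", "line", "sex_line", "error")
  dfree <- stats::setNames(ss$Df, names(ms))
  f_sex <- ms["sex"] / ms["sex_line"]
  f_line <- ms["line"] / ms["sex_line"]
  f_sl <- ms["sex_line"] / ms["error"]
  p_sex <- stats::pf(f_sex, dfree["sex"], dfree["sex_line"], lower.tail = FALSE)
  p_line <- stats::pf(f_line, dfree["line"], dfree["sex_line"], lower.tail = FALSE)
  p_sl <- stats::pf(f_sl, dfree["sex_line"], dfree["error"], lower.tail = FALSE)

  cell_n <- as.vector(table(df$line_id, df$sex))
  n_h <- harmonic_mean(cell_n)
  n_sex <- nlevels(df$sex)
  sigma_e <- ms[["error"]]
  sigma_sl_raw <- (ms[["sex_line"]] - sigma_e) / n_h
  sigma_l_raw <- (ms[["line"]] - ms[["sex_line"]]) / (n_sex * n_h)
  truncated <- c(if (sigma_l_raw < 0) "line", if (sigma_sl_raw < 0) "sex_line")
  comp <- c(line = max(sigma_l_raw, 0), sex_line = max(sigma_sl_raw, 0),
            error = sigma_e)
  tab <- data.frame(
    Source = c("Sex", "Line", "Sex*Line", "Error"),
    df = unname(dfree[c("sex", "line", "sex_line", "error")]),
    MS = unname(ms[c("sex", "line", "sex_line", "error")]),
    F = c(f_sex, f_line, f_sl, NA),
    P = c(p_sex, p_line, p_sl, NA))
  new_variance_components("pooled_sex", tab, comp, n_h, truncated %||% character(0))
}

as_phenotype_frame <- function(data) {
  if (inherits(data, "event_table")) {
    d <- data[data$treatment == "pathogen" & data$status == "dead", , drop = FALSE]
    return(data.frame(value = d$time_h, line_id = d$line_id, sex = d$sex,
                      stringsAsFactors = FALSE))
  }
  df <- as.data.frame(data)
  stopifnot("value" %in% names(df), "line_id" %in% names(df))
  df
}

#' Broad-sense heritability from variance components
#'
#' Pooled model: H^2 = (sigma_L^2 + sigma_SL^2) / (sigma_L^2 + sigma_SL^2 +
#' sigma_E^2). Single-sex model: H^2 = sigma_L^2 / (sigma_L^2 + sigma_E^2).
#'
#' @param vc a `variance_components` object (from [anova_mixed()],
#'   [variance_level_heritability()] or [variance_components()]).
#' @return heritability in `[0, 1]`, with attribute `components`; `NA`
#'   flagged `defined = FALSE` when every component is zero.
#' @export
broad_sense_heritability <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  comp <- vc$components
  gen <- if (vc$model == "pooled_sex") comp[["line"]] + comp[["sex_line"]]
         else comp[["line"]]
  tot <- gen + comp[["error"]]
  if (tot == 0) return(structure(NA_real_, defined = FALSE, components = comp))
  structure(gen / tot, defined = TRUE, components = comp)
}

#' Factorial ANOVA with line nested in infection status
#'
#' Fits Y = mu + S + I + SxI + L(I) + SxL(I) + e, where I is a line-level
#' infection status (e.g. Wolbachia), S is the fixed sex effect and line
#' is random and nested in I (each line carries one infection state).
#' The infection main effect is tested over the line-within-infection
#' mean square; sex and sex-by-infection over sex-by-line-within-infection;
#' the random terms over error.
#'
#' @param data data frame with columns `value`, `sex`, `line_id`,
#'   `infection` (two states, both represented).
#' @return list with the ANOVA `table` and `p_infection`, the P-value for
#'   the infection main effect.
#' @export
covariate_anova <- function(data) {
  df <- as.data.frame(data)
  stopifnot(all(c("value", "sex", "line_id", "infection") %in% names(df)))
  df$infection <- factor(df$infection)
  if (nlevels(df$infection) < 2)
    stop_format("design error: need both infection states represented")
  df$sex <- factor(df$sex); df$line_id <- factor(df$line_id)
  ## line_id is nested in infection, so sequential SS with infection fitted
  ## before line gives SS(I) and SS(L within I); interactions follow.
  fit <- stats::lm(value ~ sex * infection + line_id + sex:line_id, data = df)
  a <- stats::anova(fit)
  rn <- rownames(a)
  get <- function(term) {
    i <- match(term, rn)
    c(df = a$Df[i], ms = a$`Mean Sq`[i])
  }
  s <- get("sex"); i_ <- get("infection"); l <- get("line_id")
  si <- get("sex:infection"); sl <- get("sex:line_id"); e <- get("Residuals")
  ftest <- function(num, den)
    c(F = num[["ms"]] / den[["ms"]],
      P = stats::pf(num[["ms"]] / den[["ms"]], num[["df"]], den[["df"]],
                    lower.tail = FALSE))
  tab <- data.frame(
    Source = c("Sex", "Infection", "Sex*Infection", "Line(Infection)",
               "Sex*Line(Infection)", "Error"),
    df = c(s[["df"]], i_[["df"]], si[["df"]], l[["df"]], sl[["df"]], e[["df"]]),
    MS = c(s[["ms"]], i_[["ms"]], si[["ms"]], l[["ms"]], sl[["ms"]], e[["ms"]]),
    F = c(ftest(s, sl)[["F"]], ftest(i_, l)[["F"]], ftest(si, sl)[["F"]],
          ftest(l, e)[["F"]], ftest(sl, e)[["F"]], NA),
    P = c(ftest(s, sl)[["P"]], ftest(i_, l)[["P"]], ftest(si, sl)[["P"]],
          ftest(l, e)[["P"]], ftest(sl, e)[["P"]], NA))
  list(table = tab, p_infection = tab$P[tab$Source == "Infection"])
}

#' Levene's test for heterogeneity of within-line variance
#'
#' One-way ANOVA on absolute deviations from the group center; classic
#' Levene uses the group mean (default), the Brown-Forsythe variant the
#' median. Groups with fewer than two observations are dropped with a
#' warning.
#'
#' @param value numeric observations.
#' @param group grouping factor (line).
#' @param center `"mean"` or `"median"`.
#' @return list `statistic` (F), `df`, `p`, `n_groups`.
#' @export
levene_test <- function(value, group, center = c("mean", "median")) {
  center <- match.arg(center)
  group <- factor(group)
  cnt <- table(group)
  if (any(cnt < 2)) {
    warning(sprintf("dropping %d group(s) with < 2 observations", sum(cnt < 2)))
    keep <- group %in% names(cnt)[cnt >= 2]
    value <- value[keep]; group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2)
    stop_format("need >= 2 groups with >= 2 observations")
  res <- car::leveneTest(value, group,
                         center = if (center == "mean") mean else stats::median)
  list(statistic = res$`F value`[1], df = c(res$Df[1], res$Df[2]),
       p = res$`Pr(>F)`[1], n_groups = nlevels(group))
}

#' Variance-level broad-sense heritability of micro-environmental plasticity
#'
#' Treats each replicate tube's ln(sigma_E) as one observation and fits the
#' one-way random-effects model Y = mu + L + e; H^2 = sigma_L^2 /
#' (sigma_L^2 + sigma_E^2). Lines contributing fewer than two usable
#' replicates are dropped with a warning.
#'
#' @param rep_summaries output of [replicate_summaries()] (or any data
#'   frame with `line_id` and `ln_sigma`); pass one sex at a time.
#' @return list `h2` and the underlying `vc` (`variance_components`).
#' @export
variance_level_heritability <- function(rep_summaries) {
  df <- as.data.frame(rep_summaries)
  stopifnot(all(c("line_id", "ln_sigma") %in% names(df)))
  df <- df[!is.na(df$ln_sigma), , drop = FALSE]
  cnt <- table(df$line_id)
  drop <- names(cnt)[cnt < 2]
  if (length(drop) > 0) {
    warning(sprintf("dropping %d line(s) with a single usable replicate",
                    length(drop)))
    df <- df[!df$line_id %in% drop, , drop = FALSE]
  }
  vc <- anova_mixed(data.frame(value = df$ln_sigma, line_id = df$line_id),
                    model = "single_sex")
  list(h2 = as.numeric(broad_sense_heritability(vc)), vc = vc)
}

#' Cross-sex genetic correlation of line means
#'
#' Pearson correlation between male and female line values (LT50 by
#' default); lines missing a sex are excluded with a count.
#'
#' @param summaries a `line_summary`.
#' @param value_col column to correlate (`"lt50_h"` or `"mean_h"`).
#' @return list `r`, `p`, `n`, `n_dropped`.
#' @export
cross_sex_correlation <- function(summaries, value_col = "lt50_h") {
  df <- as.data.frame(summaries)
  m <- df[df$sex == "M", c("line_id", value_col)]
  f <- df[df$sex == "F", c("line_id", value_col)]
  merged <- merge(m, f, by = "line_id", suffixes = c("_m", "_f"))
  merged <- merged[stats::complete.cases(merged), , drop = FALSE]
  n_dropped <- length(union(m$line_id, f$line_id)) - nrow(merged)
  if (nrow(merged) < 3)
    stop_format("insufficient-data error: < 3 lines with both sexes")
  ct <- stats::cor.test(merged[[2]], merged[[3]], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(merged),
       n_dropped = n_dropped)
}

#' Serialize variance components as a JSON report
#'
#' Mirrors a published ANOVA layout (Source, df, MS, F, P, Variance) plus
#' a heritability block.
#'
#' @param vc a `variance_components`.
#' @param path output JSON path.
#' @export
write_varcomp_report <- function(vc, path) {
  rep <- list(model = vc$model, anova = vc$table,
              components = as.list(vc$components),
              truncated = vc$truncated,
              h2 = as.numeric(broad_sense_heritability(vc)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
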