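## Cross-trait correlation analysis on line means with family-wise error
## control. Pairwise-complete deletion per trait pair (public panel traits
## cover different line subsets); Pearson by default to match line-mean
## correlation conventions, Spearman selectable.

#' Holm-Bonferroni step-down rejection flags
#'
#' Sort ascending; reject p_(i) while p_(i) <= alpha / (m - i + 1); stop at
#' the first failure; map flags back to the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error rate.
#' @return logical vector of rejection flags, input order.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m == 0) return(logical(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_format("p-values must lie in [0, 1]")
  ord <- order(p_values)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[ord[i]] <= alpha / (m - i + 1)) reject_sorted[i] <- TRUE
    else break
  }
  reject <- logical(m)
  reject[ord] <- reject_sorted
  reject
}

#' Pairwise trait correlations with Holm-Bonferroni control
#'
#' Pearson (or Spearman) correlation for every trait pair of a lines x
#' traits table, pairwise-complete per pair, with the step-down procedure
#' applied across the full declared family of pairs. Traits with fewer
#' than 3 non-missing lines are excluded with a warning.
#'
#' @param trait_table data frame of line traits; either a `line_id` column
#'   plus numeric trait columns, or numeric columns with line rownames.
#' @param family_alpha family-wise error rate for the Holm flags.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a `correlation_results` data frame: `trait_a`, `trait_b`, `r`,
#'   `p`, `n`, `holm_pass`.
#' @export
trait_matrix <- function(trait_table, family_alpha = 0.05,
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- as.data.frame(trait_table)
  if ("line_id" %in% names(df)) {
    rownames(df) <- df$line_id
    df$line_id <- NULL
  }
  usable <- vapply(df, function(col) sum(!is.na(col)) >= 3, logical(1))
  if (any(!usable)) {
    warning(sprintf("excluding trait(s) with < 3 lines: %s",
                    paste(names(df)[!usable], collapse = ", ")))
    df <- df[, usable, drop = FALSE]
  }
  traits <- names(df)
  if (length(traits) < 2) stop_format("need >= 2 usable traits")
  pairs <- utils::combn(traits, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- df[[pairs[1, k]]]; b <- df[[pairs[2, k]]]
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3)
      return(data.frame(trait_a = pairs[1, k], trait_b = pairs[2, k],
                        r = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- stats::cor.test(a[ok], b[ok], method = method, exact = FALSE)
    data.frame(trait_a = pairs[1, k], trait_b = pairs[2, k],
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  res <- do.call(rbind, out)
  res$holm_pass <- FALSE
  ok <- !is.na(res$p)
  res$holm_pass[ok] <- holm_bonferroni(res$p[ok], family_alpha)
  rownames(res) <- NULL
  structure(res, class = c("correlation_results", "data.frame"),
            family_alpha = family_alpha, method = method)
}

#' Write correlation results as TSV
#'
#' @param results a `correlation_results`.
#' @param path output path.
#' @export
write_correlation_results <- function(results, path) {
  write_result_table(as.data.frame(results), path, sep = "\t")
}
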