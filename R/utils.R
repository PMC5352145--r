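#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical marker identifiers
#'
#' Builds `chrom:pos:ref:alt` identifiers, the key used to join association
#' records, classifications, and panels.
#'
#' @param markers data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return character vector of identifiers.
#' @export
marker_ids <- function(markers) {
  paste(markers$chrom, markers$pos, markers$ref, markers$alt, sep = ":")
}

## Fixed-format numeric printing for result tables: 6 significant digits,
## "." decimal separator, no locale dependence -- keeps outputs diffable.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(signif(v, 6), scientific = FALSE, trim = TRUE, decimal.mark = ".")
  }, character(1))
  out
}

write_result_table <- function(df, path, sep = ",") {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

harmonic_mean <- function(x) length(x) / sum(1 / x)
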