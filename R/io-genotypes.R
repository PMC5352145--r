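## Homozygous genotype panels. Inbred panel lines (DGRP-style, 20 generations
## of sib-mating) are modeled as fully homozygous, so dosages are 0 (ref/ref)
## or 2 (alt/alt); residual heterozygous calls become missing and are counted.

#' Construct a genotype panel
#'
#' @param markers data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, optionally `class_hint`.
#' @param dosage integer matrix, markers x lines, values in `{0, 2, NA}`
#'   (dosage of the alt allele); column names are line ids.
#' @return a `genotype_panel`: list with `markers`, `dosage`, `line_ids`,
#'   and derived per-marker `maf`, `minor_allele` (`"ref"`/`"alt"`, ties
#'   broken toward alt), `minor_lines` (lines homozygous for the minor
#'   allele) and `n_called`.
#' @export
genotype_panel <- function(markers, dosage) {
  stopifnot(is.matrix(dosage), nrow(markers) == nrow(dosage))
  ok <- dosage %in% c(0, 2) | is.na(dosage)
  if (!all(ok))
    stop_format("dosage validation error: values outside {0, 2, NA}")
  if (is.null(colnames(dosage)))
    stop_format("dosage matrix must carry line ids as column names")
  n_called <- rowSums(!is.na(dosage))
  alt_freq <- rowMeans(dosage == 2, na.rm = TRUE)
  minor_allele <- ifelse(alt_freq <= 0.5, "alt", "ref")
  maf <- pmin(alt_freq, 1 - alt_freq)
  minor_lines <- ifelse(minor_allele == "alt",
                        rowSums(dosage == 2, na.rm = TRUE),
                        rowSums(dosage == 0, na.rm = TRUE))
  structure(list(markers = as.data.frame(markers), dosage = dosage,
                 line_ids = colnames(dosage), maf = as.numeric(maf),
                 minor_allele = minor_allele,
                 minor_lines = as.integer(minor_lines),
                 n_called = as.integer(n_called)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d markers x %d lines; median MAF %.3f\n",
              nrow(x$markers), length(x$line_ids), stats::median(x$maf)))
  invisible(x)
}

#' Dosage matrix oriented to the minor allele
#'
#' @param panel a `genotype_panel`.
#' @return matrix of minor-allele dosages in `{0, 2, NA}`.
#' @export
minor_dosage <- function(panel) {
  d <- panel$dosage
  flip <- panel$minor_allele == "ref"
  d[flip, ] <- 2 - d[flip, , drop = FALSE]
  d
}

#' Read a genotype panel from TSV or a VCF subset
#'
#' The TSV dialect is one marker per row with header
#' `chrom,pos,ref,alt,<line ids...>` and dosage tokens `{0, 2, NA}`.
#' The VCF route keeps biallelic records only (multi-allelic records are
#' skipped with a warning count), reads the GT field, maps homozygous calls
#' to 0/2 and heterozygous or half-missing calls to missing; the number of
#' heterozygous cells set missing is reported in the `n_het_dropped`
#' attribute.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return a `genotype_panel`.
#' @export
read_genotype_panel <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            na.strings = "NA")
    fixed <- c("chrom", "pos", "ref", "alt")
    if (!all(fixed %in% names(df)[1:4]))
      stop_format("genotype TSV format error: first columns must be %s",
                  paste(fixed, collapse = ","))
    line_cols <- setdiff(names(df), fixed)
    dos <- as.matrix(df[, line_cols, drop = FALSE])
    bad <- !(dos %in% c(0, 2) | is.na(dos))
    if (any(bad))
      stop_format("dosage token outside {0,2,NA} for marker row(s) %s",
                  paste(utils::head(which(rowSums(matrix(bad, nrow(dos))) > 0), 10),
                        collapse = ", "))
    storage.mode(dos) <- "integer"
    colnames(dos) <- line_cols
    panel <- genotype_panel(df[, fixed], dos)
    attr(panel, "n_het_dropped") <- 0L
    attr(panel, "n_multiallelic_skipped") <- 0L
    return(panel)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  n_skip <- sum(!bi)
  if (n_skip > 0) {
    warning(sprintf("skipped %d multi-allelic VCF record(s)", n_skip))
    vcf <- vcf[bi, ]
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% "0/0"] <- 0L
  dos[gt %in% "1/1"] <- 2L
  n_het <- sum(gt %in% c("0/1", "1/0"), na.rm = TRUE)
  markers <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  panel <- genotype_panel(markers, dos)
  attr(panel, "n_het_dropped") <- n_het
  attr(panel, "n_multiallelic_skipped") <- n_skip
  panel
}

#' Write a genotype panel as TSV
#'
#' @inheritParams minor_dosage
#' @param path output TSV path.
#' @export
write_genotype_panel <- function(panel, path) {
  df <- cbind(panel$markers[, c("chrom", "pos", "ref", "alt")],
              as.data.frame(panel$dosage, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read line covariates (symbiont infection and inversion genotypes)
#'
#' Expects header `line_id,wolbachia,In2Lt,In2RNS,In3RP,In3RK,In3RMo`:
#' infection status 0/1 and one column per major cosmopolitan inversion
#' (0 = standard, 1 = inverted arrangement for these homozygous lines).
#'
#' @param path CSV path.
#' @return a `covariate_table` data frame, one row per line.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  covariate_table(df)
}

INVERSION_NAMES <- c("In2Lt", "In2RNS", "In3RP", "In3RK", "In3RMo")

#' @rdname read_covariates
#' @param df data frame with the covariate columns.
#' @export
covariate_table <- function(df) {
  need <- c("line_id", "wolbachia", INVERSION_NAMES)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_format("covariate format error: missing column(s) %s",
                paste(miss, collapse = ", "))
  if (anyDuplicated(df$line_id))
    stop_format("covariate validation error: duplicated line_id")
  for (col in c("wolbachia", INVERSION_NAMES))
    if (!all(df[[col]] %in% c(0, 1, 2)))
      stop_format("covariate validation error: %s outside {0,1,2}", col)
  df$line_id <- as.character(df$line_id)
  structure(df[, need], class = c("covariate_table", "data.frame"))
}

#' @rdname read_covariates
#' @param covariates a `covariate_table`.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(as.data.frame(covariates), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
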