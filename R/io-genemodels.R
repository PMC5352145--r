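## Gene models for polymorphism site classification. Internally every
## interval is 0-based half-open; 1-based inclusive coordinates exist only
## at the GFF boundary, so there is a single conversion point.

FEATURE_TYPES <- c("exon_cds", "utr5", "utr3")

#' Construct a gene-model set
#'
#' @param genes data frame `gene_id`, `chrom`, `strand` (`+`/`-`/`.`),
#'   `start`, `end` (0-based half-open gene span).
#' @param features data frame `gene_id`, `type` (one of `exon_cds`, `utr5`,
#'   `utr3`), `start`, `end` (0-based half-open). Intronic positions are
#'   derived as gene-span positions covered by no sub-feature.
#' @param codon_context optional data frame `chrom`, `pos` (1-based genomic),
#'   `ref_codon` (coding-strand orientation), `codon_pos` (1-3) giving the
#'   reference codon context at coding positions; required for
#'   synonymous/non-synonymous calls.
#' @return a `gene_model_set`.
#' @export
gene_model_set <- function(genes, features, codon_context = NULL) {
  genes <- as.data.frame(genes)
  features <- as.data.frame(features)
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)),
            all(c("gene_id", "type", "start", "end") %in% names(features)))
  if (!all(genes$strand %in% c("+", "-", ".")))
    stop_format("gene model validation error: strand must be +, - or .")
  if (any(genes$start >= genes$end) || any(features$start >= features$end))
    stop_format("gene model validation error: intervals need start < end")
  if (!all(features$type %in% FEATURE_TYPES))
    stop_format("gene model validation error: unknown feature type(s) %s",
                paste(setdiff(features$type, FEATURE_TYPES), collapse = ", "))
  span <- genes[match(features$gene_id, genes$gene_id), ]
  out <- is.na(span$gene_id) | features$start < span$start | features$end > span$end
  if (any(out))
    stop_format("sub-feature outside gene span for gene(s): %s",
                paste(unique(features$gene_id[out]), collapse = ", "))
  if (!is.null(codon_context)) {
    codon_context <- as.data.frame(codon_context)
    stopifnot(all(c("chrom", "pos", "ref_codon", "codon_pos") %in% names(codon_context)))
    if (!all(codon_context$codon_pos %in% 1:3))
      stop_format("codon_pos must be 1, 2 or 3")
  }
  structure(list(genes = genes, features = features,
                 codon_context = codon_context),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("gene_model_set: %d genes, %d sub-features, codon context for %d sites\n",
              nrow(x$genes), nrow(x$features),
              if (is.null(x$codon_context)) 0L else nrow(x$codon_context)))
  invisible(x)
}

#' Read gene models from a BED-like TSV or a GFF3 subset
#'
#' The BED-like dialect is a TSV with header
#' `chrom,start,end,gene_id,strand,type` using 0-based half-open intervals;
#' rows with `type == "gene"` define the gene spans and the remaining rows
#' (`exon_cds`, `utr5`, `utr3`) the sub-features. The GFF3 route accepts
#' feature types `gene`, `CDS`, `five_prime_UTR` and `three_prime_UTR`
#' (1-based inclusive, converted on read); bare `exon` rows carry no class
#' information here and are ignored.
#'
#' @param path input file.
#' @param format `"bed_like"` or `"gff_subset"`.
#' @param codon_context optional codon-context table or TSV path
#'   (see [gene_model_set()]).
#' @return a `gene_model_set`.
#' @export
read_gene_models <- function(path, format = c("bed_like", "gff_subset"),
                             codon_context = NULL) {
  format <- match.arg(format)
  if (is.character(codon_context))
    codon_context <- utils::read.table(codon_context, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
  if (format == "bed_like") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    genes <- df[df$type == "gene",
                c("gene_id", "chrom", "strand", "start", "end")]
    features <- df[df$type != "gene", c("gene_id", "type", "start", "end")]
    rownames(genes) <- rownames(features) <- NULL
    return(gene_model_set(genes, features, codon_context))
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  ## GFF is 1-based inclusive: [start, end] -> 0-based half-open [start-1, end)
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  id_col <- if (!is.null(df$ID)) "ID" else "Name"
  gid <- function(d) {
    ids <- if (!is.null(d$Parent) && any(lengths(d$Parent) > 0))
      vapply(d$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
             character(1)) else rep(NA_character_, nrow(d))
    ifelse(is.na(ids) | ids == "", as.character(d[[id_col]]), ids)
  }
  genes_df <- df[df$type == "gene", , drop = FALSE]
  genes <- data.frame(gene_id = as.character(genes_df[[id_col]]),
                      chrom = as.character(genes_df$seqnames),
                      strand = ifelse(as.character(genes_df$strand) == "*", ".",
                                      as.character(genes_df$strand)),
                      start = genes_df$start0, end = genes_df$end0,
                      stringsAsFactors = FALSE)
  type_map <- c(CDS = "exon_cds", five_prime_UTR = "utr5",
                three_prime_UTR = "utr3")
  feat_df <- df[df$type %in% names(type_map), , drop = FALSE]
  features <- data.frame(gene_id = gid(feat_df),
                         type = unname(type_map[as.character(feat_df$type)]),
                         start = feat_df$start0, end = feat_df$end0,
                         stringsAsFactors = FALSE)
  gene_model_set(genes, features, codon_context)
}

#' Write gene models in the BED-like TSV dialect
#'
#' @param gm a `gene_model_set`.
#' @param path output path.
#' @export
write_gene_models <- function(gm, path) {
  g <- data.frame(chrom = gm$genes$chrom, start = gm$genes$start,
                  end = gm$genes$end, gene_id = gm$genes$gene_id,
                  strand = gm$genes$strand, type = "gene")
  f <- data.frame(chrom = gm$genes$chrom[match(gm$features$gene_id, gm$genes$gene_id)],
                  start = gm$features$start, end = gm$features$end,
                  gene_id = gm$features$gene_id,
                  strand = gm$genes$strand[match(gm$features$gene_id, gm$genes$gene_id)],
                  type = gm$features$type)
  utils::write.table(rbind(g, f), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
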