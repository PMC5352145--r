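## Site classification under the gene-proximity rule: a polymorphism is
## genic if it lies in a gene model or within 1 kb (inclusive of the
## 1000th base) upstream or downstream of one. When several features or
## overlapping genes apply, a fixed precedence resolves the single class
## while every gene hit is reported.

SITE_CLASSES <- c("non_synonymous", "synonymous", "exon_other", "utr5", "utr3",
                  "intron", "downstream_1kb", "upstream_1kb", "intergenic")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

substitute_codon <- function(codon, codon_pos, base) {
  s <- strsplit(toupper(codon), "")[[1]]
  s[codon_pos] <- toupper(base)
  paste(s, collapse = "")
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

classify_one <- function(chrom, pos, ref, alt, gm, flank = 1000L) {
  pos0 <- pos - 1L                 # 0-based point
  g <- gm$genes[gm$genes$chrom == chrom, , drop = FALSE]
  near <- g[pos0 >= g$start - flank & pos0 < g$end + flank, , drop = FALSE]
  if (nrow(near) == 0)
    return(list(class = "intergenic", gene_ids = character(0)))
  classes <- character(nrow(near))
  for (i in seq_len(nrow(near))) {
    gene <- near[i, ]
    if (pos0 >= gene$start && pos0 < gene$end) {
      feats <- gm$features[gm$features$gene_id == gene$gene_id &
                             gm$features$start <= pos0 &
                             gm$features$end > pos0, , drop = FALSE]
      if (nrow(feats) == 0) {
        classes[i] <- "intron"
      } else if ("exon_cds" %in% feats$type) {
        classes[i] <- classify_coding(chrom, pos, ref, alt, gene, gm)
      } else {
        classes[i] <- if ("utr5" %in% feats$type) "utr5" else "utr3"
      }
    } else {
      left <- pos0 < gene$start
      up <- if (gene$strand == "-") !left else left
      classes[i] <- if (up) "upstream_1kb" else "downstream_1kb"
    }
  }
  cls <- SITE_CLASSES[min(match(classes, SITE_CLASSES))]
  list(class = cls, gene_ids = near$gene_id)
}

classify_coding <- function(chrom, pos, ref, alt, gene, gm) {
  cc <- gm$codon_context
  if (!is.null(cc)) {
    hit <- which(cc$chrom == chrom & cc$pos == pos)
    if (length(hit) == 1 && nchar(ref) == 1 && nchar(alt) == 1) {
      alt_base <- if (gene$strand == "-") COMPLEMENT[[toupper(alt)]] else alt
      aa_ref <- translate_codon(cc$ref_codon[hit])
      aa_alt <- translate_codon(substitute_codon(cc$ref_codon[hit],
                                                 cc$codon_pos[hit], alt_base))
      if (!is.na(aa_ref) && !is.na(aa_alt))
        return(if (aa_ref == aa_alt) "synonymous" else "non_synonymous")
    }
  }
  warning(sprintf("coding site %s:%d lacks codon context; classified exon_other",
                  chrom, pos))
  "exon_other"
}

#' Classify polymorphisms into gene-model site classes
#'
#' Precedence for multi-feature hits: coding (non-synonymous >
#' synonymous) > UTR > intron > downstream/upstream within 1 kb >
#' intergenic. Coding synonymy requires codon context on the gene models;
#' without it a coding site becomes `exon_other` with a warning, never a
#' guessed call. Overlapping genes are all reported. The genic flag is
#' true for every class except `intergenic` (the within-1-kb classes count
#' as genic).
#'
#' @param markers data frame `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param gene_models a `gene_model_set`.
#' @param flank gene-proximity window in bases (default 1000, inclusive).
#' @return data frame `chrom`, `pos`, `ref`, `alt`, `class`, `genic`,
#'   `gene_ids` (comma-joined).
#' @export
classify_sites <- function(markers, gene_models, flank = 1000L) {
  markers <- as.data.frame(markers)
  out <- vector("list", nrow(markers))
  for (i in seq_len(nrow(markers))) {
    cl <- classify_one(markers$chrom[i], markers$pos[i], markers$ref[i],
                       markers$alt[i], gene_models, flank)
    out[[i]] <- data.frame(chrom = markers$chrom[i], pos = markers$pos[i],
                           ref = markers$ref[i], alt = markers$alt[i],
                           class = cl$class, genic = cl$class != "intergenic",
                           gene_ids = paste(cl$gene_ids, collapse = ","),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname classify_sites
#' @param chrom,pos,ref,alt a single marker.
#' @export
classify_site <- function(chrom, pos, ref, alt, gene_models, flank = 1000L) {
  classify_sites(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                            stringsAsFactors = FALSE), gene_models, flank)
}

#' Two-cell goodness-of-fit chi-square for class enrichment
#'
#' Tests an observed count against an expected genome-composition
#' proportion with the 1-df chi-square sum((O - E)^2 / E) over the two
#' cells, no continuity correction.
#'
#' @param observed_in_class hits in the class of interest.
#' @param total total hits.
#' @param expected_proportion genome-wide proportion of the class
#'   (e.g. 0.482 genic).
#' @return list `chisq`, `df`, `p`, `expected`, `valid` (`FALSE` with a
#'   warning when an expected cell is below 1).
#' @export
enrichment_chisq <- function(observed_in_class, total, expected_proportion) {
  if (observed_in_class < 0 || observed_in_class > total)
    stop_format("need 0 <= observed <= total")
  if (expected_proportion <= 0 || expected_proportion >= 1)
    stop_format("expected_proportion must lie in (0, 1)")
  e1 <- total * expected_proportion
  e2 <- total - e1
  valid <- min(e1, e2) >= 1
  if (!valid) warning("expected cell below 1; chi-square approximation fragile")
  chisq <- (observed_in_class - e1)^2 / e1 + ((total - observed_in_class) - e2)^2 / e2
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       expected = e1, valid = valid)
}

## Genome-composition defaults (fly genome): fractions of the genome that
## are genic / exonic / intronic / intergenic. Inputs, not code: override
## per genome build as needed.
#' @export
GENOME_COMPOSITION <- c(genic = 0.482, exonic = 0.183, intronic = 0.30,
                        intergenic = 0.518)

#' Inventory of site classes among associated polymorphisms
#'
#' Counts per class plus the "functional" fraction (introns + UTRs +
#' non-synonymous over total) and the genic fraction.
#'
#' @param classes character vector of site classes (values of
#'   `SITE_CLASSES`) or the output of [classify_sites()].
#' @return list `counts` (named integer over all classes),
#'   `functional_fraction`, `genic_fraction`, `n`.
#' @export
class_inventory <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  if (length(classes) == 0) stop_format("empty-input error: no classifications")
  if (!all(classes %in% SITE_CLASSES))
    stop_format("unknown site class(es): %s",
                paste(setdiff(classes, SITE_CLASSES), collapse = ", "))
  counts <- table(factor(classes, levels = SITE_CLASSES))
  n <- length(classes)
  functional <- sum(counts[c("intron", "utr5", "utr3", "non_synonymous")])
  genic <- sum(counts[setdiff(SITE_CLASSES, "intergenic")])
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       functional_fraction = functional / n, genic_fraction = genic / n, n = n)
}

#' Write site classifications and an enrichment report
#'
#' @param classifications output of [classify_sites()].
#' @param path output TSV path.
#' @export
write_classifications <- function(classifications, path) {
  write_result_table(classifications, path, sep = "\t")
}

#' @rdname write_classifications
#' @param enrichment output of [enrichment_chisq()] (or a list of them).
#' @export
write_enrichment_report <- function(enrichment, path) {
  jsonlite::write_json(enrichment, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
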