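#' Functional classes and their severity order
#'
#' The fixed vocabulary of functional classes used in per-pool count tables,
#' ordered from most to least severe. The order drives the "most severe"
#' reduction of multi-annotated variants in [reduce_per_variant()].
#'
#' @return Character vector of class names, most severe first.
#' @export
functional_classes <- function() {
  c("Stop_gain", "Stop_lost", "Essential_splice_site",
    "Nonsynonymous_coding", "Synonymous_coding", "Splice_site",
    "3'_UTR", "5'_UTR", "miRNA", "Intronic", "Within_non_coding_gene",
    "Upstream_gene", "Downstream_gene", "Intergenic")
}

.so_to_class <- c(
  missense_variant = "Nonsynonymous_coding",
  synonymous_variant = "Synonymous_coding",
  stop_gained = "Stop_gain",
  stop_lost = "Stop_lost",
  splice_region_variant = "Splice_site",
  splice_donor_variant = "Essential_splice_site",
  splice_acceptor_variant = "Essential_splice_site",
  intron_variant = "Intronic",
  upstream_gene_variant = "Upstream_gene",
  downstream_gene_variant = "Downstream_gene",
  `3_prime_UTR_variant` = "3'_UTR",
  `5_prime_UTR_variant` = "5'_UTR",
  mature_miRNA_variant = "miRNA",
  non_coding_transcript_variant = "Within_non_coding_gene",
  non_coding_transcript_exon_variant = "Within_non_coding_gene",
  intergenic_variant = "Intergenic")

#' Map Sequence Ontology consequence terms to functional classes
#'
#' Deterministic mapping from annotator (VEP-style) consequence terms to the
#' class vocabulary of [functional_classes()]. Terms outside the mapping fall
#' into an `"unmapped"` bucket and are reported with a message rather than
#' silently dropped.
#'
#' @param term Character vector of consequence terms.
#' @return Character vector of functional classes (or `"unmapped"`).
#' @examples
#' classify_consequence("missense_variant")  # "Nonsynonymous_coding"
#' classify_consequence("stop_gained")       # "Stop_gain"
#' @export
classify_consequence <- function(term) {
  stopifnot(all(nzchar(term)))
  out <- unname(.so_to_class[term])
  if (anyNA(out)) {
    message(sum(is.na(out)), " consequence term(s) unmapped: ",
            paste(utils::head(unique(term[is.na(out)]), 5L), collapse = ", "))
    out[is.na(out)] <- "unmapped"
  }
  out
}

#' Read a consequence table
#'
#' Minimal projection of annotator tabular output: a headered TSV with
#' columns `chrom`, `pos`, `ref`, `alt`, `consequence`, `gene`, `transcript`
#' (one row per variant/transcript/term).
#'
#' @param path Path to the TSV.
#' @return Data frame of consequence rows.
#' @export
read_consequences <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("chrom", "pos", "ref", "alt", "consequence")
  stopifnot(all(need %in% names(df)))
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  if (!"transcript" %in% names(df)) df$transcript <- NA_character_
  df
}

#' Reduce multi-annotated variants to one class
#'
#' A variant locus may carry several transcript annotations. In the default
#' `"severe"` mode each variant keeps the single most severe class under the
#' fixed order of [functional_classes()] (ties collapse to one row, so the
#' result is independent of input row order). In `"all"` mode every
#' annotation row is kept and a variant can contribute to several classes.
#'
#' @param rows Data frame with at least `chrom`, `pos`, `ref`, `alt`, and
#'   `class` (from [classify_consequence()]).
#' @param mode `"severe"` (default) or `"all"`.
#' @return Data frame with one row per variant (`"severe"`) or one row per
#'   distinct variant-class pair (`"all"`).
#' @export
reduce_per_variant <- function(rows, mode = c("severe", "all")) {
  mode <- match.arg(mode)
  stopifnot("class" %in% names(rows))
  key <- .variant_key(rows$chrom, rows$pos, rows$ref, rows$alt)
  sev <- c(functional_classes(), "unmapped")
  rank <- match(rows$class, sev)
  if (mode == "severe") {
    ord <- order(key, rank)
    rows <- rows[ord, , drop = FALSE]
    keep <- !duplicated(key[ord])
    out <- rows[keep, , drop = FALSE]
  } else {
    keep <- !duplicated(paste(key, rows$class, sep = "|"))
    out <- rows[keep, , drop = FALSE]
    out <- out[order(.variant_key(out$chrom, out$pos, out$ref, out$alt),
                     match(out$class, sev)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Tabulate functional classes per pool
#'
#' Builds a count table in the layout of the classic per-breed annotation
#' summaries: one row per functional class, one count and one within-pool
#' percentage column per pool, plus a `Total` column equal to the row-wise
#' sum of pool counts. Percentages are count / total variants of the given
#' type in that pool (so all classes including Intergenic sum to 100 within
#' rounding).
#'
#' @param classified Data frame from [reduce_per_variant()] (or any frame
#'   with `chrom`, `pos`, `ref`, `alt`, `class`).
#' @param present Logical matrix (variants of `classified` x pools) saying
#'   which pools carry each variant, e.g. built with [pool_presence()] and
#'   row-matched by variant key; or `NULL` for a single unnamed pool.
#' @param pool_totals Optional named vector of per-pool denominators for the
#'   percentages; defaults to the per-pool number of classified variants.
#' @return Data frame with columns `class`, `<pool>`, `<pool>_pct`, ...,
#'   `Total`.
#' @export
tabulate_classes <- function(classified, present = NULL, pool_totals = NULL) {
  cls <- c(functional_classes(), "unmapped")
  if (is.null(present)) {
    present <- matrix(TRUE, nrow(classified), 1L,
                      dimnames = list(NULL, "all"))
  }
  stopifnot(nrow(present) == nrow(classified))
  pools <- colnames(present)
  counts <- sapply(pools, function(p) {
    tab <- table(factor(classified$class[present[, p]], levels = cls))
    as.vector(tab)
  })
  counts <- matrix(counts, nrow = length(cls),
                   dimnames = list(cls, pools))
  if (is.null(pool_totals)) pool_totals <- colSums(counts)
  out <- data.frame(class = cls, stringsAsFactors = FALSE)
  for (p in pools) {
    out[[p]] <- counts[, p]
    out[[paste0(p, "_pct")]] <-
      round_half_up(100 * counts[, p] / pool_totals[[p]], 2L)
  }
  out$Total <- rowSums(counts)
  drop <- out$class == "unmapped" & out$Total == 0
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
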