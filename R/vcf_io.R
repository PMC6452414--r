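#' Multi-pool variant container
#'
#' In-memory representation of a joint-called pool-seq VCF. Site-level fields
#' (coordinates, alleles, QUAL and the six INFO metrics used by the hard
#' filters) live in a data frame; per-pool genotype (GT), allele depths (AD)
#' and genotype quality (GQ) live in aligned matrices with one column per
#' pool. Missing INFO metrics are `NA`, meaning "absent", never zero.
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt` (comma-separated alternates), `qual`, and the INFO metrics
#'   `QD`, `MQ`, `FS`, `HaplotypeScore`, `MQRankSum`, `ReadPosRankSum`.
#' @param gt Character matrix of VCF genotype strings (e.g. `"0/0/1"` at pool
#'   ploidy), `NA` for missing.
#' @param ad Character matrix of comma-separated allele depths (ref first).
#' @param gq Numeric matrix of genotype qualities.
#' @return An object of class `pool_vcf`.
#' @export
pool_vcf <- function(variants, gt, ad, gq) {
  info_cols <- c("QD", "MQ", "FS", "HaplotypeScore", "MQRankSum",
                 "ReadPosRankSum")
  need <- c("chrom", "pos", "id", "ref", "alt", "qual", info_cols)
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(variants)
  gt <- as.matrix(gt); ad <- as.matrix(ad); gq <- as.matrix(gq)
  stopifnot(nrow(gt) == n, nrow(ad) == n, nrow(gq) == n,
            ncol(gt) == ncol(ad), ncol(gt) == ncol(gq))
  if (is.null(colnames(gt))) colnames(gt) <- paste0("pool", seq_len(ncol(gt)))
  colnames(ad) <- colnames(gq) <- colnames(gt)
  if (n > 0) {
    if (any(variants$pos < 1)) stop("VCF positions are 1-based: pos >= 1")
    if (any(!nzchar(variants$ref))) stop("empty REF allele")
    # AD length must be 1 + number of alternate alleles wherever present
    n_alt <- lengths(strsplit(variants$alt, ",", fixed = TRUE))
    n_ad <- lengths(strsplit(ad, ",", fixed = TRUE))
    ok <- is.na(ad) | n_ad == rep(n_alt + 1L, ncol(ad))
    if (!all(ok)) {
      bad <- which(!ok, arr.ind = FALSE)[1L]
      stop("AD length != 1 + n_alts at record ", (bad - 1L) %% n + 1L)
    }
  }
  structure(list(variants = variants, gt = gt, ad = ad, gq = gq),
            class = "pool_vcf")
}

#' @export
print.pool_vcf <- function(x, ...) {
  cat(sprintf("pool_vcf: %d variants x %d pools (%s)\n",
              nrow(x$variants), ncol(x$gt),
              paste(colnames(x$gt), collapse = ", ")))
  invisible(x)
}

#' Number of variant records
#' @param x A [pool_vcf()].
#' @return Integer count of variant rows.
#' @export
n_variants <- function(x) nrow(x$variants)

#' Pool names
#' @param x A [pool_vcf()].
#' @return Character vector of pool (sample column) names.
#' @export
pool_names <- function(x) colnames(x$gt)

#' Subset variant records
#'
#' @param x A [pool_vcf()].
#' @param i Row index (logical or integer) over variant records.
#' @param ... Unused.
#' @return The subset `pool_vcf`.
#' @export
`[.pool_vcf` <- function(x, i, ...) {
  pool_vcf(x$variants[i, , drop = FALSE],
           x$gt[i, , drop = FALSE],
           x$ad[i, , drop = FALSE],
           x$gq[i, , drop = FALSE])
}

.info_metrics <- c("QD", "MQ", "FS", "HaplotypeScore", "MQRankSum",
                   "ReadPosRankSum")

#' Read a multi-pool VCF
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a [pool_vcf()]. QUAL and the
#' six INFO metrics consumed by [apply_hard_filters()] are pulled into
#' numeric columns; a metric absent from a record's INFO field stays `NA`.
#' GT, AD and GQ are kept per pool. When a `layout` is supplied, records on
#' contigs not in the layout are dropped with a warning (unplaced scaffolds
#' are outside the autosome-scan scope).
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param layout Optional [genome_layout()] restricting contigs.
#' @return A [pool_vcf()].
#' @export
read_pool_vcf <- function(path, layout = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n <- nrow(fix)
  info <- lapply(.info_metrics, function(m)
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = m))))
  names(info) <- .info_metrics
  if (n == 0L) {
    info <- lapply(.info_metrics, function(m) numeric(0))
    names(info) <- .info_metrics
  }
  variants <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.numeric(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", as.character(fix[, "ID"])),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE)
  variants <- cbind(variants, as.data.frame(info, optional = TRUE))
  grab <- function(el) {
    if (is.null(v@gt) || ncol(v@gt) < 2L) {
      return(matrix(NA_character_, n, 0L))
    }
    m <- vcfR::extract.gt(v, element = el)
    if (is.null(m)) {
      m <- matrix(NA_character_, n, ncol(v@gt) - 1L,
                  dimnames = list(NULL, colnames(v@gt)[-1L]))
    }
    # single-record files can come back as a named vector
    if (!is.matrix(m)) {
      m <- matrix(m, nrow = n, byrow = TRUE, dimnames = list(NULL, names(m)))
    }
    m
  }
  gt <- grab("GT")
  ad <- grab("AD")
  gq_chr <- grab("GQ")
  gq <- matrix(suppressWarnings(as.numeric(gq_chr)), nrow = n,
               dimnames = dimnames(gq_chr))
  rownames(gt) <- rownames(ad) <- rownames(gq) <- NULL
  out <- pool_vcf(variants, gt, ad, gq)
  if (!is.null(layout)) {
    keep <- out$variants$chrom %in% layout$chrom
    if (!all(keep)) {
      warning(sum(!keep), " record(s) on contigs absent from layout skipped")
      out <- out[keep]
    }
  }
  out
}

#' Write a multi-pool VCF
#'
#' Emits plain-text VCF 4.2 with the INFO metrics and the GT:AD:GQ FORMAT
#' fields this package consumes, so that `read_pool_vcf(write_pool_vcf(x))`
#' round-trips all supported fields exactly.
#'
#' @param x A [pool_vcf()].
#' @param path Output path.
#' @param layout Optional [genome_layout()] written as contig header lines.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(x, path, layout = NULL) {
  stopifnot(inherits(x, "pool_vcf"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolsweep",
    if (!is.null(layout))
      sprintf("##contig=<ID=%s,length=%d>", layout$chrom, layout$length),
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Variant confidence normalized by depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled strand bias">',
    '##INFO=<ID=HaplotypeScore,Number=1,Type=Float,Description="Haplotype consistency">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x$gt)), collapse = "\t"))
  va <- x$variants
  n <- nrow(va)
  fmt_num <- function(z) ifelse(is.na(z), NA_character_,
                                format(z, trim = TRUE, scientific = FALSE,
                                       digits = 15))
  info_parts <- vapply(seq_len(n), function(i) {
    vals <- vapply(.info_metrics, function(m) va[[m]][i], numeric(1))
    pres <- !is.na(vals)
    if (!any(pres)) return(".")
    paste(paste0(.info_metrics[pres], "=", fmt_num(vals[pres])),
          collapse = ";")
  }, character(1))
  gtcell <- matrix(paste(ifelse(is.na(x$gt), ".", x$gt),
                         ifelse(is.na(x$ad), ".", x$ad),
                         ifelse(is.na(x$gq), ".", fmt_num(x$gq)),
                         sep = ":"),
                   nrow = n)
  body <- paste(va$chrom, fmt_num(va$pos),
                ifelse(is.na(va$id) | va$id == "", ".", va$id),
                va$ref, va$alt,
                ifelse(is.na(va$qual), ".", fmt_num(va$qual)),
                ".", info_parts, "GT:AD:GQ",
                sep = "\t")
  if (ncol(gtcell) > 0 && n > 0) {
    body <- paste(body, apply(gtcell, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
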