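#' Hard-filter criteria
#'
#' Thresholds for GATK-style hard filtering of pooled variant calls. A record
#' fails when any *present* metric violates its threshold with a strict
#' inequality: QUAL < 30.0, QD < 2.0, MQ < 40.0, FS > 60.0,
#' HaplotypeScore > 13.0, MQRankSum < -12.5, ReadPosRankSum < -8.0. Values
#' exactly at a threshold pass. `gq_min` is the per-pool genotype-quality
#' mask applied by [mask_low_gq()] (GQ < 20 masks the pool; GQ = 20 is kept).
#'
#' @param qual_min,qd_min,mq_min Lower bounds (fail when metric < bound).
#' @param fs_max,haplotype_score_max Upper bounds (fail when metric > bound).
#' @param mq_rank_sum_min,read_pos_rank_sum_min Lower bounds on rank sums.
#' @param gq_min Minimum per-pool genotype quality (mask when GQ < `gq_min`).
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(qual_min = 30.0, qd_min = 2.0, mq_min = 40.0,
                            fs_max = 60.0, haplotype_score_max = 13.0,
                            mq_rank_sum_min = -12.5,
                            read_pos_rank_sum_min = -8.0, gq_min = 20) {
  cr <- list(qual_min = qual_min, qd_min = qd_min, mq_min = mq_min,
             fs_max = fs_max, haplotype_score_max = haplotype_score_max,
             mq_rank_sum_min = mq_rank_sum_min,
             read_pos_rank_sum_min = read_pos_rank_sum_min, gq_min = gq_min)
  if (!all(vapply(cr, is.finite, logical(1)))) {
    stop("all filter thresholds must be finite")
  }
  structure(cr, class = "filter_criteria")
}

#' Apply hard filters to variant records
#'
#' Evaluates each record against [filter_criteria()]. Inequalities are strict;
#' a metric absent from a record (`NA`) can never fail it, because the caller
#' (GATK) omits site-class-dependent annotations such as the rank sums at
#' sites without heterozygous support, and those sites are still valid. The
#' verdict lists *every* violated criterion, sorted and deduplicated.
#'
#' @param x A [pool_vcf()].
#' @param criteria A [filter_criteria()].
#' @return Data frame with logical `passed` and character `reasons`
#'   (comma-separated violated criterion names, `""` when passed).
#' @examples
#' # a record with QD = 1.5 fails with reasons = "QD"
#' @export
apply_hard_filters <- function(x, criteria = filter_criteria()) {
  stopifnot(inherits(x, "pool_vcf"))
  va <- x$variants
  viol <- cbind(
    QUAL = !is.na(va$qual) & va$qual < criteria$qual_min,
    QD = !is.na(va$QD) & va$QD < criteria$qd_min,
    MQ = !is.na(va$MQ) & va$MQ < criteria$mq_min,
    FS = !is.na(va$FS) & va$FS > criteria$fs_max,
    HaplotypeScore = !is.na(va$HaplotypeScore) &
      va$HaplotypeScore > criteria$haplotype_score_max,
    MQRankSum = !is.na(va$MQRankSum) &
      va$MQRankSum < criteria$mq_rank_sum_min,
    ReadPosRankSum = !is.na(va$ReadPosRankSum) &
      va$ReadPosRankSum < criteria$read_pos_rank_sum_min)
  nm <- sort(colnames(viol))
  viol <- viol[, nm, drop = FALSE]
  reasons <- apply(viol, 1L, function(r) paste(nm[r], collapse = ","))
  if (nrow(va) == 0L) reasons <- character(0)
  data.frame(passed = rowSums(viol) == 0L, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Mask pools with low genotype quality
#'
#' Sets GT, AD and GQ to missing in every pool whose GQ is below `gq_min`
#' (GQ exactly at the threshold is retained). Records in which every pool is
#' masked carry no per-pool information; set `drop_empty = TRUE` to remove
#' them from downstream per-pool analyses.
#'
#' @param x A [pool_vcf()].
#' @param criteria A [filter_criteria()].
#' @param drop_empty Drop records with all pools masked (default `FALSE`).
#' @return The masked [pool_vcf()].
#' @export
mask_low_gq <- function(x, criteria = filter_criteria(), drop_empty = FALSE) {
  stopifnot(inherits(x, "pool_vcf"))
  mask <- !is.na(x$gq) & x$gq < criteria$gq_min
  x$gt[mask] <- NA_character_
  x$ad[mask] <- NA_character_
  x$gq[mask] <- NA_real_
  if (drop_empty && ncol(x$gt) > 0) {
    keep <- rowSums(!is.na(x$gt)) > 0L
    x <- x[keep]
  }
  x
}

#' Classify variant records as SNP, indel or mixed
#'
#' A record is a SNP when REF and every ALT are single bases; an indel when
#' at least one allele changes length; and mixed when it carries both a
#' same-length substitution ALT and a length-changing ALT.
#'
#' @param x A [pool_vcf()] or a data frame with `ref` and `alt` columns.
#' @return Character vector in `{"SNP", "indel", "mixed"}`.
#' @export
classify_variant_type <- function(x) {
  va <- if (inherits(x, "pool_vcf")) x$variants else x
  alts <- strsplit(va$alt, ",", fixed = TRUE)
  ref_len <- nchar(va$ref)
  vapply(seq_along(alts), function(i) {
    al <- nchar(alts[[i]])
    subst <- al == ref_len[i] & ref_len[i] == 1L
    len_ch <- al != ref_len[i] | ref_len[i] > 1L
    if (all(subst)) "SNP" else if (all(len_ch)) "indel" else "mixed"
  }, character(1))
}

#' Classify pool zygosity
#'
#' Within one pool, a variant site is `fixed` when all ploidy alleles carry
#' the same non-reference allele, `segregating` when two or more distinct
#' alleles are present, and `reference` when every allele is the reference
#' (the site is not a variant in this pool; joint-called multi-pool VCFs
#' contain such pool-level non-variant rows).
#'
#' @param x A [pool_vcf()].
#' @param pool Pool name or column index.
#' @return Character vector in `{"fixed", "segregating", "reference"}`.
#'   A missing (masked) genotype is an error naming the record.
#' @export
classify_zygosity <- function(x, pool) {
  stopifnot(inherits(x, "pool_vcf"))
  gt <- x$gt[, pool]
  if (anyNA(gt)) {
    stop("missing (masked) genotype for pool ", pool, " at record ",
         which(is.na(gt))[1L])
  }
  u <- unique(gt)
  cls <- vapply(strsplit(u, "[/|]"), function(al) {
    al <- al[al != "."]
    if (length(al) == 0L) return(NA_character_)
    d <- unique(al)
    if (length(d) >= 2L) "segregating"
    else if (d == "0") "reference"
    else "fixed"
  }, character(1))
  out <- cls[match(gt, u)]
  if (anyNA(out)) {
    stop("empty genotype for pool ", pool, " at record ",
         which(is.na(out))[1L])
  }
  out
}

.purines <- c("A", "G")
.pyrimidines <- c("C", "T")

#' Transition/transversion ratio
#'
#' Counts transitions (A<->G, C<->T) and transversions (purine <->
#' pyrimidine) over SNP records and returns their ratio, the standard
#' sequencing-quality indicator (about 2.1-2.2 genome-wide in cattle).
#' Multiallelic SNPs contribute one ref->alt substitution per alternate
#' allele, so each substitution is counted exactly once.
#'
#' @param x A [pool_vcf()], or a data frame with `ref`/`alt` columns, already
#'   restricted to SNP records (see [classify_variant_type()]); non-SNP rows
#'   are ignored with a warning.
#' @return List with `ti`, `tv` and `ratio` (`NaN` with a warning when there
#'   are no transversions).
#' @export
titv_ratio <- function(x) {
  va <- if (inherits(x, "pool_vcf")) x$variants else x
  type <- classify_variant_type(va)
  if (any(type != "SNP")) {
    warning(sum(type != "SNP"), " non-SNP record(s) ignored in Ti/Tv")
    va <- va[type == "SNP", , drop = FALSE]
  }
  alts <- strsplit(va$alt, ",", fixed = TRUE)
  ref <- rep(va$ref, lengths(alts))
  alt <- unlist(alts, use.names = FALSE)
  if (length(ref) == 0L) return(list(ti = 0L, tv = 0L, ratio = NaN))
  is_ti <- (ref %in% .purines & alt %in% .purines) |
    (ref %in% .pyrimidines & alt %in% .pyrimidines)
  ti <- sum(is_ti)
  tv <- sum(!is_ti)
  if (tv == 0L) {
    warning("no transversions: Ti/Tv undefined")
    return(list(ti = ti, tv = 0L, ratio = NaN))
  }
  list(ti = ti, tv = tv, ratio = ti / tv)
}
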