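#' Normalise a variant to a canonical key
#'
#' Trims bases shared between REF and ALT — from the right first, then from
#' the left, adjusting the position for every base trimmed on the left — so
#' that equivalent representations of the same indel produce the same
#' (chrom, pos, ref, alt) key. At least one base is always retained on each
#' allele. SNPs are unchanged. Full left-alignment against a reference
#' sequence is intentionally out of scope; trimming needs no reference.
#'
#' @param chrom,pos,ref,alt Vectors describing variants (1-based `pos`).
#' @return Data frame with normalised `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalise_variant("chr1", 100, "CA", "CG")   # -> pos 101, A > G
#' normalise_variant("chr1", 100, "ATT", "AT")  # -> pos 101, TT > T
#' @export
normalise_variant <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("empty allele")
  if (any(ref == alt)) {
    stop("ref equals alt (not a variant) at record ",
         which(ref == alt)[1L])
  }
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "")[[1L]]
    a <- strsplit(alt[i], "")[[1L]]
    # left trim first, advancing pos; each allele keeps >= 1 base
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1
    }
    # then right trim
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

.variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Load a known-variant catalogue
#'
#' Accepts either a VCF or a headered 4+ column TSV (`chrom`, `pos`, `ref`,
#' `alt`). Entries are normalised with [normalise_variant()] (multiallelic
#' VCF rows are split per alternate allele) and deduplicated.
#'
#' @param path Path to the catalogue file.
#' @return A `known_catalogue`: character vector of unique normalised keys.
#' @export
read_catalogue <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF") || grepl("\\.vcf(\\.gz)?$", path)) {
    v <- read_pool_vcf(path)
    alts <- strsplit(v$variants$alt, ",", fixed = TRUE)
    df <- data.frame(chrom = rep(v$variants$chrom, lengths(alts)),
                     pos = rep(v$variants$pos, lengths(alts)),
                     ref = rep(v$variants$ref, lengths(alts)),
                     alt = unlist(alts, use.names = FALSE),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  }
  make_catalogue(df$chrom, df$pos, df$ref, df$alt)
}

#' Build a known-variant catalogue from vectors
#'
#' @param chrom,pos,ref,alt Variant fields (1-based `pos`).
#' @return A `known_catalogue`: character vector of unique normalised keys.
#' @export
make_catalogue <- function(chrom, pos, ref, alt) {
  nv <- normalise_variant(chrom, pos, ref, alt)
  structure(unique(.variant_key(nv$chrom, nv$pos, nv$ref, nv$alt)),
            class = "known_catalogue")
}

#' Flag variants as known or novel against a catalogue
#'
#' A record is *known* when its normalised key is present in the catalogue.
#' The default match is allele-exact (chrom + pos + ref + alt, the dbSNP
#' convention); `mode = "position"` matches on chrom + normalised pos only.
#' Multiallelic records are known iff any of their alternate alleles is known.
#'
#' @param x A [pool_vcf()] or data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param catalogue A `known_catalogue` from [make_catalogue()] or
#'   [read_catalogue()].
#' @param mode `"allele"` (default) or `"position"`.
#' @return Logical vector, `TRUE` = known, `FALSE` = novel.
#' @export
match_known <- function(x, catalogue, mode = c("allele", "position")) {
  mode <- match.arg(mode)
  va <- if (inherits(x, "pool_vcf")) x$variants else x
  if (nrow(va) == 0L) return(logical(0))
  alts <- strsplit(va$alt, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(va)), lengths(alts))
  nv <- normalise_variant(va$chrom[idx], va$pos[idx], va$ref[idx],
                          unlist(alts, use.names = FALSE))
  if (mode == "allele") {
    hit <- .variant_key(nv$chrom, nv$pos, nv$ref, nv$alt) %in%
      unclass(catalogue)
  } else {
    cat_pos <- unique(sub("^([^:]+:[^:]+):.*$", "\\1", unclass(catalogue)))
    hit <- paste(nv$chrom, nv$pos, sep = ":") %in% cat_pos
  }
  # idx is sorted, one group per record, so tapply returns record order
  as.vector(tapply(hit, idx, any))
}

#' Per-pool novelty summary
#'
#' Tabulates known and novel variant counts per pool. A variant contributes
#' to a pool when the pool carries a non-reference genotype for it (or for
#' every pool when per-pool genotypes are unavailable). The reported
#' proportion of novel variants is rounded half-up to 2 decimals; the
#' cross-pool average is the unweighted mean of the per-pool proportions.
#'
#' @param known Logical vector from [match_known()].
#' @param present Logical matrix (records x pools): does the pool carry the
#'   variant? Use [pool_presence()] to derive it from genotypes.
#' @return Data frame with one row per pool plus an `Average` row: columns
#'   `pool`, `known`, `novel`, `total`, `proportion_novel`.
#' @export
novelty_summary <- function(known, present) {
  stopifnot(is.logical(known), nrow(present) == length(known))
  pools <- colnames(present)
  rows <- lapply(seq_along(pools), function(j) {
    tot <- sum(present[, j])
    nov <- sum(present[, j] & !known)
    data.frame(pool = pools[j], known = tot - nov, novel = nov, total = tot,
               proportion_novel = if (tot == 0L) NA_real_
                                  else round_half_up(nov / tot, 2L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  avg <- mean(out$proportion_novel, na.rm = TRUE)
  rbind(out, data.frame(pool = "Average",
                        known = sum(out$known), novel = sum(out$novel),
                        total = sum(out$total),
                        proportion_novel = round_half_up(avg, 2L),
                        stringsAsFactors = FALSE))
}

#' Novelty summary from per-pool counts
#'
#' Builds the same report as [novelty_summary()] directly from per-pool known
#' and novel counts, for use when the counts come from an external summary
#' rather than from record-level flags.
#'
#' @param pool Pool names.
#' @param known,novel Per-pool counts.
#' @return Data frame as in [novelty_summary()], with an `Average` row.
#' @export
novelty_from_counts <- function(pool, known, novel) {
  stopifnot(length(pool) == length(known), length(pool) == length(novel))
  total <- known + novel
  prop <- ifelse(total == 0, NA_real_, round_half_up(novel / total, 2L))
  out <- data.frame(pool = pool, known = known, novel = novel, total = total,
                    proportion_novel = prop, stringsAsFactors = FALSE)
  rbind(out, data.frame(pool = "Average", known = sum(known),
                        novel = sum(novel), total = sum(total),
                        proportion_novel = round_half_up(
                          mean(prop, na.rm = TRUE), 2L),
                        stringsAsFactors = FALSE))
}

#' Which pools carry each variant
#'
#' @param x A [pool_vcf()].
#' @return Logical matrix (records x pools), `TRUE` when the pool genotype
#'   contains at least one non-reference allele. Masked genotypes are `FALSE`.
#' @export
pool_presence <- function(x) {
  stopifnot(inherits(x, "pool_vcf"))
  pres <- matrix(FALSE, nrow(x$gt), ncol(x$gt), dimnames = dimnames(x$gt))
  for (j in seq_len(ncol(x$gt))) {
    gt <- x$gt[, j]
    u <- unique(gt)
    has_alt <- vapply(strsplit(u, "[/|]"), function(al) {
      al <- al[al != "." & al != ""]
      any(al != "0")
    }, logical(1))
    has_alt[is.na(u)] <- FALSE
    pres[, j] <- has_alt[match(gt, u)]
  }
  pres
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported proportions follow the
#' conventional half-up rule instead (0.065 -> 0.07 at 2 decimals).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
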