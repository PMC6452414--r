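#' Per-pool major/minor read counts
#'
#' For each SNP and pool, extracts from the allele depths (AD) the read count
#' of the most abundant allele (`n_maj`) and of the least abundant allele
#' (`n_min`). Biallelic sites use the two depths directly; multiallelic sites
#' use the two largest depths. A tie in "most abundant" is harmless because
#' the pooled-heterozygosity formula is symmetric in the two counts. Sites
#' with zero total depth (or masked AD) get `NA` and are skipped by the scan.
#'
#' @param x A [pool_vcf()].
#' @param pool Pool name or column index.
#' @return Data frame with `n_maj` and `n_min`, one row per record.
#' @examples
#' # AD = "12,8"  -> n_maj = 12, n_min = 8
#' # AD = "10,6,4" -> n_maj = 10, n_min = 6  (two largest)
#' @export
pool_allele_counts <- function(x, pool) {
  stopifnot(inherits(x, "pool_vcf"))
  ad <- x$ad[, pool]
  n <- length(ad)
  n_maj <- n_min <- rep(NA_real_, n)
  parts <- strsplit(ad, ",", fixed = TRUE)
  len <- lengths(parts)
  vals <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
  off <- cumsum(c(1L, len))
  # biallelic fast path
  i2 <- which(len == 2L)
  if (length(i2)) {
    a <- vals[off[i2]]
    b <- vals[off[i2] + 1L]
    n_maj[i2] <- pmax(a, b)
    n_min[i2] <- pmin(a, b)
  }
  # multiallelic: the two largest depths
  im <- which(len > 2L)
  for (i in im) {
    d <- sort(vals[seq.int(off[i], length.out = len[i])], decreasing = TRUE)
    n_maj[i] <- d[1L]
    n_min[i] <- d[2L]
  }
  bad <- is.na(n_maj) | is.na(n_min) | (n_maj + n_min) == 0
  n_maj[bad] <- NA_real_
  n_min[bad] <- NA_real_
  data.frame(n_maj = n_maj, n_min = n_min)
}

#' Sliding windows over a genome
#'
#' Tiles each chromosome with windows of `size` bp starting every
#' `size * (1 - overlap)` bp (the default 150 kb windows with 50% overlap
#' step every 75 kb). Only full-length windows are produced: starts run
#' 0, step, 2*step, ... while `start + size <= L`, so every interior base is
#' covered by exactly `1/(1 - overlap)` windows and no truncated trailing
#' window is emitted. Chromosomes shorter than `size` contribute no windows.
#'
#' @param layout A [genome_layout()].
#' @param size Window size in bp (default 150000).
#' @param overlap Fractional overlap between consecutive windows in (0, 1)
#'   (default 0.5).
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
make_sliding_windows <- function(layout, size = 150000, overlap = 0.5) {
  stopifnot(inherits(layout, "genome_layout"),
            size >= 1, overlap > 0, overlap < 1)
  step <- size * (1 - overlap)
  if (step != round(step)) stop("size * (1 - overlap) must be a whole bp")
  res <- lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]
    if (L < size) {
      message("chromosome ", layout$chrom[i], " shorter than ", size,
              " bp: no windows")
      return(NULL)
    }
    starts <- seq(0, L - size, by = step)
    data.frame(chrom = layout$chrom[i], start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Pooled heterozygosity of a window
#'
#' `Hp = 2 * sum(n_maj) * sum(n_min) / (sum(n_maj) + sum(n_min))^2`, where
#' the sums run over all SNPs in the window. Hp lies in [0, 0.5]: it is 0
#' exactly when no minor-allele reads are seen (monomorphic window) and 0.5
#' exactly when major and minor read sums balance.
#'
#' @param sum_maj,sum_min Window sums of per-SNP major/minor read counts.
#' @return Numeric Hp values.
#' @examples
#' pooled_heterozygosity(18, 6)  # (10,2) + (8,4): 216/576 = 0.375
#' @export
pooled_heterozygosity <- function(sum_maj, sum_min) {
  tot <- sum_maj + sum_min
  ifelse(tot > 0, 2 * sum_maj * sum_min / tot^2, NA_real_)
}

#' Genome-wide ZHp selective-sweep scan
#'
#' The central estimator of this package. For one pool it (1) extracts
#' per-SNP major/minor read counts from the allele depths, (2) tiles the
#' genome with 150 kb sliding windows at 50% overlap (full windows only),
#' (3) computes pooled heterozygosity `Hp` per window from the windowed
#' count sums, and (4) Z-transforms the Hp values genome-wide,
#' `ZHp = (Hp - mean(Hp)) / sd(Hp)`, using the population standard deviation
#' (divisor N) over all scored windows. Windows with fewer than `min_snps`
#' SNPs carrying read support are left unscored and excluded from the mean,
#' the standard deviation and sweep calling. Strongly negative ZHp marks
#' windows of excess homozygosity, the signature of a selective sweep.
#'
#' Only SNP records enter the scan; indel/mixed records and records failing
#' the hard filters should be removed beforehand (see [run_pipeline()]) or
#' via `snp_only`.
#'
#' @param x A [pool_vcf()], already filtered.
#' @param layout A [genome_layout()].
#' @param pool Pool name or column index (default first pool).
#' @param window_size Window size in bp (default 150000).
#' @param overlap Fractional window overlap (default 0.5).
#' @param min_snps Minimum SNPs with read support for a window to be scored
#'   (default 10; 0 scores every window with any reads).
#' @param snp_only Drop non-SNP records first (default `TRUE`).
#' @return An object of class `zhp_scan`: list with `pool`, `windows` (data
#'   frame: `chrom`, `start`, `end`, `n_snps`, `sum_maj`, `sum_min`, `hp`,
#'   `zhp`), `mu_hp`, `sigma_hp`, `min_snps`, `window_size`, `overlap`.
#' @seealso [call_sweeps()], [sweep_report()], [plot.zhp_scan()]
#' @export
zhp_scan <- function(x, layout, pool = 1L, window_size = 150000,
                     overlap = 0.5, min_snps = 10, snp_only = TRUE) {
  stopifnot(inherits(x, "pool_vcf"), inherits(layout, "genome_layout"))
  if (snp_only) {
    x <- x[classify_variant_type(x) == "SNP"]
  }
  keep <- x$variants$chrom %in% layout$chrom
  if (!all(keep)) {
    warning(sum(!keep), " SNP(s) on contigs absent from layout skipped")
    x <- x[keep]
  }
  cnt <- pool_allele_counts(x, pool)
  ok <- !is.na(cnt$n_maj)
  win <- make_sliding_windows(layout, window_size, overlap)
  win$n_snps <- 0
  win$sum_maj <- 0
  win$sum_min <- 0
  step <- window_size * (1 - overlap)
  chrom <- x$variants$chrom[ok]
  pos0 <- x$variants$pos[ok] - 1
  maj <- cnt$n_maj[ok]
  mn <- cnt$n_min[ok]
  phases <- as.integer(window_size / step)
  for (ch in unique(win$chrom)) {
    wi <- which(win$chrom == ch)
    nw <- length(wi)
    si <- which(chrom == ch)
    if (!length(si) || nw == 0L) next
    p <- pos0[si]
    # windows containing p start at j*step with j in
    # [ceil((p - size + 1)/step), floor(p/step)]; walk the (at most
    # size/step) candidates back from the rightmost start
    jmax <- floor(p / step)
    for (k in seq_len(phases) - 1L) {
      j <- jmax - k
      valid <- j >= 0 & j * step + window_size > p & j < nw
      if (!any(valid)) next
      rows <- wi[j[valid] + 1L]
      add <- rowsum(cbind(1, maj[si][valid], mn[si][valid]), rows)
      tgt <- as.integer(rownames(add))
      win$n_snps[tgt] <- win$n_snps[tgt] + add[, 1L]
      win$sum_maj[tgt] <- win$sum_maj[tgt] + add[, 2L]
      win$sum_min[tgt] <- win$sum_min[tgt] + add[, 3L]
    }
  }
  win$hp <- ifelse(win$n_snps >= max(min_snps, 1L),
                   pooled_heterozygosity(win$sum_maj, win$sum_min),
                   NA_real_)
  scored <- !is.na(win$hp)
  if (sum(scored) < 2L) stop("fewer than 2 scored windows")
  mu <- mean(win$hp[scored])
  sigma <- sqrt(mean((win$hp[scored] - mu)^2))
  if (sigma == 0) stop("zero variance in Hp")
  win$zhp <- (win$hp - mu) / sigma
  structure(list(pool = if (is.numeric(pool)) colnames(x$gt)[pool] else pool,
                 windows = win, mu_hp = mu, sigma_hp = sigma,
                 min_snps = min_snps, window_size = window_size,
                 overlap = overlap),
            class = "zhp_scan")
}

#' Z-transform a vector of Hp values
#'
#' `ZHp = (Hp - mean) / sd` with the *population* standard deviation
#' (divisor N), computed over the non-missing values. With two distinct
#' values the scores are exactly -1 and +1.
#'
#' @param hp Numeric vector (NA = unscored window).
#' @return List with `zhp` (same length as `hp`), `mu` and `sigma`.
#' @export
z_transform <- function(hp) {
  sc <- !is.na(hp)
  if (sum(sc) < 2L) stop("need >= 2 scored values")
  mu <- mean(hp[sc])
  sigma <- sqrt(mean((hp[sc] - mu)^2))
  if (sigma == 0) stop("zero variance in Hp")
  list(zhp = (hp - mu) / sigma, mu = mu, sigma = sigma)
}

#' Sweep tier thresholds
#'
#' ZHp score thresholds defining the three sweep tiers: windows at or below
#' -4 are candidate sweeps, at or below -5 putative sweeps, and at or below
#' -6 extreme sweeps.
#'
#' @param candidate,putative,extreme Tier thresholds (must satisfy
#'   `extreme <= putative <= candidate < 0`).
#' @return Named numeric vector of thresholds.
#' @export
sweep_thresholds <- function(candidate = -4, putative = -5, extreme = -6) {
  th <- c(candidate = candidate, putative = putative, extreme = extreme)
  if (!(extreme <= putative && putative <= candidate && candidate < 0)) {
    stop("need extreme <= putative <= candidate < 0")
  }
  th
}

#' Call sweep loci from a ZHp scan
#'
#' For each tier, selects windows with `zhp <= threshold` and merges
#' overlapping or book-ended selected windows on the same chromosome into
#' distinct loci spanning their union; a locus records the minimum ZHp and
#' the number of merged windows. Tiers are computed independently, so an
#' extreme locus also lies inside a putative and a candidate locus.
#'
#' @param scan A [zhp_scan()].
#' @param thresholds From [sweep_thresholds()].
#' @return Data frame of loci: `pool`, `tier`, `chrom`, `start`, `end`,
#'   `min_zhp`, `n_windows`. Zero rows when no window reaches any tier.
#' @export
call_sweeps <- function(scan, thresholds = sweep_thresholds()) {
  stopifnot(inherits(scan, "zhp_scan"))
  win <- scan$windows
  out <- list()
  for (tier in names(thresholds)) {
    sel <- !is.na(win$zhp) & win$zhp <= thresholds[[tier]]
    if (!any(sel)) next
    sw <- win[sel, , drop = FALSE]
    for (ch in unique(sw$chrom)) {
      s <- sw[sw$chrom == ch, , drop = FALSE]
      ir <- IRanges::IRanges(s$start + 1, s$end)  # closed, for reduce
      red <- IRanges::reduce(ir, min.gapwidth = 1L)
      ov <- IRanges::findOverlaps(ir, red)
      grp <- S4Vectors::subjectHits(ov)
      out[[length(out) + 1L]] <- data.frame(
        pool = scan$pool %||% NA_character_,
        tier = tier,
        chrom = ch,
        start = IRanges::start(red) - 1,
        end = IRanges::end(red),
        min_zhp = as.vector(tapply(s$zhp[S4Vectors::queryHits(ov)], grp, min)),
        n_windows = as.vector(table(grp)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(pool = character(0), tier = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), min_zhp = numeric(0),
                      n_windows = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$tier, names(thresholds)), res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Multi-pool sweep report
#'
#' Counts distinct loci per tier for each pool's scan and intersects the
#' candidate loci across pools to report regions shared by two or more pools.
#'
#' @param scans Named list of [zhp_scan()] objects (one per pool).
#' @param thresholds From [sweep_thresholds()].
#' @return List with `loci` (row-bound [call_sweeps()] output), `tier_counts`
#'   (pools x tiers matrix of distinct-locus counts) and `shared` (candidate
#'   loci overlapping between pool pairs).
#' @export
sweep_report <- function(scans, thresholds = sweep_thresholds()) {
  loci <- do.call(rbind, lapply(scans, call_sweeps, thresholds = thresholds))
  rownames(loci) <- NULL
  pools <- unname(vapply(scans, function(s) s$pool %||% "pool", character(1)))
  tiers <- names(thresholds)
  tier_counts <- sapply(tiers, function(t)
    vapply(pools, function(p) sum(loci$tier == t & loci$pool == p),
           integer(1)))
  tier_counts <- matrix(tier_counts, nrow = length(pools),
                        dimnames = list(pools, tiers))
  shared <- list()
  cand <- loci[loci$tier == "candidate", , drop = FALSE]
  if (length(pools) >= 2L && nrow(cand)) {
    pairs <- utils::combn(pools, 2L, simplify = FALSE)
    for (pr in pairs) {
      a <- cand[cand$pool == pr[1L], , drop = FALSE]
      b <- cand[cand$pool == pr[2L], , drop = FALSE]
      for (ch in intersect(a$chrom, b$chrom)) {
        ia <- IRanges::IRanges(a$start[a$chrom == ch] + 1,
                               a$end[a$chrom == ch])
        ib <- IRanges::IRanges(b$start[b$chrom == ch] + 1,
                               b$end[b$chrom == ch])
        hit <- IRanges::findOverlaps(ia, ib)
        if (!length(hit)) next
        inter <- IRanges::pintersect(ia[S4Vectors::queryHits(hit)],
                                     ib[S4Vectors::subjectHits(hit)])
        shared[[length(shared) + 1L]] <- data.frame(
          pool_a = pr[1L], pool_b = pr[2L], chrom = ch,
          start = IRanges::start(inter) - 1, end = IRanges::end(inter),
          stringsAsFactors = FALSE)
      }
    }
  }
  shared <- if (length(shared)) do.call(rbind, shared)
            else data.frame(pool_a = character(0), pool_b = character(0),
                            chrom = character(0), start = numeric(0),
                            end = numeric(0))
  list(loci = loci, tier_counts = tier_counts, shared = shared)
}

#' @export
print.zhp_scan <- function(x, ...) {
  sc <- sum(!is.na(x$windows$hp))
  cat(sprintf("ZHp scan%s: %d windows (%d scored) of %g kb, step %g kb\n",
              if (!is.null(x$pool)) paste0(" [", x$pool, "]") else "",
              nrow(x$windows), sc, x$window_size / 1000,
              x$window_size * (1 - x$overlap) / 1000))
  cat(sprintf("  mean Hp = %.4f, sd Hp = %.4f (population)\n",
              x$mu_hp, x$sigma_hp))
  if (sc) {
    cat(sprintf("  ZHp range: %.2f .. %.2f\n",
                min(x$windows$zhp, na.rm = TRUE),
                max(x$windows$zhp, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.zhp_scan <- function(object, thresholds = sweep_thresholds(), ...) {
  loci <- call_sweeps(object, thresholds)
  counts <- vapply(names(thresholds),
                   function(t) sum(loci$tier == t), integer(1))
  out <- list(scan = object, thresholds = thresholds, loci = loci,
              tier_counts = counts)
  class(out) <- "summary.zhp_scan"
  out
}

#' @export
print.summary.zhp_scan <- function(x, ...) {
  print(x$scan)
  cat("Distinct sweep loci:",
      paste(sprintf("%s (ZHp <= %g): %d", names(x$tier_counts),
                    x$thresholds, x$tier_counts), collapse = "; "), "\n")
  if (nrow(x$loci)) {
    cat("Top loci by min ZHp:\n")
    top <- x$loci[order(x$loci$min_zhp), , drop = FALSE]
    print(utils::head(top, 5L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.zhp_scan <- function(x, ...) x$windows

#' Manhattan-style plot of a ZHp scan
#'
#' Plots window midpoints against ZHp along concatenated chromosomes, with
#' horizontal lines at the tier thresholds.
#'
#' @param x A [zhp_scan()].
#' @param thresholds From [sweep_thresholds()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.zhp_scan <- function(x, thresholds = sweep_thresholds(), ...) {
  win <- x$windows[!is.na(x$windows$zhp), , drop = FALSE]
  chroms <- unique(x$windows$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(x$windows$end[x$windows$chrom == ch]), numeric(1))))
  names(offs) <- c(chroms, "END")
  gx <- offs[win$chrom] + (win$start + win$end) / 2
  graphics::plot(gx, win$zhp, pch = 16, cex = 0.4,
                 col = c("grey30", "grey60")[1 + match(win$chrom, chroms) %% 2],
                 xlab = "genome position", ylab = "ZHp", xaxt = "n", ...)
  graphics::axis(1, at = offs[-length(offs)] + diff(offs) / 2,
                 labels = chroms, tick = FALSE)
  graphics::abline(h = thresholds, lty = 2, col = "firebrick")
  invisible(x)
}
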