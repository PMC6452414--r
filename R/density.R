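#' Tile a genome into fixed non-overlapping windows
#'
#' Per chromosome, windows start at 0, `size`, `2*size`, ... (0-based
#' half-open); the final window is truncated at the chromosome end, so every
#' base is covered exactly once.
#'
#' @param layout A [genome_layout()].
#' @param size Window size in bp (default 1 Mb).
#' @return Data frame with `chrom`, `start`, `end`.
#' @export
make_fixed_windows <- function(layout, size = 1e6) {
  stopifnot(inherits(layout, "genome_layout"), size >= 1)
  res <- lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]
    starts <- seq(0, L - 1, by = size)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + size, L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count SNPs per window in four categories
#'
#' Assigns each SNP to the fixed window containing it (1-based position `p`
#' falls in the window with `start <= p - 1 < end`) and accumulates counts
#' for the four density categories: `all` (every SNP), `missense`, `lof`
#' (stop gain or stop loss) and `novel`. A SNP increments every category it
#' belongs to; categories are not exclusive. Density is count per kb of true
#' window length, so truncated terminal windows are not biased.
#'
#' @param windows Data frame from [make_fixed_windows()].
#' @param chrom,pos SNP coordinates (1-based `pos`).
#' @param missense,lof,novel Logical category flags per SNP (default all
#'   `FALSE`).
#' @return `windows` with count columns `all`, `missense`, `lof`, `novel` and
#'   matching `*_density` columns (SNPs per kb). SNPs on chromosomes missing
#'   from `windows` are skipped with a warning.
#' @export
assign_counts <- function(windows, chrom, pos,
                          missense = logical(length(pos)),
                          lof = logical(length(pos)),
                          novel = logical(length(pos))) {
  stopifnot(length(chrom) == length(pos))
  known_chr <- unique(windows$chrom)
  keep <- chrom %in% known_chr
  if (!all(keep)) {
    warning(sum(!keep), " SNP(s) on chromosomes absent from windows skipped")
    chrom <- chrom[keep]; pos <- pos[keep]
    missense <- missense[keep]; lof <- lof[keep]; novel <- novel[keep]
  }
  win_id <- integer(length(pos))
  for (ch in unique(chrom)) {
    w <- which(windows$chrom == ch)
    s <- which(chrom == ch)
    # windows are contiguous from 0, so the container is found by interval
    # lookup on starts; pos is 1-based, internal coordinate is pos - 1
    idx <- findInterval(pos[s] - 1, windows$start[w])
    ok <- idx >= 1L & (pos[s] - 1) < windows$end[w][idx]
    if (!all(ok)) stop("SNP outside chromosome bounds on ", ch)
    win_id[s] <- w[idx]
  }
  add <- function(flag) {
    tab <- table(factor(win_id[flag], levels = seq_len(nrow(windows))))
    as.vector(tab)
  }
  windows$all <- add(rep(TRUE, length(win_id)))
  windows$missense <- add(as.logical(missense))
  windows$lof <- add(as.logical(lof))
  windows$novel <- add(as.logical(novel))
  kb <- (windows$end - windows$start) / 1000
  for (cat in c("all", "missense", "lof", "novel")) {
    windows[[paste0(cat, "_density")]] <- windows[[cat]] / kb
  }
  windows
}

#' Extract the top fraction of windows by category density
#'
#' Windows are ranked by the category's density, descending, with ties broken
#' by genomic order (chromosome order in the input layout, then start), and
#' the first `ceiling(fraction * N)` windows are returned. By default `N`
#' counts all windows; set `denominator = "nonzero"` to count only windows
#' with at least one SNP in any category.
#'
#' @param windows Data frame from [assign_counts()].
#' @param category One of `"all"`, `"missense"`, `"lof"`, `"novel"`.
#' @param fraction Fraction of windows to keep (default 0.01).
#' @param denominator `"all"` (default) or `"nonzero"`.
#' @return The selected rows of `windows`, ranked.
#' @export
top_percent <- function(windows, category = "all", fraction = 0.01,
                        denominator = c("all", "nonzero")) {
  denominator <- match.arg(denominator)
  stopifnot(fraction > 0, fraction < 1, nrow(windows) > 0)
  dens <- windows[[paste0(category, "_density")]]
  if (is.null(dens)) stop("unknown category: ", category)
  n <- if (denominator == "all") nrow(windows)
       else sum(windows$all > 0)
  k <- ceiling(fraction * n)
  chrom_rank <- match(windows$chrom, unique(windows$chrom))
  ord <- order(-dens, chrom_rank, windows$start)
  out <- windows[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate windows with overlapping genes
#'
#' Ascribes to each window the names of all genes whose interval overlaps it
#' by at least 1 bp (both in 0-based half-open coordinates, so a gene
#' abutting the window end does not overlap). Names are deduplicated and
#' sorted; windows without genes keep an empty string.
#'
#' @param windows Data frame with `chrom`, `start`, `end`.
#' @param genes Data frame from [read_genes()] (columns `chrom`, `start`,
#'   `end`, `gene_name`).
#' @return `windows` with a `genes` column (comma-separated names).
#' @export
annotate_windows <- function(windows, genes) {
  out <- windows
  out$genes <- ""
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    # half-open [start, end) -> closed IRanges [start+1, end]
    wr <- IRanges::IRanges(windows$start[wi] + 1, windows$end[wi])
    gr <- IRanges::IRanges(genes$start[gi] + 1, genes$end[gi])
    hits <- IRanges::findOverlaps(wr, gr, minoverlap = 1L)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    nm <- tapply(genes$gene_name[gi][sh], qh,
                 function(g) paste(sort(unique(g)), collapse = ","))
    out$genes[wi[as.integer(names(nm))]] <- as.vector(nm)
  }
  out
}

#' Density scan report
#'
#' Runs the four-category 1 Mb density scan for one pool's SNP set and
#' returns both the full window table and the gene-annotated top windows per
#' category.
#'
#' @param layout A [genome_layout()].
#' @param chrom,pos SNP coordinates (1-based).
#' @param missense,lof,novel Logical flags per SNP.
#' @param genes Optional gene intervals for annotation.
#' @param size Window size (default 1 Mb).
#' @param fraction Top fraction (default 0.01).
#' @return List with `windows` (all windows with counts/densities) and `top`
#'   (named list of top-window tables per category).
#' @export
density_scan <- function(layout, chrom, pos, missense = NULL, lof = NULL,
                         novel = NULL, genes = NULL, size = 1e6,
                         fraction = 0.01) {
  zeros <- logical(length(pos))
  win <- assign_counts(make_fixed_windows(layout, size), chrom, pos,
                       missense %||% zeros, lof %||% zeros, novel %||% zeros)
  top <- lapply(stats::setNames(nm = c("all", "missense", "lof", "novel")),
                function(cat) {
                  t <- top_percent(win, cat, fraction)
                  if (!is.null(genes)) t <- annotate_windows(t, genes)
                  t
                })
  list(windows = win, top = top)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
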