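#' Simulation parameters for synthetic pool-seq data
#'
#' Defines the study design the generator emulates: a small number of breed
#' pools of diploid animals sequenced as DNA pools, joint-called into one
#' multi-pool VCF. Defaults mirror a three-breed design of 30 animals per
#' pool (pool ploidy 60) at ~20x coverage per pool, with 11% of variants
#' being indels and 93% of variants present in the known-variant catalogue.
#'
#' @param layout A [genome_layout()].
#' @param n_pools Number of pools (default 3).
#' @param pool_names Pool names (default `pool1..pooln`).
#' @param pool_size Diploid individuals per pool (default 30, ploidy 60).
#' @param mean_coverage Expected reads per pool per site (default 20).
#' @param snp_rate Expected variants per bp outside hotspots (default 1/250).
#' @param maf_spectrum Probability weights over alternate-allele copy counts
#'   1..(ploidy-1); default is the neutral spectrum P(k) proportional to 1/k.
#' @param planted_sweeps Data frame (`chrom`, `start`, `end`,
#'   `het_reduction` in \[0, 1\]) of regions where the minor-allele frequency
#'   is multiplied by `1 - het_reduction`; `NULL` for none.
#' @param planted_hotspots Data frame (`chrom`, `start`, `end`, `multiplier`
#'   >= 1) of regions with multiplied variant density; `NULL` for none.
#' @param known_fraction Probability a variant enters the catalogue (0.93).
#' @param indel_fraction Fraction of variants simulated as indels (0.11).
#' @param fail_fraction Fraction of records given a hard-filter-violating
#'   INFO metric via [inject_filter_failures()] (default 0.05).
#' @param low_gq_fraction Per-pool probability of a genotype quality below
#'   20 (default 0.02).
#' @param titv_target Transition/transversion ratio of simulated SNPs
#'   (default 2.2, the genome-wide cattle value).
#' @param seed Integer seed; one stream drives all randomness.
#' @return A `sim_params` list.
#' @export
sim_params <- function(layout, n_pools = 3, pool_names = NULL,
                       pool_size = 30, mean_coverage = 20,
                       snp_rate = 1 / 250, maf_spectrum = NULL,
                       planted_sweeps = NULL, planted_hotspots = NULL,
                       known_fraction = 0.93, indel_fraction = 0.11,
                       fail_fraction = 0.05, low_gq_fraction = 0.02,
                       titv_target = 2.2, seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"),
            known_fraction >= 0, known_fraction <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            fail_fraction >= 0, fail_fraction <= 1,
            pool_size >= 1, mean_coverage > 0, snp_rate > 0)
  ploidy <- 2L * pool_size
  if (is.null(pool_names)) pool_names <- paste0("pool", seq_len(n_pools))
  stopifnot(length(pool_names) == n_pools)
  if (is.null(maf_spectrum)) maf_spectrum <- 1 / seq_len(ploidy - 1L)
  stopifnot(length(maf_spectrum) == ploidy - 1L, all(maf_spectrum >= 0))
  chk <- function(df, extra, lo, hi) {
    if (is.null(df)) return(invisible())
    stopifnot(all(c("chrom", "start", "end", extra) %in% names(df)))
    idx <- match(df$chrom, layout$chrom)
    if (anyNA(idx)) stop("planted interval on unknown chromosome")
    if (any(df$start < 0 | df$end > layout$length[idx] | df$start >= df$end)) {
      stop("planted interval outside layout")
    }
    if (any(df[[extra]] < lo | df[[extra]] > hi)) {
      stop("planted ", extra, " out of range")
    }
  }
  chk(planted_sweeps, "het_reduction", 0, 1)
  chk(planted_hotspots, "multiplier", 1, Inf)
  structure(list(layout = layout, n_pools = n_pools,
                 pool_names = pool_names, pool_size = pool_size,
                 ploidy = ploidy, mean_coverage = mean_coverage,
                 snp_rate = snp_rate, maf_spectrum = maf_spectrum,
                 planted_sweeps = planted_sweeps,
                 planted_hotspots = planted_hotspots,
                 known_fraction = known_fraction,
                 indel_fraction = indel_fraction,
                 fail_fraction = fail_fraction,
                 low_gq_fraction = low_gq_fraction,
                 titv_target = titv_target, seed = as.integer(seed)),
            class = "sim_params")
}

.bases <- c("A", "C", "G", "T")
.transition <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate a synthetic pool-seq study
#'
#' Generates one multi-pool variant call set plus the side inputs the
#' analysis consumes, with the statistical structure the pipeline assumes:
#'
#' * variant positions are Poisson with rate `snp_rate` per bp, multiplied
#'   inside planted hotspots;
#' * each pool independently draws an alternate-allele copy count from the
#'   neutral 1/f spectrum; inside a planted sweep the minor-allele frequency
#'   is multiplied by `1 - het_reduction` (frequency compression, so SNP
#'   density inside sweeps stays roughly constant and windowed
#'   heterozygosity is the detecting signal);
#' * per-pool read depth is Poisson(`mean_coverage`), split binomially by
#'   the pool allele frequency into the AD field;
#' * INFO metrics are drawn from pass-region distributions, then
#'   [inject_filter_failures()] plants `fail_fraction` filter-failing
#'   records;
#' * a `known_fraction` random subset of variants is written to the
#'   catalogue, and each variant gets annotator consequence rows.
#'
#' Output is deterministic for a fixed `params$seed`.
#'
#' @param params A [sim_params()].
#' @return A `poolseq_sim` list: `vcf` ([pool_vcf()]), `catalogue`
#'   (`known_catalogue`), `catalogue_df`, `consequences` (data frame),
#'   `genes` (data frame), `truth` (list: per-variant data frame with true
#'   pool frequencies, category, novelty and injected-failure flags, plus the
#'   planted intervals) and `params`.
#' @export
simulate_poolseq <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  lay <- params$layout
  ploidy <- params$ploidy

  ## --- variant positions -------------------------------------------------
  pos_l <- list()
  for (i in seq_len(nrow(lay))) {
    ch <- lay$chrom[i]
    L <- lay$length[i]
    n_base <- stats::rpois(1L, params$snp_rate * L)
    p <- sample.int(L, min(n_base, L))
    hs <- params$planted_hotspots
    if (!is.null(hs)) {
      hs <- hs[hs$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(hs))) {
        extra <- stats::rpois(1L, params$snp_rate *
                                (hs$multiplier[k] - 1) *
                                (hs$end[k] - hs$start[k]))
        p <- c(p, hs$start[k] + sample.int(hs$end[k] - hs$start[k], extra,
                                           replace = TRUE))
      }
    }
    p <- sort(unique(p))
    pos_l[[i]] <- data.frame(chrom = ch, pos = p, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, pos_l)
  n <- nrow(sites)

  ## --- alleles ------------------------------------------------------------
  ref <- sample(.bases, n, replace = TRUE)
  is_indel <- stats::runif(n) < params$indel_fraction
  alt <- character(n)
  ti <- stats::runif(n) < params$titv_target / (params$titv_target + 1)
  alt[!is_indel & ti] <- .transition[ref[!is_indel & ti]]
  tv_pick <- function(r) {
    opts <- if (r %in% .purines) .pyrimidines else .purines
    opts[sample.int(2L, 1L)]
  }
  sel <- which(!is_indel & !ti)
  alt[sel] <- vapply(ref[sel], tv_pick, character(1))
  ins <- is_indel & stats::runif(n) < 0.5
  del <- is_indel & !ins
  ext <- sample(.bases, n, replace = TRUE)
  # insertions: REF = base, ALT = base+ext; deletions: REF = base+ext, ALT = base
  alt[ins] <- paste0(ref[ins], ext[ins])
  refdel <- paste0(ref, ext)
  alt[del] <- ref[del]
  ref[del] <- refdel[del]

  ## --- per-pool frequencies, genotypes, depths ----------------------------
  sweep_hr <- numeric(n)  # het_reduction applying to each site (0 = none)
  sw <- params$planted_sweeps
  if (!is.null(sw)) {
    for (k in seq_len(nrow(sw))) {
      inside <- sites$chrom == sw$chrom[k] &
        (sites$pos - 1) >= sw$start[k] & (sites$pos - 1) < sw$end[k]
      sweep_hr[inside] <- pmax(sweep_hr[inside], sw$het_reduction[k])
    }
  }
  gt_templates <- vapply(0:ploidy, function(k)
    paste(c(rep("0", ploidy - k), rep("1", k)), collapse = "/"), character(1))
  gt <- ad <- matrix(NA_character_, n, params$n_pools,
                     dimnames = list(NULL, params$pool_names))
  gq <- matrix(NA_real_, n, params$n_pools,
               dimnames = list(NULL, params$pool_names))
  true_p <- matrix(NA_real_, n, params$n_pools,
                   dimnames = list(NULL, paste0("p_", params$pool_names)))
  for (j in seq_len(params$n_pools)) {
    k_alt <- sample.int(ploidy - 1L, n, replace = TRUE,
                        prob = params$maf_spectrum)
    p <- k_alt / ploidy
    maf <- pmin(p, 1 - p) * (1 - sweep_hr)
    p <- ifelse(p <= 0.5, maf, 1 - maf)
    true_p[, j] <- p
    dose <- round(p * ploidy)
    gt[, j] <- gt_templates[dose + 1L]
    depth <- stats::rpois(n, params$mean_coverage)
    alt_reads <- stats::rbinom(n, depth, p)
    ad[, j] <- paste0(depth - alt_reads, ",", alt_reads)
    g <- 99 - stats::rgeom(n, 0.08)
    low <- stats::runif(n) < params$low_gq_fraction
    g[low] <- sample(5:19, sum(low), replace = TRUE)
    gq[, j] <- pmax(g, ifelse(low, g, 20))
  }

  ## --- INFO metrics: pass-region distributions ----------------------------
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  variants <- data.frame(
    chrom = sites$chrom, pos = sites$pos, id = ".",
    ref = ref, alt = alt,
    qual = 30 + stats::rexp(n, 1 / 300),
    QD = clip(stats::rnorm(n, 20, 6), 2.01, 40),
    MQ = clip(stats::rnorm(n, 60, 2.5), 40.01, 70),
    FS = clip(stats::rexp(n, 1 / 5), 0, 59.9),
    HaplotypeScore = clip(stats::rexp(n, 1 / 3), 0, 12.9),
    MQRankSum = clip(stats::rnorm(n, 0, 2), -12.4, 12.4),
    ReadPosRankSum = clip(stats::rnorm(n, 0, 2), -7.9, 7.9),
    stringsAsFactors = FALSE)
  # GATK omits rank sums at sites without heterozygous support
  variants$MQRankSum[stats::runif(n) < 0.2] <- NA_real_
  variants$ReadPosRankSum[stats::runif(n) < 0.2] <- NA_real_
  variants$HaplotypeScore[stats::runif(n) < 0.1] <- NA_real_
  vcf <- pool_vcf(variants, gt, ad, gq)
  inj <- inject_filter_failures(vcf, params$fail_fraction)
  vcf <- inj$vcf

  ## --- catalogue, consequences, genes -------------------------------------
  known <- stats::runif(n) < params$known_fraction
  catalogue_df <- data.frame(chrom = sites$chrom[known],
                             pos = sites$pos[known],
                             ref = ref[known], alt = alt[known],
                             stringsAsFactors = FALSE)
  catalogue <- if (any(known)) {
    make_catalogue(catalogue_df$chrom, catalogue_df$pos,
                   catalogue_df$ref, catalogue_df$alt)
  } else structure(character(0), class = "known_catalogue")

  terms <- c(intergenic_variant = 0.62, intron_variant = 0.265,
             upstream_gene_variant = 0.044, downstream_gene_variant = 0.044,
             synonymous_variant = 0.004, missense_variant = 0.0032,
             mature_miRNA_variant = 0.0033,
             non_coding_transcript_variant = 0.0009,
             `3_prime_UTR_variant` = 0.002, `5_prime_UTR_variant` = 0.0004,
             splice_region_variant = 0.0008,
             splice_donor_variant = 0.00003, splice_acceptor_variant = 0.00003,
             stop_gained = 0.00002, stop_lost = 0.0001)
  term <- sample(names(terms), n, replace = TRUE, prob = terms)
  genic <- !(term %in% c("intergenic_variant", "intron_variant"))
  consequences <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = ref,
                             alt = alt, consequence = term,
                             gene = ifelse(term == "intergenic_variant", "",
                                           paste0("GENE",
                                                  cumsum(!duplicated(
                                                    paste(sites$chrom,
                                                          sites$pos %/% 1e5))))),
                             transcript = "tx1", stringsAsFactors = FALSE)
  # a second, weaker annotation for some genic variants exercises the
  # most-severe reduction downstream
  dup <- which(genic & stats::runif(n) < 0.3)
  if (length(dup)) {
    extra_rows <- consequences[dup, , drop = FALSE]
    extra_rows$consequence <- "intron_variant"
    extra_rows$transcript <- "tx2"
    consequences <- rbind(consequences, extra_rows)
    ord <- order(match(consequences$chrom, lay$chrom), consequences$pos)
    consequences <- consequences[ord, , drop = FALSE]
    rownames(consequences) <- NULL
  }

  genes_l <- list()
  for (i in seq_len(nrow(lay))) {
    L <- lay$length[i]
    n_genes <- max(1L, floor(L / 1e5))
    start <- sort(sample.int(max(L - 50000L, 1L), n_genes))
    len <- pmax(1000, round(stats::rgamma(n_genes, shape = 2, scale = 15000)))
    genes_l[[i]] <- data.frame(chrom = lay$chrom[i], start = start - 1,
                               end = pmin(start - 1 + len, L),
                               gene_name = sprintf("G%s_%04d", lay$chrom[i],
                                                   seq_len(n_genes)),
                               strand = sample(c("+", "-"), n_genes,
                                               replace = TRUE),
                               stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes_l)
  rownames(genes) <- NULL

  truth_variants <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt,
    type = ifelse(is_indel, "indel", "SNP"),
    category = term, known = known, stringsAsFactors = FALSE)
  truth_variants <- cbind(truth_variants, as.data.frame(true_p))
  truth_variants$filter_injected <- seq_len(n) %in% inj$failed

  structure(list(vcf = vcf, catalogue = catalogue,
                 catalogue_df = catalogue_df, consequences = consequences,
                 genes = genes,
                 truth = list(variants = truth_variants,
                              sweeps = params$planted_sweeps,
                              hotspots = params$planted_hotspots,
                              failed_records = inj$failed),
                 params = params),
            class = "poolseq_sim")
}

#' @export
print.poolseq_sim <- function(x, ...) {
  cat(sprintf("poolseq_sim: %d variants, %d pools, %d chromosome(s), seed %d\n",
              n_variants(x$vcf), x$params$n_pools, nrow(x$params$layout),
              x$params$seed))
  invisible(x)
}

#' Plant hard-filter failures in a call set
#'
#' Gives exactly `round(fraction * N)` randomly chosen records one INFO/QUAL
#' metric violating the hard-filter criteria (one violated criterion per
#' chosen record, drawn uniformly from the seven). All other records are
#' untouched, so filtering removes exactly the modified set when the input
#' metrics lie in the pass region.
#'
#' @param x A [pool_vcf()].
#' @param fraction Fraction of records to fail, in \[0, 1\].
#' @param seed Optional seed; by default the current RNG stream is used (as
#'   when called from [simulate_poolseq()]).
#' @return List with `vcf` (modified) and `failed` (sorted record indices).
#' @export
inject_filter_failures <- function(x, fraction, seed = NULL) {
  stopifnot(inherits(x, "pool_vcf"), fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_variants(x)
  k <- round(fraction * n)
  if (k == 0L) return(list(vcf = x, failed = integer(0)))
  idx <- sort(sample.int(n, k))
  which_metric <- sample.int(7L, k, replace = TRUE)
  bad <- list(
    function(i) x$variants$qual[i] <<- 10,
    function(i) x$variants$QD[i] <<- 1.0,
    function(i) x$variants$MQ[i] <<- 30,
    function(i) x$variants$FS[i] <<- 70,
    function(i) x$variants$HaplotypeScore[i] <<- 15,
    function(i) x$variants$MQRankSum[i] <<- -13,
    function(i) x$variants$ReadPosRankSum[i] <<- -9)
  for (m in 1:7) {
    sel <- idx[which_metric == m]
    if (length(sel)) bad[[m]](sel)
  }
  list(vcf = x, failed = idx)
}

#' Write a simulated study to disk
#'
#' Emits the file set the pipeline reads: `calls.vcf`, `layout.fai`,
#' `catalogue.tsv`, `consequences.tsv`, `genes.bed` and `truth.tsv`.
#'
#' @param sim A `poolseq_sim` from [simulate_poolseq()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "poolseq_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "calls.vcf"),
             layout = file.path(dir, "layout.fai"),
             catalogue = file.path(dir, "catalogue.tsv"),
             consequences = file.path(dir, "consequences.tsv"),
             genes = file.path(dir, "genes.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_pool_vcf(sim$vcf, paths["vcf"], layout = sim$params$layout)
  write_layout(sim$params$layout, paths["layout"])
  write_tsv(sim$catalogue_df, paths["catalogue"])
  write_tsv(sim$consequences, paths["consequences"])
  write_bed(sim$genes, paths["genes"], layout = sim$params$layout)
  write_tsv(sim$truth$variants, paths["truth"])
  invisible(paths)
}
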