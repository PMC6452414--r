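test_that("major/minor read counts come from the two largest depths", {
  x <- make_vcf(pos = 1:4, alt = c("G", "G", "G,T", "G"),
                ad = c("12,8", "0,20", "10,6,4", "0,0"))
  cnt <- pool_allele_counts(x, 1)
  expect_equal(cnt$n_maj, c(12, 20, 10, NA))
  expect_equal(cnt$n_min, c(8, 0, 6, NA))
  # enumeration oracle for the multiallelic case: two largest of any depth set
  set.seed(151)
  for (i in 1:50) {
    d <- sample(0:30, sample(3:5, 1), TRUE)
    if (sum(d) == 0) next
    xx <- make_vcf(alt = paste(rep("G", length(d) - 1), collapse = ","),
                   ad = paste(d, collapse = ","))
    cc <- pool_allele_counts(xx, 1)
    expect_equal(c(cc$n_maj, cc$n_min), sort(d, decreasing = TRUE)[1:2])
  }
})

test_that("sliding windows follow the full-window convention", {
  expect_equal(nrow(make_sliding_windows(genome_layout("1", 150000))), 1L)
  w <- make_sliding_windows(genome_layout("1", 300000))
  expect_equal(w$start, c(0, 75000, 150000))
  expect_equal(w$end - w$start, rep(150000, 3))
  # chromosome shorter than one window contributes none
  expect_message(w0 <- make_sliding_windows(genome_layout("1", 100000)),
                 "no windows")
  expect_equal(nrow(w0), 0L)
})

test_that("pooled heterozygosity matches its closed form and bounds", {
  expect_equal(pooled_heterozygosity(5, 5), 0.5)
  expect_equal(pooled_heterozygosity(17, 0), 0)
  # worked window: (10,2) + (8,4) -> sums (18,6) -> 216/576
  expect_equal(pooled_heterozygosity(18, 6), 0.375)
  # bounds and the iff conditions, over random count pairs
  set.seed(161)
  maj <- sample(0:100, 500, TRUE)
  mn <- sample(0:100, 500, TRUE)
  sm <- pmax(maj, mn); sn <- pmin(maj, mn)
  hp <- pooled_heterozygosity(sm, sn)
  ok <- !is.na(hp)
  expect_true(all(hp[ok] >= 0 & hp[ok] <= 0.5))
  expect_equal(hp[ok] == 0.5, (sm == sn)[ok])
  expect_equal(hp[ok] == 0, (sn == 0)[ok])
  # symmetry: swapping the two count labels leaves Hp unchanged
  expect_equal(pooled_heterozygosity(6, 18), pooled_heterozygosity(18, 6))
})

test_that("the Z-transform is exactly standardising (population SD)", {
  z <- z_transform(c(0.2, 0.4))
  expect_equal(z$zhp, c(-1, 1))
  expect_error(z_transform(c(0.3, 0.3, 0.3)), "zero variance")
  expect_error(z_transform(0.3), ">= 2")
  set.seed(171)
  hp <- runif(500, 0, 0.5)
  z2 <- z_transform(hp)
  expect_lt(abs(mean(z2$zhp)), 1e-9)
  expect_lt(abs(sqrt(mean(z2$zhp^2)) - 1), 1e-9)
})

test_that("windowed Hp equals brute-force recomputation from flat counts", {
  set.seed(181)
  lay <- genome_layout("1", 3e6)
  sim <- simulate_poolseq(sim_params(lay, seed = 181, n_pools = 1,
                                     indel_fraction = 0))
  scan <- zhp_scan(sim$vcf, lay, pool = 1, min_snps = 1)
  cnt <- pool_allele_counts(sim$vcf, 1)
  pos0 <- sim$vcf$variants$pos - 1
  win <- scan$windows
  for (i in seq_len(nrow(win))) {
    sel <- pos0 >= win$start[i] & pos0 < win$end[i] & !is.na(cnt$n_maj)
    expect_equal(win$n_snps[i], sum(sel))
    expect_equal(win$sum_maj[i], sum(cnt$n_maj[sel]))
    expect_equal(win$sum_min[i], sum(cnt$n_min[sel]))
    sm <- sum(cnt$n_maj[sel]); sn <- sum(cnt$n_min[sel])
    brute <- if (sm + sn > 0) 2 * sm * sn / (sm + sn)^2 else NA_real_
    expect_equal(win$hp[i], brute)
  }
  # every interior base is covered by exactly two windows: total window
  # SNP count is twice the SNPs in the doubly-covered region
  inner <- pos0 >= 75000 & pos0 < max(win$end) - 75000 & !is.na(cnt$n_maj)
  outer <- (pos0 < 75000 | pos0 >= max(win$end) - 75000) &
    pos0 < max(win$end) & !is.na(cnt$n_maj)
  expect_equal(sum(win$n_snps), 2 * sum(inner) + sum(outer))
})

test_that("Hp is invariant to SNP permutation and per-site label swaps", {
  set.seed(191)
  d1 <- sample(0:30, 40, TRUE)
  d2 <- sample(0:30, 40, TRUE)
  maj <- pmax(d1, d2)
  mn <- pmin(d1, d2)
  hp0 <- pooled_heterozygosity(sum(maj), sum(mn))
  perm <- sample(40)
  expect_equal(pooled_heterozygosity(sum(maj[perm]), sum(mn[perm])), hp0)
  # swapping the raw depth labels at any site and re-sorting into
  # (major, minor) leaves the windowed sums, hence Hp, unchanged
  swap <- runif(40) < 0.5
  a <- ifelse(swap, d2, d1)
  b <- ifelse(swap, d1, d2)
  expect_equal(pooled_heterozygosity(sum(pmax(a, b)), sum(pmin(a, b))), hp0)
})

test_that("scan ZHp is standardised over scored windows only", {
  lay <- genome_layout(c("1", "2"), c(2e6, 1e6))
  set.seed(201)
  sim <- simulate_poolseq(sim_params(lay, seed = 201))
  scan <- zhp_scan(sim$vcf, lay, pool = 2)
  z <- scan$windows$zhp
  sc <- !is.na(z)
  expect_lt(abs(mean(z[sc])), 1e-9)
  expect_lt(abs(sqrt(mean(z[sc]^2)) - 1), 1e-9)
  # unscored windows (below min_snps) carry no zhp
  few <- scan$windows$n_snps < scan$min_snps
  expect_true(all(is.na(z[few])))
})

test_that("sweep calling merges overlapping windows into distinct loci", {
  scan <- structure(list(
    pool = "p1",
    windows = data.frame(
      chrom = c("1", "1", "1", "2"),
      start = c(0, 75000, 300000, 0),
      end = c(150000, 225000, 450000, 150000),
      n_snps = 50, sum_maj = 100, sum_min = 1,
      hp = 0.1, zhp = c(-5.2, -6.1, -1, -4.5)),
    mu_hp = 0.2, sigma_hp = 0.05, min_snps = 10,
    window_size = 150000, overlap = 0.5), class = "zhp_scan")
  loci <- call_sweeps(scan)
  cand <- loci[loci$tier == "candidate", ]
  # overlapping windows merge into one locus spanning their union
  expect_equal(nrow(cand), 2L)
  m <- cand[cand$chrom == "1", ]
  expect_equal(m$start, 0)
  expect_equal(m$end, 225000)
  expect_equal(m$min_zhp, -6.1)
  expect_equal(m$n_windows, 2L)
  # windows on different chromosomes stay separate loci
  expect_equal(cand$chrom, c("1", "2"))
  # tiers are independent: the extreme window is inside every tier
  expect_equal(nrow(loci[loci$tier == "putative", ]), 1L)
  expect_equal(nrow(loci[loci$tier == "extreme", ]), 1L)
  expect_equal(loci$min_zhp[loci$tier == "extreme"], -6.1)
})

test_that("no loci are called when nothing crosses a threshold", {
  scan <- structure(list(
    pool = "p", windows = data.frame(
      chrom = "1", start = 0, end = 150000, n_snps = 50,
      sum_maj = 10, sum_min = 5, hp = 0.4, zhp = -2),
    mu_hp = 0.3, sigma_hp = 0.05, min_snps = 10,
    window_size = 150000, overlap = 0.5), class = "zhp_scan")
  expect_equal(nrow(call_sweeps(scan)), 0L)
})

test_that("book-ended windows all below a threshold merge per chromosome", {
  win <- make_sliding_windows(genome_layout(c("1", "2"), c(6e5, 45e4)))
  win$n_snps <- 50; win$sum_maj <- 100; win$sum_min <- 0
  win$hp <- 0; win$zhp <- -5.5
  scan <- structure(list(pool = "p", windows = win, mu_hp = 0.2,
                         sigma_hp = 0.04, min_snps = 10,
                         window_size = 150000, overlap = 0.5),
                    class = "zhp_scan")
  loci <- call_sweeps(scan)
  put <- loci[loci$tier == "putative", ]
  expect_equal(nrow(put), 2L)  # exactly one merged locus per chromosome
  expect_equal(put$end - put$start, c(6e5, 45e4))
})

test_that("lowering the candidate threshold never adds candidate loci", {
  lay <- genome_layout("1", 5e6)
  sim <- simulate_poolseq(sim_params(
    lay, seed = 211,
    planted_sweeps = data.frame(chrom = "1", start = c(1e6, 3e6),
                                end = c(1.3e6, 3.3e6),
                                het_reduction = 0.95)))
  scan <- zhp_scan(sim$vcf, lay, pool = 1)
  n_prev <- Inf
  for (thr in c(-3, -4, -5, -6, -7)) {
    loci <- call_sweeps(scan, sweep_thresholds(candidate = thr,
                                               putative = thr - 1,
                                               extreme = thr - 2))
    n_now <- sum(loci$tier == "candidate")
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("scan object methods print, summarise and export windows", {
  lay <- genome_layout("1", 2e6)
  sim <- simulate_poolseq(sim_params(lay, seed = 221))
  scan <- zhp_scan(sim$vcf, lay, pool = 1)
  expect_output(print(scan), "ZHp scan")
  s <- summary(scan)
  expect_s3_class(s, "summary.zhp_scan")
  expect_output(print(s), "Distinct sweep loci")
  df <- as.data.frame(scan)
  expect_true(all(c("hp", "zhp") %in% names(df)))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_invisible(plot(scan))
  grDevices::dev.off()
})
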