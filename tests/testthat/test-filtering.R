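test_that("hard filters fail on each printed criterion, strictly", {
  cases <- list(
    list(args = list(QD = 1.5), reason = "QD"),
    list(args = list(FS = 70.0), reason = "FS"),
    list(args = list(qual = 29.9), reason = "QUAL"),
    list(args = list(MQ = 39.9), reason = "MQ"),
    list(args = list(HaplotypeScore = 13.1), reason = "HaplotypeScore"),
    list(args = list(MQRankSum = -12.6), reason = "MQRankSum"),
    list(args = list(ReadPosRankSum = -8.1), reason = "ReadPosRankSum"))
  for (cs in cases) {
    x <- do.call(make_vcf, cs$args)
    v <- apply_hard_filters(x)
    expect_false(v$passed, info = cs$reason)
    expect_equal(v$reasons, cs$reason)
  }
})

test_that("values exactly at a threshold pass (strict inequalities)", {
  x <- make_vcf(qual = 30.0, QD = 2.0, MQ = 40.0, FS = 60.0,
                HaplotypeScore = 13.0, MQRankSum = -12.5,
                ReadPosRankSum = -8.0)
  v <- apply_hard_filters(x)
  expect_true(v$passed)
  expect_equal(v$reasons, "")
})

test_that("absent INFO metrics never fail a record", {
  x <- make_vcf(QD = NA_real_, MQRankSum = NA_real_,
                ReadPosRankSum = NA_real_, HaplotypeScore = NA_real_)
  expect_true(apply_hard_filters(x)$passed)
})

test_that("a failing record lists every violated criterion, sorted", {
  x <- make_vcf(QD = 1.0, FS = 80, MQ = 10)
  v <- apply_hard_filters(x)
  expect_equal(v$reasons, "FS,MQ,QD")
})

test_that("relaxing exactly one violated criterion flips exactly that reason", {
  relax <- list(
    QUAL = function() filter_criteria(qual_min = 0),
    QD = function() filter_criteria(qd_min = 0),
    MQ = function() filter_criteria(mq_min = 0),
    FS = function() filter_criteria(fs_max = 1e6),
    HaplotypeScore = function() filter_criteria(haplotype_score_max = 1e6),
    MQRankSum = function() filter_criteria(mq_rank_sum_min = -1e6),
    ReadPosRankSum = function() filter_criteria(read_pos_rank_sum_min = -1e6))
  bad <- list(qual = 10, QD = 1, MQ = 30, FS = 70, HaplotypeScore = 15,
              MQRankSum = -13, ReadPosRankSum = -9)
  nm_map <- c(qual = "QUAL", QD = "QD", MQ = "MQ", FS = "FS",
              HaplotypeScore = "HaplotypeScore", MQRankSum = "MQRankSum",
              ReadPosRankSum = "ReadPosRankSum")
  for (f in names(bad)) {
    x <- do.call(make_vcf, stats::setNames(list(bad[[f]]), f))
    crit_name <- nm_map[[f]]
    expect_equal(apply_hard_filters(x)$reasons, crit_name)
    expect_true(apply_hard_filters(x, relax[[crit_name]]())$passed,
                info = crit_name)
  }
})

test_that("tightening any single threshold never increases passing count", {
  set.seed(301)
  sim <- simulate_poolseq(sim_params(tiny_layout(1, 2e5), seed = 301,
                                     snp_rate = 1 / 400,
                                     fail_fraction = 0.2))
  x <- sim$vcf
  base <- sum(apply_hard_filters(x)$passed)
  tighter <- list(filter_criteria(qual_min = 100),
                  filter_criteria(qd_min = 10),
                  filter_criteria(mq_min = 55),
                  filter_criteria(fs_max = 10),
                  filter_criteria(haplotype_score_max = 2),
                  filter_criteria(mq_rank_sum_min = -1),
                  filter_criteria(read_pos_rank_sum_min = -1))
  for (cr in tighter) {
    expect_lte(sum(apply_hard_filters(x, cr)$passed), base)
  }
})

test_that("low-GQ pools are masked at GQ < 20, kept at exactly 20", {
  x <- make_vcf(pos = 1:3, gq = matrix(c(19, 20, 21,
                                         15, 99, 10), ncol = 2),
                gt = "0/1", ad = "10,10", pools = c("a", "b"))
  m <- mask_low_gq(x)
  expect_true(is.na(m$gt[1, "a"]))    # 19 -> masked
  expect_false(is.na(m$gt[2, "a"]))   # 20 -> retained
  expect_true(is.na(m$gt[3, "b"]))
  # all pools below 20 -> record dropped when requested
  x2 <- make_vcf(pos = 1:2, gq = matrix(c(10, 99, 12, 99), ncol = 2,
                                        byrow = TRUE))
  expect_equal(n_variants(mask_low_gq(x2, drop_empty = TRUE)), 2L)
  x3 <- make_vcf(pos = 1:2, gq = matrix(c(10, 12, 12, 99), ncol = 2,
                                        byrow = TRUE))
  expect_equal(n_variants(mask_low_gq(x3, drop_empty = TRUE)), 1L)
})

test_that("variant types classify as SNP, indel or mixed", {
  x <- make_vcf(pos = 1:4, ref = c("A", "AT", "A", "A"),
                alt = c("G", "A", "G,AT", "AT"),
                ad = c("10,10", "10,10", "10,6,4", "10,10"))
  expect_equal(classify_variant_type(x), c("SNP", "indel", "mixed", "indel"))
})

test_that("pool zygosity separates fixed, segregating and reference", {
  x <- make_vcf(pos = 1:3, gt = c(gt_str(60), gt_str(30), gt_str(0)),
                ad = "10,10")
  expect_equal(classify_zygosity(x, 1),
               c("fixed", "segregating", "reference"))
  xm <- make_vcf(gq = 10)
  xm <- mask_low_gq(xm)
  expect_error(classify_zygosity(xm, 1), "masked")
})

test_that("Ti/Tv counts worked examples correctly", {
  # {A->G, C->T, A->C}: 2 transitions, 1 transversion
  x <- make_vcf(pos = 1:3, ref = c("A", "C", "A"), alt = c("G", "T", "C"))
  expect_equal(titv_ratio(x)$ratio, 2.0)
  # all transversions -> 0
  x2 <- make_vcf(pos = 1:2, ref = c("A", "G"), alt = c("T", "C"))
  expect_equal(titv_ratio(x2)$ratio, 0)
  # no transversions -> NaN with warning
  x3 <- make_vcf(ref = "A", alt = "G")
  expect_warning(r <- titv_ratio(x3), "undefined")
  expect_true(is.nan(r$ratio))
  # multiallelic SNP contributes one substitution per alt
  x4 <- make_vcf(ref = "A", alt = "G,T", ad = "10,6,4")
  r4 <- titv_ratio(x4)
  expect_equal(r4$ti + r4$tv, 2L)
})

test_that("uniform substitutions give Ti/Tv of 1/2 within sampling error", {
  # 4 of the 12 ordered substitution types are transitions, so with N
  # draws Ti ~ Binomial(N, 1/3) and Ti/Tv is near 0.5; delta-method SD of
  # the ratio is sqrt(p(1-p)/N)/(1-p)^2
  set.seed(77)
  n <- 12000
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  r <- titv_ratio(data.frame(ref = ref, alt = alt,
                             stringsAsFactors = FALSE))
  sd_ratio <- sqrt((1 / 3) * (2 / 3) / n) / (2 / 3)^2
  expect_lt(abs(r$ratio - 0.5), 3 * sd_ratio)
})

test_that("Ti/Tv is invariant under record order and merging", {
  set.seed(78)
  ref <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  df <- data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
  perm <- sample(nrow(df))
  expect_equal(titv_ratio(df)$ratio, titv_ratio(df[perm, ])$ratio)
  # merge: combined counts equal the sums of the split counts
  a <- titv_ratio(df[1:100, ]); b <- titv_ratio(df[101:300, ])
  whole <- titv_ratio(df)
  expect_equal(whole$ti, a$ti + b$ti)
  expect_equal(whole$tv, a$tv + b$tv)
})
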