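test_that("variant normalisation trims shared bases and shifts position", {
  # SNP unchanged
  expect_equal(normalise_variant("chr1", 100, "A", "G"),
               data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                          stringsAsFactors = FALSE))
  # shared leading base trimmed, position advanced (hand oracle)
  expect_equal(normalise_variant("chr1", 100, "CA", "CG"),
               data.frame(chrom = "chr1", pos = 101, ref = "A", alt = "G",
                          stringsAsFactors = FALSE))
  # deletion in a repeat: leading anchor trimmed, one base kept per allele
  expect_equal(normalise_variant("chr1", 100, "ATT", "AT"),
               data.frame(chrom = "chr1", pos = 101, ref = "TT", alt = "T",
                          stringsAsFactors = FALSE))
  expect_error(normalise_variant("chr1", 100, "A", "A"), "not a variant")
})

test_that("normalisation is idempotent on random indel representations", {
  set.seed(101)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    core_r <- paste(sample(bases, sample(1:3, 1), TRUE), collapse = "")
    core_a <- paste(sample(bases, sample(1:3, 1), TRUE), collapse = "")
    pad_l <- paste(sample(bases, sample(0:3, 1), TRUE), collapse = "")
    pad_r <- paste(sample(bases, sample(0:3, 1), TRUE), collapse = "")
    ref <- paste0(pad_l, core_r, pad_r)
    alt <- paste0(pad_l, core_a, pad_r)
    if (ref == alt) next
    n1 <- normalise_variant("1", 500, ref, alt)
    n2 <- normalise_variant(n1$chrom, n1$pos, n1$ref, n1$alt)
    expect_equal(n1, n2)
  }
})

test_that("matching against catalogues follows the stated modes", {
  x <- make_vcf(pos = c(100, 200, 300), ref = "A", alt = c("G", "G", "G"))
  # empty catalogue: everything novel
  empty <- make_catalogue(character(0), numeric(0), character(0),
                          character(0))
  expect_equal(match_known(x, empty), c(FALSE, FALSE, FALSE))
  # the record set itself: everything known
  self <- make_catalogue(x$variants$chrom, x$variants$pos, x$variants$ref,
                         x$variants$alt)
  expect_equal(match_known(x, self), c(TRUE, TRUE, TRUE))
  # same position, different alt: novel in allele mode, known in position mode
  cat2 <- make_catalogue("1", 100, "A", "T")
  expect_false(match_known(x, cat2)[1])
  expect_true(match_known(x, cat2, mode = "position")[1])
  # equivalent indel representations match through normalisation
  y <- make_vcf(pos = 100, ref = "CA", alt = "CG")
  cat3 <- make_catalogue("1", 101, "A", "G")
  expect_true(match_known(y, cat3))
})

test_that("catalogue growth never increases novel counts (monotonicity)", {
  set.seed(111)
  sim <- simulate_poolseq(sim_params(tiny_layout(1, 5e5), seed = 111,
                                     known_fraction = 0.5))
  x <- sim$vcf
  pres <- pool_presence(x)
  k1 <- match_known(x, sim$catalogue)
  s1 <- novelty_summary(k1, pres)
  # grow the catalogue with every simulated variant
  grown <- make_catalogue(x$variants$chrom, x$variants$pos, x$variants$ref,
                          x$variants$alt)
  k2 <- match_known(x, grown)
  s2 <- novelty_summary(k2, pres)
  expect_true(all(s2$novel <= s1$novel))
  # partition invariant holds in both
  expect_equal(s1$known + s1$novel, s1$total)
  expect_equal(s2$known + s2$novel, s2$total)
})

test_that("novelty summaries reproduce the reported proportions", {
  # per-breed SNP counts: AFR 8,576,732 known + 617,296 novel -> 0.07
  tab <- novelty_from_counts(
    pool = c("AFR", "DRA", "NGI"),
    known = c(8576732, 5764627, 9793635),
    novel = c(617296, 413795, 647269))
  expect_equal(tab$proportion_novel[tab$pool == "AFR"], 0.07)
  expect_equal(tab$total[tab$pool == "AFR"], 9194028)
  expect_equal(tab$novel[tab$pool == "Average"], 1678360)
  # small direct fractions
  expect_equal(novelty_from_counts("p", 93, 7)$proportion_novel[1], 0.07)
  expect_equal(novelty_from_counts("p", 10, 0)$proportion_novel[1], 0)
})

test_that("novelty summary handles flags, empty pools and averaging", {
  known <- c(TRUE, TRUE, FALSE, TRUE)
  present <- cbind(a = c(TRUE, TRUE, TRUE, FALSE),
                   b = c(FALSE, FALSE, FALSE, FALSE))
  s <- novelty_summary(known, present)
  expect_equal(s$total, c(3, 0, 3))
  expect_equal(s$novel[1], 1)
  expect_true(is.na(s$proportion_novel[2]))  # zero total -> missing
  expect_equal(s$proportion_novel[1], 0.33)
})
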