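# In-code fixtures shared across test files.

# A pool_vcf built from a compact spec. `...` overrides site-level defaults
# (vectors recycled); gt/ad/gq are matrices or vectors (one pool).
make_vcf <- function(chrom = "1", pos = 100, ref = "A", alt = "G",
                     qual = 100, QD = 25, MQ = 60, FS = 5,
                     HaplotypeScore = 2, MQRankSum = 0, ReadPosRankSum = 0,
                     gt = "0/1", ad = "10,10", gq = 99, pools = NULL) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  va <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = rep_len(pos, n), id = ".",
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   qual = rep_len(qual, n), QD = rep_len(QD, n),
                   MQ = rep_len(MQ, n), FS = rep_len(FS, n),
                   HaplotypeScore = rep_len(HaplotypeScore, n),
                   MQRankSum = rep_len(MQRankSum, n),
                   ReadPosRankSum = rep_len(ReadPosRankSum, n),
                   stringsAsFactors = FALSE)
  np <- max(1L, if (is.matrix(gt)) ncol(gt) else 1L,
            if (is.matrix(ad)) ncol(ad) else 1L,
            if (is.matrix(gq)) ncol(gq) else 1L,
            length(pools))
  as_mat <- function(v) {
    if (is.matrix(v)) v else matrix(rep_len(v, n * np), nrow = n)
  }
  gt <- as_mat(gt); ad <- as_mat(ad); gq <- as_mat(gq)
  if (!is.null(pools)) colnames(gt) <- colnames(ad) <- colnames(gq) <- pools
  pool_vcf(va, gt, ad, gq)
}

tiny_layout <- function(n_chrom = 1, len = 1e6) {
  genome_layout(as.character(seq_len(n_chrom)), rep_len(len, n_chrom))
}

# genotype string at given ploidy with k alt alleles
gt_str <- function(k, ploidy = 60) {
  paste(c(rep("0", ploidy - k), rep("1", k)), collapse = "/")
}
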