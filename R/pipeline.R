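#' Per-pool variant summary
#'
#' Tabulates, per pool, the number of variant records the pool carries, the
#' SNP/indel split and their proportions (rounded half-up to 2 decimals),
#' plus a cross-pool `Average` row whose proportions are the unweighted means
#' of the per-pool proportions (multi-pool totals are unions, so headline
#' shares are means of per-pool shares, not ratios of summed totals).
#'
#' @param type Character vector from [classify_variant_type()].
#' @param present Logical matrix (records x pools) from [pool_presence()];
#'   `NULL` treats all records as belonging to one pool `"all"`.
#' @return Data frame: `pool`, `n_variants`, `n_snps`, `prop_snps`,
#'   `n_indels`, `prop_indels`.
#' @export
summarize_variants <- function(type, present = NULL) {
  if (is.null(present)) {
    present <- matrix(TRUE, length(type), 1L, dimnames = list(NULL, "all"))
  }
  stopifnot(nrow(present) == length(type))
  rows <- lapply(colnames(present), function(p) {
    tot <- sum(present[, p])
    snp <- sum(present[, p] & type == "SNP")
    ind <- sum(present[, p] & type != "SNP")
    data.frame(pool = p, n_variants = tot, n_snps = snp,
               prop_snps = if (tot) round_half_up(snp / tot, 2L) else NA_real_,
               n_indels = ind,
               prop_indels = if (tot) round_half_up(ind / tot, 2L)
                             else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(pool = "Average",
                        n_variants = sum(out$n_variants),
                        n_snps = sum(out$n_snps),
                        prop_snps = round_half_up(mean(out$prop_snps,
                                                       na.rm = TRUE), 2L),
                        n_indels = sum(out$n_indels),
                        prop_indels = round_half_up(mean(out$prop_indels,
                                                         na.rm = TRUE), 2L),
                        stringsAsFactors = FALSE))
}

#' Variant summary from per-pool counts
#'
#' Builds the same per-pool SNP/indel table as [summarize_variants()] from
#' pre-tabulated counts. The `Average` row's proportions are unweighted means
#' of the per-pool proportions.
#'
#' @param pool Pool names.
#' @param n_variants,n_snps Per-pool counts (indels = difference).
#' @return Data frame as in [summarize_variants()].
#' @export
summarize_from_counts <- function(pool, n_variants, n_snps) {
  stopifnot(length(pool) == length(n_variants),
            length(pool) == length(n_snps), all(n_snps <= n_variants))
  prop_snp <- round_half_up(n_snps / n_variants, 2L)
  prop_ind <- round_half_up((n_variants - n_snps) / n_variants, 2L)
  out <- data.frame(pool = pool, n_variants = n_variants, n_snps = n_snps,
                    prop_snps = prop_snp, n_indels = n_variants - n_snps,
                    prop_indels = prop_ind, stringsAsFactors = FALSE)
  rbind(out, data.frame(pool = "Average", n_variants = sum(n_variants),
                        n_snps = sum(n_snps),
                        prop_snps = round_half_up(mean(prop_snp), 2L),
                        n_indels = sum(n_variants - n_snps),
                        prop_indels = round_half_up(mean(prop_ind), 2L),
                        stringsAsFactors = FALSE))
}

#' Pipeline run configuration
#'
#' Collects the inputs, outputs and stage parameters of one reproducible
#' pipeline run. Either `sim` (an in-memory [simulate_poolseq()] result) or
#' `vcf_path` + `layout_path` must be given; catalogue, consequence and gene
#' inputs are optional and their stages degrade gracefully when absent.
#'
#' @param sim Optional `poolseq_sim`.
#' @param vcf_path,layout_path,catalogue_path,consequences_path,genes_path
#'   Input file paths (ignored when `sim` is given).
#' @param out_dir Output directory; `NULL` suppresses file output.
#' @param criteria [filter_criteria()].
#' @param thresholds [sweep_thresholds()].
#' @param window_size,overlap,min_snps ZHp scan parameters.
#' @param density_window Density window size (default 1 Mb).
#' @param top_fraction Density top fraction (default 0.01).
#' @param match_mode Novelty matching, `"allele"` or `"position"`.
#' @param severity_mode Consequence reduction, `"severe"` or `"all"`.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, vcf_path = NULL, layout_path = NULL,
                       catalogue_path = NULL, consequences_path = NULL,
                       genes_path = NULL, out_dir = NULL,
                       criteria = filter_criteria(),
                       thresholds = sweep_thresholds(),
                       window_size = 150000, overlap = 0.5, min_snps = 10,
                       density_window = 1e6, top_fraction = 0.01,
                       match_mode = "allele", severity_mode = "severe") {
  if (is.null(sim) && (is.null(vcf_path) || is.null(layout_path))) {
    stop("need either `sim` or both `vcf_path` and `layout_path`")
  }
  structure(as.list(environment()), class = "run_config")
}

.stage_log <- function(stage, n_in, n_out, note = "") {
  message(sprintf("[%s] in=%d out=%d %s", stage, n_in, n_out, note))
}

#' Run the full pool-seq analysis pipeline
#'
#' Orchestrates the stages in order: load (or take simulated) calls ->
#' genotype-quality mask -> hard filters -> variant-type and zygosity
#' classification with Ti/Tv -> novelty against the catalogue -> consequence
#' classification and per-pool class tables -> 1 Mb density scan ->
#' per-pool ZHp sweep scan -> report. Each stage logs one structured line
#' with record counts; identical config and seed give an identical report.
#' Stages whose optional inputs are missing are marked `skipped` in the
#' report and the rest completes.
#'
#' @param config A [run_config()].
#' @return A `run_report` list with sections `variant_summary` (per-pool
#'   SNP/indel table), `titv` (per-pool Ti/Tv), `novelty`, `class_tables`
#'   (SNP and indel), `density` (per-pool top windows), `sweeps`
#'   (tier counts, loci, shared) and `scans` (the `zhp_scan` objects).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$sim)) {
    sim <- config$sim
    x <- sim$vcf
    layout <- sim$params$layout
    catalogue <- sim$catalogue
    cons <- sim$consequences
    genes <- sim$genes
  } else {
    layout <- read_layout(config$layout_path)
    x <- read_pool_vcf(config$vcf_path, layout)
    catalogue <- if (!is.null(config$catalogue_path))
      read_catalogue(config$catalogue_path) else NULL
    cons <- if (!is.null(config$consequences_path))
      read_consequences(config$consequences_path) else NULL
    genes <- if (!is.null(config$genes_path))
      read_genes(config$genes_path) else NULL
  }
  n0 <- n_variants(x)

  ## genotype-quality mask
  x <- mask_low_gq(x, config$criteria, drop_empty = TRUE)
  .stage_log("mask_gq", n0, n_variants(x))

  ## hard filters
  verdict <- apply_hard_filters(x, config$criteria)
  rejects <- data.frame(chrom = x$variants$chrom[!verdict$passed],
                        pos = x$variants$pos[!verdict$passed],
                        reasons = verdict$reasons[!verdict$passed],
                        stringsAsFactors = FALSE)
  x <- x[verdict$passed]
  .stage_log("hard_filter", length(verdict$passed), n_variants(x))

  ## classification + Ti/Tv
  type <- classify_variant_type(x)
  present <- pool_presence(x)
  variant_summary <- summarize_variants(type, present)
  snps <- x[type == "SNP"]
  snp_present <- present[type == "SNP", , drop = FALSE]
  titv <- lapply(colnames(present), function(p) {
    sub <- snps$variants[snp_present[, p], , drop = FALSE]
    titv_ratio(sub)$ratio
  })
  names(titv) <- colnames(present)
  .stage_log("classify", n_variants(x), nrow(snps$variants),
             sprintf("snps=%d indels=%d", sum(type == "SNP"),
                     sum(type != "SNP")))

  ## novelty
  if (!is.null(catalogue)) {
    known_all <- match_known(x, catalogue, mode = config$match_mode)
    novelty_all <- novelty_summary(known_all, present)
    known_snp <- known_all[type == "SNP"]
    novelty_snp <- novelty_summary(known_snp, snp_present)
    novelty <- list(all_variants = novelty_all, snps = novelty_snp,
                    skipped = FALSE)
    .stage_log("novelty", n_variants(x), sum(!known_all))
  } else {
    known_snp <- NULL
    novelty <- list(skipped = TRUE)
    .stage_log("novelty", n_variants(x), 0L, "(skipped: no catalogue)")
  }

  ## consequences
  if (!is.null(cons)) {
    cons$class <- classify_consequence(cons$consequence)
    reduced <- reduce_per_variant(cons, mode = config$severity_mode)
    key_x <- .variant_key(x$variants$chrom, x$variants$pos, x$variants$ref,
                          x$variants$alt)
    key_r <- .variant_key(reduced$chrom, reduced$pos, reduced$ref,
                          reduced$alt)
    hit <- match(key_r, key_x)
    reduced <- reduced[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
    r_type <- type[hit]
    r_present <- present[hit, , drop = FALSE]
    class_tables <- list(
      SNP = tabulate_classes(reduced[r_type == "SNP", , drop = FALSE],
                             r_present[r_type == "SNP", , drop = FALSE]),
      indel = tabulate_classes(reduced[r_type != "SNP", , drop = FALSE],
                               r_present[r_type != "SNP", , drop = FALSE]),
      skipped = FALSE)
    class_by_variant <- reduced$class[match(key_x, key_r)]
    .stage_log("consequences", nrow(cons), nrow(reduced))
  } else {
    class_tables <- list(skipped = TRUE)
    class_by_variant <- rep(NA_character_, n_variants(x))
    .stage_log("consequences", 0L, 0L, "(skipped: no consequence table)")
  }

  ## per-pool zygosity of carried variants (masked genotypes ignored)
  zygosity <- t(vapply(colnames(present), function(p) {
    gt_ok <- !is.na(x$gt[, p])
    z <- classify_zygosity(x[gt_ok], p)
    c(fixed = sum(z == "fixed"), segregating = sum(z == "segregating"),
      reference = sum(z == "reference"))
  }, c(fixed = 0L, segregating = 0L, reference = 0L)))

  ## density scan (per pool, on that pool's passing SNPs)
  snp_class <- class_by_variant[type == "SNP"]
  is_missense <- !is.na(snp_class) & snp_class == "Nonsynonymous_coding"
  is_lof <- !is.na(snp_class) & snp_class %in% c("Stop_gain", "Stop_lost")
  density <- lapply(colnames(present), function(p) {
    sel <- snp_present[, p]
    va <- snps$variants[sel, , drop = FALSE]
    density_scan(layout, va$chrom, va$pos,
                 missense = is_missense[sel],
                 lof = is_lof[sel],
                 novel = if (!is.null(known_snp)) (!known_snp)[sel]
                         else rep(FALSE, sum(sel)),
                 genes = genes, size = config$density_window,
                 fraction = config$top_fraction)
  })
  names(density) <- colnames(present)
  .stage_log("density", nrow(snps$variants),
             nrow(density[[1L]]$windows))

  ## ZHp sweep scan per pool
  scans <- lapply(colnames(present), function(p)
    zhp_scan(snps, layout, pool = p, window_size = config$window_size,
             overlap = config$overlap, min_snps = config$min_snps,
             snp_only = FALSE))
  names(scans) <- colnames(present)
  sweeps <- sweep_report(scans, config$thresholds)
  .stage_log("sweeps", nrow(scans[[1L]]$windows), nrow(sweeps$loci))

  report <- structure(list(variant_summary = variant_summary, titv = titv,
                           zygosity = zygosity, novelty = novelty,
                           class_tables = class_tables, rejects = rejects,
                           density = density, sweeps = sweeps, scans = scans),
                      class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    write_pool_vcf(x, file.path(od, "pass.vcf"), layout)
    write_tsv(rejects, file.path(od, "rejects.tsv"))
    write_tsv(variant_summary, file.path(od, "variant_summary.tsv"))
    if (!novelty$skipped) {
      write_tsv(novelty$all_variants, file.path(od, "novelty_all.tsv"))
      write_tsv(novelty$snps, file.path(od, "novelty_snps.tsv"))
    }
    if (!class_tables$skipped) {
      write_tsv(class_tables$SNP, file.path(od, "classes_snp.tsv"))
      write_tsv(class_tables$indel, file.path(od, "classes_indel.tsv"))
    }
    for (p in names(density)) {
      win <- density[[p]]$windows
      write_tsv(win, file.path(od, paste0("density_", p, ".tsv")))
      for (cat in names(density[[p]]$top)) {
        top <- density[[p]]$top[[cat]]
        top$name <- top[[paste0(cat, "_density")]]
        write_bed(top[, c("chrom", "start", "end", "name")],
                  file.path(od, paste0("density_top_", p, "_", cat, ".bed")))
      }
    }
    for (p in names(scans)) {
      write_tsv(scans[[p]]$windows[, c("chrom", "start", "end", "n_snps",
                                       "sum_maj", "sum_min", "hp", "zhp")],
                file.path(od, paste0("zhp_", p, ".tsv")))
    }
    write_tsv(sweeps$loci, file.path(od, "sweep_loci.tsv"))
    for (tier in unique(sweeps$loci$tier)) {
      sel <- sweeps$loci$tier == tier
      write_bed(sweeps$loci[sel, c("chrom", "start", "end", "pool",
                                   "min_zhp")],
                file.path(od, paste0("sweeps_", tier, ".bed")))
    }
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("poolsweep run report\n")
  cat("\nVariant summary (per pool):\n")
  print(x$variant_summary, row.names = FALSE)
  cat("\nTi/Tv:", paste(sprintf("%s=%.2f", names(x$titv),
                                unlist(x$titv)), collapse = "  "), "\n")
  if (!isTRUE(x$novelty$skipped)) {
    cat("\nNovelty (SNPs):\n")
    print(x$novelty$snps, row.names = FALSE)
  } else cat("\nNovelty: skipped (no catalogue)\n")
  if (!isTRUE(x$class_tables$skipped)) {
    cat("\nFunctional classes (SNPs):\n")
    print(x$class_tables$SNP, row.names = FALSE)
  }
  cat("\nSweep loci per tier:\n")
  print(x$sweeps$tier_counts)
  invisible(x)
}
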