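#' Genome layout
#'
#' A genome layout is the ordered table of chromosome names and lengths over
#' which windows are tiled. The order of the rows is the reporting order used
#' by every downstream scan.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer-ish vector of chromosome lengths in bp (>= 1).
#' @return A `genome_layout`: a data frame with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("layout must contain at least one chromosome")
  if (length(chrom) != length(length)) stop("chrom and length differ in length")
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome name: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (anyNA(length) || any(length != round(length))) {
    stop("chromosome lengths must be integers")
  }
  if (any(length < 1)) stop("chromosome lengths must be >= 1 bp")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Read a genome layout from a FASTA-index style file
#'
#' Reads a tab-separated file in the `.fai` dialect: chromosome name in the
#' first column, length in bp in the second; any further columns are ignored.
#' Row order is preserved as the reporting order.
#'
#' @param path Path to the file.
#' @return A [genome_layout()].
#' @export
read_layout <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L) {
    stop("empty layout file: ", path)
  }
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("layout file needs at least 2 columns: ", path)
  len <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(len)) {
    stop("non-integer length at line ", which(is.na(len))[1L], " of ", path)
  }
  genome_layout(tab[[1L]], len)
}

#' Write a genome layout in FASTA-index dialect
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  utils::write.table(layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' UMD3.1 bovine autosome lengths
#'
#' Lengths in bp of the 29 Bos taurus autosomes in the UMD3.1 (bosTau6)
#' reference assembly, in chromosome order. These are the coordinates over
#' which genome-wide window scans of cattle pool-seq data are tiled.
#'
#' @return A [genome_layout()] with 29 rows.
#' @examples
#' nrow(umd31_autosomes())
#' @export
umd31_autosomes <- function() {
  genome_layout(
    chrom = as.character(1:29),
    length = c(
      158337067, 137060424, 121430405, 120829699, 121191424, 119458736,
      112638659, 113384836, 105708250, 104305016, 107310763, 91163125,
      84240350, 84648390, 85296676, 81724687, 75158596, 66004023,
      64057457, 72042655, 71599096, 61435874, 52530062, 62714930,
      42904170, 51681464, 45407902, 46312546, 51505224)
  )
}

#' Write intervals as BED
#'
#' Intervals are handled internally in 0-based half-open coordinates, which is
#' the BED convention, so this is a plain column dump. Extra columns beyond
#' `chrom`, `start`, `end` are written as BED4+ fields in their input order.
#'
#' @param intervals Data frame with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @param layout Optional [genome_layout()]; when given, intervals exceeding a
#'   chromosome length are an error.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, layout = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (!is.null(layout)) {
    idx <- match(intervals$chrom, layout$chrom)
    bad <- !is.na(idx) & intervals$end > layout$length[idx]
    if (any(bad)) {
      stop("interval exceeds chromosome length: ",
           intervals$chrom[bad][1L], ":", intervals$end[bad][1L])
    }
  }
  first <- c("chrom", "start", "end")
  ord <- c(first, setdiff(names(intervals), first))
  utils::write.table(intervals[, ord, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a table as TSV with a header row
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read gene intervals from BED or GFF3
#'
#' BED input (detected by extension `.bed` or by a numeric second column with
#' 0-based starts) is taken as chrom/start/end/name/score/strand. GFF3 input
#' keeps rows whose type is `gene` and converts the 1-based closed coordinates
#' to the internal 0-based half-open convention; the gene name is taken from
#' the `Name=` attribute, falling back to `ID=`.
#'
#' @param path Path to a BED or GFF3 file.
#' @return Data frame with columns `chrom`, `start`, `end`, `gene_name`,
#'   `strand` (0-based half-open).
#' @export
read_genes <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    gff <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    gff <- gff[gff[[3L]] == "gene", , drop = FALSE]
    attr_get <- function(a, key) {
      m <- regmatches(a, regexpr(paste0(key, "=[^;]+"), a))
      ifelse(lengths(regmatches(a, gregexpr(paste0(key, "="), a))) > 0,
             sub(paste0(key, "="), "", m), NA_character_)
    }
    name <- attr_get(gff[[9L]], "Name")
    id <- attr_get(gff[[9L]], "ID")
    name[is.na(name) | name == ""] <- id[is.na(name) | name == ""]
    out <- data.frame(chrom = as.character(gff[[1L]]),
                      start = as.numeric(gff[[4L]]) - 1,
                      end = as.numeric(gff[[5L]]),
                      gene_name = name,
                      strand = as.character(gff[[7L]]),
                      stringsAsFactors = FALSE)
  } else {
    bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(chrom = as.character(bed[[1L]]),
                      start = as.numeric(bed[[2L]]),
                      end = as.numeric(bed[[3L]]),
                      gene_name = if (ncol(bed) >= 4L) as.character(bed[[4L]])
                                  else NA_character_,
                      strand = if (ncol(bed) >= 6L) as.character(bed[[6L]])
                               else "+",
                      stringsAsFactors = FALSE)
  }
  if (any(out$start < 0 | out$start >= out$end)) {
    stop("invalid gene interval (need 0 <= start < end): ", path)
  }
  out
}
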