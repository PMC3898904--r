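#' Genome index: chromosome sizes plus a fixed bin width
#'
#' A `genome_index` holds the ordered chromosome names and lengths of
#' the reference the reads were aligned to, together with the width of
#' the non-overlapping genome-tiling bins used for siRNA counting
#' (500 bp by default).  Bins are derived on demand with
#' [genome_bins()]; the terminal bin of each chromosome may be shorter
#' than `bin_width`.
#'
#' @param chromosomes data frame with columns `chrom` (character) and
#'   `length` (positive integer, bp), in the desired order.
#' @param bin_width bin width in bp.
#' @return An object of class `genome_index` with elements
#'   `chromosomes` (data frame) and `bin_width`.
#' @export
#' @examples
#' genome_index(data.frame(chrom = "chr1", length = 1001L), bin_width = 500)
genome_index <- function(chromosomes, bin_width = 500L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length <- as.numeric(chromosomes$length)
  .check_scalar(bin_width, "bin_width", integerish = TRUE)
  if (anyDuplicated(chromosomes$chrom)) {
    dup <- chromosomes$chrom[duplicated(chromosomes$chrom)][1L]
    stop(sprintf("duplicate chromosome name '%s'", dup), call. = FALSE)
  }
  if (any(is.na(chromosomes$length)) || any(chromosomes$length <= 0) ||
      any(chromosomes$length != floor(chromosomes$length))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  structure(list(chromosomes = chromosomes[, c("chrom", "length")],
                 bin_width = as.integer(bin_width)),
            class = "genome_index")
}

#' Load a genome index from a chromosome-sizes file
#'
#' Reads a two-column tab-separated file of chromosome name and length
#' (the `samtools faidx` / UCSC "chrom.sizes" convention); lines
#' starting with '#' are ignored.  Chromosome order is preserved.
#'
#' @param path path to the chromosome-sizes file.
#' @param bin_width bin width in bp (default 500, the region-calling
#'   resolution).
#' @return A [genome_index()].
#' @export
load_genome <- function(path, bin_width = 500L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  parsed <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    len <- suppressWarnings(as.numeric(f[2]))
    if (length(f) < 2L || is.na(len) || len <= 0 || len != floor(len)) {
      stop(sprintf("malformed chromosome-sizes line %d: '%s'",
                   lineno[i], lines[lineno[i]]), call. = FALSE)
    }
    data.frame(chrom = f[1], length = len)
  })
  genome_index(do.call(rbind, parsed), bin_width = bin_width)
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: %d chromosome(s), %s bp total, %d-bp bins (%d bins)\n",
              nrow(x$chromosomes), format(sum(x$chromosomes$length), big.mark = ","),
              x$bin_width, sum(n_bins(x))))
  invisible(x)
}

#' Number of bins per chromosome
#'
#' @param genome a [genome_index()].
#' @return Named integer vector, `ceiling(length / bin_width)` per
#'   chromosome.
#' @export
n_bins <- function(genome) {
  stopifnot(inherits(genome, "genome_index"))
  stats::setNames(as.integer(ceiling(genome$chromosomes$length / genome$bin_width)),
                  genome$chromosomes$chrom)
}

#' Derive the genome-tiling bins
#'
#' Bins are consecutive, non-overlapping `bin_width` tiles in 0-based
#' half-open coordinates; the last bin of each chromosome is truncated
#' at the chromosome end.
#'
#' @param genome a [genome_index()].
#' @param as `"data.frame"` (default) or `"GRanges"`.
#' @return A data frame with columns `bin_id`, `chrom`, `start`, `end`
#'   (0-based half-open), or the equivalent
#'   [GenomicRanges::GRanges] (1-based) when `as = "GRanges"`.
#' @export
genome_bins <- function(genome, as = c("data.frame", "GRanges")) {
  stopifnot(inherits(genome, "genome_index"))
  as <- match.arg(as)
  bw <- genome$bin_width
  per <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    chrom <- genome$chromosomes$chrom[i]
    len <- genome$chromosomes$length[i]
    starts <- seq.int(0L, len - 1L, by = bw)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + bw, len))
  })
  bins <- do.call(rbind, per)
  bins <- data.frame(bin_id = .bin_id(bins$chrom, bins$start, bins$end), bins,
                     stringsAsFactors = FALSE)
  if (as == "GRanges") {
    gr <- GenomicRanges::GRanges(
      seqnames = bins$chrom,
      ranges = IRanges::IRanges(start = bins$start + 1L, end = bins$end),
      bin_id = bins$bin_id)
    return(gr)
  }
  bins
}

# named chromosome length lookup
.chrom_len <- function(genome) {
  stats::setNames(genome$chromosomes$length, genome$chromosomes$chrom)
}

#' Write a chromosome-sizes file
#'
#' @param genome a [genome_index()].
#' @param path output path.
#' @param meta optional '#' metadata lines.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path, meta = character()) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  writeLines(sprintf("%s\t%d", genome$chromosomes$chrom,
                     as.integer(genome$chromosomes$length)), con)
  invisible(path)
}
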