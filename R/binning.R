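#' Filter reads by length and mapping uniqueness
#'
#' Retains reads whose length lies in `[min_len, max_len]` (the 18-27
#' nt small-RNA window by default) and, when `unique_only = TRUE`,
#' whose `n_hits` equals 1.  The number of retained reads is the
#' library size used for reads-per-ten-million normalization when the
#' default window is in force.
#'
#' @param reads data frame of aligned reads (see [read_alignments()]).
#' @param min_len,max_len inclusive length window in nt.
#' @param unique_only drop multi-mapped reads (`n_hits > 1`)?
#' @return list with elements `reads` (the retained rows) and
#'   `retained_count`.
#' @export
filter_by_length <- function(reads, min_len = 18L, max_len = 27L,
                             unique_only = TRUE) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  keep <- reads$length >= min_len & reads$length <= max_len
  if (unique_only) keep <- keep & reads$n_hits == 1L
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, retained_count = nrow(out))
}

#' Count reads of one length per genomic bin
#'
#' Each read of exactly `target_len` increments the single bin
#' containing its 5'-end base: `start` for a plus-strand read,
#' `start + length - 1` for a minus-strand read.  Assigning by the
#' 5'-end base guarantees every read hits exactly one bin, with no
#' double counting at bin boundaries.  Reads of other lengths
#' contribute nothing here (they are still part of the library size).
#'
#' @param reads data frame of (already length/uniqueness-filtered)
#'   aligned reads.
#' @param genome a [genome_index()].
#' @param target_len the counted read length in nt (24 for
#'   heterochromatic siRNAs).
#' @return Named integer vector over all genome bins (names are
#'   `bin_id`s in genome order).
#' @export
count_in_bins <- function(reads, genome, target_len = 24L) {
  stopifnot(inherits(genome, "genome_index"))
  bins <- genome_bins(genome)
  nb <- n_bins(genome)
  offsets <- stats::setNames(cumsum(c(0L, unname(nb)))[seq_along(nb)], names(nb))
  counts <- integer(nrow(bins))
  r <- reads[reads$length == target_len, , drop = FALSE]
  if (nrow(r)) {
    lens <- .chrom_len(genome)
    fivep <- ifelse(r$strand == "-", r$start + r$length - 1L, r$start)
    bad <- which(fivep < 0L | fivep >= lens[r$chrom])
    if (length(bad)) {
      stop(sprintf("read %d (%s:%d, %s strand) has its 5' end outside the chromosome",
                   bad[1L], r$chrom[bad[1L]], r$start[bad[1L]], r$strand[bad[1L]]),
           call. = FALSE)
    }
    idx <- offsets[r$chrom] + fivep %/% genome$bin_width + 1L
    counts <- tabulate(idx, nbins = nrow(bins))
  }
  stats::setNames(as.integer(counts), bins$bin_id)
}

#' Build a bin x library count matrix from read sets
#'
#' Applies [filter_by_length()] to each library, counts
#' `target_len`-nt reads per bin with [count_in_bins()], and records
#' each library's normalization denominator.  The denominator
#' (`library_size`) is, by choice of `library_size`:
#' \describe{
#'   \item{`"retained"`}{retained reads in the length/uniqueness
#'     window (default; the mapping universe of the analysis),}
#'   \item{`"target"`}{retained reads of exactly `target_len` nt,}
#'   \item{`"total"`}{all input alignments before filtering.}
#' }
#'
#' @param read_sets named list of aligned-read data frames, one per
#'   library; names become `library_id`s.
#' @param genome a [genome_index()].
#' @param target_len counted read length (nt).
#' @param min_len,max_len,unique_only passed to [filter_by_length()].
#' @param library_size which denominator to record (see Details).
#' @param genotypes optional character vector of genotype labels,
#'   parallel to `read_sets` (defaults to the library ids).
#' @return object of class `bin_matrix` with elements `bins` (data
#'   frame `bin_id`/`chrom`/`start`/`end`), `values` (integer matrix,
#'   bins x libraries), `libraries` (data frame `library_id`,
#'   `genotype`, `library_size`) and `unit = "count"`.
#' @export
bin_count_matrix <- function(read_sets, genome, target_len = 24L,
                             min_len = 18L, max_len = 27L, unique_only = TRUE,
                             library_size = c("retained", "target", "total"),
                             genotypes = names(read_sets)) {
  stopifnot(is.list(read_sets), length(read_sets) >= 1L,
            !is.null(names(read_sets)), !anyDuplicated(names(read_sets)))
  library_size <- match.arg(library_size)
  if (anyDuplicated(genotypes)) {
    stop("genotype labels must be unique across the libraries of one analysis",
         call. = FALSE)
  }
  bins <- genome_bins(genome)
  cols <- vector("list", length(read_sets))
  sizes <- numeric(length(read_sets))
  for (i in seq_along(read_sets)) {
    flt <- filter_by_length(read_sets[[i]], min_len, max_len, unique_only)
    cols[[i]] <- count_in_bins(flt$reads, genome, target_len)
    sizes[i] <- switch(library_size,
                       retained = flt$retained_count,
                       target = sum(flt$reads$length == target_len),
                       total = nrow(read_sets[[i]]))
  }
  values <- do.call(cbind, cols)
  dimnames(values) <- list(bins$bin_id, names(read_sets))
  structure(list(bins = bins,
                 values = values,
                 libraries = data.frame(library_id = names(read_sets),
                                        genotype = genotypes,
                                        library_size = sizes,
                                        stringsAsFactors = FALSE),
                 unit = "count"),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("bin_matrix [%s]: %d bins x %d libraries (%s)\n",
              x$unit, nrow(x$values), ncol(x$values),
              paste(x$libraries$library_id, collapse = ", ")))
  invisible(x)
}

#' Normalize bin counts to reads per ten million (RPTM)
#'
#' Every cell becomes `count * 1e7 / library_size`, so a library
#' sequenced to exactly ten million retained reads keeps its raw
#' counts.
#'
#' @param counts a `bin_matrix` of raw counts (see
#'   [bin_count_matrix()]).
#' @param library_sizes optional numeric vector (one per library)
#'   overriding the sizes recorded in `counts`; must be positive.
#' @return A `bin_matrix` with `unit = "RPTM"`.
#' @export
normalize_rptm <- function(counts, library_sizes = NULL) {
  stopifnot(inherits(counts, "bin_matrix"))
  if (counts$unit != "count") stop("input is already normalized", call. = FALSE)
  sizes <- library_sizes %||% counts$libraries$library_size
  if (length(sizes) != ncol(counts$values)) {
    stop("need one library size per library", call. = FALSE)
  }
  if (any(is.na(sizes)) || any(sizes <= 0)) {
    bad <- counts$libraries$library_id[which(is.na(sizes) | sizes <= 0)[1L]]
    stop(sprintf("library '%s' has non-positive library size", bad), call. = FALSE)
  }
  out <- counts
  out$values <- sweep(counts$values, 2L, sizes, function(v, s) v * 1e7 / s)
  out$libraries$library_size <- sizes
  out$unit <- "RPTM"
  out
}

#' Serialize a bin matrix as TSV
#'
#' Columns `chrom`, `start`, `end`, then one column per library.
#'
#' @param x a `bin_matrix`.
#' @param path output path.
#' @param meta optional '#' metadata lines.
#' @return `path`, invisibly.
#' @export
write_bin_matrix <- function(x, path, meta = character()) {
  stopifnot(inherits(x, "bin_matrix"))
  df <- cbind(x$bins[, c("chrom", "start", "end")],
              as.data.frame(x$values, check.names = FALSE))
  write_tsv(df, path, meta = c(sprintf("unit: %s", x$unit), meta))
}
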