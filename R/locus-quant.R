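#' Count target-length reads at a locus
#'
#' Counts the reads of exactly `target_len` nt whose 5'-end base lies
#' in the half-open interval `[start, end)` of the locus, matching
#' the bin-assignment convention of [count_in_bins()].
#'
#' @param reads data frame of aligned reads.
#' @param locus one locus: a list or one-row data frame with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param target_len counted read length (nt).
#' @return integer count.
#' @export
count_locus <- function(reads, locus, target_len = 24L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(locus)),
            locus$start < locus$end)
  r <- reads[reads$length == target_len & reads$chrom == locus$chrom, ,
             drop = FALSE]
  if (!nrow(r)) return(0L)
  fivep <- ifelse(r$strand == "-", r$start + r$length - 1L, r$start)
  sum(fivep >= locus$start & fivep < locus$end)
}

#' Count target-length reads at several loci across libraries
#'
#' @param read_sets named list of aligned-read data frames (one per
#'   library).
#' @param loci data frame of loci as returned by [load_loci()].
#' @param target_len counted read length (nt).
#' @return integer matrix, loci x libraries.
#' @export
count_loci <- function(read_sets, loci, target_len = 24L) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)), nrow(loci) >= 1L)
  mat <- sapply(read_sets, function(reads) {
    vapply(seq_len(nrow(loci)), function(i) {
      count_locus(reads, loci[i, ], target_len)
    }, integer(1L))
  })
  mat <- matrix(mat, nrow = nrow(loci),
                dimnames = list(loci$name, names(read_sets)))
  mat
}

#' Control-normalized relative siRNA accumulation
#'
#' For each library, the raw locus count is divided by the count of a
#' control siRNA locus (ta-siRNA255 in the original design, whose
#' accumulation is independent of the factors under study) in the
#' same library; the resulting normalized values are then expressed
#' relative to a reference library (wild type), whose relative value
#' is exactly 1.
#'
#' @param locus_counts matrix (loci x libraries, e.g. from
#'   [count_loci()]) or named numeric vector (one locus, named by
#'   library).
#' @param control_counts named numeric vector of control-locus counts
#'   per library; every library must have a positive control count.
#' @param reference library id of the reference (default `"WT"`).
#' @return data frame `locus`, `library`, `raw`, `normalized`,
#'   `relative`.
#' @export
#' @examples
#' relative_accumulation(c(WT = 100, mut = 10), c(WT = 50, mut = 50), "WT")
relative_accumulation <- function(locus_counts, control_counts,
                                  reference = "WT") {
  if (is.null(dim(locus_counts))) {
    locus_counts <- matrix(locus_counts, nrow = 1L,
                           dimnames = list("locus", names(locus_counts)))
  }
  libs <- colnames(locus_counts)
  if (!reference %in% libs) {
    stop(sprintf("reference library '%s' not present", reference), call. = FALSE)
  }
  ctrl <- control_counts[libs]
  bad <- libs[is.na(ctrl) | ctrl <= 0]
  if (length(bad)) {
    stop(sprintf("control locus count is zero or missing for library '%s'",
                 bad[1L]), call. = FALSE)
  }
  normalized <- sweep(locus_counts, 2L, ctrl, "/")
  relative <- sweep(normalized, 1L, normalized[, reference], "/")
  data.frame(locus = rep(rownames(locus_counts), times = length(libs)),
             library = rep(libs, each = nrow(locus_counts)),
             raw = as.vector(locus_counts),
             normalized = as.vector(normalized),
             relative = as.vector(relative),
             stringsAsFactors = FALSE)
}
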