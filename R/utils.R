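#' Round half away from zero
#'
#' Rounds to a fixed number of decimal places with ties going up
#' (e.g. 0.05 -> 0.1 at one decimal), the convention used for all
#' reported overlap percentages.  Base [round()] uses banker's
#' rounding, which would turn e.g. 0.25 into 0.2.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector, rounded.
#' @export
#' @examples
#' round_half_up(63.8084, 1)
#' round_half_up(0.25, 1)   # 0.3, not base round()'s 0.2
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single positive scalar check with a readable error
.check_scalar <- function(x, name, positive = TRUE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0 (got %s)", name, format(x)), call. = FALSE)
  }
  if (integerish && x != floor(x)) {
    stop(sprintf("'%s' must be a whole number (got %s)", name, format(x)), call. = FALSE)
  }
  invisible(x)
}

# canonical bin/region identifier: "<chrom>:<start>-<end>", 0-based half-open
.bin_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Write a data frame as TSV with '#' metadata header lines
#'
#' All tabular outputs of the package use this format: optional
#' '#'-prefixed metadata lines, then a header row, then tab-separated
#' values.
#'
#' @param x data frame.
#' @param path output file path.
#' @param meta character vector of metadata lines (written '# '-prefixed).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
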