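# quick constructors and independent oracles shared across the test files

make_reads <- function(start, length = 24L, chrom = "chr1", strand = "+",
                       n_hits = 1L) {
  data.frame(chrom = chrom, start = as.integer(start),
             length = as.integer(length),
             strand = strand, n_hits = as.integer(n_hits),
             stringsAsFactors = FALSE)
}

toy_genome <- function(lengths = c(chr1 = 1000L), bin_width = 500L) {
  genome_index(data.frame(chrom = names(lengths), length = unname(lengths)),
               bin_width = bin_width)
}

# brute-force oracle for bin counting: per read, linear scan of every bin
# interval of its chromosome testing 5'-end membership
brute_count_bins <- function(reads, genome, target_len = 24L) {
  bins <- genome_bins(genome)
  counts <- stats::setNames(integer(nrow(bins)), bins$bin_id)
  r <- reads[reads$length == target_len, , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    f <- if (r$strand[i] == "-") r$start[i] + r$length[i] - 1L else r$start[i]
    on_chrom <- which(bins$chrom == r$chrom[i])
    hit <- on_chrom[bins$start[on_chrom] <= f & f < bins$end[on_chrom]]
    stopifnot(length(hit) == 1L)
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# build an RPTM bin_matrix directly from a bins x libraries value matrix
# (one chromosome, consecutive 500-bp bins); library_size defaults to 1e7
# so RPTM values equal raw counts
toy_rptm <- function(values, library_size = 1e7, bin_width = 500L) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("lib", seq_len(ncol(values)))
  }
  genome <- toy_genome(c(chr1 = nrow(values) * bin_width), bin_width)
  bins <- genome_bins(genome)
  rownames(values) <- bins$bin_id
  sizes <- rep_len(library_size, ncol(values))
  structure(list(bins = bins, values = values,
                 libraries = data.frame(library_id = colnames(values),
                                        genotype = colnames(values),
                                        library_size = sizes,
                                        stringsAsFactors = FALSE),
                 unit = "RPTM"),
            class = "bin_matrix")
}

# a small, fast synthetic preset used where the full default is overkill
small_spec <- function(seed = 7L, centromere_fraction = 0.2, ...) {
  synthetic_spec(seed = seed, n_chromosomes = 2L, chromosome_length = 1e5,
                 centromere_fraction = centromere_fraction,
                 n_loci = c(polIV_polV_dep = 10L, polIV_only = 10L,
                            independent = 10L),
                 background_rate = 2000, ...)
}

write_sam <- function(reads, genome, path, extra_records = character()) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", genome$chromosomes$chrom,
                   as.integer(genome$chromosomes$length)))
  rec <- if (nrow(reads)) {
    sprintf("r%d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
            seq_len(nrow(reads)),
            ifelse(reads$strand == "-", 16L, 0L),
            reads$chrom, reads$start + 1L, 255L, reads$length,
            strrep("A", reads$length), reads$n_hits)
  } else character()
  writeLines(c(hdr, rec, extra_records), path)
  path
}
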