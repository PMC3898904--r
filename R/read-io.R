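#' Read aligned small-RNA reads from SAM/BAM or BED6
#'
#' Returns one row per alignment record as a data frame of
#' `AlignedRead`s: `chrom`, `start` (0-based leftmost), `length`
#' (aligned query length for SAM/BAM, `end - start` for BED),
#' `strand` and `n_hits` (number of reported genomic placements).
#' Unmapped SAM records are skipped.  SAM's 1-based positions are
#' converted to the package-wide 0-based half-open convention on
#' ingest, so BED and SAM encodings of the same alignments yield
#' identical streams.
#'
#' `n_hits` is taken from the SAM `NH` tag when present; records
#' without an `NH` tag are assumed uniquely mapped.  With
#' `unique_by = "mapq"`, a record is instead treated as unique when
#' `MAPQ > 0` (`n_hits` set to 1 or 2 accordingly).  BED input carries
#' no multi-mapping information and is always `n_hits = 1`.
#'
#' @param path path to a `.sam`, `.bam` or `.bed` file.
#' @param genome a [genome_index()]; every record must reference one
#'   of its chromosomes and lie within its bounds, otherwise an error
#'   names the offending record.
#' @param format `"auto"` (by file extension), `"bed"`, `"sam"` or
#'   `"bam"`.
#' @param unique_by how to derive `n_hits` from SAM/BAM records:
#'   `"nh"` (NH tag, default) or `"mapq"`.
#' @return data frame with columns `chrom`, `start`, `length`,
#'   `strand`, `n_hits`.
#' @export
read_alignments <- function(path, genome,
                            format = c("auto", "bed", "sam", "bam"),
                            unique_by = c("nh", "mapq")) {
  stopifnot(inherits(genome, "genome_index"))
  format <- match.arg(format)
  unique_by <- match.arg(unique_by)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", sam = "sam", bam = "bam",
                     stop(sprintf("unsupported alignment format '.%s' (use SAM/BAM or BED6)", ext),
                          call. = FALSE))
  }
  reads <- if (format == "bed") .read_bed_alignments(path)
           else .read_bam_alignments(path, sam = format == "sam", unique_by = unique_by)
  .validate_reads(reads, genome)
}

.read_bed_alignments <- function(path) {
  # strip comment/track lines before handing to rtracklayer
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b|$)", lines)
  tmp <- tempfile(fileext = ".bed")
  on.exit(unlink(tmp))
  writeLines(lines[keep], tmp)
  gr <- rtracklayer::import(tmp, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             length = GenomicRanges::width(gr),
             strand = strand,
             n_hits = 1L,
             stringsAsFactors = FALSE)
}

.read_bam_alignments <- function(path, sam = FALSE, unique_by = "nh") {
  if (sam) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    what = c("rname", "strand", "pos", "qwidth", "mapq"),
    tag = "NH")
  rec <- Rsamtools::scanBam(path, param = param)[[1L]]
  n <- length(rec$pos)
  nh <- rec$tag$NH
  n_hits <- if (unique_by == "mapq") {
    ifelse(!is.na(rec$mapq) & rec$mapq > 0L, 1L, 2L)
  } else if (!is.null(nh)) {
    ifelse(is.na(nh), 1L, as.integer(nh))
  } else rep(1L, n)
  data.frame(chrom = as.character(rec$rname),
             start = rec$pos - 1L,
             length = as.integer(rec$qwidth),
             strand = as.character(rec$strand),
             n_hits = n_hits,
             stringsAsFactors = FALSE)
}

.validate_reads <- function(reads, genome) {
  lens <- .chrom_len(genome)
  bad <- which(!(reads$chrom %in% names(lens)))
  if (length(bad)) {
    stop(sprintf("alignment record %d references unknown chromosome '%s'",
                 bad[1L], reads$chrom[bad[1L]]), call. = FALSE)
  }
  oob <- which(reads$start < 0L | reads$start >= lens[reads$chrom] |
               reads$length < 1L)
  if (length(oob)) {
    stop(sprintf("alignment record %d (%s:%d, length %d) violates chromosome bounds",
                 oob[1L], reads$chrom[oob[1L]], reads$start[oob[1L]],
                 reads$length[oob[1L]]), call. = FALSE)
  }
  if (any(reads$n_hits < 1L)) stop("n_hits must be >= 1", call. = FALSE)
  rownames(reads) <- NULL
  reads
}

#' Load named locus intervals from BED6
#'
#' Loci (e.g. 180 bp CEN, AtGP1, AtSN1, MEA-ISR and the ta-siRNA255
#' normalization control) are supplied as BED6 with a mandatory,
#' unique name field; coordinates are kept 0-based half-open.
#'
#' @param path BED6 file path.
#' @param genome a [genome_index()] used for bounds validation.
#' @return data frame with columns `name`, `chrom`, `start`, `end`.
#' @export
load_loci <- function(path, genome) {
  stopifnot(inherits(genome, "genome_index"))
  gr <- rtracklayer::import(path, format = "BED")
  name <- gr$name
  if (is.null(name) || anyNA(name) || any(name == "")) {
    stop("locus BED requires a name in column 4 for every interval", call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop(sprintf("duplicate locus name '%s'", name[duplicated(name)][1L]), call. = FALSE)
  }
  loci <- data.frame(name = as.character(name),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
  lens <- .chrom_len(genome)
  bad <- which(!(loci$chrom %in% names(lens)) | loci$start < 0L |
               loci$end > lens[loci$chrom] | loci$start >= loci$end)
  if (length(bad)) {
    stop(sprintf("locus '%s' is not a valid interval within the genome",
                 loci$name[bad[1L]]), call. = FALSE)
  }
  loci
}

#' Load a per-gene differential-expression table
#'
#' Reads a TSV with a header naming the gene-id, log2 fold-change
#' (mutant over wild type) and p-value columns, and validates it:
#' gene ids unique, p-values in \[0, 1\], fold changes finite.
#'
#' @param path TSV path ('#' comment lines ignored).
#' @param gene_col,lfc_col,p_col column names in the file header.
#' @return data frame with columns `gene_id`, `log2fc`, `p_value`.
#' @export
load_de_table <- function(path, gene_col = "gene_id", lfc_col = "log2fc",
                          p_col = "p_value") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c(gene_col, lfc_col, p_col), names(tab))
  if (length(missing)) {
    stop(sprintf("missing column(s) in DE table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  de <- data.frame(gene_id = as.character(tab[[gene_col]]),
                   log2fc = suppressWarnings(as.numeric(tab[[lfc_col]])),
                   p_value = suppressWarnings(as.numeric(tab[[p_col]])),
                   stringsAsFactors = FALSE)
  validate_de_table(de)
}

#' Validate a differential-expression table
#'
#' @param de data frame with columns `gene_id`, `log2fc`, `p_value`.
#' @return `de`, invisibly checked (errors name the offending row).
#' @export
validate_de_table <- function(de) {
  stopifnot(is.data.frame(de),
            all(c("gene_id", "log2fc", "p_value") %in% names(de)))
  bad <- which(is.na(de$log2fc) | !is.finite(de$log2fc) |
               is.na(de$p_value))
  if (length(bad)) {
    stop(sprintf("non-numeric or non-finite value in DE table row %d (gene '%s')",
                 bad[1L], de$gene_id[bad[1L]]), call. = FALSE)
  }
  if (anyDuplicated(de$gene_id)) {
    stop(sprintf("duplicate gene id '%s' in DE table",
                 de$gene_id[duplicated(de$gene_id)][1L]), call. = FALSE)
  }
  outp <- which(de$p_value < 0 | de$p_value > 1)
  if (length(outp)) {
    stop(sprintf("p-value out of [0, 1] in DE table row %d (gene '%s')",
                 outp[1L], de$gene_id[outp[1L]]), call. = FALSE)
  }
  rownames(de) <- NULL
  de
}

#' Write aligned reads as BED6
#'
#' Inverse of the BED branch of [read_alignments()]: 0-based
#' half-open intervals, read names `r1..rN`, score 0.
#'
#' @param reads data frame of aligned reads.
#' @param path output path.
#' @param meta optional '#' metadata lines written before the records.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path, meta = character()) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  if (nrow(reads)) {
    writeLines(sprintf("%s\t%d\t%d\tr%d\t0\t%s",
                       reads$chrom, as.integer(reads$start),
                       as.integer(reads$start + reads$length),
                       seq_len(nrow(reads)), reads$strand), con)
  }
  invisible(path)
}
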