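#' Configuration for siRNA region calling
#'
#' Bundles the thresholds of the dependence-classification procedure:
#' the low-abundance filter (bins below `min_rptm` RPTM in every
#' library are discarded), the wild-type/mutant fold threshold (a bin
#' is "decreased" in a mutant when WT exceeds `fold_threshold` times
#' the mutant, strictly), and the pseudocount added to both sides of
#' the ratio so that bins silenced to zero in a mutant yield finite,
#' large ratios.
#'
#' @param min_rptm abundance floor in RPTM (default 200).
#' @param fold_threshold WT/mutant fold (default 5, strict `>`).
#' @param pseudocount RPTM added to numerator and denominator
#'   (default 0.01).
#' @param per_genotype_fold optional named numeric vector mapping
#'   genotype labels to fold thresholds that override the default for
#'   those genotypes.
#' @return object of class `region_call_config`.
#' @export
region_call_config <- function(min_rptm = 200, fold_threshold = 5,
                               pseudocount = 0.01, per_genotype_fold = NULL) {
  if (!is.numeric(min_rptm) || min_rptm < 0) stop("min_rptm must be >= 0", call. = FALSE)
  if (!is.numeric(fold_threshold) || fold_threshold <= 1) {
    stop("fold_threshold must be > 1", call. = FALSE)
  }
  .check_scalar(pseudocount, "pseudocount")
  if (!is.null(per_genotype_fold)) {
    stopifnot(is.numeric(per_genotype_fold), !is.null(names(per_genotype_fold)),
              all(per_genotype_fold > 1))
  }
  structure(list(min_rptm = min_rptm, fold_threshold = fold_threshold,
                 pseudocount = pseudocount, per_genotype_fold = per_genotype_fold),
            class = "region_call_config")
}

#' Remove low-abundance bins
#'
#' A bin is removed iff its RPTM is strictly below `min_rptm` in
#' every library; a bin reaching the threshold in even one library is
#' retained.
#'
#' @param rptm an RPTM `bin_matrix` (see [normalize_rptm()]).
#' @param cfg a [region_call_config()].
#' @return character vector of retained `bin_id`s, in genome order.
#' @export
filter_low_abundance <- function(rptm, cfg = region_call_config()) {
  stopifnot(inherits(rptm, "bin_matrix"), rptm$unit == "RPTM",
            nrow(rptm$values) > 0L)
  keep <- rowSums(rptm$values >= cfg$min_rptm) > 0L
  rownames(rptm$values)[keep]
}

# shared fold rule: decreased iff (WT + pc) > fold * (mutant + pc)
.fold_decreased <- function(rptm, wt, mutant, fold, pseudocount, universe) {
  for (lib in c(wt, mutant)) {
    if (!lib %in% colnames(rptm$values)) {
      stop(sprintf("library '%s' not found in the matrix", lib), call. = FALSE)
    }
  }
  missing <- setdiff(universe, rownames(rptm$values))
  if (length(missing)) {
    stop(sprintf("bin '%s' is not in the matrix", missing[1L]), call. = FALSE)
  }
  w <- rptm$values[universe, wt]
  m <- rptm$values[universe, mutant]
  universe[(w + pseudocount) > fold * (m + pseudocount)]
}

#' Call Pol IV-dependent siRNA regions
#'
#' Among the abundance-retained bins, a bin is a Pol IV-dependent
#' siRNA region when its wild-type RPTM is (strictly) more than
#' `fold_threshold` times its RPTM in the Pol IV mutant `nrpd1`,
#' after adding the pseudocount to both sides.
#'
#' @param rptm an RPTM `bin_matrix`.
#' @param wt,nrpd1 library ids of the wild-type and Pol IV-mutant
#'   columns.
#' @param cfg a [region_call_config()].
#' @param retained bin universe from [filter_low_abundance()]
#'   (computed from `rptm` and `cfg` when omitted).
#' @return character vector of Pol IV-dependent `bin_id`s.
#' @export
call_poliv_dependent <- function(rptm, wt = "WT", nrpd1 = "nrpd1",
                                 cfg = region_call_config(),
                                 retained = filter_low_abundance(rptm, cfg)) {
  .fold_decreased(rptm, wt, nrpd1, cfg$fold_threshold, cfg$pseudocount, retained)
}

#' Call bins with decreased siRNAs in one mutant
#'
#' Applies the same fold rule as [call_poliv_dependent()] for an
#' arbitrary mutant library, restricted to a region universe
#' (typically the Pol IV-dependent regions).  A per-genotype fold
#' override in the configuration takes precedence over the default
#' threshold.
#'
#' @param rptm an RPTM `bin_matrix`.
#' @param wt wild-type library id.
#' @param mutant mutant library id.
#' @param cfg a [region_call_config()].
#' @param universe bin ids the call is restricted to.
#' @return object of class `dependence_call_set`: list with
#'   `genotype` (the mutant's genotype label) and `regions`
#'   (character vector of bin ids called decreased).
#' @export
call_decreased <- function(rptm, wt = "WT", mutant, cfg = region_call_config(),
                           universe = filter_low_abundance(rptm, cfg)) {
  genotype <- {
    hit <- match(mutant, rptm$libraries$library_id)
    if (is.na(hit)) mutant else rptm$libraries$genotype[hit]
  }
  fold <- cfg$per_genotype_fold[genotype]
  if (is.null(fold) || is.na(fold)) fold <- cfg$fold_threshold
  structure(list(genotype = genotype,
                 regions = .fold_decreased(rptm, wt, mutant, fold,
                                           cfg$pseudocount, universe)),
            class = "dependence_call_set")
}

#' @export
print.dependence_call_set <- function(x, ...) {
  cat(sprintf("dependence_call_set: %d region(s) decreased in %s\n",
              length(x$regions), x$genotype))
  invisible(x)
}

#' Partition Pol IV-dependent regions by Pol V dependence
#'
#' Splits the Pol IV-dependent siRNA regions into the Pol V-dependent
#' group (also decreased in the Pol V mutant `nrpe1`) and its
#' complement, the Pol V-independent group.  The two groups are
#' disjoint and their union is the input set.
#'
#' @param poliv_regions character vector of Pol IV-dependent bin ids.
#' @param nrpe1_calls a `dependence_call_set` for `nrpe1` computed
#'   over `poliv_regions` (or a plain character vector of decreased
#'   bin ids).
#' @return list with `polv_dependent` and `polv_independent`
#'   character vectors.
#' @export
partition_polv <- function(poliv_regions, nrpe1_calls) {
  dec <- if (inherits(nrpe1_calls, "dependence_call_set")) nrpe1_calls$regions
         else nrpe1_calls
  list(polv_dependent = intersect(poliv_regions, dec),
       polv_independent = setdiff(poliv_regions, dec))
}

#' Overlap summary between a subset and its universe
#'
#' Reports `n_overlap`, `n_total` and the percentage
#' `100 * n_overlap / n_total` rounded half-up to one decimal — the
#' form in which region-set and gene-set overlaps are reported
#' throughout this analysis.  Accepts either two sets (the subset
#' must be contained in the universe) or two counts.
#'
#' @param set_a subset (character vector) or the overlap count
#'   (single number).
#' @param universe universe set (character vector) or total count
#'   (single number).
#' @param label comparison label carried into the output row.
#' @return one-row data frame `comparison`, `n_overlap`, `n_total`,
#'   `percent`.
#' @export
#' @examples
#' overlap_summary(3670, 5751, "PolIV-dep also decreased in nrpe1")
overlap_summary <- function(set_a, universe, label = "") {
  if (is.numeric(set_a) && length(set_a) == 1L &&
      is.numeric(universe) && length(universe) == 1L) {
    n_overlap <- set_a
    n_total <- universe
    if (n_overlap > n_total || n_overlap < 0) {
      stop("need 0 <= n_overlap <= n_total", call. = FALSE)
    }
  } else {
    set_a <- unique(set_a)
    universe <- unique(universe)
    if (!all(set_a %in% universe)) {
      stop("set_a must be a subset of the universe", call. = FALSE)
    }
    n_overlap <- length(set_a)
    n_total <- length(universe)
  }
  if (n_total == 0) stop("empty universe in overlap summary", call. = FALSE)
  data.frame(comparison = label, n_overlap = n_overlap, n_total = n_total,
             percent = round_half_up(100 * n_overlap / n_total, 1),
             stringsAsFactors = FALSE)
}

#' Chromosome-scale siRNA profile over large windows
#'
#' Sums, per consecutive genomic window (500 kb by default) and per
#' library, the RPTM of the Pol IV-dependent bins whose start lies in
#' the window — the quantity plotted along chromosomes to show where
#' Pol IV-dependent siRNAs concentrate (centromeres vs arms).
#'
#' @param rptm an RPTM `bin_matrix`.
#' @param poliv_regions character vector of Pol IV-dependent bin ids.
#' @param genome a [genome_index()].
#' @param window window width in bp (default 5e5).
#' @return data frame `chrom`, `window_start`, `window_end`, then one
#'   column of summed RPTM per library.
#' @export
chromosome_profile <- function(rptm, poliv_regions, genome, window = 500000L) {
  stopifnot(inherits(rptm, "bin_matrix"), rptm$unit == "RPTM",
            inherits(genome, "genome_index"))
  if (window < genome$bin_width) {
    stop("window must be at least one bin wide", call. = FALSE)
  }
  grid <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    chrom <- genome$chromosomes$chrom[i]
    len <- genome$chromosomes$length[i]
    starts <- seq.int(0L, len - 1L, by = window)
    data.frame(chrom = chrom, window_start = starts,
               window_end = pmin(starts + window, len),
               stringsAsFactors = FALSE)
  }))
  libs <- colnames(rptm$values)
  mat <- matrix(0, nrow = nrow(grid), ncol = length(libs),
                dimnames = list(NULL, libs))
  sel <- rptm$bins$bin_id %in% poliv_regions
  if (any(sel)) {
    b <- rptm$bins[sel, , drop = FALSE]
    key <- paste0(b$chrom, ":", b$start %/% window)
    gkey <- paste0(grid$chrom, ":", grid$window_start %/% window)
    sums <- rowsum(rptm$values[sel, , drop = FALSE], group = key)
    hit <- match(rownames(sums), gkey)
    mat[hit, ] <- sums
  }
  cbind(grid, as.data.frame(mat, check.names = FALSE))
}

#' Write region calls as BED6 and a master table
#'
#' Emits the Pol IV-dependent regions as BED6 with the Pol V class in
#' the name field, plus a TSV master table of per-library RPTM and
#' class flags for every retained bin.
#'
#' @param rptm an RPTM `bin_matrix`.
#' @param retained bin universe from [filter_low_abundance()].
#' @param poliv_regions Pol IV-dependent bin ids.
#' @param partition list from [partition_polv()].
#' @param decreased named list of `dependence_call_set`s (optional).
#' @param bed_path,table_path output paths (either may be `NULL` to
#'   skip).
#' @param meta optional '#' metadata lines.
#' @return invisibly, the master table data frame.
#' @export
write_region_calls <- function(rptm, retained, poliv_regions, partition,
                               decreased = list(), bed_path = NULL,
                               table_path = NULL, meta = character()) {
  bins <- rptm$bins[rptm$bins$bin_id %in% retained, , drop = FALSE]
  tab <- data.frame(bins[, c("bin_id", "chrom", "start", "end")],
                    as.data.frame(rptm$values[bins$bin_id, , drop = FALSE],
                                  check.names = FALSE),
                    poliv_dependent = bins$bin_id %in% poliv_regions,
                    polv_dependent = bins$bin_id %in% partition$polv_dependent,
                    stringsAsFactors = FALSE)
  for (nm in names(decreased)) {
    tab[[paste0("decreased_", nm)]] <- bins$bin_id %in% decreased[[nm]]$regions
  }
  if (!is.null(table_path)) write_tsv(tab, table_path, meta)
  if (!is.null(bed_path)) {
    dep <- bins[bins$bin_id %in% poliv_regions, , drop = FALSE]
    class <- ifelse(dep$bin_id %in% partition$polv_dependent,
                    "PolIV_dep.PolV_dep", "PolIV_dep.PolV_indep")
    con <- file(bed_path, "wt")
    on.exit(close(con))
    if (length(meta)) writeLines(paste0("# ", meta), con)
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+", dep$chrom,
                       as.integer(dep$start), as.integer(dep$end), class), con)
  }
  invisible(tab)
}
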