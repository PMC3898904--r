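#' Call upregulated genes from a DE table
#'
#' A gene is upregulated when `log2fc > fc_threshold` AND
#' `p_value < p_threshold`, both strict — boundary genes (log2 fold
#' change exactly 1, or p exactly 0.01) are excluded.  No
#' multiple-testing correction is applied by default; `fdr = TRUE`
#' replaces the raw p-values with Benjamini-Hochberg adjusted ones
#' before thresholding.
#'
#' @param de DE table (see [load_de_table()]).
#' @param fc_threshold log2 fold-change threshold (default 1).
#' @param p_threshold p-value threshold (default 0.01).
#' @param fdr apply Benjamini-Hochberg adjustment first?
#' @return sorted character vector of upregulated gene ids.
#' @export
call_upregulated <- function(de, fc_threshold = 1, p_threshold = 0.01,
                             fdr = FALSE) {
  de <- validate_de_table(de)
  p <- if (fdr) stats::p.adjust(de$p_value, method = "BH") else de$p_value
  sort(de$gene_id[de$log2fc > fc_threshold & p < p_threshold])
}

#' Overlap structure of several upregulated-gene sets
#'
#' Computes, for two or more named gene sets: the gene x set
#' membership matrix; every pairwise overlap, reported in both
#' directions as "fraction of A also in B"; the count of every
#' non-empty intersection among the sets (for Venn diagrams); and,
#' with three or more sets, the fraction of each set found in the
#' union of the others.  Percentages follow [overlap_summary()]
#' (half-up, one decimal).
#'
#' @param sets named list (length >= 2) of character vectors of gene
#'   ids.
#' @return list with elements `membership` (logical matrix),
#'   `pairwise` (data frame of [overlap_summary()] rows),
#'   `intersections` (data frame `sets`, `n` with the size of every
#'   k-way intersection, k >= 2), and `in_union_of_rest` (data frame,
#'   `NULL` when only two sets).
#' @export
gene_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)),
            !anyDuplicated(names(sets)))
  sets <- lapply(sets, unique)
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  membership <- matrix(membership, nrow = length(genes),
                       dimnames = list(genes, names(sets)))

  pairwise <- do.call(rbind, apply(utils::combn(names(sets), 2L), 2L, function(p) {
    ab <- length(intersect(sets[[p[1]]], sets[[p[2]]]))
    rbind(.overlap_row(ab, length(sets[[p[1]]]), sprintf("%s_in_%s", p[1], p[2])),
          .overlap_row(ab, length(sets[[p[2]]]), sprintf("%s_in_%s", p[2], p[1])))
  }, simplify = FALSE))

  ks <- unlist(lapply(2:length(sets), function(k) {
    utils::combn(names(sets), k, simplify = FALSE)
  }), recursive = FALSE)
  intersections <- data.frame(
    sets = vapply(ks, paste, character(1L), collapse = "&"),
    n = vapply(ks, function(nm) {
      length(Reduce(intersect, sets[nm]))
    }, numeric(1L)),
    stringsAsFactors = FALSE)

  in_union <- NULL
  if (length(sets) >= 3L) {
    in_union <- do.call(rbind, lapply(names(sets), function(nm) {
      others <- unique(unlist(sets[setdiff(names(sets), nm)], use.names = FALSE))
      .overlap_row(length(intersect(sets[[nm]], others)), length(sets[[nm]]),
                   sprintf("%s_in_union_of_rest", nm))
    }))
  }
  list(membership = membership, pairwise = pairwise,
       intersections = intersections, in_union_of_rest = in_union)
}

# overlap_summary row tolerating an empty reference set
.overlap_row <- function(n_overlap, n_total, label) {
  if (n_total == 0) {
    return(data.frame(comparison = label, n_overlap = n_overlap,
                      n_total = 0, percent = NA_real_,
                      stringsAsFactors = FALSE))
  }
  overlap_summary(n_overlap, n_total, label)
}

#' Log2 fold-change matrix for heat-map export
#'
#' Returns the plain matrix of log2(Mutant/WT) values restricted to
#' genes with `p_value < p_threshold` in at least one genotype
#' (0.05 by default, the looser "significant differential
#' expression" cut used for genome-wide visualization, as opposed to
#' the 0.01 cut of [call_upregulated()]).  Rendering is left to the
#' user.
#'
#' @param tables named list of DE tables, one per genotype.
#' @param p_threshold inclusion threshold (strict `<`).
#' @return numeric matrix genes x genotypes (`NA` where a gene is
#'   absent from a table).
#' @export
de_heatmap_matrix <- function(tables, p_threshold = 0.05) {
  stopifnot(is.list(tables), length(tables) >= 1L, !is.null(names(tables)))
  tables <- lapply(tables, validate_de_table)
  sig <- sort(unique(unlist(lapply(tables, function(de) {
    de$gene_id[de$p_value < p_threshold]
  }), use.names = FALSE)))
  mat <- matrix(NA_real_, nrow = length(sig), ncol = length(tables),
                dimnames = list(sig, names(tables)))
  for (g in names(tables)) {
    mat[, g] <- tables[[g]]$log2fc[match(sig, tables[[g]]$gene_id)]
  }
  mat
}
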