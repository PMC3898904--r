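#' Run the full dependence-classification analysis
#'
#' Convenience wrapper chaining the pipeline stages on an RPTM
#' matrix: low-abundance filtering, Pol IV-dependent region calling
#' (WT vs `nrpd1`), per-mutant "decreased" calls over the Pol
#' IV-dependent universe, the Pol V-dependent/independent partition
#' (via `nrpe1`), and the standard overlap summaries: the fraction
#' of Pol IV-dependent regions decreased in each mutant, and per
#' mutant the fractions of the Pol V-dependent and Pol V-independent
#' groups it decreases.
#'
#' @param rptm an RPTM `bin_matrix` whose columns include `wt` and
#'   `nrpd1`.
#' @param wt,nrpd1,nrpe1 library ids of the wild type and the Pol IV
#'   and Pol V mutants.
#' @param mutants library ids for the per-mutant calls (defaults to
#'   every library except `wt` and `nrpd1`).
#' @param cfg a [region_call_config()].
#' @return list with `retained`, `poliv_regions`, `partition`,
#'   `decreased` (named list of `dependence_call_set`s) and
#'   `summaries` (data frame of [overlap_summary()] rows).
#' @export
classify_regions <- function(rptm, wt = "WT", nrpd1 = "nrpd1", nrpe1 = "nrpe1",
                             mutants = NULL, cfg = region_call_config()) {
  stopifnot(inherits(rptm, "bin_matrix"), rptm$unit == "RPTM")
  libs <- colnames(rptm$values)
  mutants <- mutants %||% setdiff(libs, c(wt, nrpd1))
  if (!nrpe1 %in% mutants) mutants <- c(nrpe1, mutants)

  retained <- filter_low_abundance(rptm, cfg)
  poliv <- call_poliv_dependent(rptm, wt, nrpd1, cfg, retained)
  decreased <- lapply(stats::setNames(mutants, mutants), function(m) {
    call_decreased(rptm, wt, m, cfg, universe = poliv)
  })
  part <- partition_polv(poliv, decreased[[nrpe1]])

  summaries <- list()
  for (m in mutants) {
    dec <- decreased[[m]]$regions
    summaries[[length(summaries) + 1L]] <-
      overlap_summary(dec, poliv, sprintf("%s_decreased_in_polIV_dep", m))
    if (length(part$polv_dependent)) {
      summaries[[length(summaries) + 1L]] <-
        overlap_summary(intersect(dec, part$polv_dependent), part$polv_dependent,
                        sprintf("%s_decreased_in_polV_dep", m))
    }
    if (length(part$polv_independent)) {
      summaries[[length(summaries) + 1L]] <-
        overlap_summary(intersect(dec, part$polv_independent),
                        part$polv_independent,
                        sprintf("%s_decreased_in_polV_indep", m))
    }
  }
  list(retained = retained, poliv_regions = poliv, partition = part,
       decreased = decreased, summaries = do.call(rbind, summaries))
}
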