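---
title: "Classifying Pol IV- and Pol V-dependent siRNA regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Pol IV- and Pol V-dependent siRNA regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnadep)
```

## The analysis

In plants, RNA-directed DNA methylation (RdDM) silences transposons and
repeats through two specialized RNA polymerases.  Pol IV initiates the
biogenesis of 24-nt siRNAs; Pol V — recruited with the help of the DDR
chromatin-remodeling complex and the redundant SRA/SET-domain paralogs
SUVH2 and SUVH9 — produces scaffold transcripts at target loci.  Sequencing
small-RNA libraries from wild type and pathway mutants and asking *where*
24-nt siRNA abundance collapses in each mutant reveals which genomic regions
depend on which factor, and therefore where each factor acts in the pathway.

`sirnadep` implements that comparison as a reusable pipeline:

1. **Binning.** The genome is tiled into consecutive, non-overlapping
   500-bp bins.  Aligned reads are filtered to the 18–27-nt small-RNA
   window (uniquely mapped by default) and the 24-nt reads are counted per
   bin.  Each read increments exactly one bin — the bin containing its
   5'-end base (`start` on the plus strand, `start + length - 1` on the
   minus strand).  5'-end assignment avoids double counting where a read
   spans a bin boundary.  Strand is recorded but pooled for counting.
2. **Normalization.** Counts are scaled to reads per ten million (RPTM):
   `count × 10^7 / library_size`.  The library size is, by default, the
   number of retained (uniquely mapped, 18–27-nt) reads — the mapping
   universe of the analysis.  `bin_count_matrix()` can instead record the
   24-nt-only total (`library_size = "target"`) or the unfiltered alignment
   total (`"total"`); the choice is recorded in the returned object so the
   denominator is always explicit.
3. **Abundance filter.** Bins below 200 RPTM in *every* library are
   removed (strictly below: a bin at exactly 200 RPTM in one library is
   retained).  Filtering precedes dependence calling.
4. **Dependence calling.** A retained bin is a *Pol IV-dependent siRNA
   region* when wild-type RPTM strictly exceeds 5× the `nrpd1` (Pol IV
   mutant) RPTM.  The same fold rule, restricted to the Pol IV-dependent
   universe, defines the bins "decreased" in each downstream mutant
   (`nrpe1`, `dms3`, `suvh2`, `suvh9`, `suvh2suvh9`).  The regions
   decreased in `nrpe1` form the *Pol V-dependent* partition; the
   complement within the Pol IV-dependent set is *Pol V-independent*.
5. **Summaries.** Overlaps between call sets are reported as
   `n_overlap / n_total` with the percentage rounded half-up to one
   decimal; chromosome-scale profiles sum Pol IV-dependent RPTM in
   consecutive 500-kb windows; named loci are quantified relative to a
   control siRNA locus; upregulated-gene sets from RNA-seq tables
   (`log2(Mutant/WT) > 1` and `P < 0.01`, both strict) are intersected
   the same way.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `bin_width` | 500 bp | region resolution; a "region" is a single retained bin |
| `min_len`, `max_len` | 18, 27 nt | small-RNA retention window; retained count = library size |
| `target_len` | 24 nt | the counted heterochromatic-siRNA length |
| `min_rptm` | 200 RPTM | low-abundance floor, applied across all libraries |
| `fold_threshold` | 5 | WT/mutant ratio for "decreased" (strict `>`) |
| `pseudocount` | 0.01 RPTM | added to both sides of the ratio |

Numerical choices worth spelling out:

* **Strict inequalities everywhere.** The fold rule, the abundance floor
  and both DE thresholds use strict comparisons, so boundary cases (ratio
  exactly 5, a bin at exactly 200 RPTM, a gene at log2FC exactly 1 or
  P exactly 0.01) are resolved deterministically and are covered by tests.
* **Pseudocount.** Mutant bins silenced to zero would give an infinite
  ratio; adding 0.01 RPTM to numerator and denominator keeps ratios finite
  and preserves their ordering while being ~4 orders of magnitude below
  the abundance floor, so it never changes a call at retained bins except
  to make zero denominators well defined.
* **Percentage rounding** is half-up at one decimal (`round_half_up()`),
  not banker's rounding, matching how such overlaps are conventionally
  printed.
* **Per-genotype folds.** Only the WT-vs-`nrpd1` threshold is canonical.
  For the downstream mutants the same 5-fold rule is applied by default
  (uniformity being the least surprising choice), but
  `region_call_config(per_genotype_fold = …)` can relax it per genotype,
  because "significantly decreased" is a weaker notion than Pol IV
  dependence and a user may prefer a milder cut.
* **No bin merging.** Adjacent dependent bins are *not* merged into larger
  regions; region counts are at bin granularity.
* **Multi-mapped reads** are dropped (`n_hits == 1`, from the SAM `NH` tag
  when present; `MAPQ > 0` is available as an alternative via
  `unique_by = "mapq"`).  Fractional multi-mapper counting is out of scope.
* Coordinates are 0-based half-open internally; SAM positions are
  converted on ingest so BED and SAM encodings of the same alignments are
  interchangeable.

## What the simulator emulates

`synthetic_spec()` describes a toy multi-genotype experiment whose
structure mirrors the biology the pipeline is meant to detect:

* a genome of 5 chromosomes × 8 Mb (80,000 bins) — a scaled-down
  five-chromosome plant genome, chosen so that chromosome-scale profiles
  and the abundance filter behave as they do at full scale while a full
  run takes seconds;
* three planted locus classes of 100 loci each: `polIV_polV_dep`
  (chromosome arms, lost in `nrpd1`, `nrpe1`, `dms3` and, redundantly, in
  the SUVH pair), `polIV_only` (inside the centered centromeric span,
  lost only in `nrpd1`), and `independent` (arms, unaffected — the
  false-positive control);
* per-locus 24-nt read counts that are Poisson with mean
  `base_rate × multiplier`, `base_rate = 50` in wild type, with
  multipliers `nrpd1 = 0.02`, `nrpe1 = dms3 = 0.05` (arm class only),
  `suvh2 = suvh9 = 0.6` singly and `0.08` jointly — the partial, redundant
  depletion characteristic of a paralog pair;
* a uniform background of 3 × 10^5 reads per library with lengths uniform
  on 18–27 nt.

The background depth is the load-bearing choice.  With ~3.15 × 10^5 reads
per library, 200 RPTM corresponds to ≥ 7 reads in a bin, while the uniform
background deposits only ~0.375 expected 24-nt reads per bin; background
bins therefore essentially never survive the abundance filter
(expected survivors ≪ 1 genome-wide), whereas planted loci sit near
1,600 RPTM in wild type.  This reproduces, at desk scale, the regime of
real multi-million-read libraries, where singleton bins fall far below
the floor.  Deeper backgrounds with the same genome size would instead
put several background reads in every bin and blur the filter — a
sequencing-depth effect users should keep in mind when applying the
5-fold rule to shallow libraries.

Loci are 300 bp, centered within distinct full-width bins, so planted
truth maps 1:1 to bins and recovery can be scored exactly.  Every planted
locus emits reads only within itself; real heterochromatic siRNA loci are
ragged, overlap bin boundaries, and sit in locally repetitive sequence
where unique mapping is biased.  Passing recovery tests therefore shows
the *calling logic* is correct at realistic abundance ratios — not that
mapping artifacts or boundary-straddling loci are handled, which no
simulation of pre-aligned reads can show.

The DE simulator plants true upregulated genes
(`log2FC ~ N(2, 0.5)`, `p ~ U(0, 0.005)`) among nulls
(`log2FC ~ N(0, 0.3)`, `p ~ U(0, 1)`) in tables of 20,000 genes, with
per-genotype set sizes of 361/383/303 and half the smallest set shared
across genotypes — the scale and overlap structure typical of RdDM-mutant
transcriptomes.  About 2.3% of true positives draw a fold change below
the strict threshold, so recall is expected slightly below 1 by design.

All randomness flows from the single `seed` in the spec; the genome,
library and DE stages use `seed`, `seed + 1` and `seed + 2` respectively,
so each stage is reproducible independently of call order, and every file
written by `simulate_to_dir()` records the seed in a `#` header.

## A worked run

```{r run}
spec <- synthetic_spec(seed = 42)
sim <- simulate_genome(spec)
libs <- simulate_libraries(sim$genome, sim$truth, spec)
rptm <- normalize_rptm(bin_count_matrix(libs$reads, sim$genome))
res <- classify_regions(rptm)
length(res$poliv_regions)
lengths(res$partition)
head(res$summaries)
```

Scoring against the planted truth:

```{r score}
truth_dep <- sim$truth$bin_id[sim$truth$class != "independent"]
c(sensitivity = length(intersect(res$poliv_regions, truth_dep)) / length(truth_dep),
  precision   = length(intersect(res$poliv_regions, truth_dep)) /
                  length(res$poliv_regions))
```

## Known limitations

* One library per genotype, as in the experimental design the pipeline
  targets; there is no replicate-aware dispersion model, and "decreased"
  is a fold threshold, not a statistical test.
* Region granularity is the bin; no merging, no sub-bin localization.
* Multi-mapped reads are discarded rather than fractionally assigned, so
  counts at young, high-copy repeats are conservative.
* The relative-accumulation module assumes the control locus is genuinely
  unaffected in every genotype; a perturbed control silently rescales all
  relative values.
* The DE module consumes per-gene tables; expression estimation itself
  (mapping, assembly, FPKM) is out of scope, as are methylation calling
  and annotation against transposon catalogs.
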