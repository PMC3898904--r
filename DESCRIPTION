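Package: sirnadep
Title: Dependence Classification of 24-nt siRNA Regions from
    Multi-Genotype Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies genomic 24-nt short interfering RNA (siRNA)
    regions by their dependence on the plant-specific RNA polymerases
    Pol IV and Pol V and on downstream RNA-directed DNA methylation
    (RdDM) factors, from aligned small-RNA libraries of wild-type and
    mutant genotypes.  Implements fixed-width genome binning,
    reads-per-ten-million (RPTM) normalization, low-abundance
    filtering, fold-change dependence calling between wild type and
    mutants, partitioning of Pol IV-dependent regions into Pol
    V-dependent and Pol V-independent groups with overlap statistics,
    chromosome-scale siRNA profiles, control-locus-normalized siRNA
    quantification, upregulated-gene overlap analysis, and a seeded
    multi-genotype small-RNA simulator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
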