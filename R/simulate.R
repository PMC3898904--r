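#' Default genotype-by-class siRNA effect multipliers
#'
#' Rate multipliers applied to the wild-type siRNA production rate of
#' each planted locus class in each genotype.  They encode the
#' biology the simulator emulates: loss of Pol IV (`nrpd1`) abolishes
#' siRNAs from both Pol IV-dependent classes; loss of Pol V
#' (`nrpe1`) or of the DDR component DMS3 depletes only the
#' chromosome-arm, Pol V-dependent class; the redundant paralogs
#' SUVH2 and SUVH9 each give a mild depletion singly and a strong
#' depletion jointly; the independent class is untouched everywhere.
#'
#' @return numeric matrix, genotypes x classes
#'   (`polIV_polV_dep`, `polIV_only`, `independent`).
#' @export
default_effect_multipliers <- function() {
  classes <- c("polIV_polV_dep", "polIV_only", "independent")
  genotypes <- c("WT", "nrpd1", "nrpe1", "dms3", "suvh2", "suvh9", "suvh2suvh9")
  m <- matrix(1, nrow = length(genotypes), ncol = length(classes),
              dimnames = list(genotypes, classes))
  m["nrpd1", c("polIV_polV_dep", "polIV_only")] <- 0.02
  m["nrpe1", "polIV_polV_dep"] <- 0.05
  m["dms3", "polIV_polV_dep"] <- 0.05
  m["suvh2", "polIV_polV_dep"] <- 0.6
  m["suvh9", "polIV_polV_dep"] <- 0.6
  m["suvh2suvh9", "polIV_polV_dep"] <- 0.08
  m
}

#' Specification of a synthetic multi-genotype siRNA experiment
#'
#' Describes a toy genome with planted siRNA loci of three classes —
#' Pol IV- and Pol V-dependent loci on chromosome arms, Pol
#' IV-dependent but Pol V-independent loci inside the centromeric
#' span, and independent (unaffected) loci — plus a uniform 18-27-nt
#' background, sequenced once per genotype.  Locus read counts are
#' Poisson with rate `base_rate` times the genotype-by-class
#' multiplier.  All randomness flows from `seed`.
#'
#' @param seed RNG seed (integer).
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of each chromosome in bp.
#' @param centromere_fraction fraction of each chromosome (centered)
#'   designated centromeric.
#' @param bin_width genome bin width in bp.
#' @param locus_length planted locus length in bp; must fit inside
#'   one bin so that truth maps 1:1 to bins.
#' @param n_loci named integer vector: loci per class.
#' @param base_rate expected 24-nt reads per planted locus in WT.
#' @param background_rate expected non-locus 18-27-nt reads per
#'   library.
#' @param effect_multipliers genotype x class rate-multiplier matrix
#'   (see [default_effect_multipliers()]); the WT row must be all 1.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 42L,
                           n_chromosomes = 5L,
                           chromosome_length = 8e6,
                           centromere_fraction = 0.2,
                           bin_width = 500L,
                           locus_length = 300L,
                           n_loci = c(polIV_polV_dep = 100L, polIV_only = 100L,
                                      independent = 100L),
                           base_rate = 50,
                           background_rate = 3e5,
                           effect_multipliers = default_effect_multipliers()) {
  .check_scalar(seed, "seed", positive = FALSE, integerish = TRUE)
  .check_scalar(n_chromosomes, "n_chromosomes", integerish = TRUE)
  .check_scalar(chromosome_length, "chromosome_length", integerish = TRUE)
  .check_scalar(bin_width, "bin_width", integerish = TRUE)
  .check_scalar(locus_length, "locus_length", integerish = TRUE)
  .check_scalar(base_rate, "base_rate")
  if (!is.numeric(centromere_fraction) || centromere_fraction < 0 ||
      centromere_fraction >= 1) {
    stop("centromere_fraction must be in [0, 1)", call. = FALSE)
  }
  if (background_rate < 0) stop("background_rate must be >= 0", call. = FALSE)
  if (locus_length > bin_width) {
    stop("locus_length must fit inside one bin", call. = FALSE)
  }
  stopifnot(is.matrix(effect_multipliers),
            !is.null(rownames(effect_multipliers)),
            all(c("polIV_polV_dep", "polIV_only", "independent") %in%
                  colnames(effect_multipliers)))
  if (any(effect_multipliers < 0)) stop("multipliers must be >= 0", call. = FALSE)
  if (!"WT" %in% rownames(effect_multipliers) ||
      any(effect_multipliers["WT", ] != 1)) {
    stop("the WT row of effect_multipliers must be all 1", call. = FALSE)
  }
  if (is.null(names(n_loci)) ||
      !all(names(n_loci) %in% colnames(effect_multipliers))) {
    stop("n_loci must be named by locus class", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = chromosome_length,
                 centromere_fraction = centromere_fraction,
                 bin_width = as.integer(bin_width),
                 locus_length = as.integer(locus_length),
                 n_loci = n_loci,
                 base_rate = base_rate,
                 background_rate = background_rate,
                 effect_multipliers = effect_multipliers),
            class = "synthetic_spec")
}

#' Simulate the toy genome and planted-locus truth table
#'
#' Builds the [genome_index()] and places the planted loci uniformly
#' at random in distinct full-width bins, without overlap:
#' `polIV_only` loci inside the centered centromeric span of bins,
#' the other classes on the arms.  Each locus is centered within its
#' bin, so truth maps 1:1 to bins.  Deterministic given the spec's
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `genome` (a `genome_index`) and `truth` (data
#'   frame `name`, `chrom`, `start`, `end`, `class`, `bin_id`, plus
#'   one `rate_<genotype>` column of expected 24-nt reads per
#'   genotype).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  genome <- genome_index(
    data.frame(chrom = paste0("chr", seq_len(spec$n_chromosomes)),
               length = rep(spec$chromosome_length, spec$n_chromosomes)),
    bin_width = spec$bin_width)
  bins <- genome_bins(genome)
  full <- bins$end - bins$start == spec$bin_width  # exclude truncated terminal bins

  # centered centromeric span, in whole bins per chromosome
  nb <- n_bins(genome)
  centro <- logical(nrow(bins))
  for (chrom in names(nb)) {
    idx <- which(bins$chrom == chrom)
    k <- length(idx)
    n_cen <- round(k * spec$centromere_fraction)
    if (n_cen > 0L) {
      lo <- floor((k - n_cen) / 2) + 1L
      centro[idx[seq.int(lo, length.out = n_cen)]] <- TRUE
    }
  }

  want_cen <- spec$n_loci[names(spec$n_loci) == "polIV_only"]
  if (sum(want_cen) > 0L && !any(centro)) {
    stop("centromeric loci requested but centromere_fraction is 0", call. = FALSE)
  }
  pool_cen <- which(centro & full)
  pool_arm <- which(!centro & full)
  if (sum(want_cen) > length(pool_cen) ||
      sum(spec$n_loci) - sum(want_cen) > length(pool_arm)) {
    stop("not enough bins to place the requested loci without overlap; reduce n_loci",
         call. = FALSE)
  }

  picks <- integer(0)
  classes <- character(0)
  for (cls in names(spec$n_loci)) {
    n <- spec$n_loci[[cls]]
    if (n == 0L) next
    pool <- if (cls == "polIV_only") setdiff(pool_cen, picks)
            else setdiff(pool_arm, picks)
    sel <- pool[sample.int(length(pool), n)]
    picks <- c(picks, sel)
    classes <- c(classes, rep(cls, n))
  }
  ord <- order(picks)
  picks <- picks[ord]
  classes <- classes[ord]

  offset <- (spec$bin_width - spec$locus_length) %/% 2L
  truth <- data.frame(
    name = sprintf("locus_%04d", seq_along(picks)),
    chrom = bins$chrom[picks],
    start = bins$start[picks] + offset,
    end = bins$start[picks] + offset + spec$locus_length,
    class = classes,
    bin_id = bins$bin_id[picks],
    stringsAsFactors = FALSE)
  for (g in rownames(spec$effect_multipliers)) {
    truth[[paste0("rate_", g)]] <-
      spec$base_rate * spec$effect_multipliers[g, truth$class]
  }
  list(genome = genome, truth = truth)
}

#' Simulate one aligned small-RNA library per genotype
#'
#' For each genotype, every planted locus emits a Poisson number of
#' 24-nt reads (rate = `base_rate` x the genotype/class multiplier)
#' whose 5' ends are uniform within the locus and whose strands are
#' random; background reads (Poisson, `background_rate` expected per
#' library) have lengths uniform on 18-27 nt and positions uniform on
#' the genome.  All reads are uniquely mapped (`n_hits = 1`).
#' Deterministic given the spec's seed.
#'
#' @param genome,truth output of [simulate_genome()].
#' @param spec the same [synthetic_spec()].
#' @return list with `reads` (named list of aligned-read data frames,
#'   one per genotype) and `profiles` (data frame `library_id`,
#'   `genotype`, `library_size` where `library_size` is the total
#'   emitted reads).
#' @export
simulate_libraries <- function(genome, truth, spec) {
  stopifnot(inherits(genome, "genome_index"), inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  lens <- .chrom_len(genome)
  genotypes <- rownames(spec$effect_multipliers)
  reads <- stats::setNames(vector("list", length(genotypes)), genotypes)
  for (g in genotypes) {
    rate <- spec$base_rate * spec$effect_multipliers[g, truth$class]
    n_per_locus <- stats::rpois(nrow(truth), rate)
    tot <- sum(n_per_locus)
    li <- rep.int(seq_len(nrow(truth)), n_per_locus)
    fivep <- truth$start[li] +
      floor(stats::runif(tot) * (truth$end[li] - truth$start[li]))
    strand <- sample(c("+", "-"), tot, replace = TRUE)
    planted <- data.frame(chrom = truth$chrom[li],
                          start = as.integer(ifelse(strand == "-", fivep - 23L, fivep)),
                          length = rep(24L, tot), strand = strand,
                          n_hits = rep(1L, tot), stringsAsFactors = FALSE)

    nb <- stats::rpois(1L, spec$background_rate)
    bg_len <- sample(18:27, nb, replace = TRUE)
    bg_chrom <- sample(names(lens), nb, replace = TRUE,
                       prob = lens / sum(lens))
    bg_start <- floor(stats::runif(nb) * (lens[bg_chrom] - bg_len + 1))
    background <- data.frame(chrom = bg_chrom, start = as.integer(bg_start),
                             length = bg_len,
                             strand = sample(c("+", "-"), nb, replace = TRUE),
                             n_hits = rep(1L, nb), stringsAsFactors = FALSE)
    lib <- rbind(planted, background)
    rownames(lib) <- NULL
    reads[[g]] <- lib
  }
  profiles <- data.frame(library_id = genotypes, genotype = genotypes,
                         library_size = vapply(reads, nrow, integer(1L)),
                         stringsAsFactors = FALSE)
  rownames(profiles) <- NULL
  list(reads = reads, profiles = profiles)
}

#' Simulate per-genotype differential-expression tables
#'
#' For each genotype, `n_true_up` genes are truly upregulated (log2
#' fold change ~ Normal(2, 0.5), p ~ Uniform(0, 0.005)); the rest are
#' null (log2 fold change ~ Normal(0, 0.3), p ~ Uniform(0, 1)).  A
#' designated fraction of the true-up genes is shared across all
#' genotypes; the remainder is drawn per genotype from the non-shared
#' pool.  Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()] (only its seed is used).
#' @param n_genes genes per table.
#' @param n_true_up named integer vector: truly upregulated genes per
#'   genotype.
#' @param shared_fraction fraction (of the smallest `n_true_up`)
#'   shared across all genotypes.
#' @return list with `tables` (named list of DE data frames) and
#'   `truth` (named list of true-up gene-id vectors).
#' @export
simulate_de_tables <- function(spec, n_genes = 20000L,
                               n_true_up = c(nrpe1 = 361L, dms3 = 383L,
                                             suvh2suvh9 = 303L),
                               shared_fraction = 0.5) {
  stopifnot(inherits(spec, "synthetic_spec"),
            !is.null(names(n_true_up)), all(n_true_up <= n_genes),
            shared_fraction >= 0, shared_fraction <= 1)
  set.seed(spec$seed + 2L)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  n_shared <- round(shared_fraction * min(n_true_up))
  shared <- sample(genes, n_shared)
  rest_pool <- setdiff(genes, shared)

  truth <- lapply(n_true_up, function(n) {
    sort(c(shared, sample(rest_pool, n - n_shared)))
  })
  tables <- lapply(truth, function(up) {
    is_up <- genes %in% up
    lfc <- stats::rnorm(n_genes, 0, 0.3)
    p <- stats::runif(n_genes)
    lfc[is_up] <- stats::rnorm(sum(is_up), 2, 0.5)
    p[is_up] <- stats::runif(sum(is_up), 0, 0.005)
    data.frame(gene_id = genes, log2fc = lfc, p_value = p,
               stringsAsFactors = FALSE)
  })
  list(tables = tables, truth = truth)
}

#' Write a full synthetic experiment to disk
#'
#' Emits `chrom.sizes`, `truth.tsv`, one BED of aligned reads per
#' genotype and `profiles.tsv` into a directory; every file carries
#' the seed in a '#' header.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param de also write synthetic DE tables (`de_<genotype>.tsv`)?
#' @return invisibly, a list of the written paths.
#' @export
simulate_to_dir <- function(spec, dir, de = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- sprintf("seed: %d", spec$seed)
  sim <- simulate_genome(spec)
  libs <- simulate_libraries(sim$genome, sim$truth, spec)
  paths <- list(chrom_sizes = file.path(dir, "chrom.sizes"),
                truth = file.path(dir, "truth.tsv"),
                profiles = file.path(dir, "profiles.tsv"))
  write_chrom_sizes(sim$genome, paths$chrom_sizes, meta)
  write_tsv(sim$truth, paths$truth, meta)
  write_tsv(libs$profiles, paths$profiles, meta)
  for (g in names(libs$reads)) {
    p <- file.path(dir, paste0(g, ".bed"))
    write_reads_bed(libs$reads[[g]], p, meta)
    paths[[paste0("reads_", g)]] <- p
  }
  if (de) {
    det <- simulate_de_tables(spec)
    for (g in names(det$tables)) {
      p <- file.path(dir, paste0("de_", g, ".tsv"))
      write_tsv(det$tables[[g]], p, meta)
      paths[[paste0("de_", g)]] <- p
    }
  }
  invisible(paths)
}
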