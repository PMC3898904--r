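test_that("genome simulation is seed-deterministic with valid, class-placed loci", {
  spec <- small_spec(seed = 1L)
  sim1 <- simulate_genome(spec)
  sim2 <- simulate_genome(spec)
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(sim1$genome$chromosomes, sim2$genome$chromosomes)
  expect_equal(nrow(sim1$truth), 30L)

  truth <- sim1$truth
  # non-overlapping: one locus per bin, each fully inside its 500-bp bin
  expect_false(anyDuplicated(truth$bin_id) > 0)
  bins <- genome_bins(sim1$genome)
  b <- bins[match(truth$bin_id, bins$bin_id), ]
  expect_true(all(truth$start >= b$start & truth$end <= b$end))
  # centromeric class inside the centered span, arm classes outside
  nb <- n_bins(sim1$genome)[1]
  cen_lo <- (floor((nb - round(nb * 0.2)) / 2)) * 500
  cen_hi <- cen_lo + round(nb * 0.2) * 500
  cen <- truth[truth$class == "polIV_only", ]
  arm <- truth[truth$class != "polIV_only", ]
  expect_true(all(cen$start >= cen_lo & cen$end <= cen_hi))
  expect_true(all(arm$end <= cen_lo | arm$start >= cen_hi))
  # expected-rate columns reflect the multipliers
  expect_equal(truth$rate_WT, rep(50, 30))
  expect_equal(unique(truth$rate_nrpd1[truth$class != "independent"]), 1)

  other_seed <- simulate_genome(small_spec(seed = 2L))
  expect_false(identical(other_seed$truth$bin_id, sim1$truth$bin_id))
})

test_that("impossible placements raise informative errors", {
  expect_error(simulate_genome(small_spec(centromere_fraction = 0)),
               "centromere_fraction is 0")
  expect_error(
    simulate_genome(synthetic_spec(seed = 1, n_chromosomes = 1L,
                                   chromosome_length = 5000,
                                   n_loci = c(polIV_polV_dep = 50L,
                                              polIV_only = 0L,
                                              independent = 0L))),
    "reduce n_loci")
  expect_error(synthetic_spec(locus_length = 600), "fit inside one bin")
  expect_error(synthetic_spec(effect_multipliers = {
    m <- default_effect_multipliers(); m["WT", 1] <- 2; m
  }), "WT row")
})

test_that("library simulation follows the planted Poisson rates", {
  spec <- small_spec(seed = 3L)
  sim <- simulate_genome(spec)
  libs1 <- simulate_libraries(sim$genome, sim$truth, spec)
  libs2 <- simulate_libraries(sim$genome, sim$truth, spec)
  expect_identical(libs1$reads, libs2$reads)
  expect_equal(libs1$profiles$library_size,
               unname(vapply(libs1$reads, nrow, integer(1))))

  # a zeroed multiplier silences every planted locus in that genotype
  m <- default_effect_multipliers()
  m["nrpd1", c("polIV_polV_dep", "polIV_only")] <- 0
  spec0 <- small_spec(seed = 3L, effect_multipliers = m)
  sim0 <- simulate_genome(spec0)
  libs0 <- simulate_libraries(sim0$genome, sim0$truth, spec0)
  dep_loci <- sim0$truth[sim0$truth$class != "independent", ]
  n_at_loci <- sum(vapply(seq_len(nrow(dep_loci)), function(i) {
    count_locus(libs0$reads$nrpd1, dep_loci[i, ])
  }, integer(1)))
  # only background reads can fall there; none of the planted 24-nt bursts
  bg_expect <- spec0$background_rate * 0.1 *
    nrow(dep_loci) * 300 / sum(sim0$genome$chromosomes$length)
  expect_true(n_at_loci <= stats::qpois(0.999, bg_expect) + 1)

  # Poisson totals: 200 WT loci at rate 50 -> within 3 SD of 10,000
  spec200 <- synthetic_spec(seed = 5L, n_chromosomes = 2L,
                            chromosome_length = 1e6,
                            n_loci = c(polIV_polV_dep = 100L, polIV_only = 100L,
                                       independent = 0L),
                            background_rate = 0)
  sim200 <- simulate_genome(spec200)
  libs200 <- simulate_libraries(sim200$genome, sim200$truth, spec200)
  total <- nrow(libs200$reads$WT)
  expect_true(abs(total - 10000) <= 3 * sqrt(10000))

  # different seed: different placements, same expected scale
  libs_b <- simulate_libraries(sim$genome, sim$truth, small_spec(seed = 4L))
  expect_false(identical(libs_b$reads$WT, libs1$reads$WT))
})

test_that("DE simulation plants shared true-up genes and calibrated nulls", {
  spec <- small_spec(seed = 6L)
  de1 <- simulate_de_tables(spec)
  de2 <- simulate_de_tables(spec)
  expect_identical(de1$tables, de2$tables)
  expect_equal(vapply(de1$truth, length, integer(1)),
               c(nrpe1 = 361L, dms3 = 383L, suvh2suvh9 = 303L))
  shared <- Reduce(intersect, de1$truth)
  expect_gte(length(shared), round(0.5 * 303))

  # shared_fraction 1 with equal sizes -> identical true-up sets
  all_shared <- simulate_de_tables(spec, n_genes = 1000,
                                   n_true_up = c(a = 50L, b = 50L),
                                   shared_fraction = 1)
  expect_identical(all_shared$truth$a, all_shared$truth$b)

  # pure-null tables: |upregulated| is near n_genes * P(p < .01) * P(lfc > 1)
  null_de <- simulate_de_tables(spec, n_genes = 20000,
                                n_true_up = c(a = 0L), shared_fraction = 0)
  n_up <- length(call_upregulated(null_de$tables$a))
  # analytic bound: Binomial(20000, 0.01 * P(N(0,0.3) > 1)), mean ~ 0.086
  expect_lte(n_up, stats::qbinom(0.999, 20000,
                                 0.01 * stats::pnorm(1, 0, 0.3, lower.tail = FALSE)))

  # recovery through the caller: planted truth is found near-completely
  called <- lapply(de1$tables, call_upregulated)
  for (g in names(called)) {
    recall <- length(intersect(called[[g]], de1$truth[[g]])) /
      length(de1$truth[[g]])
    expect_gte(recall, 0.9)  # ~2.3% of true-ups draw log2fc below 1
    precision <- length(intersect(called[[g]], de1$truth[[g]])) /
      length(called[[g]])
    expect_gte(precision, 0.99)
  }
})
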