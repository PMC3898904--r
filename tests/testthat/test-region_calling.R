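test_that("low-abundance filter removes a bin only when below threshold everywhere", {
  rptm <- toy_rptm(rbind(c(150, 180, 100),   # below in all -> removed
                         c(250, 0, 0),       # reaches it once -> retained
                         c(200, 0, 0),       # boundary: 200 is not < 200
                         c(199.999, 0, 0)))  # strictly below everywhere
  kept <- filter_low_abundance(rptm, region_call_config())
  expect_equal(kept, rptm$bins$bin_id[c(2, 3)])
})

test_that("the fold rule is a strict ratio with a pseudocount", {
  cfg <- region_call_config()
  rptm <- toy_rptm(cbind(WT = c(1000, 400, 300, 500, 500),
                         nrpd1 = c(100, 100, 0, 100, 99.99)))
  universe <- rptm$bins$bin_id
  called <- call_poliv_dependent(rptm, "WT", "nrpd1", cfg, universe)
  # ratio 10 -> called; ratio 4 -> not; mutant zero -> (300.01)/(0.01) -> called
  # ratio exactly 5 (500.05 vs 5 * 100.01... not exact) use explicit boundary:
  expect_true(universe[1] %in% called)
  expect_false(universe[2] %in% called)
  expect_true(universe[3] %in% called)
  # exact-equality boundary: WT = fold * mutant + (fold-1) * pc is NOT called
  pc <- cfg$pseudocount
  exact <- toy_rptm(cbind(WT = 5 * (100 + pc) - pc, nrpd1 = 100))
  expect_length(call_poliv_dependent(exact, "WT", "nrpd1", cfg,
                                     exact$bins$bin_id), 0L)
  expect_error(call_poliv_dependent(rptm, "WT", "missing", cfg, universe),
               "'missing' not found")
})

test_that("per-mutant decreased calls honour genotype fold overrides and the universe", {
  rptm <- toy_rptm(cbind(WT = c(500, 500, 500), dms3 = c(50, 400, 50)))
  cfg <- region_call_config()
  calls <- call_decreased(rptm, "WT", "dms3", cfg, universe = rptm$bins$bin_id[1:2])
  expect_s3_class(calls, "dependence_call_set")
  expect_equal(calls$genotype, "dms3")
  expect_equal(calls$regions, rptm$bins$bin_id[1])  # bin 3 outside the universe
  # identical columns -> ratio 1 -> empty set
  same <- toy_rptm(cbind(WT = c(100, 300), m = c(100, 300)))
  expect_length(call_decreased(same, "WT", "m",
                               universe = same$bins$bin_id)$regions, 0L)
  # a genotype-specific fold of 2 relaxes the call
  relaxed <- region_call_config(per_genotype_fold = c(dms3 = 2))
  r2 <- toy_rptm(cbind(WT = 500, dms3 = 200))
  expect_length(call_decreased(r2, "WT", "dms3", relaxed,
                               universe = r2$bins$bin_id)$regions, 1L)
  expect_length(call_decreased(r2, "WT", "dms3", cfg,
                               universe = r2$bins$bin_id)$regions, 0L)
})

test_that("raising the fold threshold never enlarges a call set", {
  set.seed(31)
  for (rep in 1:5) {
    rptm <- toy_rptm(cbind(WT = rexp(50, 1 / 300), mut = rexp(50, 1 / 150)))
    u <- rptm$bins$bin_id
    folds <- c(1.5, 2, 5, 10, 50)
    sets <- lapply(folds, function(f) {
      call_decreased(rptm, "WT", "mut", region_call_config(fold_threshold = f),
                     universe = u)$regions
    })
    for (i in seq_along(sets)[-1]) {
      expect_true(all(sets[[i]] %in% sets[[i - 1]]))
    }
  }
})

test_that("the Pol V partition is a disjoint union of the Pol IV-dependent set", {
  set.seed(13)
  for (rep in 1:10) {
    universe <- sprintf("bin%03d", sample(500, 80))
    dec <- sample(universe, sample(0:80, 1))
    part <- partition_polv(universe, dec)
    expect_length(intersect(part$polv_dependent, part$polv_independent), 0L)
    expect_setequal(c(part$polv_dependent, part$polv_independent), universe)
    expect_equal(length(part$polv_dependent) + length(part$polv_independent),
                 length(universe))
  }
  all_bins <- sprintf("b%d", 1:10)
  expect_equal(partition_polv(all_bins, character(0))$polv_independent, all_bins)
  expect_equal(partition_polv(all_bins, all_bins)$polv_dependent, all_bins)
})

test_that("overlap summaries report half-up one-decimal percentages", {
  expect_equal(overlap_summary(3670, 5751)$percent, 63.8)
  expect_equal(overlap_summary(3264, 3670)$percent, 88.9)
  expect_equal(overlap_summary(0, 10)$percent, 0)
  expect_equal(overlap_summary(1, 1600)$percent, 0.1)  # 0.0625% -> 0.1 half-up
  expect_equal(overlap_summary(1, 4000)$percent, 0)    # 0.025% -> 0.0
  sets <- overlap_summary(c("a", "b"), c("a", "b", "c"), "pair")
  expect_equal(sets$n_overlap, 2)
  expect_equal(sets$percent, 66.7)
  expect_error(overlap_summary("a", c("b", "c")), "subset")
  expect_error(overlap_summary(character(0), character(0)), "empty universe")
  expect_error(overlap_summary(5, 3), "n_overlap")
})

test_that("chromosome profiles sum dependent-bin RPTM per 500-kb window", {
  g <- toy_genome(c(chr1 = 1.2e6), bin_width = 500L)
  bins <- genome_bins(g)
  vals <- matrix(0, nrow(bins), 2, dimnames = list(bins$bin_id, c("WT", "nrpe1")))
  vals[1, ] <- c(300, 30)        # window 1
  vals[3, ] <- c(200, 20)        # window 1
  vals[1001, ] <- c(111, 11)     # start 500000 -> window 2
  rptm <- structure(list(bins = bins, values = vals,
                         libraries = data.frame(library_id = c("WT", "nrpe1"),
                                                genotype = c("WT", "nrpe1"),
                                                library_size = c(1e7, 1e7)),
                         unit = "RPTM"), class = "bin_matrix")
  dep <- rownames(vals)[c(1, 3, 1001)]
  prof <- chromosome_profile(rptm, dep, g)
  expect_equal(prof$window_start, c(0, 5e5, 1e6))
  expect_equal(prof$window_end, c(5e5, 1e6, 1.2e6))
  expect_equal(prof$WT, c(500, 111, 0))
  expect_equal(prof$nrpe1, c(50, 11, 0))
  # restricting the dependent set drops its contribution
  prof2 <- chromosome_profile(rptm, dep[1], g)
  expect_equal(prof2$WT, c(300, 0, 0))
})
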