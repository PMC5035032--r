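# deviation metrics, zone confusion matrix, sweeps, clinical-table summaries

test_that("deviation metrics behave as absolute / relative errors", {
  expect_equal(deviation_e1(0.10, 0.11), 1.0)
  expect_equal(deviation_e1(0.035, 0.035), 0)
  expect_equal(deviation_e1(0.077, 0.113), 3.6)
  expect_equal(deviation_e1(0.113, 0.077), 3.6)  # symmetric in sign
  expect_equal(deviation_e2(0.10, 0.11), 0.10)
  expect_equal(deviation_e2(0.20, 0.20), 0)
  expect_equal(deviation_e2(0.05, 0.0), 1.0)
  expect_equal(deviation_e2(0.11, 0.10), deviation_e2(0.11, 0.12))
  expect_error(deviation_e2(0, 0.1), "undefined")
})

test_that("zone sensitivity/specificity read the confusion matrix with AAab positive", {
  loci <- snp_counts("chr1", 1:4, "A", c("G", "G", "G", "."),
                     c(180, 178, 120, 200), c(20, 22, 80, 0))
  labels <- factor(c("AAab", "AAab", "ABab", "AAaa"),
                   levels = c("AAaa", "AAab", "ABaa", "ABab"))
  ds <- structure(list(loci = loci, labels = labels), class = "sim_dataset")
  ss <- zone_sensitivity_specificity(ds, build_boundaries(200))
  expect_equal(unname(ss), c(100, 100))
  ds$labels <- factor(c("AAaa", "AAaa", "ABab", "AAaa"), levels = levels(labels))
  expect_error(zone_sensitivity_specificity(ds), "AAab")
})

test_that("sensitivity degrades at low fraction and is monotone in f", {
  mean_sens <- vapply(c(0.02, 0.10, 0.20), function(f) {
    mean(vapply(1:5, function(r) {
      ds <- simulate_dataset(sim_params(n_loci = 4000L, D = 65, f = f,
                                        seed = 700L + 10L * r))
      zone_sensitivity_specificity(ds)[["sensitivity"]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sens) > 0))
  expect_lt(mean_sens[1], 50)
  ss <- zone_sensitivity_specificity(
    simulate_dataset(sim_params(n_loci = 4000L, D = 65, f = 0.10, seed = 7)))
  expect_true(all(ss >= 0 & ss <= 100))
})

test_that("depth sweep reports decreasing deviation and a minimal depth", {
  sw <- min_depth_sweep(f = 0.035, n_loci = 3000L,
                        depths = seq(50, 150, by = 25), n_reps = 4L,
                        seed = 31L, model = tiny_model())
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw$points), 5L)
  expect_true(all(diff(sw$points$depth) > 0))
  # a generous criterion is met at the first swept depth
  sw_loose <- min_depth_sweep(f = 0.035, n_loci = 1000L,
                              depths = c(60, 80), n_reps = 2L, seed = 32L,
                              criterion = 100, model = tiny_model())
  expect_equal(sw_loose$minimal, 60)
  # an impossible criterion reports no minimal depth
  sw_none <- min_depth_sweep(f = 0.035, n_loci = 1000L, depths = c(60, 80),
                             n_reps = 2L, seed = 32L, criterion = 0,
                             model = tiny_model())
  expect_true(is.na(sw_none$minimal))
})

test_that("SNP-count sweep tracks the zone census alongside the deviation", {
  sw <- min_snps_sweep(D = 65, f = 0.10, loci_counts = c(250, 1000, 4000),
                       n_reps = 4L, seed = 33L, model = tiny_model())
  expect_equal(sw$points$n_loci, c(250, 1000, 4000))
  expect_true(all(diff(sw$points$mean_zone_loci) > 0))
  # census threshold reading: smallest count whose zone holds > 30 loci
  expect_true(is.na(sw$minimal_by_zone) ||
                sw$points$mean_zone_loci[match(sw$minimal_by_zone,
                                               sw$points$n_loci)] > 30)
  expect_equal(min_snps_sweep(D = 65, f = 0.10, loci_counts = c(250, 1000),
                              n_reps = 2L, seed = 34L, criterion = 10,
                              model = tiny_model())$minimal, 250)
})

test_that("sweep results serialise to TSV", {
  sw <- min_depth_sweep(f = 0.05, n_loci = 500L, depths = c(60, 90),
                        n_reps = 2L, seed = 35L, model = tiny_model())
  path <- tempfile(fileext = ".tsv")
  write_sweep_tsv(sw, path)
  back <- read.delim(path)
  expect_equal(back$depth, sw$points$depth)
  expect_equal(back$mean_e1, sw$points$mean_e1)
})

test_that("the packaged clinical table has the published structure", {
  tab <- clinical_table()
  expect_equal(nrow(tab), 18L)
  expect_equal(sum(tab$depth < 100), 8L)
  expect_equal(sum(!is.na(tab$corrected_cff)), 8L)
  expect_true(all(tab$sensitivity >= 0 & tab$sensitivity <= 100))
})

test_that("clinical-table summaries reproduce the published medians", {
  s <- summarize_clinical_table(clinical_table())
  expect_equal(s$median_depth, 125)
  expect_equal(s$pre_correction$median, 1.8)
  expect_equal(c(s$pre_correction$min, s$pre_correction$max), c(0.6, 3.6))
  expect_equal(s$post_correction$median, 0.65)
  expect_equal(c(s$post_correction$min, s$post_correction$max), c(0.2, 2.1))
  expect_equal(s$median_final_deviation, 0.35)
})

test_that("low-depth rows without a corrected value are excluded with a warning", {
  tab <- clinical_table()
  tab$corrected_cff[tab$sample == "p-1"] <- NA
  expect_warning(s <- summarize_clinical_table(tab), "excluded")
  expect_equal(s$post_correction$median, 0.7)  # median of the remaining 7
})
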