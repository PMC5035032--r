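# boundary geometry, per-locus estimator, median aggregation, chrY estimator

counts_grid <- function(x, y) {
  keep <- x >= y
  n <- sum(keep)
  snp_counts(rep("chr1", n), seq_len(n), rep("A", n),
             ifelse(y[keep] > 0, "G", "."), x[keep], y[keep])
}

# independent re-derivation of the zone inequalities from the line
# equations: Line 1 y = x/3; Line 2 y = (x+y)e + k*sqrt(e(x+y));
# Lines 3/4 x + y = D -/+ 3*sqrt(D)
oracle_in_zone <- function(x, y, D, e) {
  k <- if (D < 100) 2 else 3
  ok1 <- y <= x / 3
  ok2 <- y > (x + y) * e + k * sqrt(e * (x + y))
  ok34 <- (x + y) >= D - 3 * sqrt(D) & (x + y) <= D + 3 * sqrt(D)
  ok1 && ok2 && ok34
}

test_that("sample depth is the median of per-locus totals", {
  mk <- function(tot) counts_grid(tot, rep(0, length(tot)))
  expect_equal(estimate_sample_depth(mk(c(100, 120, 110))), 110)
  expect_equal(estimate_sample_depth(mk(c(100, 120))), 110)
  expect_equal(estimate_sample_depth(mk(50)), 50)
  expect_error(estimate_sample_depth(mk(numeric(0))), "no loci")
})

test_that("the error-line multiplier relaxes below 100-fold", {
  expect_equal(build_boundaries(150)$k_error, 3)
  expect_equal(build_boundaries(65)$k_error, 2)
  expect_equal(build_boundaries(100)$k_error, 3)  # 'less than 100' is strict
  expect_equal(build_boundaries(99.9)$k_error, 2)
  expect_error(build_boundaries(0), "positive")
  expect_error(build_boundaries(150, e = 0), "in \\(0, 1\\)")
})

test_that("zone membership matches hand-computed thresholds", {
  b <- build_boundaries(200, e = 0.01)
  # (190, 10): error line 200*0.01 + 3*sqrt(2) = 6.24 < 10; 10 <= 63.3;
  # window [157.6, 242.4] holds 200
  expect_true(in_targeted_zone(counts_grid(190, 10), b))
  expect_false(in_targeted_zone(counts_grid(100, 0), b))   # at error floor
  expect_false(in_targeted_zone(counts_grid(90, 40), build_boundaries(130)))
  expect_false(in_targeted_zone(counts_grid(300, 10), b))  # out of window
})

test_that("zone membership equals the brute-force oracle on an integer grid", {
  for (D in c(65, 130)) {
    b <- build_boundaries(D)
    xs <- 0:(2 * D)
    for (y in c(0:10, seq(12, 60, by = 3))) {
      x <- xs[xs >= y]
      got <- in_targeted_zone(counts_grid(x, rep(y, length(x))), b)
      want <- vapply(x, function(xi) oracle_in_zone(xi, y, D, 0.01), TRUE)
      expect_equal(got, want)
    }
  }
})

test_that("accepted loci always imply a fraction at most 0.5", {
  set.seed(31)
  for (D in c(65, 120, 200)) {
    b <- build_boundaries(D)
    x <- rpois(4000, D * 0.9)
    y <- pmin(rpois(4000, D * 0.12), x)
    loci <- counts_grid(x, y)
    inside <- in_targeted_zone(loci, b)
    if (any(inside))
      expect_lte(max(locus_fetal_fraction(loci$x[inside], loci$y[inside])), 0.5)
  }
})

test_that("lowering e never shrinks the accepted set", {
  set.seed(32)
  x <- rpois(3000, 60)
  y <- pmin(rpois(3000, 6), x)
  loci <- counts_grid(x, y)
  inside_hi <- in_targeted_zone(loci, build_boundaries(65, e = 0.02))
  inside_lo <- in_targeted_zone(loci, build_boundaries(65, e = 0.005))
  expect_true(all(inside_lo[inside_hi]))
})

test_that("per-locus fraction follows 2y/(x+y)", {
  expect_equal(locus_fetal_fraction(95, 5), 0.10)
  expect_equal(locus_fetal_fraction(50, 50), 1.0)
  expect_equal(locus_fetal_fraction(75, 25), 0.5)
  expect_error(locus_fetal_fraction(0, 0), "zero depth")
})

test_that("pipeline recovers the fraction at high depth and high f", {
  ds <- simulate_dataset(sim_params(D = 150, f = 0.15, seed = 101))
  est <- estimate_fetal_fraction(ds$loci)
  expect_s3_class(est, "fetal_fraction_estimate")
  expect_lt(abs(est$f_raw - 0.15), 0.01)
  expect_false(est$corrected)
  expect_false(est$low_confidence)
  expect_equal(est$f_raw, median(est$per_locus_f))
  expect_equal(est$n_effective, length(est$per_locus_f))
})

test_that("all-homozygous samples have no effective SNPs", {
  set.seed(33)
  x <- rpois(2000, 150)
  y <- rbinom(2000, x, 0.002)  # error-level minor counts only
  loci <- counts_grid(pmax(x, y), pmin(x, y))
  expect_error(estimate_fetal_fraction(loci), "no effective SNPs")
})

test_that("correction triggers below 100-fold or below 10 percent", {
  ds_low <- simulate_dataset(sim_params(D = 65, f = 0.12, seed = 5))
  expect_warning(est <- estimate_fetal_fraction(ds_low$loci), "no correction model")
  expect_false(est$corrected)
  est2 <- suppressWarnings(estimate_fetal_fraction(ds_low$loci,
                                                   model = tiny_model()))
  expect_true(est2$corrected)
  expect_true(is.finite(est2$f_corrected))
  expect_equal(final_fraction(est2), est2$f_corrected)
  # high depth + high fraction: never corrected, even with a model
  ds_hi <- simulate_dataset(sim_params(D = 150, f = 0.15, seed = 6))
  est3 <- estimate_fetal_fraction(ds_hi$loci, model = tiny_model())
  expect_false(est3$corrected)
  expect_equal(final_fraction(est3), est3$f_raw)
})

test_that("estimates serialise to JSON with both unit conventions", {
  ds <- simulate_dataset(sim_params(D = 150, f = 0.15, seed = 8))
  est <- estimate_fetal_fraction(ds$loci)
  parsed <- jsonlite::fromJSON(estimate_to_json(est))
  expect_equal(parsed$f_raw, est$f_raw)
  expect_equal(parsed$f_raw_percent, 100 * est$f_raw)
  expect_equal(parsed$n_effective, est$n_effective)
  expect_false(parsed$corrected)
})

test_that("chrY coverage scales to the diploid mixture and clamps", {
  expect_equal(estimate_fraction_chrY(10, 200), 0.10)
  expect_equal(estimate_fraction_chrY(0, 200), 0)
  expect_equal(estimate_fraction_chrY(100, 200), 1.0)
  expect_error(estimate_fraction_chrY(numeric(0), 200), "chrY")
})

test_that("chrY estimator recovers f on simulated male-fetus coverage", {
  set.seed(34)
  D <- 200
  for (f in c(0.05, 0.10, 0.20)) {
    chrY <- rpois(2000, f * D / 2)
    auto <- rpois(8000, D)
    expect_lt(abs(estimate_fraction_chrY(chrY, auto) - f), 0.01)
  }
})
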