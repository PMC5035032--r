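#' Deviation metrics between standard and deduced fetal fractions
#'
#' `deviation_e1` is the absolute deviation expressed in percentage
#' points; `deviation_e2` is the deviation relative to the standard
#' value (a fraction: 0.10 means the estimate is off by 10% of the true
#' value).
#'
#' @param standard_f true (standard) fetal fraction, in [0, 1].
#' @param deduced_f estimated fetal fraction, in [0, 1].
#' @return `deviation_e1`: percentage points; `deviation_e2`: relative
#'   fraction.
#' @export
deviation_e1 <- function(standard_f, deduced_f) {
  100 * abs(standard_f - deduced_f)
}

#' @rdname deviation_e1
#' @export
deviation_e2 <- function(standard_f, deduced_f) {
  if (any(standard_f == 0)) stop("relative deviation undefined at standard_f = 0")
  abs(standard_f - deduced_f) / standard_f
}

#' Zone sensitivity and specificity on a labelled dataset
#'
#' With the effective category AAab as the positive class: sensitivity is
#' the percentage of true AAab loci inside the targeted zone, specificity
#' the percentage of non-AAab loci outside it.
#'
#' @param ds a `sim_dataset` (or any list with `loci` and `labels`).
#' @param boundaries a `zone_boundaries` object; default builds them from
#'   the dataset's own median depth.
#' @return Named numeric vector `c(sensitivity, specificity)`, in
#'   percent.
#' @export
zone_sensitivity_specificity <- function(ds, boundaries = NULL) {
  if (is.null(boundaries))
    boundaries <- build_boundaries(estimate_sample_depth(ds$loci))
  pos <- ds$labels == "AAab"
  if (!any(pos)) stop("dataset has no AAab loci; sensitivity undefined")
  inside <- in_targeted_zone(ds$loci, boundaries)
  sens <- 100 * sum(inside & pos) / sum(pos)
  spec <- if (any(!pos)) 100 * sum(!inside & !pos) / sum(!pos) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Minimum-depth sweep
#'
#' Simulates datasets over a grid of sequencing depths at a fixed fetal
#' fraction, estimates each with the corrected estimator, and reports the
#' mean absolute deviation e1 (percentage points) per depth. The minimal
#' depth is the smallest swept depth whose mean e1 falls below the
#' criterion.
#'
#' @param f true fetal fraction; default 0.035.
#' @param n_loci loci per dataset; default 11000.
#' @param depths depth grid; default 40 to 200 in steps of 5.
#' @param n_reps replicates per depth; default 20.
#' @param seed base seed; replicate seeds are derived from it.
#' @param criterion e1 threshold in percentage points; default 1.
#' @param model a `correction_model` used for every estimate.
#' @param e zone error rate; default 0.01.
#' @return An object of class `sweep_result`: list with `axis`
#'   (`"depth"`), `points` (data.frame of axis value, mean deviation,
#'   replicate count), `criterion` and `minimal` (`NA` when no point
#'   meets the criterion).
#' @export
min_depth_sweep <- function(f = 0.035, n_loci = 11000L,
                            depths = seq(40, 200, by = 5), n_reps = 20L,
                            seed = 1L, criterion = 1.0, model, e = 0.01) {
  stopifnot(inherits(model, "correction_model"), n_reps >= 1L)
  depths <- sort(depths)
  restore <- local_rng_seed(seed)
  on.exit(restore(), add = TRUE)
  rep_seeds <- matrix(sample.int(.Machine$integer.max,
                                 length(depths) * n_reps),
                      nrow = length(depths))
  mean_dev <- vapply(seq_along(depths), function(di) {
    devs <- vapply(seq_len(n_reps), function(r) {
      ds <- simulate_dataset(sim_params(n_loci = n_loci, D = depths[di],
                                        f = f, seed = rep_seeds[di, r]))
      est <- tryCatch(estimate_fetal_fraction(ds$loci, model = model, e = e),
                      error = function(err) NULL)
      if (is.null(est)) return(NA_real_)
      deviation_e1(standard_f_of_dataset(ds), final_fraction(est))
    }, numeric(1))
    mean(devs, na.rm = TRUE)
  }, numeric(1))
  points <- data.frame(depth = depths, mean_e1 = mean_dev, n_reps = n_reps)
  ok <- which(!is.nan(mean_dev) & mean_dev < criterion)
  structure(list(axis = "depth", points = points, criterion = criterion,
                 minimal = if (length(ok)) depths[min(ok)] else NA_real_),
            class = "sweep_result")
}

#' Minimum-SNP sweep
#'
#' Simulates datasets at fixed depth and fetal fraction over a grid of
#' predefined locus counts and reports, per count, the mean relative
#' deviation e2 of the corrected estimator and the mean number of loci
#' in the targeted zone. Two minimal-count readings are reported: the
#' smallest count whose mean e2 falls below the criterion, and the
#' smallest count at which the zone holds more than `min_zone` loci on
#' average.
#'
#' @param D sequencing depth; default 65.
#' @param f true fetal fraction.
#' @param loci_counts grid of predefined locus counts.
#' @param n_reps replicates per count; default 20.
#' @param seed base seed.
#' @param criterion e2 threshold (relative fraction); default 0.01.
#' @param model a `correction_model`.
#' @param min_zone zone-census threshold for the second reading; default
#'   30.
#' @param e zone error rate; default 0.01.
#' @return A `sweep_result` whose `points` also carry `mean_zone_loci`,
#'   and with both `minimal` (e2 reading) and `minimal_by_zone` (zone
#'   census reading).
#' @export
min_snps_sweep <- function(D = 65, f = 0.10,
                           loci_counts = c(100, 250, 500, 1000, 2000,
                                           4000, 8000, 11000),
                           n_reps = 20L, seed = 1L, criterion = 0.01,
                           model, min_zone = 30L, e = 0.01) {
  stopifnot(inherits(model, "correction_model"), n_reps >= 1L)
  loci_counts <- sort(loci_counts)
  restore <- local_rng_seed(seed)
  on.exit(restore(), add = TRUE)
  rep_seeds <- matrix(sample.int(.Machine$integer.max,
                                 length(loci_counts) * n_reps),
                      nrow = length(loci_counts))
  rows <- lapply(seq_along(loci_counts), function(ci) {
    devs <- zone_n <- rep(NA_real_, n_reps)
    for (r in seq_len(n_reps)) {
      ds <- simulate_dataset(sim_params(n_loci = loci_counts[ci], D = D,
                                        f = f, seed = rep_seeds[ci, r]))
      est <- tryCatch(estimate_fetal_fraction(ds$loci, model = model, e = e),
                      error = function(err) NULL)
      zone_n[r] <- if (is.null(est)) 0 else est$n_effective
      if (is.null(est)) next
      devs[r] <- deviation_e2(standard_f_of_dataset(ds), final_fraction(est))
    }
    data.frame(n_loci = loci_counts[ci],
               mean_e2 = mean(devs, na.rm = TRUE),
               mean_zone_loci = mean(zone_n),
               n_reps = n_reps)
  })
  points <- do.call(rbind, rows)
  ok_e2 <- which(!is.nan(points$mean_e2) & points$mean_e2 < criterion)
  ok_zone <- which(points$mean_zone_loci > min_zone)
  structure(list(axis = "n_loci", points = points, criterion = criterion,
                 minimal = if (length(ok_e2)) loci_counts[min(ok_e2)] else NA_real_,
                 minimal_by_zone = if (length(ok_zone)) loci_counts[min(ok_zone)] else NA_real_),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep over %s (%d points, criterion %g): minimal %s = %s\n",
              x$axis, nrow(x$points), x$criterion, x$axis,
              if (is.na(x$minimal)) "none" else format(x$minimal)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Write a sweep result as TSV
#'
#' @param sweep a `sweep_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  utils::write.table(sweep$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' The packaged clinical-sample table
#'
#' Estimated, corrected and chromosome-Y-standard fetal fractions (all in
#' percent) for 18 clinical maternal plasma samples, as published;
#' corrected values exist only for the 8 samples sequenced below
#' 100-fold, the regime where correction is applied.
#'
#' @return A data.frame with columns `sample`, `depth`, `sensitivity`,
#'   `specificity`, `standard_cff`, `estimated_cff`, `corrected_cff`
#'   (`NA` when unavailable).
#' @export
clinical_table <- function() {
  path <- system.file("extdata", "clinical_samples_table.tsv",
                      package = "cffmix", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "-")
}

#' Summary statistics of a clinical-sample table
#'
#' For the low-depth samples (depth < 100-fold, the corrected regime)
#' computes the median and range of the absolute deviation between the
#' standard and the estimated fraction before and after correction; over
#' all samples computes the median depth and the median deviation of the
#' final value (corrected where present, else estimated). The final
#' deviation is reported both absolutely (percentage points) and
#' relative to the standard value, the two possible readings of a
#' "median bias".
#'
#' All medians use the mean-of-central-pair convention for even counts.
#'
#' @param rows a data.frame as returned by [clinical_table()].
#' @return A list with `n_samples`, `median_depth`, `pre_correction`
#'   and `post_correction` (each `median`/`min`/`max`, percentage
#'   points, low-depth rows only), `median_final_deviation` (pp, all
#'   rows) and `median_final_relative_deviation` (percent of the
#'   standard value, all rows).
#' @export
summarize_clinical_table <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0L,
            all(c("depth", "standard_cff", "estimated_cff",
                  "corrected_cff") %in% names(rows)))
  low <- rows[rows$depth < 100, , drop = FALSE]
  pre <- abs(low$standard_cff - low$estimated_cff)
  post_rows <- low[!is.na(low$corrected_cff), , drop = FALSE]
  if (nrow(post_rows) < nrow(low))
    warning(nrow(low) - nrow(post_rows),
            " low-depth sample(s) lack a corrected value; excluded from the post-correction summary")
  post <- abs(post_rows$standard_cff - post_rows$corrected_cff)
  final <- ifelse(is.na(rows$corrected_cff), rows$estimated_cff,
                  rows$corrected_cff)
  final_dev <- abs(rows$standard_cff - final)
  list(
    n_samples = nrow(rows),
    n_low_depth = nrow(low),
    median_depth = stats::median(rows$depth),
    pre_correction = list(median = stats::median(pre),
                          min = min(pre), max = max(pre)),
    post_correction = list(median = stats::median(post),
                           min = min(post), max = max(post)),
    median_final_deviation = stats::median(final_dev),
    median_final_relative_deviation =
      stats::median(100 * final_dev / rows$standard_cff)
  )
}
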