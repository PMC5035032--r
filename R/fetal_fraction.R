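#' Median sequencing depth of a sample
#'
#' The sample depth `D` is the median of the per-locus total counts
#' `x + y`; the median of an even-length vector is the mean of the two
#' central values.
#'
#' @param loci a `snp_counts` data.frame.
#' @return Sample depth in fold coverage.
#' @export
estimate_sample_depth <- function(loci) {
  if (is.null(loci) || nrow(loci) == 0L) stop("no loci")
  stats::median(loci$x + loci$y)
}

#' Boundary lines of the targeted zone
#'
#' A locus is plotted at (x, y) = (major count, minor count). Four lines
#' delimit the zone holding the effective loci (mother homozygous, fetus
#' heterozygous):
#'
#' * the ratio line `y = x/3`, above which lie loci with a heterozygous
#'   mother (a fetal fraction above the 50% ceiling would be implied);
#' * the sequencing-error line `y = (x+y)e + k_error * sqrt(e(x+y))`,
#'   below which a minor count is indistinguishable from error at rate
#'   `e` (Poisson error counts, normal approximation);
#' * the depth window `D - 3*sqrt(D) <= x+y <= D + 3*sqrt(D)`, which
#'   keeps loci whose total coverage is typical for the sample.
#'
#' Below 100-fold coverage the error multiplier is relaxed from 3 to 2
#' standard deviations so that enough effective loci survive; the
#' resulting extra error leakage is what the depth-bias correction
#' ([build_correction_model()]) later removes.
#'
#' @param D sample depth (fold), positive.
#' @param e sequencing-error rate; default 0.01 (the Q20 filter bound).
#' @return An object of class `zone_boundaries` with fields `D`, `e`,
#'   `k_error` (3 when `D >= 100`, else 2), `k_depth` (3) and `max_f`
#'   (0.5).
#' @export
build_boundaries <- function(D, e = 0.01) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("depth D must be a positive number")
  if (!is.numeric(e) || length(e) != 1L || e <= 0 || e >= 1)
    stop("error rate e must be in (0, 1)")
  structure(
    list(D = D, e = e, k_error = if (D >= 100) 3 else 2,
         k_depth = 3, max_f = 0.5),
    class = "zone_boundaries"
  )
}

#' @export
print.zone_boundaries <- function(x, ...) {
  cat(sprintf(
    "targeted-zone boundaries: D = %.1f-fold, e = %.4f, error line %d sd, depth window %d sd\n",
    x$D, x$e, x$k_error, x$k_depth))
  invisible(x)
}

#' Test loci for membership of the targeted zone
#'
#' Vectorised over loci. A locus (x, y) is effective iff it lies on or
#' below the ratio line (`y <= x/3`), strictly above the error line
#' (`y > (x+y)e + k_error*sqrt(e(x+y))`) and inside the depth window
#' (`|x + y - D| <= 3*sqrt(D)`). Strictness above the error line means a
#' minor count exactly at the error ceiling is rejected, so `y = 0` loci
#' are never effective.
#'
#' @param locus a `snp_counts` data.frame (one or more rows).
#' @param b a `zone_boundaries` object.
#' @return Logical vector, one element per row of `locus`.
#' @export
in_targeted_zone <- function(locus, b) {
  stopifnot(inherits(b, "zone_boundaries"))
  x <- locus$x
  y <- locus$y
  tot <- x + y
  below_ratio <- y <= x / 3
  above_error <- y > tot * b$e + b$k_error * sqrt(b$e * tot)
  in_window <- abs(tot - b$D) <= b$k_depth * sqrt(b$D)
  below_ratio & above_error & in_window
}

#' Per-locus fetal fraction
#'
#' At an effective locus the fetus contributes the only copies of the
#' minor allele, one of its two haplotypes, so the fetal fraction is
#' `f = 2y / (x + y)`.
#'
#' @param x,y major and minor allele counts (vectorised).
#' @return Numeric vector of per-locus fractions.
#' @export
locus_fetal_fraction <- function(x, y) {
  tot <- x + y
  if (any(tot == 0)) stop("zero depth locus")
  2 * y / tot
}

#' Estimate the fetal fraction of a sample
#'
#' The full estimation pipeline: compute the sample depth `D`, build the
#' zone boundaries, keep the loci inside the targeted zone, take the
#' median of their per-locus fractions as the raw estimate, and — when
#' `D < 100` or the raw estimate is below 10% — apply the depth-bias
#' correction if a calibrated model is supplied.
#'
#' @param loci a `snp_counts` data.frame.
#' @param model a correction model from [build_correction_model()] /
#'   [load_model()], or `NULL` to skip correction.
#' @param e sequencing-error rate for the zone boundaries; default 0.01.
#' @param min_effective minimum number of zone loci below which the
#'   estimate is flagged `low_confidence`; default 30.
#' @return An object of class `fetal_fraction_estimate`: a list with
#'   `depth`, `f_raw`, `f_corrected` (`NA` when no correction applied),
#'   `n_effective`, `per_locus_f`, `corrected` and `low_confidence`.
#' @examples
#' ds <- simulate_dataset(sim_params(D = 150, f = 0.15, seed = 1))
#' estimate_fetal_fraction(ds$loci)
#' @export
estimate_fetal_fraction <- function(loci, model = NULL, e = 0.01,
                                    min_effective = 30L) {
  D <- estimate_sample_depth(loci)
  b <- build_boundaries(D, e)
  eff <- loci[in_targeted_zone(loci, b), , drop = FALSE]
  if (nrow(eff) == 0L) stop("no effective SNPs")
  per_f <- locus_fetal_fraction(eff$x, eff$y)
  f_raw <- stats::median(per_f)

  needs_corr <- D < 100 || f_raw < 0.10
  f_corrected <- NA_real_
  corrected <- FALSE
  if (needs_corr) {
    if (is.null(model)) {
      warning("correction indicated (D < 100-fold or f_raw < 10%) ",
              "but no correction model supplied; returning raw estimate")
    } else {
      f_corrected <- apply_correction(f_raw, D, model)
      corrected <- TRUE
    }
  }

  structure(
    list(depth = D, f_raw = f_raw, f_corrected = f_corrected,
         n_effective = length(per_f), per_locus_f = per_f,
         corrected = corrected,
         low_confidence = length(per_f) < min_effective),
    class = "fetal_fraction_estimate"
  )
}

#' @export
print.fetal_fraction_estimate <- function(x, ...) {
  cat(sprintf("fetal fraction estimate (depth %.1f-fold, %d effective SNPs%s)\n",
              x$depth, x$n_effective,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  cat(sprintf("  raw:       %.4f (%.2f%%)\n", x$f_raw, 100 * x$f_raw))
  if (x$corrected)
    cat(sprintf("  corrected: %.4f (%.2f%%)\n", x$f_corrected,
                100 * x$f_corrected))
  invisible(x)
}

#' Final fraction of an estimate
#'
#' The corrected value when a correction was applied, otherwise the raw
#' median.
#'
#' @param est a `fetal_fraction_estimate`.
#' @return Numeric scalar.
#' @export
final_fraction <- function(est) {
  stopifnot(inherits(est, "fetal_fraction_estimate"))
  if (isTRUE(est$corrected)) est$f_corrected else est$f_raw
}

#' Serialise an estimate to JSON
#'
#' @param est a `fetal_fraction_estimate`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
estimate_to_json <- function(est, path = NULL) {
  stopifnot(inherits(est, "fetal_fraction_estimate"))
  obj <- list(
    depth = est$depth,
    f_raw = est$f_raw, f_raw_percent = 100 * est$f_raw,
    f_corrected = if (est$corrected) est$f_corrected else NULL,
    f_corrected_percent = if (est$corrected) 100 * est$f_corrected else NULL,
    n_effective = est$n_effective,
    corrected = est$corrected,
    low_confidence = est$low_confidence
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Fetal fraction from chromosome-Y coverage
#'
#' For a male fetus the chrY sequences in plasma are exclusively fetal
#' and haploid: a fetal fraction `f` contributes `f/2` chrY
#' haploid-equivalents per diploid autosomal genome, so
#' `f = 2 * median(chrY depth) / median(autosomal depth)`, clamped to
#' [0, 1]. Used as an orthogonal check on the SNP-based estimator.
#'
#' @param chrY_site_depths per-site read depths at chrY SNPs.
#' @param autosomal_site_depths per-site read depths at autosomal SNPs.
#' @return Fetal fraction in [0, 1].
#' @export
estimate_fraction_chrY <- function(chrY_site_depths, autosomal_site_depths) {
  if (length(chrY_site_depths) == 0L) stop("no chrY site depths")
  if (length(autosomal_site_depths) == 0L) stop("no autosomal site depths")
  f <- 2 * stats::median(chrY_site_depths) / stats::median(autosomal_site_depths)
  min(max(f, 0), 1)
}
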