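#' Calibrate the depth-bias correction
#'
#' Below 100-fold coverage (or below a 10% fetal fraction) the relaxed
#' error line lets error-inflated loci into the targeted zone and the
#' zone truncates the low tail of the minor-count distribution, so the
#' raw median over-estimates the fetal fraction. The correction is a
#' per-depth regression, calibrated on synthetic datasets, that maps a
#' raw estimate back to the truth scale: for each calibration depth,
#' datasets are simulated over a grid of true fractions, the raw
#' estimator is run without correction, and the standard (true-label)
#' fraction is regressed on the raw estimate by least squares.
#'
#' The raw-vs-true relation is hockey-stick shaped — unbiased above the
#' detection limit, flattening towards an error floor below it — so the
#' default fit is a continuous one-knot linear spline (`form = "hinge"`,
#' knot chosen by residual sum of squares over a quantile grid), which
#' follows both branches; `form = "linear"` gives the single straight
#' line, kept for comparison but a poor fit across the knee (see the
#' methods vignette). Replicates whose targeted zone holds fewer than 30
#' loci are excluded from the fit: below that census the raw estimate is
#' flagged unusable by the estimator itself, and at very low fractions
#' such near-empty-zone replicates produce wild values that would
#' dominate the regression.
#'
#' @param depths calibration depths (fold); default 40 to 95 in steps of
#'   5, the regime in which correction is always triggered. Extend the
#'   grid when correcting deeper samples with a sub-10% raw estimate.
#' @param f_grid grid of true fractions; default 0.5% to 25% in steps of
#'   0.5%.
#' @param n_reps simulated replicates per (depth, fraction) cell;
#'   default 25.
#' @param seed calibration seed; every simulated dataset derives its
#'   seed from it.
#' @param form `"hinge"` (default) or `"linear"`.
#' @param n_loci loci per simulated dataset; default 10000.
#' @param e error rate passed to the zone boundaries; default 0.01.
#' @param min_effective zone census below which a calibration replicate
#'   is discarded; default 30.
#' @return An object of class `correction_model`: a list with `entries`
#'   (named by depth; each holds `depth`, `form`, `coefficients` —
#'   `(intercept, slope)` for a linear fit, `(intercept, slope_left,
#'   slope_right, knot)` for a hinge — and `n_points`), plus `f_grid`,
#'   `n_reps`, `form` and `seed`.
#' @seealso [apply_correction()], [save_model()], [load_model()]
#' @examples
#' \donttest{
#' model <- build_correction_model(depths = 65, n_reps = 5, seed = 1)
#' apply_correction(0.118, 65, model)
#' }
#' @export
build_correction_model <- function(depths = seq(40, 95, by = 5),
                                   f_grid = seq(0.005, 0.25, by = 0.005),
                                   n_reps = 25L, seed = 1L,
                                   form = c("hinge", "linear"),
                                   n_loci = 10000L, e = 0.01,
                                   min_effective = 30L) {
  form <- match.arg(form)
  if (length(depths) == 0L) stop("depths must be non-empty")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (length(f_grid) == 0L || any(f_grid < 0) || any(f_grid > 0.5))
    stop("f_grid values must lie in [0, 0.5]")

  restore <- local_rng_seed(seed)
  on.exit(restore(), add = TRUE)
  dataset_seeds <- matrix(
    sample.int(.Machine$integer.max, length(depths) * length(f_grid) * n_reps),
    nrow = length(depths))

  entries <- list()
  for (di in seq_along(depths)) {
    d <- depths[di]
    raw <- std <- numeric(0)
    dropped_f <- numeric(0)
    n_usable_cells <- 0L
    for (fi in seq_along(f_grid)) {
      cell_raw <- cell_std <- rep(NA_real_, n_reps)
      for (r in seq_len(n_reps)) {
        ds <- simulate_dataset(sim_params(
          n_loci = n_loci, D = d, f = f_grid[fi],
          seed = dataset_seeds[di, (fi - 1L) * n_reps + r]))
        est <- tryCatch(
          suppressWarnings(estimate_fetal_fraction(ds$loci, model = NULL, e = e)),
          error = function(err) NULL)
        if (is.null(est) || est$n_effective < min_effective) next
        cell_raw[r] <- est$f_raw
        cell_std[r] <- standard_f_of_dataset(ds)
      }
      ok <- !is.na(cell_raw)
      if (!any(ok)) {
        dropped_f <- c(dropped_f, f_grid[fi])
        next
      }
      n_usable_cells <- n_usable_cells + 1L
      raw <- c(raw, cell_raw[ok])
      std <- c(std, cell_std[ok])
    }
    if (length(dropped_f) > 0L)
      warning(sprintf(
        "depth %.0f: no usable replicate (empty or sub-census zone) at f = %s; cell(s) dropped",
        d, paste(format(dropped_f), collapse = ", ")))
    if (n_usable_cells < 5L)
      stop(sprintf("depth %.0f has only %d usable calibration cells (need >= 5)",
                   d, n_usable_cells))
    entries[[as.character(d)]] <- c(
      list(depth = d), fit_calibration(raw, std, form),
      list(n_points = length(raw)))
  }

  structure(list(entries = entries, f_grid = f_grid,
                 n_reps = as.integer(n_reps), form = form,
                 seed = as.integer(seed)),
            class = "correction_model")
}

## least-squares fit of standard on raw; hinge = continuous 1-knot spline
fit_calibration <- function(raw, std, form) {
  if (form == "linear" || length(raw) < 30L) {
    fit <- stats::lm.fit(cbind(1, raw), std)
    return(list(form = "linear", coefficients = unname(fit$coefficients)))
  }
  knots <- seq(stats::quantile(raw, 0.05), stats::quantile(raw, 0.95),
               length.out = 25L)
  best <- NULL
  best_rss <- Inf
  for (k in knots) {
    fit <- stats::lm.fit(cbind(1, pmin(raw, k), pmax(raw - k, 0)), std)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- c(unname(fit$coefficients), k)
    }
  }
  list(form = "hinge", coefficients = best)
}

#' Apply the depth-bias correction to a raw estimate
#'
#' Looks up the calibration entry whose depth is nearest to `D` (ties
#' resolved towards the lower depth), evaluates its fitted curve at
#' `f_raw`, and clamps the result to \[0, 0.5\].
#'
#' @param f_raw raw fetal-fraction estimate.
#' @param D sample depth (fold).
#' @param model a `correction_model`.
#' @return Corrected fraction in \[0, 0.5\].
#' @export
apply_correction <- function(f_raw, D, model) {
  stopifnot(inherits(model, "correction_model"))
  if (length(model$entries) == 0L) stop("correction model has no entries")
  cal_depths <- vapply(model$entries, `[[`, numeric(1), "depth")
  dist <- abs(cal_depths - D)
  entry <- model$entries[[order(dist, cal_depths)[1L]]]
  co <- entry$coefficients
  val <- if (entry$form == "hinge") {
    co[1L] + co[2L] * pmin(f_raw, co[4L]) + co[3L] * pmax(f_raw - co[4L], 0)
  } else {
    co[1L] + co[2L] * f_raw
  }
  pmin(pmax(val, 0), 0.5)
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "depth-bias correction model: %d depth entries (%s fits), %d-point f grid, %d reps, seed %d\n",
    length(x$entries), x$form, length(x$f_grid), x$n_reps, x$seed))
  for (en in x$entries)
    cat(sprintf("  depth %5.1f: %s [%s]  (%d points)\n", en$depth, en$form,
                paste(sprintf("%.4g", en$coefficients), collapse = ", "),
                en$n_points))
  invisible(x)
}

#' Save / load a correction model as JSON
#'
#' @param model a `correction_model`.
#' @param path file path.
#' @return `path` invisibly (save); the model (load). Round-trip
#'   identity holds up to numeric serialisation.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "correction_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed model JSON: ",
                                           conditionMessage(e)))
  for (key in c("entries", "f_grid", "n_reps", "form", "seed")) {
    if (is.null(obj[[key]]))
      stop("model file is missing the '", key, "' key")
  }
  entries <- lapply(obj$entries, function(en) {
    if (is.null(en$depth) || is.null(en$coefficients) || is.null(en$form))
      stop("model entry is missing 'depth', 'form' or 'coefficients'")
    list(depth = as.numeric(en$depth), form = as.character(en$form),
         coefficients = as.numeric(en$coefficients),
         n_points = as.integer(en$n_points))
  })
  structure(list(entries = entries, f_grid = as.numeric(obj$f_grid),
                 n_reps = as.integer(obj$n_reps),
                 form = as.character(obj$form),
                 seed = as.integer(obj$seed)),
            class = "correction_model")
}
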