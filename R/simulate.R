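#' Parameters for the synthetic allele-count generator
#'
#' The generator reproduces the study conditions used for calibration and
#' evaluation: 10,000 SNP loci per dataset, maternal-fetal genotype
#' categories drawn as AAaa : AAab : ABaa : ABab = 0.7 : 0.1 : 0.1 : 0.1,
#' and allele counts drawn from normal distributions with variance equal
#' to the mean (the normal limit of Poisson-dispersed counts). The AAaa
#' minor-allele mean is `e_sim * D` with `e_sim = 0.0026`, the HiSeq2000
#' platform error rate — distinct from the `e = 0.01` Q20 bound used by
#' the zone boundaries, and never conflated with it.
#'
#' @param n_loci number of SNP loci; default 10000.
#' @param proportions category mix over (AAaa, AAab, ABaa, ABab); must sum
#'   to 1.
#' @param D predefined median sequencing depth (fold).
#' @param f true cffDNA fraction, in [0, 0.5].
#' @param e_sim platform error rate driving AAaa minor counts; default
#'   0.0026.
#' @param seed integer random seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_loci = 10000L,
                       proportions = c(AAaa = 0.7, AAab = 0.1,
                                       ABaa = 0.1, ABab = 0.1),
                       D = 150, f = 0.10, e_sim = 0.0026, seed = 1L) {
  if (length(proportions) != 4L || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must be 4 non-negative values summing to 1")
  if (is.null(names(proportions)))
    names(proportions) <- c("AAaa", "AAab", "ABaa", "ABab")
  if (f < 0 || f > 0.5) stop("f must be in [0, 0.5]")
  if (D <= 0) stop("D must be positive")
  if (n_loci < 1L) stop("n_loci must be >= 1")
  structure(list(n_loci = as.integer(n_loci), proportions = proportions,
                 D = D, f = f, e_sim = e_sim, seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate a labelled synthetic maternal-plasma dataset
#'
#' Each locus is assigned a maternal-fetal genotype category, and its
#' minor-allele count mean follows from the plasma mixture (mother
#' contributes `1 - f` of the DNA, fetus `f`):
#'
#' * `AAaa`: errors only, mean `e_sim * D`;
#' * `AAab`: the fetal heterozygous allele, mean `(f/2) * D`;
#' * `ABaa`: the maternal-only allele, mean `((1-f)/2) * D`;
#' * `ABab`: a shared heterozygous allele, mean `D/2`.
#'
#' The major mean is `D` minus the minor mean. Each count is a normal
#' draw with variance equal to its mean, rounded to the nearest integer
#' and truncated at zero; (x, y) are then re-ordered so `x >= y`.
#' Deterministic under a fixed seed (local RNG state; the caller's RNG
#' is untouched).
#'
#' @param params a `sim_params` object.
#' @return A list of class `sim_dataset` with elements `loci` (a
#'   `snp_counts` data.frame), `labels` (factor of category labels,
#'   parallel to `loci`) and `params`.
#' @examples
#' ds <- simulate_dataset(sim_params(D = 200, f = 0.10, seed = 7))
#' table(ds$labels)
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  categories <- c("AAaa", "AAab", "ABaa", "ABab")
  withr_seed <- local_rng_seed(params$seed)
  on.exit(withr_seed(), add = TRUE)

  n <- params$n_loci
  D <- params$D
  f <- params$f
  lab <- sample(categories, n, replace = TRUE, prob = params$proportions)
  minor_mean <- c(AAaa = params$e_sim * D, AAab = (f / 2) * D,
                  ABaa = ((1 - f) / 2) * D, ABab = D / 2)[lab]
  major_mean <- D - minor_mean
  draw <- function(mu) {
    v <- round(stats::rnorm(n, mean = mu, sd = sqrt(pmax(mu, 0))))
    pmax(as.integer(v), 0L)
  }
  a <- draw(major_mean)   # allele carried at mean D - m
  b <- draw(minor_mean)   # allele carried at mean m
  x <- pmax(a, b)
  y <- pmin(a, b)
  swap <- b > a
  major <- rep("A", n); major[swap] <- "G"
  minor <- rep("G", n); minor[swap] <- "A"
  minor[y == 0L] <- "."
  loci <- validate_snp_counts(data.frame(
    chrom = "chrS", pos = seq_len(n), major = major, minor = minor,
    x = x, y = y, stringsAsFactors = FALSE))
  structure(list(loci = loci,
                 labels = factor(lab, levels = categories),
                 params = params),
            class = "sim_dataset")
}

## run code under a private RNG stream; returns a restorer function
local_rng_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Standard (true-label) fetal fraction of a simulated dataset
#'
#' The reference value a simulated estimate is judged against: the median
#' of `2y/(x+y)` over the loci whose true label is AAab. Uses the labels,
#' not zone membership, so it is independent of the boundary geometry.
#'
#' @param ds a `sim_dataset`.
#' @return Numeric scalar.
#' @export
standard_f_of_dataset <- function(ds) {
  stopifnot(inherits(ds, "sim_dataset"))
  sel <- ds$labels == "AAab" & (ds$loci$x + ds$loci$y) > 0L
  if (!any(sel)) stop("dataset has no AAab loci with coverage")
  stats::median(locus_fetal_fraction(ds$loci$x[sel], ds$loci$y[sel]))
}

#' Write / read a labelled simulated dataset
#'
#' The counts TSV of [write_counts_table()] extended with a `category`
#' column holding the true genotype label.
#'
#' @param ds a `sim_dataset`.
#' @param path output path.
#' @return `path` invisibly (write); a list with `loci` and `labels`
#'   (read).
#' @export
write_sim_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "sim_dataset"))
  out <- ds$loci[, c("chrom", "pos", "major", "minor", "x", "y")]
  out$category <- as.character(ds$labels)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_sim_dataset
#' @export
read_sim_dataset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         major = "character",
                                         minor = "character"))
  if (!"category" %in% names(df))
    stop("labelled dataset must carry a 'category' column")
  loci <- validate_snp_counts(df[, c("chrom", "pos", "major", "minor", "x", "y")])
  list(loci = loci,
       labels = factor(df$category, levels = c("AAaa", "AAab", "ABaa", "ABab")))
}
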