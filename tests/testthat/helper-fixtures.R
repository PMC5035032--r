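# shared fixture builders; everything is generated in code at test time

random_snp_counts <- function(n, seed = 1L) {
  set.seed(seed)
  x <- rpois(n, 80)
  y <- pmin(rpois(n, 8), x)
  bases <- c("A", "C", "G", "T")
  major <- sample(bases, n, replace = TRUE)
  minor <- vapply(major, function(b) sample(setdiff(bases, b), 1L), "")
  snp_counts(chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
             pos = sample.int(1e6, n), major = major, minor = minor,
             x = x, y = y)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# independent straight-line tally of a pileup base string: walks the string
# character by character, mirroring the format definition rather than the
# package decoder
oracle_pileup_tally <- function(bases, quals, ref, min_q = 0L) {
  chars <- strsplit(bases, "")[[1]]
  qv <- utf8ToInt(quals) - 33L
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  qi <- 0L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "^") { i <- i + 2L; next }
    if (ch == "$") { i <- i + 1L; next }
    if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
      next
    }
    qi <- qi + 1L  # every remaining symbol consumes one quality character
    base <- if (ch %in% c(".", ",")) toupper(ref)
            else if (ch %in% c("*", ">", "<")) NA_character_
            else toupper(ch)
    if (!is.na(base) && base %in% names(counts) && qv[qi] >= min_q)
      counts[base] <- counts[base] + 1L
    i <- i + 1L
  }
  counts
}

# one small cached correction model for unit tests that just need *a* model
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(build_correction_model(
        depths = c(65, 150), f_grid = seq(0.01, 0.25, by = 0.02),
        n_reps = 4L, seed = 71L))
    }
    cache
  }
})
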