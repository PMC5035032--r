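#' Construct a table of per-SNP allele counts
#'
#' The central data structure of the package: one row per biallelic SNP locus
#' with the counts of its two most frequent alleles after quality filtering.
#' `x` is always the major (most frequent) count and `y` the minor count;
#' rows supplied with `x < y` are normalised by swapping both the counts and
#' the base labels.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param major,minor single-character base labels (A/C/G/T); `minor` is `"."`
#'   when no second allele was observed (`y == 0`).
#' @param x,y non-negative integer allele counts, major and minor.
#'
#' @return A `data.frame` with columns `chrom`, `pos`, `major`, `minor`,
#'   `x`, `y` and class `snp_counts`.
#' @examples
#' snp_counts("chr1", 12345, "A", "G", 95, 5)
#' @export
snp_counts <- function(chrom, pos, major, minor, x, y) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    major = as.character(major), minor = as.character(minor),
    x = as.integer(x), y = as.integer(y),
    stringsAsFactors = FALSE
  )
  validate_snp_counts(normalize_snp_counts(df))
}

## swap (x, y) and (major, minor) wherever x < y so x is the major count
normalize_snp_counts <- function(df) {
  swap <- df$x < df$y
  if (any(swap)) {
    tmp_ct <- df$x[swap]; df$x[swap] <- df$y[swap]; df$y[swap] <- tmp_ct
    tmp_bs <- df$major[swap]; df$major[swap] <- df$minor[swap]; df$minor[swap] <- tmp_bs
  }
  df$minor[df$y == 0L] <- "."
  df
}

validate_snp_counts <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "pos", "major", "minor", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("snp_counts is missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$y < 0L) || any(df$x < df$y))
    stop("allele counts must satisfy x >= y >= 0")
  if (any(df$pos < 1L))
    stop("positions must be 1-based (pos >= 1)")
  bad <- df$y > 0L & df$major == df$minor
  if (any(bad))
    stop("major and minor base must differ when y > 0 (first offender pos ",
         df$pos[which(bad)[1L]], ")")
  class(df) <- unique(c("snp_counts", class(df)))
  df
}

#' Read a per-SNP allele-count table
#'
#' Reads the tab-separated counts format written by [write_counts_table()]:
#' a header line `chrom pos major minor x y` followed by one row per locus.
#' Rows in which the stated minor count exceeds the major count are
#' normalised by swapping counts and base labels, so the invariant
#' `x >= y` always holds on return.
#'
#' @param path path to a tab-separated counts file.
#' @return A `snp_counts` data.frame (zero rows for a header-only file).
#' @seealso [write_counts_table()], [counts_from_pileup()]
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("counts file is empty (no header): ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("chrom", "pos", "major", "minor", "x", "y")
  if (!all(need %in% header))
    stop("counts header must name the fields ", paste(need, collapse = ", "))
  idx <- match(need, header)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(snp_counts(character(), integer(), character(), character(),
                      integer(), integer()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) == length(header)
  if (!all(ncol_ok))
    stop("malformed row at line ", which(!ncol_ok)[1L] + 1L,
         ": expected ", length(header), " tab-separated fields")
  mat <- do.call(rbind, fields)[, idx, drop = FALSE]
  parse_count <- function(col, name) {
    val <- suppressWarnings(as.numeric(mat[, col]))
    bad <- is.na(val) | val < 0 | val != floor(val)
    if (any(bad))
      stop("malformed row at line ", which(bad)[1L] + 1L,
           ": column '", name, "' must be a non-negative integer")
    as.integer(val)
  }
  pos <- parse_count(2L, "pos")
  if (any(pos < 1L))
    stop("malformed row at line ", which(pos < 1L)[1L] + 1L,
         ": pos must be >= 1")
  snp_counts(mat[, 1L], pos, mat[, 3L], mat[, 4L],
             parse_count(5L, "x"), parse_count(6L, "y"))
}

#' Write a per-SNP allele-count table
#'
#' @param records a `snp_counts` data.frame.
#' @param path output path; overwritten if present.
#' @return `path`, invisibly. Guarantees
#'   `read_counts_table(path)` reproduces `records`.
#' @export
write_counts_table <- function(records, path) {
  records <- validate_snp_counts(records)
  out <- records[, c("chrom", "pos", "major", "minor", "x", "y")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a SNP panel from a BED3 file
#'
#' Panel sites are given in BED convention (0-based half-open intervals);
#' they are converted to 1-based positions on load so they can be matched
#' against pileup coordinates. `track`/`browser`/comment lines are skipped.
#'
#' @param path path to a BED3 file.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, normalised and sorted) of class `snp_panel`.
#' @export
read_bed_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L)
    return(structure(data.frame(chrom = character(), start = integer(),
                                end = integer()), class = c("snp_panel", "data.frame")))
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3L))
    stop("BED line with fewer than 3 fields at line ",
         which(lengths(fields) < 3L)[1L])
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end) || any(df$end <= df$start))
    stop("BED intervals must have integer bounds with end > start")
  df <- unique(df[order(df$chrom, df$start), , drop = FALSE])
  rownames(df) <- NULL
  class(df) <- c("snp_panel", "data.frame")
  df
}
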