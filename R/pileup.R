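#' Derive allele counts from a samtools text pileup
#'
#' Decodes the read-bases column of a 6-column samtools text pileup
#' (`chrom pos ref depth bases quals`) at the positions named in a SNP
#' panel, discards base calls below a Phred quality threshold, and tallies
#' the two most frequent remaining nucleotides as (major, minor).
#'
#' Decoding follows the samtools conventions: `.`/`,` are the reference
#' base on the forward/reverse strand; `ACGT`/`acgt` are explicit
#' mismatches; `^X` marks a read start (the mapping-quality character `X`
#' is skipped); `$` marks a read end; `+N<seq>`/`-N<seq>` are insertions
#' and deletions attached to the preceding base (skipped); `*`, `>` and
#' `<` are placeholders (deletion or reference skip) that consume a
#' quality character but contribute no base. Only A/C/G/T calls are
#' tallied; `N` and ambiguity codes are dropped before quality filtering.
#'
#' @param pileup path to a samtools text pileup.
#' @param panel a `snp_panel` from [read_bed_panel()], or any data.frame
#'   with 0-based half-open `chrom`/`start`/`end` columns.
#' @param min_base_quality minimum Phred base quality (Sanger +33 encoding)
#'   for a call to be counted; default 20, i.e. a 1% call-error ceiling.
#' @return A `snp_counts` data.frame, one row per panel position that has
#'   at least one surviving base call. When two bases tie, alphabetical
#'   order (A < C < G < T) decides which is major; when no second allele
#'   survives, `minor` is `"."`.
#' @seealso [read_counts_table()] for pre-tabulated counts.
#' @export
counts_from_pileup <- function(pileup, panel, min_base_quality = 20L) {
  if (!file.exists(pileup)) stop("pileup file not found: ", pileup)
  stopifnot(is.data.frame(panel), all(c("chrom", "start", "end") %in% names(panel)))
  lines <- readLines(pileup)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(snp_counts(character(), integer(), character(), character(),
                      integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L))
    stop("pileup line ", which(lengths(fields) < 6L)[1L],
         " has fewer than 6 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  ref <- toupper(vapply(fields, `[[`, "", 3L))

  # panel is BED (0-based half-open); pileup positions are 1-based
  keep <- logical(length(lines))
  for (i in seq_len(nrow(panel))) {
    keep <- keep | (chrom == panel$chrom[i] &
                      pos > panel$start[i] & pos <= panel$end[i])
  }

  rows <- lapply(which(keep), function(i) {
    calls <- decode_pileup_bases(fields[[i]][5L], ref[i], line = i)
    quals <- utf8ToInt(fields[[i]][6L]) - 33L
    if (length(calls) != length(quals))
      stop("pileup line ", i, ": decoded ", length(calls),
           " base(s) but quality string has ", length(quals))
    bases <- calls[calls %in% c("A", "C", "G", "T") & quals >= min_base_quality]
    if (length(bases) == 0L) return(NULL)
    tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
    ord <- order(-tab, names(tab))  # count desc, then A<C<G<T
    major <- names(tab)[ord[1L]]
    x <- as.integer(tab[ord[1L]])
    y <- as.integer(tab[ord[2L]])
    minor <- if (y > 0L) names(tab)[ord[2L]] else "."
    data.frame(chrom = chrom[i], pos = pos[i], major = major, minor = minor,
               x = x, y = y, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(snp_counts(character(), integer(), character(), character(),
                      integer(), integer()))
  }
  validate_snp_counts(do.call(rbind, rows))
}

## Decode one read-bases string into one upper-case symbol per aligned call.
## Placeholders (* > <) are kept as-is so the caller can align qualities.
decode_pileup_bases <- function(bases, ref, line = NA) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  out <- character(length(chars))
  n_out <- 0L
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L  # mapping-quality character follows
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
      if (j == i + 1L)
        stop("pileup line ", line, ": indel marker '", ch,
             "' not followed by a length")
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len  # skip the inserted/deleted sequence
    } else if (ch == "." || ch == ",") {
      n_out <- n_out + 1L; out[n_out] <- ref; i <- i + 1L
    } else if (ch %in% c("*", ">", "<")) {
      n_out <- n_out + 1L; out[n_out] <- ch; i <- i + 1L
    } else if (grepl("^[ACGTNacgtn]$", ch)) {
      n_out <- n_out + 1L; out[n_out] <- toupper(ch); i <- i + 1L
    } else {
      stop("pileup line ", line, ": unknown symbol '", ch,
           "' in read-bases string")
    }
  }
  out[seq_len(n_out)]
}
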