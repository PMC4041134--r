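# Raw-read cleaning and tag collapsing. Filters follow the standard sRNA
# cleaning cascade: low-quality reads, 5'-adaptor contaminants, reads
# without a 3' adaptor, insertless reads, poly-A artifacts, and inserts
# shorter than 18 nt. Filters are evaluated in that fixed order so each
# discarded read carries exactly one reason and tallies are reproducible.

#' Cleaning configuration
#'
#' @param min_insert minimum insert length kept (default 18 nt).
#' @param max_insert inserts longer than this are kept in the clean set but
#'   flagged for exclusion from miRNA analysis (default 30 nt).
#' @param adaptor_match_len number of 3'-adaptor prefix bases that must match
#'   exactly (default 8); the leftmost occurrence wins.
#' @param adaptor_mismatch allowed mismatches in the adaptor match (0 or 1;
#'   default 0).
#' @param max_n_frac maximum fraction of N bases tolerated (default 0.1).
#' @param min_phred minimum per-base Phred quality tolerated (default 10).
#' @param polya_frac adenine fraction at or above which an insert is called
#'   poly-A (default 0.8).
#' @param polya_run terminal adenine run length at or above which an insert
#'   is called poly-A (default 10).
#' @param passthrough when TRUE, reads with no 3'-adaptor hit are passed
#'   through whole instead of discarded (for re-cleaning already-trimmed
#'   inserts); default FALSE.
#' @return a list of class `cleaning_config`.
#' @export
cleaning_config <- function(min_insert = 18L, max_insert = 30L,
                            adaptor_match_len = 8L, adaptor_mismatch = 0L,
                            max_n_frac = 0.1, min_phred = 10L,
                            polya_frac = 0.8, polya_run = 10L,
                            passthrough = FALSE) {
  stopifnot(min_insert >= 1L, max_insert >= min_insert,
            adaptor_match_len >= 1L, adaptor_mismatch %in% c(0L, 1L))
  structure(list(min_insert = as.integer(min_insert),
                 max_insert = as.integer(max_insert),
                 adaptor_match_len = as.integer(adaptor_match_len),
                 adaptor_mismatch = as.integer(adaptor_mismatch),
                 max_n_frac = max_n_frac, min_phred = as.integer(min_phred),
                 polya_frac = polya_frac, polya_run = as.integer(polya_run),
                 passthrough = isTRUE(passthrough)),
            class = "cleaning_config")
}

filter_reasons <- c("low_quality", "adaptor5_contaminant", "no_3prime_adaptor",
                    "no_insert", "poly_A", "too_short")

# Vectorized cleaning core. Returns a list with `insert` (NA where discarded)
# and `reason` (NA where kept).
clean_core <- function(seqs, quals, adaptor3, adaptor5 = "", config = cleaning_config()) {
  if (any(!nzchar(seqs))) stop("clean: empty read sequence", call. = FALSE)
  if (!nzchar(adaptor3)) stop("clean: 3' adaptor must be non-empty", call. = FALSE)
  seqs <- as_dna(seqs)
  check_alphabet(seqs, "read")
  n <- length(seqs)
  reason <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)

  # 1. low quality: any base below min_phred, or N fraction above max_n_frac
  nfrac <- letter_fraction(seqs, "N")
  low <- nfrac > config$max_n_frac
  if (!is.null(quals) && config$min_phred > 0L) {
    # Phred+33: bases below min_phred are the ASCII range [33, 33+min_phred)
    pat <- sprintf("[\\x21-\\x%02x]", 33L + config$min_phred - 1L)
    low <- low | grepl(pat, quals, perl = TRUE)
  }
  reason[low] <- "low_quality"
  todo <- is.na(reason)

  # 2. 5'-adaptor contaminant: read begins with the 5'-adaptor prefix
  if (nzchar(adaptor5)) {
    k5 <- min(config$adaptor_match_len, nchar(adaptor5))
    hit5 <- startsWith(seqs, substr(as_dna(adaptor5), 1L, k5))
    reason[todo & hit5] <- "adaptor5_contaminant"
    todo <- is.na(reason)
  }

  # 3. 3' adaptor: leftmost exact occurrence of the adaptor prefix
  k3 <- min(config$adaptor_match_len, nchar(adaptor3))
  probe <- substr(as_dna(adaptor3), 1L, k3)
  pos <- find_adaptor(seqs, probe, config$adaptor_mismatch)
  nohit <- pos < 0L
  if (config$passthrough) {
    pos[nohit] <- nchar(seqs)[nohit] + 1L
  } else {
    reason[todo & nohit] <- "no_3prime_adaptor"
    todo <- is.na(reason)
  }
  ins <- substr(seqs, 1L, pmax(pos - 1L, 0L))

  # 4. no insert: adaptor starts at the first base
  reason[todo & nchar(ins) == 0L] <- "no_insert"
  todo <- is.na(reason)

  # 5. poly-A artifacts
  pa <- letter_fraction(ins, "A") >= config$polya_frac |
    endsWith_run(ins, "A", config$polya_run)
  reason[todo & pa] <- "poly_A"
  todo <- is.na(reason)

  # 6. too short
  reason[todo & nchar(ins) < config$min_insert] <- "too_short"
  todo <- is.na(reason)

  insert[todo] <- ins[todo]
  list(insert = insert, reason = reason)
}

# TRUE when the sequence ends with a run of >= k of the given letter.
endsWith_run <- function(x, letter = "A", k = 10L) {
  if (k <= 0L) return(rep(TRUE, length(x)))
  grepl(sprintf("%s{%d}$", letter, k), x)
}

# Leftmost match start (1-based) of `probe` in each sequence, or -1.
# With one allowed mismatch, every probe variant is tried and the leftmost
# hit over all variants wins.
find_adaptor <- function(seqs, probe, mismatch = 0L) {
  hit <- regexpr(probe, seqs, fixed = TRUE)
  pos <- as.integer(hit)
  if (mismatch >= 1L) {
    k <- nchar(probe)
    for (i in seq_len(k)) {
      pat <- paste0(substr(probe, 1L, i - 1L), ".", substr(probe, i + 1L, k))
      h <- regexpr(pat, seqs)
      h <- as.integer(h)
      better <- h > 0L & (pos < 0L | h < pos)
      pos[better] <- h[better]
    }
  }
  pos
}

#' Clean a single raw read
#'
#' Applies the filter cascade to one read and returns either the insert (the
#' sequence upstream of the leftmost 3'-adaptor occurrence) or the single
#' discard reason, evaluated in the fixed order low_quality ->
#' adaptor5_contaminant -> no_3prime_adaptor -> no_insert -> poly_A ->
#' too_short.
#'
#' @param sequence read sequence (ACGTN).
#' @param quality Phred+33 quality string of the same length, or NULL.
#' @param adaptor3 3' adaptor sequence (required).
#' @param adaptor5 5' adaptor sequence (optional, "" disables the check).
#' @param config a [cleaning_config()].
#' @return list with `kept` (logical), `insert` (or NA) and `reason` (or NA).
#' @export
clean_read <- function(sequence, quality = NULL, adaptor3, adaptor5 = "",
                       config = cleaning_config()) {
  if (!is.null(quality) && nchar(quality) != nchar(sequence)) {
    stop("clean_read: sequence and quality lengths differ", call. = FALSE)
  }
  res <- clean_core(sequence, quality, adaptor3, adaptor5, config)
  list(kept = is.na(res$reason), insert = res$insert[1L], reason = res$reason[1L])
}

#' Read a FASTQ file into sequences and qualities
#'
#' Minimal strict Sanger FASTQ reader (Phred+33). Errors name the index of
#' the first malformed record.
#'
#' @param path FASTQ file path.
#' @return list with character vectors `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': %d lines (not a multiple of 4)",
                 path, length(lines)), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(list(id = character(), sequence = character(), quality = character()))
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- !startsWith(hd, "@") | !startsWith(pl, "+") | nchar(sq) != nchar(ql)
  if (any(bad)) {
    stop(sprintf("malformed FASTQ '%s' at record %d", path, which(bad)[1L]),
         call. = FALSE)
  }
  list(id = sub("^@", "", hd), sequence = sq, quality = ql)
}

#' Clean a FASTQ library and collapse to unique tags
#'
#' Applies [clean_read()]'s cascade to every record, collapses the surviving
#' inserts into unique tags with occurrence counts, and tallies discard
#' reasons. Tags are ordered by descending count then lexicographic sequence
#' so output is deterministic.
#'
#' @param fastq path to a FASTQ file (Phred+33).
#' @param adaptor3 3' adaptor sequence.
#' @param adaptor5 optional 5' adaptor sequence.
#' @param config a [cleaning_config()].
#' @return an object of class `clean_read_set`: list with
#'   `tags` (data.frame `sequence`, `count`, `length`), `total_clean`,
#'   `n_raw`, and `filter_stats` (named integer vector over discard reasons).
#' @export
clean_library <- function(fastq, adaptor3, adaptor5 = "", config = cleaning_config()) {
  fq <- read_fastq(fastq)
  n_raw <- length(fq$sequence)
  if (n_raw == 0L) {
    stats <- stats::setNames(integer(length(filter_reasons)), filter_reasons)
    return(structure(list(tags = data.frame(sequence = character(),
                                            count = integer(), length = integer(),
                                            stringsAsFactors = FALSE),
                          total_clean = 0L, n_raw = 0L, filter_stats = stats),
                     class = "clean_read_set"))
  }
  res <- clean_core(fq$sequence, fq$quality, adaptor3, adaptor5, config)
  stats <- stats::setNames(integer(length(filter_reasons)), filter_reasons)
  tab <- table(factor(res$reason, levels = filter_reasons))
  stats[names(tab)] <- as.integer(tab)
  kept <- res$insert[!is.na(res$insert)]
  srt <- sort(kept, method = "radix")
  r <- rle(srt)
  tags <- data.frame(sequence = r$values, count = r$lengths,
                     stringsAsFactors = FALSE)
  tags <- tags[order(-tags$count, tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL
  tags$length <- nchar(tags$sequence)
  out <- structure(list(tags = tags, total_clean = length(kept),
                        n_raw = n_raw, filter_stats = stats),
                   class = "clean_read_set")
  stopifnot(out$total_clean + sum(out$filter_stats) == n_raw,
            sum(tags$count) == out$total_clean)
  out
}

#' @export
print.clean_read_set <- function(x, ...) {
  cat(sprintf("clean_read_set: %d raw reads, %d clean (%d unique tags)\n",
              x$n_raw, x$total_clean, nrow(x$tags)))
  cat("discarded:", paste(sprintf("%s=%d", names(x$filter_stats), x$filter_stats),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Length distribution of clean tags
#'
#' Counts clean reads (weighted by tag count) per insert length over a fixed
#' range; lengths outside the range fall into an `overflow` bin so the
#' distribution always sums to the total clean reads.
#'
#' @param set a `clean_read_set` from [clean_library()].
#' @param range integer range of lengths reported individually (default 18:30).
#' @return data.frame with columns `length` (as character; includes
#'   `"overflow"`) and `count`.
#' @export
length_distribution <- function(set, range = 18:30) {
  lens <- set$tags$length
  cnts <- set$tags$count
  out <- data.frame(length = c(as.character(range), "overflow"),
                    count = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(range)) {
    out$count[i] <- sum(cnts[lens == range[i]])
  }
  out$count[length(range) + 1L] <- sum(cnts[!(lens %in% range)])
  stopifnot(sum(out$count) == set$total_clean)
  out
}

#' Write collapsed tags as FASTA
#'
#' Headers use the collapsed-read dialect `>t<rank>_x<count>`.
#'
#' @param set a `clean_read_set`.
#' @param path output FASTA path.
#' @export
write_tags_fasta <- function(set, path) {
  hdr <- sprintf(">t%d_x%d", seq_len(nrow(set$tags)), set$tags$count)
  writeLines(paste0(hdr, "\n", set$tags$sequence), path)
  invisible(path)
}
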