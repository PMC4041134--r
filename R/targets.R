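# Plant miRNA target prediction by complementarity penalty scoring.
# Each transcript window the length of the miRNA is aligned gaplessly
# against the miRNA (miRNA 5'->3' versus target 3'->5'); mispairing is
# penalized (mismatch 1.0, G:U wobble 0.5, gap 2.0), penalties at miRNA
# positions 2-13 are doubled, and sites above the penalty cap are dropped.
# Optional positional constraints reject sites with a mismatch at positions
# 10-11 (the cleavage site) or more than one mismatch in positions 2-12.

#' Score one miRNA/target-window duplex
#'
#' Positions are numbered from the miRNA 5' end; the target window is given
#' 5'->3' and aligned antiparallel, so miRNA position i faces window
#' position `length - i + 1`. Gapless.
#'
#' @param mirna miRNA sequence (5'->3', DNA or RNA alphabet).
#' @param window target window (5'->3'), same length as the miRNA.
#' @param mismatch,wobble,gap penalty units (defaults 1, 0.5, 2; the gapless
#'   aligner never emits gaps, the gap penalty is kept for completeness).
#' @param double_zone miRNA positions whose penalties are doubled (default
#'   2:13).
#' @param cleavage_zone positions where any mismatch raises a flag (default
#'   10:11).
#' @param seed_zone positions where more than one mismatch raises a flag
#'   (default 2:12).
#' @return list with `penalty`, `flags` (character vector, possibly empty,
#'   from `cleavage_site_mismatch`, `seed_mismatches`), `pairs` (per-position
#'   classification: `match`, `wobble`, `mismatch`), and `alignment` (a
#'   3-line string: miRNA 3'<-5' on top is avoided — miRNA printed 5'->3',
#'   pairing row, target printed 3'->5').
#' @export
score_duplex_penalty <- function(mirna, window, mismatch = 1, wobble = 0.5,
                                 gap = 2, double_zone = 2:13,
                                 cleavage_zone = 10:11, seed_zone = 2:12) {
  mirna <- as_dna(mirna)
  window <- as_dna(window)
  check_alphabet(c(mirna, window), "duplex")
  n <- nchar(mirna)
  if (nchar(window) != n) {
    stop("score_duplex_penalty: window and miRNA lengths differ", call. = FALSE)
  }
  m <- strsplit(mirna, "")[[1]]
  # target base opposite miRNA position i, read 3'->5'
  t <- rev(strsplit(window, "")[[1]])
  cls <- classify_pairs(m, t)
  unit <- ifelse(cls == "match", 0, ifelse(cls == "wobble", wobble, mismatch))
  mult <- ifelse(seq_len(n) %in% double_zone, 2, 1)
  penalty <- sum(unit * mult)
  flags <- character(0)
  mm <- cls == "mismatch"
  if (any(mm[intersect(cleavage_zone, seq_len(n))])) {
    flags <- c(flags, "cleavage_site_mismatch")
  }
  if (sum(mm[intersect(seed_zone, seq_len(n))]) > 1L) {
    flags <- c(flags, "seed_mismatches")
  }
  pairing <- ifelse(cls == "match", "|", ifelse(cls == "wobble", "o", " "))
  alignment <- paste(paste(m, collapse = ""),
                     paste(pairing, collapse = ""),
                     paste(t, collapse = ""), sep = "\n")
  list(penalty = penalty, flags = flags, pairs = cls, alignment = alignment)
}

# Watson-Crick match / G:U wobble / mismatch per aligned base pair.
# `m` is the miRNA base, `t` the target base facing it. With DNA-alphabet
# storage the wobble pairs are G:T(=U) and T(=U):G.
classify_pairs <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G")
  wb <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, "match", ifelse(wb, "wobble", "mismatch"))
}

#' Scan transcripts for miRNA target sites
#'
#' Scores every window of miRNA length along each transcript with
#' [score_duplex_penalty()] and keeps sites at or below the penalty cap,
#' optionally rejecting sites with positional-constraint flags. Sites are
#' sorted by penalty, then transcript, then coordinate.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcripts path to a transcript FASTA, or a named character
#'   vector of transcript sequences.
#' @param max_penalty penalty cap (default 4.0).
#' @param enforce_flags reject flagged sites when TRUE (default FALSE).
#' @param ... further arguments to [score_duplex_penalty()].
#' @return data.frame with columns `mirna`, `transcript`, `start`, `end`
#'   (1-based inclusive on the transcript), `penalty`, `flags`
#'   (comma-separated, "" when none), `alignment`.
#' @export
scan_transcripts <- function(mirna, transcripts, max_penalty = 4.0,
                             enforce_flags = FALSE, ...) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    ss <- Biostrings::readBStringSet(transcripts)
    tx <- stats::setNames(as_dna(as.character(ss)), sub("\\s.*$", "", names(ss)))
  } else {
    tx <- stats::setNames(as_dna(transcripts), names(transcripts))
  }
  empty <- data.frame(mirna = character(), transcript = character(),
                      start = integer(), end = integer(), penalty = numeric(),
                      flags = character(), alignment = character(),
                      stringsAsFactors = FALSE)
  if (!length(tx)) return(empty)
  mirna <- as_dna(mirna)
  n <- nchar(mirna)
  rows <- list()
  for (id in names(tx)) {
    s <- tx[[id]]
    L <- nchar(s)
    if (L < n) next
    for (st in seq_len(L - n + 1L)) {
      win <- substr(s, st, st + n - 1L)
      sc <- score_duplex_penalty(mirna, win, ...)
      if (sc$penalty > max_penalty) next
      if (enforce_flags && length(sc$flags)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mirna, transcript = id, start = st, end = st + n - 1L,
        penalty = sc$penalty, flags = paste(sc$flags, collapse = ","),
        alignment = sc$alignment, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$penalty, out$transcript, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
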