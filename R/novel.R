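# Novel miRNA prediction from unannotated, genome-mapped tags: candidate
# hairpin windows around each perfect hit are folded, the miRNA/miRNA* duplex
# is derived from the structure, and candidates are kept only when they meet
# all the hairpin criteria (length bounds, minimum free energy, duplex
# pairing, bulge, asymmetry, spacing, genome copy number).

#' Hairpin prediction parameters
#'
#' The full criterion set for calling a hairpin a miRNA precursor. Defaults
#' are the conventional plant miRNA prediction settings: mature length
#' 18-25 nt, star (reference) length 20-23 nt, at most 20 genome copies,
#' precursor free energy at most -18 kcal/mol, at most 300 nt between miRNA
#' and miRNA*, at least 16 base pairs in the duplex, at most a 4-nt bulge,
#' at most 4 nt of duplex asymmetry, and 20 nt of precursor flank.
#'
#' @param min_mirna_len,max_mirna_len mature length bounds (nt).
#' @param min_ref_len,max_ref_len star-sequence length bounds (nt).
#' @param max_genome_copies maximum perfect genomic hits for the mature tag.
#' @param max_free_energy precursor MFE threshold (kcal/mol; must be < 0).
#' @param max_spacing maximum nucleotides between miRNA and miRNA*.
#' @param min_duplex_pairs minimum paired bases in the miRNA/miRNA* duplex.
#' @param max_bulge maximum interior unpaired run in the duplex (nt).
#' @param max_asymmetry maximum |unpaired(miRNA) - unpaired(miRNA*)| (nt).
#' @param flank precursor flank length around the mature hit (nt).
#' @return a list of class `novel_params`.
#' @export
novel_params <- function(min_mirna_len = 18L, max_mirna_len = 25L,
                         min_ref_len = 20L, max_ref_len = 23L,
                         max_genome_copies = 20L, max_free_energy = -18,
                         max_spacing = 300L, min_duplex_pairs = 16L,
                         max_bulge = 4L, max_asymmetry = 4L, flank = 20L) {
  stopifnot(min_mirna_len <= max_mirna_len, min_ref_len <= max_ref_len,
            max_free_energy < 0, max_genome_copies >= 1L, flank >= 0L)
  structure(list(min_mirna_len = as.integer(min_mirna_len),
                 max_mirna_len = as.integer(max_mirna_len),
                 min_ref_len = as.integer(min_ref_len),
                 max_ref_len = as.integer(max_ref_len),
                 max_genome_copies = as.integer(max_genome_copies),
                 max_free_energy = max_free_energy,
                 max_spacing = as.integer(max_spacing),
                 min_duplex_pairs = as.integer(min_duplex_pairs),
                 max_bulge = as.integer(max_bulge),
                 max_asymmetry = as.integer(max_asymmetry),
                 flank = as.integer(flank)),
            class = "novel_params")
}

#' Extract candidate precursor windows around unannotated tag hits
#'
#' For each perfect genomic hit of each tag (tags with more than
#' `max_genome_copies` hits are excluded), two windows are proposed so the
#' star arm can sit on either side of the mature tag: one extending upstream
#' by `flank + max_spacing + max_ref_len`, one extending downstream by the
#' same amount, each with `flank` on the near side. Windows are clipped to
#' chromosome bounds, never erroring at contig edges.
#'
#' @param tags data.frame of unannotated tags (`sequence`, `count`).
#' @param index a [genome_index()].
#' @param params a [novel_params()].
#' @return data.frame with columns `tag`, `count`, `chrom`, `start`, `end`,
#'   `strand`, `win_start`, `win_end`, `side` ("up"/"down"), `n_hits`;
#'   coordinates 1-based inclusive on the forward strand.
#' @export
extract_candidate_loci <- function(tags, index, params = novel_params()) {
  hits <- genome_lookup(index, tags$sequence)
  if (!nrow(hits)) {
    return(data.frame(tag = character(), count = integer(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      win_start = integer(), win_end = integer(),
                      side = character(), n_hits = integer(),
                      stringsAsFactors = FALSE))
  }
  n_hits <- table(hits$tag)
  hits$n_hits <- as.integer(n_hits[hits$tag])
  hits <- hits[hits$n_hits <= params$max_genome_copies, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(tag = character(), count = integer(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      win_start = integer(), win_end = integer(),
                      side = character(), n_hits = integer(),
                      stringsAsFactors = FALSE))
  }
  hits$count <- tags$count[match(hits$tag, as_dna(tags$sequence))]
  far <- params$flank + params$max_spacing + params$max_ref_len
  up <- within(hits, {
    win_start <- pmax(start - far, 1L)
    win_end <- pmin(end + params$flank, unname(index$lengths[chrom]))
    side <- "up"
  })
  dn <- within(hits, {
    win_start <- pmax(start - params$flank, 1L)
    win_end <- pmin(end + far, unname(index$lengths[chrom]))
    side <- "down"
  })
  out <- rbind(up, dn)
  out <- out[order(out$chrom, out$start, out$strand, out$side, out$tag), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("tag", "count", "chrom", "start", "end", "strand",
          "win_start", "win_end", "side", "n_hits")]
}

#' Derive miRNA/miRNA* duplex statistics from a folded precursor
#'
#' Given the precursor's dot-bracket structure and the mature arm placement,
#' locates the star arm as the region pairing with the mature positions,
#' extends it by the canonical 2-nt 3' overhang, and computes the duplex
#' statistics used by the hairpin criteria.
#'
#' @param structure dot-bracket string of the precursor.
#' @param mature_start,mature_len 1-based start and length of the mature arm
#'   within the precursor.
#' @return list with `star_start`, `star_end` (1-based inclusive, NA when the
#'   mature arm is entirely unpaired), `paired_bases` (mature positions
#'   paired to star positions), `max_bulge` (longest interior unpaired run on
#'   either strand of the duplex), `asymmetry` (|interior unpaired in mature
#'   - interior unpaired in star|), `spacing` (nucleotides strictly between
#'   mature and star).
#' @export
derive_duplex <- function(structure, mature_start, mature_len) {
  pt <- pair_table(structure)
  n <- length(pt)
  m_from <- as.integer(mature_start)
  m_to <- m_from + as.integer(mature_len) - 1L
  if (m_from < 1L || m_to > n) {
    stop("derive_duplex: mature arm outside the precursor", call. = FALSE)
  }
  mpos <- m_from:m_to
  partners <- pt[mpos]
  outside <- partners != 0L & (partners < m_from | partners > m_to)
  if (!any(outside)) {
    return(list(star_start = NA_integer_, star_end = NA_integer_,
                paired_bases = 0L, max_bulge = NA_integer_,
                asymmetry = NA_integer_, spacing = NA_integer_))
  }
  # the star arm is the densest contiguous cluster of pairing partners;
  # stray long-range pairings of a few mature bases (common when folding a
  # large scan window) must not stretch the star span
  pp <- sort(partners[outside])
  cl <- cumsum(c(1L, diff(pp) > 10L))
  best <- as.integer(names(which.max(table(cl))))
  s_from <- min(pp[cl == best])
  s_to <- max(pp[cl == best])
  # canonical 2-nt 3' overhang: the star's 3' (right) end extends 2 nt
  s_to <- min(s_to + 2L, n)
  spos <- s_from:s_to
  paired <- partners >= s_from & partners <= s_to
  paired_bases <- sum(paired)

  interior_unpaired <- function(pos, ok) {
    # unpaired runs strictly inside the first..last paired position
    idx <- which(ok)
    if (length(idx) < 2L) return(integer(0))
    inner <- ok[idx[1L]:idx[length(idx)]]
    r <- rle(inner)
    r$lengths[!r$values]
  }
  m_runs <- interior_unpaired(mpos, paired)
  star_paired <- pt[spos] >= m_from & pt[spos] <= m_to
  s_runs <- interior_unpaired(spos, star_paired)
  max_bulge <- max(c(m_runs, s_runs, 0L))
  asymmetry <- abs(sum(m_runs) - sum(s_runs))
  spacing <- if (s_from > m_to) s_from - m_to - 1L else m_from - s_to - 1L
  spacing <- max(spacing, 0L)
  list(star_start = s_from, star_end = s_to, paired_bases = paired_bases,
       max_bulge = as.integer(max_bulge), asymmetry = as.integer(asymmetry),
       spacing = as.integer(spacing))
}

#' Evaluate a hairpin candidate against the full criterion set
#'
#' @param candidate list with fields `mature_len`, `mfe`, `paired_bases`,
#'   `max_bulge`, `asymmetry`, `spacing`, `n_genome_copies` (a row of
#'   [predict_novel()]'s report, or hand-built).
#' @param params a [novel_params()].
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty when passing). Criterion names:
#'   `mature_length`, `free_energy`, `spacing`, `min_duplex_pairs`,
#'   `max_bulge`, `asymmetry`, `genome_copies`.
#' @export
evaluate_candidate <- function(candidate, params = novel_params()) {
  fails <- character(0)
  chk <- function(cond, name) {
    if (!isTRUE(cond)) fails <<- c(fails, name)
  }
  grab <- function(f) {
    v <- candidate[[f]]
    if (is.null(v) || !length(v)) NA else v
  }
  candidate <- stats::setNames(
    lapply(c("mature_len", "mfe", "paired_bases", "max_bulge", "asymmetry",
             "spacing", "n_genome_copies"), grab),
    c("mature_len", "mfe", "paired_bases", "max_bulge", "asymmetry",
      "spacing", "n_genome_copies"))
  ml <- candidate$mature_len
  chk(!is.na(ml) && ml >= params$min_mirna_len && ml <= params$max_mirna_len,
      "mature_length")
  chk(!is.na(candidate$mfe) && candidate$mfe <= params$max_free_energy,
      "free_energy")
  chk(!is.na(candidate$spacing) && candidate$spacing <= params$max_spacing,
      "spacing")
  chk(!is.na(candidate$paired_bases) &&
        candidate$paired_bases >= params$min_duplex_pairs, "min_duplex_pairs")
  chk(is.na(candidate$max_bulge) == FALSE &&
        candidate$max_bulge <= params$max_bulge, "max_bulge")
  chk(!is.na(candidate$asymmetry) &&
        candidate$asymmetry <= params$max_asymmetry, "asymmetry")
  nc <- candidate$n_genome_copies
  if (is.null(nc) || is.na(nc)) nc <- 1L
  chk(nc <= params$max_genome_copies, "genome_copies")
  # a mature arm with no star partner fails the duplex criteria
  if (is.na(candidate$paired_bases) || candidate$paired_bases == 0L) {
    fails <- union(fails, "min_duplex_pairs")
  }
  list(pass = length(fails) == 0L, reasons = fails)
}

#' Predict novel miRNAs from unannotated tags
#'
#' Runs the whole module: candidate windows ([extract_candidate_loci()]),
#' folding ([fold_rna()]), duplex derivation ([derive_duplex()]) and
#' criterion evaluation ([evaluate_candidate()]). For each (tag, hit) the
#' better-scoring passing window (lower MFE) is kept; passing candidates are
#' deduplicated by overlapping precursor locus, the most abundant tag
#' defining the mature arm. Per-library counts sum all tags equal to the
#' mature sequence.
#'
#' @param tags_a,tags_b data.frames of unannotated tags per library
#'   (`sequence`, `count`); `tags_b` may be NULL for single-library use.
#' @param index a [genome_index()].
#' @param params a [novel_params()].
#' @param backend folding backend passed to [fold_rna()].
#' @return list with `mirnas`: data.frame (`id`, `mature`, `precursor`,
#'   `chrom`, `start`, `end`, `strand`, `mfe`, `count_a`, `count_b`) sorted
#'   by locus, and `report`: per-candidate criterion table including fail
#'   reasons.
#' @export
predict_novel <- function(tags_a, tags_b = NULL, index, params = novel_params(),
                          backend = "auto") {
  empty_tags <- data.frame(sequence = character(), count = integer(),
                           stringsAsFactors = FALSE)
  if (is.null(tags_a) || !nrow(tags_a)) tags_a <- empty_tags
  pool <- tags_a
  if (!is.null(tags_b) && !nrow(tags_b)) tags_b <- NULL
  if (!is.null(tags_b)) {
    pool <- merge(tags_a, tags_b, by = "sequence", all = TRUE,
                  suffixes = c("_a", "_b"))
    pool$count <- rowSums(cbind(pool$count_a, pool$count_b), na.rm = TRUE)
  } else {
    pool$count_a <- pool$count
    pool$count_b <- rep(0L, nrow(pool))
  }
  loci <- extract_candidate_loci(pool[, c("sequence", "count")] |>
                                   stats::setNames(c("sequence", "count")),
                                 index, params)
  empty_mirnas <- data.frame(id = character(), mature = character(),
                             precursor = character(), chrom = character(),
                             start = integer(), end = integer(),
                             strand = character(), mfe = numeric(),
                             count_a = integer(), count_b = integer(),
                             stringsAsFactors = FALSE)
  if (!nrow(loci)) return(list(mirnas = empty_mirnas, report = loci))

  # length guard for the folder
  loci <- loci[loci$win_end - loci$win_start + 1L <= 1000L, , drop = FALSE]
  precursor <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    win <- Biostrings::subseq(index$genome[[loci$chrom[i]]],
                              loci$win_start[i], loci$win_end[i])
    precursor[i] <- as.character(win)
  }
  minus <- loci$strand == "-"
  precursor[minus] <- revcomp(precursor[minus])
  # mature placement within the window (strand-aware)
  mat_start <- ifelse(minus, loci$win_end - loci$end + 1L,
                      loci$start - loci$win_start + 1L)
  mat_len <- loci$end - loci$start + 1L

  foldable <- !grepl("N", precursor, fixed = TRUE)
  rep_df <- loci
  rep_df$mature_len <- mat_len
  rep_df$mfe <- NA_real_
  rep_df$structure <- NA_character_
  rep_df$paired_bases <- NA_integer_
  rep_df$max_bulge <- NA_integer_
  rep_df$asymmetry <- NA_integer_
  rep_df$duplex_spacing <- NA_integer_
  rep_df$prec_start <- NA_integer_
  rep_df$prec_end <- NA_integer_
  rep_df$pass <- FALSE
  rep_df$reasons <- NA_character_
  rep_df$precursor <- NA_character_

  # stage 1: fold the scan windows and locate the star arm
  win_struct <- rep(NA_character_, nrow(loci))
  if (any(foldable)) {
    folded <- fold_rna(precursor[foldable], backend = backend)
    win_struct[foldable] <- folded$structure
  }
  trim_a <- rep(NA_integer_, nrow(loci))
  trim_b <- rep(NA_integer_, nrow(loci))
  for (i in which(foldable)) {
    dx <- derive_duplex(win_struct[i], mat_start[i], mat_len[i])
    if (is.na(dx$star_start)) {
      rep_df$paired_bases[i] <- 0L
      v <- evaluate_candidate(list(mature_len = mat_len[i], mfe = NA,
                                   paired_bases = 0L, max_bulge = NA,
                                   asymmetry = NA, spacing = NA,
                                   n_genome_copies = rep_df$n_hits[i]), params)
      rep_df$reasons[i] <- paste(v$reasons, collapse = ",")
      next
    }
    trim_a[i] <- max(1L, min(mat_start[i], dx$star_start) - params$flank)
    trim_b[i] <- min(nchar(precursor[i]),
                     max(mat_start[i] + mat_len[i] - 1L, dx$star_end) +
                       params$flank)
  }

  # stage 2: refold the trimmed hairpin precursor and evaluate the criteria
  # on its local structure
  trimmed_i <- which(!is.na(trim_a))
  if (length(trimmed_i)) {
    trimmed <- substr(precursor[trimmed_i], trim_a[trimmed_i], trim_b[trimmed_i])
    refolded <- fold_rna(trimmed, backend = backend)
    for (k in seq_along(trimmed_i)) {
      i <- trimmed_i[k]
      m_start2 <- mat_start[i] - trim_a[i] + 1L
      dx <- derive_duplex(refolded$structure[k], m_start2, mat_len[i])
      rep_df$mfe[i] <- refolded$mfe[k]
      rep_df$structure[i] <- refolded$structure[k]
      rep_df$paired_bases[i] <- dx$paired_bases
      rep_df$max_bulge[i] <- dx$max_bulge
      rep_df$asymmetry[i] <- dx$asymmetry
      rep_df$duplex_spacing[i] <- dx$spacing
      rep_df$precursor[i] <- trimmed[k]
      # genomic extent of the trimmed precursor (strand-aware)
      if (loci$strand[i] == "+") {
        rep_df$prec_start[i] <- loci$win_start[i] + trim_a[i] - 1L
        rep_df$prec_end[i] <- loci$win_start[i] + trim_b[i] - 1L
      } else {
        rep_df$prec_start[i] <- loci$win_end[i] - trim_b[i] + 1L
        rep_df$prec_end[i] <- loci$win_end[i] - trim_a[i] + 1L
      }
      verdict <- evaluate_candidate(list(mature_len = mat_len[i],
                                         mfe = rep_df$mfe[i],
                                         paired_bases = dx$paired_bases,
                                         max_bulge = dx$max_bulge,
                                         asymmetry = dx$asymmetry,
                                         spacing = dx$spacing,
                                         n_genome_copies = rep_df$n_hits[i]),
                                    params)
      rep_df$pass[i] <- verdict$pass
      rep_df$reasons[i] <- paste(verdict$reasons, collapse = ",")
    }
  }

  ok <- rep_df[rep_df$pass, , drop = FALSE]
  if (!nrow(ok)) return(list(mirnas = empty_mirnas, report = rep_df))
  # best window per (tag, hit): lower MFE wins
  key <- paste(ok$tag, ok$chrom, ok$start, ok$strand)
  ok <- ok[order(key, ok$mfe), , drop = FALSE]
  ok <- ok[!duplicated(paste(ok$tag, ok$chrom, ok$start, ok$strand)), ,
           drop = FALSE]
  # deduplicate overlapping precursor loci (window extent, so a star-arm hit
  # of the same hairpin merges with its mature-arm hit); the most abundant
  # tag defines the mature arm
  ok <- ok[order(ok$chrom, -ok$count, ok$start), , drop = FALSE]
  keep <- logical(nrow(ok))
  taken <- GenomicRanges::GRanges()
  for (i in seq_len(nrow(ok))) {
    gr <- GenomicRanges::GRanges(ok$chrom[i],
                                 IRanges::IRanges(ok$prec_start[i], ok$prec_end[i]))
    if (!length(GenomicRanges::findOverlaps(gr, taken))) {
      keep[i] <- TRUE
      taken <- c(taken, gr)
    }
  }
  ok <- ok[keep, , drop = FALSE]
  ok <- ok[order(ok$chrom, ok$start, ok$strand), , drop = FALSE]

  count_for <- function(tbl, seqs) {
    if (is.null(tbl)) return(integer(length(seqs)))
    s <- as_dna(tbl$sequence)
    vapply(seqs, function(q) as.integer(sum(tbl$count[s == q])), integer(1),
           USE.NAMES = FALSE)
  }
  mirnas <- data.frame(id = sprintf("novel-m%04d", seq_len(nrow(ok))),
                       mature = ok$tag, precursor = ok$precursor,
                       chrom = ok$chrom,
                       start = ok$prec_start, end = ok$prec_end,
                       strand = ok$strand, mfe = ok$mfe,
                       count_a = count_for(tags_a, ok$tag),
                       count_b = if (is.null(tags_b))
                                   integer(nrow(ok))
                                 else count_for(tags_b, ok$tag),
                       stringsAsFactors = FALSE)
  rownames(mirnas) <- NULL
  list(mirnas = mirnas, report = rep_df)
}
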