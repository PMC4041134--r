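# Perfect-match genome mapping and the single-category annotation cascade:
# each clean tag is assigned to exactly one of miRNA, rRNA, tRNA, snRNA,
# snoRNA, exon/intron (sense/antisense) or unannotated, in a configurable
# priority order, and tallied per library. Coordinates are handled 0-based
# half-open internally and 1-based inclusive at the GFF3 boundary.

default_priority <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                      "exon_sense", "exon_antisense",
                      "intron_sense", "intron_antisense", "unannotated")

#' Build an exact-match genome index
#'
#' Wraps the genome for perfect-match lookups on both strands. Lookups are
#' grouped by tag width and executed with Biostrings preprocessed
#' dictionaries, so querying many tags at once is fast.
#'
#' @param genome path to a genome FASTA file, or a named character vector /
#'   `DNAStringSet` of chromosome sequences.
#' @return an object of class `genome_index`.
#' @export
genome_index <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  } else if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(stats::setNames(as_dna(genome),
                                                       names(genome)))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome_index: all chromosomes must be named", call. = FALSE)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    stop("genome_index: duplicate chromosome names", call. = FALSE)
  }
  structure(list(genome = genome,
                 strings = stats::setNames(as.character(genome), names(genome)),
                 lengths = stats::setNames(Biostrings::width(genome), names(genome)),
                 cache = new.env(parent = emptyenv())),
            class = "genome_index")
}

# All genome substrings of a fixed prefilter width, both strands, cached.
# genome_lookup prefilters query tags with a hash join on their first
# `prefilter_width` bases before the exact positional search; sized for
# toy/test genomes (O(genome size) strings).
prefilter_width <- 18L

substring_pool <- function(index) {
  if (!is.null(index$cache$pool)) return(index$cache$pool)
  w <- prefilter_width
  rc <- revcomp(index$strings)
  pool <- unlist(lapply(c(index$strings, rc), function(s) {
    L <- nchar(s)
    if (L < w) return(character(0))
    substring(s, 1:(L - w + 1L), w:L)
  }), use.names = FALSE)
  index$cache$pool <- pool
  pool
}

#' Look up perfect genomic matches of tags
#'
#' Finds every position where each tag occurs exactly, on the forward or
#' reverse strand. Coordinates are 1-based inclusive on the forward strand;
#' a minus-strand hit means the tag equals the reverse complement of the
#' reported genomic window.
#'
#' @param index a [genome_index()].
#' @param tags character vector of tag sequences (DNA or RNA alphabet).
#' @return data.frame with columns `tag`, `chrom`, `start`, `end`, `strand`,
#'   sorted by tag, chrom, start, strand; zero rows when nothing matches.
#' @export
genome_lookup <- function(index, tags) {
  stopifnot(inherits(index, "genome_index"))
  tags <- as_dna(tags)
  empty <- data.frame(tag = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!length(tags)) return(empty)
  check_alphabet(tags, "tag")
  # N-containing tags cannot match the genome perfectly; skip the search
  utags <- unique(tags[!grepl("N", tags, fixed = TRUE)])
  if (!length(utags)) return(empty)
  # hash-join prefilter on the tag prefix: a perfect full-length hit implies
  # its prefix occurs in the genome, so non-survivors cannot match; the few
  # (possibly false-positive) survivors go to the exact positional search
  long_enough <- nchar(utags) >= prefilter_width
  pre <- substr(utags, 1L, prefilter_width) %in% substring_pool(index)
  utags <- utags[pre | !long_enough]
  if (!length(utags)) return(empty)
  hits <- list()
  for (w in unique(nchar(utags))) {
    grp <- utags[nchar(utags) == w]
    fwd <- Biostrings::DNAStringSet(grp)
    rev <- Biostrings::reverseComplement(fwd)
    for (strand in c("+", "-")) {
      pd <- Biostrings::PDict(if (strand == "+") fwd else rev)
      for (ch in names(index$genome)) {
        m <- Biostrings::matchPDict(pd, index$genome[[ch]])
        st <- IRanges::start(m)
        n_per <- lengths(st)
        if (sum(n_per) == 0L) next
        hits[[length(hits) + 1L]] <- data.frame(
          tag = rep(grp, n_per),
          chrom = ch,
          start = unlist(st, use.names = FALSE),
          end = unlist(st, use.names = FALSE) + w - 1L,
          strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[out$tag %in% tags, , drop = FALSE]
  out <- out[order(out$tag, out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a mature miRNA catalog
#'
#' Reads a miRBase-style FASTA of mature sequences and returns a
#' T/U-normalized lookup table. Duplicate sequences are retained so ties can
#' be audited.
#'
#' @param fasta path to a mature-miRNA FASTA, or a named character vector.
#' @return data.frame with columns `id`, `sequence` (DNA alphabet), in file
#'   order.
#' @export
read_mature_db <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    ss <- Biostrings::readBStringSet(fasta)
    seqs <- as_dna(as.character(ss))
    ids <- sub("\\s.*$", "", names(ss))
  } else {
    seqs <- as_dna(fasta)
    ids <- names(fasta)
  }
  if (!length(seqs)) stop("read_mature_db: empty mature database", call. = FALSE)
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Match tags against known mature miRNAs (perfect match only)
#'
#' A tag is called a known miRNA only when its sequence equals a mature
#' sequence exactly after T/U normalization; length variants and isomiRs are
#' excluded. When several identical catalog entries match, the first in file
#' order is reported and all are retained in the audit column.
#'
#' @param tags character vector of tag sequences.
#' @param mature_db a mature catalog from [read_mature_db()] (or a path /
#'   named vector accepted by it).
#' @return data.frame with columns `tag`, `mirna_id` (NA when unmatched),
#'   `all_ids` (comma-separated audit list, NA when unmatched).
#' @export
match_known_mirna <- function(tags, mature_db) {
  if (!is.data.frame(mature_db)) mature_db <- read_mature_db(mature_db)
  tags <- as_dna(tags)
  first <- match(tags, mature_db$sequence)
  audit <- rep(NA_character_, length(tags))
  for (i in which(!is.na(first))) {
    audit[i] <- paste(mature_db$id[mature_db$sequence == tags[i]],
                      collapse = ",")
  }
  data.frame(tag = tags,
             mirna_id = ifelse(is.na(first), NA_character_, mature_db$id[first]),
             all_ids = audit, stringsAsFactors = FALSE)
}

#' Read annotation tracks from GFF3
#'
#' Imports a GFF3 file and keeps the feature types used by the cascade
#' (miRNA_primary_transcript, rRNA, tRNA, snRNA, snoRNA, exon, intron).
#'
#' @param path GFF3 file path.
#' @return a `GRanges` with a `type` metadata column.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("miRNA_primary_transcript", "rRNA",
                                       "tRNA", "snRNA", "snoRNA",
                                       "exon", "intron")
  gr <- gr[keep]
  gr$type <- as.character(gr$type)
  gr
}

#' Classify tags into annotation categories
#'
#' Assigns each tag exactly one category by the priority cascade. A tag is
#' eligible for `miRNA` by perfect mature-catalog match (mapped or not); the
#' ncRNA and gene-structure categories require a perfect genomic hit
#' overlapping a feature of that type (strand-aware: `rRNA`/`tRNA`/`snRNA`/
#' `snoRNA` require a sense-strand hit, exon/intron categories split by
#' sense/antisense). Tags matching nothing are `unannotated`.
#'
#' @param tags data.frame with columns `sequence`, `count` (a
#'   `clean_read_set$tags` works directly).
#' @param index a [genome_index()].
#' @param annotation a `GRanges` from [read_annotation()] (or NULL for none).
#' @param mature_db mature catalog ([read_mature_db()] input), or NULL.
#' @param priority character vector ordering the categories (default
#'   miRNA > rRNA > tRNA > snRNA > snoRNA > exon_sense > exon_antisense >
#'   intron_sense > intron_antisense > unannotated).
#' @return data.frame with columns `sequence`, `count`, `category`,
#'   `mapped` (logical: >= 1 perfect genomic hit), `n_hits`, `mirna_id`.
#' @export
classify_tags <- function(tags, index, annotation = NULL, mature_db = NULL,
                          priority = default_priority) {
  stopifnot(is.data.frame(tags), all(c("sequence", "count") %in% names(tags)))
  if (!all(default_priority %in% priority)) {
    stop("classify_tags: priority must cover all categories", call. = FALSE)
  }
  seqs <- as_dna(tags$sequence)
  n <- length(seqs)
  hits <- genome_lookup(index, seqs)
  n_hits <- stats::setNames(integer(n), seqs)
  if (nrow(hits)) {
    tb <- table(hits$tag)
    n_hits[names(tb)] <- as.integer(tb)
  }
  mapped <- n_hits > 0L

  mirna_id <- rep(NA_character_, n)
  eligible <- matrix(FALSE, nrow = n, ncol = length(default_priority),
                     dimnames = list(NULL, default_priority))
  if (!is.null(mature_db)) {
    mm <- match_known_mirna(seqs, mature_db)
    mirna_id <- mm$mirna_id
    eligible[, "miRNA"] <- !is.na(mm$mirna_id)
  }
  if (!is.null(annotation) && length(annotation) && nrow(hits)) {
    hit_gr <- GenomicRanges::GRanges(hits$chrom,
                                     IRanges::IRanges(hits$start, hits$end),
                                     strand = hits$strand)
    ov <- GenomicRanges::findOverlaps(hit_gr, annotation, ignore.strand = TRUE)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov)
      si <- S4Vectors::subjectHits(ov)
      ftype <- annotation$type[si]
      fstrand <- as.character(GenomicRanges::strand(annotation))[si]
      hstrand <- hits$strand[qi]
      sense <- fstrand == "*" | hstrand == fstrand
      tag_i <- match(hits$tag[qi], seqs)
      mark <- function(cat, sel) {
        if (any(sel)) {
          eligible[cbind(tag_i[sel], match(cat, default_priority))] <<- TRUE
        }
      }
      mark("rRNA", ftype == "rRNA" & sense)
      mark("tRNA", ftype == "tRNA" & sense)
      mark("snRNA", ftype == "snRNA" & sense)
      mark("snoRNA", ftype == "snoRNA" & sense)
      mark("exon_sense", ftype == "exon" & sense)
      mark("exon_antisense", ftype == "exon" & !sense)
      mark("intron_sense", ftype == "intron" & sense)
      mark("intron_antisense", ftype == "intron" & !sense)
    }
  }
  eligible[, "unannotated"] <- TRUE
  ord <- priority[priority %in% default_priority]
  category <- ord[max.col(eligible[, ord, drop = FALSE] * 1L,
                          ties.method = "first")]
  data.frame(sequence = seqs, count = tags$count, category = category,
             mapped = unname(mapped), n_hits = unname(n_hits),
             mirna_id = mirna_id, stringsAsFactors = FALSE)
}

#' Tally classified tags into a summary table
#'
#' Produces the per-category unique-tag and total-read counts with
#' percentages of the library-wide unique and total clean reads, formatted
#' to two decimals, plus a `mapped_to_genome` row (a tag counts there when
#' it has at least one perfect hit, independent of its category).
#'
#' @param classified output of [classify_tags()].
#' @return data.frame with columns `category`, `unique_count`, `unique_pct`,
#'   `total_count`, `total_pct`; percentages are numeric, rounded to 2
#'   decimals. Use [format_percentage()] for the printed form.
#' @export
tally_categories <- function(classified) {
  u_total <- nrow(classified)
  t_total <- sum(classified$count)
  if (u_total == 0L || t_total == 0L) {
    stop("tally_categories: empty library (zero total)", call. = FALSE)
  }
  cats <- c("mapped_to_genome", default_priority)
  out <- data.frame(category = cats, unique_count = 0L, unique_pct = 0,
                    total_count = 0L, total_pct = 0, stringsAsFactors = FALSE)
  for (i in seq_along(cats)) {
    sel <- if (cats[i] == "mapped_to_genome") classified$mapped
           else classified$category == cats[i]
    out$unique_count[i] <- sum(sel)
    out$total_count[i] <- sum(classified$count[sel])
  }
  out$unique_pct <- round_half_up(100 * out$unique_count / u_total, 2)
  out$total_pct <- round_half_up(100 * out$total_count / t_total, 2)
  attr(out, "unique_total") <- u_total
  attr(out, "read_total") <- t_total
  out
}

#' Format a count as a percentage of a total, two decimals
#'
#' The printed-table convention: `100 * count / total`, rounded half-up to
#' two decimals and suffixed with `%` (e.g. 5003869 of 21668361 prints
#' "23.09%").
#'
#' @param count,total numeric; `total > 0`.
#' @return character vector like `"23.09%"`.
#' @export
format_percentage <- function(count, total) {
  if (any(total <= 0)) stop("format_percentage: total must be > 0", call. = FALSE)
  sprintf("%.2f%%", round_half_up(100 * count / total, 2))
}

# round half up at the k-th decimal, the printed-table convention
round_half_up <- function(x, k = 2) {
  floor(x * 10^k + 0.5) / 10^k
}
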