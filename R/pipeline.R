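# The assembled two-library analysis: clean -> map/annotate -> known-miRNA
# counts -> novel prediction from unannotated tags -> differential
# expression for both catalogs.

#' Run the full two-library sRNA analysis
#'
#' Cleans both FASTQ libraries, maps and classifies tags against the genome
#' and annotation, counts known miRNAs by perfect catalog match, predicts
#' novel miRNAs from unannotated genome-mapped tags, and tests differential
#' expression (treatment vs control) for both sets with the TPM filter and
#' fold-change/p-value cut-offs.
#'
#' @param fastq_control,fastq_treatment FASTQ paths.
#' @param genome genome FASTA path (or named character vector).
#' @param gff annotation GFF3 path or `GRanges` (NULL: none).
#' @param mature mature catalog FASTA path / named vector (NULL: none, all
#'   miRNA discovery is novel).
#' @param adaptor3,adaptor5 adaptor sequences for cleaning.
#' @param config a [cleaning_config()].
#' @param params a [novel_params()].
#' @param fc_cutoff,p_cutoff,min_tpm,fc_scale,filter_mode DE settings, see
#'   [de_analysis()].
#' @param backend folding backend for [predict_novel()].
#' @return list with `clean` (per-library `clean_read_set`s), `tally`
#'   (per-library category tallies), `known_counts`, `de_known`, `novel`
#'   (the [predict_novel()] result), `de_novel`, and `totals` (N1, N2).
#' @export
analyze_experiment <- function(fastq_control, fastq_treatment, genome,
                               gff = NULL, mature = NULL,
                               adaptor3, adaptor5 = "",
                               config = cleaning_config(),
                               params = novel_params(),
                               fc_cutoff = 1.5, p_cutoff = 0.01,
                               min_tpm = 10, fc_scale = "linear",
                               filter_mode = "both", backend = "auto") {
  cs_a <- clean_library(fastq_control, adaptor3, adaptor5, config)
  cs_b <- clean_library(fastq_treatment, adaptor3, adaptor5, config)
  idx <- if (inherits(genome, "genome_index")) genome else genome_index(genome)
  ann <- if (is.null(gff)) NULL
         else if (methods::is(gff, "GRanges")) gff
         else read_annotation(gff)
  mdb <- if (is.null(mature)) NULL else read_mature_db(mature)
  cl_a <- classify_tags(cs_a$tags, idx, ann, mdb)
  cl_b <- classify_tags(cs_b$tags, idx, ann, mdb)
  tally <- list(control = tally_categories(cl_a),
                treatment = tally_categories(cl_b))
  N1 <- cs_a$total_clean
  N2 <- cs_b$total_clean

  de_known <- NULL
  known_counts <- NULL
  if (!is.null(mdb)) {
    ids <- unique(mdb$id)
    cnt <- function(cl) {
      vapply(ids, function(id) {
        as.integer(sum(cl$count[!is.na(cl$mirna_id) & cl$mirna_id == id]))
      }, integer(1))
    }
    known_counts <- data.frame(id = ids, x = cnt(cl_a), y = cnt(cl_b),
                               stringsAsFactors = FALSE)
    de_known <- de_analysis(known_counts, N1, N2, fc_cutoff, p_cutoff,
                            fc_scale, min_tpm, filter_mode)
  }

  un_a <- cl_a[cl_a$category == "unannotated" & cl_a$mapped,
               c("sequence", "count")]
  un_b <- cl_b[cl_b$category == "unannotated" & cl_b$mapped,
               c("sequence", "count")]
  novel <- predict_novel(un_a, un_b, idx, params, backend)
  de_novel <- NULL
  if (nrow(novel$mirnas)) {
    de_novel <- de_analysis(data.frame(id = novel$mirnas$id,
                                       x = novel$mirnas$count_a,
                                       y = novel$mirnas$count_b,
                                       stringsAsFactors = FALSE),
                            N1, N2, fc_cutoff, p_cutoff, fc_scale, min_tpm,
                            filter_mode)
  }
  list(clean = list(control = cs_a, treatment = cs_b), tally = tally,
       known_counts = known_counts, de_known = de_known,
       novel = novel, de_novel = de_novel, totals = c(N1 = N1, N2 = N2))
}

#' Score one synthetic experiment against its ground truth
#'
#' Runs [simulate_experiment()] and [analyze_experiment()] under one seed
#' and compares the outcome with the truth table: differential-expression
#' recall among planted DE miRNAs (known-catalog route), false-call rate
#' among planted non-DE miRNAs, and novel-precursor recall/precision
#' (catalog withheld, so every planted miRNA must be rediscovered from its
#' hairpin).
#'
#' @param spec a [synthetic_spec()].
#' @param outdir scratch directory for the simulated files.
#' @param backend folding backend.
#' @return one-row data.frame: `de_tp`, `de_fn`, `false_calls`, `n_nonde`,
#'   `novel_tp`, `novel_fp`, `n_planted`.
#' @export
recovery_metrics <- function(spec, outdir = tempfile("recovery"),
                             backend = "auto") {
  ex <- simulate_experiment(spec, outdir, backend = backend)
  sg <- ex$sg
  truth <- sg$truth[sg$truth$kind == "miRNA", , drop = FALSE]
  res <- analyze_experiment(ex$paths$fastq_control, ex$paths$fastq_treatment,
                            ex$paths$genome, ex$paths$gff,
                            mature = NULL, # novel route: catalog withheld
                            adaptor3 = spec$adaptor3,
                            adaptor5 = spec$adaptor5, backend = backend)
  # novel-precursor recovery: a prediction matches a planted precursor when
  # its locus overlaps the truth locus and the mature sequence agrees
  pred <- res$novel$mirnas
  matched <- logical(nrow(truth))
  pred_match <- logical(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    j <- which(truth$mature == pred$mature[i] &
                 pred$start[i] <= truth$end & pred$end[i] >= truth$start)
    if (length(j)) {
      matched[j[1]] <- TRUE
      pred_match[i] <- TRUE
    }
  }
  # DE recovery through the known-catalog route on the same libraries
  mdb <- stats::setNames(truth$mature, truth$id)
  cl_a <- match_known_mirna(res$clean$control$tags$sequence, mdb)
  cl_b <- match_known_mirna(res$clean$treatment$tags$sequence, mdb)
  cnt <- function(cl, tags) {
    vapply(truth$id, function(id) {
      as.integer(sum(tags$count[!is.na(cl$mirna_id) & cl$mirna_id == id]))
    }, integer(1))
  }
  counts <- data.frame(id = truth$id,
                       x = cnt(cl_a, res$clean$control$tags),
                       y = cnt(cl_b, res$clean$treatment$tags),
                       stringsAsFactors = FALSE)
  de <- de_analysis(counts, res$totals[["N1"]], res$totals[["N2"]])
  call <- de$call[match(truth$id, de$id)]
  want <- ifelse(!truth$is_de, "ns", ifelse(truth$fold_change > 1, "up", "down"))
  de_tp <- sum(truth$is_de & call == want)
  false_calls <- sum(!truth$is_de & call %in% c("up", "down"))
  data.frame(de_tp = de_tp, de_fn = sum(truth$is_de) - de_tp,
             false_calls = false_calls, n_nonde = sum(!truth$is_de),
             novel_tp = sum(matched), novel_fp = sum(!pred_match),
             n_planted = nrow(truth))
}
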