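# qPCR validation: ddCt relative expression against a reference gene with
# the control condition as calibrator, and the concordance rate between
# sequencing DE calls and qPCR outcomes.

#' ddCt relative expression for one target
#'
#' dCt = Ct_target - Ct_reference per replicate; ddCt = mean dCt(treatment)
#' - mean dCt(control); relative expression of the treatment condition is
#' 2^(-ddCt) with the control fixed at exactly 1 (the calibrator).
#' Amplification efficiency is the canonical 2; no efficiency correction.
#'
#' @param ct data.frame with columns `condition` (values `control` /
#'   `treatment`), `ct_target`, `ct_reference`, and optionally `replicate`.
#' @return list with `re_control` (1), `re_treatment` (2^-ddCt), `ddct`,
#'   `dct_control`, `dct_treatment` (per-replicate dCt vectors),
#'   `re_replicates` (per-replicate treatment REs against the mean control
#'   dCt), `sd_treatment` (SD of those REs), `p_value` (Welch t-test on
#'   replicate dCts; NA when either condition has < 2 replicates).
#' @export
ddct_relative_expression <- function(ct) {
  need <- c("condition", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) {
    stop("ddct_relative_expression: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyNA(ct$ct_reference)) {
    bad <- which(is.na(ct$ct_reference))[1L]
    lab <- if ("sample" %in% names(ct)) ct$sample[bad] else paste("row", bad)
    stop("ddct_relative_expression: missing reference Ct for ", lab,
         call. = FALSE)
  }
  if (anyNA(ct$ct_target)) {
    bad <- which(is.na(ct$ct_target))[1L]
    lab <- if ("sample" %in% names(ct)) ct$sample[bad] else paste("row", bad)
    stop("ddct_relative_expression: missing target Ct for ", lab, call. = FALSE)
  }
  cond <- as.character(ct$condition)
  if (!all(cond %in% c("control", "treatment"))) {
    stop("ddct_relative_expression: condition must be control/treatment",
         call. = FALSE)
  }
  dct <- ct$ct_target - ct$ct_reference
  dct_c <- dct[cond == "control"]
  dct_t <- dct[cond == "treatment"]
  if (!length(dct_c) || !length(dct_t)) {
    stop("ddct_relative_expression: need both conditions", call. = FALSE)
  }
  ddct <- mean(dct_t) - mean(dct_c)
  re_reps <- 2^(-(dct_t - mean(dct_c)))
  p <- if (length(dct_c) >= 2L && length(dct_t) >= 2L) {
    # zero-variance replicates make the t statistic undefined; report a
    # clear-cut p for a nonzero difference and 1 for identical groups
    tryCatch(stats::t.test(dct_t, dct_c)$p.value,
             error = function(e) {
               if (isTRUE(all.equal(mean(dct_t), mean(dct_c)))) 1 else 0
             })
  } else NA_real_
  list(re_control = 1, re_treatment = 2^(-ddct), ddct = ddct,
       dct_control = dct_c, dct_treatment = dct_t,
       re_replicates = re_reps,
       sd_treatment = if (length(re_reps) >= 2L) stats::sd(re_reps) else NA_real_,
       p_value = p)
}

#' ddCt relative expression for a whole Ct table
#'
#' @param ct data.frame with columns `target`, `condition`, `ct_target`,
#'   `ct_reference` (one row per replicate).
#' @return data.frame with one row per target: `target`, `re_treatment`,
#'   `ddct`, `sd_treatment`, `p_value`.
#' @export
ddct_table <- function(ct) {
  stopifnot("target" %in% names(ct))
  targets <- unique(as.character(ct$target))
  rows <- lapply(targets, function(tg) {
    r <- ddct_relative_expression(ct[ct$target == tg, , drop = FALSE])
    data.frame(target = tg, re_treatment = r$re_treatment, ddct = r$ddct,
               sd_treatment = r$sd_treatment, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance between sequencing DE calls and qPCR relative expression
#'
#' A miRNA is concordant when the sign of its qPCR log2 relative expression
#' agrees with the sequencing call (`up` expects RE > 1, `down` RE < 1) and,
#' under the default mode, the qPCR difference is significant at
#' `alpha`. miRNAs present in only one table are excluded with a warning and
#' counted as untested.
#'
#' @param seq_calls data.frame with columns `id`, `call` (`up`/`down`; other
#'   calls are ignored as untestable).
#' @param qpcr data.frame from [ddct_table()] (columns `target`,
#'   `re_treatment`, `p_value`).
#' @param mode `"direction+significance"` (default) or `"direction"`.
#' @param alpha significance level for the qPCR test (default 0.05).
#' @return list with `rate_pct` (percentage to one decimal), `n_concordant`,
#'   `n_tested`, `n_untested`, and `verdicts` (per-miRNA data.frame).
#' @export
concordance_rate <- function(seq_calls, qpcr,
                             mode = c("direction+significance", "direction"),
                             alpha = 0.05) {
  mode <- match.arg(mode)
  calls <- seq_calls[seq_calls$call %in% c("up", "down"), , drop = FALSE]
  common <- intersect(calls$id, qpcr$target)
  missing <- union(setdiff(calls$id, qpcr$target),
                   setdiff(qpcr$target, calls$id))
  if (length(missing)) {
    warning("concordance_rate: ids present in one table only: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!length(common)) {
    return(list(rate_pct = NA_real_, n_concordant = 0L, n_tested = 0L,
                n_untested = length(missing),
                verdicts = data.frame(id = character(), call = character(),
                                      re_treatment = numeric(),
                                      concordant = logical(),
                                      stringsAsFactors = FALSE)))
  }
  calls <- calls[match(common, calls$id), , drop = FALSE]
  q <- qpcr[match(common, qpcr$target), , drop = FALSE]
  dir_ok <- (calls$call == "up" & q$re_treatment > 1) |
    (calls$call == "down" & q$re_treatment < 1)
  conc <- if (mode == "direction") dir_ok else {
    dir_ok & !is.na(q$p_value) & q$p_value < alpha
  }
  rate <- round_half_up(100 * sum(conc) / length(conc), 1)
  list(rate_pct = rate, n_concordant = sum(conc), n_tested = length(conc),
       n_untested = length(missing),
       verdicts = data.frame(id = common, call = calls$call,
                             re_treatment = q$re_treatment,
                             concordant = conc, stringsAsFactors = FALSE))
}
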