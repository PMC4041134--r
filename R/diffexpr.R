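# Differential expression between two un-replicated sRNA libraries:
# TPM normalization, log2 fold change, and the exact two-library count test
# (the classic digital-expression tail-probability test), with the
# low-expression filter and fold-change / p-value cut-offs.

#' Normalize a read count to tags per million (TPM)
#'
#' TPM = count / total clean reads * 1e6. A zero count maps to 0; the
#' pseudo-count floor is applied only inside fold-change computation.
#'
#' @param count non-negative read count(s).
#' @param total total clean reads in the library (> 0).
#' @return numeric TPM value(s).
#' @export
normalize_tpm <- function(count, total) {
  if (any(total <= 0)) stop("normalize_tpm: total clean reads must be > 0", call. = FALSE)
  if (any(count < 0)) stop("normalize_tpm: negative count", call. = FALSE)
  count / total * 1e6
}

#' Log2 fold change between two TPM values
#'
#' log2(max(tpm_treatment, pseudo) / max(tpm_control, pseudo)); positive
#' values mean higher expression in the treatment library. The pseudo floor
#' guards zero TPMs.
#'
#' @param tpm_treatment,tpm_control TPM values (>= 0).
#' @param pseudo small TPM floor applied to zeros (default 0.01).
#' @return numeric log2 ratio(s).
#' @export
log2_fold_change <- function(tpm_treatment, tpm_control, pseudo = 0.01) {
  log2(pmax(tpm_treatment, pseudo) / pmax(tpm_control, pseudo))
}

#' Exact two-library count test
#'
#' For a tag observed `x` times in a library of `N1` clean reads and `y`
#' times in a library of `N2` clean reads, the probability of the second
#' count conditional on the first is
#' `p(y|x) = (N2/N1)^y * (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`.
#' The lower tail is `C = sum_{k<=y} p(k|x)` and the upper tail
#' `D = 1 - sum_{k<=y-1} p(k|x)` (exact complement, no infinite sum). The
#' reported p-value is two-sided by default, `min(1, 2*min(C, D))`; the
#' one-sided option reports `min(C, D)`.
#'
#' Computed in log space via `lgamma` so large counts do not overflow.
#'
#' @param x,y non-negative integer counts (vectors recycle).
#' @param N1,N2 library totals (> 0).
#' @param sided `"two"` (default) or `"one"`.
#' @return a data.frame with columns `x`, `y`, `p_low` (C), `p_high` (D),
#'   `p_value`.
#' @examples
#' ac_pvalue(1, 1, 1e6, 1e6) # p(1|1) = 0.25 enters the tails
#' @export
ac_pvalue <- function(x, y, N1, N2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y))) {
    stop("ac_pvalue: counts must be non-negative integers", call. = FALSE)
  }
  if (N1 <= 0 || N2 <= 0) stop("ac_pvalue: library totals must be > 0", call. = FALSE)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  lr <- log(N2) - log(N1)          # log(N2/N1)
  l1r <- log1p(exp(lr))            # log(1 + N2/N1)
  cum_low <- function(xi, yi) {
    # sum_{k=0..yi} p(k|xi) in log space
    k <- 0:yi
    lp <- k * lr + lgamma(xi + k + 1) - lgamma(xi + 1) - lgamma(k + 1) -
      (xi + k + 1) * l1r
    min(1, exp(logsumexp(lp)))
  }
  upper_direct <- function(xi, yi) {
    # sum_{k>=yi} p(k|xi), extending the summation window until the last
    # term is negligible; the term ratio (xi+k+1)/(k+1) * N2/(N1+N2) drops
    # below 1, so the tail is eventually geometric
    K <- 256L
    repeat {
      k <- yi:(yi + K)
      lp <- k * lr + lgamma(xi + k + 1) - lgamma(xi + 1) - lgamma(k + 1) -
        (xi + k + 1) * l1r
      if (lp[length(lp)] < max(lp) + log(1e-18) || K > 2e6) break
      K <- K * 4L
    }
    min(exp(logsumexp(lp)), 1)
  }
  p_low <- mapply(cum_low, x, y)
  # the exact complement avoids infinite summation but carries an absolute
  # rounding floor (~1e-15) that ruins small upper tails; below 0.5 the
  # tail is recomputed by direct upward summation at full relative accuracy
  p_high <- ifelse(y == 0, 1,
                   pmax(0, 1 - mapply(cum_low, x, pmax(y - 1, 0))))
  refine <- which(y > 0 & p_high < 0.5)
  if (length(refine)) {
    p_high[refine] <- mapply(upper_direct, x[refine], y[refine])
  }
  p_high[y == 0] <- 1
  p <- if (sided == "two") pmin(1, 2 * pmin(p_low, p_high)) else pmin(p_low, p_high)
  data.frame(x = x, y = y, p_low = p_low, p_high = p_high, p_value = p)
}

#' Partition expression records by the low-expression filter
#'
#' Records are filtered out when the normalized expression is below the
#' threshold in both libraries (default reading) or in either library
#' (`mode = "either"`).
#'
#' @param records data.frame with columns `tpm1`, `tpm2`.
#' @param threshold TPM threshold (default 10).
#' @param mode `"both"` (filter when below threshold in both libraries,
#'   default) or `"either"`.
#' @return list with data.frames `retained` and `filtered`.
#' @export
filter_low_expression <- function(records, threshold = 10, mode = c("both", "either")) {
  mode <- match.arg(mode)
  low <- if (mode == "both") {
    records$tpm1 < threshold & records$tpm2 < threshold
  } else {
    records$tpm1 < threshold | records$tpm2 < threshold
  }
  list(retained = records[!low, , drop = FALSE],
       filtered = records[low, , drop = FALSE])
}

#' Call differential expression from fold change and p-value
#'
#' `up` when log2fc >= log2(fc_cutoff) and p < p_cutoff; `down` when
#' log2fc <= -log2(fc_cutoff) and p < p_cutoff; otherwise `ns`. The
#' fold-change cut-off is linear by default (1.5-fold, i.e. |log2fc| >=
#' 0.585); `fc_scale = "log2"` treats the cut-off as a log2 threshold.
#'
#' @param log2fc numeric log2 fold change(s).
#' @param p_value numeric p-value(s).
#' @param fc_cutoff fold-change cut-off (default 1.5).
#' @param p_cutoff p-value cut-off (default 0.01).
#' @param fc_scale `"linear"` (default) or `"log2"`.
#' @return character vector of calls in `up`, `down`, `ns`.
#' @export
call_de <- function(log2fc, p_value, fc_cutoff = 1.5, p_cutoff = 0.01,
                    fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  lfc_cut <- if (fc_scale == "linear") log2(fc_cutoff) else fc_cutoff
  out <- rep("ns", length(log2fc))
  out[log2fc >= lfc_cut & p_value < p_cutoff] <- "up"
  out[log2fc <= -lfc_cut & p_value < p_cutoff] <- "down"
  out
}

#' Two-library differential expression analysis
#'
#' Runs the whole module on a per-miRNA count table: TPM normalization,
#' low-expression filtering, log2 fold change (treatment over control), the
#' exact two-library test, DE calls, and an informational BH-adjusted column
#' (never used in the calls, since no multiple-testing correction enters the
#' cut-off rule).
#'
#' @param counts data.frame with columns `id`, `x` (control count), `y`
#'   (treatment count).
#' @param N1,N2 total clean reads in the control / treatment library.
#' @param fc_cutoff,p_cutoff,fc_scale see [call_de()].
#' @param min_tpm low-expression TPM threshold (default 10).
#' @param filter_mode `"both"` or `"either"`, see [filter_low_expression()].
#' @param pseudo_tpm TPM floor used inside the fold change only.
#' @param sided sidedness of the exact test, see [ac_pvalue()].
#' @return data.frame with columns `id`, `x`, `y`, `tpm1`, `tpm2`, `log2fc`,
#'   `p_low`, `p_high`, `p_value`, `padj`, `call`; filtered records carry
#'   call `"filtered"` and NA test columns.
#' @export
de_analysis <- function(counts, N1, N2, fc_cutoff = 1.5, p_cutoff = 0.01,
                        fc_scale = c("linear", "log2"), min_tpm = 10,
                        filter_mode = c("both", "either"), pseudo_tpm = 0.01,
                        sided = c("two", "one")) {
  stopifnot(all(c("id", "x", "y") %in% names(counts)))
  rec <- data.frame(id = as.character(counts$id),
                    x = as.integer(counts$x), y = as.integer(counts$y),
                    stringsAsFactors = FALSE)
  rec$tpm1 <- normalize_tpm(rec$x, N1)
  rec$tpm2 <- normalize_tpm(rec$y, N2)
  parts <- filter_low_expression(rec, min_tpm, match.arg(filter_mode))
  ret <- parts$retained
  flt <- parts$filtered
  for (col in c("log2fc", "p_low", "p_high", "p_value", "padj")) {
    rec[[col]] <- NA_real_
  }
  rec$call <- "filtered"
  if (nrow(ret)) {
    lfc <- log2_fold_change(ret$tpm2, ret$tpm1, pseudo_tpm)
    tst <- ac_pvalue(ret$x, ret$y, N1, N2, match.arg(sided))
    i <- match(ret$id, rec$id)
    rec$log2fc[i] <- lfc
    rec$p_low[i] <- tst$p_low
    rec$p_high[i] <- tst$p_high
    rec$p_value[i] <- tst$p_value
    rec$padj[i] <- stats::p.adjust(tst$p_value, method = "BH")
    rec$call[i] <- call_de(lfc, tst$p_value, fc_cutoff, p_cutoff,
                           match.arg(fc_scale))
  }
  rec
}
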