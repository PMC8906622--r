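# Feature shortlisting: per-feature Welch tests on log values plus the
# 1.5-fold cutoff, the selection rule feeding all downstream vector
# statistics.

log_with_pseudo <- function(values) {
  pos <- values[values > 0]
  if (length(pos) == 0L) ov_stop("table is all zero; nothing to test", "value")
  log(pmax(values, min(pos) / 2))
}

samples_of_condition <- function(t, key) {
  g <- group_samples(t)
  if (is.null(g[[key]])) {
    ov_stop(sprintf("condition '%s' not present in table", key), "key")
  }
  g[[key]]
}

#' Differential test between two conditions with a fold-change cutoff
#'
#' For every feature: Welch two-sample t test on natural-log values
#' (zeros replaced by half the smallest positive value in the table
#' before logging), Benjamini-Hochberg adjustment across features, and
#' selection when `adjusted_p <= alpha` AND the b-over-a fold change is
#' at least `fc_cutoff` in either direction (`>= fc_cutoff` or
#' `<= 1/fc_cutoff`).
#'
#' @param t a [feature_table()].
#' @param a,b condition keys (see [condition_id()]); fold change is b
#'   over a.
#' @param alpha adjusted-p significance level (default 0.05).
#' @param fc_cutoff fold-change cutoff, `>= 1` (default 1.5).
#' @return data.frame with one row per feature: `feature_id`, `mean_a`,
#'   `mean_b`, `fold_change`, `p_value`, `adjusted_p`, `selected`.
#' @export
differential_test <- function(t, a, b, alpha = 0.05, fc_cutoff = 1.5) {
  stopifnot(inherits(t, "feature_table"))
  if (fc_cutoff < 1) ov_stop("fc_cutoff must be >= 1", "value")
  if (alpha < 0 || alpha > 1) ov_stop("alpha must be in [0, 1]", "value")
  sa <- samples_of_condition(t, a)
  sb <- samples_of_condition(t, b)
  if (length(sa) < 2L || length(sb) < 2L) {
    ov_stop("each condition needs at least 2 samples for a Welch test", "replication")
  }
  lv <- log_with_pseudo(t$values)
  xa <- lv[sa, , drop = FALSE]
  xb <- lv[sb, , drop = FALSE]
  raw_a <- colMeans(t$values[sa, , drop = FALSE])
  raw_b <- colMeans(t$values[sb, , drop = FALSE])
  p <- vapply(seq_len(ncol(lv)), function(j) {
    va <- xa[, j]; vb <- xb[, j]
    if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
      if (mean(va) == mean(vb)) 1 else 0
    } else {
      stats::t.test(vb, va)$p.value
    }
  }, numeric(1))
  adj <- stats::p.adjust(p, method = "BH")
  # fold change on the log scale (geometric means), matching the test
  fc <- exp(colMeans(xb) - colMeans(xa))
  res <- data.frame(
    feature_id = colnames(t$values),
    mean_a = raw_a, mean_b = raw_b,
    fold_change = fc, p_value = p, adjusted_p = adj,
    selected = adj <= alpha & (fc >= fc_cutoff | fc <= 1 / fc_cutoff),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "contrast") <- c(a = a, b = b)
  res
}

#' Shortlists for a set of condition contrasts
#'
#' Applies [differential_test()] per contrast and returns the selected
#' feature sets, the union structure consumed by the overlap and
#' pro/anti ratio analytics.
#'
#' @param t a [feature_table()].
#' @param contrasts list of 2-vectors `c(a, b)` of condition keys.
#' @param alpha,fc_cutoff passed to [differential_test()].
#' @return Named list (one entry per contrast, named `"a vs b"`):
#'   character vector of selected feature ids, with the full result
#'   data.frame in attribute `"result"`.
#' @export
shortlist_matrix <- function(t, contrasts, alpha = 0.05, fc_cutoff = 1.5) {
  out <- list()
  for (ct in contrasts) {
    res <- differential_test(t, ct[1], ct[2], alpha = alpha, fc_cutoff = fc_cutoff)
    sel <- res$feature_id[res$selected]
    attr(sel, "result") <- res
    out[[paste(ct[1], "vs", ct[2])]] <- sel
  }
  out
}
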