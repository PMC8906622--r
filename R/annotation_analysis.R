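# Annotation-level analytics: pro/anti-inflammatory ratios of
# shortlists, common/unique overlap counts, the clinical
# disease-activity score, condition-level correlation of inflammation
# markers with taxa and metabolic categories.

#' Pro/anti-inflammatory ratio of a feature shortlist
#'
#' Counts shortlisted features by inflammation label and reports
#' n_pro / n_anti. When no anti-labelled feature is present the ratio is
#' explicitly undefined (`NA` with `undefined = TRUE`) rather than
#' infinite, so downstream consumers fail loudly.
#'
#' @param selected character vector of feature ids (e.g. one entry of
#'   [shortlist_matrix()]).
#' @param annotation an [annotation_table()] covering every selected
#'   feature.
#' @return List: `n_pro`, `n_anti`, `n_neutral`, `ratio` (numeric or
#'   `NA`), `undefined` (logical).
#' @export
pro_anti_ratio <- function(selected, annotation) {
  lab <- annotation$label[match(selected, annotation$feature_id)]
  if (any(is.na(lab))) {
    ov_stop(sprintf("unannotated feature(s): %s",
                    paste(selected[is.na(lab)], collapse = ", ")), "annotation")
  }
  n_pro <- sum(lab == "pro"); n_anti <- sum(lab == "anti")
  list(n_pro = n_pro, n_anti = n_anti, n_neutral = sum(lab == "neutral"),
       ratio = if (n_anti > 0) n_pro / n_anti else NA_real_,
       undefined = n_anti == 0)
}

#' Common/unique overlap counts of two feature sets
#'
#' The Venn-diagram arithmetic comparing shortlists (e.g. the two
#' strains' significantly altered genes).
#'
#' @param left,right character vectors (treated as sets).
#' @return List: `n_common`, `n_unique_left`, `n_unique_right`.
#' @export
overlap_counts <- function(left, right) {
  left <- unique(left); right <- unique(right)
  list(n_common = length(intersect(left, right)),
       n_unique_left = length(setdiff(left, right)),
       n_unique_right = length(setdiff(right, left)))
}

#' Clinical disease-severity score
#'
#' Grades each record on the standard DSS disease-activity rubric:
#' weight loss <1% -> 0, 1-5% -> 1, 5-10% -> 2, 10-15% -> 3, >15% -> 4;
#' stool-consistency and rectal-bleeding grades pass through; the total
#' (0-12) is their sum. Band edges and grade sources can be replaced via
#' `rubric`.
#'
#' @param records a [clinical_records()] object.
#' @param rubric list with element `weight_breaks`: increasing loss-%
#'   cut points mapped to grades 1..4 (default `c(1, 5, 10, 15)`).
#' @return data.frame: `sample_id`, `weight_grade`, `stool_grade`,
#'   `blood_grade`, `total`.
#' @export
clinical_severity_score <- function(records, rubric = list(weight_breaks = c(1, 5, 10, 15))) {
  stopifnot(inherits(records, "clinical_records"))
  br <- rubric$weight_breaks
  if (length(br) != 4L || is.unsorted(br, strictly = TRUE)) {
    ov_stop("rubric$weight_breaks must be 4 strictly increasing loss percentages", "value")
  }
  loss <- pmax(0, -records$weight_change)
  wg <- findInterval(loss, br)   # < br[1] -> 0 ... >= br[4] -> 4
  data.frame(sample_id = records$sample_id,
             weight_grade = as.integer(wg),
             stool_grade = records$stool_grade,
             blood_grade = records$blood_grade,
             total = as.integer(wg + records$stool_grade + records$blood_grade),
             stringsAsFactors = FALSE)
}

#' Condition-level correlation of two variable blocks
#'
#' Correlates every column of `x_block` with every column of `y_block`
#' across conditions (rows), with Benjamini-Hochberg adjustment over all
#' cell tests. Spearman by default: with ~12 conditions, rank
#' correlation is the defensible choice. Constant columns yield an `NA`
#' cell flagged in `reason`.
#'
#' @param x_block,y_block numeric matrices/data.frames with identical
#'   row sets (conditions, >= 3) and named columns.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List of class `correlation_matrix`: `r`, `p`, `adjusted_p`
#'   (matrices rows = x columns, cols = y columns), `reason` (character
#'   matrix, `NA` where defined), `method`, `n`.
#' @export
correlate_blocks <- function(x_block, y_block, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- as.matrix(x_block); y <- as.matrix(y_block)
  if (nrow(x) != nrow(y)) ov_stop("blocks must share the condition (row) set", "value")
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    if (!setequal(rownames(x), rownames(y))) {
      ov_stop("blocks must share the condition (row) set", "value")
    }
    y <- y[rownames(x), , drop = FALSE]
  }
  if (nrow(x) < 3L) ov_stop("need >= 3 conditions to correlate", "value")
  r <- p <- matrix(NA_real_, ncol(x), ncol(y), dimnames = list(colnames(x), colnames(y)))
  reason <- matrix(NA_character_, ncol(x), ncol(y), dimnames = dimnames(r))
  for (i in seq_len(ncol(x))) for (j in seq_len(ncol(y))) {
    xi <- x[, i]; yj <- y[, j]
    if (stats::sd(xi) == 0 || stats::sd(yj) == 0) {
      reason[i, j] <- "constant vector: correlation undefined"
    } else {
      ct <- suppressWarnings(stats::cor.test(xi, yj, method = method, exact = FALSE))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  adj <- p
  adj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  structure(list(r = r, p = p, adjusted_p = adj, reason = reason,
                 method = method, n = nrow(x)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %s over %d conditions\n", x$method, x$n))
  print(round(x$r, 3))
  invisible(x)
}

#' Per-category mean log fold change of a condition vs its day-0 control
#'
#' Aggregates a metabolite table into category scores: for each category
#' (e.g. carbohydrate / nucleotide / amino-acid / lipid metabolism), the
#' mean over member features of the condition-mean natural-log fold
#' change against the day-0 control of the same strain. Uncategorized
#' features are excluded; empty categories are dropped with a warning.
#'
#' @param t a [feature_table()].
#' @param categories named character vector: feature_id -> category.
#' @param condition condition key to score.
#' @return Named numeric vector of category scores.
#' @export
category_score <- function(t, categories, condition) {
  cond <- parse_condition(condition)
  ref <- condition_id(cond$strain, 0L, "control")
  sids <- samples_of_condition(t, condition)
  rids <- samples_of_condition(t, ref)
  lv <- log_with_pseudo(t$values)
  lfc <- colMeans(lv[sids, , drop = FALSE]) - colMeans(lv[rids, , drop = FALSE])
  cats <- categories[colnames(t$values)]
  keep <- !is.na(cats)
  out <- numeric(0)
  for (cc in unique(stats::na.omit(unname(cats)))) {
    members <- keep & cats == cc
    if (!any(members)) {
      ov_warn(sprintf("category '%s' has no features in the table; dropped", cc))
      next
    }
    out[cc] <- mean(lfc[members])
  }
  if (length(out) == 0L) return(out)
  out[order(names(out))]
}
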