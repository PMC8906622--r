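# OTU filtering, total-sum scaling, taxonomic aggregation and the
# Evenness Index (Shannon entropy of a composition), with
# treated/control evenness ratios per strain and day.

#' Filter OTUs by minimum count and prevalence
#'
#' Keeps an OTU iff its count is at least `min_count` in at least
#' `ceiling(prevalence * n_samples)` samples; the sample set is
#' unchanged. Defaults are the conventional minimum count of 2 at 20%
#' prevalence.
#'
#' @param t an otu-layer [feature_table()].
#' @param min_count non-negative integer count threshold.
#' @param prevalence required fraction of samples in `[0, 1]`.
#' @return A [feature_table()] with the surviving OTUs.
#' @export
filter_otus <- function(t, min_count = 2, prevalence = 0.2) {
  stopifnot(inherits(t, "feature_table"))
  if (min_count < 0) ov_stop("min_count must be >= 0", "value")
  if (prevalence < 0 || prevalence > 1) ov_stop("prevalence must be in [0, 1]", "value")
  need <- ceiling(prevalence * nrow(t$values))
  keep <- colSums(t$values >= min_count) >= need
  feature_table(t$values[, keep, drop = FALSE], t$layer, t$metadata)
}

#' Total-sum scaling to relative abundances
#'
#' Divides each sample's values by its total so every sample's
#' proportions sum to 1.
#'
#' @param t a [feature_table()] with positive sample totals.
#' @return An `abundance_profile`: list with `proportions` (samples x
#'   features matrix of row-stochastic proportions), `rank` (feature
#'   rank label), `metadata`.
#' @export
total_sum_scale <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  tot <- rowSums(t$values)
  if (any(tot <= 0)) {
    ov_stop(sprintf("sample(s) with zero total: %s",
                    paste(rownames(t$values)[tot <= 0], collapse = ", ")), "degenerate")
  }
  structure(list(proportions = t$values / tot,
                 rank = if (t$layer == "otu") "otu" else "metabolite",
                 metadata = t$metadata),
            class = "abundance_profile")
}

#' Aggregate an abundance profile to a taxonomic rank
#'
#' Sums proportions within rank groups (e.g. genus-level OTUs up to
#' phylum); per-sample totals stay 1.
#'
#' @param p an `abundance_profile` from [total_sum_scale()].
#' @param tax a [taxonomy_map()] resolving every feature at `rank`.
#' @param rank a rank column of `tax` (e.g. `"phylum"`, `"genus"`).
#' @return An `abundance_profile` at the requested rank.
#' @export
aggregate_taxa <- function(p, tax, rank) {
  stopifnot(inherits(p, "abundance_profile"))
  if (!rank %in% setdiff(names(tax), "feature_id")) {
    ov_stop(sprintf("unknown rank '%s' (have: %s)", rank,
                    paste(setdiff(names(tax), "feature_id"), collapse = ", ")), "value")
  }
  fids <- colnames(p$proportions)
  grp <- tax[[rank]][match(fids, tax$feature_id)]
  if (any(is.na(grp))) {
    ov_stop(sprintf("feature(s) missing from taxonomy: %s",
                    paste(fids[is.na(grp)], collapse = ", ")), "key")
  }
  levels <- sort(unique(grp))
  agg <- vapply(levels, function(g)
    rowSums(p$proportions[, grp == g, drop = FALSE]), numeric(nrow(p$proportions)))
  if (nrow(p$proportions) == 1L) agg <- matrix(agg, nrow = 1, dimnames = list(rownames(p$proportions), levels))
  structure(list(proportions = agg, rank = rank, metadata = p$metadata),
            class = "abundance_profile")
}

#' Evenness Index of a composition
#'
#' `E = -sum_i p_i ln p_i` over the entries of a proportion vector
#' (Shannon entropy in nats; `0 * ln 0 := 0`). Maximal at `ln k` for a
#' uniform composition over `k` categories, 0 when one category holds
#' everything. `normalize = TRUE` divides by `ln k` (Pielou evenness),
#' an optional variant beyond the plain index.
#'
#' @param proportions non-negative numeric vector summing to 1 within
#'   1e-9.
#' @param normalize divide by `ln(k)`? Default FALSE (plain index).
#' @return Non-negative scalar.
#' @examples
#' evenness_index(rep(1 / 4, 4)) # log(4)
#' @export
evenness_index <- function(proportions, normalize = FALSE) {
  p <- as.numeric(proportions)
  if (any(!is.finite(p)) || any(p < 0)) ov_stop("proportions must be finite and >= 0", "value")
  if (abs(sum(p) - 1) > 1e-9) ov_stop("proportions must sum to 1 (within 1e-9)", "value")
  pp <- p[p > 0]
  e <- -sum(pp * log(pp))
  if (normalize) {
    k <- length(p)
    if (k > 1L) e <- e / log(k)
  }
  e
}

# condition-mean composition vectors (pooled replicates) of a profile
condition_mean_proportions <- function(p) {
  keys <- metadata_condition_ids(p$metadata)
  out <- t(vapply(sort(unique(keys)), function(k)
    colMeans(p$proportions[keys == k, , drop = FALSE]),
    numeric(ncol(p$proportions))))
  colnames(out) <- colnames(p$proportions)
  out
}

#' Per-condition Evenness Index and treated/control ratios
#'
#' Computes E on each condition's mean composition (replicates pooled by
#' averaging proportions; `per_sample = TRUE` instead averages
#' per-sample E values), then the treated/control E ratio for every
#' (strain, day).
#'
#' @param p an `abundance_profile` (any rank).
#' @param per_sample average per-sample evenness instead of evenness of
#'   the mean composition.
#' @return List of class `evenness_report`: `evenness` (data.frame
#'   strain/day/arm/E) and `ratios` (data.frame strain/day/ratio).
#' @export
evenness_ratio_report <- function(p, per_sample = FALSE) {
  stopifnot(inherits(p, "abundance_profile"))
  keys <- metadata_condition_ids(p$metadata)
  uk <- sort(unique(keys))
  E <- if (per_sample) {
    vapply(uk, function(k) mean(apply(p$proportions[keys == k, , drop = FALSE],
                                      1, evenness_index)), numeric(1))
  } else {
    cm <- condition_mean_proportions(p)
    apply(cm, 1, evenness_index)
  }
  parsed <- lapply(uk, parse_condition)
  ev <- data.frame(strain = vapply(parsed, `[[`, "", "strain"),
                   day = vapply(parsed, `[[`, 0L, "day"),
                   arm = vapply(parsed, `[[`, "", "arm"),
                   E = as.numeric(E), stringsAsFactors = FALSE)
  ratios <- NULL
  for (st in unique(ev$strain)) for (dy in unique(ev$day[ev$strain == st])) {
    et <- ev$E[ev$strain == st & ev$day == dy & ev$arm == "treated"]
    ec <- ev$E[ev$strain == st & ev$day == dy & ev$arm == "control"]
    if (length(et) == 1L && length(ec) == 1L) {
      if (ec == 0) ov_stop(sprintf("control evenness is 0 at %s day %d", st, dy), "degenerate")
      ratios <- rbind(ratios, data.frame(strain = st, day = dy, ratio = et / ec,
                                         stringsAsFactors = FALSE))
    }
  }
  if (is.null(ratios)) {
    ov_stop("no (strain, day) has both arms; cannot form treated/control ratios", "value")
  }
  structure(list(evenness = ev, ratios = ratios), class = "evenness_report")
}

#' @export
print.evenness_report <- function(x, ...) {
  cat("<evenness_report>\n")
  print(x$evenness, row.names = FALSE)
  cat("treated/control ratios:\n")
  print(x$ratios, row.names = FALSE)
  invisible(x)
}

#' Count features detected in a condition
#'
#' Number of features whose condition-mean value exceeds a detection
#' threshold — the richness-style count used to track how many
#' metabolites are present at each disease stage.
#'
#' @param t a [feature_table()].
#' @param condition condition key.
#' @param detect_threshold numeric threshold (strictly exceeded).
#' @return Non-negative integer.
#' @export
count_detected_features <- function(t, condition, detect_threshold = 0) {
  sids <- samples_of_condition(t, condition)
  cm <- colMeans(t$values[sids, , drop = FALSE])
  sum(cm > detect_threshold)
}
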