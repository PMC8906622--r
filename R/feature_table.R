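#' Construct a validated feature table
#'
#' The common currency of all three omics layers: a samples x features
#' matrix of finite non-negative values (counts or concentrations)
#' together with per-sample design metadata. Zero is the explicit
#' representation of an absent/undetected feature; missing cells are not
#' allowed.
#'
#' @param values numeric matrix, samples in rows, features in columns,
#'   with unique non-empty dimnames.
#' @param layer one of `"transcript"`, `"serum_metabolite"`,
#'   `"cecal_metabolite"`, `"otu"`.
#' @param metadata data.frame with columns `sample_id`, `strain`, `day`,
#'   `arm` covering every sample in `values`.
#' @return An object of class `feature_table` with elements `values`,
#'   `layer`, `metadata` (metadata rows reordered to match `values`).
#' @seealso [read_feature_table()], [group_samples()]
#' @export
feature_table <- function(values, layer, metadata) {
  layers <- c("transcript", "serum_metabolite", "cecal_metabolite", "otu")
  if (!is.character(layer) || length(layer) != 1L || !layer %in% layers) {
    ov_stop(sprintf("layer must be one of: %s", paste(layers, collapse = ", ")), "value")
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    ov_stop("values must be a numeric matrix (samples x features)", "value")
  }
  sids <- rownames(values)
  fids <- colnames(values)
  if ((is.null(sids) && nrow(values) > 0L) || (is.null(fids) && ncol(values) > 0L) ||
      any(sids == "") || any(fids == "")) {
    ov_stop("values must carry sample (row) and feature (column) names", "format")
  }
  if (anyDuplicated(sids)) {
    ov_stop(sprintf("duplicated sample id(s): %s",
                    paste(unique(sids[duplicated(sids)]), collapse = ", ")), "format")
  }
  if (anyDuplicated(fids)) {
    ov_stop(sprintf("duplicated feature id(s): %s",
                    paste(unique(fids[duplicated(fids)]), collapse = ", ")), "format")
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    ov_stop(sprintf("non-finite or negative value at sample '%s', feature '%s'",
                    sids[bad[1, 1]], fids[bad[1, 2]]), "value")
  }
  need <- c("sample_id", "strain", "day", "arm")
  if (!is.data.frame(metadata) || !all(need %in% names(metadata))) {
    ov_stop("metadata must be a data.frame with columns sample_id, strain, day, arm", "metadata")
  }
  missing <- setdiff(sids, metadata$sample_id)
  if (length(missing) > 0L) {
    ov_stop(sprintf("sample(s) without metadata: %s", paste(missing, collapse = ", ")), "metadata")
  }
  metadata <- metadata[match(sids, metadata$sample_id), need, drop = FALSE]
  metadata$day <- as.integer(metadata$day)
  # validates day/arm values as a side effect
  invisible(condition_id(metadata$strain, metadata$day, metadata$arm))
  rownames(metadata) <- NULL
  structure(list(values = values, layer = layer, metadata = metadata),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> layer=%s: %d samples x %d features\n",
              x$layer, nrow(x$values), ncol(x$values)))
  conds <- sort(unique(metadata_condition_ids(x$metadata)))
  cat(sprintf("  %d conditions: %s\n", length(conds),
              paste(utils::head(conds, 4), collapse = ", ")),
      if (length(conds) > 4) "  ...\n" else "")
  invisible(x)
}

#' Partition the samples of a feature table by condition
#'
#' Groups samples by their (strain, day, arm) condition key. The result
#' is always a disjoint cover of the sample set, with keys sorted for
#' reproducibility.
#'
#' @param t a [feature_table()].
#' @return Named list: condition key -> character vector of sample ids.
#' @export
group_samples <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  ids <- metadata_condition_ids(t$metadata)
  g <- split(t$metadata$sample_id, ids)
  g[order(names(g))]
}

#' Taxonomy map: OTU feature -> ranked lineage
#'
#' @param df data.frame with column `feature_id` plus one column per rank
#'   (at minimum `phylum` and `genus`); unknown ranks are the explicit
#'   string `"unclassified"`.
#' @return A `taxonomy_map` object (validated data.frame).
#' @export
taxonomy_map <- function(df) {
  if (!is.data.frame(df) || !all(c("feature_id", "phylum", "genus") %in% names(df))) {
    ov_stop("taxonomy map needs columns feature_id, phylum, genus", "format")
  }
  if (anyDuplicated(df$feature_id)) ov_stop("duplicated feature_id in taxonomy map", "format")
  ranks <- setdiff(names(df), "feature_id")
  for (r in ranks) df[[r]] <- as.character(df[[r]])
  structure(df, class = c("taxonomy_map", "data.frame"))
}

#' Annotation table: feature -> inflammation label
#'
#' @param df data.frame with columns `feature_id` and `label`; labels are
#'   restricted to `"pro"`, `"anti"`, `"neutral"`.
#' @param layer omics layer tag the annotation belongs to.
#' @return An `annotation_table` object.
#' @export
annotation_table <- function(df, layer = "transcript") {
  if (!is.data.frame(df) || !all(c("feature_id", "label") %in% names(df))) {
    ov_stop("annotation table needs columns feature_id, label", "format")
  }
  bad <- setdiff(unique(df$label), c("pro", "anti", "neutral"))
  if (length(bad) > 0L) {
    ov_stop(sprintf("annotation labels must be pro/anti/neutral, got: %s",
                    paste(bad, collapse = ", ")), "annotation")
  }
  if (anyDuplicated(df$feature_id)) ov_stop("duplicated feature_id in annotation table", "format")
  structure(df, layer = layer, class = c("annotation_table", "data.frame"))
}

#' Clinical observation records
#'
#' One record per sample: weight change relative to day 0 (percent,
#' negative = loss), and integer stool-consistency and rectal-bleeding
#' grades on the 0-4 disease-activity rubric.
#'
#' @param df data.frame with columns `sample_id`, `weight_change`,
#'   `stool_grade`, `blood_grade`.
#' @return A `clinical_records` object.
#' @export
clinical_records <- function(df) {
  need <- c("sample_id", "weight_change", "stool_grade", "blood_grade")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    ov_stop("clinical records need columns sample_id, weight_change, stool_grade, blood_grade", "format")
  }
  if (any(!is.finite(df$weight_change))) ov_stop("weight_change must be finite", "value")
  for (g in c("stool_grade", "blood_grade")) {
    v <- df[[g]]
    if (any(!is.finite(v) | v < 0 | v > 4 | v != floor(v))) {
      ov_stop(sprintf("%s must be an integer in 0..4", g), "value")
    }
    df[[g]] <- as.integer(v)
  }
  structure(df[need], class = c("clinical_records", "data.frame"))
}
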