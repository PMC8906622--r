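# End-to-end orchestration: simulate -> shortlist -> project ->
# vector stats -> microbiome profiles -> annotation analytics ->
# correlations, with a reproducibility manifest. All stage outputs are
# plain TSV; each stage reads its inputs back from the output tree, so
# deleting one stage's files and rerunning regenerates that stage and
# its dependents only.

#' Build a validated pipeline run configuration
#'
#' @param outdir output directory (created if missing).
#' @param seed integer master seed.
#' @param calibration calibration YAML path or parsed list (default:
#'   built-in study calibration).
#' @param alpha,fc_cutoff shortlisting parameters (see
#'   [differential_test()]).
#' @param shrinkage LDA shrinkage (see [discriminant_plane()]).
#' @param center Disease Severity Index center rule (see
#'   [disease_severity_index()]).
#' @param min_count,prevalence OTU filter parameters (see
#'   [filter_otus()]).
#' @param weight_breaks clinical rubric bands (see
#'   [clinical_severity_score()]).
#' @return A validated `run_config` list.
#' @export
run_config <- function(outdir, seed = 1, calibration = NULL,
                       alpha = 0.05, fc_cutoff = 1.5, shrinkage = "auto",
                       center = "global-mean", min_count = 2, prevalence = 0.2,
                       weight_breaks = c(1, 5, 10, 15)) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) ov_stop("alpha must be in (0, 1]", "value")
  if (!is.numeric(fc_cutoff) || fc_cutoff < 1) ov_stop("fc_cutoff must be >= 1", "value")
  if (!identical(shrinkage, "auto") &&
      (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1)) {
    ov_stop("shrinkage must be 'auto' or in [0, 1]", "value")
  }
  if (prevalence < 0 || prevalence > 1) ov_stop("prevalence must be in [0, 1]", "value")
  if (!is_count(min_count)) ov_stop("min_count must be a non-negative integer", "value")
  if (!is.numeric(seed) || length(seed) != 1L || seed != floor(seed)) {
    ov_stop("seed must be a single integer", "value")
  }
  if (is.character(calibration) && !file.exists(calibration)) {
    ov_stop(sprintf("calibration file not found: %s", calibration), "io")
  }
  structure(list(outdir = outdir, seed = as.integer(seed), calibration = calibration,
                 alpha = alpha, fc_cutoff = fc_cutoff, shrinkage = shrinkage,
                 center = center, min_count = min_count, prevalence = prevalence,
                 weight_breaks = weight_breaks),
            class = "run_config")
}

path_in <- function(cfg, ...) file.path(cfg$outdir, ...)

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

expression_layers <- c("transcript", "serum_metabolite", "cecal_metabolite")

stage_simulate <- function(cfg) {
  study <- default_study(cfg$calibration, seed = cfg$seed)
  for (layer in names(study$tables)) {
    write_feature_table(study$tables[[layer]], path_in(cfg, paste0(layer, ".tsv")))
  }
  write_metadata(study$metadata, path_in(cfg, "metadata.tsv"))
  write_taxonomy(study$taxonomy, path_in(cfg, "taxonomy.tsv"))
  for (layer in names(study$annotations)) {
    write_annotation(study$annotations[[layer]], path_in(cfg, paste0("annotation_", layer, ".tsv")))
  }
  for (layer in names(study$categories)) {
    write_tsv(data.frame(feature_id = names(study$categories[[layer]]),
                         category = unname(study$categories[[layer]])),
              path_in(cfg, paste0("categories_", layer, ".tsv")))
  }
  write_clinical(study$clinical, path_in(cfg, "clinical.tsv"))
}

read_layer <- function(cfg, layer) {
  read_feature_table(path_in(cfg, paste0(layer, ".tsv")), layer, path_in(cfg, "metadata.tsv"))
}

# treated-arm day contrasts per strain: 0->7, 0->15, 7->15
strain_contrasts <- function(strain, days = c(0, 7, 15)) {
  pairs <- utils::combn(sort(days), 2)
  lapply(seq_len(ncol(pairs)), function(j)
    c(condition_id(strain, pairs[1, j], "treated"),
      condition_id(strain, pairs[2, j], "treated")))
}

stage_shortlist <- function(cfg) {
  for (layer in expression_layers) {
    t <- read_layer(cfg, layer)
    rows <- NULL
    for (strain in unique(t$metadata$strain)) {
      for (ct in strain_contrasts(strain, unique(t$metadata$day))) {
        res <- differential_test(t, ct[1], ct[2], alpha = cfg$alpha,
                                 fc_cutoff = cfg$fc_cutoff)
        res <- cbind(contrast = paste(ct[1], "vs", ct[2]), res)
        rows <- rbind(rows, res)
      }
    }
    write_tsv(rows, path_in(cfg, paste0("shortlist_", layer, ".tsv")))
  }
}

read_shortlist <- function(cfg, layer) {
  utils::read.delim(path_in(cfg, paste0("shortlist_", layer, ".tsv")),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

stage_project <- function(cfg) {
  for (layer in expression_layers) {
    t <- read_layer(cfg, layer)
    sl <- read_shortlist(cfg, layer)
    coords <- NULL; cents <- NULL
    for (strain in unique(t$metadata$strain)) {
      keep <- t$metadata$strain == strain
      sub <- feature_table(t$values[keep, , drop = FALSE], t$layer, t$metadata[keep, ])
      sel <- unique(sl$feature_id[sl$selected %in% c("TRUE", TRUE) &
                                    startsWith(sl$contrast, strain)])
      feats <- if (length(sel) >= 2) intersect(colnames(sub$values), sel) else colnames(sub$values)
      sub <- feature_table(sub$values[, feats, drop = FALSE], t$layer, sub$metadata)
      fit <- discriminant_plane(sub, shrinkage = cfg$shrinkage)
      coords <- rbind(coords, data.frame(
        sample_id = rownames(fit$scores), condition = unname(fit$grouping),
        LD1 = fit$scores[, 1], LD2 = fit$scores[, 2],
        strain = strain, stringsAsFactors = FALSE, row.names = NULL))
      cents <- rbind(cents, data.frame(
        condition = rownames(fit$centroids),
        LD1 = fit$centroids[, 1], LD2 = fit$centroids[, 2],
        strain = strain, shrinkage = fit$shrinkage,
        stringsAsFactors = FALSE, row.names = NULL))
    }
    write_tsv(coords, path_in(cfg, paste0("coords_", layer, ".tsv")))
    write_tsv(cents, path_in(cfg, paste0("centroids_", layer, ".tsv")))
  }
}

#' Rebuild a minimal embedding from written-out coordinates
#'
#' @param coords data.frame with columns `sample_id`, `condition`,
#'   `LD1`, `LD2` (as written by the pipeline's project stage).
#' @return A `discriminant_plane`-compatible embedding usable by the
#'   vector statistics.
#' @export
embedding_from_coords <- function(coords) {
  scores <- as.matrix(coords[, c("LD1", "LD2")])
  rownames(scores) <- coords$sample_id
  grouping <- stats::setNames(coords$condition, coords$sample_id)
  keys <- sort(unique(coords$condition))
  cents <- t(vapply(keys, function(k)
    colMeans(scores[grouping == k, , drop = FALSE]), numeric(2)))
  structure(list(scores = scores, centroids = cents, grouping = grouping),
            class = "discriminant_plane")
}

stage_vectorstats <- function(cfg) {
  for (layer in expression_layers) {
    coords <- utils::read.delim(path_in(cfg, paste0("coords_", layer, ".tsv")),
                                check.names = FALSE, stringsAsFactors = FALSE)
    rows <- NULL; drows <- NULL; trows <- NULL
    for (strain in unique(coords$strain)) {
      e <- embedding_from_coords(coords[coords$strain == strain, ])
      pr <- pairwise_dissimilarity(e)
      rows <- rbind(rows, cbind(strain = strain, layer = layer, pr))
      treated <- paste0(strain, "|", c(0, 7, 15), "|treated")
      treated <- treated[treated %in% rownames(e$centroids)]
      for (i in seq_len(length(treated) - 1)) for (j in seq(i + 1, length(treated))) {
        drows <- rbind(drows, data.frame(
          strain = strain, layer = layer,
          cond_a = treated[i], cond_b = treated[j],
          D = disease_severity_index(e, treated[i], treated[j], center = cfg$center),
          stringsAsFactors = FALSE))
      }
      tr <- trajectory(e, treated)
      trows <- rbind(trows, data.frame(
        strain = strain, layer = layer,
        from = tr$conditions[-length(tr$conditions)], to = tr$conditions[-1],
        length = tr$lengths, stringsAsFactors = FALSE))
    }
    write_tsv(rows, path_in(cfg, paste0("dissimilarity_", layer, ".tsv")))
    write_tsv(drows, path_in(cfg, paste0("severity_index_", layer, ".tsv")))
    write_tsv(trows, path_in(cfg, paste0("trajectory_", layer, ".tsv")))
  }
}

stage_microbiome <- function(cfg) {
  otu <- read_layer(cfg, "otu")
  tax <- read_taxonomy(path_in(cfg, "taxonomy.tsv"))
  filt <- filter_otus(otu, min_count = cfg$min_count, prevalence = cfg$prevalence)
  prof <- total_sum_scale(filt)
  for (rank in c("phylum", "genus")) {
    agg <- aggregate_taxa(prof, tax, rank)
    cm <- condition_mean_proportions(agg)
    write_tsv(cbind(data.frame(condition = rownames(cm), stringsAsFactors = FALSE),
                    as.data.frame(cm)),
              path_in(cfg, paste0("profile_", rank, ".tsv")))
    if (rank == "phylum") {
      rep <- evenness_ratio_report(agg)
      write_tsv(rep$evenness, path_in(cfg, "evenness_phylum.tsv"))
      write_tsv(rep$ratios, path_in(cfg, "evenness_ratio_phylum.tsv"))
    }
  }
}

stage_annotation <- function(cfg) {
  rrows <- NULL
  sl_by_layer <- list()
  for (layer in expression_layers) {
    ann <- read_annotation(path_in(cfg, paste0("annotation_", layer, ".tsv")), layer)
    sl <- read_shortlist(cfg, layer)
    sl_by_layer[[layer]] <- sl
    for (ct in unique(sl$contrast)) {
      sel <- sl$feature_id[sl$contrast == ct & sl$selected %in% c("TRUE", TRUE)]
      pa <- pro_anti_ratio(sel, ann)
      rrows <- rbind(rrows, data.frame(
        layer = layer, contrast = ct, n_pro = pa$n_pro, n_anti = pa$n_anti,
        n_neutral = pa$n_neutral,
        ratio = if (pa$undefined) "undefined" else fmt_num(pa$ratio),
        stringsAsFactors = FALSE))
    }
  }
  write_tsv(rrows, path_in(cfg, "pro_anti_ratios.tsv"))

  # strain-vs-strain overlap of shortlists for matching day contrasts
  orows <- NULL
  for (layer in expression_layers) {
    sl <- sl_by_layer[[layer]]
    cts <- unique(sl$contrast)
    strains <- unique(sub("\\|.*$", "", cts))
    if (length(strains) == 2) {
      for (ct1 in cts[startsWith(cts, strains[1])]) {
        ct2 <- gsub(strains[1], strains[2], ct1, fixed = TRUE)
        if (!ct2 %in% cts) next
        oc <- overlap_counts(sl$feature_id[sl$contrast == ct1 & sl$selected %in% c("TRUE", TRUE)],
                             sl$feature_id[sl$contrast == ct2 & sl$selected %in% c("TRUE", TRUE)])
        orows <- rbind(orows, data.frame(
          layer = layer, left = ct1, right = ct2,
          n_common = oc$n_common, n_unique_left = oc$n_unique_left,
          n_unique_right = oc$n_unique_right, stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(orows)) write_tsv(orows, path_in(cfg, "overlaps.tsv"))

  records <- read_clinical(path_in(cfg, "clinical.tsv"))
  scores <- clinical_severity_score(records, rubric = list(weight_breaks = cfg$weight_breaks))
  write_tsv(scores, path_in(cfg, "clinical_scores.tsv"))
}

stage_correlate <- function(cfg) {
  phylum <- utils::read.delim(path_in(cfg, "profile_phylum.tsv"),
                              check.names = FALSE, stringsAsFactors = FALSE)
  rownames(phylum) <- phylum$condition
  ybl <- as.matrix(phylum[, -1, drop = FALSE])

  meta <- read_metadata(path_in(cfg, "metadata.tsv"))
  keys <- sort(unique(metadata_condition_ids(meta)))

  tr <- read_layer(cfg, "transcript")
  ann <- read_annotation(path_in(cfg, "annotation_transcript.tsv"), "transcript")
  lv <- log_with_pseudo(tr$values)
  kk <- metadata_condition_ids(tr$metadata)
  marker_mean <- function(lab) vapply(keys, function(k)
    mean(lv[kk == k, ann$feature_id[ann$label == lab], drop = FALSE]), numeric(1))
  xbl <- cbind(pro_marker = marker_mean("pro"), anti_marker = marker_mean("anti"))

  scores <- utils::read.delim(path_in(cfg, "clinical_scores.tsv"),
                              check.names = FALSE, stringsAsFactors = FALSE)
  sk <- metadata_condition_ids(meta[match(scores$sample_id, meta$sample_id), ])
  xbl <- cbind(xbl, clinical = vapply(keys, function(k) mean(scores$total[sk == k]), numeric(1)))

  cats_rows <- NULL
  for (layer in c("serum_metabolite", "cecal_metabolite")) {
    t <- read_layer(cfg, layer)
    cmap <- utils::read.delim(path_in(cfg, paste0("categories_", layer, ".tsv")),
                              check.names = FALSE, stringsAsFactors = FALSE)
    categories <- stats::setNames(cmap$category, cmap$feature_id)
    cs <- t(vapply(keys, function(k) category_score(t, categories, k), numeric(4)))
    colnames(cs) <- paste(substr(layer, 1, 1), colnames(cs), sep = "_")
    cats_rows <- if (is.null(cats_rows)) cs else cbind(cats_rows, cs)
  }
  ybl <- cbind(ybl[keys, , drop = FALSE], cats_rows[keys, , drop = FALSE])

  cm <- correlate_blocks(xbl[keys, , drop = FALSE], ybl, method = "spearman")
  long <- expand.grid(x = rownames(cm$r), y = colnames(cm$r),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$r <- as.numeric(cm$r[cbind(long$x, long$y)])
  long$p <- as.numeric(cm$p[cbind(long$x, long$y)])
  long$adjusted_p <- as.numeric(cm$adjusted_p[cbind(long$x, long$y)])
  long$reason <- cm$reason[cbind(long$x, long$y)]
  write_tsv(long, path_in(cfg, "correlations.tsv"))
}

pipeline_stages <- function() {
  list(
    simulate = list(fn = stage_simulate,
                    outputs = c("transcript.tsv", "serum_metabolite.tsv",
                                "cecal_metabolite.tsv", "otu.tsv", "metadata.tsv",
                                "taxonomy.tsv", "annotation_transcript.tsv",
                                "annotation_serum_metabolite.tsv",
                                "annotation_cecal_metabolite.tsv",
                                "categories_serum_metabolite.tsv",
                                "categories_cecal_metabolite.tsv", "clinical.tsv")),
    shortlist = list(fn = stage_shortlist,
                     outputs = paste0("shortlist_", expression_layers, ".tsv")),
    project = list(fn = stage_project,
                   outputs = c(paste0("coords_", expression_layers, ".tsv"),
                               paste0("centroids_", expression_layers, ".tsv"))),
    vectorstats = list(fn = stage_vectorstats,
                       outputs = c(paste0("dissimilarity_", expression_layers, ".tsv"),
                                   paste0("severity_index_", expression_layers, ".tsv"),
                                   paste0("trajectory_", expression_layers, ".tsv"))),
    microbiome = list(fn = stage_microbiome,
                      outputs = c("profile_phylum.tsv", "profile_genus.tsv",
                                  "evenness_phylum.tsv", "evenness_ratio_phylum.tsv")),
    annotation = list(fn = stage_annotation,
                      outputs = c("pro_anti_ratios.tsv", "overlaps.tsv",
                                  "clinical_scores.tsv")),
    correlate = list(fn = stage_correlate, outputs = "correlations.tsv")
  )
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order under `config$outdir` and
#' writes a reproducibility manifest (`manifest.json`: config echo,
#' package version, seed, per-file MD5 checksums). A stage whose outputs
#' all exist is skipped unless a stage it depends on was rerun, so the
#' pipeline is restartable after deleting any stage's files. The
#' manifest contains no volatile fields: rerunning with the same config
#' and seed reproduces it byte for byte.
#'
#' @param config a [run_config()].
#' @param force rerun all stages even if outputs exist.
#' @param quiet suppress per-stage log lines.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- pipeline_stages()
  dirty <- force
  for (name in names(stages)) {
    st <- stages[[name]]
    have <- file.exists(path_in(config, st$outputs))
    if (dirty || !all(have)) {
      t0 <- proc.time()[["elapsed"]]
      tryCatch(st$fn(config), error = function(e) {
        ov_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), "stage")
      })
      dirty <- TRUE
      if (!quiet) message(sprintf("[omivec] stage %-11s wrote %2d file(s) in %.1fs",
                                  name, length(st$outputs),
                                  proc.time()[["elapsed"]] - t0))
    } else if (!quiet) {
      message(sprintf("[omivec] stage %-11s up to date, skipped", name))
    }
  }
  files <- sort(unlist(lapply(stages, `[[`, "outputs"), use.names = FALSE))
  sums <- tools::md5sum(path_in(config, files))
  manifest <- list(
    package = "omivec",
    version = as.character(utils::packageVersion("omivec")),
    seed = config$seed,
    config = config[setdiff(names(config), c("outdir", "calibration"))],
    calibration = if (is.character(config$calibration)) basename(config$calibration) else "built-in",
    files = stats::setNames(as.list(unname(sums)), files)
  )
  jsonlite::write_json(manifest, path_in(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
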