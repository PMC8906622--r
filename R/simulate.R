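# Synthetic multi-omics study generator. The defaults (in
# inst/extdata/default_calibration.yaml) encode the strain x day x arm
# design of a DSS-colitis time course: overdispersed 16S counts via a
# Dirichlet-multinomial, log-normal expression/concentration layers with
# label-specific condition shifts, and jittered clinical grades. One
# master seed is split deterministically per layer/condition so
# regenerating one layer never perturbs another.

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9]", "", x)

make_sample_ids <- function(strain, day, arm, n) {
  sprintf("%s_d%d_%s_%d", sanitize_label(strain), day, arm, seq_len(n))
}

#' Per-condition taxon composition profile
#'
#' Holds the expected genus-level proportions for every condition of the
#' design plus a Dirichlet concentration controlling replicate
#' overdispersion (larger = tighter around the expected composition;
#' `Inf` gives exact multinomial sampling at the stated proportions).
#'
#' @param taxa data.frame with columns `feature_id`, `genus`, `phylum`.
#' @param proportions named list: condition key -> named numeric vector of
#'   proportions over `taxa$genus`, each summing to 1 within 1e-9.
#' @param concentration positive scalar (may be `Inf`).
#' @return A `composition_profile` object.
#' @export
composition_profile <- function(taxa, proportions, concentration) {
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration <= 0) {
    ov_stop("concentration must be a positive scalar", "value")
  }
  taxa <- taxonomy_map(taxa)
  for (key in names(proportions)) {
    p <- unlist(proportions[[key]])
    if (!setequal(names(p), taxa$genus)) {
      ov_stop(sprintf("proportions for '%s' do not cover the taxon set", key), "value")
    }
    p <- p[taxa$genus]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      ov_stop(sprintf("proportions for '%s' must be non-negative and sum to 1", key), "value")
    }
    proportions[[key]] <- p
  }
  structure(list(taxa = taxa, proportions = proportions, concentration = concentration),
            class = "composition_profile")
}

#' Simulate an OTU count table from a composition profile
#'
#' For each condition, `n_per_group` samples are drawn from a
#' Dirichlet-multinomial: a composition is drawn from
#' Dirichlet(concentration x proportions), then counts from
#' Multinomial(depth, composition). Counts of every sample sum exactly to
#' `depth`. With `concentration = Inf` the Dirichlet step is skipped and
#' counts are plain multinomial at the stated proportions.
#'
#' @param profile a [composition_profile()].
#' @param n_per_group samples per condition.
#' @param depth sequencing depth (total count) per sample.
#' @param seed integer master seed.
#' @return List with elements `table` (an otu-layer [feature_table()])
#'   and `taxonomy` (a [taxonomy_map()]).
#' @export
simulate_otu_table <- function(profile, n_per_group, depth, seed) {
  stopifnot(inherits(profile, "composition_profile"))
  if (!is_count(n_per_group) || n_per_group < 1) ov_stop("n_per_group must be >= 1", "value")
  if (!is_count(depth) || depth < 1) ov_stop("depth must be >= 1", "value")
  if (depth < nrow(profile$taxa)) {
    ov_warn(sprintf("depth %d is below the number of taxa (%d); rare taxa will drop out",
                    depth, nrow(profile$taxa)))
  }
  keys <- sort(names(profile$proportions))
  k <- nrow(profile$taxa)
  rows <- list(); meta <- list()
  for (key in keys) {
    cond <- parse_condition(key)
    p <- profile$proportions[[key]]
    set.seed(derive_seed(seed, paste0("otu/", key)))
    comp <- if (is.infinite(profile$concentration)) {
      matrix(rep(p, each = n_per_group), nrow = n_per_group)
    } else {
      rdirichlet(n_per_group, profile$concentration * p)
    }
    cm <- vapply(seq_len(n_per_group),
                 function(i) as.numeric(stats::rmultinom(1, depth, comp[i, ])),
                 numeric(k))
    counts <- if (k == 1L) matrix(cm, ncol = 1L) else t(cm)
    sids <- make_sample_ids(cond$strain, cond$day, cond$arm, n_per_group)
    dimnames(counts) <- list(sids, profile$taxa$feature_id)
    rows[[key]] <- counts
    meta[[key]] <- data.frame(sample_id = sids, strain = cond$strain,
                              day = cond$day, arm = cond$arm,
                              stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, rows)
  metadata <- do.call(rbind, c(meta, make.row.names = FALSE))
  list(table = feature_table(values, "otu", metadata), taxonomy = profile$taxa)
}

#' Effect profile for a log-normal expression/concentration layer
#'
#' Each feature has a baseline log-mean and log-sd; each condition adds a
#' label-specific (pro/anti/neutral) log-scale mean shift. A simulated
#' value is `exp(log_mean + shift + N(0, log_sd))`, so shifts are
#' additive on the log scale and multiplicative fold changes on the
#' natural scale, matching fold-change shortlisting semantics.
#'
#' @param layer omics layer tag.
#' @param baseline data.frame with columns `feature_id`, `log_mean`,
#'   `log_sd` (log_sd >= 0).
#' @param shifts named list: condition key -> named numeric vector with
#'   entries `pro` and `anti` (neutral is always 0); missing conditions
#'   shift by 0.
#' @param metadata sample design data.frame (sample_id, strain, day, arm).
#' @return An `effect_profile` object.
#' @export
effect_profile <- function(layer, baseline, shifts, metadata) {
  if (!all(c("feature_id", "log_mean", "log_sd") %in% names(baseline))) {
    ov_stop("baseline needs columns feature_id, log_mean, log_sd", "format")
  }
  if (any(baseline$log_sd < 0)) ov_stop("log_sd must be >= 0", "value")
  structure(list(layer = layer, baseline = baseline, shifts = shifts,
                 metadata = metadata),
            class = "effect_profile")
}

#' Simulate one expression / metabolite layer
#'
#' @param effects an [effect_profile()].
#' @param annotation an [annotation_table()] labelling every baseline
#'   feature pro/anti/neutral.
#' @param seed integer master seed.
#' @return A [feature_table()] of the profile's layer.
#' @export
simulate_feature_layer <- function(effects, annotation, seed) {
  stopifnot(inherits(effects, "effect_profile"))
  base <- effects$baseline
  lab <- annotation$label[match(base$feature_id, annotation$feature_id)]
  if (any(is.na(lab))) {
    ov_stop(sprintf("feature(s) without annotation label: %s",
                    paste(base$feature_id[is.na(lab)], collapse = ", ")), "annotation")
  }
  meta <- effects$metadata
  keys <- metadata_condition_ids(meta)
  values <- matrix(0, nrow = nrow(meta), ncol = nrow(base),
                   dimnames = list(meta$sample_id, base$feature_id))
  for (key in sort(unique(keys))) {
    idx <- which(keys == key)
    sh <- effects$shifts[[key]]
    shift_by_label <- c(pro = 0, anti = 0, neutral = 0)
    if (!is.null(sh)) shift_by_label[names(sh)] <- unlist(sh)
    mu <- base$log_mean + shift_by_label[lab]
    set.seed(derive_seed(seed, paste0(effects$layer, "/", key)))
    noise <- matrix(stats::rnorm(length(idx) * nrow(base), sd = rep(base$log_sd, each = length(idx))),
                    nrow = length(idx))
    values[idx, ] <- exp(matrix(mu, nrow = length(idx), ncol = nrow(base), byrow = TRUE) + noise)
  }
  feature_table(values, effects$layer, meta)
}

#' Simulate clinical observation records
#'
#' Grades are the per-condition rubric values jittered by at most
#' `grade_noise` (integer, uniform on -noise..noise) and clamped to the
#' 0-4 rubric; weight change gets Gaussian noise.
#'
#' @param design sample design data.frame (sample_id, strain, day, arm).
#' @param severity_map named list: condition key -> list(weight, stool,
#'   blood); every design condition must be present.
#' @param grade_noise non-negative integer jitter bound.
#' @param weight_sd Gaussian sd of the weight-change noise (percent).
#' @param seed integer master seed.
#' @return A [clinical_records()] object, one row per design sample.
#' @export
simulate_clinical <- function(design, severity_map, grade_noise = 1, weight_sd = 1, seed = 1) {
  keys <- metadata_condition_ids(design)
  if (!is_count(grade_noise)) ov_stop("grade_noise must be a non-negative integer", "value")
  for (key in unique(keys)) {
    sm <- severity_map[[key]]
    if (is.null(sm)) ov_stop(sprintf("severity_map missing condition '%s'", key), "key")
    if (any(unlist(sm[c("stool", "blood")]) < 0 | unlist(sm[c("stool", "blood")]) > 4)) {
      ov_stop(sprintf("severity_map grades for '%s' outside 0..4", key), "value")
    }
  }
  out <- design["sample_id"]
  out$weight_change <- NA_real_
  out$stool_grade <- NA_integer_
  out$blood_grade <- NA_integer_
  for (key in sort(unique(keys))) {
    idx <- which(keys == key)
    sm <- severity_map[[key]]
    set.seed(derive_seed(seed, paste0("clinical/", key)))
    out$weight_change[idx] <- sm$weight + stats::rnorm(length(idx), sd = weight_sd)
    jit <- function(g) pmin(4L, pmax(0L, g + sample(seq(-grade_noise, grade_noise), length(idx), replace = TRUE)))
    out$stool_grade[idx] <- jit(sm$stool)
    out$blood_grade[idx] <- jit(sm$blood)
  }
  clinical_records(out)
}

#' Load the study calibration config
#'
#' @param path YAML calibration file; default is the package's built-in
#'   calibration of the DSS-colitis study design.
#' @return Parsed calibration list.
#' @export
default_calibration <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_calibration.yaml", package = "omivec")
  }
  if (!file.exists(path)) ov_stop(sprintf("calibration file not found: %s", path), "io")
  yaml::read_yaml(path)
}

# full 12-condition proportion list, filling unlisted conditions with the
# shared control profile
expand_proportions <- function(cal) {
  d <- cal$design
  keys <- as.character(t(outer(d$strains, unlist(lapply(d$days, function(day)
    paste(day, d$arms, sep = "|"))), paste, sep = "|")))
  props <- list()
  for (key in keys) {
    props[[key]] <- if (!is.null(cal$otu$proportions[[key]])) {
      cal$otu$proportions[[key]]
    } else {
      cal$otu$proportions$control
    }
  }
  props
}

design_metadata <- function(cal) {
  d <- cal$design
  grid <- expand.grid(rep = seq_len(d$n_per_group), arm = d$arms, day = d$days,
                      strain = d$strains, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_d%d_%s_%d", sanitize_label(grid$strain),
                                 grid$day, grid$arm, grid$rep),
             strain = grid$strain, day = grid$day, arm = grid$arm,
             stringsAsFactors = FALSE)
}

layer_bundle <- function(cal, layer, prefix, metadata, seed) {
  lc <- cal[[layer]]
  n <- lc$n_features
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  labels <- rep("neutral", n)
  labels[seq_len(lc$n_pro)] <- "pro"
  labels[lc$n_pro + seq_len(lc$n_anti)] <- "anti"
  ann <- annotation_table(data.frame(feature_id = ids, label = labels,
                                     stringsAsFactors = FALSE), layer = layer)
  set.seed(derive_seed(seed, paste0(layer, "/baseline")))
  baseline <- data.frame(feature_id = ids,
                         log_mean = stats::rnorm(n, lc$baseline_log_mean, lc$baseline_log_mean_sd),
                         log_sd = rep(lc$log_sd, n),
                         stringsAsFactors = FALSE)
  eff <- effect_profile(layer, baseline, lc$shifts, metadata)
  list(table = simulate_feature_layer(eff, ann, seed), annotation = ann,
       effects = eff)
}

# metabolic-category map used by the correlation analytics: pro features
# alternate amino_acid/lipid, anti features carbohydrate/nucleotide,
# neutral features cycle all four
metabolite_categories <- function(annotation) {
  labs <- annotation$label
  cats <- character(length(labs))
  cats[labs == "pro"] <- rep(c("amino_acid", "lipid"), length.out = sum(labs == "pro"))
  cats[labs == "anti"] <- rep(c("carbohydrate", "nucleotide"), length.out = sum(labs == "anti"))
  cats[labs == "neutral"] <- rep(c("carbohydrate", "nucleotide", "amino_acid", "lipid"),
                                 length.out = sum(labs == "neutral"))
  stats::setNames(cats, annotation$feature_id)
}

#' Generate the complete default synthetic study
#'
#' Builds the full 2-strain x 3-day x 2-arm x 3-replicate bundle the
#' analysis pipeline consumes: transcript, serum-metabolite and
#' cecal-metabolite tables, an OTU table with taxonomy, per-layer
#' inflammation annotations, metabolite category maps, and clinical
#' records — all calibrated by [default_calibration()].
#'
#' @param calibration calibration list or YAML path (default: built-in).
#' @param seed integer master seed; default taken from the calibration.
#' @return A list with elements `tables` (named by layer), `taxonomy`,
#'   `annotations`, `categories`, `clinical`, `metadata`, `calibration`,
#'   `seed`.
#' @examples
#' study <- default_study(seed = 1)
#' sapply(study$tables, function(t) dim(t$values))
#' @export
default_study <- function(calibration = NULL, seed = NULL) {
  cal <- if (is.list(calibration)) calibration else default_calibration(calibration)
  if (is.null(seed)) seed <- cal$seed
  metadata <- design_metadata(cal)

  taxa <- do.call(rbind, lapply(cal$otu$taxa, function(x)
    data.frame(feature_id = x$feature_id, genus = x$genus, phylum = x$phylum,
               stringsAsFactors = FALSE)))
  profile <- composition_profile(taxa, expand_proportions(cal), cal$otu$concentration)
  otu <- simulate_otu_table(profile, cal$design$n_per_group, cal$otu$depth, seed)

  tr <- layer_bundle(cal, "transcript", "gene", metadata, seed)
  se <- layer_bundle(cal, "serum_metabolite", "smet", metadata, seed)
  ce <- layer_bundle(cal, "cecal_metabolite", "cmet", metadata, seed)

  sev <- cal$clinical$severity
  keys <- unique(metadata_condition_ids(metadata))
  severity_map <- stats::setNames(lapply(keys, function(k)
    if (!is.null(sev[[k]])) sev[[k]] else sev$control), keys)
  clinical <- simulate_clinical(metadata, severity_map,
                                grade_noise = cal$clinical$grade_noise,
                                weight_sd = cal$clinical$weight_sd, seed = seed)

  list(
    tables = list(transcript = tr$table, serum_metabolite = se$table,
                  cecal_metabolite = ce$table, otu = otu$table),
    taxonomy = otu$taxonomy,
    annotations = list(transcript = tr$annotation, serum_metabolite = se$annotation,
                       cecal_metabolite = ce$annotation),
    categories = list(serum_metabolite = metabolite_categories(se$annotation),
                      cecal_metabolite = metabolite_categories(ce$annotation)),
    clinical = clinical,
    metadata = metadata,
    calibration = cal,
    seed = seed
  )
}
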