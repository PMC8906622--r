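test_that("OTU counts conserve depth and hit the multinomial limit", {
  taxa <- data.frame(feature_id = c("o1", "o2"), genus = c("ga", "gb"),
                     phylum = c("pa", "pb"))
  prof <- composition_profile(taxa, list("C57BL/6|0|treated" = c(ga = 0.5, gb = 0.5)),
                              concentration = Inf)
  sim <- simulate_otu_table(prof, n_per_group = 1, depth = 1000, seed = 11)
  expect_identical(sum(sim$table$values), 1000)
  # multinomial at (.5,.5): 5 sigma ~ 79
  expect_lt(abs(sim$table$values[1, "o1"] - 500), 5 * sqrt(1000 * 0.25))

  single <- composition_profile(data.frame(feature_id = "o1", genus = "g", phylum = "p"),
                                list("C57BL/6|0|treated" = c(g = 1)), 10)
  ssim <- simulate_otu_table(single, 4, 777, seed = 2)
  expect_true(all(ssim$table$values == 777))
})

test_that("Dirichlet-multinomial means recover the profile proportions", {
  taxa <- data.frame(feature_id = paste0("o", 1:3), genus = paste0("g", 1:3),
                     phylum = paste0("p", 1:3))
  p0 <- c(g1 = 0.6, g2 = 0.3, g3 = 0.1)
  prof <- composition_profile(taxa, list("C57BL/6|0|treated" = p0), concentration = 50)
  sim <- simulate_otu_table(prof, n_per_group = 200, depth = 2000, seed = 5)
  props <- sim$table$values / rowSums(sim$table$values)
  for (j in 1:3) {
    se <- stats::sd(props[, j]) / sqrt(nrow(props))
    expect_lt(abs(mean(props[, j]) - p0[j]), 3 * se + 1e-12)
  }
})

test_that("simulators are bit-reproducible and per-stream independent", {
  study1 <- default_study(seed = 9)
  study2 <- default_study(seed = 9)
  expect_identical(study1$tables$otu$values, study2$tables$otu$values)
  expect_identical(study1$tables$transcript$values, study2$tables$transcript$values)
  expect_identical(as.data.frame(study1$clinical), as.data.frame(study2$clinical))
  # seed streams are split per layer: distinct layers differ
  expect_false(identical(study1$tables$serum_metabolite$values,
                         study1$tables$cecal_metabolite$values))
})

test_that("log-normal layer obeys noise-free limit and shift calibration", {
  meta <- data.frame(sample_id = paste0("s", 1:4), strain = "C57BL/6",
                     day = rep(c(0L, 15L), each = 2), arm = "treated")
  base <- data.frame(feature_id = c("f1", "f2"), log_mean = c(1, 2), log_sd = 0)
  ann <- annotation_table(data.frame(feature_id = c("f1", "f2"),
                                     label = c("pro", "neutral")))
  eff <- effect_profile("transcript", base, shifts = list(), metadata = meta)
  ft <- simulate_feature_layer(eff, ann, seed = 1)
  expect_equal(unname(ft$values[, "f1"]), rep(exp(1), 4))
  expect_equal(unname(ft$values[, "f2"]), rep(exp(2), 4))

  # planted shift log(4) on a pro feature: geometric-mean ratio ~ 4
  n <- 1000
  meta2 <- data.frame(sample_id = paste0("s", seq_len(2 * n)), strain = "C57BL/6",
                      day = rep(c(0L, 15L), each = n), arm = "treated")
  base2 <- data.frame(feature_id = "f1", log_mean = 1, log_sd = 0.5)
  eff2 <- effect_profile("transcript", base2,
                         shifts = list("C57BL/6|15|treated" = list(pro = log(4))),
                         metadata = meta2)
  ft2 <- simulate_feature_layer(eff2, annotation_table(
    data.frame(feature_id = "f1", label = "pro")), seed = 4)
  lv <- log(ft2$values[, 1])
  ratio <- exp(mean(lv[meta2$day == 15]) - mean(lv[meta2$day == 0]))
  se <- 0.5 * sqrt(2 / n) # sd of the log-mean difference
  expect_lt(abs(log(ratio) - log(4)), 3 * se)

  # a feature without a label is refused
  base3 <- rbind(base2, data.frame(feature_id = "f9", log_mean = 0, log_sd = 0.1))
  eff3 <- effect_profile("transcript", base3, list(), meta2)
  expect_error(simulate_feature_layer(eff3, annotation_table(
    data.frame(feature_id = "f1", label = "pro")), seed = 1),
    class = "omivec_error_annotation")
})

test_that("clinical simulation respects the jitter bound and rubric clamp", {
  key <- "C57BL/6|15|treated"
  design <- data.frame(sample_id = paste0("m", 1:500), strain = "C57BL/6",
                       day = 15L, arm = "treated")
  sev <- list(list(weight = -16, stool = 4, blood = 4))
  names(sev) <- key
  rec <- simulate_clinical(design, sev, grade_noise = 1, weight_sd = 0.5, seed = 6)
  expect_true(all(rec$stool_grade %in% c(3L, 4L)))
  expect_true(all(rec$blood_grade %in% c(3L, 4L)))
  rec0 <- simulate_clinical(design, sev, grade_noise = 0, weight_sd = 0, seed = 6)
  expect_true(all(rec0$stool_grade == 4L))
  expect_true(all(rec0$weight_change == -16))

  sev_bad <- list(list(weight = 0, stool = 7, blood = 0)); names(sev_bad) <- key
  expect_error(simulate_clinical(design, sev_bad, seed = 1), class = "omivec_error_value")
})

test_that("default study bundle is valid and matches its calibration peaks", {
  study <- default_study(seed = 21)
  for (t in study$tables) {
    expect_s3_class(t, "feature_table")
    expect_true(all(is.finite(t$values)) && all(t$values >= 0))
  }
  expect_true(all(rowSums(study$tables$otu$values) == study$calibration$otu$depth))
  expect_setequal(study$taxonomy$feature_id, colnames(study$tables$otu$values))

  # treated C57BL/6 day-15 Proteobacteria mean over seeds vs calibration
  cal <- study$calibration
  target <- cal$otu$proportions[["C57BL/6|15|treated"]]$Helicobacter
  reps <- vapply(1:20, function(s) {
    st <- default_study(seed = s)
    prof <- aggregate_taxa(total_sum_scale(filter_otus(st$tables$otu)),
                           st$taxonomy, "phylum")
    keys <- with(prof$metadata, condition_id(strain, day, arm))
    mean(prof$proportions[keys == "C57BL/6|15|treated", "Proteobacteria"])
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - target), 3 * se)
})
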