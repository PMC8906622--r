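ann_fixture <- annotation_table(data.frame(
  feature_id = paste0("f", 1:12),
  label = rep(c("pro", "anti", "neutral"), each = 4)))

test_that("pro/anti ratios count labels and flag undefined denominators", {
  r <- pro_anti_ratio(c("f1", "f2", "f3", "f5", "f9"), ann_fixture)
  expect_identical(r$n_pro, 3L); expect_identical(r$n_anti, 1L)
  expect_identical(r$n_neutral, 1L)
  expect_equal(r$ratio, 3)
  expect_false(r$undefined)
  expect_identical(r$n_pro + r$n_anti + r$n_neutral, 5L)

  r0 <- pro_anti_ratio(c("f5", "f6"), ann_fixture)
  expect_equal(r0$ratio, 0)

  ru <- pro_anti_ratio(c("f1", "f2"), ann_fixture)
  expect_true(ru$undefined)
  expect_true(is.na(ru$ratio))

  err <- expect_error(pro_anti_ratio(c("f1", "zz"), ann_fixture),
                      class = "omivec_error_annotation")
  expect_match(conditionMessage(err), "zz")
})

test_that("overlap counts match brute-force set arithmetic", {
  oc <- overlap_counts(c("a", "b", "c"), c("b", "c", "d"))
  expect_identical(oc, list(n_common = 2L, n_unique_left = 1L, n_unique_right = 1L))
  expect_identical(overlap_counts(c("a"), c("b"))$n_common, 0L)
  expect_identical(overlap_counts(c("a", "b"), c("a", "b", "c"))$n_unique_left, 0L)

  set.seed(12)
  universe <- paste0("x", 1:40)
  for (i in 1:20) {
    l <- sample(universe, sample(0:25, 1))
    r <- sample(universe, sample(0:25, 1))
    oc <- overlap_counts(l, r)
    expect_identical(oc$n_common + oc$n_unique_left, length(unique(l)))
    expect_identical(oc$n_common + oc$n_unique_right, length(unique(r)))
    expect_identical(oc$n_common, sum(universe %in% l & universe %in% r))
  }
})

test_that("clinical scoring follows the disease-activity rubric", {
  rec <- clinical_records(data.frame(
    sample_id = c("healthy", "sick", "edge"),
    weight_change = c(0, -12, 15),   # weight GAIN never grades
    stool_grade = c(0L, 3L, 0L),
    blood_grade = c(0L, 2L, 0L)))
  sc <- clinical_severity_score(rec)
  expect_identical(sc$total, c(0L, 8L, 0L))
  expect_identical(sc$weight_grade, c(0L, 3L, 0L))

  # weight band edges: 1, 5, 10, 15 % loss
  bands <- clinical_severity_score(clinical_records(data.frame(
    sample_id = paste0("b", 1:6),
    weight_change = -c(0.5, 1, 4.9, 7, 14, 20),
    stool_grade = 0L, blood_grade = 0L)))
  expect_identical(bands$weight_grade, c(0L, 1L, 1L, 2L, 3L, 4L))

  # total non-decreasing in each grade
  set.seed(23)
  for (i in 1:20) {
    w <- -runif(1, 0, 25); s <- sample(0:3, 1); b <- sample(0:3, 1)
    base <- clinical_severity_score(clinical_records(data.frame(
      sample_id = "m", weight_change = w, stool_grade = s, blood_grade = b)))$total
    up <- clinical_severity_score(clinical_records(data.frame(
      sample_id = "m", weight_change = w, stool_grade = s + 1L, blood_grade = b)))$total
    expect_gte(up, base)
  }
})

test_that("block correlations hit exact values and handle degeneracy", {
  x <- cbind(a = 1:6)
  cm <- correlate_blocks(x, cbind(double = 2 * (1:6), neg = -(1:6)),
                         method = "pearson")
  expect_equal(unname(cm$r["a", "double"]), 1)
  expect_equal(unname(cm$r["a", "neg"]), -1)
  expect_true(all(abs(cm$r) <= 1, na.rm = TRUE))

  cmc <- correlate_blocks(x, cbind(flat = rep(3, 6)))
  expect_true(is.na(cmc$r["a", "flat"]))
  expect_match(cmc$reason["a", "flat"], "constant")

  set.seed(34)
  blk <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("v", 1:4)))
  sym <- correlate_blocks(blk, blk)
  expect_equal(sym$r, t(sym$r), tolerance = 1e-12)
  expect_equal(unname(diag(sym$r)), rep(1, 4))
  expect_error(correlate_blocks(blk[1:2, ], blk[1:2, ]), class = "omivec_error_value")
})

test_that("Proteobacteria tracks pro-inflammatory markers by construction", {
  hits <- vapply(1:20, function(s) {
    st <- default_study(seed = s)
    phy <- aggregate_taxa(total_sum_scale(filter_otus(st$tables$otu)),
                          st$taxonomy, "phylum")
    keys <- with(phy$metadata, condition_id(strain, day, arm))
    uk <- sort(unique(keys))
    proteo <- vapply(uk, function(k)
      mean(phy$proportions[keys == k, "Proteobacteria"]), numeric(1))
    tr <- st$tables$transcript
    ann <- st$annotations$transcript
    tk <- with(tr$metadata, condition_id(strain, day, arm))
    pro <- vapply(uk, function(k)
      mean(log(tr$values[tk == k, ann$feature_id[ann$label == "pro"]])), numeric(1))
    cor(proteo, pro, method = "spearman") > 0
  }, logical(1))
  expect_gte(sum(hits), 19L)
})

test_that("category scores aggregate log fold changes vs day-0 control", {
  # condition mean is exp(mu): two categories engineered to +1 and -1
  vals <- rbind(exp(c(0, 0, 0, 0)), exp(c(0, 0, 0, 0)),
                exp(c(1, 1, -1, -1)), exp(c(1, 1, -1, -1)))
  dimnames(vals) <- list(paste0("s", 1:4), paste0("f", 1:4))
  meta <- data.frame(sample_id = rownames(vals), strain = "C57BL/6",
                     day = rep(c(0L, 7L), each = 2),
                     arm = rep(c("control", "treated"), each = 2))
  ft <- feature_table(vals, "serum_metabolite", meta)
  cats <- c(f1 = "up_cat", f2 = "up_cat", f3 = "down_cat", f4 = "down_cat")
  sc <- category_score(ft, cats, condition_id("C57BL/6", 7, "treated"))
  expect_equal(sc, c(down_cat = -1, up_cat = 1))

  all_one <- category_score(ft, c(f1 = "only", f2 = "only", f3 = "only", f4 = "only"),
                            condition_id("C57BL/6", 7, "treated"))
  expect_equal(unname(all_one), 0)
  expect_length(category_score(ft, character(0), condition_id("C57BL/6", 7, "treated")), 0L)
})
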