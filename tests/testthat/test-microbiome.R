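test_that("the OTU filter applies count-and-prevalence arithmetic", {
  vals <- rbind(c(2, 1, 0), c(0, 1, 0), c(0, 1, 0), c(0, 1, 0), c(0, 1, 3))
  dimnames(vals) <- list(paste0("s", 1:5), c("keep", "drop", "also"))
  ft <- make_ft(vals, layer = "otu")
  kept <- filter_otus(ft, min_count = 2, prevalence = 0.2)
  # count >= 2 in 1/5 = 20% of samples is enough; all-ones never reaches 2
  expect_true("keep" %in% colnames(kept$values))
  expect_false("drop" %in% colnames(kept$values))
  expect_true("also" %in% colnames(kept$values))
  expect_identical(rownames(kept$values), rownames(vals))
  ident <- filter_otus(ft, min_count = 0, prevalence = 0)
  expect_identical(ident$values, ft$values)
})

test_that("total-sum scaling yields row-stochastic proportions, idempotently", {
  ft <- make_ft(matrix(c(2, 3, 5), 1, 3, dimnames = list("s1", c("a", "b", "c"))),
                layer = "otu")
  p <- total_sum_scale(ft)
  expect_equal(unname(p$proportions[1, ]), c(0.2, 0.3, 0.5))
  p2 <- total_sum_scale(make_ft(p$proportions, layer = "otu"))
  expect_equal(p2$proportions, p$proportions)

  one <- total_sum_scale(make_ft(matrix(7, 3, 1), layer = "otu"))
  expect_true(all(one$proportions == 1))

  zero <- make_ft(rbind(c(1, 1), c(0, 0)), layer = "otu")
  err <- expect_error(total_sum_scale(zero), class = "omivec_error_degenerate")
  expect_match(conditionMessage(err), "s2")
})

test_that("taxonomic aggregation conserves per-sample mass", {
  tax <- taxonomy_map(data.frame(feature_id = c("o1", "o2", "o3"),
                                 phylum = c("P1", "P1", "P2"),
                                 genus = c("g1", "g2", "g3")))
  ft <- make_ft(rbind(c(4, 6, 10), c(1, 1, 2)), layer = "otu")
  colnames(ft$values) <- c("o1", "o2", "o3")
  p <- total_sum_scale(ft)
  agg <- aggregate_taxa(p, tax, "phylum")
  expect_equal(rowSums(agg$proportions), c(s1 = 1, s2 = 1))
  expect_equal(unname(agg$proportions[1, c("P1", "P2")]), c(0.5, 0.5))
  expect_error(aggregate_taxa(p, tax, "family"), class = "omivec_error_value")
  # identity taxonomy leaves an aggregated profile unchanged
  idtax <- taxonomy_map(data.frame(feature_id = c("P1", "P2"),
                                   phylum = c("P1", "P2"), genus = c("P1", "P2")))
  again <- aggregate_taxa(agg, idtax, "phylum")
  expect_equal(again$proportions, agg$proportions)
})

test_that("phylum proportions equal the sum of member-genus proportions", {
  st <- default_study(seed = 8)
  prof <- total_sum_scale(filter_otus(st$tables$otu))
  gen <- aggregate_taxa(prof, st$taxonomy, "genus")
  phy <- aggregate_taxa(prof, st$taxonomy, "phylum")
  for (p in unique(st$taxonomy$phylum)) {
    members <- st$taxonomy$genus[st$taxonomy$phylum == p]
    members <- intersect(members, colnames(gen$proportions))
    expect_equal(unname(phy$proportions[, p]),
                 unname(rowSums(gen$proportions[, members, drop = FALSE])),
                 tolerance = 1e-12)
  }
})

test_that("the evenness index is Shannon entropy with its invariances", {
  expect_equal(evenness_index(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_identical(evenness_index(1), 0)
  expect_equal(evenness_index(c(0.5, 0.25, 0.25)), 1.5 * log(2), tolerance = 1e-12)
  expect_error(evenness_index(c(0.9, 0.2)), class = "omivec_error_value")
  expect_error(evenness_index(c(-0.1, 1.1)), class = "omivec_error_value")

  set.seed(55)
  for (i in 1:30) {
    k <- sample(2:10, 1)
    p <- as.numeric(rmultinom(1, 500, runif(k) + 0.05)) / 500
    expect_lte(evenness_index(p), log(k) + 1e-12)
    expect_equal(evenness_index(sample(p)), evenness_index(p), tolerance = 1e-12)
    expect_equal(evenness_index(c(p, 0)), evenness_index(p), tolerance = 1e-12)
  }
  expect_equal(evenness_index(rep(0.25, 4), normalize = TRUE), 1, tolerance = 1e-12)
})

test_that("merging two equal-proportion categories strictly lowers evenness", {
  set.seed(66)
  for (i in 1:30) {
    k <- sample(2:8, 1)
    p <- as.numeric(rmultinom(1, 400, runif(k) + 0.2)) / 400
    p <- p[p > 0]
    q <- p[1] / 2
    split_p <- c(q, q, p[-1])           # split one category into equal halves
    expect_gt(evenness_index(split_p / sum(split_p)),
              evenness_index(p / sum(p)))
  }
})

test_that("evenness ratios respond to arm differences as constructed", {
  mkprof <- function(tr_props) {
    vals <- rbind(c(0.5, 0.5), c(0.5, 0.5), tr_props, tr_props)
    dimnames(vals) <- list(paste0("s", 1:4), c("P1", "P2"))
    meta <- data.frame(sample_id = rownames(vals), strain = "C57BL/6", day = 7L,
                       arm = rep(c("control", "treated"), each = 2))
    total_sum_scale(feature_table(vals, "otu", meta))
  }
  eq <- evenness_ratio_report(mkprof(c(0.5, 0.5)))
  expect_equal(eq$ratios$ratio, 1)
  collapsed <- evenness_ratio_report(mkprof(c(1, 0)))
  expect_equal(collapsed$ratios$ratio, 0)
})

test_that("treated/control evenness falls with severity in C57BL/6", {
  ratios <- t(vapply(1:20, function(s) {
    st <- default_study(seed = s)
    phy <- aggregate_taxa(total_sum_scale(filter_otus(st$tables$otu)),
                          st$taxonomy, "phylum")
    rep <- evenness_ratio_report(phy)
    r <- rep$ratios[rep$ratios$strain == "C57BL/6", ]
    c(d0 = r$ratio[r$day == 0], d15 = r$ratio[r$day == 15])
  }, numeric(2)))
  expect_true(mean(ratios[, "d15"] < ratios[, "d0"]) >= 0.9)
  expect_lt(mean(ratios[, "d15"]), mean(ratios[, "d0"]))
})

test_that("detected-feature counts respect the threshold", {
  vals <- matrix(c(5, 5, 0.1, 0.1, 9, 9), 2, 3,
                 dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  ft <- make_ft(vals, days = 7L)
  expect_identical(count_detected_features(ft, cond(7), 0), 3L + 0L)
  expect_identical(count_detected_features(ft, cond(7), 100), 0L)
  expect_identical(count_detected_features(ft, cond(7), 1), 2L)
})
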