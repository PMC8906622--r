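# Programmatic fixtures shared across the suite.

# small feature table: one condition per n-sample block
make_ft <- function(values, layer = "serum_metabolite",
                    strain = "C57BL/6", days = 0L, arm = "treated") {
  n <- nrow(values)
  if (is.null(rownames(values)) && n > 0) rownames(values) <- paste0("s", seq_len(n))
  if (is.null(colnames(values)) && ncol(values) > 0) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  meta <- data.frame(sample_id = rownames(values),
                     strain = rep_len(strain, n),
                     day = rep_len(days, n),
                     arm = rep_len(arm, n),
                     stringsAsFactors = FALSE)
  feature_table(values, layer, meta)
}

# two-condition table with per-feature group means on the natural scale,
# multiplicative spread exp(+-d) so geometric means are exact
make_two_group_ft <- function(means_a, means_b, n = 3, d = 0.05) {
  spread <- exp(seq(-d, d, length.out = n))
  va <- outer(spread, means_a)
  vb <- outer(spread, means_b)
  values <- rbind(va, vb)
  rownames(values) <- paste0("s", seq_len(2 * n))
  colnames(values) <- paste0("f", seq_along(means_a))
  meta <- data.frame(sample_id = rownames(values),
                     strain = "C57BL/6",
                     day = rep(c(0L, 7L), each = n),
                     arm = "treated", stringsAsFactors = FALSE)
  feature_table(values, "serum_metabolite", meta)
}

cond <- function(day, arm = "treated", strain = "C57BL/6") condition_id(strain, day, arm)

# embedding fixture straight from point coordinates
make_embedding <- function(points, conditions) {
  embedding_from_coords(data.frame(
    sample_id = paste0("s", seq_len(nrow(points))),
    condition = conditions, LD1 = points[, 1], LD2 = points[, 2],
    stringsAsFactors = FALSE))
}

# independent Fisher-LDA oracle: dense generalized eigendecomposition of
# the scatter pencil via explicit solve() and a non-symmetric eigen call
# (the implementation uses symmetric whitening), same normalization
# (w' Wreg w = 1) and sign convention
fisher_oracle <- function(x, grouping, lambda) {
  groups <- sort(unique(grouping))
  n <- nrow(x); p <- ncol(x); g <- length(groups)
  xs <- sweep(x, 2, colMeans(x))
  means <- t(sapply(groups, function(k) colMeans(xs[grouping == k, , drop = FALSE])))
  sizes <- as.numeric(table(grouping)[groups])
  B <- t(means) %*% (means * sizes)
  xc <- xs - means[match(grouping, groups), , drop = FALSE]
  W <- crossprod(xc) / (n - g)
  Wreg <- (1 - lambda) * W + diag(lambda * mean(diag(W)), p)
  ev <- eigen(solve(Wreg) %*% B)
  ord <- order(Re(ev$values), decreasing = TRUE)
  w <- Re(ev$vectors[, ord[1:2], drop = FALSE])
  for (j in 1:2) {
    w[, j] <- w[, j] / sqrt(drop(t(w[, j]) %*% Wreg %*% w[, j]))
    if (w[which.max(abs(w[, j])), j] < 0) w[, j] <- -w[, j]
  }
  xs %*% w
}

# brute-force Disease Severity Index by explicit double loop
dsi_brute <- function(A, B, center) {
  total <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    rho_x <- sqrt(sum((A[i, ] - center)^2))
    rho_y <- sqrt(sum((B[j, ] - center)^2))
    rxy <- sqrt(sum((A[i, ] - B[j, ])^2))
    total <- total + rho_x * rho_y * rxy
  }
  total
}

# random Gaussian-cluster instance for LDA oracle checks
random_lda_instance <- function(n_groups = 3, per_group = 3, p = 5, sep = 3) {
  g <- rep(paste0("g", seq_len(n_groups)), each = per_group)
  mu <- matrix(rnorm(n_groups * p, sd = sep), n_groups, p)
  x <- mu[rep(seq_len(n_groups), each = per_group), ] + matrix(rnorm(length(g) * p), length(g), p)
  rownames(x) <- paste0("s", seq_along(g))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, g = g)
}
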