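# Shrinkage-regularized multi-class Fisher discriminant ordination.
# The study design pits a handful of replicates against thousands of
# features, so the within-class scatter is singular; the within-class
# covariance is shrunk toward a scaled identity (Ledoit-Wolf intensity
# by default) before solving the Fisher criterion.

# Ledoit-Wolf shrinkage intensity toward mean(diag)*I, computed on
# within-class-centered rows
lw_shrinkage <- function(xc) {
  n <- nrow(xc); p <- ncol(xc)
  s <- crossprod(xc) / n
  m <- mean(diag(s))
  d2 <- sum((s - diag(m, p))^2)
  if (d2 <= .Machine$double.eps) return(0)
  b2bar <- 0
  for (i in seq_len(n)) {
    xi <- xc[i, ]
    b2bar <- b2bar + sum((tcrossprod(xi) - s)^2)
  }
  b2 <- min(b2bar / n^2, d2)
  b2 / d2
}

#' Fit a 2D discriminant plane (regularized multi-class Fisher LDA)
#'
#' Projects samples onto the two leading Fisher discriminant axes: the
#' directions maximizing between-class over (regularized) within-class
#' scatter. Intended as an ordination of condition groups, not a
#' classifier. Axes are normalized to unit within-class variance
#' (`w' W w = 1`) and their sign is fixed so each axis's
#' largest-magnitude loading is positive, making coordinates
#' reproducible across runs and platforms.
#'
#' @param x samples x features numeric matrix, or a [feature_table()].
#' @param grouping character/factor of group labels per row of `x`; for
#'   a feature table it defaults to the sample condition keys.
#' @param shrinkage `"auto"` (Ledoit-Wolf intensity) or a number in
#'   `[0, 1]` mixing the within-class covariance with a scaled identity.
#' @param scale center and unit-variance scale features first (default
#'   TRUE; concentrations span scales).
#' @param ... passed between methods.
#' @return An object of class `discriminant_plane`: `scores` (n x 2),
#'   `centroids` (group x 2), `loadings` (p x 2), `explained` (length-2
#'   discriminant-eigenvalue ratios), `grouping`, `shrinkage` (the
#'   intensity used), plus the centering/scaling needed by `predict`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 15, 4)
#' g <- rep(c("a", "b", "c"), each = 5)
#' x[g == "b", 1] <- x[g == "b", 1] + 4
#' x[g == "c", 2] <- x[g == "c", 2] + 4
#' fit <- discriminant_plane(x, g)
#' centroids(fit)
#' @export
discriminant_plane <- function(x, ...) UseMethod("discriminant_plane")

#' @rdname discriminant_plane
#' @export
discriminant_plane.feature_table <- function(x, grouping = NULL, shrinkage = "auto",
                                             scale = TRUE, ...) {
  if (is.null(grouping)) grouping <- metadata_condition_ids(x$metadata)
  fit <- discriminant_plane.default(x$values, grouping, shrinkage = shrinkage,
                                    scale = scale)
  fit$layer <- x$layer
  fit
}

#' @rdname discriminant_plane
#' @export
discriminant_plane.default <- function(x, grouping, shrinkage = "auto",
                                       scale = TRUE, ...) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == nrow(x))
  sizes <- table(grouping)
  if (length(sizes) < 3L) {
    ov_stop(sprintf("need >= 3 groups for a 2D discriminant plane, got %d", length(sizes)),
            "dimensionality")
  }
  if (any(sizes < 2L)) {
    ov_stop(sprintf("every group needs >= 2 samples (offending: %s)",
                    paste(names(sizes)[sizes < 2], collapse = ", ")), "replication")
  }
  n <- nrow(x); p <- ncol(x); g <- length(sizes)

  center <- colMeans(x)
  scl <- if (scale) {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else rep(1, p)
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")

  groups <- sort(unique(grouping))
  means <- t(vapply(groups, function(gg) colMeans(xs[grouping == gg, , drop = FALSE]),
                    numeric(p)))
  xc <- xs - means[match(grouping, groups), , drop = FALSE]

  B <- crossprod(means * sqrt(as.numeric(sizes[groups])))      # between-class scatter
  if (sum(B^2) <= 1e-24) {
    ov_stop("zero between-class scatter: all group means coincide (degenerate input)",
            "degenerate")
  }
  W <- crossprod(xc) / (n - g)                                 # within-class covariance

  lam <- if (identical(shrinkage, "auto")) lw_shrinkage(xc) else {
    if (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1) {
      ov_stop("shrinkage must be 'auto' or a number in [0, 1]", "value")
    }
    shrinkage
  }
  Wreg <- (1 - lam) * W + diag(lam * mean(diag(W)), p)

  ew <- eigen(Wreg, symmetric = TRUE)
  if (min(ew$values) <= max(ew$values) * 1e-10) {
    ov_stop("within-class scatter is singular; use shrinkage > 0 (or 'auto')",
            "numerical")
  }
  whalf <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))    # Wreg^{-1/2}
  M <- whalf %*% B %*% whalf
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  evals <- pmax(em$values, 0)
  naxes <- min(2L, g - 1L, p)
  if (naxes < 2L) ov_stop("design admits fewer than 2 discriminant axes", "dimensionality")
  w <- whalf %*% em$vectors[, seq_len(naxes), drop = FALSE]    # w' Wreg w = I
  # sign convention: largest-|loading| entry of each axis is positive
  for (j in seq_len(naxes)) {
    if (w[which.max(abs(w[, j])), j] < 0) w[, j] <- -w[, j]
  }
  dimnames(w) <- list(colnames(x), paste0("LD", seq_len(naxes)))
  scores <- xs %*% w
  cents <- t(vapply(groups, function(gg) colMeans(scores[grouping == gg, , drop = FALSE]),
                    numeric(naxes)))
  colnames(cents) <- colnames(w)

  structure(list(
    scores = scores, centroids = cents, loadings = w,
    explained = evals[seq_len(naxes)] / sum(evals),
    eigenvalues = evals,
    grouping = stats::setNames(grouping, rownames(x)),
    shrinkage = lam, center = center, scale = scl, scaled = scale,
    call = match.call()
  ), class = "discriminant_plane")
}

#' Per-condition centroids of a discriminant plane
#'
#' @param e a `discriminant_plane` fit.
#' @return Matrix, one row per condition group, columns `LD1`, `LD2`.
#' @export
centroids <- function(e) UseMethod("centroids")

#' @export
centroids.discriminant_plane <- function(e) e$centroids

#' @export
print.discriminant_plane <- function(x, ...) {
  cat(sprintf("<discriminant_plane> %d samples, %d features, %d groups\n",
              nrow(x$scores), nrow(x$loadings), nrow(x$centroids)))
  cat(sprintf("  shrinkage = %.4f; discriminant ratio LD1 = %.3f, LD2 = %.3f\n",
              x$shrinkage, x$explained[1], x$explained[2]))
  invisible(x)
}

#' @export
summary.discriminant_plane <- function(object, ...) {
  sizes <- table(object$grouping)
  out <- list(n = nrow(object$scores), p = nrow(object$loadings),
              groups = sizes, shrinkage = object$shrinkage,
              explained = object$explained, centroids = object$centroids)
  class(out) <- "summary.discriminant_plane"
  out
}

#' @export
print.summary.discriminant_plane <- function(x, ...) {
  cat(sprintf("Discriminant plane: %d samples x %d features, %d groups\n",
              x$n, x$p, length(x$groups)))
  cat(sprintf("Shrinkage intensity: %.4f\n", x$shrinkage))
  cat(sprintf("Discriminant-eigenvalue ratio: LD1 %.3f, LD2 %.3f\n",
              x$explained[1], x$explained[2]))
  cat("Centroids:\n")
  print(round(x$centroids, 4))
  invisible(x)
}

#' @export
coef.discriminant_plane <- function(object, ...) object$loadings

#' @export
fitted.discriminant_plane <- function(object, ...) object$scores

#' Project new samples onto a fitted discriminant plane
#'
#' @param object a `discriminant_plane` fit.
#' @param newdata samples x features matrix (or [feature_table()]) with
#'   the same features as the fit.
#' @param ... unused.
#' @return n x 2 matrix of coordinates.
#' @export
predict.discriminant_plane <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center)) {
    ov_stop("newdata feature set does not match the fit", "value")
  }
  if (!is.null(colnames(newdata)) && !is.null(rownames(object$loadings)) &&
      !identical(colnames(newdata), rownames(object$loadings))) {
    newdata <- newdata[, rownames(object$loadings), drop = FALSE]
  }
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  xs %*% object$loadings
}

#' @export
plot.discriminant_plane <- function(x, trajectory = NULL, ...) {
  grp <- factor(x$grouping)
  cols <- grDevices::hcl.colors(nlevels(grp), "Dark 3")
  graphics::plot(x$scores[, 1], x$scores[, 2], col = cols[as.integer(grp)],
                 pch = 19, xlab = "LD1", ylab = "LD2", ...)
  graphics::points(x$centroids[, 1], x$centroids[, 2], pch = 3, cex = 1.5,
                   col = cols[match(rownames(x$centroids), levels(grp))])
  if (!is.null(trajectory)) {
    ctr <- x$centroids[trajectory, , drop = FALSE]
    graphics::lines(ctr[, 1], ctr[, 2], lty = 2)
    graphics::arrows(ctr[-nrow(ctr), 1], ctr[-nrow(ctr), 2],
                     ctr[-1, 1], ctr[-1, 2], length = 0.08)
  }
  graphics::legend("topright", legend = levels(grp), col = cols, pch = 19, cex = 0.6)
  invisible(x)
}
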