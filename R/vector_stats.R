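# Bespoke discriminant-plane statistics: the Dissimilarity Coefficient
# (Euclidean distance between condition centroids), its condition-pair
# ratios, centroid trajectories, and the Disease Severity Index
# D = sum over cross-condition sample pairs of rho_x * rho_y * r_xy.

as_point <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p))) {
    ov_stop("a plane point must be 2 finite coordinates", "value")
  }
  p
}

#' Dissimilarity Coefficient: distance between two plane points
#'
#' The package's measure of between-condition change: the Euclidean
#' distance `r = sqrt((x2-x1)^2 + (y2-y1)^2)` between two points
#' (typically condition centroids) on the discriminant plane.
#'
#' @param p1,p2 numeric length-2 coordinates.
#' @return Non-negative scalar; zero iff the points coincide.
#' @examples
#' dissimilarity_coefficient(c(0, 0), c(3, 4)) # 5
#' @export
dissimilarity_coefficient <- function(p1, p2) {
  p1 <- as_point(p1); p2 <- as_point(p2)
  sqrt(sum((p2 - p1)^2))
}

condition_centroid <- function(e, key) {
  ctr <- centroids(e)
  if (!key %in% rownames(ctr)) {
    ov_stop(sprintf("condition '%s' not in the embedding", key), "key")
  }
  ctr[key, ]
}

condition_scores <- function(e, key) {
  idx <- which(e$grouping == key)
  if (length(idx) == 0L) ov_stop(sprintf("condition '%s' has no samples", key), "key")
  e$scores[idx, , drop = FALSE]
}

#' Ratio of centroid distances for two condition pairs
#'
#' `r(pair_numerator) / r(pair_denominator)` on the embedding's
#' centroids; the kinetics readout comparing how far apart two disease
#' stages moved relative to another pair of stages.
#'
#' @param e a [discriminant_plane()] fit.
#' @param pair_numerator,pair_denominator 2-vectors of condition keys.
#' @return Positive scalar.
#' @export
dissimilarity_ratio <- function(e, pair_numerator, pair_denominator) {
  num <- dissimilarity_coefficient(condition_centroid(e, pair_numerator[1]),
                                   condition_centroid(e, pair_numerator[2]))
  den <- dissimilarity_coefficient(condition_centroid(e, pair_denominator[1]),
                                   condition_centroid(e, pair_denominator[2]))
  if (den == 0) {
    ov_stop("denominator pair has coincident centroids (degenerate geometry)",
            "degenerate")
  }
  num / den
}

#' Disease Severity Index between two conditions
#'
#' `D = sum over all cross pairs (x in A, y in B) of rho_x * rho_y *
#' r_xy`, where `rho` is a sample's distance from the center of the
#' plane and `r_xy` the distance between the two samples. Displacement
#' from the healthy center and separation between the two stages both
#' inflate D, making it a combined severity readout. The sum runs over
#' the full cross product of the two conditions' samples, which makes D
#' symmetric in its two conditions.
#'
#' @param e a [discriminant_plane()] fit.
#' @param cond_a,cond_b condition keys.
#' @param center `"global-mean"` (default: mean of all embedded
#'   samples), a condition key whose centroid to use, or a length-2
#'   numeric point.
#' @return Non-negative scalar.
#' @examples
#' # single cross pair: rho_x=3, rho_y=4, r=5 -> D = 60
#' @export
disease_severity_index <- function(e, cond_a, cond_b, center = "global-mean") {
  A <- condition_scores(e, cond_a)
  B <- condition_scores(e, cond_b)
  ctr <- if (is.numeric(center)) {
    as_point(center)
  } else if (identical(center, "global-mean")) {
    colMeans(e$scores)
  } else {
    condition_centroid(e, center)
  }
  rho_a <- sqrt(rowSums(sweep(A, 2, ctr)^2))
  rho_b <- sqrt(rowSums(sweep(B, 2, ctr)^2))
  # r_xy for all cross pairs
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  rxy <- sqrt(pmax(d2, 0))
  sum(outer(rho_a, rho_b) * rxy)
}

#' Centroid trajectory over an ordered set of conditions
#'
#' The polyline followed by condition centroids on the discriminant
#' plane (e.g. day 0 -> 7 -> 15 of one arm), with per-segment lengths
#' equal to the Dissimilarity Coefficient of consecutive centroids.
#'
#' @param e a [discriminant_plane()] fit.
#' @param ordered_conditions character vector (length >= 2) of condition
#'   keys in visit order.
#' @return List of class `plane_trajectory`: `conditions`, `points`
#'   (k x 2 matrix), `lengths` (k-1 segment lengths), `total`.
#' @export
trajectory <- function(e, ordered_conditions) {
  if (length(ordered_conditions) < 2L) {
    ov_stop("a trajectory needs at least 2 conditions", "value")
  }
  pts <- t(vapply(ordered_conditions, function(k) condition_centroid(e, k), numeric(2)))
  lens <- vapply(seq_len(nrow(pts) - 1L), function(i)
    dissimilarity_coefficient(pts[i, ], pts[i + 1L, ]), numeric(1))
  structure(list(conditions = ordered_conditions, points = pts,
                 lengths = lens, total = sum(lens)),
            class = "plane_trajectory")
}

#' @export
print.plane_trajectory <- function(x, ...) {
  cat("<plane_trajectory>", paste(x$conditions, collapse = " -> "), "\n")
  cat("  segment lengths:", paste(sprintf("%.4g", x$lengths), collapse = ", "),
      sprintf(" (total %.4g)\n", x$total))
  invisible(x)
}

#' All pairwise Dissimilarity Coefficients of an embedding
#'
#' @param e a [discriminant_plane()] fit.
#' @return data.frame with columns `cond_a`, `cond_b`, `r` for every
#'   unordered condition pair.
#' @export
pairwise_dissimilarity <- function(e) {
  ctr <- centroids(e)
  keys <- rownames(ctr)
  pairs <- utils::combn(keys, 2)
  data.frame(
    cond_a = pairs[1, ], cond_b = pairs[2, ],
    r = apply(pairs, 2, function(pp)
      dissimilarity_coefficient(ctr[pp[1], ], ctr[pp[2], ])),
    stringsAsFactors = FALSE
  )
}
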