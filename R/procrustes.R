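#' Normalized stress between two point configurations
#'
#' Compares the within-configuration Euclidean distance sets of two matched
#' point configurations:
#' `stress = sum_{i<j} (d1_ij - d2_ij)^2 / sum_{i<j} (d1_ij - mean(d1))^2`.
#' Zero means the two geometries are identical. The measure depends only on
#' inter-point distances, so it is invariant to rotation, reflection and
#' translation of either configuration, but not to relative scale. It is
#' asymmetric: the denominator is computed from the first configuration, so
#' the order of arguments matters and should be recorded.
#'
#' @param X First configuration (n x k matrix); its distances normalize the
#'   measure and must not be all equal.
#' @param Y Second configuration, same dimensions, rows corresponding.
#' @return Non-negative stress value.
#' @examples
#' X <- rbind(c(0, 0), c(1, 0), c(0, 1))
#' stress(X, 2 * X)
#' @export
stress <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("configurations must have the same number of points",
                                class = "attnspace_domain_error")
  d1 <- stats::dist(X); d2 <- stats::dist(Y)
  den <- sum((d1 - mean(d1))^2)
  if (den <= sum(d1^2) * 1e-14) {
    abort("all reference distances equal: stress undefined",
          class = "attnspace_degenerate_error")
  }
  sum((d1 - d2)^2) / den
}

#' Procrustes alignment of two configurations
#'
#' Finds the translation, orthogonal rotation/reflection, and (optionally)
#' uniform scale that minimize the summed squared coordinate differences
#' between `X` and the transformed `Y`, then reports the [stress()] between
#' `X` and the aligned `Y`. With scaling disabled the scale factor is fixed
#' at 1, so differences in overall size remain in the stress.
#'
#' @param X Reference configuration (n x k, n >= 3).
#' @param Y Configuration to align, same dimensions, corresponding rows.
#' @param allow_scaling Include the uniform scale factor? (`TRUE` = full
#'   Procrustes.)
#' @return An object of class `attn_procrustes`: list with `Yaligned`,
#'   `rotation` (k x k orthogonal matrix, reflections permitted),
#'   `translation`, `scale`, `stress`, and the two unique-pair distance sets
#'   `d1`, `d2` (after alignment) that enter the stress.
#' @examples
#' X <- rbind(c(0, 0), c(1, 0), c(0, 1))
#' procrustes_align(X, 2 * X, allow_scaling = TRUE)$stress # 0
#' @export
procrustes_align <- function(X, Y, allow_scaling = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || nrow(X) < 3) {
    abort("`X` and `Y` must be equal-shape n x k matrices with n >= 3",
          class = "attnspace_domain_error")
  }
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  ssY <- sum(Yc^2)
  if (ssY == 0 || sum(Xc^2) == 0) {
    abort("degenerate (all-coincident) configuration", class = "attnspace_degenerate_error")
  }
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)                      # Y %*% R best aligns to X
  b <- if (allow_scaling) sum(s$d) / ssY else 1
  Yal <- b * Yc %*% R + matrix(cx, nrow(X), ncol(X), byrow = TRUE)
  structure(
    list(Yaligned = Yal, rotation = R, translation = cx - b * (cy %*% R)[1, ],
         scale = b, stress = stress(X, Yal),
         d1 = as.numeric(stats::dist(X)), d2 = as.numeric(stats::dist(Yal))),
    class = "attn_procrustes"
  )
}

#' Convex hull area and mean vertex radius of a 2-D configuration
#'
#' The convex hull drawn around the points of an MDS map gives a rough
#' measure of the size of the representation space; its area and the mean
#' distance of hull vertices from the configuration centroid scale with the
#' mean response distance.
#'
#' @param points n x 2 coordinate matrix, n >= 3, not all collinear.
#' @return One-row tibble: `area`, `mean_radius`, `n_vertices`.
#' @examples
#' convex_hull_summary(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' @export
convex_hull_summary <- function(points) {
  P <- as.matrix(points)
  stopifnot(ncol(P) == 2, nrow(P) >= 3)
  h <- chull(P)
  V <- P[h, , drop = FALSE]
  m <- nrow(V)
  # shoelace formula
  area <- 0.5 * abs(sum(V[, 1] * V[c(2:m, 1), 2] - V[c(2:m, 1), 1] * V[, 2]))
  if (area == 0) {
    abort("collinear points: hull degenerate", class = "attnspace_degenerate_error")
  }
  centroid <- colMeans(P)
  tibble::tibble(
    area = area,
    mean_radius = mean(sqrt(rowSums(sweep(V, 2, centroid)^2))),
    n_vertices = m
  )
}

#' @export
print.attn_procrustes <- function(x, ...) {
  cat(sprintf("<attn_procrustes> scale %.4f, stress %.5f\n", x$scale, x$stress))
  invisible(x)
}
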