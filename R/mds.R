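#' Classical (Torgerson) metric multidimensional scaling
#'
#' Embeds a distance matrix in `k` dimensions by double centering:
#' `B = -1/2 * J %*% D^2 %*% J` with `J` the centering projector, followed by
#' eigendecomposition; coordinates are the top-`k` eigenvectors scaled by the
#' square roots of their (non-negative) eigenvalues. Correlation-distance
#' matrices are generally non-Euclidean, so some eigenvalues may be negative;
#' those never enter the coordinates or the variance normalization (a message
#' is emitted when their magnitude exceeds 5% of the positive spectrum).
#' Each coordinate axis is reflected so that its largest-magnitude component
#' is positive, making the output deterministic.
#'
#' @param dm Symmetric hollow distance matrix (e.g. from
#'   [distance_matrix()]).
#' @param k Embedding dimension, `1 <= k <= n - 1` (default 2, the number of
#'   dimensions plotted).
#' @return An object of class `attn_mds`: list with `points` (n x k, centered
#'   coordinates), `eigenvalues` (all n, descending), `variance_explained`
#'   (per retained dimension, fractions of the positive spectrum), `k`, and
#'   `labels`.
#' @examples
#' d <- as.matrix(dist(cbind(c(0, 3, 0), c(0, 0, 4))))
#' classical_mds(d, k = 2)$points
#' @export
classical_mds <- function(dm, k = 2) {
  D <- unclass(dm)
  n <- nrow(D)
  stopifnot(ncol(D) == n, k >= 1, k <= n - 1)
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12)) {
    abort("`dm` must be symmetric with zero diagonal", class = "attnspace_domain_error")
  }
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- ev > max(ev, 0) * 1e-12
  n_pos <- sum(pos)
  neg_mass <- sum(abs(ev[ev < 0]))
  if (n_pos > 0 && neg_mass > 0.05 * sum(ev[pos])) {
    inform(sprintf("non-Euclidean input: negative eigenvalue mass %.1f%% of positive spectrum",
                   100 * neg_mass / sum(ev[pos])))
  }
  k_eff <- min(k, n_pos)
  if (k_eff < k) {
    warn(sprintf("only %d positive eigenvalue(s); trailing dimensions set to zero", n_pos))
  }
  X <- matrix(0, n, k)
  if (k_eff > 0) {
    V <- e$vectors[, seq_len(k_eff), drop = FALSE]
    # deterministic reflection: largest-|.| component of each axis positive
    for (j in seq_len(k_eff)) {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    X[, seq_len(k_eff)] <- V %*% diag(sqrt(ev[seq_len(k_eff)]), k_eff)
  }
  labels <- rownames(D) %||% as.character(seq_len(n))
  dimnames(X) <- list(labels, paste0("dim", seq_len(k)))
  structure(
    list(points = X, eigenvalues = ev, k = k, labels = labels,
         variance_explained = if (n_pos > 0) {
           pmax(ev[seq_len(k)], 0) / sum(ev[pos])
         } else rep(NA_real_, k)),
    class = "attn_mds"
  )
}

#' Fraction of variance captured by the leading MDS dimensions
#'
#' Sum of the top-`k` positive eigenvalues over the sum of all positive
#' eigenvalues (negative eigenvalues of a non-Euclidean input are excluded
#' from both).
#'
#' @param eigenvalues Eigenvalue vector (an `attn_mds` object also works).
#' @param k Number of leading dimensions.
#' @return Fraction in `[0, 1]`.
#' @examples
#' variance_explained(c(3, 1, -0.5), k = 1) # 0.75
#' @export
variance_explained <- function(eigenvalues, k) {
  if (inherits(eigenvalues, "attn_mds")) eigenvalues <- eigenvalues$eigenvalues
  ev <- sort(eigenvalues, decreasing = TRUE)
  pos <- ev[ev > 0]
  if (length(pos) == 0) {
    abort("no positive eigenvalue: variance undefined",
          class = "attnspace_degenerate_error")
  }
  sum(pos[seq_len(min(k, length(pos)))]) / sum(pos)
}

#' @export
print.attn_mds <- function(x, ...) {
  cat(sprintf("<attn_mds> %d points in %d dimension(s); variance explained %.1f%%\n",
              nrow(x$points), x$k,
              100 * sum(x$variance_explained[seq_len(x$k)], na.rm = TRUE)))
  print(round(x$points, 4))
  invisible(x)
}
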