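# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Eq.-1-style stress computed directly from the two distance sets
oracle_stress <- function(X, Y) {
  d1 <- as.numeric(dist(X))
  d2 <- as.numeric(dist(Y))
  sum((d1 - d2)^2) / sum((d1 - mean(d1))^2)
}

# exact two-sided rank-sum p by exhaustive enumeration of group labelings
oracle_rank_sum <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# exact two-sided signed-rank p by enumeration of all sign patterns
oracle_sign_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# slope through the origin by direct 1-D minimization of the residual sum
oracle_origin_slope <- function(x, y) {
  optimize(function(b) sum((y - b * x)^2), c(0, 100), tol = 1e-12)$minimum
}

# tiny simulated sessions for pipeline-level tests
tiny_config <- function(seed, ...) {
  sim_config(n_cells_ait = 8, n_cells_lip = 8, reps_attention = 6,
             reps_passive_shape = 4, reps_passive_location = 6,
             seed = seed, ...)
}

noiseless_config <- function(seed, ...) {
  tiny_config(seed, noise = "none", catch_fraction = 0, ...)
}

# gain table claiming unit gain for every cell/task/space, for building
# passive-equivalent population matrices
unit_gains <- function(trials) {
  tidyr::expand_grid(
    cell_id = unique(trials$cell_id),
    task = c("shape_attention", "location_attention"),
    decode_space = c("shape", "location")
  ) |>
    dplyr::left_join(dplyr::distinct(trials, cell_id, area), by = "cell_id") |>
    dplyr::mutate(gain = 1, n_points = 3L)
}
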