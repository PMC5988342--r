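test_that("correlation distance matches hand-evaluated Pearson values", {
  v <- c(1, 2, 3, 4)
  expect_equal(correlation_distance(v, v), 0)
  expect_equal(correlation_distance(c(1, 2, 3), c(3, 2, 1)), 2)
  expect_equal(correlation_distance(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.2)
  expect_error(correlation_distance(c(1, 1, 1), c(1, 2, 3)),
               class = "attnspace_degenerate_error")
  expect_error(correlation_distance(c(1, 2), c(1, 2)), class = "attnspace_domain_error")
})

test_that("distance matrices are symmetric, hollow, bounded and scale-invariant", {
  withr::with_seed(31, {
    M <- matrix(rlnorm(20 * 8), 20, 8)
  })
  D <- distance_matrix(M)
  expect_equal(dim(D), c(8, 8))
  expect_equal(unclass(D), t(unclass(D)))
  expect_equal(diag(D), rep(0, 8), ignore_attr = TRUE)
  expect_true(all(D >= 0 & D <= 2))
  # 28 unique off-diagonal distances for 8 stimuli
  expect_equal(sum(upper.tri(D)), 28)
  expect_equal(length(unique(round(D[upper.tri(D)], 12))), 28)
  # common positive scaling of all columns leaves distances unchanged
  expect_equal(unclass(distance_matrix(M * 3.7)), unclass(D))
  # identical columns give an all-zero matrix
  M2 <- matrix(rep(c(1, 5, 2, 4), 8), ncol = 8)
  expect_equal(max(abs(distance_matrix(M2))), 0)
})

test_that("constant cells are dropped with a warning before correlation", {
  withr::with_seed(8, M <- matrix(rlnorm(5 * 8), 5, 8))
  M[3, ] <- 2
  expect_warning(D <- distance_matrix(M), "constant")
  expect_equal(unclass(D), unclass(distance_matrix(M[-3, ])))
})

test_that("mean distance averages the unique pairs with a standard error", {
  D <- matrix(0, 3, 3)
  D[upper.tri(D)] <- c(0.1, 0.2, 0.3)
  D <- D + t(D)
  md <- mean_distance(D)
  expect_equal(md$mean_distance, 0.2)
  expect_equal(md$n_pairs, 3)
  expect_equal(md$se, sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  expect_equal(mean_distance(matrix(0, 4, 4))$mean_distance, 0)
})

test_that("percent change is plain relative change with a guarded baseline", {
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(1.2, 1), 20)
  expect_equal(percent_change(0.831, 1), -16.9)
  expect_error(percent_change(1, 0), class = "attnspace_domain_error")
})

test_that("population matrices respect eccentricity bands and gain scaling", {
  sim <- simulate_population(tiny_config(seed = 17))
  tr <- sim$trials
  gains <- suppressMessages(estimate_gains(tr))

  pm <- build_population_matrix(tr, gains, decode_space = "shape",
                                task = "shape_attention", area = "ait")
  pp <- build_population_matrix(tr, decode_space = "shape",
                                task = "passive", area = "ait")
  g <- dplyr::filter(gains, area == "ait", task == "shape_attention",
                     decode_space == "shape")
  gv <- g$gain[match(rownames(pm), g$cell_id)]
  expect_equal(unclass(pm), unclass(pp) * gv, ignore_attr = TRUE)

  # band excluding every cell errors; inclusive endpoints retain boundary cells
  expect_error(build_population_matrix(tr, gains, "shape", "passive", "ait",
                                       ecc_band = c(90, 99)),
               class = "attnspace_empty_error")
  ecc <- dplyr::distinct(tr[tr$area == "ait", ], cell_id, eccentricity_deg)
  lo <- min(ecc$eccentricity_deg)
  pm2 <- build_population_matrix(tr, gains, "shape", "passive", "ait",
                                 ecc_band = c(lo, lo))
  expect_equal(nrow(pm2), sum(ecc$eccentricity_deg == lo))

  # unit gains reproduce the passive matrix exactly
  pm3 <- build_population_matrix(tr, unit_gains(tr), "shape",
                                 "shape_attention", "ait")
  expect_equal(unclass(pm3), unclass(pp), ignore_attr = TRUE)
})

test_that("uniform gains leave the distance matrix unchanged on noiseless data", {
  gd <- default_gain_distributions()
  gd$sdlog <- 0
  # zero angle jitter keeps the attention measurement angle identical to the
  # passive one, so the fitted gains are exactly uniform across cells
  cfg <- noiseless_config(seed = 23, gain_distributions = gd,
                          gain_sdlog_resid = 0, active_angle_jitter = 0)
  sim <- simulate_population(cfg)
  gains <- suppressMessages(estimate_gains(sim$trials))
  Dp <- distance_matrix(build_population_matrix(sim$trials, decode_space = "shape",
                                                task = "passive", area = "ait"))
  Da <- distance_matrix(build_population_matrix(sim$trials, gains, "shape",
                                                "shape_attention", "ait"))
  expect_equal(unclass(Da), unclass(Dp), tolerance = 1e-9)
})

test_that("mean distance grows with gain dispersion on a fixed noiseless population", {
  withr::with_seed(41, {
    P <- matrix(rlnorm(30 * 8, log(20), 0.7), 30, 8)
    rungs <- c(0, 0.2, 0.4, 0.8)
    means <- vapply(rungs, function(s) {
      mean(vapply(1:20, function(r) {
        g <- rlnorm(30, 0, s)
        mean_distance(distance_matrix(P * g))$mean_distance
      }, numeric(1)))
    }, numeric(1))
  })
  # shared per-cell scaling acts as common multiplicative noise on every
  # stimulus column, so increasing dispersion monotonically raises the
  # between-column correlations and shrinks the mean distance
  expect_true(all(diff(means) < 0))
})
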