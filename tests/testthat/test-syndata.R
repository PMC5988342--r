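test_that("simulated sessions honor the recording design", {
  sim <- simulate_population(tiny_config(seed = 11))
  tr <- sim$trials

  expect_setequal(unique(tr$task),
                  c("shape_attention", "location_attention",
                    "passive_shape", "passive_location"))

  # per-cell structure: attention tasks use exactly 3 shapes x 3 locations,
  # passive-shape all 8 shapes at one location, passive-location all 8
  # locations with one shape
  per_cell <- tr |>
    dplyr::filter(!is_catch) |>
    dplyr::group_by(cell_id, task) |>
    dplyr::summarise(n_shapes = dplyr::n_distinct(shape_id),
                     n_locs = dplyr::n_distinct(round(polar_angle_deg, 6)),
                     n = dplyr::n(), .groups = "drop")
  attn <- dplyr::filter(per_cell, task %in% c("shape_attention", "location_attention"))
  expect_true(all(attn$n_shapes == 3) && all(attn$n_locs == 3))
  expect_true(all(attn$n == 9 * 6))
  ps <- dplyr::filter(per_cell, task == "passive_shape")
  expect_true(all(ps$n_shapes == 8) && all(ps$n_locs == 1))
  pl <- dplyr::filter(per_cell, task == "passive_location")
  expect_true(all(pl$n_shapes == 1) && all(pl$n_locs == 8))

  # rates are non-negative; eccentricity bands respected, one per cell
  expect_true(all(tr$rate_hz >= 0))
  ecc <- dplyr::distinct(tr, cell_id, area, eccentricity_deg)
  expect_equal(nrow(ecc), 16)
  expect_true(all(ecc$eccentricity_deg[ecc$area == "ait"] >= 2 &
                    ecc$eccentricity_deg[ecc$area == "ait"] <= 6))
  expect_true(all(ecc$eccentricity_deg[ecc$area == "lip"] >= 7 &
                    ecc$eccentricity_deg[ecc$area == "lip"] <= 12))

  # catch trials flagged and near the configured fraction of attention trials
  n_catch <- sum(tr$is_catch)
  n_attn <- sum(tr$task %in% c("shape_attention", "location_attention"))
  expect_equal(n_catch / n_attn, 0.20, tolerance = 0.05)
})

test_that("a fixed seed reproduces the session exactly", {
  cfg <- tiny_config(seed = 5)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$cells, s2$cells)
  s3 <- simulate_population(tiny_config(seed = 6))
  expect_false(identical(s1$trials$rate_hz, s3$trials$rate_hz))
})

test_that("noiseless unit-gain sessions reproduce passive tuning in the attention tasks", {
  gd <- default_gain_distributions()
  gd$meanlog <- 0
  gd$sdlog <- 0
  cfg <- noiseless_config(seed = 2, gain_distributions = gd, gain_sdlog_resid = 0)
  sim <- simulate_population(cfg)

  # every attention-task trial rate equals the corresponding tuning value
  for (i in c(1, 9)) {
    cell <- sim$cells[i, ]
    tr <- dplyr::filter(sim$trials, cell_id == cell$cell_id,
                        task == "shape_attention", !is_catch)
    expected <- cell$shape_rates[[1]][tr$shape_id] *
      exp(cell$location_kappa *
            (cos(angular_distance(tr$polar_angle_deg, cell$preferred_angle) * pi / 180) - 1))
    expect_equal(tr$rate_hz, expected, tolerance = 1e-12)
  }
})

test_that("location tuning follows the von Mises profile", {
  cell <- list(preferred_angle = 30, location_kappa = 2,
               shape_rates = list(c(5, 20, 10)), shift_deg = 0)
  peak <- 20
  # maximum at preference
  expect_equal(location_tuning(cell, 30), peak)
  # 90 degrees away: peak * exp(kappa * (cos 90 - 1)) = peak * e^-2
  expect_equal(location_tuning(cell, 120), peak * exp(-2), tolerance = 1e-12)
  # flat tuning at kappa = 0
  flat <- list(preferred_angle = 30, location_kappa = 0,
               shape_rates = list(c(5, 20, 10)), shift_deg = 0)
  expect_equal(location_tuning(flat, c(0, 77, 211)), rep(peak, 3))
})

test_that("attentional gain application scales rates and validates labels", {
  cell <- list(task_gains = list(c(shape_attention = 2, location_attention = 1,
                                   passive_shape = 1, passive_location = 1)),
               het_shape = list(numeric(0)), het_location = list(numeric(0)))
  expect_equal(apply_attention(10, cell, "shape_attention"), 20)
  expect_equal(apply_attention(10, cell, "location_attention"), 10)
  expect_error(apply_attention(10, cell, "sideways_attention"),
               class = "attnspace_label_error")
  expect_error(apply_attention(-1, cell, "shape_attention"),
               class = "attnspace_domain_error")
})

test_that("a zero-magnitude heterogeneity warp is identical to no warp", {
  s0 <- simulate_population(tiny_config(seed = 4, warp_mode = "none"))
  s1 <- simulate_population(tiny_config(seed = 4, warp_mode = "gain_heterogeneity",
                                        warp_magnitude = 0))
  expect_equal(s0$trials$rate_hz, s1$trials$rate_hz)
})

test_that("Poisson trial sampling has the right mean and is seed-stable", {
  expect_equal(sample_trials(0, 20, seed = 1), rep(0, 20))
  r <- sample_trials(20, 10000, window = 0.5, seed = 42)
  se <- sqrt(20 / 0.5) / sqrt(10000)
  expect_lt(abs(mean(r) - 20), 3 * se)
  expect_identical(r, sample_trials(20, 10000, window = 0.5, seed = 42))
  expect_error(sample_trials(-5, 10), class = "attnspace_domain_error")
})

test_that("active stimulus selection picks two best + worst shapes and a 120-degree triplet", {
  sel <- select_active_stimuli(c(9, 8, 1, 2, 3, 4, 5, 6), rep(1, 8))
  expect_equal(sel$shapes, c(1, 2, 3))
  # best location angle 10 degrees -> triplet {10, 130, 250}
  sel2 <- select_active_stimuli(c(1, 2, 3), c(0, 5, 1, 0),
                                location_angles = c(300, 10, 90, 200))
  expect_equal(sel2$angles, c(10, 130, 250))
  # all shape rates equal -> lowest indices by the tie rule
  sel3 <- select_active_stimuli(rep(2, 8), rep(1, 8))
  expect_equal(sel3$shapes, c(1, 2, 3))
})
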