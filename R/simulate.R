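#' Equally spaced polar angles for a stimulus ring
#'
#' @param n Number of locations.
#' @return Numeric vector of `n` angles in degrees, equally spaced on
#'   `[0, 360)` starting at 0.
#' @export
location_angles <- function(n) {
  seq(0, 360, length.out = n + 1)[seq_len(n)]
}

#' Choose a cell's active stimulus subset
#'
#' Given a cell's passive responses to the full shape and location sets,
#' selects the 3 shapes and 3 locations used in the attention tasks: the two
#' shapes with the strongest response plus the weakest (ties resolved toward
#' the lowest index), and the best passive location plus the two angles 120
#' degrees away on either side.
#'
#' @param passive_shape_rates Numeric vector of passive responses to the
#'   shapes (spikes/s).
#' @param passive_location_rates Numeric vector of passive responses to the
#'   locations (spikes/s).
#' @param location_angles Polar angles (degrees) of the passive locations;
#'   defaults to an equally spaced ring.
#' @return A list with `shapes` (3 integer indices) and `angles` (3 polar
#'   angles in degrees, wrapped to `[0, 360)`).
#' @examples
#' select_active_stimuli(c(9, 8, 1, 2, 3, 4, 5, 6), rep(1, 8))
#' @export
select_active_stimuli <- function(passive_shape_rates, passive_location_rates,
                                  location_angles = NULL) {
  stopifnot(length(passive_shape_rates) >= 3, length(passive_location_rates) >= 1)
  location_angles <- location_angles %||%
    attnspace::location_angles(length(passive_location_rates))

  top2 <- order(-passive_shape_rates)[1:2]        # stable: ties keep low index
  weakest <- setdiff(order(passive_shape_rates), top2)[1]
  best_angle <- location_angles[which.max(passive_location_rates)]
  list(
    shapes = sort(c(top2, weakest)),
    angles = wrap_angle(best_angle + c(0, 120, 240))
  )
}

#' von Mises spatial tuning of a simulated cell
#'
#' Evaluates the cell's location tuning curve: a von Mises profile
#' `exp(kappa * (cos(theta - preferred) - 1))` scaled so the peak equals the
#' cell's peak firing rate. Under the `tuning_shift` warp, attention to
#' location pulls the tuning curve toward the attended (stimulus) location,
#' which shrinks the effective angular distance by the cell's `shift_deg`.
#'
#' @param cell One row of the ground-truth cell table from
#'   [simulate_population()] (or any list with `preferred_angle`,
#'   `location_kappa`, `shape_rates`, `shift_deg`).
#' @param polar_angle Stimulus polar angle(s), degrees.
#' @param task Task label; the tuning shift applies only under
#'   `"location_attention"`.
#' @return Firing rate(s), spikes/s.
#' @export
location_tuning <- function(cell, polar_angle, task = "passive_location") {
  stopifnot(all(is.finite(polar_angle)))
  check_task(task)
  cell <- as.list(cell)
  peak <- max(unlist(cell$shape_rates))
  shift <- if (identical(task, "location_attention")) cell$shift_deg %||% 0 else 0
  dtheta <- pmax(angular_distance(polar_angle, cell$preferred_angle) - shift, 0)
  peak * exp(cell$location_kappa * (cos(deg2rad(dtheta)) - 1))
}

check_task <- function(task) {
  if (!all(task %in% task_levels())) {
    abort(paste0("unknown task label(s): ",
                 paste(setdiff(task, task_levels()), collapse = ", ")),
          class = "attnspace_label_error")
  }
  invisible(task)
}

#' Apply a cell's attentional state gain to a firing rate
#'
#' With `decode_space = NULL`, multiplies by the cell's per-task state gain
#' (the quantity that actually scales trials in the generator). With a decode
#' space given, multiplies by the corresponding attentional gain factor -- the
#' ratio of the task's state gain to the relevant passive task's state gain,
#' which is what [fit_gain()] recovers from data. Under the
#' `gain_heterogeneity` warp, per-stimulus jitter factors stored in the cell's
#' ground truth are applied when `shape_id` / `location_index` are supplied.
#'
#' @param rate Non-negative firing rate(s), spikes/s.
#' @param cell One ground-truth cell row (see [simulate_population()]).
#' @param task Task label.
#' @param decode_space `NULL`, `"shape"` or `"location"`.
#' @param shape_id,location_index Optional stimulus identifiers for the
#'   heterogeneous-gain warp.
#' @return Scaled rate(s), spikes/s.
#' @export
apply_attention <- function(rate, cell, task, decode_space = NULL,
                            shape_id = NULL, location_index = NULL) {
  if (any(rate < 0)) abort("`rate` must be non-negative", class = "attnspace_domain_error")
  check_task(task)
  cell <- as.list(cell)
  g <- if (is.null(decode_space)) {
    unlist(cell$task_gains)[[task]]
  } else {
    gains <- cell$gains[[1]] %||% cell$gains
    gains[gains$task == task & gains$decode_space == decode_space, "gain"][[1]]
  }
  het <- 1
  if (task %in% attention_tasks()) {
    hs <- unlist(cell$het_shape)
    hl <- unlist(cell$het_location)
    if (!is.null(shape_id) && length(hs)) {
      het <- het * matrix(hs, nrow = 2,
                          dimnames = list(attention_tasks(), NULL))[task, shape_id]
    }
    if (!is.null(location_index) && length(hl)) {
      het <- het * matrix(hl, nrow = 2,
                          dimnames = list(attention_tasks(), NULL))[task, location_index]
    }
  }
  rate * g * het
}

#' Draw Poisson trial rates around a mean rate
#'
#' Spike counts are drawn as Poisson with mean `mean_rate * window` and
#' converted back to rates, the package's trial-noise model.
#'
#' @param mean_rate Mean firing rate, spikes/s (scalar, non-negative).
#' @param n_reps Number of trials to draw.
#' @param window Counting window, seconds.
#' @param seed Optional integer seed for a self-contained reproducible draw;
#'   `NULL` uses (and advances) the current RNG stream.
#' @return Numeric vector of `n_reps` trial firing rates.
#' @examples
#' sample_trials(20, 5, window = 0.5, seed = 1)
#' @export
sample_trials <- function(mean_rate, n_reps, window = 0.5, seed = NULL) {
  if (!is.numeric(mean_rate) || length(mean_rate) != 1 || mean_rate < 0) {
    abort("`mean_rate` must be a single non-negative number",
          class = "attnspace_domain_error")
  }
  stopifnot(n_reps >= 1, window > 0)
  draw <- function() rpois(n_reps, mean_rate * window) / window
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# ---------------------------------------------------------------------------
# full-session generator

draw_preferred_angles <- function(n, spread) {
  if (spread <= 0) return(runif(n, 0, 360))
  # wrapped-normal clustering around a random population direction; larger
  # `spread` concentrates coverage (sd = 1/sqrt(spread) radians)
  mu <- runif(1, 0, 360)
  wrap_angle(mu + rnorm(n, 0, 1 / sqrt(spread)) * 180 / pi)
}

draw_cells_for_area <- function(config, area) {
  n <- if (area == "ait") config$n_cells_ait else config$n_cells_lip
  band <- if (area == "ait") config$ecc_band_ait else config$ecc_band_lip
  kappa <- config$location_kappa[[area]]
  grid <- location_angles(config$n_locations)
  sigma <- config$shape_lognormal_sigma

  gd <- config$gain_distributions
  gd <- gd[gd$area == area, ]
  # a cell's modulability is shared across task states: one latent per cell
  # scaled by the task's sdlog, plus a small task-specific residual. Broad
  # marginal gain distributions thus coexist with near-constant per-cell
  # gain ratios between tasks, so an unwarped population is null for the
  # stress comparison.
  u <- rnorm(n)
  resid <- config$gain_sdlog_resid
  if (length(resid) > 1) resid <- resid[[area]]
  state_gains <- vapply(task_levels(), function(tk) {
    row <- gd[gd$task == tk, ]
    exp(row$meanlog + row$sdlog * u + rnorm(n, 0, resid))
  }, numeric(n))
  if (n == 1) state_gains <- matrix(state_gains, nrow = 1,
                                    dimnames = list(NULL, task_levels()))

  pref <- draw_preferred_angles(n, config$pref_spread[[area]])
  ecc <- runif(n, band[1], band[2])
  shape_rates <- lapply(seq_len(n), function(i) {
    config$base_rate * rlnorm(config$n_shapes, -sigma^2 / 2, sigma)
  })

  warp_here <- area %in% config$warp_areas
  shift_on <- warp_here && config$warp_mode %in% c("tuning_shift", "both")
  het_on <- warp_here && config$warp_mode %in% c("gain_heterogeneity", "both")
  shift_deg <- if (shift_on) rep(config$warp_magnitude * 22.5, n) else rep(0, n)
  blend_w <- if (shift_on) rep(config$warp_magnitude, n) else rep(0, n)
  het_shape <- lapply(seq_len(n), function(i) {
    if (het_on) rlnorm(2 * config$n_shapes, 0, config$warp_magnitude) else numeric(0)
  })
  het_location <- lapply(seq_len(n), function(i) {
    if (het_on) rlnorm(2 * 3, 0, config$warp_magnitude) else numeric(0)
  })

  cells <- tibble::tibble(
    cell_id = sprintf("%s_%03d", area, seq_len(n)),
    area = area,
    preferred_angle = pref,
    location_kappa = kappa,
    eccentricity = ecc,
    shape_rates = shape_rates,
    g_shape_attention = state_gains[, "shape_attention"],
    g_location_attention = state_gains[, "location_attention"],
    g_passive_shape = state_gains[, "passive_shape"],
    g_passive_location = state_gains[, "passive_location"],
    shift_deg = shift_deg,
    blend_w = blend_w,
    het_shape = het_shape,
    het_location = het_location
  )

  # per-cell active subsets from noiseless passive responses; the 120-degree
  # triplet is snapped to the passive grid and then jittered per location, so
  # active angles sit a few degrees off the measured grid as in real sessions
  jit <- config$active_angle_jitter
  sel <- purrr::pmap(cells, function(preferred_angle, shape_rates,
                                     location_kappa, ...) {
    vm <- exp(location_kappa * (cos(deg2rad(angular_distance(grid, preferred_angle))) - 1))
    ps <- shape_rates * vm[which.max(vm)]
    pl <- max(shape_rates) * vm
    act <- select_active_stimuli(ps, pl, grid)
    snapped <- vapply(act$angles,
                      function(a) grid[which.min(angular_distance(a, grid))],
                      numeric(1))
    list(shapes = act$shapes,
         angles = wrap_angle(snapped + runif(3, -jit, jit)),
         passive_angle = grid[which.max(pl)],
         best_shape = which.max(shape_rates))
  })
  cells$active_shapes <- purrr::map(sel, "shapes")
  cells$active_angles <- purrr::map(sel, "angles")
  cells$passive_angle <- purrr::map_dbl(sel, "passive_angle")
  cells$best_shape <- purrr::map_int(sel, ~ as.integer(.x$best_shape))
  cells
}

# noiseless mean rate for condition rows; `df` carries per-row tuning columns
condition_mean_rate <- function(df, config) {
  shift <- ifelse(df$task == "location_attention", df$shift_deg, 0)
  dtheta <- pmax(angular_distance(df$polar_angle_deg, df$preferred_angle) - shift, 0)
  vm <- exp(df$location_kappa * (cos(deg2rad(dtheta)) - 1))
  shape_comp <- ifelse(df$task == "shape_attention",
                       (1 - df$blend_w) * df$shape_rate + df$blend_w * df$peak_rate,
                       df$shape_rate)
  shape_comp * vm * df$state_gain * df$het
}

#' Simulate a two-area delayed match-to-sample recording session
#'
#' Generates a long-format trial table with the statistical structure the
#' population-geometry analysis assumes: every cell is recorded in the two
#' attention tasks (3 shapes x 3 locations, `reps_attention` repetitions of
#' each of the 9 sample conditions per task, plus flagged catch trials), a
#' passive-shape task (all shapes at the cell's best location) and a
#' passive-location task (all locations with the cell's best shape).
#' Attention acts as a per-cell multiplicative state gain, optionally
#' augmented by warping mechanisms (heterogeneous per-stimulus gain, tuning
#' shift toward the attended stimulus). Trial noise is Poisson in a fixed
#' counting window.
#'
#' The active location triplet is the cell's best passive angle plus/minus
#' 120 degrees, offset by a per-cell jitter so active angles fall between the
#' passive grid angles as in real sessions (mean interpolation shift about 5
#' degrees with the default jitter).
#'
#' @param config A [sim_config()].
#' @return An object of class `attn_sim`: a list with
#'   \describe{
#'     \item{trials}{tibble, one row per trial: `cell_id`, `area`, `task`,
#'       `shape_id`, `polar_angle_deg`, `eccentricity_deg`, `rep`, `rate_hz`,
#'       `is_catch`.}
#'     \item{cells}{ground-truth tibble: tuning parameters, per-task state
#'       gains, implied attentional gain factors (see [cell_gain_factors()]),
#'       warp settings, and active stimulus subsets.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_population(sim_config(n_cells_ait = 4, n_cells_lip = 4, seed = 1))
#' dplyr::count(sim$trials, task)
#' @export
simulate_population <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config object", class = "attnspace_config_error")
  }
  withr::with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  cells <- dplyr::bind_rows(
    draw_cells_for_area(config, "ait"),
    draw_cells_for_area(config, "lip")
  )

  # long parameter tables for vectorized rate computation
  shape_tbl <- tidyr::unnest(
    dplyr::transmute(cells, .data$cell_id, shape_id = list(seq_len(config$n_shapes)),
                     shape_rate = .data$shape_rates),
    c("shape_id", "shape_rate")
  )
  gain_tbl <- tidyr::pivot_longer(
    dplyr::select(cells, "cell_id", dplyr::starts_with("g_")),
    -"cell_id", names_to = "task", names_prefix = "g_", values_to = "state_gain"
  )
  het_shape_tbl <- het_long(cells, "het_shape", "shape_id", config$n_shapes)
  het_loc_tbl <- het_long(cells, "het_location", "loc_index", 3)

  conds <- build_condition_grid(cells, config)

  meta <- dplyr::select(cells, "cell_id", "area", "preferred_angle",
                        "location_kappa", "eccentricity", "shift_deg", "blend_w")
  meta$peak_rate <- purrr::map_dbl(cells$shape_rates, max)

  df <- conds |>
    dplyr::left_join(meta, by = "cell_id") |>
    dplyr::left_join(shape_tbl, by = c("cell_id", "shape_id")) |>
    dplyr::left_join(gain_tbl, by = c("cell_id", "task"))
  df$het <- rep(1, nrow(df))
  if (nrow(het_shape_tbl)) {
    df <- dplyr::left_join(df, het_shape_tbl, by = c("cell_id", "task", "shape_id"))
    df <- dplyr::left_join(df, het_loc_tbl, by = c("cell_id", "task", "loc_index"))
    df$het <- dplyr::coalesce(df$het_s, 1) * dplyr::coalesce(df$het_l, 1)
  }
  df$mean_rate <- condition_mean_rate(df, config)

  trials <- df |>
    dplyr::select("cell_id", "area", "task", "shape_id", "polar_angle_deg",
                  "mean_rate", "is_catch", "n_reps", eccentricity_deg = "eccentricity") |>
    tidyr::uncount(.data$n_reps, .id = "rep")
  trials$rate_hz <- if (config$noise == "poisson") {
    rpois(nrow(trials), trials$mean_rate * config$window) / config$window
  } else {
    trials$mean_rate
  }
  trials <- dplyr::select(
    trials, "cell_id", "area", "task", "shape_id", "polar_angle_deg",
    "eccentricity_deg", "rep", "rate_hz", "is_catch"
  )

  cells$task_gains <- purrr::pmap(
    dplyr::select(cells, dplyr::starts_with("g_")),
    function(g_shape_attention, g_location_attention, g_passive_shape, g_passive_location) {
      c(shape_attention = g_shape_attention, location_attention = g_location_attention,
        passive_shape = g_passive_shape, passive_location = g_passive_location)
    }
  )
  cells$gains <- purrr::map(cells$task_gains, function(g) {
    tidyr::expand_grid(task = attention_tasks(), decode_space = c("shape", "location")) |>
      dplyr::mutate(gain = unname(
        g[.data$task] / ifelse(.data$decode_space == "shape",
                               g["passive_shape"], g["passive_location"])
      ))
  })

  structure(list(trials = trials, cells = cells, config = config),
            class = "attn_sim")
}

het_long <- function(cells, col, idx_name, nidx) {
  keep <- lengths(cells[[col]]) > 0
  if (!any(keep)) return(tibble::tibble())
  out <- tidyr::expand_grid(
    cell_id = cells$cell_id[keep],
    task = attention_tasks(),
    idx = seq_len(nidx)
  )
  out <- out[order(match(out$cell_id, cells$cell_id[keep])), ]
  # values were drawn as a 2 x nidx matrix (tasks in rows) per cell
  vals <- unlist(cells[[col]][keep])
  m <- matrix(vals, nrow = 2)
  out$val <- as.vector(vapply(seq_len(sum(keep)), function(i) {
    block <- m[, ((i - 1) * nidx + 1):(i * nidx), drop = FALSE]
    as.vector(t(block))   # task-major within cell
  }, numeric(2 * nidx)))
  names(out)[names(out) == "idx"] <- idx_name
  names(out)[names(out) == "val"] <- if (idx_name == "shape_id") "het_s" else "het_l"
  out
}

build_condition_grid <- function(cells, config) {
  grid <- location_angles(config$n_locations)

  passive_shape <- tidyr::expand_grid(
    cell_id = cells$cell_id, shape_id = seq_len(config$n_shapes)
  ) |>
    dplyr::left_join(dplyr::select(cells, "cell_id", "passive_angle"), by = "cell_id") |>
    dplyr::transmute(.data$cell_id, task = "passive_shape", .data$shape_id,
                     polar_angle_deg = .data$passive_angle, loc_index = NA_integer_,
                     is_catch = FALSE, n_reps = config$reps_passive_shape)

  passive_location <- tidyr::expand_grid(
    cell_id = cells$cell_id, grid_idx = seq_len(config$n_locations)
  ) |>
    dplyr::left_join(dplyr::select(cells, "cell_id", "best_shape"), by = "cell_id") |>
    dplyr::transmute(.data$cell_id, task = "passive_location",
                     shape_id = .data$best_shape,
                     polar_angle_deg = grid[.data$grid_idx], loc_index = NA_integer_,
                     is_catch = FALSE, n_reps = config$reps_passive_location)

  active <- cells |>
    dplyr::transmute(.data$cell_id,
                     combo = purrr::map2(.data$active_shapes, .data$active_angles,
                                         ~ tidyr::expand_grid(
                                           shape_id = .x,
                                           loc_index = seq_along(.y)
                                         ) |>
                                           dplyr::mutate(polar_angle_deg = .y[.data$loc_index]))) |>
    tidyr::unnest("combo")
  attn <- tidyr::expand_grid(task = attention_tasks(),
                             active[c("cell_id", "shape_id", "loc_index", "polar_angle_deg")]) |>
    dplyr::mutate(is_catch = FALSE, n_reps = config$reps_attention)

  n_catch <- round(9 * config$reps_attention *
                     config$catch_fraction / (1 - config$catch_fraction))
  catch <- tibble::tibble()
  if (n_catch > 0) {
    catch <- attn |>
      dplyr::group_by(.data$cell_id, .data$task) |>
      dplyr::slice_sample(n = n_catch, replace = TRUE) |>
      dplyr::ungroup() |>
      dplyr::mutate(is_catch = TRUE, n_reps = 1L)
  }

  dplyr::bind_rows(passive_shape, passive_location, attn, catch)
}

#' Attentional gain factors implied by the generator's ground truth
#'
#' For each simulated cell, the four gain factors the analysis should
#' recover: attention-task state gain divided by the passive-shape state gain
#' (shape decode space) or by the passive-location state gain (location
#' decode space).
#'
#' @param cells Ground-truth cell tibble from [simulate_population()].
#' @return Tibble with `cell_id`, `area`, `task`, `decode_space`, `gain`.
#' @export
cell_gain_factors <- function(cells) {
  cells |>
    dplyr::select("cell_id", "area", "gains") |>
    tidyr::unnest("gains")
}

#' @export
print.attn_sim <- function(x, ...) {
  cat("<attn_sim>\n")
  cat(sprintf("  %d trials from %d cells (%d AIT-like, %d LIP-like)\n",
              nrow(x$trials), nrow(x$cells),
              sum(x$cells$area == "ait"), sum(x$cells$area == "lip")))
  cat(sprintf("  %d catch trials flagged; seed %d\n",
              sum(x$trials$is_catch), x$config$seed))
  invisible(x)
}
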