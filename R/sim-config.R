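#' Default gain-state distributions for the simulator
#'
#' Lognormal (meanlog, sdlog) parameters for the per-cell multiplicative
#' state gain of each task, per area. The generator draws one gain per
#' (cell, task); the four attentional gain factors the analysis recovers are
#' the ratios attention-task gain / passive-task gain, so these defaults
#' imply shape-decode gain factors above 1 in both areas (larger in the
#' LIP-like area) and location-decode gain factors below 1 in the LIP-like
#' area, mirroring the qualitative single-cell pattern of attention studies
#' in ventral vs dorsal stream.
#'
#' @return A tibble with columns `area`, `task`, `meanlog`, `sdlog`.
#' @export
default_gain_distributions <- function() {
  tibble::tribble(
    ~area,  ~task,                ~meanlog,   ~sdlog,
    "ait",  "shape_attention",    log(1.10),  0.25,
    "ait",  "location_attention", log(1.00),  0.25,
    "ait",  "passive_shape",      0,          0.25,
    "ait",  "passive_location",   0,          0.25,
    "lip",  "shape_attention",    log(1.25),  0.25,
    "lip",  "location_attention", log(1.20),  0.25,
    "lip",  "passive_shape",      0,          0.25,
    "lip",  "passive_location",   log(1.40),  0.25
  )
}

#' Simulation configuration for the synthetic recording session
#'
#' Builds a validated configuration for [simulate_population()]. The defaults
#' reproduce the study design the analysis assumes: two areas (an AIT-like
#' ventral population of 85 cells and a LIP-like dorsal population of 53
#' cells), 8 shapes, 8 iso-eccentric locations equally spaced on the circle,
#' per-cell active subsets of 3 shapes and 3 locations, 12 repetitions of
#' each of the 9 sample conditions in each attention task (216 non-catch
#' attention trials per cell), 20% catch trials, and Poisson trial noise in a
#' fixed counting window.
#'
#' @param n_cells_ait,n_cells_lip Cells simulated per area.
#' @param n_shapes,n_locations Stimulus set sizes (locations are equally
#'   spaced polar angles on `[0, 360)`).
#' @param ecc_band_ait,ecc_band_lip Eccentricity bands (degrees of visual
#'   angle); each cell's stimuli sit at a single eccentricity drawn uniformly
#'   in its area's band.
#' @param reps_attention Repetitions per sample condition per attention task.
#' @param reps_passive_shape,reps_passive_location Repetitions per stimulus in
#'   the passive tasks.
#' @param catch_fraction Fraction of attention-task trials that are catch
#'   trials (generated, flagged, excluded from analysis).
#' @param base_rate Mean peak firing rate scale, spikes/s.
#' @param location_kappa von Mises concentration of spatial tuning, named per
#'   area. The LIP-like default is sharper.
#' @param pref_spread Concentration of preferred-angle coverage, named per
#'   area: 0 means uniform coverage (LIP-like default); larger values cluster
#'   preferred angles (AIT-like default), degrading the population's spatial
#'   map.
#' @param shape_lognormal_sigma sdlog of the per-cell lognormal shape-rate
#'   profile.
#' @param gain_distributions Tibble as [default_gain_distributions()]. The
#'   `sdlog` column scales a single per-cell latent shared by all four task
#'   states, so marginal gain distributions are broad while a cell's gain
#'   ratio between any two tasks stays close to the ratio of the group
#'   means.
#' @param gain_sdlog_resid sdlog of the small task-specific residual on top
#'   of the shared per-cell gain latent (a scalar, or a vector named per
#'   area); this is the true cell-to-cell
#'   heterogeneity of gain ratios between task states, kept near the
#'   estimation noise floor (the through-origin slope SE is about 5% at the
#'   default rates and repetition counts) so that an unwarped population is
#'   statistically null for the stress comparison.
#' @param active_angle_jitter Half-width (degrees) of the uniform per-cell
#'   offset between the active-task location triplet and the passive grid;
#'   the default of 10 makes the mean interpolation shift about 5 degrees.
#' @param warp_mode One of `"none"`, `"gain_heterogeneity"`,
#'   `"tuning_shift"`, `"both"`: attentional warping mechanisms beyond
#'   uniform gain.
#' @param warp_magnitude Dimensionless warp strength in `[0, 1]`: sdlog of the
#'   per-stimulus gain jitter for `gain_heterogeneity`; for `tuning_shift`,
#'   the tuning displacement is `warp_magnitude * 22.5` degrees (half the
#'   passive grid spacing) and the shape-blend weight is `warp_magnitude`.
#' @param warp_areas Areas the warp applies to (default `"ait"`).
#' @param window Spike-counting window in seconds for Poisson trial noise.
#' @param noise `"poisson"` or `"none"` (noiseless condition means).
#' @param seed Integer seed; a fixed seed makes the simulated session
#'   byte-identical across runs.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_population()]
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_cells_ait
#' @export
sim_config <- function(n_cells_ait = 85,
                       n_cells_lip = 53,
                       n_shapes = 8,
                       n_locations = 8,
                       ecc_band_ait = c(2, 6),
                       ecc_band_lip = c(7, 12),
                       reps_attention = 12,
                       reps_passive_shape = 4,
                       reps_passive_location = 12,
                       catch_fraction = 0.20,
                       base_rate = 25,
                       location_kappa = c(ait = 0.8, lip = 3),
                       pref_spread = c(ait = 1.5, lip = 0),
                       shape_lognormal_sigma = 0.7,
                       gain_distributions = default_gain_distributions(),
                       gain_sdlog_resid = 0.02,
                       active_angle_jitter = 10,
                       warp_mode = c("none", "gain_heterogeneity",
                                     "tuning_shift", "both"),
                       warp_magnitude = 0,
                       warp_areas = "ait",
                       window = 0.5,
                       noise = c("poisson", "none"),
                       seed = 1L) {
  warp_mode <- match.arg(warp_mode)
  noise <- match.arg(noise)

  counts <- c(n_cells_ait = n_cells_ait, n_cells_lip = n_cells_lip,
              n_shapes = n_shapes, n_locations = n_locations,
              reps_attention = reps_attention,
              reps_passive_shape = reps_passive_shape,
              reps_passive_location = reps_passive_location)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("all count fields must be integers >= 1", class = "attnspace_config_error")
  }
  if (!is.numeric(catch_fraction) || catch_fraction < 0 || catch_fraction >= 1) {
    abort("`catch_fraction` must be in [0, 1)", class = "attnspace_config_error")
  }
  for (band in list(ecc_band_ait = ecc_band_ait, ecc_band_lip = ecc_band_lip)) {
    if (length(band) != 2 || any(band <= 0) || band[1] > band[2]) {
      abort("eccentricity bands must be positive non-empty intervals c(lo, hi)",
            class = "attnspace_config_error")
    }
  }
  if (base_rate <= 0 || window <= 0) {
    abort("`base_rate` and `window` must be positive", class = "attnspace_config_error")
  }
  if (warp_magnitude < 0 || warp_magnitude > 1) {
    abort("`warp_magnitude` must be in [0, 1]", class = "attnspace_config_error")
  }
  for (nm in c("ait", "lip")) {
    if (!nm %in% names(location_kappa) || !nm %in% names(pref_spread)) {
      abort("`location_kappa` and `pref_spread` must be named vectors with 'ait' and 'lip'",
            class = "attnspace_config_error")
    }
  }
  req <- tidyr::expand_grid(area = c("ait", "lip"), task = task_levels())
  gd <- dplyr::semi_join(gain_distributions, req, by = c("area", "task"))
  if (nrow(gd) != nrow(req)) {
    abort("`gain_distributions` must contain (meanlog, sdlog) for every (area, task)",
          class = "attnspace_config_error")
  }

  structure(
    list(
      n_cells_ait = as.integer(n_cells_ait),
      n_cells_lip = as.integer(n_cells_lip),
      n_shapes = as.integer(n_shapes),
      n_locations = as.integer(n_locations),
      ecc_band_ait = as.numeric(ecc_band_ait),
      ecc_band_lip = as.numeric(ecc_band_lip),
      reps_attention = as.integer(reps_attention),
      reps_passive_shape = as.integer(reps_passive_shape),
      reps_passive_location = as.integer(reps_passive_location),
      catch_fraction = catch_fraction,
      base_rate = base_rate,
      location_kappa = location_kappa,
      pref_spread = pref_spread,
      shape_lognormal_sigma = shape_lognormal_sigma,
      gain_distributions = gain_distributions,
      gain_sdlog_resid = gain_sdlog_resid,
      active_angle_jitter = active_angle_jitter,
      warp_mode = warp_mode,
      warp_magnitude = warp_magnitude,
      warp_areas = warp_areas,
      window = window,
      noise = noise,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

task_levels <- function() {
  c("shape_attention", "location_attention", "passive_shape", "passive_location")
}

attention_tasks <- function() c("shape_attention", "location_attention")

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cells: %d AIT-like (ecc %g-%g deg), %d LIP-like (ecc %g-%g deg)\n",
              x$n_cells_ait, x$ecc_band_ait[1], x$ecc_band_ait[2],
              x$n_cells_lip, x$ecc_band_lip[1], x$ecc_band_lip[2]))
  cat(sprintf("  stimuli: %d shapes x %d locations; active subsets 3 x 3\n",
              x$n_shapes, x$n_locations))
  cat(sprintf("  reps: %d per attention condition, %d passive-shape, %d passive-location; %.0f%% catch\n",
              x$reps_attention, x$reps_passive_shape, x$reps_passive_location,
              100 * x$catch_fraction))
  cat(sprintf("  noise: %s (window %g s); warp: %s (magnitude %g, areas %s)\n",
              x$noise, x$window, x$warp_mode, x$warp_magnitude,
              paste(x$warp_areas, collapse = ",")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
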