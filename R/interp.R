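#' Periodic spline interpolation of spatial tuning along the stimulus ring
#'
#' Estimates a cell's passive response at arbitrary polar angles from its
#' responses at the passive grid angles, by cubic spline interpolation with
#' periodic boundary conditions along the iso-eccentric circle. The spline
#' passes through the sampled responses exactly; values are clamped at zero
#' from below because firing rates are non-negative.
#'
#' @param responses Passive responses (spikes/s) at the grid angles.
#' @param target_angles Angles (degrees) at which to estimate responses;
#'   wrapped to `[0, 360)`.
#' @param polar_angles Grid angles (degrees); default an equally spaced ring.
#' @return Interpolated responses at `target_angles` (non-negative).
#' @examples
#' r <- 10 * (1 + cos(( location_angles(8) - 45) * pi / 180))
#' interpolate_passive(r, 45) # hits the sample exactly
#' @export
interpolate_passive <- function(responses, target_angles,
                                polar_angles = location_angles(length(responses))) {
  stopifnot(length(responses) == length(polar_angles), all(is.finite(target_angles)))
  if (any(responses < 0)) {
    abort("responses must be non-negative", class = "attnspace_domain_error")
  }
  ord <- order(wrap_angle(polar_angles))
  x <- wrap_angle(polar_angles)[ord]
  y <- responses[ord]
  if (anyDuplicated(x)) {
    abort("duplicate sample angles: interpolation grid degenerate",
          class = "attnspace_degenerate_error")
  }
  # close the circle: periodic spline needs y[1] == y[n] at x[1] + 360
  fit <- spline(c(x, x[1] + 360), c(y, y[1]), method = "periodic",
                xout = wrap_angle(target_angles))
  pmax(fit$y, 0)
}

#' Angular displacement incurred by interpolation
#'
#' For each active-task angle, the shortest angular distance to the nearest
#' passive grid angle -- how far in polar angle the interpolated estimate sits
#' from a measured data point.
#'
#' @param active_angles Angles (degrees) used in the attention tasks.
#' @param passive_angles Passive grid angles (degrees).
#' @return Numeric vector of shifts in degrees (one per active angle), each
#'   bounded by half the grid spacing.
#' @export
angular_shift <- function(active_angles, passive_angles) {
  vapply(wrap_angle(active_angles),
         function(a) min(angular_distance(a, passive_angles)),
         numeric(1))
}

#' Per-area summary of interpolation shifts
#'
#' Aggregates [angular_shift()] over all cells: the mean and median absolute
#' polar-angle displacement between each cell's active locations and the
#' passive grid, per area.
#'
#' @param cells Ground-truth cell tibble from [simulate_population()], or any
#'   tibble with `area`, list-column `active_angles`, and either a
#'   `passive_grid` list-column or a shared grid given via `passive_angles`.
#' @param passive_angles Passive grid angles shared by all cells.
#' @return Tibble with `area`, `mean_shift_deg`, `median_shift_deg`,
#'   `n_cells`.
#' @export
angular_shift_report <- function(cells, passive_angles = location_angles(8)) {
  if (nrow(cells) == 0) abort("no cells", class = "attnspace_domain_error")
  cells |>
    dplyr::mutate(shift = purrr::map(.data$active_angles, angular_shift,
                                     passive_angles = passive_angles)) |>
    tidyr::unnest("shift") |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(mean_shift_deg = mean(.data$shift),
                     median_shift_deg = stats::median(.data$shift),
                     n_cells = dplyr::n_distinct(.data$cell_id), .groups = "drop")
}
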