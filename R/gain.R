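#' Attentional gain factor by regression through the origin
#'
#' The gain factor of a cell for one attention task and decode space is the
#' slope of the least-squares regression of its attention-task responses on
#' its matched passive responses, constrained to pass through the origin:
#' `b = sum(x * y) / sum(x^2)`. Under the assumption that attention scales a
#' cell's passive tuning multiplicatively, `b` estimates that multiplier.
#'
#' @param attention_responses Attention-task mean responses (spikes/s),
#'   length >= 2 (3 overlapping stimuli in the study design).
#' @param passive_responses Matched passive-task responses, same length.
#' @param cell_id,task,decode_space Optional labels carried into the result.
#' @return A one-row tibble (`cell_id`, `task`, `decode_space`, `gain`,
#'   `n_points`).
#' @examples
#' fit_gain(c(4, 8, 12), c(2, 4, 6))$gain # 2
#' @export
fit_gain <- function(attention_responses, passive_responses,
                     cell_id = NA_character_, task = NA_character_,
                     decode_space = NA_character_) {
  x <- passive_responses
  y <- attention_responses
  if (length(x) != length(y) || length(x) < 2) {
    abort("responses must be matched vectors of length >= 2",
          class = "attnspace_domain_error")
  }
  if (any(x < 0) || any(y < 0)) {
    abort("firing rates must be non-negative", class = "attnspace_domain_error")
  }
  if (all(x == 0)) {
    abort("passive responses are all zero: gain undefined",
          class = "attnspace_degenerate_error")
  }
  tibble::tibble(
    cell_id = cell_id, task = task, decode_space = decode_space,
    gain = sum(x * y) / sum(x^2), n_points = length(x)
  )
}

#' Scale a passive tuning vector by a fitted gain factor
#'
#' Estimates a cell's attention-task responses to the full stimulus set by
#' multiplying its passive responses elementwise by the gain factor fitted on
#' the overlapping stimuli.
#'
#' @param passive_responses Passive responses to the full stimulus set.
#' @param gain A gain factor (number, or a row from [fit_gain()]).
#' @return Estimated attention-condition responses, same length.
#' @export
apply_gain <- function(passive_responses, gain) {
  if (is.data.frame(gain)) gain <- gain$gain
  stopifnot(is.numeric(gain), length(gain) == 1, is.finite(gain), gain > 0)
  passive_responses * gain
}

#' Fit all four gain factors for every cell in a trial table
#'
#' For each cell, task and decode space, regresses the attention-task
#' condition means for the 3 overlapping stimuli through the origin on the
#' matched passive responses. For the shape space the overlap is the 3 active
#' shapes at the active location nearest the passive-shape location; for the
#' location space it is the 3 active locations with the best (passive-task)
#' shape, with passive responses estimated at the active angles by periodic
#' spline interpolation ([interpolate_passive()]). Cells whose passive
#' overlap responses are all zero are dropped for that decode space with a
#' message.
#'
#' @param trials Trial tibble as produced by [simulate_population()] (catch
#'   trials are excluded automatically).
#' @return Tibble with one row per (cell, task, decode space): `cell_id`,
#'   `area`, `task`, `decode_space`, `gain`, `n_points`.
#' @export
estimate_gains <- function(trials) {
  out <- purrr::map(c("shape", "location"), function(space) {
    dat <- purrr::map(unique(trials$area), function(ar) {
      prep <- prep_decode_data(trials, area = ar, decode_space = space)
      gains_from_prep(prep)
    })
    dplyr::bind_rows(dat)
  })
  dplyr::bind_rows(out)
}

gains_from_prep <- function(prep) {
  purrr::map_dfr(attention_tasks(), function(tk) {
    y <- prep$attention_means[[tk]]
    tibble::tibble(
      cell_id = prep$cell_ids, area = prep$area, task = tk,
      decode_space = prep$decode_space,
      gain = unname(rowSums(prep$overlap_passive * y) / rowSums(prep$overlap_passive^2)),
      n_points = ncol(y)
    )
  })
}

#' Summarize gain factors per area and task
#'
#' Mean and median gain per (area, task, decode space), plus the paired
#' Wilcoxon signed-rank p-value between the two attention tasks within each
#' (area, decode space) -- the comparison reported alongside gain-factor
#' histograms.
#'
#' @param gains Tibble from [estimate_gains()] (or [fit_gain()] rows bound
#'   together) with columns `cell_id`, `area`, `task`, `decode_space`,
#'   `gain`.
#' @return A list of two tibbles: `summary` (per-group mean/median/n) and
#'   `task_comparison` (per area and decode space, the signed-rank p-value
#'   between tasks).
#' @export
gain_summary <- function(gains) {
  if (nrow(gains) == 0) abort("no gain estimates", class = "attnspace_grouping_error")
  summary <- gains |>
    dplyr::group_by(.data$area, .data$task, .data$decode_space) |>
    dplyr::summarise(mean_gain = mean(.data$gain), median_gain = stats::median(.data$gain),
                     n_cells = dplyr::n(), .groups = "drop")
  if (any(summary$n_cells < 2)) {
    abort("each (area, task, decode_space) group needs >= 2 estimates",
          class = "attnspace_grouping_error")
  }
  task_comparison <- gains |>
    tidyr::pivot_wider(id_cols = c("cell_id", "area", "decode_space"),
                       names_from = "task", values_from = "gain") |>
    dplyr::group_by(.data$area, .data$decode_space) |>
    dplyr::summarise(
      p_value = sign_rank_test(.data$shape_attention - .data$location_attention),
      n_pairs = dplyr::n(), .groups = "drop"
    )
  list(summary = summary, task_comparison = task_comparison)
}
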