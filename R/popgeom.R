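# ---------------------------------------------------------------------------
# internal workhorse: reshape a trial table into the per-decode-space
# structures the analysis needs (passive tuning matrix, overlap responses,
# attention condition means, and per-trial arrays for the bootstrap)

prep_decode_data <- function(trials, area, decode_space, ecc_band = NULL) {
  stopifnot(decode_space %in% c("shape", "location"))
  tr <- trials[trials$area == area & !trials$is_catch, ]
  if (nrow(tr) == 0) {
    abort(paste0("no trials for area '", area, "'"), class = "attnspace_empty_error")
  }

  info <- tr |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      eccentricity = .data$eccentricity_deg[1],
      has_all = all(task_levels() %in% .data$task),
      .groups = "drop"
    )
  if (!is.null(ecc_band)) {
    info <- info[info$eccentricity >= ecc_band[1] & info$eccentricity <= ecc_band[2], ]
  }
  info <- info[info$has_all, ]
  if (nrow(info) == 0) {
    abort("no cells retained (eccentricity band or missing tasks)",
          class = "attnspace_empty_error")
  }
  tr <- tr[tr$cell_id %in% info$cell_id, ]
  cell_ids <- info$cell_id
  n <- length(cell_ids)

  passive_task <- if (decode_space == "shape") "passive_shape" else "passive_location"
  pt <- tr[tr$task == passive_task, ]

  if (decode_space == "shape") {
    stim_of <- function(d) d$shape_id
    pt$stim <- pt$shape_id
    stim_levels <- sort(unique(pt$stim))
  } else {
    pt$stim <- round(wrap_angle(pt$polar_angle_deg), 6)
    stim_levels <- sort(unique(pt$stim))
  }
  n_stim <- length(stim_levels)

  pm <- pt |>
    dplyr::group_by(.data$cell_id, .data$stim) |>
    dplyr::summarise(rate = mean(.data$rate_hz), .groups = "drop")
  P <- matrix(0, n, n_stim, dimnames = list(cell_ids, as.character(stim_levels)))
  P[cbind(match(pm$cell_id, cell_ids), match(pm$stim, stim_levels))] <- pm$rate

  # per-cell overlap stimuli from the attention tasks
  at <- tr[tr$task %in% attention_tasks(), ]
  acts <- at |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      shapes = list(sort(unique(.data$shape_id))),
      angles = list(sort(unique(round(wrap_angle(.data$polar_angle_deg), 6)))),
      .groups = "drop"
    )
  acts <- acts[match(cell_ids, acts$cell_id), ]

  if (decode_space == "shape") {
    # overlap = the 3 active shapes, measured at the active angle nearest the
    # passive-shape location
    pangle <- pt |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(a = wrap_angle(.data$polar_angle_deg[1]), .groups = "drop")
    pangle <- pangle$a[match(cell_ids, pangle$cell_id)]
    ref_angle <- purrr::map2_dbl(acts$angles, pangle,
                                 ~ .x[which.min(angular_distance(.x, .y))])
    overlap <- do.call(rbind, acts$shapes)
    x <- matrix(P[cbind(rep(seq_len(n), 3), match(as.vector(overlap), stim_levels))], n, 3)
    at_overlap <- at[abs(angular_distance(at$polar_angle_deg,
                                          ref_angle[match(at$cell_id, cell_ids)])) < 1e-6, ]
    at_overlap$stim <- at_overlap$shape_id
    nearest_passive_stim <- overlap   # same stimulus identity
  } else {
    best_shape <- pt$shape_id[match(cell_ids, pt$cell_id)]
    overlap <- do.call(rbind, acts$angles)
    x <- t(vapply(seq_len(n), function(i) {
      interpolate_passive(P[i, ], overlap[i, ], polar_angles = stim_levels)
    }, numeric(3)))
    at_overlap <- at[at$shape_id == best_shape[match(at$cell_id, cell_ids)], ]
    at_overlap$stim <- round(wrap_angle(at_overlap$polar_angle_deg), 6)
    nearest_passive_stim <- matrix(vapply(as.vector(overlap), function(a) {
      stim_levels[which.min(angular_distance(a, stim_levels))]
    }, numeric(1)), n, 3)
  }

  # attention condition means over the overlap stimuli, cells x 3
  overlap_key <- tibble::tibble(
    cell_id = rep(cell_ids, 3),
    stim = as.vector(overlap),
    col = rep(1:3, each = n)
  )
  attention_means <- lapply(attention_tasks(), function(tk) {
    d <- at_overlap[at_overlap$task == tk, ] |>
      dplyr::group_by(.data$cell_id, .data$stim) |>
      dplyr::summarise(rate = mean(.data$rate_hz), .groups = "drop") |>
      dplyr::inner_join(overlap_key, by = c("cell_id", "stim"))
    m <- matrix(NA_real_, n, 3, dimnames = list(cell_ids, NULL))
    m[cbind(match(d$cell_id, cell_ids), d$col)] <- d$rate
    m
  })
  names(attention_means) <- attention_tasks()

  # drop cells whose passive overlap vector is all zero (gain undefined) or
  # with missing attention conditions
  bad <- rowSums(x^2) == 0 |
    Reduce(`|`, lapply(attention_means, function(m) rowSums(is.na(m)) > 0))
  if (any(bad)) {
    inform(sprintf("dropping %d cell(s) with undefined gain (%s space, %s)",
                   sum(bad), decode_space, area))
    keep <- !bad
    cell_ids <- cell_ids[keep]; P <- P[keep, , drop = FALSE]
    x <- x[keep, , drop = FALSE]; overlap <- overlap[keep, , drop = FALSE]
    nearest_passive_stim <- nearest_passive_stim[keep, , drop = FALSE]
    attention_means <- lapply(attention_means, function(m) m[keep, , drop = FALSE])
    info <- info[keep, ]
    at_overlap <- at_overlap[at_overlap$cell_id %in% cell_ids, ]
    pt <- pt[pt$cell_id %in% cell_ids, ]
  }
  if (length(cell_ids) == 0) {
    abort("all cells dropped", class = "attnspace_empty_error")
  }

  list(
    area = area, decode_space = decode_space,
    cell_ids = cell_ids, eccentricity = info$eccentricity,
    stim_levels = stim_levels, passive8 = P,
    overlap = overlap, overlap_passive = x,
    nearest_passive_stim = nearest_passive_stim,
    attention_means = attention_means,
    attention_trials = at_overlap[, c("cell_id", "task", "stim", "rate_hz")],
    passive_trials = pt[, c("cell_id", "task", "stim", "rate_hz")]
  )
}

#' Assemble a cells-by-stimuli population response matrix
#'
#' Builds the population matrix for one (area, decode space, task): each row
#' is a cell, each column a stimulus, entries are mean firing rates. For the
#' attention tasks the passive full-set tuning of each cell is scaled by that
#' cell's fitted gain factor; `task = "passive"` returns the unscaled passive
#' means. Cells outside the eccentricity band (inclusive endpoints) are
#' excluded, and the stimulus eccentricity of the retained population is
#' summarized by its mean (stored as an attribute), mirroring the analysis
#' convention of treating all cells as recorded at a common eccentricity.
#'
#' @param trials Trial tibble (catch trials excluded automatically).
#' @param gains Gain tibble from [estimate_gains()]; ignored for
#'   `task = "passive"`.
#' @param decode_space `"shape"` or `"location"`.
#' @param task `"shape_attention"`, `"location_attention"` or `"passive"`.
#' @param area Area label present in `trials`.
#' @param ecc_band Optional inclusive eccentricity interval `c(lo, hi)`.
#' @return A `population_matrix`: numeric matrix (cells x stimuli) with
#'   attributes `area`, `task`, `decode_space`, `mean_eccentricity`.
#' @export
build_population_matrix <- function(trials, gains = NULL, decode_space, task,
                                    area, ecc_band = NULL) {
  prep <- prep_decode_data(trials, area = area, decode_space = decode_space,
                           ecc_band = ecc_band)
  population_matrix_from_prep(prep, gains, task)
}

population_matrix_from_prep <- function(prep, gains, task) {
  if (task == "passive") {
    M <- prep$passive8
  } else {
    check_task(task)
    g <- gains[gains$task == task & gains$decode_space == prep$decode_space &
                 gains$area == prep$area, ]
    gv <- g$gain[match(prep$cell_ids, g$cell_id)]
    if (anyNA(gv)) {
      abort("gains missing for some retained cells", class = "attnspace_domain_error")
    }
    M <- prep$passive8 * gv
  }
  structure(M, class = c("population_matrix", class(M)),
            area = prep$area, task = task, decode_space = prep$decode_space,
            mean_eccentricity = mean(prep$eccentricity))
}

#' Correlation distance between two population response vectors
#'
#' `d = 1 - r`, with `r` the Pearson correlation between the two vectors'
#' elements across cells; ranges over `[0, 2]`.
#'
#' @param u,v Equal-length numeric vectors (length >= 3), neither constant.
#' @return The correlation distance.
#' @examples
#' correlation_distance(c(1, 2, 3), c(3, 2, 1)) # 2
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v) || length(u) < 3) {
    abort("vectors must be matched with length >= 3", class = "attnspace_domain_error")
  }
  if (sd(u) == 0 || sd(v) == 0) {
    abort("correlation undefined for a constant response vector",
          class = "attnspace_degenerate_error")
  }
  1 - cor(u, v)
}

#' Correlation-distance matrix between all stimulus response vectors
#'
#' Pairwise correlation distances between the columns (stimuli) of a
#' population matrix. Cells whose response vector is constant across all
#' stimuli carry no discriminative signal and break the Pearson correlation;
#' they are dropped with a warning before the computation.
#'
#' @param pm A `population_matrix` (cells x stimuli), or any numeric matrix
#'   with >= 3 rows.
#' @return A symmetric, hollow `n x n` matrix of class `attn_dist` with
#'   entries in `[0, 2]` and stimulus labels as dimnames.
#' @export
distance_matrix <- function(pm) {
  M <- unclass(pm)
  const <- apply(M, 1, function(r) sd(r) == 0)
  # cells flat across all stimuli carry no discriminative signal; keep them
  # only when dropping would leave too few cells to correlate (e.g. the
  # degenerate identical-columns case, where the correlation is still defined)
  if (any(const) && sum(!const) >= 3) {
    warn(sprintf("dropping %d cell(s) with constant response vectors", sum(const)))
    M <- M[!const, , drop = FALSE]
  }
  if (nrow(M) < 3) {
    abort("need >= 3 cells", class = "attnspace_domain_error")
  }
  if (any(apply(M, 2, sd) == 0)) {
    abort("a stimulus column is constant across cells: correlation undefined",
          class = "attnspace_degenerate_error")
  }
  D <- 1 - cor(M)
  diag(D) <- 0
  structure(D, class = c("attn_dist", "matrix"))
}

#' Mean of the unique pairwise response distances
#'
#' Averages the `n(n-1)/2` unique off-diagonal entries of a distance matrix
#' and reports their standard error.
#'
#' @param dm Distance matrix (from [distance_matrix()]).
#' @return One-row tibble: `mean_distance`, `se`, `n_pairs`.
#' @export
mean_distance <- function(dm) {
  D <- unclass(dm)
  stopifnot(nrow(D) >= 2, isTRUE(all.equal(D, t(D))))
  d <- D[upper.tri(D)]
  tibble::tibble(mean_distance = mean(d),
                 se = if (length(d) > 1) sd(d) / sqrt(length(d)) else NA_real_,
                 n_pairs = length(d))
}

#' Percent change between two mean distances
#'
#' `100 * (a - b) / b`; positive values mean `a` (e.g. the shape-attention
#' condition) is larger.
#'
#' @param a,b Mean distances; `b` is the baseline and must be positive.
#' @return Percent change.
#' @export
percent_change <- function(a, b) {
  if (!is.numeric(b) || any(b <= 0)) {
    abort("baseline `b` must be positive", class = "attnspace_domain_error")
  }
  100 * (a - b) / b
}
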