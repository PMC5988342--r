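#' Validate a long-format trial table
#'
#' Checks the schema (required columns, non-negative rates) and that every
#' area contains all four tasks; errors list exactly what is missing.
#'
#' @param trials Trial tibble (see [simulate_population()] for the layout).
#' @return `trials`, invisibly, with catch trials still present.
#' @export
validate_trial_table <- function(trials) {
  req <- c("cell_id", "area", "task", "shape_id", "polar_angle_deg",
           "eccentricity_deg", "rep", "rate_hz", "is_catch")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols)) {
    abort(paste0("trial table lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "attnspace_validation_error")
  }
  if (any(trials$rate_hz < 0)) {
    abort("negative firing rates in trial table", class = "attnspace_validation_error")
  }
  check_task(unique(trials$task))
  by_area <- split(trials$task, trials$area)
  absent <- purrr::imap_chr(by_area, function(tk, ar) {
    miss <- setdiff(task_levels(), unique(tk))
    if (length(miss)) paste0(ar, ": ", paste(miss, collapse = ", ")) else NA_character_
  })
  absent <- absent[!is.na(absent)]
  if (length(absent)) {
    abort(paste0("missing task(s) -- ", paste(absent, collapse = "; ")),
          class = "attnspace_validation_error")
  }
  invisible(trials)
}

#' Stress between an MDS map and the physical stimulus ring
#'
#' Places the physical stimuli on the circle of the given eccentricity at
#' their polar angles, aligns that configuration to the MDS map by the full
#' Procrustes transform (scaling included), and returns the stress with the
#' MDS configuration as configuration 1. Low values mean the neural map
#' recovers the physical arrangement of the stimuli.
#'
#' @param embedding An `attn_mds` with 2-D points for the location stimuli
#'   (or an n x 2 coordinate matrix).
#' @param physical_angles Polar angles of the stimuli, degrees, in the same
#'   row order as the embedding.
#' @param eccentricity Ring eccentricity, degrees of visual angle.
#' @return Stress value.
#' @export
stress_vs_physical <- function(embedding, physical_angles,
                               eccentricity = 1) {
  X <- if (inherits(embedding, "attn_mds")) embedding$points[, 1:2] else as.matrix(embedding)
  stopifnot(nrow(X) == length(physical_angles))
  ring <- eccentricity * cbind(cos(deg2rad(physical_angles)),
                               sin(deg2rad(physical_angles)))
  procrustes_align(X, ring, allow_scaling = TRUE)$stress
}

report_conditions <- function() c("shape_attention", "location_attention", "passive")

#' Run the full population-geometry analysis
#'
#' End-to-end pipeline for one trial table: per-cell gain factors, periodic
#' spline interpolation for the location space, gain-scaled population
#' matrices, correlation-distance matrices and mean distances, classical MDS
#' (four attention-condition embeddings per area plus passive baselines),
#' Procrustes/stress comparisons between conditions with shuffle-split
#' bootstrap p-values, rank-sum comparisons of the 28 unique distances,
#' stress against the physical stimulus ring (location space), convex-hull
#' summaries, and the interpolation shift report.
#'
#' @param trials Trial tibble covering all four tasks (catch trials are
#'   excluded automatically).
#' @param k Embedding dimension (2, as plotted).
#' @param n_boot Shuffle-split iterations per stress comparison; 0 skips the
#'   bootstrap (stress values still reported, p-values `NA`).
#' @param seed Integer seed for the bootstrap streams.
#' @param ecc_bands Named list of inclusive eccentricity bands applied when
#'   decoding for location (`NULL` entries skip the filter).
#' @param allow_scaling Scaling aspect of the Procrustes transform used in
#'   the stress comparisons (`TRUE` isolates warping beyond magnification).
#' @return An object of class `attn_report`: list of tidy tables
#'   (`gains`, `gain_summary`, `distances`, `distance_comparisons`,
#'   `stress_comparisons`, `stress_physical`, `hulls`, `interpolation`),
#'   a named list `embeddings` of `attn_mds` objects, and `provenance`.
#' @export
run_full_analysis <- function(trials, k = 2, n_boot = 1000, seed = 1,
                              ecc_bands = list(ait = c(2, 6), lip = c(7, 12)),
                              allow_scaling = TRUE) {
  validate_trial_table(trials)
  areas <- sort(unique(trials$area))
  grid <- tidyr::expand_grid(area = areas, decode_space = c("shape", "location"))

  preps <- purrr::pmap(grid, function(area, decode_space) {
    band <- if (decode_space == "location") ecc_bands[[area]] else NULL
    prep_decode_data(trials, area = area, decode_space = decode_space,
                     ecc_band = band)
  })

  gains <- dplyr::bind_rows(purrr::map(preps, gains_from_prep))
  gsum <- gain_summary(gains)

  # distance + embedding per condition
  cond_tbl <- list()
  embeddings <- list()
  hulls <- list()
  for (i in seq_along(preps)) {
    prep <- preps[[i]]
    for (cond in report_conditions()) {
      M <- population_matrix_from_prep(prep, gains, cond)
      D <- suppressWarnings(distance_matrix(M))
      md <- mean_distance(D)
      emb <- suppressMessages(classical_mds(D, k = k))
      id <- paste(prep$area, prep$decode_space, cond, sep = ".")
      embeddings[[id]] <- emb
      hulls[[id]] <- dplyr::bind_cols(
        tibble::tibble(area = prep$area, decode_space = prep$decode_space,
                       condition = cond),
        convex_hull_summary(emb$points[, 1:2])
      )
      cond_tbl[[id]] <- tibble::tibble(
        area = prep$area, decode_space = prep$decode_space, condition = cond,
        mean_distance = md$mean_distance, se = md$se, n_pairs = md$n_pairs,
        n_cells = length(prep$cell_ids),
        var_explained = sum(emb$variance_explained[seq_len(k)], na.rm = TRUE),
        distances = list(D)
      )
    }
  }
  distances <- dplyr::bind_rows(cond_tbl)

  three_task_avg <- distances |>
    dplyr::group_by(.data$area, .data$decode_space) |>
    dplyr::summarise(condition = "three_task_average",
                     mean_distance = mean(.data$mean_distance), .groups = "drop")

  pairs <- tibble::tribble(
    ~cond_a,            ~cond_b,
    "shape_attention",  "location_attention",
    "shape_attention",  "passive",
    "location_attention", "passive"
  )

  dist_of <- function(ar, sp, cond) {
    distances$distances[[which(distances$area == ar & distances$decode_space == sp &
                                 distances$condition == cond)]]
  }
  mean_of <- function(ar, sp, cond) {
    distances$mean_distance[distances$area == ar & distances$decode_space == sp &
                              distances$condition == cond]
  }

  comp_grid <- tidyr::expand_grid(grid, pairs)
  distance_comparisons <- comp_grid |>
    dplyr::mutate(
      mean_a = purrr::pmap_dbl(list(.data$area, .data$decode_space, .data$cond_a), mean_of),
      mean_b = purrr::pmap_dbl(list(.data$area, .data$decode_space, .data$cond_b), mean_of),
      pct_change = percent_change(.data$mean_a, .data$mean_b),
      p_value = purrr::pmap_dbl(
        list(.data$area, .data$decode_space, .data$cond_a, .data$cond_b),
        function(ar, sp, a, b) {
          da <- dist_of(ar, sp, a); db <- dist_of(ar, sp, b)
          rank_sum_test(da[upper.tri(da)], db[upper.tri(db)])
        })
    )

  stress_comparisons <- comp_grid
  stress_comparisons$stress <- NA_real_
  stress_comparisons$p_value <- NA_real_
  for (j in seq_len(nrow(stress_comparisons))) {
    row <- stress_comparisons[j, ]
    i <- which(grid$area == row$area & grid$decode_space == row$decode_space)
    prep <- preps[[i]]
    if (n_boot > 0) {
      bt <- boot_from_prep(prep, row$cond_a, row$cond_b, n_boot = n_boot,
                           seed = seed + j, k = k, allow_scaling = allow_scaling)
      stress_comparisons$stress[j] <- bt$observed_stress
      stress_comparisons$p_value[j] <- bt$p_value
    } else {
      A <- embeddings[[paste(row$area, row$decode_space, row$cond_a, sep = ".")]]
      B <- embeddings[[paste(row$area, row$decode_space, row$cond_b, sep = ".")]]
      stress_comparisons$stress[j] <-
        procrustes_align(A$points[, 1:k], B$points[, 1:k],
                         allow_scaling = allow_scaling)$stress
    }
  }

  stress_physical <- purrr::map_dfr(seq_along(preps), function(i) {
    prep <- preps[[i]]
    if (prep$decode_space != "location") return(tibble::tibble())
    purrr::map_dfr(report_conditions(), function(cond) {
      emb <- embeddings[[paste(prep$area, "location", cond, sep = ".")]]
      tibble::tibble(
        area = prep$area, condition = cond,
        stress = stress_vs_physical(emb, prep$stim_levels,
                                    eccentricity = mean(prep$eccentricity))
      )
    })
  })

  acts <- trials[trials$task %in% attention_tasks() & !trials$is_catch, ] |>
    dplyr::group_by(.data$cell_id, .data$area) |>
    dplyr::summarise(active_angles = list(unique(round(wrap_angle(.data$polar_angle_deg), 6))),
                     .groups = "drop")
  interpolation <- angular_shift_report(
    acts, passive_angles = sort(unique(round(wrap_angle(
      trials$polar_angle_deg[trials$task == "passive_location"]), 6))))

  structure(
    list(
      gains = gains,
      gain_summary = gsum,
      distances = dplyr::select(distances, -"distances"),
      three_task_average = three_task_avg,
      distance_matrices = setNames(distances$distances,
                                   paste(distances$area, distances$decode_space,
                                         distances$condition, sep = ".")),
      distance_comparisons = distance_comparisons,
      stress_comparisons = stress_comparisons,
      stress_physical = stress_physical,
      embeddings = embeddings,
      hulls = dplyr::bind_rows(hulls),
      interpolation = interpolation,
      provenance = list(seed = seed, k = k, n_boot = n_boot,
                        allow_scaling = allow_scaling,
                        n_trials = nrow(trials),
                        package_version = as.character(utils::packageVersion("attnspace")))
    ),
    class = "attn_report"
  )
}

#' @export
print.attn_report <- function(x, ...) {
  cat("<attn_report>\n")
  cat(sprintf("  %d gain estimates; %d embeddings (k = %d)\n",
              nrow(x$gains), length(x$embeddings), x$provenance$k))
  cat("  mean distances:\n")
  d <- x$distances
  for (i in seq_len(nrow(d))) {
    cat(sprintf("    %-4s %-8s %-20s %.4f (var expl %.0f%%)\n",
                d$area[i], d$decode_space[i], d$condition[i],
                d$mean_distance[i], 100 * d$var_explained[i]))
  }
  cat("  stress comparisons:\n")
  s <- x$stress_comparisons
  for (i in seq_len(nrow(s))) {
    cat(sprintf("    %-4s %-8s %s vs %s: stress %.4f, p %s\n",
                s$area[i], s$decode_space[i], s$cond_a[i], s$cond_b[i],
                s$stress[i], ifelse(is.na(s$p_value[i]), "--",
                                    sprintf("%.3f", s$p_value[i]))))
  }
  invisible(x)
}
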