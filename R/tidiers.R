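#' Tidy an MDS embedding
#'
#' @param x An `attn_mds`.
#' @param ... Unused.
#' @return Tibble with `stimulus` and one column per dimension.
#' @export
tidy.attn_mds <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(stimulus = x$labels),
                   tibble::as_tibble(x$points))
}

#' @rdname tidy.attn_mds
#' @return `glance()`: one-row tibble with the embedding dimension, variance
#'   explained by the retained dimensions, and the negative eigenvalue mass.
#' @export
glance.attn_mds <- function(x, ...) {
  ev <- x$eigenvalues
  tibble::tibble(
    n_points = nrow(x$points), k = x$k,
    var_explained = sum(x$variance_explained[seq_len(x$k)], na.rm = TRUE),
    negative_eigenvalue_mass = sum(abs(ev[ev < 0])) / max(sum(ev[ev > 0]), .Machine$double.eps)
  )
}

#' Tidy a Procrustes alignment
#'
#' @param x An `attn_procrustes`.
#' @param ... Unused.
#' @return Tibble of the paired unique inter-point distances (`d1`, `d2`)
#'   entering the stress.
#' @export
tidy.attn_procrustes <- function(x, ...) {
  tibble::tibble(pair = seq_along(x$d1), d1 = x$d1, d2 = x$d2)
}

#' @rdname tidy.attn_procrustes
#' @export
glance.attn_procrustes <- function(x, ...) {
  tibble::tibble(stress = x$stress, scale = x$scale,
                 reflected = det(x$rotation) < 0)
}

#' Tidy a bootstrap stress test
#'
#' @param x An `attn_boot`.
#' @param ... Unused.
#' @return Tibble of the null stress values, one row per iteration.
#' @export
tidy.attn_boot <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$null_stresses),
                 null_stress = x$null_stresses)
}

#' @rdname tidy.attn_boot
#' @export
glance.attn_boot <- function(x, ...) {
  tibble::tibble(
    task_a = x$task_a, task_b = x$task_b, area = x$area,
    decode_space = x$decode_space,
    observed_stress = x$observed_stress, p_value = x$p_value,
    n_boot = x$n_boot,
    null_q95 = unname(stats::quantile(x$null_stresses, 0.95))
  )
}
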