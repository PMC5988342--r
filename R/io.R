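#' Read and write trial tables
#'
#' Trial tables are plain CSV with the canonical header
#' `cell_id, area, task, shape_id, polar_angle_deg, eccentricity_deg, rep,
#' rate_hz, is_catch`.
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `read_trial_table()` returns a validated tibble;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          cell_id = readr::col_character(),
                          area = readr::col_character(),
                          task = readr::col_character(),
                          shape_id = readr::col_integer(),
                          rep = readr::col_integer(),
                          is_catch = readr::col_logical(),
                          .default = readr::col_double()
                        ))
  validate_trial_table(tr)
  tr
}

#' Write a distance matrix as square CSV
#'
#' Stimulus labels form the header row and first column.
#'
#' @param dm Distance matrix (`attn_dist` or plain matrix with dimnames).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  D <- unclass(dm)
  df <- tibble::as_tibble(D, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(stimulus = rownames(D) %||%
                                          as.character(seq_len(nrow(D)))), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Serialize ground truth or a bootstrap result to JSON
#'
#' @param x Ground-truth cell tibble, `attn_boot`, or any list-like object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_json_result <- function(x, path) {
  if (inherits(x, "attn_boot")) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an embedding as CSV plus its spectrum as JSON
#'
#' @param embedding An `attn_mds`.
#' @param path CSV path for the coordinates; the eigenvalue spectrum is
#'   written next to it with extension `.spectrum.json`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "attn_mds"))
  readr::write_csv(tidy(embedding), path)
  jsonlite::write_json(
    list(eigenvalues = embedding$eigenvalues,
         variance_explained = embedding$variance_explained),
    sub("\\.csv$", ".spectrum.json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
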