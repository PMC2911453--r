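#' Tidy an epitope-selection result
#'
#' One row per selected epitope, with the number of target proteins it
#' covers and the covered accessions, in selection order (greedy variants)
#' or lexicographic order (exact solvers).
#'
#' @param x a `txp_solve_result`.
#' @param ... unused.
#' @return tibble `side`, `epitope`, `n_proteins`, `proteins`
#'   (comma-separated accessions).
#' @exportS3Method generics::tidy
tidy.txp_solve_result <- function(x, ...) {
  if (nrow(x$selected) == 0L) {
    return(tibble(side = character(), epitope = character(),
                  n_proteins = integer(), proteins = character()))
  }
  per_epitope <- x$hits |>
    group_by(.data$side, .data$epitope) |>
    summarise(n_proteins = n(),
              proteins = paste(sort(.data$accession), collapse = ","),
              .groups = "drop")
  left_join(x$selected, per_epitope, by = c("side", "epitope"))
}

#' Glance at an epitope-selection result
#'
#' @param x a `txp_solve_result`.
#' @param ... unused.
#' @return one-row tibble: `variant`, `status`, `objective`, `n_selected`,
#'   `n_proteins`, `coverage_score`, `n_single_covered`, `n_multi_covered`,
#'   `n_uncovered`.
#' @exportS3Method generics::glance
glance.txp_solve_result <- function(x, ...) {
  sol <- x$solution
  tibble(
    variant = x$variant,
    status = x$status,
    objective = x$objective,
    n_selected = nrow(x$selected),
    n_proteins = if (is.null(sol)) 0L else nrow(sol$cover_count),
    coverage_score = if (is.null(sol)) NA_real_ else sol$coverage_score,
    n_single_covered = if (is.null(sol)) NA_integer_ else sol$n_single_covered,
    n_multi_covered = if (is.null(sol)) NA_integer_ else sol$n_multi_covered,
    n_uncovered = if (is.null(sol)) NA_integer_ else length(sol$uncovered)
  )
}

#' @rdname glance.txp_solve_result
#' @exportS3Method generics::glance
glance.txp_solution <- function(x, ...) {
  tibble(
    n_selected = nrow(x$selected),
    n_proteins = nrow(x$cover_count),
    coverage_score = x$coverage_score,
    n_single_covered = x$n_single_covered,
    n_multi_covered = x$n_multi_covered,
    n_uncovered = length(x$uncovered)
  )
}

#' @rdname tidy.txp_solve_result
#' @exportS3Method generics::tidy
tidy.txp_solution <- function(x, ...) {
  x$cover_count
}
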