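#' Plot a filter report
#'
#' Surviving detectable combinations (log scale where helpful) after each
#' filter stage, mirroring the tabular filter-impact report.
#'
#' @param object a `txp_filtered` result from [run_filter_pipeline()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.txp_filtered <- function(object, ...) {
  rep <- object$report |>
    mutate(filter = factor(.data$filter, levels = .data$filter)) |>
    tidyr::pivot_longer(c("n_epitopes", "n_proteins", "n_combinations"),
                        names_to = "quantity", values_to = "n") |>
    mutate(quantity = sub("^n_", "", .data$quantity))
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$filter, y = .data$n,
                                    group = .data$quantity,
                                    colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "filter stage", y = "surviving (detectable)",
                  colour = NULL, title = "Filter pipeline impact") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot per-protein coverage of a selection
#'
#' Histogram of cover counts: how many selected epitopes capture each target
#' protein. Multicovered proteins (count >= 2) are the redundancy the
#' multicover variants aim for.
#'
#' @param object a `txp_solve_result`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.txp_solve_result <- function(object, ...) {
  if (is.null(object$solution)) abort("Result has no scored solution to plot.")
  cc <- object$solution$cover_count |>
    count(.data$n_cover)
  ggplot2::ggplot(cc, ggplot2::aes(x = factor(.data$n_cover), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "covering epitopes per protein", y = "proteins",
      title = paste0("Coverage profile (", object$variant, ", |L| = ",
                     nrow(object$selected), ")")
    ) +
    ggplot2::theme_minimal()
}
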