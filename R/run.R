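#' Run the full epitope-selection workflow
#'
#' Orchestrates digest, combination enumeration, filter pipeline, cover-graph
#' construction (with optional target restriction and robinson removal) and
#' solving, optionally writing every artifact to disk: the filter report,
#' the graph edge list, the selected-epitope table and a JSON run summary
#' (including a config hash for reproducibility).
#'
#' @param proteome a proteome tibble ([read_proteome()]) or path to a FASTA
#'   file.
#' @param targets optional character vector of target accessions, or path to
#'   a plain-text file with one accession per line.
#' @param lengths,sides epitope lengths and termini for
#'   [enumerate_combinations()].
#' @param filter a [filter_config()].
#' @param method solver name, see [solve_cover()].
#' @param drop_robinson remove single-capture epitopes before solving.
#' @param mass_type `"monoisotopic"` or `"average"` residue masses.
#' @param output_dir if non-`NULL`, artifacts are written here as
#'   tab-delimited tables plus `summary.json`.
#' @param ... further solver arguments (`s_cov`, `s_mcov`, `cost_max`,
#'   `time_limit`).
#' @return A list of class `txp_run` with elements `digest`, `filtered`
#'   (`txp_filtered`), `graph`, `result` (`txp_solve_result`) and `summary`
#'   (named list, also written as JSON).
#' @export
txp_run <- function(proteome, targets = NULL,
                    lengths = c(4L, 5L), sides = c("n", "c"),
                    filter = filter_config(),
                    method = "greedy",
                    drop_robinson = TRUE,
                    mass_type = c("monoisotopic", "average"),
                    output_dir = NULL, ...) {
  mass_type <- match.arg(mass_type)
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome)) {
    proteome <- read_proteome(proteome)
  }
  check_proteome(proteome)
  if (is.character(targets) && length(targets) == 1L && file.exists(targets)) {
    targets <- read_stoplist(targets) # same one-per-line format
  }
  table <- mass_table(mass_type)
  digest <- tryptic_digest(proteome, table)
  combos <- enumerate_combinations(digest, lengths = lengths, sides = sides)
  filtered <- run_filter_pipeline(combos, filter)
  graph <- build_cover_graph(filtered, targets = targets)
  if (drop_robinson) graph <- remove_robinson(graph)
  result <- solve_cover(graph, method = method, ...)

  config <- list(lengths = lengths, sides = sides, filter = unclass(filter),
                 method = method, drop_robinson = drop_robinson,
                 mass_type = mass_type, extra = list(...))
  summary <- list(
    config_hash = rlang::hash(config),
    method = method,
    status = result$status,
    objective = result$objective,
    n_selected = nrow(result$selected),
    n_proteins = length(graph$proteins),
    coverage_score = if (!is.null(result$solution)) result$solution$coverage_score,
    n_single_covered = if (!is.null(result$solution)) result$solution$n_single_covered,
    n_multi_covered = if (!is.null(result$solution)) result$solution$n_multi_covered,
    uncoverable_targets = graph$uncoverable
  )
  run <- structure(list(digest = digest, filtered = filtered, graph = graph,
                        result = result, summary = summary),
                   class = "txp_run")
  if (!is.null(output_dir)) write_run_artifacts(run, output_dir)
  run
}

#' @export
print.txp_run <- function(x, ...) {
  cat("txp run [", x$summary$method, "]: ", x$summary$n_selected,
      " epitopes for ", x$summary$n_proteins, " proteins (status ",
      x$summary$status, ")\n", sep = "")
  invisible(x)
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$digest, file.path(dir, "digest.tsv"))
  readr::write_tsv(run$filtered$combinations, file.path(dir, "combinations.tsv"))
  readr::write_tsv(run$filtered$report, file.path(dir, "filter_report.tsv"))
  edges <- run$graph$edges |>
    mutate(peptides = map_chr(.data$peptides, paste, collapse = ",")) |>
    select("side", "epitope", "accession", "n_peptides", "peptides")
  readr::write_tsv(edges, file.path(dir, "graph_edges.tsv"))
  readr::write_tsv(tidy(run$result), file.path(dir, "solution.tsv"))
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
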