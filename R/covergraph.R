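#' Build the bipartite protein-epitope cover graph
#'
#' Connects a protein and an epitope whenever at least one *detectable*
#' combination links them in the filtered set. When a target list is given,
#' the protein side is restricted to the targets found in the combination
#' set, and only edges into targets are kept; targets without any detectable
#' combination are reported as uncoverable. Restriction happens *after*
#' filtering, so epitope loads reflect the full background proteome.
#'
#' @param combinations a filtered combination tibble (or a `txp_filtered`
#'   result from [run_filter_pipeline()]).
#' @param targets optional character vector of target accessions; `NULL`
#'   covers every protein in the set.
#' @return An object of class `cover_graph`: list with `edges` (tibble
#'   `side`, `epitope`, `accession`, `n_peptides`, `peptides` list-column of
#'   supporting detectable peptide species), `proteins`, `epitopes` (tibble
#'   `side`, `epitope`), and `uncoverable` (targets absent from the set).
#' @export
build_cover_graph <- function(combinations, targets = NULL) {
  if (inherits(combinations, "txp_filtered")) combinations <- combinations$combinations
  x <- filter(combinations, .data$detectable)
  uncoverable <- character()
  if (!is.null(targets)) {
    targets <- unique(targets)
    uncoverable <- setdiff(targets, unique(x$accession))
    x <- filter(x, .data$accession %in% targets)
    if (nrow(x) == 0L) {
      abort(paste0("No target protein is coverable. Uncoverable targets: ",
                   paste(uncoverable, collapse = ", ")))
    }
    if (length(uncoverable) > 0L) {
      warn(paste0("Target(s) without any detectable combination: ",
                  paste(uncoverable, collapse = ", ")))
    }
  }
  edges <- x |>
    group_by(.data$side, .data$epitope, .data$accession) |>
    summarise(peptides = list(sort(unique(.data$peptide))), .groups = "drop") |>
    mutate(n_peptides = lengths(.data$peptides)) |>
    arrange(.data$side, .data$epitope, .data$accession)
  new_cover_graph(edges, uncoverable)
}

new_cover_graph <- function(edges, uncoverable = character()) {
  structure(list(
    edges = edges,
    proteins = sort(unique(edges$accession)),
    epitopes = distinct(edges, .data$side, .data$epitope) |>
      arrange(.data$side, .data$epitope),
    uncoverable = uncoverable
  ), class = "cover_graph")
}

#' @export
print.cover_graph <- function(x, ...) {
  cat("Cover graph: ", length(x$proteins), " proteins, ",
      nrow(x$epitopes), " epitopes, ", nrow(x$edges), " edges\n", sep = "")
  if (length(x$uncoverable) > 0L) {
    cat("Uncoverable targets: ", paste(x$uncoverable, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Remove single-capture ("robinson") epitopes
#'
#' An epitope capturing exactly one detectable peptide species from exactly
#' one protein is never preferable to an epitope capturing more from the
#' same protein, so such epitopes are pruned before optimisation. An epitope
#' that is the *only* cover of its protein is kept (removing it would orphan
#' the protein) and reported via message.
#'
#' @param graph a [build_cover_graph()] result.
#' @return the pruned `cover_graph`.
#' @export
remove_robinson <- function(graph) {
  stopifnot(inherits(graph, "cover_graph"))
  e <- graph$edges
  epi_stats <- e |>
    group_by(.data$side, .data$epitope) |>
    summarise(n_prot = n(), tot_pep = sum(.data$n_peptides), .groups = "drop")
  robinson <- e |>
    inner_join(filter(epi_stats, .data$n_prot == 1L, .data$tot_pep == 1L),
               by = c("side", "epitope"))
  # guard: a protein must retain >= 1 edge; if all its edges are robinson,
  # keep its lexicographically first robinson epitope
  non_rob <- anti_join(e, robinson, by = c("side", "epitope")) |>
    distinct(.data$accession)
  guarded <- robinson |>
    filter(!.data$accession %in% non_rob$accession) |>
    arrange(.data$accession, .data$side, .data$epitope) |>
    group_by(.data$accession) |>
    slice(1L) |>
    ungroup()
  drop <- anti_join(robinson, guarded, by = c("side", "epitope")) |>
    distinct(.data$side, .data$epitope)
  if (nrow(guarded) > 0L) {
    inform(paste0(nrow(guarded), " single-capture epitope(s) kept as sole cover of ",
                  "their protein."))
  }
  new_cover_graph(anti_join(e, drop, by = c("side", "epitope")), graph$uncoverable)
}

#' Score an epitope selection against a cover graph
#'
#' Computes per-protein cover counts (how many selected epitopes are adjacent
#' to each protein) and the coverage score, defined as the number of selected
#' epitopes divided by the number of proteins to cover — lower means fewer
#' antibodies per protein.
#'
#' @param graph a `cover_graph`.
#' @param selected the selection: a tibble with columns `side` and `epitope`
#'   (extra columns ignored), or a `txp_solve_result`.
#' @return An object of class `txp_solution`: list with `selected`,
#'   `cover_count` (tibble `accession`, `n_cover`), `coverage_score`,
#'   `uncovered`, `n_single_covered`, `n_multi_covered`.
#' @export
score_solution <- function(graph, selected) {
  stopifnot(inherits(graph, "cover_graph"))
  if (inherits(selected, "txp_solve_result")) selected <- selected$selected
  selected <- distinct(as_tibble(selected)[, c("side", "epitope")])
  known <- epitope_key(graph$epitopes$side, graph$epitopes$epitope)
  keys <- epitope_key(selected$side, selected$epitope)
  if (!all(keys %in% known)) {
    abort(paste0("Selected epitope(s) not in graph: ",
                 paste(keys[!keys %in% known], collapse = ", ")))
  }
  hits <- semi_join(graph$edges, selected, by = c("side", "epitope"))
  cover_count <- tibble(accession = graph$proteins) |>
    left_join(count(hits, .data$accession, name = "n_cover"), by = "accession") |>
    mutate(n_cover = coalesce(.data$n_cover, 0L))
  structure(list(
    selected = selected,
    cover_count = cover_count,
    coverage_score = nrow(selected) / length(graph$proteins),
    uncovered = cover_count$accession[cover_count$n_cover == 0L],
    n_single_covered = sum(cover_count$n_cover == 1L),
    n_multi_covered = sum(cover_count$n_cover >= 2L)
  ), class = "txp_solution")
}

#' @export
print.txp_solution <- function(x, ...) {
  cat("Epitope selection: ", nrow(x$selected), " epitopes for ",
      nrow(x$cover_count), " proteins (coverage score ",
      sprintf("%.3f", x$coverage_score), ")\n", sep = "")
  cat("  single-covered: ", x$n_single_covered,
      ", multi-covered: ", x$n_multi_covered,
      ", uncovered: ", length(x$uncovered), "\n", sep = "")
  invisible(x)
}

#' Flag elongation pairs in a selection
#'
#' Enforced multicovering tends to select elongated variants of an already
#' selected epitope (e.g. `IER` and `EIER` at the C terminus), which capture
#' nearly the same peptide group. This reports every pair in a selection
#' where one epitope extends another inward from the same terminus.
#'
#' @param selected tibble with `side` and `epitope` columns (or a
#'   `txp_solve_result`).
#' @return tibble `side`, `shorter`, `longer` (possibly empty).
#' @export
elongation_pairs <- function(selected) {
  if (inherits(selected, "txp_solve_result")) selected <- selected$selected
  s <- distinct(as_tibble(selected)[, c("side", "epitope")])
  pairs <- tidyr::expand_grid(a = seq_len(nrow(s)), b = seq_len(nrow(s))) |>
    filter(.data$a != .data$b)
  keep <- pmap(pairs, function(a, b) {
    if (s$side[a] != s$side[b]) return(NULL)
    short <- s$epitope[a]; long <- s$epitope[b]
    if (nchar(short) >= nchar(long)) return(NULL)
    ext <- if (s$side[a] == "c") endsWith(long, short) else startsWith(long, short)
    if (ext) tibble(side = s$side[a], shorter = short, longer = long) else NULL
  })
  bind_rows(keep)
}
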