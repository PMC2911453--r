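#' Filter pipeline configuration
#'
#' Bundles the thresholds of the detectability filter pipeline. The default
#' order is: unknown-positions, methionine, high-abundant-epitope, weight,
#' length, stoplist. The unknown-positions, methionine and stoplist filters
#' commute; the other three evaluate the per-epitope combination load and are
#' order-dependent: the high-abundant-epitope filter must precede the weight
#' filter, which must precede the length filter. A `filter_order` violating
#' that constraint is rejected here, before any work is done.
#'
#' @param max_epitope_load epitopes capturing more than this many
#'   combinations are discarded (antibodies against them would be cluttered
#'   and insensitive). Default 600.
#' @param delta_min minimum mass separation in Da for two different peptides
#'   captured by the same epitope to give distinguishable peaks. 2-10 Da is
#'   reasonable for MALDI-TOF; default 2.
#' @param min_peptide_len,max_peptide_len inclusive detector length range in
#'   residues; 8-30 is a good rule of thumb.
#' @param stoplist accessions of high-abundant proteins whose epitopes are
#'   unsuitable (e.g. actin, tubulin).
#' @param filter_order character vector ordering the six filters.
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_epitope_load = 600L,
                          delta_min = 2,
                          min_peptide_len = 8L,
                          max_peptide_len = 30L,
                          stoplist = character(),
                          filter_order = c("unknown_positions", "methionine",
                                           "high_abundant_epitope", "weight",
                                           "length", "stoplist")) {
  known <- c("unknown_positions", "methionine", "high_abundant_epitope",
             "weight", "length", "stoplist")
  bad <- setdiff(filter_order, known)
  if (length(bad) > 0L) abort(paste0("Unknown filter(s): ", paste(bad, collapse = ", ")))
  if (anyDuplicated(filter_order)) abort("`filter_order` must not repeat filters.")
  pos <- match(c("high_abundant_epitope", "weight", "length"), filter_order)
  pos <- pos[!is.na(pos)]
  if (is.unsorted(pos)) {
    abort(paste0("Invalid filter order: the high-abundant-epitope filter must ",
                 "precede the weight filter, which must precede the length filter."))
  }
  if (delta_min <= 0) abort("`delta_min` must be positive.")
  if (max_epitope_load < 1L) abort("`max_epitope_load` must be >= 1.")
  if (min_peptide_len < 1L || min_peptide_len > max_peptide_len) {
    abort("Need 1 <= min_peptide_len <= max_peptide_len.")
  }
  structure(list(
    max_epitope_load = as.integer(max_epitope_load),
    delta_min = delta_min,
    min_peptide_len = as.integer(min_peptide_len),
    max_peptide_len = as.integer(max_peptide_len),
    stoplist = stoplist,
    filter_order = filter_order
  ), class = "filter_config")
}

#' Individual combination filters
#'
#' Each filter takes and returns a combination tibble (see
#' [enumerate_combinations()]). Most remove rows; the weight filter instead
#' clears the `detectable` flag, so the affected combinations stay visible in
#' dumps but never contribute coverage.
#'
#' * `filter_unknown_positions()`: drops combinations whose *peptide* has no
#'   computable mass (contains X or another mass-less code).
#' * `filter_methionine()`: drops combinations whose *epitope* contains
#'   methionine (M), whose chemical modification can defeat antibody
#'   recognition; M elsewhere in the peptide is fine.
#' * `filter_high_abundant_epitope()`: drops every combination of any epitope
#'   whose current load exceeds `max_load` (strictly; a load of exactly
#'   `max_load` survives).
#' * `filter_weight()`: within each epitope's combination set, two *different*
#'   peptide sequences closer than `delta_min` Da would give overlapping
#'   peaks; all combinations of both are marked `detectable = FALSE`.
#'   Identical sequences from different proteins are one molecular species
#'   (one peak) and never conflict with themselves. Peptides with unknown
#'   mass are marked undetectable too.
#' * `filter_length()`: keeps combinations whose peptide length lies in
#'   `[min_len, max_len]` (inclusive).
#' * `filter_stoplist()`: collects every epitope occurring on a peptide of a
#'   stoplisted (high-abundant) protein and removes *all* combinations
#'   carrying any of those epitopes, whatever their protein.
#'
#' @param combinations a combination tibble.
#' @param max_load positive integer load threshold.
#' @param delta_min minimum distinguishable mass separation in Da.
#' @param min_len,max_len inclusive peptide length range.
#' @param stoplist character vector of high-abundant protein accessions.
#' @return the filtered combination tibble.
#' @name combination_filters
NULL

#' @rdname combination_filters
#' @export
filter_unknown_positions <- function(combinations) {
  filter(combinations, !is.na(.data$mass))
}

#' @rdname combination_filters
#' @export
filter_methionine <- function(combinations) {
  filter(combinations, !grepl("M", .data$epitope, fixed = TRUE))
}

#' @rdname combination_filters
#' @export
filter_high_abundant_epitope <- function(combinations, max_load = 600L) {
  if (max_load < 1L) abort("`max_load` must be >= 1.")
  combinations |>
    group_by(.data$side, .data$epitope) |>
    filter(n() <= max_load) |>
    ungroup()
}

#' @rdname combination_filters
#' @export
filter_weight <- function(combinations, delta_min = 2) {
  if (delta_min <= 0) abort("`delta_min` must be positive.")
  species <- combinations |>
    distinct(.data$side, .data$epitope, .data$peptide, .data$mass) |>
    group_by(.data$side, .data$epitope) |>
    arrange(.data$mass, .by_group = TRUE) |>
    mutate(conflict = weight_conflicts(.data$mass, delta_min)) |>
    ungroup()
  combinations |>
    left_join(select(species, "side", "epitope", "peptide", "conflict"),
              by = c("side", "epitope", "peptide")) |>
    mutate(detectable = .data$detectable & !.data$conflict) |>
    select(-"conflict")
}

# masses sorted ascending within one epitope's distinct peptide species;
# a species conflicts if a neighbouring *different* species is < delta_min away
# (both parties of a near-isobaric pair are ambiguous). NA mass => conflict.
weight_conflicts <- function(mass, delta_min) {
  conflict <- is.na(mass)
  m <- mass[!conflict]
  if (length(m) > 1L) {
    d <- diff(m) # ascending, NAs sorted last by the caller
    close <- c(d < delta_min, FALSE) | c(FALSE, d < delta_min)
    conflict[!conflict] <- close
  }
  conflict
}

#' @rdname combination_filters
#' @export
filter_length <- function(combinations, min_len = 8L, max_len = 30L) {
  if (min_len < 1L || min_len > max_len) abort("Need 1 <= min_len <= max_len.")
  filter(combinations, nchar(.data$peptide) >= min_len, nchar(.data$peptide) <= max_len)
}

#' @rdname combination_filters
#' @export
filter_stoplist <- function(combinations, stoplist = character()) {
  if (length(stoplist) == 0L) return(combinations)
  missing <- setdiff(stoplist, unique(combinations$accession))
  if (length(missing) > 0L) {
    warn(paste0("Stoplist accession(s) not present in the combination set: ",
                paste(missing, collapse = ", ")))
  }
  stop_epi <- combinations |>
    filter(.data$accession %in% stoplist) |>
    distinct(.data$side, .data$epitope)
  anti_join(combinations, stop_epi, by = c("side", "epitope"))
}

#' Run the ordered filter pipeline
#'
#' Applies the six detectability filters in the configured order and records
#' a per-stage report of surviving epitopes, proteins and combinations
#' (counting only detectable combinations, and only epitopes/proteins that
#' retain at least one detectable combination).
#'
#' @param combinations a combination tibble from [enumerate_combinations()].
#' @param config a [filter_config()].
#' @return A list of class `txp_filtered` with elements `combinations` (the
#'   surviving tibble; undetectable rows retained with `detectable = FALSE`)
#'   and `report` (tibble `filter`, `n_epitopes`, `n_proteins`,
#'   `n_combinations`, first row `"unfiltered"`).
#' @export
run_filter_pipeline <- function(combinations, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  steps <- config$filter_order
  report <- list(pipeline_counts("unfiltered", combinations))
  x <- combinations
  for (f in steps) {
    x <- switch(f,
      unknown_positions = filter_unknown_positions(x),
      methionine = filter_methionine(x),
      high_abundant_epitope = filter_high_abundant_epitope(x, config$max_epitope_load),
      weight = filter_weight(x, config$delta_min),
      length = filter_length(x, config$min_peptide_len, config$max_peptide_len),
      stoplist = filter_stoplist(x, config$stoplist)
    )
    report <- c(report, list(pipeline_counts(f, x)))
  }
  structure(list(combinations = x, report = bind_rows(report), config = config),
            class = "txp_filtered")
}

pipeline_counts <- function(stage, combinations) {
  d <- filter(combinations, .data$detectable)
  tibble(
    filter = stage,
    n_epitopes = nrow(distinct(d, .data$side, .data$epitope)),
    n_proteins = n_distinct(d$accession),
    n_combinations = nrow(d)
  )
}

#' @export
print.txp_filtered <- function(x, ...) {
  cat("Filtered combination set\n")
  print(x$report)
  invisible(x)
}

#' Read a stop list of high-abundant protein accessions
#'
#' One accession per line; blank lines and `#` comments are ignored.
#'
#' @param path path to the stop-list file.
#' @return character vector of accessions.
#' @export
read_stoplist <- function(path) {
  if (!file.exists(path)) abort(paste0("Stoplist file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
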