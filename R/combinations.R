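#' Enumerate peptide/terminal-epitope combinations
#'
#' For every peptide of a digest, every epitope length `l` not exceeding the
#' peptide length, and every requested terminus, one combination is produced:
#' the quadruple (protein, peptide, terminus side, terminal epitope). The
#' epitope of a combination is the first (`side = "n"`) or last
#' (`side = "c"`) `l` residues of the peptide. A peptide whose length equals
#' `l` contributes the whole peptide as its epitope on either side. The same
#' sequence at opposite termini is two distinct epitopes.
#'
#' Enumeration order is deterministic: input peptide order, then epitope
#' length ascending, then side `n` before `c`.
#'
#' @param digest a digest tibble from [tryptic_digest()] (columns
#'   `accession`, `peptide`, `mass`; other columns are carried along).
#' @param lengths integer vector of epitope lengths; the method is designed
#'   for short termini (3-5 residues), default `c(4, 5)`.
#' @param sides termini to enumerate: subset of `c("n", "c")`.
#' @return A combination tibble: `accession`, `peptide`, `mass`, `length`,
#'   `side`, `epitope`, `detectable` (all `TRUE` initially; the weight filter
#'   may clear it).
#' @examples
#' d <- tryptic_digest(tibble::tibble(accession = "P1", sequence = "AKPLR"))
#' enumerate_combinations(d, lengths = 4, sides = c("n", "c"))
#' @export
enumerate_combinations <- function(digest, lengths = c(4L, 5L), sides = c("n", "c")) {
  if (length(lengths) == 0L || any(lengths < 1L)) {
    abort("`lengths` must be a non-empty set of integers >= 1.")
  }
  sides <- match.arg(sides, c("n", "c"), several.ok = TRUE)
  lengths <- sort(unique(as.integer(lengths)))
  sides <- intersect(c("n", "c"), sides)  # n before c, deduplicated

  base <- digest |>
    select("accession", "peptide", "mass") |>
    mutate(.row = row_number())
  grid <- tidyr::expand_grid(.row = base$.row, length = lengths, side = sides)
  out <- grid |>
    inner_join(base, by = ".row") |>
    filter(nchar(.data$peptide) >= .data$length) |>
    mutate(
      epitope = ifelse(.data$side == "n",
                       substr(.data$peptide, 1L, .data$length),
                       substr(.data$peptide, nchar(.data$peptide) - .data$length + 1L,
                              nchar(.data$peptide))),
      detectable = TRUE
    ) |>
    select("accession", "peptide", "mass", "length", "side", "epitope", "detectable")
  out
}

# Epitope identity is the (side, sequence) pair.
epitope_key <- function(side, epitope) paste(side, epitope, sep = ":")

#' Summarise a combination set per epitope
#'
#' Counts, for each epitope (a `(side, sequence)` pair), its load: the number
#' of combinations it would capture. Undetectable combinations can be
#' excluded.
#'
#' @param combinations a combination tibble.
#' @param detectable_only count only detectable combinations.
#' @return tibble `side`, `epitope`, `n_combinations`, `n_proteins`,
#'   `n_peptides` (distinct peptide species), sorted by decreasing load.
#' @export
epitope_load <- function(combinations, detectable_only = FALSE) {
  x <- if (detectable_only) filter(combinations, .data$detectable) else combinations
  x |>
    group_by(.data$side, .data$epitope) |>
    summarise(
      n_combinations = n(),
      n_proteins = n_distinct(.data$accession),
      n_peptides = n_distinct(.data$peptide),
      .groups = "drop"
    ) |>
    arrange(desc(.data$n_combinations), .data$side, .data$epitope)
}
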