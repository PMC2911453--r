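#' Amino-acid residue mass tables
#'
#' Residue (i.e. dehydrated amino-acid) masses in Dalton, plus the mass of one
#' water molecule, as used by [peptide_mass()]. Monoisotopic masses are the
#' default: the package targets MALDI-TOF read-out, where monoisotopic peaks
#' are the quantity measured. An average-mass table is available for
#' completeness.
#'
#' Selenocysteine (`U`) and pyrrolysine (`O`) carry their standard masses but
#' can be declared mass-less via `unknown`, which is how the ambiguity codes
#' `X`, `B`, `Z` and `J` are always treated: peptides containing them have no
#' computable mass.
#'
#' @param type `"monoisotopic"` (default) or `"average"`.
#' @param unknown additional residue letters to treat as having no computable
#'   mass (on top of `X`, `B`, `Z`, `J`).
#' @return A named numeric vector of residue masses with attribute `water`
#'   (mass of H2O in Da) and class `"mass_table"`.
#' @examples
#' tab <- mass_table()
#' tab[["G"]] + attr(tab, "water") # monoisotopic mass of bare glycine
#' @export
mass_table <- function(type = c("monoisotopic", "average"), unknown = character()) {
  type <- match.arg(type)
  masses <- switch(type,
    monoisotopic = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
      T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
      N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
      E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
      R = 156.10111, Y = 163.06333, W = 186.07931,
      U = 150.95364, O = 237.14773
    ),
    average = c(
      G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
      T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594,
      N = 114.1038, D = 115.0886, Q = 128.1307, K = 128.1741,
      E = 129.1155, M = 131.1926, H = 137.1411, F = 147.1766,
      R = 156.1875, Y = 163.1760, W = 186.2132,
      U = 150.0388, O = 237.3018
    )
  )
  water <- switch(type, monoisotopic = 18.010565, average = 18.01528)
  masses <- masses[setdiff(names(masses), toupper(unknown))]
  structure(masses, water = water, type = type, class = "mass_table")
}

#' Peptide mass from a residue table
#'
#' Sums residue masses and adds one water mass per peptide. Vectorised over
#' `sequence`. A peptide containing any residue absent from the table (the
#' ambiguity codes `X`, `B`, `Z`, `J`, or anything configured as unknown)
#' gets `NA`: its mass is not computable and it cannot be read out by the
#' mass spectrometer.
#'
#' @param sequence character vector of peptide sequences (one-letter code,
#'   upper case).
#' @param table a [mass_table()].
#' @return numeric vector of masses in Da; `NA` where not computable.
#' @examples
#' peptide_mass(c("AYEQLGYR", "HLEILGYR")) # differ by 1.068 Da
#' peptide_mass("AXK") # NA: X has no mass
#' @export
peptide_mass <- function(sequence, table = mass_table()) {
  if (length(sequence) == 0L) return(numeric())
  if (any(is.na(sequence)) || any(!nzchar(sequence))) {
    abort("`sequence` must be non-empty strings.")
  }
  water <- attr(table, "water")
  known <- names(table)
  vapply(strsplit(sequence, "", fixed = TRUE), function(res) {
    if (all(res %in% known)) sum(unclass(table)[res]) + water else NA_real_
  }, numeric(1))
}
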