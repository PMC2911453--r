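#' Complete in-silico tryptic digest
#'
#' Cleaves every protein after lysine (K) or arginine (R) unless the next
#' residue is proline (P), with no missed cleavages: the digest is a
#' partition of each protein into consecutive peptides. N-terminal
#' methionine is not specially removed. Masses are computed with
#' [peptide_mass()]; peptides containing residues without a defined mass
#' (ambiguity codes such as X) get `NA`.
#'
#' @param proteins a proteome tibble with columns `accession` and `sequence`
#'   (see [read_proteome()]), or a single sequence string.
#' @param table residue [mass_table()] used for peptide masses.
#' @return A tibble with one row per peptide: `accession`, `peptide_index`
#'   (1-based, N- to C-terminal), `peptide`, `start`, `end` (1-based
#'   positions in the parent), and `mass` (Da, `NA` if not computable).
#' @examples
#' tryptic_digest(tibble::tibble(accession = "P1", sequence = "MKAKPLR"))
#' @export
tryptic_digest <- function(proteins, table = mass_table()) {
  if (is.character(proteins)) {
    proteins <- tibble(accession = paste0("SEQ", seq_along(proteins)),
                       sequence = proteins)
  }
  check_proteome(proteins)
  pieces <- strsplit(proteins$sequence, "(?<=[KR])(?!P)", perl = TRUE)
  out <- tibble(
    accession = rep(proteins$accession, lengths(pieces)),
    peptide = unlist(pieces, use.names = FALSE)
  )
  out <- out |>
    group_by(.data$accession) |>
    mutate(
      peptide_index = row_number(),
      end = cumsum(nchar(.data$peptide)),
      start = .data$end - nchar(.data$peptide) + 1L
    ) |>
    ungroup() |>
    mutate(mass = peptide_mass(.data$peptide, table)) |>
    select("accession", "peptide_index", "peptide", "start", "end", "mass")
  # restore input protein order (group_by sorts keys)
  out[order(match(out$accession, proteins$accession), out$peptide_index), ]
}
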