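#' Read a proteome from FASTA
#'
#' Parses a (possibly multi-line) amino-acid FASTA file into a tibble of
#' protein records. Accessions are extracted per entry: UniProt-style
#' pipe-delimited headers (`db|ACC|NAME ...`) yield `ACC`; any other header
#' yields its first whitespace-delimited token. Sequences are upper-cased and
#' `*` stop characters are stripped.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `accession` and `sequence`, one row per
#'   entry, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P1|X", "MKAK", ">P2", "ggr"), fa)
#' read_proteome(fa)
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) abort(paste0("FASTA file has no entries: ", path))
  headers <- names(aa)
  seqs <- toupper(gsub("*", "", as.character(aa), fixed = TRUE))
  acc <- vapply(headers, parse_accession, character(1), USE.NAMES = FALSE)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("FASTA entry with empty sequence: ", paste(acc[empty], collapse = ", ")))
  }
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0L) {
    abort(paste0("Duplicate accession(s) in proteome: ", paste(dup, collapse = ", ")))
  }
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad)) {
    abort(paste0("Non-amino-acid characters in sequence of: ",
                 paste(acc[bad], collapse = ", ")))
  }
  tibble(accession = acc, sequence = unname(seqs))
}

# "sp|P12345|NAME description" -> "P12345"; otherwise first token.
parse_accession <- function(header) {
  token <- sub("\\s.*$", "", header)
  parts <- strsplit(token, "|", fixed = TRUE)[[1]]
  acc <- if (length(parts) >= 2L) parts[[2]] else parts[[1]]
  if (!nzchar(acc)) abort(paste0("Cannot parse accession from header: ", header))
  acc
}

#' Write a proteome tibble to FASTA
#'
#' @param proteins tibble with `accession` and `sequence` columns (and an
#'   optional `description` column appended to headers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteins, path) {
  check_proteome(proteins)
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$accession))
  if ("description" %in% names(proteins)) {
    names(aa) <- paste(proteins$accession, proteins$description)
  }
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

check_proteome <- function(proteins) {
  if (!is.data.frame(proteins) || !all(c("accession", "sequence") %in% names(proteins))) {
    abort("`proteins` must be a data frame with columns `accession` and `sequence`.")
  }
  if (anyDuplicated(proteins$accession)) abort("Accessions must be unique.")
  if (any(!nzchar(proteins$sequence))) abort("Sequences must be non-empty.")
  invisible(proteins)
}
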