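`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a cover graph directly from epitope -> protein sets (all C-terminal,
# two peptide species per edge so no epitope is a robinson by accident).
graph_from_sets <- function(sets, side = "c", n_peptides = 2L) {
  rows <- purrr::imap(sets, function(prots, epi) {
    tidyr::expand_grid(accession = prots, k = seq_len(n_peptides)) |>
      dplyr::mutate(side = side, epitope = epi,
                    peptide = paste0(epi, "_", accession, "_", k),
                    mass = NA_real_, detectable = TRUE)
  })
  build_cover_graph(dplyr::bind_rows(rows))
}

# e1 dominates: covers everything the others cover
star_graph <- function() {
  graph_from_sets(list(e1 = c("P1", "P2", "P3"), e2 = "P1", e3 = "P2"))
}

# Classic greedy trap: the size-4 epitope looks best but forces a 3-set
# cover; the two disjoint size-3 epitopes are the optimum.
pathological_graph <- function() {
  graph_from_sets(list(
    big = c("P1", "P2", "P3", "P4"),
    odd = c("P1", "P3", "P5"),
    even = c("P2", "P4", "P6")
  ))
}

# Redundancy-rewarding instance: covering P5/P6 via the overlapping epitopes
# multicovers four proteins, covering them via the disjoint one multicovers
# none.
redundancy_graph <- function() {
  graph_from_sets(list(
    base = c("P1", "P2", "P3", "P4"),
    overlap = c("P1", "P2", "P3", "P5"),
    disjoint = c("P5", "P6")
  ))
}

harmonic <- function(n) sum(1 / seq_len(max(n, 1L)))

# A small FASTA on disk; returns the path
write_tmp_fasta <- function(lines, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = envir)
  writeLines(lines, path)
  path
}

# tiny proteome exercising every digest rule
toy_proteome <- function() {
  tibble::tibble(
    accession = c("P1", "P2", "P3"),
    sequence = c("MKAKPLR", "GGR", "AKRK")
  )
}
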