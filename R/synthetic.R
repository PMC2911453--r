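#' Seeded synthetic proteome with planted structure
#'
#' Generates a proteome whose complete tryptic digest contains structure
#' planted by construction, so every pipeline stage can be exercised and
#' verified without downloading a real proteome:
#'
#' * `shared_groups` — groups of proteins sharing a planted terminal epitope
#'   (each member carries one tryptic peptide ending/starting with it);
#' * `near_isobaric_pairs` — pairs of distinct peptides sharing a planted
#'   C-terminal epitope whose monoisotopic masses differ by 1.068 Da
#'   (an AYEQ/HLEI N-terminal swap), i.e. indistinguishable at a 2 Da
#'   resolution but separable at 1 Da;
#' * `abundant_epitope` — one epitope planted onto `load` distinct peptides,
#'   for exercising the high-abundant-epitope filter.
#'
#' Filler peptides avoid K, R, M and X internally (terminating in K/R), so
#' planted structure is not corrupted by accidental cleavage sites or filter
#' hits, and filler peptides are rejected if they accidentally carry a
#' planted terminal epitope. Within each planted shared group, fillers are
#' re-drawn until member peptide masses are pairwise more than 2.5 Da apart,
#' so the weight filter fires only on the planted near-isobaric pairs.
#' Generation is a pure function of the arguments and `seed`.
#'
#' @param n_proteins number of proteins.
#' @param protein_length_range target protein length range in residues
#'   (filler peptides are appended until the target is reached).
#' @param shared_groups list of planted shared-terminus groups, each a list
#'   with `epitope` (4-5 residues; C-terminal epitopes must end in K or R,
#'   N-terminal ones must not start with P; no internal K/R, no M/X),
#'   `side` (`"n"` or `"c"`), and `n` (group size, at most `n_proteins`).
#' @param near_isobaric_pairs number of planted near-isobaric peptide pairs.
#' @param abundant_epitope optional list with `epitope` (C-terminal, same
#'   rules) and `load` (number of distinct planted peptides carrying it).
#' @param seed integer random seed.
#' @return A proteome tibble (`accession`, `sequence`, `description`) with
#'   attribute `manifest`: a list recording the planted truths (`groups`,
#'   `isobaric`, `abundant` tibbles of member accessions and peptides, plus
#'   the call parameters). Retrieve it with [synthetic_manifest()].
#' @examples
#' prot <- synthetic_proteome(n_proteins = 6,
#'   shared_groups = list(list(epitope = "LGYR", side = "c", n = 3)), seed = 1)
#' synthetic_manifest(prot)$groups
#' @export
synthetic_proteome <- function(n_proteins = 20L,
                               protein_length_range = c(120L, 300L),
                               shared_groups = list(),
                               near_isobaric_pairs = 0L,
                               abundant_epitope = NULL,
                               seed = 1L) {
  stopifnot(n_proteins >= 1L, length(protein_length_range) == 2L,
            protein_length_range[1] <= protein_length_range[2])
  for (g in shared_groups) {
    validate_planted_epitope(g$epitope, g$side)
    if (g$n > n_proteins) abort("Planted group size exceeds `n_proteins`.")
  }
  if (!is.null(abundant_epitope)) {
    validate_planted_epitope(abundant_epitope$epitope, "c")
  }
  planted_c <- c(vapply(Filter(function(g) g$side == "c", shared_groups),
                        `[[`, character(1), "epitope"),
                 if (!is.null(abundant_epitope)) abundant_epitope$epitope)
  planted_n <- vapply(Filter(function(g) g$side == "n", shared_groups),
                      `[[`, character(1), "epitope")

  withr::with_seed(seed, {
    acc <- sprintf("SYN%04d", seq_len(n_proteins))
    # per-protein peptide lists, grown from planted material then filler
    peps <- replicate(n_proteins, character(), simplify = FALSE)
    roles <- replicate(n_proteins, character(), simplify = FALSE)

    groups <- list()
    for (g in shared_groups) {
      members <- sample.int(n_proteins, g$n)
      member_peps <- plant_group_peptides(g$epitope, g$side, g$n, planted_c, planted_n)
      for (k in seq_along(members)) {
        i <- members[k]
        peps[[i]] <- c(peps[[i]], member_peps[k])
        roles[[i]] <- c(roles[[i]], paste0("group:", g$side, ":", g$epitope))
      }
      groups <- c(groups, list(tibble(
        epitope = g$epitope, side = g$side,
        accession = acc[members], peptide = member_peps
      )))
    }

    isobaric <- list()
    if (near_isobaric_pairs > 0L) {
      for (k in seq_len(near_isobaric_pairs)) {
        epi <- random_clean_epitope(4L, terminal = TRUE, avoid = c(planted_c, planted_n))
        planted_c <- c(planted_c, epi)
        mid <- filler_run(4L)
        pair <- paste0(c("AYEQ", "HLEI"), mid, epi)
        members <- sample.int(n_proteins, 2L)
        for (j in 1:2) {
          i <- members[j]
          peps[[i]] <- c(peps[[i]], pair[j])
          roles[[i]] <- c(roles[[i]], paste0("isobaric:", k))
        }
        pair_masses <- peptide_mass(pair)
        isobaric <- c(isobaric, list(tibble(
          pair = k, epitope = epi, side = "c",
          accession = acc[members], peptide = !!pair, mass = pair_masses
        )))
      }
    }

    abundant <- NULL
    if (!is.null(abundant_epitope)) {
      epi <- abundant_epitope$epitope
      load <- abundant_epitope$load
      carriers <- unique_filler_prefixes(load, 6L:12L)
      carrier_peps <- paste0(carriers, epi)
      hosts <- rep_len(seq_len(n_proteins), load)
      for (j in seq_len(load)) {
        i <- hosts[j]
        peps[[i]] <- c(peps[[i]], carrier_peps[j])
        roles[[i]] <- c(roles[[i]], paste0("abundant:", epi))
      }
      abundant <- tibble(epitope = epi, side = "c", load = load,
                         accession = acc[hosts], peptide = carrier_peps)
    }

    # pad every protein with clean filler peptides up to its target length
    target <- sample(protein_length_range[1]:protein_length_range[2],
                     n_proteins, replace = TRUE)
    for (i in seq_len(n_proteins)) {
      while (sum(nchar(peps[[i]])) < target[i]) {
        peps[[i]] <- c(peps[[i]], clean_filler_peptide(planted_c, planted_n))
      }
      # planted peptides sit at random positions within the protein
      ord <- sample.int(length(peps[[i]]))
      peps[[i]] <- peps[[i]][ord]
    }
    sequences <- vapply(peps, paste, character(1), collapse = "")
    descr <- vapply(roles, function(r) {
      if (length(r) == 0L) "role=filler" else paste0("role=", paste(r, collapse = ","))
    }, character(1))

    out <- tibble(accession = acc, sequence = sequences, description = descr)
    attr(out, "manifest") <- list(
      seed = seed,
      n_proteins = n_proteins,
      groups = if (length(groups) > 0L) bind_rows(groups) else
        tibble(epitope = character(), side = character(),
               accession = character(), peptide = character()),
      isobaric = if (length(isobaric) > 0L) bind_rows(isobaric) else
        tibble(pair = integer(), epitope = character(), side = character(),
               accession = character(), peptide = character(), mass = numeric()),
      abundant = abundant
    )
    out
  })
}

#' @rdname synthetic_proteome
#' @param proteins a tibble produced by `synthetic_proteome()`.
#' @export
synthetic_manifest <- function(proteins) {
  m <- attr(proteins, "manifest")
  if (is.null(m)) abort("Not a synthetic proteome: no manifest attribute.")
  m
}

# residues allowed in filler: no K/R (cleavage), no M (epitope filter),
# no ambiguity codes; P excluded so planted termini stay cleavable anywhere
filler_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "N",
                     "Q", "S", "T", "V", "W", "Y")

filler_run <- function(n) {
  paste(sample(filler_alphabet, n, replace = TRUE), collapse = "")
}

# random C-terminal epitope (ends in K/R) distinct from, and not
# suffix-nested with, the already-planted ones
random_clean_epitope <- function(len, terminal = TRUE, avoid = character()) {
  repeat {
    body <- filler_run(len - if (terminal) 1L else 0L)
    epi <- if (terminal) paste0(body, sample(c("K", "R"), 1L)) else body
    nested <- any(vapply(avoid, function(e) {
      endsWith(epi, e) || endsWith(e, epi)
    }, logical(1)))
    if (!nested) return(epi)
  }
}

validate_planted_epitope <- function(epitope, side) {
  if (is.null(epitope) || !nzchar(epitope) || nchar(epitope) < 3L) {
    abort("Planted epitopes need at least 3 residues.")
  }
  res <- strsplit(epitope, "")[[1]]
  n <- length(res)
  if (any(res %in% c("M", "X", "B", "Z", "J", "U", "O"))) {
    abort(paste0("Planted epitope ", epitope,
                 " contains methionine or an ambiguity code; it would be filtered."))
  }
  internal <- if (side == "c") res[-n] else res
  if (any(internal %in% c("K", "R"))) {
    abort(paste0("Planted epitope ", epitope, " has an internal cleavage site ",
                 "(K/R); the digest would split it."))
  }
  if (side == "c" && !res[n] %in% c("K", "R")) {
    abort(paste0("C-terminal planted epitope ", epitope, " must end in K or R."))
  }
  if (side == "n" && res[1] == "P") {
    abort(paste0("N-terminal planted epitope ", epitope, " must not start with P: ",
                 "proline blocks the preceding cleavage."))
  }
  invisible(epitope)
}

# a filler tryptic peptide (8-20 residues incl. terminal K/R) that does not
# accidentally carry a planted terminal epitope
clean_filler_peptide <- function(planted_c, planted_n) {
  repeat {
    body <- filler_run(sample(7:19, 1L))
    pep <- paste0(body, sample(c("K", "R"), 1L))
    hit_c <- any(vapply(planted_c, function(e) endsWith(pep, e), logical(1)))
    hit_n <- any(vapply(planted_n, function(e) startsWith(pep, e), logical(1)))
    if (!hit_c && !hit_n) return(pep)
  }
}

unique_filler_prefixes <- function(n, len_choices) {
  pick_len <- function() {
    if (length(len_choices) == 1L) len_choices else sample(len_choices, 1L)
  }
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, filler_run(pick_len())))
  }
  out[seq_len(n)]
}

# peptides for one shared-terminus group: distinct sequences, pairwise mass
# gaps > 2.5 Da so the planted group never trips the weight filter
plant_group_peptides <- function(epitope, side, n, planted_c, planted_n) {
  out <- character(0)
  masses <- numeric(0)
  while (length(out) < n) {
    fill <- filler_run(sample(5:12, 1L))
    pep <- if (side == "c") paste0(fill, epitope)
           else paste0(epitope, fill, sample(c("K", "R"), 1L))
    if (pep %in% out) next
    m <- peptide_mass(pep)
    if (length(masses) > 0L && min(abs(masses - m)) <= 2.5) next
    hit_c <- any(vapply(setdiff(planted_c, epitope),
                        function(e) endsWith(pep, e), logical(1)))
    hit_n <- any(vapply(setdiff(planted_n, epitope),
                        function(e) startsWith(pep, e), logical(1)))
    if (hit_c || hit_n) next
    out <- c(out, pep)
    masses <- c(masses, m)
  }
  out
}

#' Random feasible cover-graph instance
#'
#' Generates a random bipartite protein-epitope graph for solver testing:
#' each protein-epitope pair is an edge with probability `density`, and any
#' protein left isolated is repaired with one random edge, so the instance
#' is always fully coverable. Deterministic per seed.
#'
#' @param n_proteins,n_epitopes vertex counts (`n_epitopes >= 1`).
#' @param density edge probability in (0, 1].
#' @param seed integer random seed.
#' @return a `cover_graph`.
#' @export
random_cover_graph <- function(n_proteins, n_epitopes, density = 0.3, seed = 1L) {
  if (n_epitopes < 1L) abort("`n_epitopes` must be >= 1.")
  if (density <= 0 || density > 1) abort("`density` must be in (0, 1].")
  withr::with_seed(seed, {
    prot <- sprintf("T%03d", seq_len(n_proteins))
    epi <- unique_filler_prefixes(n_epitopes, 3L)
    epi <- paste0(epi, "R") # plausible C-terminal 4-mers
    hit <- matrix(runif(n_proteins * n_epitopes) < density,
                  nrow = n_proteins, ncol = n_epitopes)
    for (i in seq_len(n_proteins)) {
      if (!any(hit[i, ])) hit[i, sample.int(n_epitopes, 1L)] <- TRUE
    }
    idx <- which(hit, arr.ind = TRUE)
    edges <- tibble(
      side = "c",
      epitope = epi[idx[, "col"]],
      accession = prot[idx[, "row"]],
      peptides = map2(epi[idx[, "col"]], prot[idx[, "row"]],
                      function(e, p) paste0("PEP_", p, "_", e)),
      n_peptides = 1L
    ) |>
      arrange(.data$side, .data$epitope, .data$accession)
    new_cover_graph(edges)
  })
}
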