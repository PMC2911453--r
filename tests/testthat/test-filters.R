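combos_from_peptides <- function(peptides, accession = NULL, lengths = 4L,
                                 sides = "c") {
  if (is.null(accession)) accession <- paste0("P", seq_along(peptides))
  d <- tibble::tibble(
    accession = accession,
    peptide = peptides,
    mass = peptide_mass(peptides)
  )
  enumerate_combinations(d, lengths = lengths, sides = sides)
}

test_that("unknown-positions filter removes peptides without computable mass", {
  co <- combos_from_peptides(c("AXLLGYR", "AYEQLGYR"), lengths = 4)
  out <- filter_unknown_positions(co)
  expect_equal(out$peptide, "AYEQLGYR")
  clean <- combos_from_peptides("AYEQLGYR")
  expect_identical(filter_unknown_positions(clean), clean)
})

test_that("methionine filter targets the epitope, not the peptide", {
  co <- combos_from_peptides(c("MAYEQLGYR", "AAAAMGYR"), lengths = 4, sides = "c")
  out <- filter_methionine(co)
  # M inside the peptide but outside the C-terminal epitope LGYR: kept
  expect_true("MAYEQLGYR" %in% out$peptide)
  # epitope "AMGYR"? no: epitope is MGYR -> removed
  expect_false("AAAAMGYR" %in% out$peptide)
})

test_that("high-abundant-epitope filter is strict at the threshold", {
  # 1000 distinct prefixes, deterministically
  alpha <- c("A", "G", "S", "T", "V", "L", "E", "F", "H", "I")
  grid <- expand.grid(alpha, alpha, alpha, stringsAsFactors = FALSE)
  prefixes <- do.call(paste0, grid)
  peps <- paste0(prefixes[1:601], "LGYR")
  co <- combos_from_peptides(peps, lengths = 4, sides = "c")
  expect_equal(nrow(filter_high_abundant_epitope(co, max_load = 600L)), 0L)
  co600 <- combos_from_peptides(peps[1:600], lengths = 4, sides = "c")
  expect_equal(nrow(filter_high_abundant_epitope(co600, max_load = 600L)), 600L)
  # max_load 1 on singleton epitopes is the identity
  singles <- combos_from_peptides(c("AAAEFGYK", "CCDEFGHR"), lengths = 4, sides = "c")
  expect_identical(filter_high_abundant_epitope(singles, max_load = 1L), singles)
})

test_that("weight filter marks near-isobaric pairs undetectable, both parties", {
  co <- combos_from_peptides(c("AYEQLGYR", "HLEILGYR"), lengths = 4, sides = "c")
  out2 <- filter_weight(co, delta_min = 2.0)
  expect_equal(out2$detectable, c(FALSE, FALSE)) # delta = 1.068 < 2
  out1 <- filter_weight(co, delta_min = 1.0)
  expect_equal(out1$detectable, c(TRUE, TRUE)) # 1.068 >= 1
})

test_that("identical peptide sequences from two proteins are one species", {
  co <- combos_from_peptides(c("AYEQLGYR", "AYEQLGYR"), accession = c("A", "B"),
                             lengths = 4, sides = "c")
  out <- filter_weight(co, delta_min = 2.0)
  expect_true(all(out$detectable))
})

test_that("length filter bounds are inclusive", {
  peps <- c("AAEFGYK",                         # 7: below range
            "AAEFGHYK",                        # 8: inclusive lower bound
            paste0(strrep("A", 26), "GHYK"),   # 30: inclusive upper bound
            paste0(strrep("A", 27), "GHYK"))   # 31: above range
  co <- combos_from_peptides(peps, lengths = 4, sides = "c")
  out <- filter_length(co, 8L, 30L)
  expect_setequal(nchar(out$peptide), c(8L, 30L))
})

test_that("stoplist removes the abundant protein's epitopes everywhere", {
  co <- combos_from_peptides(c("AAAEFAGFA", "CCDEFAGFA", "GGHILMNQK"),
                             accession = c("ACTB", "TGT1", "TGT2"),
                             lengths = 4, sides = "c")
  out <- filter_stoplist(co, stoplist = "ACTB")
  # epitope AGFA occurs on ACTB and TGT1: both removed; TGT2 untouched
  expect_equal(out$accession, "TGT2")
  expect_identical(filter_stoplist(co, character()), co)
  expect_warning(filter_stoplist(co, c("ACTB", "NOPE")), "NOPE")
})

test_that("pipeline enforces the hard filter ordering upfront", {
  expect_error(filter_config(filter_order = c("weight", "high_abundant_epitope",
                                              "length", "unknown_positions",
                                              "methionine", "stoplist")),
               "must precede")
  expect_error(filter_config(filter_order = c("high_abundant_epitope", "length",
                                              "weight", "unknown_positions",
                                              "methionine", "stoplist")),
               "must precede")
  # order-free filters may move around
  expect_s3_class(filter_config(filter_order = c("stoplist", "methionine",
                                                 "high_abundant_epitope", "weight",
                                                 "length", "unknown_positions")),
                  "filter_config")
})

test_that("pipeline report is monotonically non-increasing", {
  prot <- synthetic_proteome(n_proteins = 8, near_isobaric_pairs = 2,
                             abundant_epitope = list(epitope = "AGFR", load = 15),
                             seed = 5)
  co <- enumerate_combinations(tryptic_digest(prot), lengths = 4L)
  fr <- run_filter_pipeline(co, filter_config(max_epitope_load = 10))
  expect_true(all(diff(fr$report$n_combinations) <= 0))
  expect_true(all(diff(fr$report$n_epitopes) <= 0))
  expect_true(all(diff(fr$report$n_proteins) <= 0))
  expect_equal(fr$report$filter[1], "unfiltered")
})

test_that("order-free filters commute", {
  prot <- synthetic_proteome(n_proteins = 6, seed = 9)
  co <- enumerate_combinations(tryptic_digest(prot), lengths = 4L)
  # plant an X-peptide and a stoplisted protein artificially
  co$peptide[1] <- sub(".", "X", co$peptide[1])
  co$mass[1] <- NA_real_
  stop_acc <- co$accession[5]
  perm1 <- filter_stoplist(filter_methionine(filter_unknown_positions(co)), stop_acc)
  perm2 <- filter_unknown_positions(filter_stoplist(filter_methionine(co), stop_acc))
  perm3 <- filter_methionine(filter_unknown_positions(filter_stoplist(co, stop_acc)))
  key <- function(x) dplyr::arrange(x, accession, peptide, length, side)
  expect_equal(key(perm1), key(perm2))
  expect_equal(key(perm1), key(perm3))
})

test_that("permissive pipeline is the identity on clean input", {
  prot <- synthetic_proteome(n_proteins = 5, seed = 13)
  co <- enumerate_combinations(tryptic_digest(prot), lengths = 4L)
  cfg <- filter_config(max_epitope_load = .Machine$integer.max,
                       delta_min = 1e-9, min_peptide_len = 1L,
                       max_peptide_len = 10000L)
  fr <- run_filter_pipeline(co, cfg)
  expect_equal(nrow(fr$combinations), nrow(co))
  expect_true(all(fr$combinations$detectable))
})

test_that("empty combination set yields empty output and a zero report", {
  co <- combos_from_peptides("AYEQLGYR")[0, ]
  fr <- run_filter_pipeline(co, filter_config())
  expect_equal(nrow(fr$combinations), 0L)
  expect_true(all(fr$report$n_combinations == 0L))
})

test_that("stop lists parse with comments and blanks", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# abundant proteins", "ACTB", "", "TUBB # beta tubulin"), f)
  expect_equal(read_stoplist(f), c("ACTB", "TUBB"))
})
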