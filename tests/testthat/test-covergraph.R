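test_that("graph connects proteins and epitopes through detectable combinations", {
  co <- tibble::tibble(
    accession = c("P1", "P2", "P2"),
    peptide = c("AAAEFLGYR", "CCDEFLGYR", "GGHILNQEK"),
    mass = peptide_mass(c("AAAEFLGYR", "CCDEFLGYR", "GGHILNQEK")),
    length = 4L, side = "c",
    epitope = c("LGYR", "LGYR", "NQEK"),
    detectable = c(TRUE, TRUE, FALSE)
  )
  g <- build_cover_graph(co)
  expect_equal(sort(g$proteins), c("P1", "P2"))
  expect_equal(nrow(g$edges), 2L) # undetectable NQEK edge absent
  expect_equal(sort(g$edges$accession), c("P1", "P2"))
})

test_that("target restriction keeps only target edges and reports uncoverable", {
  co <- tibble::tibble(
    accession = c("P1", "P2"), peptide = c("AAAEFLGYR", "CCDEFLGYR"),
    mass = 1:2 + 0, length = 4L, side = "c", epitope = "LGYR", detectable = TRUE
  )
  expect_warning(g <- build_cover_graph(co, targets = c("P1", "P3")), "P3")
  expect_equal(g$proteins, "P1")
  expect_equal(g$uncoverable, "P3")
  expect_error(build_cover_graph(co, targets = "P9"), "Uncoverable")
})

test_that("robinson epitopes are removed, multi-peptide epitopes kept", {
  co <- tibble::tibble(
    accession = c("P1", "P1", "P1", "P2"),
    peptide = c("AAAEFLGYR", "CCDEFLGYR", "GGHILNQEK", "DDEFHNQEK"),
    mass = 1:4 + 0, length = 4L, side = "c",
    epitope = c("LGYR", "LGYR", "NQEK", "NQEK"),
    detectable = TRUE
  )
  # add a true robinson: one peptide, one protein, P1 has other cover
  co <- dplyr::bind_rows(co, tibble::tibble(
    accession = "P1", peptide = "EEFFGHIK", mass = 5,
    length = 4L, side = "c", epitope = "GHIK", detectable = TRUE
  ))
  g <- build_cover_graph(co)
  g2 <- remove_robinson(g)
  keys <- paste(g2$epitopes$side, g2$epitopes$epitope)
  expect_false("c GHIK" %in% keys) # robinson removed
  expect_true("c LGYR" %in% keys)  # two peptides of one protein: kept
  expect_true("c NQEK" %in% keys)  # two proteins: kept
})

test_that("robinson removal never orphans a protein (guard)", {
  # P3's only cover is a robinson epitope
  co <- tibble::tibble(
    accession = c("P1", "P2", "P3"),
    peptide = c("AAAEFLGYR", "CCDEFLGYR", "EEFFGHIK"),
    mass = 1:3 + 0, length = 4L, side = "c",
    epitope = c("LGYR", "LGYR", "GHIK"), detectable = TRUE
  )
  g <- build_cover_graph(co)
  expect_message(g2 <- remove_robinson(g), "sole cover")
  expect_equal(sort(g2$proteins), c("P1", "P2", "P3"))

  # property: on random instances, coverable stays coverable
  for (s in 1:10) {
    rg <- random_cover_graph(10, 8, density = 0.15, seed = s)
    rg2 <- suppressMessages(remove_robinson(rg))
    expect_setequal(rg2$proteins, rg$proteins)
    expect_true(all(rg$proteins %in% rg2$edges$accession))
  }
})

test_that("solution scoring matches the coverage-score definition", {
  # 133 proteins partitioned over 55 epitopes: score = 55/133 ~ 41.4%
  prots <- sprintf("P%03d", 1:133)
  sets <- split(prots, rep(1:55, length.out = 133))
  names(sets) <- sprintf("E%02dR", 1:55)
  g <- graph_from_sets(sets)
  sol <- score_solution(g, g$epitopes)
  expect_equal(sol$coverage_score, 55 / 133, tolerance = 1e-12)
  expect_equal(round(sol$coverage_score, 3), 0.414)
  expect_equal(length(sol$uncovered), 0L)

  empty <- score_solution(g, g$epitopes[0, ])
  expect_equal(empty$coverage_score, 0)
  expect_equal(length(empty$uncovered), 133L)
  expect_error(score_solution(g, tibble::tibble(side = "c", epitope = "ZZZZ")),
               "not in graph")
})

test_that("single- and multi-covered counts are consistent", {
  g <- redundancy_graph()
  sol <- score_solution(g, g$epitopes)
  expect_equal(sol$n_single_covered + sol$n_multi_covered + length(sol$uncovered),
               length(g$proteins))
  expect_equal(sol$n_multi_covered,
               sum(sol$cover_count$n_cover >= 2L))
})

test_that("elongation pairs are surfaced", {
  sel <- tibble::tibble(side = c("c", "c", "n"),
                        epitope = c("IER", "EIER", "IER"))
  ep <- elongation_pairs(sel)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$shorter, "IER")
  expect_equal(ep$longer, "EIER")
  expect_equal(ep$side, "c")
  expect_equal(nrow(elongation_pairs(sel[c(1, 3), ])), 0L)
})
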