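test_that("greedy picks the dominant epitope on a star instance", {
  res <- greedy_cover(star_graph())
  expect_equal(res$selected$epitope, "e1")
  expect_equal(res$objective, 1)
  expect_equal(res$status, "optimal")
})

test_that("greedy falls into the classic trap, exact solver does not", {
  g <- pathological_graph()
  expect_equal(greedy_cover(g)$objective, 3)
  expect_equal(ilp_cover(g)$objective, 2)
  expect_equal(brute_force_cover(g, "ip")$objective, 2)
})

test_that("exact solvers agree with the brute-force oracle on random instances", {
  for (s in 1:15) {
    rg <- random_cover_graph(n_proteins = 5 + (s %% 8), n_epitopes = 5 + (s %% 6),
                             density = 0.2 + 0.03 * (s %% 5), seed = s)
    expect_equal(ilp_cover(rg)$objective, brute_force_cover(rg, "ip")$objective)
    mc <- ilp_multicover(rg)$objective
    expect_equal(mc, brute_force_cover(rg, "ip_mc")$objective)
    expect_equal(ilp_max_multicover(rg, cost_max = mc)$objective,
                 brute_force_cover(rg, "ip_mmc", cost_max = mc)$objective)
  }
})

test_that("greedy respects the harmonic approximation bound", {
  for (s in 1:20) {
    rg <- random_cover_graph(n_proteins = 6 + (s %% 10), n_epitopes = 4 + (s %% 8),
                             density = 0.25, seed = 100 + s)
    gsize <- greedy_cover(rg)$objective
    opt <- brute_force_cover(rg, "ip")$objective
    idx <- txpcover:::graph_index(rg)
    n_max <- max(lengths(idx$adj))
    expect_lte(gsize, harmonic(n_max) * opt)
  }
})

test_that("multicover greedy reduces to plain greedy when s_mcov = 0", {
  for (s in 1:8) {
    rg <- random_cover_graph(10, 9, density = 0.3, seed = 200 + s)
    expect_identical(greedy_multicover(rg, s_cov = 1, s_mcov = 0)$selected,
                     greedy_cover(rg)$selected)
  }
})

test_that("redundancy-weighted greedy prefers the re-covering epitope", {
  # after 'base' is taken, 'overlap' re-covers 3 proteins but adds only P5;
  # 'disjoint' adds P5+P6 with no re-cover
  g <- redundancy_graph()
  heavy_mcov <- greedy_multicover(g, s_cov = 1, s_mcov = 10)
  expect_equal(heavy_mcov$selected$epitope[1:2], c("base", "overlap"))
  heavy_cov <- greedy_multicover(g, s_cov = 100, s_mcov = 1)
  expect_equal(heavy_cov$selected$epitope[1:2], c("base", "disjoint"))
  # hand-evaluated score table at iteration 2 (covered = {P1..P4}):
  #   overlap: new 1, re 3 -> s_cov + 3 s_mcov;  disjoint: new 2 -> 2 s_cov
  expect_gt(1 + 3 * 10, 2 * 1)    # mcov-heavy picks overlap
  expect_gt(2 * 100, 100 + 3 * 1) # cov-heavy picks disjoint
})

test_that("every added multicover-greedy epitope covers a new protein", {
  for (s in 1:5) {
    rg <- random_cover_graph(12, 10, density = 0.35, seed = 300 + s)
    res <- greedy_multicover(rg, s_cov = 1, s_mcov = 50)
    expect_lte(nrow(res$selected), length(rg$proteins))
    expect_equal(length(res$solution$uncovered), 0L)
  }
})

test_that("enforced multicover doubles where possible, degree-1 exempt", {
  # P1 coverable twice: both epitopes forced
  g <- graph_from_sets(list(e1 = "P1", e2 = "P1"))
  expect_equal(ilp_multicover(g)$objective, 2)
  # degree-1 protein only needs single cover
  g2 <- graph_from_sets(list(e1 = c("P1", "P2"), e2 = "P1"))
  r2 <- ilp_multicover(g2)
  expect_equal(r2$objective, 2)
  expect_equal(length(r2$solution$uncovered), 0L)
  # multicover optimum >= cover optimum always
  for (s in 1:8) {
    rg <- random_cover_graph(10, 8, density = 0.3, seed = 400 + s)
    expect_gte(ilp_multicover(rg)$objective, ilp_cover(rg)$objective)
  }
})

test_that("budgeted max-multicover respects its bounds and is monotone", {
  for (s in 1:5) {
    rg <- random_cover_graph(9, 8, density = 0.35, seed = 500 + s)
    lb <- ilp_cover(rg)$objective
    ub <- ilp_multicover(rg)$objective
    objs <- vapply(lb:ub, function(k) ilp_max_multicover(rg, cost_max = k)$objective,
                   numeric(1))
    expect_true(all(diff(objs) >= 0))
    deg <- table(rg$edges$accession)
    expect_equal(objs[length(objs)], sum(deg >= 2))
  }
})

test_that("infeasible budgets are refused with the bound named", {
  g <- pathological_graph()
  res <- ilp_max_multicover(g, cost_max = 1)
  expect_equal(res$status, "infeasible")
  expect_match(res$log, "minimum cover size 2")
})

test_that("brute force guards against blow-up and handles empty input", {
  rg <- random_cover_graph(5, 25, density = 0.5, seed = 1)
  expect_error(brute_force_cover(rg, "ip"), "refuses")
  empty <- graph_from_sets(list(e1 = "P1"))
  empty$edges <- empty$edges[0, ]
  empty <- txpcover:::new_cover_graph(empty$edges)
  res <- brute_force_cover(empty, "ip")
  expect_equal(res$objective, 0)
  expect_equal(nrow(res$selected), 0L)
})

test_that("solver outputs satisfy the full-cover contract independently", {
  for (s in 1:6) {
    rg <- random_cover_graph(11, 9, density = 0.3, seed = 600 + s)
    for (m in c("greedy", "greedy-mc", "ip", "ip-mc")) {
      res <- solve_cover(rg, method = m)
      sol <- score_solution(rg, res$selected) # re-score independently
      expect_equal(length(sol$uncovered), 0L)
    }
  }
})

test_that("tidy and glance summarise solve results", {
  res <- greedy_cover(star_graph())
  td <- tidy(res)
  expect_equal(td$epitope, "e1")
  expect_equal(td$n_proteins, 3L)
  gl <- glance(res)
  expect_equal(gl$n_selected, 1L)
  expect_equal(gl$n_uncovered, 0L)
  expect_equal(gl$coverage_score, 1 / 3)
})
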