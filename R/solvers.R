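#' Epitope-selection solvers
#'
#' Five procedures select a set of epitopes from a cover graph:
#'
#' * [greedy_cover()] — classical greedy set cover: repeatedly pick the
#'   epitope covering the most still-uncovered proteins. Approximation
#'   ratio H(n), n = largest epitope coverage.
#' * [greedy_multicover()] — greedy with a combined score
#'   `s_cov * (newly covered) + s_mcov * (re-covered)`; only epitopes
#'   covering at least one new protein are eligible, so it terminates with
#'   at most one epitope per protein.
#' * [ilp_cover()] — exact minimum set cover as a binary program: minimise
#'   the number of selected epitopes subject to every protein being covered
#'   at least once. Solved by the package's branch-and-bound engine.
#' * [ilp_multicover()] — enforced multicover: every protein that *can* be
#'   covered twice must be (degree-1 proteins need only single cover).
#' * [ilp_max_multicover()] — budgeted maximum multicover: maximise the
#'   number of at-least-twice-covered proteins over all full covers using at
#'   most `cost_max` epitopes. A binary indicator per protein is linked to
#'   its coverage (indicator = 1 forces two covering epitopes).
#' * [brute_force_cover()] — exhaustive subset enumeration, the independent
#'   exact oracle for small instances.
#'
#' Ties in both greedy variants are broken deterministically: highest score,
#' then larger new coverage, then lexicographic (side, sequence).
#'
#' @name solvers
NULL

# ---- internal indexed view of a cover graph -------------------------------

graph_index <- function(graph) {
  stopifnot(inherits(graph, "cover_graph"))
  epi <- arrange(graph$epitopes, .data$side, .data$epitope)
  proteins <- graph$proteins
  e <- graph$edges |>
    mutate(a = match(epitope_key(.data$side, .data$epitope),
                     epitope_key(epi$side, epi$epitope)),
           p = match(.data$accession, proteins))
  adj <- vector("list", nrow(epi))
  sp <- split(e$p, e$a)
  adj[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
  adj[vapply(adj, is.null, logical(1))] <- list(integer())
  list(epi = epi, proteins = proteins, adj = adj,
       deg = tabulate(e$p, nbins = length(proteins)))
}

new_solve_result <- function(variant, graph, idx, chosen, objective, status,
                             log = character()) {
  selected <- as_tibble(idx$epi[chosen, , drop = FALSE])
  sol <- if (length(graph$proteins) > 0L) score_solution(graph, selected) else NULL
  hits <- semi_join(graph$edges, selected, by = c("side", "epitope"))
  structure(list(
    variant = variant,
    selected = selected,
    objective = objective,
    status = status,
    solution = sol,
    hits = hits,
    log = log
  ), class = "txp_solve_result")
}

#' @export
print.txp_solve_result <- function(x, ...) {
  cat("<txp_solve_result> variant = ", x$variant,
      ", status = ", x$status,
      ", objective = ", x$objective,
      ", |L| = ", nrow(x$selected), "\n", sep = "")
  if (!is.null(x$solution)) print(x$solution)
  invisible(x)
}

check_feasible <- function(idx, variant) {
  bad <- which(idx$deg == 0L)
  if (length(bad) > 0L) {
    return(paste0("Uncoverable protein(s): ",
                  paste(idx$proteins[bad], collapse = ", ")))
  }
  NULL
}

# ---- greedy ----------------------------------------------------------------

greedy_engine <- function(graph, s_cov, s_mcov) {
  idx <- graph_index(graph)
  nP <- length(idx$proteins)
  if (nP == 0L) return(new_solve_result("greedy", graph, idx, integer(), 0L, "optimal"))
  msg <- check_feasible(idx)
  if (!is.null(msg)) {
    return(new_solve_result("greedy", graph, idx, integer(), NA_real_, "infeasible", msg))
  }
  covered <- rep(FALSE, nP)
  chosen <- integer()
  in_l <- rep(FALSE, length(idx$adj))
  while (!all(covered)) {
    best <- 0L; best_score <- -Inf; best_new <- -1L
    for (a in seq_along(idx$adj)) {
      if (in_l[a]) next
      padj <- idx$adj[[a]]
      new <- sum(!covered[padj])
      if (new == 0L) next # must cover at least one new protein
      sc <- s_cov * new + s_mcov * (length(padj) - new)
      if (sc > best_score || (sc == best_score && new > best_new)) {
        best <- a; best_score <- sc; best_new <- new
      }
    }
    stopifnot(best > 0L) # guaranteed: some protein uncovered and graph feasible
    chosen <- c(chosen, best)
    in_l[best] <- TRUE
    covered[idx$adj[[best]]] <- TRUE
  }
  new_solve_result("greedy", graph, idx, chosen, length(chosen), "optimal")
}

#' @rdname solvers
#' @param graph a [build_cover_graph()] result (typically after
#'   [remove_robinson()]).
#' @return a `txp_solve_result`: list with `variant`, `selected` (tibble
#'   `side`, `epitope`, in selection order for the greedy variants),
#'   `objective`, `status` (`optimal`, `feasible_time_limit` or
#'   `infeasible`), and `solution` (a [score_solution()] result).
#' @export
greedy_cover <- function(graph) {
  res <- greedy_engine(graph, s_cov = 1, s_mcov = 0)
  res$variant <- "greedy"
  res
}

#' @rdname solvers
#' @param s_cov,s_mcov non-negative weights for newly covered and re-covered
#'   proteins. The defaults depend on the dataset size (see
#'   `small_threshold`): large sets favour innovation (`s_cov = 100`,
#'   `s_mcov = 1`), small sets favour redundancy (`s_cov = 1`,
#'   `s_mcov = 10`), because multicoverage through high-capacity epitopes is
#'   much likelier in large datasets.
#' @param small_threshold protein count at or below which the small-dataset
#'   default weights apply.
#' @export
greedy_multicover <- function(graph, s_cov = NULL, s_mcov = NULL,
                              small_threshold = 500L) {
  if (is.null(s_cov) || is.null(s_mcov)) {
    small <- length(graph$proteins) <= small_threshold
    s_cov <- s_cov %||% if (small) 1 else 100
    s_mcov <- s_mcov %||% if (small) 10 else 1
  }
  if (s_cov < 0 || s_mcov < 0 || s_cov + s_mcov <= 0) {
    abort("Need s_cov >= 0, s_mcov >= 0 and s_cov + s_mcov > 0.")
  }
  res <- greedy_engine(graph, s_cov = s_cov, s_mcov = s_mcov)
  res$variant <- "greedy_mc"
  res
}

# ---- exact branch and bound for the binary programs ------------------------

# Minimise the number of selected epitopes subject to per-protein coverage
# requirements req (0/1/2, already capped by degree). Branches on the
# uncovered protein with the fewest available epitopes; each branch selects
# one of them and excludes the earlier siblings. Bound: chosen +
# ceil(residual total / best remaining per-epitope gain).
bnb_min_cover <- function(adj, req, deadline = Inf) {
  nA <- length(adj)
  padj <- vector("list", length(req)) # protein -> adjacent epitopes
  for (a in seq_len(nA)) for (p in adj[[a]]) padj[[p]] <- c(padj[[p]], a)

  # greedy incumbent (always feasible since req <= degree)
  residual <- req
  avail <- rep(TRUE, nA)
  inc <- integer()
  while (sum(residual) > 0L) {
    gains <- vapply(seq_len(nA), function(a) {
      if (!avail[a]) return(-1L)
      sum(residual[adj[[a]]] > 0L)
    }, integer(1))
    a <- which.max(gains)
    inc <- c(inc, a)
    avail[a] <- FALSE
    hit <- adj[[a]]
    residual[hit] <- pmax(residual[hit] - 1L, 0L)
  }
  best <- list(size = length(inc), chosen = sort(inc), proven = TRUE)
  timed_out <- FALSE

  rec <- function(chosen, residual, banned) {
    if (timed_out) return()
    if (Sys.time() > deadline) { timed_out <<- TRUE; return() }
    tot <- sum(residual)
    if (tot == 0L) {
      if (length(chosen) < best$size) {
        best <<- list(size = length(chosen), chosen = sort(chosen), proven = TRUE)
      }
      return()
    }
    open <- which(!banned)
    if (length(open) == 0L) return()
    gains <- vapply(open, function(a) sum(residual[adj[[a]]] > 0L), integer(1))
    maxg <- max(gains)
    if (maxg == 0L) return()
    if (length(chosen) + ceiling(tot / maxg) >= best$size) return()
    # branch on the neediest protein
    needy <- which(residual > 0L)
    cand <- lapply(needy, function(p) open[open %in% padj[[p]]])
    nopt <- lengths(cand)
    if (any(nopt < residual[needy])) return() # cannot meet requirement
    p_i <- which.min(nopt)
    branch_ban <- banned
    for (a in cand[[p_i]]) {
      nb <- branch_ban
      nb[a] <- TRUE # selected now; never branch on it again below
      hit <- adj[[a]]
      r2 <- residual
      r2[hit] <- pmax(r2[hit] - 1L, 0L)
      rec(c(chosen, a), r2, nb)
      branch_ban[a] <- TRUE # later branches exclude this epitope
    }
  }
  rec(integer(), req, rep(FALSE, nA))
  list(size = best$size, chosen = best$chosen,
       status = if (timed_out) "feasible_time_limit" else "optimal")
}

# Maximise the number of >=2-covered proteins over full covers of size <=
# cost_max. Depth-first include/exclude over epitopes sorted by degree,
# with feasibility and objective bounds from suffix adjacency counts.
bnb_max_multicover <- function(adj, nP, cost_max, deadline = Inf) {
  nA <- length(adj)
  ord <- order(-lengths(adj), seq_len(nA))
  adj <- adj[ord]
  # suffix adjacency count per protein: how many epitopes with index >= i cover p
  suffix <- matrix(0L, nrow = nP, ncol = nA + 1L)
  for (i in rev(seq_len(nA))) {
    suffix[, i] <- suffix[, i + 1L]
    suffix[adj[[i]], i] <- suffix[adj[[i]], i] + 1L
  }
  suffix_deg <- c(rev(cummax(rev(lengths(adj)))), 0L)

  best_obj <- -1L
  best_chosen <- NULL
  timed_out <- FALSE

  rec <- function(i, cov, used, chosen) {
    if (timed_out) return()
    if (Sys.time() > deadline) { timed_out <<- TRUE; return() }
    remaining <- cost_max - used
    uncovered <- cov == 0L
    # full cover must stay reachable
    if (any(uncovered & suffix[, i] == 0L)) return()
    n_unc <- sum(uncovered)
    if (n_unc > 0L) {
      if (remaining == 0L) return()
      if (ceiling(n_unc / max(suffix_deg[i], 1L)) > remaining) return()
    }
    cur_obj <- sum(cov >= 2L)
    potential <- cur_obj + sum(cov < 2L & (cov + suffix[, i]) >= 2L &
                                 (remaining > 0L))
    if (potential <= best_obj) return()
    if (i > nA || remaining == 0L) {
      if (n_unc == 0L && cur_obj > best_obj) {
        best_obj <<- cur_obj; best_chosen <<- chosen
      }
      return()
    }
    # include epitope i
    cov2 <- cov
    cov2[adj[[i]]] <- cov2[adj[[i]]] + 1L
    rec(i + 1L, cov2, used + 1L, c(chosen, i))
    # exclude epitope i
    rec(i + 1L, cov, used, chosen)
  }
  rec(1L, integer(nP), 0L, integer())
  list(objective = best_obj,
       chosen = if (is.null(best_chosen)) integer() else sort(ord[best_chosen]),
       status = if (timed_out) "feasible_time_limit"
                else if (best_obj < 0L) "infeasible" else "optimal")
}

#' @rdname solvers
#' @param time_limit wall-clock limit in seconds for the branch-and-bound
#'   search; on expiry the incumbent is returned with status
#'   `feasible_time_limit`. Default 300.
#' @export
ilp_cover <- function(graph, time_limit = 300) {
  ilp_engine(graph, variant = "ip", time_limit = time_limit)
}

#' @rdname solvers
#' @export
ilp_multicover <- function(graph, time_limit = 300) {
  ilp_engine(graph, variant = "ip_mc", time_limit = time_limit)
}

ilp_engine <- function(graph, variant, time_limit) {
  idx <- graph_index(graph)
  nP <- length(idx$proteins)
  if (nP == 0L) return(new_solve_result(variant, graph, idx, integer(), 0L, "optimal"))
  msg <- check_feasible(idx)
  if (!is.null(msg)) {
    return(new_solve_result(variant, graph, idx, integer(), NA_real_, "infeasible", msg))
  }
  req <- switch(variant, ip = rep(1L, nP), ip_mc = pmin(2L, idx$deg))
  deadline <- Sys.time() + time_limit
  res <- bnb_min_cover(idx$adj, req, deadline)
  new_solve_result(variant, graph, idx, res$chosen, res$size, res$status)
}

#' @rdname solvers
#' @param cost_max maximum number of epitopes (the antibody budget). Must be
#'   at least the minimum cover size (the lower bound); the size of the
#'   enforced-multicover optimum is a natural upper bound, beyond which
#'   every multicoverable protein is already multicovered.
#' @export
ilp_max_multicover <- function(graph, cost_max, time_limit = 300) {
  idx <- graph_index(graph)
  nP <- length(idx$proteins)
  if (nP == 0L) return(new_solve_result("ip_mmc", graph, idx, integer(), 0L, "optimal"))
  msg <- check_feasible(idx)
  if (!is.null(msg)) {
    return(new_solve_result("ip_mmc", graph, idx, integer(), NA_real_, "infeasible", msg))
  }
  deadline <- Sys.time() + time_limit
  lb <- bnb_min_cover(idx$adj, rep(1L, nP), deadline)
  if (cost_max < lb$size) {
    return(new_solve_result(
      "ip_mmc", graph, idx, integer(), NA_real_, "infeasible",
      paste0("cost_max = ", cost_max, " is below the minimum cover size ", lb$size)))
  }
  res <- bnb_max_multicover(idx$adj, nP, cost_max, deadline)
  new_solve_result("ip_mmc", graph, idx, res$chosen, res$objective, res$status)
}

#' @rdname solvers
#' @param variant which program the oracle solves: `"ip"` (minimum cover),
#'   `"ip_mc"` (enforced multicover) or `"ip_mmc"` (budgeted maximum
#'   multicover, requires `cost_max`).
#' @param max_epitopes refusal guard for the exhaustive oracle.
#' @export
brute_force_cover <- function(graph, variant = c("ip", "ip_mc", "ip_mmc"),
                              cost_max = NULL, max_epitopes = 20L) {
  variant <- match.arg(variant)
  idx <- graph_index(graph)
  nA <- length(idx$adj)
  nP <- length(idx$proteins)
  if (nA > max_epitopes) {
    abort(paste0("brute_force_cover refuses |A| = ", nA, " > ", max_epitopes,
                 " epitopes; use an ilp_* solver."))
  }
  if (nP == 0L) {
    return(new_solve_result(paste0("brute_", variant), graph, idx, integer(), 0L, "optimal"))
  }
  inc <- matrix(FALSE, nrow = nP, ncol = nA)
  for (a in seq_len(nA)) inc[idx$adj[[a]], a] <- TRUE
  req <- switch(variant,
    ip = rep(1L, nP),
    ip_mc = pmin(2L, idx$deg),
    ip_mmc = rep(1L, nP)
  )
  if (variant == "ip_mmc" && is.null(cost_max)) {
    abort("`cost_max` is required for variant 'ip_mmc'.")
  }
  if (variant %in% c("ip", "ip_mc")) {
    for (k in 0:nA) {
      subsets <- if (k == 0L) list(integer()) else
        asplit(combn(nA, k), 2L)
      for (s in subsets) {
        cov <- if (length(s) == 0L) integer(nP) else rowSums(inc[, s, drop = FALSE])
        if (all(cov >= req)) {
          return(new_solve_result(paste0("brute_", variant), graph, idx,
                                  as.integer(s), k, "optimal"))
        }
      }
    }
    return(new_solve_result(paste0("brute_", variant), graph, idx, integer(),
                            NA_real_, "infeasible"))
  }
  # ip_mmc: scan all full covers within budget, maximise multicovered count
  best_obj <- -1L; best_s <- NULL
  for (k in 0:min(cost_max, nA)) {
    subsets <- if (k == 0L) list(integer()) else asplit(combn(nA, k), 2L)
    for (s in subsets) {
      cov <- if (length(s) == 0L) integer(nP) else rowSums(inc[, s, drop = FALSE])
      if (all(cov >= 1L)) {
        obj <- sum(cov >= 2L)
        if (obj > best_obj) { best_obj <- obj; best_s <- as.integer(s) }
      }
    }
  }
  if (best_obj < 0L) {
    return(new_solve_result("brute_ip_mmc", graph, idx, integer(), NA_real_, "infeasible"))
  }
  new_solve_result("brute_ip_mmc", graph, idx, best_s, best_obj, "optimal")
}

#' Solve a cover graph with a named method
#'
#' Convenience dispatcher used by the command-line interface.
#'
#' @param graph a `cover_graph`.
#' @param method one of `"greedy"`, `"greedy-mc"`, `"ip"`, `"ip-mc"`,
#'   `"ip-mmc"`.
#' @param ... passed to the underlying solver (`s_cov`, `s_mcov`,
#'   `cost_max`, `time_limit`, ...).
#' @return a `txp_solve_result`.
#' @export
solve_cover <- function(graph, method = c("greedy", "greedy-mc", "ip", "ip-mc", "ip-mmc"),
                        ...) {
  method <- match.arg(method)
  switch(method,
    "greedy" = greedy_cover(graph),
    "greedy-mc" = greedy_multicover(graph, ...),
    "ip" = ilp_cover(graph, ...),
    "ip-mc" = ilp_multicover(graph, ...),
    "ip-mmc" = ilp_max_multicover(graph, ...)
  )
}
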