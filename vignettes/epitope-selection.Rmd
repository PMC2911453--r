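---
title: "Selecting terminal epitopes for immunoaffinity MS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting terminal epitopes for immunoaffinity MS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txpcover)
```

## The design problem

Immunoaffinity enrichment with antibodies against short terminal peptide
sequences lets one binder capture every tryptic peptide ending (or starting)
with its epitope; the mass spectrometer then distinguishes the captured
peptides by mass. Designing an assay for a protein list therefore reduces to
a covering problem: pick the smallest set of 3–5-residue terminal epitopes
such that every target protein contributes at least one *detectable*
captured peptide.

The model rests on explicit assumptions:

* the digest is complete — trypsin cleaves after every K or R not followed
  by P, with no missed or mis-cleavages;
* the background proteome is fully known, and the sample contains no
  proteins outside it;
* a hypothetical antibody is perfectly specific for its epitope sequence
  and terminus, and binds no variants or modifications.

These are idealisations. They make the combinatorics exact; deviations
(missed cleavages, cross-reactivity, unsequenced variants) shift real assays
away from the computed optimum but do not change the structure of the
problem.

## From digest to combinations

`tryptic_digest()` partitions each protein into consecutive peptides, and
`enumerate_combinations()` produces, for every peptide, epitope length `l`
and terminus, one combination — the quadruple (protein, peptide, side,
epitope). Epitope identity is the *(sequence, side)* pair: `LGYR` as a
C-terminus and as an N-terminus are different binders. A peptide exactly `l`
residues long is its own epitope; nothing in the enumeration forbids that,
and such peptides are real capture events. Identical peptide sequences in
several proteins yield one combination per parent protein, which is how a
single captured molecular species can cover several targets.

Peptide masses are **monoisotopic** by default. The package targets
MALDI-TOF-style read-out, where the monoisotopic peak is the measured
quantity; this choice also reproduces the canonical near-isobaric example
(AYEQLGYR vs HLEILGYR, Δ = 1.068 Da) to the printed precision, which an
average-mass table does not. An average table is available via
`mass_table("average")`. Ambiguity codes X, B, Z and J have no mass;
selenocysteine and pyrrolysine have their standard masses but can be
declared unknown in `mass_table()`.

## The filter pipeline

Six filters remove combinations that cannot contribute a detectable,
identifiable peak. Defaults, units and rationale:

| filter | parameter | default | why |
|---|---|---|---|
| unknown positions | — | — | a peptide containing X has no computable mass |
| methionine | — | — | Met oxidation can defeat epitope recognition |
| high-abundant epitope | `max_epitope_load` | 600 combinations | an antibody capturing more would be cluttered and insensitive |
| weight | `delta_min` | 2 Da | minimum peak separation; 2–10 Da is realistic for MALDI-TOF, we default to the permissive end |
| length | `min/max_peptide_len` | 8–30 residues | detector mass range, rule of thumb |
| stop list | `stoplist` | empty | epitopes found on high-abundant proteins (actin, tubulin, …) are unusable anywhere |

Ordering matters for the three filters that evaluate the per-epitope
combination load: the high-abundant-epitope filter must run before the
weight filter, which must run before the length filter, because each later
one changes the load distribution the earlier one evaluates. The
unknown-positions, methionine and stop-list filters commute and may sit
anywhere. `filter_config()` rejects an order violating the constraint before
any work is done. Each load-dependent filter evaluates |C^e| at its own
pipeline stage, not on the raw enumeration — that is what the ordering
constraint is *for*.

Three behaviours were genuinely open and are package decisions:

* **Weight filter removes both parties.** When two different peptide
  sequences under one epitope are closer than `delta_min`, the peak is
  ambiguous for both, so both are marked undetectable. Marking only one
  would pretend the survivor is identifiable, which it is not. Conflicts
  are found by sorting each epitope's distinct peptide species by mass and
  scanning neighbours — equivalent to the pairwise definition, since any
  pair within `delta_min` implies adjacent species within `delta_min`.
* **Shared peptides are one species.** The same sequence captured from two
  proteins is one molecule and one peak; Δ = 0 between a species and itself
  is not a conflict, and every parent protein retains the coverage.
* **Undetectable combinations are kept, flagged.** They never enter the
  cover graph, but they stay in dumps (`detectable = FALSE`) so a designer
  can audit what the filter did — and because the *antibody* may still
  usefully capture those peptides even if they cannot be told apart.

A peptide whose mass is unknown when the weight filter runs (possible only
if the unknown-positions filter was moved or removed) is treated as
undetectable: its peak position cannot be predicted.

## The cover graph and robinson pruning

`build_cover_graph()` connects a protein and an epitope when at least one
detectable combination links them. Target restriction happens *after*
filtering against the full background proteome, so epitope loads reflect
everything the antibody would capture in a real sample, not just the
targets. Targets absent from the filtered set are reported as uncoverable
rather than silently dropped.

An epitope capturing exactly one peptide species from exactly one protein
(a "robinson") is dominated by any alternative cover of that protein and is
pruned before optimisation. Applied literally, this rule can orphan a
protein whose *only* cover is a robinson; the pruning therefore keeps, per
otherwise-orphaned protein, its lexicographically first robinson epitope,
and reports how many were guarded. The dominance argument presupposes an
alternative exists; when none does, removal would simply make the instance
infeasible.

## Solvers

Two greedy heuristics and three exact binary programs operate on the graph.

**Greedy set cover** repeatedly selects the epitope covering the most
still-uncovered proteins; its solution is at most H(n) times the optimum,
n being the largest epitope coverage. **Multicoverage greedy** scores
`s_cov · |new| + s_mcov · |re-covered|` and requires every selected epitope
to cover at least one new protein — a hard eligibility rule, not just a
score penalty, which guarantees termination with at most one epitope per
protein. With `s_mcov = 0` it reduces exactly to plain greedy. Default
weights follow dataset size: large datasets have many high-capacity
epitopes whose protein sets overlap anyway, so innovation is scored higher
(`s_cov = 100, s_mcov = 1`); in small datasets multicoverage must be paid
for explicitly (`s_cov = 1, s_mcov = 10`). The boundary between regimes
defaults to 500 proteins and is configurable — the regimes are qualitative
("pathway-scale" vs "proteome-scale"), not a sharp threshold.

Both greedies break score ties deterministically: larger new coverage
first, then lexicographic (side, sequence). Determinism is required for
reproducible assays and for testing; the tie rule itself is arbitrary.

The exact variants are binary programs. No linear-programming backend is a
package dependency; instead an exact **branch-and-bound engine** solves all
three:

* *minimum cover* and *enforced multicover* share one search: branch on the
  protein with the fewest remaining covering epitopes, bound by
  `chosen + ceil(residual demand / best remaining per-epitope gain)`, with a
  greedy incumbent. The multicover requirement is capped at each protein's
  degree, so degree-1 proteins need only single coverage and the program is
  always feasible.
* *budgeted maximum multicover* does include/exclude search over epitopes in
  decreasing-degree order, pruning on (a) reachability of a full cover from
  the remaining suffix within the budget and (b) an optimistic bound on
  attainable double coverage.

The engine returns `optimal` only when the search completes; a `time_limit`
(default 300 s; set it to 12 h for proteome-scale instances) yields the
incumbent with status `feasible_time_limit`. The enforced multicover tends
to select elongation pairs — an epitope plus an inward extension of it
(`IER`/`EIER`) — to satisfy double coverage cheaply; these pairs capture
nearly identical peptide groups, so `elongation_pairs()` surfaces them as a
report warning. We deliberately do not add constraints against them: no
principled exclusion rule is part of the model, and hiding the behaviour
would be worse than reporting it.

The budget of the maximum multicover is bracketed by the minimum cover size
(below it the program is infeasible, and the refusal names the bound) and
the enforced-multicover optimum (above it every multicoverable protein is
already doubly covered).

`brute_force_cover()` enumerates epitope subsets in size order and is the
independent oracle in the test suite; it refuses instances above 20
epitopes. Exactness of the branch-and-bound engine is asserted against it
on 100 seeded random instances with up to 15 epitopes and 30 proteins —
sizes chosen so the oracle itself is trivially fast while the instances
still have non-trivial optima (the observed mean greedy/optimal ratio on
these instances is around 1.05, so the exact solvers are doing real work).

## The synthetic generator

`synthetic_proteome()` builds proteomes whose digests contain structure
known by construction: shared-terminus groups (several proteins each
carrying a tryptic peptide with a planted terminal epitope), near-isobaric
pairs (two peptides sharing a planted C-terminal epitope whose masses
differ by exactly the AYEQ/HLEI swap, 1.068 Da — inside a 2 Da window,
outside a 1 Da one), and an overloaded epitope planted onto a configurable
number of carrier peptides. A manifest records every planted truth, and the
test suite verifies the pipeline recovers *exactly* the planted conflicts
and overloads — no false negatives, no false positives.

To make that exactness guarantee hold, filler peptides avoid K, R, M
internally (they terminate in K/R) so no accidental cleavage sites or
methionine hits arise; fillers that would accidentally carry a planted
terminal epitope are rejected and redrawn; and within each planted group,
member peptide masses are kept pairwise more than 2.5 Da apart so the
weight filter at the default 2 Da cannot fire on planted-clean material.

What the generator does **not** emulate: realistic amino-acid composition,
protein length distributions, peptide mass clustering (real tryptic digests
are strongly non-uniform in mass), sequence homology between proteins, and
shared peptides across proteins. Passing tests on synthetic proteomes
demonstrate the correctness of the machinery — digestion, filtering, graph
construction, optimisation — not the quantitative filter losses or coverage
scores to expect on a real proteome, which depend on these unmodelled
features. `random_cover_graph()` similarly generates solver fixtures as
uniform random bipartite graphs with feasibility repaired by construction;
real cover graphs are far more skewed.

## Degenerate inputs and numerical notes

* Peptides shorter than the smallest epitope length produce no
  combinations; an empty combination set flows through the pipeline and
  produces an all-zero report rather than an error.
* An epitope left with zero detectable combinations after the weight filter
  drops out of the graph automatically (no edge survives).
* Masses are plain double sums of residue masses; no rounding is applied
  before the `delta_min` comparison, which is strict (`<`), matching the
  strict reading of "bigger than 600" for the load filter (a load of
  exactly 600 survives) and the inclusive 8–30 length range.
* `score_solution()` recomputes coverage from the edge list independently
  of any solver, and the test suite uses it to validate every solver's
  full-cover contract.
* Problem sizes in the tests: random instances up to 15 epitopes × 30
  proteins for oracle comparisons, synthetic proteomes of 8–40 proteins for
  pipeline round trips — small enough for exhaustive validation, large
  enough that greedy and optimal solutions genuinely diverge.

## Known limitations

* No missed-cleavage or modification modelling — by assumption.
* Antibody specificity is binary and exact; near-epitope cross-reactivity
  is not modelled.
* The exact solvers are practical to a few hundred epitopes; proteome-scale
  instances need the greedy heuristics or a long `time_limit`, as expected
  for an NP-hard problem.
* The multicover greedy only *favours* redundancy; it never guarantees it.
  Use the enforced multicover when double coverage is a requirement, and
  the budgeted maximum multicover when it is a preference under a fixed
  antibody budget.
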