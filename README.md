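# txpcover

Design of minimal epitope panels for immunoaffinity mass spectrometry.

Antibodies raised against short (3–5 residue) *terminal* peptide sequences
enrich whole groups of tryptic peptides that share that terminus, before the
mass-spectrometric read-out separates the group members by mass. One such
antibody can therefore report on many proteins at once — if its epitope is
chosen well. `txpcover` answers the design question: **given a proteome and a
list of target proteins, which minimal set of terminal epitopes covers every
target with a detectable peptide?**

The package is aimed at assay designers in targeted proteomics. It provides:

* a complete in-silico tryptic digest (cleave after K/R unless P follows; no
  missed cleavages) with monoisotopic peptide masses;
* enumeration of peptide/terminal-epitope combinations — the quadruple
  (protein, peptide, terminus side, epitope) — for configurable epitope
  lengths and termini;
* an ordered detectability filter pipeline: unknown residues, methionine in
  the epitope, overloaded epitopes (load > 600 by default), near-isobaric
  peptide pairs under one epitope (Δ < Δ_min, default 2 Da), detector length
  range (8–30 residues), and a high-abundant-protein stop list;
* the bipartite protein–epitope cover graph, with pruning of single-capture
  ("robinson") epitopes;
* five selection procedures, and a brute-force oracle for validating them.

## The optimisation problem

With binary variables *s_a* marking selection of epitope *a*, the minimum
cover is

```
min Σ_a s_a    s.t.   Σ_{a adjacent to i} s_a ≥ 1   for every protein i
```

Variants: the **enforced multicover** raises the right-hand side to 2 for
every protein of degree ≥ 2; the **budgeted maximum multicover** maximises
Σ_i S_i (binary indicators of double coverage, linked by
Σ_{a adj i} s_a ≥ 1 + S_i) over all full covers with Σ_a s_a ≤ cost_max.
These binary programs are solved exactly by the package's branch-and-bound
engine. Two greedy heuristics scale to whole proteomes: classical greedy set
cover (approximation ratio H(n)), and a multicoverage greedy whose score
`s_cov · |new proteins| + s_mcov · |re-covered proteins|` trades minimality
against redundancy.

The quality of a selection *L* over targets *P* is the coverage score
|L| / |P| — lower means fewer antibodies per protein.

## Worked example

A synthetic 12-protein proteome with two planted shared-terminus groups and
one planted near-isobaric peptide pair:

```r
library(txpcover)

prot <- synthetic_proteome(
  n_proteins = 12,
  shared_groups = list(list(epitope = "LGYR", side = "c", n = 5),
                       list(epitope = "FDET", side = "n", n = 4)),
  near_isobaric_pairs = 1,
  seed = 7)

digest   <- tryptic_digest(prot)
combos   <- enumerate_combinations(digest, lengths = 4, sides = c("n", "c"))
filtered <- run_filter_pipeline(combos, filter_config(max_epitope_load = 50))
filtered$report
#>   filter                n_epitopes n_proteins n_combinations
#> 1 unfiltered                   333         12            344
#> ...
#> 5 weight                       332         12            342
#> 7 stoplist                     332         12            342

graph <- build_cover_graph(filtered) |> remove_robinson()
#> 2 single-capture epitope(s) kept as sole cover of their protein.
graph
#> Cover graph: 12 proteins, 7 epitopes, 16 edges

res <- ilp_cover(graph)
glance(res)
#>   variant status  objective n_selected n_proteins coverage_score ...
#> 1 ip      optimal         5          5         12          0.417

head(tidy(res), 4)
#>   side  epitope n_proteins proteins
#> 1 c     AVVK             1 SYN0004
#> 2 c     CIQK             1 SYN0006
#> 3 c     LGYR             5 SYN0002,SYN0003,SYN0007,SYN0010,SYN0012
#> 4 c     SCAK             2 SYN0001,SYN0011
```

The weight filter flagged the planted near-isobaric pair (344 → 342
combinations): two distinct peptides sharing a C-terminal epitope whose
masses differ by 1.068 Da — indistinguishable at a 2 Da resolution. The
planted `LGYR` group makes one antibody cover five proteins, giving a
coverage score of 5/12 ≈ 0.417: five antibodies instead of twelve.

`txp_run()` wires these stages together (FASTA in, TSV/JSON artifacts out);
`inst/scripts/txp-select` exposes the same workflow on the command line with
`digest` / `simulate` / `run` subcommands. `greedy_multicover()`,
`ilp_multicover()` and `ilp_max_multicover()` extend the selection towards
redundant (≥ 2-fold) coverage; `autoplot()` on any solve result shows the
per-protein coverage profile.

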