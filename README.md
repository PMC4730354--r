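# netprox

Statistical machinery for linking a compound's predicted protein targets
to a disease gene set. Network pharmacology studies routinely face the
same question: a docking screen proposes dozens of putative targets for a
small molecule — are those proteins actually related to the disease of
interest? `netprox` answers it with three complementary, permutation-
calibrated statistics plus a docking-affinity triage, and ships seeded
synthetic generators so the whole pipeline is testable without any
external database.

## What it computes

**Inter-set network proximity.** For target set *x* (M genes) and disease
set *y* (N genes) on a background PPI network,

    Dis(x, y) = Σᵢ Σⱼ dis(xᵢ, yⱼ) / (M × N)

the mean breadth-first shortest-path length over all cross-set pairs.
Significance comes from replacing one set with uniform random node
samples of equal size: the Z-score (signed so closeness is positive) and
a one-sided, add-one–smoothed empirical p-value, run for both randomized
sides.

**GO-profile semantic similarity.** Each gene set is condensed to its
profile of level-4 biological-process terms enriched at raw
hypergeometric p < 0.05; profiles are compared by graph-based Wang-style
term similarity (edge factors 0.8 is_a / 0.6 part_of) aggregated with
the best-match average, again with gene-set permutation p-values for
both sides.

**Pathway over-representation.** One-sided Fisher exact tests of the
target set against a GMT pathway collection, raw p at 0.05.

**Binding-affinity triage.** A putative target is a *strong* binder when
the compound's MM/GBVI or pKi on the known ligand's pocket is better
than, or close to, the known ligand's (defaults: 4 kcal/mol and 1 pKi
unit of slack; OR-combined). The package ships the published 21-row
icariin comparison table as a fixture.

Readers/writers cover the standard formats: two-column TSV and SIF edge
lists, plain gene lists, OBO 1.2, GAF 2.x, GMT and CSV docking tables.
Results are tibbles (or carry `tidy()` / `glance()` methods) and have
`autoplot()` methods, so everything chains with the pipe.

## Worked example

```r
library(netprox)

# 1. the published docking table: 21 strong binders of 39 docked targets
table1 <- read_docking_table(
  system.file("extdata", "icariin_docking_table.csv", package = "netprox"))
glance(classify_table(table1, n_total = 39))
#> # A tibble: 1 × 5
#>   n_records n_strong n_weak n_total pct_strong
#>       <int>    <int>  <int>   <int>      <dbl>
#> 1        21       21      0      39       53.8

# 2. a synthetic study at the published scale: 59 targets vs 89 disease
#    genes on a 9,500-node scale-free interactome, with planted closeness
spec <- synthetic_spec(seed = 42)
net  <- gen_network(spec)
sets <- gen_proximal_sets(net, spec)
permutation_test_proximity(sets$a, sets$b, net,
                           randomized_side = "b",
                           n_permutations = 1000, seed = 42)
#> <permutation_result> average_shortest_distance: observed = 4.1868,
#>   null 4.4315 +/- 0.0372 (n = 1000)
#>   Z = 6.576, empirical p = 0.000999 (side b randomized, seed 42)

# 3. functional similarity of the same two sets on a synthetic ontology
onto <- gen_ontology_and_annotations(spec, genes = network_nodes(net),
                                     group_a = sets$a, group_b = sets$b)
permutation_test_profile_similarity(sets$a, sets$b, onto$annotations,
                                    randomized_side = "b",
                                    n_permutations = 1000, seed = 42)
#> <permutation_result> profile_similarity_bma: observed = 0.8675,
#>   null 0.3466 +/- 0.0948 (n = 1000)
#>   Z = 5.492, empirical p = 0.001044 (side b randomized, seed 42)
```

Reading the output: the two planted sets sit 4.19 edges apart on average
versus 4.43 ± 0.04 for random sets of the same size — 6.6 null standard
deviations closer than chance — and their enriched GO profiles are far
more similar (BMA 0.87) than profiles of random gene sets (0.35 on
average), both at the smallest p the permutation count allows.

`run_full_analysis(run_config(...))` chains all four stages from input
files and writes per-stage TSVs plus a machine-readable `summary.json`;
`inst/cli/netprox` wraps the same functions as a command-line tool with
`proximity`, `gosim`, `enrich`, `dockcompare`, `simulate` and `run-all`
subcommands.

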