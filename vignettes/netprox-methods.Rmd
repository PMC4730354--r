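---
title: "Methods: network proximity and functional similarity between target and disease gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network proximity and functional similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Given a compound's predicted protein targets (one gene set) and the known
proteins of a disease (a second gene set), are the two sets related — do
the targets sit unusually close to the disease proteins in the
protein–protein interaction (PPI) network, and do the two sets perform
similar biological functions? `netprox` implements the statistical
machinery for answering both questions, together with a pathway
over-representation step and a binding-affinity triage of the predicted
targets, so the full analysis can be chained end to end.

# Models and statistics

## Inter-set network proximity

For gene sets $x = \{x_1, \dots, x_M\}$ and $y = \{y_1, \dots, y_N\}$
mapped onto an undirected, unweighted background PPI network, the
proximity statistic is the inter-subnetwork average shortest path

$$\mathrm{Dis}(x, y) \;=\; \frac{\sum_{i=1}^{M}\sum_{j=1}^{N}
  \mathrm{dis}(x_i, y_j)}{M \times N},$$

where $\mathrm{dis}(\cdot,\cdot)$ is the breadth-first shortest-path
length. Genes shared by the two sets contribute distance 0 as ordinary
pairs (`drop_shared = TRUE` removes them first). Cross-component pairs
have no finite distance; by default they are excluded from the mean and
their count is reported (`unreachable_policy = "exclude"`), or they can
be scored as the network diameter plus one (`"penalize"`). Exclusion is
the default because curated PPI networks are fragmented at the margins
and a handful of orphan proteins should not dominate the mean; both
policies are exposed because published analyses rarely state which was
used.

Significance is assessed by permutation: one of the two sets is replaced
by uniform random draws of equal size (without replacement) from a
sampling universe — all network nodes by default, or an explicit
background list — and the statistic is recomputed `n_permutations`
times. The report carries

* the Z-score, the observed statistic standardised against the null and
  *signed toward the alternative*, so evidence of closeness is positive
  (the raw orientation $(\mathrm{obs}-\mu_0)/\sigma_0$ is recoverable
  from the stored `observed`, `null_mean` and `null_sd`);
* the empirical p-value, one-sided toward small distances, with add-one
  smoothing $p = (r+1)/(n+1)$ so that finite permutation counts never
  produce $p = 0$.

The null is uniform rather than degree-matched because that is the
design the statistic is normally reported under; a degree-binned null
(`null_model = "degree_binned"`) is available as a sensitivity analysis.
Both randomized sides are run by the pipeline — randomize the disease
set, then the target set — and reported as a pair.

## GO-profile semantic similarity

Each gene set is first condensed to a *functional profile*: all ontology
terms at a fixed level whose over-representation in the set is
significant at raw hypergeometric $p < \alpha$ (default level 4,
$\alpha = 0.05$, biological-process namespace). Annotations are
propagated to ancestors (true-path rule) before counting. No
multiple-testing correction is applied inside a profile — the profile is
a descriptive condensation, not an inference. Ontology "levels" are
convention-dependent, so both the path rule (shortest, the default, or
longest child-to-parent path to a root) and the root's level (0 by
default) are configurable.

Term-to-term similarity is the graph-based (Wang-style) measure: the
contribution of ancestor $a$ to term $t$ is
$S_t(a) = \max_{\text{paths } t \to a} \prod w_e$ with $S_t(t) = 1$ and
per-edge factors $w_{is\_a} = 0.8$, $w_{part\_of} = 0.6$ (the published
constants of the method; configurable). With
$SV(t) = \sum_a S_t(a)$,

$$\mathrm{sim}(t_1, t_2) = \frac{\sum_{a \in A(t_1) \cap A(t_2)}
  \bigl(S_{t_1}(a) + S_{t_2}(a)\bigr)}{SV(t_1) + SV(t_2)}.$$

Profiles are compared by the best-match average (BMA): each term's best
similarity in the other profile, averaged over both directions. The
permutation test resamples one *gene* set from the annotation
background, rebuilds its profile, and recomputes the BMA; p is one-sided
toward large similarity. Permutations whose resampled profile is empty
carry no similarity and are skipped (recorded on the result); more than
half empty is treated as a degenerate null and errors.

## Pathway over-representation

For each pathway, a one-sided (greater) Fisher exact test on the 2×2
hits table against a background universe. The default universe is the
union of all pathway members — reproducible without a genome annotation
download — and can be overridden with an explicit background list.
Raw p-values at $\alpha = 0.05$, uncorrected, matching the convention of
the analysis this package reproduces; rows are sorted by p.

## Binding-affinity triage

A predicted target is a *strong* (true) binder when the compound's
affinity on the known ligand's pocket is better than or close to the
known ligand's on at least one metric: MM/GBVI binding energy (more
negative is better) within `tol_energy`, or pKi (higher is better)
within `tol_pki`. The published analysis never defines "close"; the
defaults `tol_energy = 4` kcal/mol and `tol_pki = 1` are the smallest
round values under which every row of the published strong-binder table
classifies strong (the binding constraint is HNMT, whose pKi is worse by
0.81), and both are configurable. Metrics combine with OR, reading the
"energy or pKi" phrasing literally.

# The synthetic study generator

Real inputs for this analysis (a curated interactome, disease gene
lists, GO releases, pathway databases) are external and
version-dependent, so the package generates every input with seeded,
pure-function generators:

* **Network** — preferential attachment, 9,500 nodes, 3 edges per
  arrival (~28,500 edges, mean degree ~6). The node count mirrors the
  curated human interactome the proximity statistic is used on; the
  density sits in the curated-interactome range and was fixed, once,
  such that the radius-2 neighborhood of a 59-gene seed set is a
  minority of the graph — any denser and "within radius 2" stops being
  selective, any sparser and planted signals become unrealistically
  easy. An Erdős–Rényi alternative is available.
* **Gene sets** — set A: 59 genes, uniform; set B: 89 genes, each drawn
  from within `proximity_radius = 2` of set A with probability
  `proximity_bias = 0.95`, uniformly otherwise. Bias 0 gives two
  independent uniform sets. The sizes are the published study's scale.
  Note that this planting is *one-directional*: the radius-2 pool is
  hub-enriched, so a planted B is close to *any* gene set, and only
  randomizing B (the planted side) is calibrated to detect the signal —
  randomizing A yields small Z-scores even on planted instances. This is
  a property of neighborhood planting, not of the statistic; power
  checks therefore randomize the planted side.
* **Ontology and annotations** — a single-rooted term tree of depth 6
  and branching 3 (81 level-4 terms), edges typed `part_of` with
  probability 0.15, 10% of terms given a second parent so the structure
  is a true DAG. Each gene annotates 3 leaf terms. Two designated gene
  groups draw from 8 leaf-term families that overlap by
  `annotation_overlap` (default 0.9), with probability
  `annotation_focus = 0.8` per gene. Focus is itself a planting knob: a
  group focused on *any* family set has a larger, more coherent profile
  than a uniform resample, so a genuinely null configuration requires
  `annotation_focus = 0` as well as zero overlap.
* **Pathways** — 7 pathways of 40 genes from the universe; the first
  additionally draws 30% of its members from a designated query set
  (strength 0 reduces it to a random pathway).
* **Docking table** — 39 rows of which `round(21/39 × 39) = 21` are
  constructed to satisfy the default comparison rule and the rest fail
  both metrics beyond tolerance, mirroring the published 53.85% split.

What the generator does *not* emulate: true GO term-frequency skew,
protein families and network modularity, annotation incompleteness
bias, or docking energetics. Passing tests on synthetic data therefore
demonstrate the correctness and calibration of the statistics under
controlled conditions, not biological conclusions about any particular
compound.

# Stage-level significance in the pipeline

`run_full_analysis()` runs each permutation test with both randomized
sides and calls a stage significant only when *both* sides fall below
$\alpha$ — the two randomizations are treated as joint evidence, as in
the paired Z-scores of the analysis this package reproduces. With raw
per-test flags at $\alpha = 0.05$ an eleven-test pipeline would flag
something in ~40% of null runs; the both-sides rule keeps the pipeline's
headline calls conservative while individual p-values remain available
in the report.

# Numerical choices

* Empirical p-values use add-one smoothing; Z-scores are `NA` with a
  warning when the permutation null has zero spread (p remains valid).
* S-values are computed by a max-product fixed-point relaxation over the
  ancestor closure; closures are small (tens of terms), so no explicit
  topological sort is needed, and the recursion is cross-checked against
  exhaustive path enumeration in the tests.
* The hypergeometric tail is `phyper(k - 1, K, N - K, n, lower.tail =
  FALSE)`; the pathway route goes through `fisher.test(alternative =
  "greater")`. The two agree to 1e-12 and are deliberately kept as
  separate routes so each can check the other.
* All randomness flows through a single seeded entry point
  (`withr::with_seed`), so identical seeds give bit-identical results
  and callers' RNG state is never disturbed.
* Ties in sorting (equal p) are broken by name for reproducible output
  files.

# Problem sizes used by the test suite

The shipped tests run the calibration suite at the generator's default
network scale (200 null replicates and 50 planted replicates at 1,000
permutations each), the end-to-end pipeline checks on scaled-down
instances (2,000–3,000 nodes with proportionally smaller gene sets,
100–200 permutations), and the exhaustive oracles on graphs of at most
60 nodes and DAGs of at most 30 terms. The scaled pipeline instances
use smaller gene sets because radius-2 planting saturates on small
graphs — the neighborhood of 59 seeds covers a 400-node graph entirely.

# Known limitations

* The proximity statistic is the plain mean of Eq.-style cross-set
  distances; closest-distance and separation-score variants are out of
  scope.
* Only the biological-process aspect is used for profiles;
  information-content similarity measures (Resnik, Lin) are not
  implemented.
* Identifier mapping is the caller's responsibility: everything is keyed
  on uppercased gene symbols.
* Obsolete ontology terms are dropped, never remapped via `replaced_by`.
* The uniform permutation null ignores degree bias of curated gene sets;
  the degree-binned null is provided for sensitivity analysis but is not
  the headline test.
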