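---
title: "Methods: weighted connectome graph analysis with fcgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted connectome graph analysis with fcgraph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgraph)
```

This vignette documents the models, conventions and numerical choices
behind `fcgraph`, in the spirit of a methods section: what each stage
assumes, which parameters matter, and where the design was genuinely open.

## From timeseries to graphs

Per subject, `correlation_matrix()` computes all pairwise Pearson
correlations between node (ROI) timeseries and applies the Fisher
transform z = atanh(r), whose sampling standard deviation under
independence is 1/sqrt(T − 3) (≈ 0.041 at T = 600 timepoints). Because
atanh diverges at |r| = 1, correlations are clipped at |r| = 1 − 1e−7;
this only affects degenerate (duplicated) series. The diagonal is defined
as exactly 0. With N = 60 nodes there are N(N−1)/2 = 1770 unordered node
pairs.

`proportional_threshold()` retains the strongest fraction δ of those 1770
edges, ranking by *signed* z (strongest positive first). Negative edges
are deliberately not ranked by magnitude: the weighted metrics downstream
(clustering, rich club, modularity) assume nonnegative connectivity, and
negative weights participate only in the signed null model. The retained
edge count is round(δ·N(N−1)/2) with half rounded away from zero, and
rank ties are broken by lexicographic node index, so thresholding is a
deterministic function of the matrix. A fixed ranking also makes the
density sweep (default 6–32% in 2% steps, 14 levels, with nodal analyses
at the 16% level, 283 edges) *nested*: every edge kept at a lower density
survives at all higher ones. Retained weights are never modified.

As a data-driven alternative to a fixed δ, `bootstrap_edge_threshold()`
bootstraps subjects to form percentile confidence intervals of each
edge's cohort-mean z and reports the smallest significant |r| and the
edge density such a significance rule would imply.

## Weighted graph metrics

All metrics operate on the thresholded nonnegative weights.

* **Clustering / transitivity.** Node clustering uses the geometric-mean
  (Onnela) formulation on weights normalized by the network maximum;
  transitivity is its network-level analogue (total triangle intensity
  over total connected triples). Nodes with degree < 2 get CC = 0 — a
  recorded convention, not an error.
* **Paths.** Edge lengths are 1/weight (the standard transform for
  connectivity weights, where strong edges are short); shortest paths by
  Dijkstra. CPL averages finite pairwise distances; disconnected pairs
  are excluded from CPL and contribute 0 to global efficiency — stated
  explicitly because conventions differ between toolboxes.
* **Local efficiency** is the global efficiency of each node's
  neighbor-induced subgraph on max-normalized weights, bounded in [0, 1].
* **Assortativity** is the Pearson correlation of endpoint strength (or
  degree) over the symmetrized edge list. On regular graphs the endpoint
  variance is zero and the index is undefined; `fcgraph` returns NA with
  a warning, which is distinct from an assortativity of 0.
* **Participation coefficient** P_i = 1 − Σ_m (d_im/d_i)² uses binary
  degree by the published definition; a strength-weighted variant exists
  behind `weighted = TRUE` and is flagged as a non-standard companion.
* **Rich club.** Φ_w(k) is the ratio of the summed weights among nodes of
  degree > k to the sum of the equally many largest weights network-wide;
  the strict inequality is the boundary convention and is held fixed.
  Levels with fewer than two club nodes or no club edges are NA rather
  than 0, and Φ_norm = Φ_w/Φ_rand is NA wherever the null mean is 0 or
  undefined.
* **Small world.** SWC = γ/λ with γ and λ the transitivity and CPL ratios
  against the mean of a matched null ensemble. The lattice-referenced
  measure SWM = CPL_rand/CPL − CC/CC_latt follows the omega-style
  construction with a *non-ring* latticized reference (below). The same
  transitivity statistic stands in for "CC" in both ratios so the two
  indices are directly comparable; this is a documented convention — no
  equation-level reference standard exists for the weighted case, and SWM
  values should be compared within, not across, toolboxes.

## Null models

`randomize_signed()` randomizes positive and negative edges jointly but
sign-consistently: a swap exchanges the weights in a 2 × 2 node submatrix
only when the sign pattern guarantees that every node's count of positive
and of negative edges is unchanged (an absent edge counts as its own
"sign", so on a sparse positive network this reduces to the classic
degree-preserving double-edge swap, while on a dense signed matrix it
relocates positive and negative edges without ever stacking two edges on
one node pair). The default of 5 swap passes over the edge list is
interpreted as passes, not total swaps, and is configurable. After the
topology phase, each sign's weight multiset is re-sorted onto the new
topology by a deterministic greedy that assigns the largest remaining
weight to the edge with the largest residual endpoint-strength capacity,
updating residuals after each assignment. Degree sequences (per sign) and
the weight multiset are conserved exactly; strength sequences are
approximated with correlation ≈ 0.997 on dense 60-node matrices. Ensemble
size for SWC and Φ_norm denominators defaults to m = 100 in
`null_ensemble()` (m = 20 in the network-level convenience wrapper, which
is ample for ensemble means of global statistics).

`lattice_reference()` performs the same swap mechanics but accepts a swap
only when it reduces Σ|i − j| over edges — moving mass toward the
diagonal band under node-index ordering (the index is the only ordering
available to a generic network; any fixed ordering yields an equivalent
reference). A final re-sort places the largest weights most centrally in
the band. Banded matrices are fixed points; ER graphs gain transitivity.

## Consensus modularity

Modularity Q = Σ_c [e_c/m − (d_c/2m)²] is implemented directly and
cross-checked against an independent implementation in the test suite.
Single Louvain runs are stochastic in their node ordering, so community
structure is stabilized by consensus: 100 seeded restarts, a node-pair
co-assignment matrix, thresholding at 0.5, and re-clustering of the
thresholded co-assignment graph until all runs agree. A "median node
assignment" over label vectors is not a well-defined object; consensus
clustering preserves the intent (a stable affiliation vector) while the
run-to-run Q distribution is summarized separately by its median. The
resolution parameter is fixed at 1, labels are canonicalized by
descending module size, and the final Q is recomputed on the original
network. On every ≤ 8-node fixture the consensus attains the exhaustive
maximum over all set partitions (4140 for 8 nodes).

## AUC, FDR and the PCA inertia reference

Global metrics are summarized per subject as the trapezoidal AUC over the
density grid, in raw density-fraction units (0.06–0.32); the axis scaling
is a constant factor and cancels in group comparisons. Nodal statistics
across 60 nodes are controlled by Benjamini–Hochberg FDR at q ≤ 0.05
(delegated to `p.adjust`). Inferential machinery itself (ANOVA, MANOVA,
post-hoc tests) is out of scope: the package guarantees tidy per-subject
tables that drop directly into any standard routine.

For exploratory multivariate structure, `pca_inertia_test()` runs
correlation-matrix PCA (variables standardized — the summary tables mix
units) and compares the percent inertia of the first two dimensions
against `inertia_null_reference()`: the 95th percentile of the same
quantity across ≥ 2000 simulated standard-normal tables of identical
shape. For a 30-observation × 9-variable table this reference is ≈ 43.6%;
it decreases toward the isotropic limit 2/9 ≈ 22% as observations grow.

## The synthetic cohort generator

`cohort_spec()` defines the emulated study: three age groups × 10
subjects, 60 nodes, 600 timepoints. Each group's covariance is a block
matrix — unit diagonal, `rho_within` = 0.5 inside each of four 15-node
modules, `rho_between` outside — and the group effect is carried entirely
by `rho_between` (defaults 0.05, 0.10, 0.15 from youngest to oldest:
lower coupling, more segregated modules). Subject timeseries are
multivariate-normal draws plus i.i.d. Gaussian noise (`noise_sd` = 0.5,
i.e. noise variance one quarter of signal variance — a realistic
attenuation that leaves within-module correlations near 0.4), then
L2-normalized per node, which changes no correlation. A master seed
spawns per-subject streams, so any subject can be regenerated
independently of cohort size. Behavior tables draw per-group normal
deviates for margin distance, freezing counts (days 1–3) and fluid
volumes, truncated at zero.

What the generator does *not* emulate: hemodynamics, temporal
autocorrelation, scanner or motion artifacts, hub heterogeneity, or
group differences in anything but modular coupling. Consequences worth
stating plainly:

* Passing parameter-recovery tests (consensus Louvain recovers the
  planted 4 × 15 partition with ARI ≥ 0.9 at δ = 0.16, T = 600) shows the
  pipeline is correct, not that real cohorts of n = 10 have that power.
* Modularity-related group contrasts are faithfully recovered (lower
  `rho_between` → higher AUC-modularity in essentially every cohort
  regeneration). Assortativity contrasts are *not* reliably recoverable
  from this generator: with equal-size, equal-strength planted modules
  the group difference in strength assortativity is a second-order
  side-effect of cross-module edge admixture, far weaker than cohort
  sampling noise at n = 10. A generator that planted hub structure would
  be needed to encode that contrast; this one intentionally does not.

## Behavioral indices

The sucrose preference index is S_I = (s − w)/(s + w), undefined (NA,
flagged) at zero total intake. Fear-conditioning sessions follow the
standard cued layout (180 s baseline, four 20 s tones, 190 s intervals;
the last scored epoch ends at 870 s, inside the 17 min session); each
trial is scored over a 60 s epoch starting at tone onset (20 s pre-shock
tone + 40 s post-shock). A freezing bout must last ≥ 30 frames at 30 fps
(1 s). Bouts are assigned to the epoch containing their *start* — the
counting rule is not dictated by the definitions, so the package also
emits percent-time freezing (bout overlap clipped at epoch edges), which
is insensitive to that choice. Recall-day sessions reuse the same epoch
grid. Motion-index samples are averaged within the same epochs; empty
epochs are NA, never 0.

## Problem sizes and determinism

Default analyses (60 nodes, 14 densities, 100 Louvain restarts, null
ensembles of 20–100) run in seconds per subject. The package's own
validation suite uses 50 synthetic subjects for partition recovery and 20
cohort regenerations (2 × 10 subjects each) for direction-of-effect
checks — sizes at which the tested quantities' Monte-Carlo error is well
below the asserted margins. Every stochastic function takes a seed, all
cohort- or ensemble-level seeds derive deterministically from a single
master seed, and `run_pipeline()` writes a manifest (parameters, seeds,
output checksums) sufficient to reproduce a run bit for bit.

## Known limitations

* Negative retained weights (possible only at densities beyond any
  realistic sweep) trigger a warning; metrics then lose their [0, 1]
  guarantees.
* The SWM convention is one of several in circulation; compare values
  only within this package.
* `bootstrap_edge_threshold()` uses percentile intervals; with very few
  subjects (< 10) its implied density is only approximately calibrated.
* Consensus clustering can, in principle, fail to stabilize on
  pathological co-assignment structure; after 20 rounds the best single
  run is returned rather than looping forever.
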