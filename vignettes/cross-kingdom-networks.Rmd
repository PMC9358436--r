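---
title: "Cross-kingdom co-occurrence networks: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-kingdom co-occurrence networks: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Microbial co-occurrence networks summarize which taxa rise and fall
together across samples. Built from bacterial data alone they
misrepresent communities in which fungi (or other non-bacterial
kingdoms) shape structure: fungal nodes can be hubs, connectors between
bacterial modules, and drivers of stability. `xknet` implements a
complete comparison pipeline for this question: build a cross-kingdom
(bacteria + fungi) network and a bacteria-only network from the same
samples, then quantify what the fungal dimension changes — node
centrality, robustness to extinctions, connectance / transitivity /
modularity against degree-preserving nulls, and the nestedness of the
bacteria–fungi bipartite structure.

Because suitable paired bacterial–fungal datasets are scarce, the
package also ships a generative model — a generalized Lotka–Volterra
(gLV) community simulator — so that every stage of the pipeline can be
exercised, tested and calibrated on data with known ground truth.

## The gLV model and its conventions

Community dynamics follow

$$\frac{dx}{dt} = D(x)\,(r + A x),$$

with abundances $x(t) \ge 0$, intrinsic growth rates $r$ (1/time), and
the community matrix $A$ (1/(abundance·time)). We use the convention the
ODE itself imposes: `A[i, k]` is the per-capita effect of species *k* on
species *i* (row = affected). Statements phrased in the opposite
direction ("the effect of *i* on *j*") are read as `A[j, i]`;
`classify_interaction()` does this translation internally, so its truth
table matches the ecological reading: *i* preys on *j* when *i* harms
*j* while *j* benefits *i*; two negative cross effects are competition;
two positive, mutualism; one-sided effects are commensalism/amensalism.

### Integration to steady state

`integrate_to_steady_state()` uses the adaptive LSODA solver in probe
windows of 5 time units. A state is declared steady when every surviving
species changes by less than `rel_tol` (default 1e-6, relative) over a
window; `t_max` defaults to 1000 time units and a run that exhausts it
is flagged non-converged rather than trusted. Species dropping below
`extinct_eps` (1e-8) are clamped to exactly 0 at window boundaries:
extinction is absorbing in gLV, and exact zeros make "extinct stays
extinct" a testable invariant. Tiny negative round-off is clamped to 0.
On convergence the surviving subcommunity is polished by solving the
linear fixed-point system $A_{SS} x_S = -r_S$ (accepted only when
positive and within 10% of the integrated state), so interior steady
states satisfy the fixed-point equations to machine precision rather
than to solver tolerance.

Trajectories that diverge (positive feedback exceeding
self-limitation) are reported as blow-ups, never clipped. The subset
simulator converts blow-ups into per-subset flags with a warning; such
subsets are excluded from downstream correlation, mimicking the fact
that an unbounded trajectory is not a community sample.

### What the generator emulates — and what it does not

`sample_glv_model()` + `simulate_subset_profiles()` + `sample_reads()`
emulate a two-kingdom amplicon survey: each "sample" is a random subset
of the species pool (independent Bernoulli inclusion, probability 0.5,
subsets below 2 species resampled) integrated to steady state, then
sequenced as one multinomial draw per sample. Defaults define the
package's simulated study:

| parameter | default | rationale |
|---|---|---|
| species pool | 40 bacteria + 15 fungi | bacteria-dominated pool, fungal minority, typical of seed endophyte surveys |
| samples (subsets) | 150 | enough for rank correlations at q ≤ 0.05 after BH over ~1,500 pairs |
| connectance target | 0.12 | sparse interactions, realized fraction of interacting pairs |
| interaction scale | 0.3 (half-normal) | weak-interaction stability regime: $\sigma\sqrt{nC} \approx 0.8 < 1$ keeps most random subsets bounded while leaving a detectable co-occurrence signal |
| self-limitation | 1 | sets the abundance/time scale; off-diagonal effects are relative to it |
| sign mix | competition .35, predation .35, mutualism .10, commensalism .10, amensalism .10 | negative-interaction-dominated communities are the stable, empirically typical regime; unconstrained mutualism destabilizes gLV |
| growth rates | Uniform(0.5, 1.5) | all species viable in monoculture |
| read depth | 50,000 | typical post-filtering amplicon depth |

The generator does **not** emulate: compositional coupling beyond the
multinomial constraint, sequencing overdispersion or contamination,
sample covariates (host genotype, site), phylogenetic signal in
interactions, or time-varying environments. Tests passing on simulated
data therefore validate the *pipeline's computations*, not the
inferential power of co-occurrence analysis on any real dataset.

## Network construction

Correlations are Spearman on relative abundances (Pearson available).
Taxa present in fewer than 20% of samples, and constant taxa, are
excluded before testing. Two-sided p-values come from the
t-approximation; an exact permutation option exists for very small
sample counts. BH adjustment is applied over the upper triangle of the
pair matrix, and an edge requires `q <= q_max` and `|rho| >= rho_min`.
A centered log-ratio transform (`clr_transform()`, pseudocount 0.5) is
provided for users worried about compositional artifacts but is off by
default: the pipeline correlates raw relative abundances.

Package defaults are `q_max = 0.05`, `rho_min = 0.6`. The simulated
analyses in `analysis/` and the pipeline configuration use
`rho_min = 0.35` instead: in the weak-interaction regime chosen for
stability, between-taxon rank correlations rarely exceed 0.6, and 0.35
with BH control at n = 150 samples still bounds the pair-level false
discovery rate. Both are configuration knobs, not constants.

Nodes without a surviving edge are dropped at build time, so "n nodes"
means "connected taxa", the convention under which published
co-occurrence node counts are reported. Single-kingdom networks are
rebuilt from the kingdom-restricted table — relative abundances
recomputed within the kingdom — not by deleting fungal nodes from the
joint network, which would conflate node removal with inference.

## Topology

All metrics treat the graph as simple, undirected and unweighted; edge
signs are carried as attributes but ignored by topology, robustness and
null analyses. Betweenness uses exact shortest-path counting, reported
both raw and normalized by $(n-1)(n-2)/2$. Eigenvector centrality is
the dominant eigenvector (unit Euclidean norm) of the adjacency matrix
of the largest connected component, computed by dense symmetric
eigendecomposition for determinism; nodes outside that component get 0
with a warning — co-occurrence networks are routinely disconnected and
a per-component eigenvector has no common scale. Modularity uses greedy
agglomerative (CNM) maximization; we cut the merge tree at the step of
maximum Q ourselves because the library cut can be sub-optimal on very
small graphs. The modularity of any user-supplied partition is also
available (`modularity_q()`).

Paired centrality comparison (`compare_centrality()`) matches nodes by
taxon id between the bacteria-only and cross-kingdom networks and
reports per-node deltas plus counts above/below the y = x line — the
loess smoothing some figures add on top of such scatters is
presentation, not analysis, and is out of scope.

## Robustness with secondary extinctions

Attack orders (degree, betweenness, eigenvector, each highest-first
with lexicographic tie-breaks; or seeded random) are computed **once**
on the intact network. Recomputing centralities after every removal is
available behind a flag (`attack_order(recompute = TRUE)`) for
sensitivity analysis, but the static order is the primary mode. After
each primary removal, every surviving node whose degree has dropped to
0 is removed as a *secondary extinction* — node removal through loss of
all edges — and counts toward the x-axis fraction extinct. One sweep
suffices because removing degree-0 nodes deletes no edges. The y-axis
is the current largest component divided by the *initial largest
component* (not the node count), so a curve can stay at 1 while a
smaller component dies. The AUC is the trapezoid rule over recorded
events; random attacks are summarized over 100 replicate orders by
default.

## Null models and Z-scores

For unipartite network summaries the configuration null is the
double-edge swap: `swap_factor × m` attempted swaps, rejecting
self-loops and multi-edges, which preserves every node's degree — and
therefore node count, edge count and connectance — exactly. The
curveball algorithm, which is defined for binary matrices, is reserved
for the bipartite nestedness null; both preserve the same margins,
which is visible in the data as SD(connectance) = 0 across the null
ensemble. For that reason Z-score normalization has a fallback: when
the null SD is exactly zero (sample SD below 1e-12 is snapped to zero),
the statistic is normalized by dividing by the null mean, which for
connectance yields exactly 1 on every network. A normalized connectance
that *differs* between networks cannot arise under a degree-preserving
null; the pipeline reports the rule-consistent value. If a null
ensemble is degenerate (mean and SD both zero — e.g. transitivity on
sparse graphs whose randomizations never form a triangle),
`summary_zscores()` reports `NA` with rule `"degenerate"` and a
warning instead of failing.

## Nestedness (NODF)

NODF over the bacteria × fungi incidence matrix (a 1 wherever any
significant bacteria–fungus edge exists, sign ignored): for every pair
of rows and every pair of columns with strictly *decreasing* marginal
fill, the paired term is 100 × (shared presences) / (fill of the
sparser line); equal-fill pairs contribute 0; the total is the mean
over all $\binom{R}{2} + \binom{C}{2}$ pairs. Empty rows and columns
are dropped first. This is order-invariant, so no pre-sorting is
needed. The permutation test runs a curveball chain with the observed
margins — burn-in 5·max(R, C) trades, one sample every R trades,
1000 samples by default — and reports the add-one one-sided p-value
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n)$, which cannot be
0. Margins that admit a single configuration give p = 1 with a
warning. Note that fixed-margin nulls absorb any nestedness that the
degree sequences themselves force; the test asks whether the *overlap
structure* exceeds what the margins imply, which is the conservative
question.

## gLV inference

`infer_glv()` uses the identity
$d\log x_i/dt = r_i + \sum_k A_{ik} x_k$: the forward-difference
log-derivative of each species is regressed on the midpoint abundances
of all species plus an intercept. The intercept (the growth-rate
estimate) is unpenalized; interaction coefficients carry an L2 penalty,
solved in closed form — a transparent ridge with exact penalty
semantics. Increments where a species is at or below `min_abundance`
(default 1e-6) on either end are unusable for that species: logs of
numerical zeros carry no signal, and gLV provides no information about
a species that is absent. Species never exceeding the threshold are
excluded with a warning (zero rows/columns in the estimate, `NA`
growth rate).

Two design facts matter in practice and are reflected in the analysis
scripts:

* **Sample the transient.** Once a community sits at steady state the
  regression design matrix is constant and the increments are pure
  noise. Dense sampling of the growth phase (low inoculum) carries
  almost all the information.
* **Pool replicate series.** A single series cannot identify an
  $n^2$-entry matrix for more than a handful of species. `infer_glv()`
  accepts a list of trajectories (e.g. replicate growth curves from
  different inocula) and pools their increments.

Effects weaker than the attainable resolution are classified "neutral"
on both sides when comparing inferred and true interaction labels: a
sub-threshold effect is below the detection limit, not an error.

## Determinism and seeds

Every stochastic operation takes an explicit integer seed; composite
procedures derive per-stage/per-replicate sub-seeds from one master
seed via `sub_seed()` (a Lehmer-style mix kept below $2^{31}$). The
full pipeline (`run_full_comparison()`) is byte-for-byte reproducible
from its configuration plus master seed; its JSON report carries no
timestamps for that reason, and every condition uses the same derived
stream so that identical condition specifications produce identical
report sections.

## Problem sizes

The test-suite and acceptance computations use: communities of 2–8
species for closed-form and oracle checks; a 60-node
preferential-attachment fixture with 100 random-attack replicates for
the targeted-vs-random contrast; 200 random matrices up to 8×8 for the
NODF oracle; 10,000 curveball trades for margin conservation and
10,000 chain samples for the 3×3 uniformity check; and the full
two-condition pipeline at 40 bacteria + 15 fungi with 150
subset-samples per condition. These sizes were chosen so every
statistical check has comfortable power while the whole suite remains
quick to run on a laptop.

## Known limitations

* Correlation networks on the simulator's subset design mix two signal
  sources — co-exclusion through interactions and co-absence through
  subset membership; the permutation sanity test controls for the
  latter, but real-data artifacts (compositionality, batch effects) are
  not modelled.
* Ridge inference recovers sign patterns reliably only for interactions
  comfortably above the noise floor; weak effects are reported but
  should be read as undetermined.
* The degree-preserving null cannot produce network-dependent
  normalized connectance (the ratio rule forces 1); comparisons of
  normalized connectance across networks are therefore uninformative
  under this null family.
* Robustness uses static attack orders by default; recomputed orders
  (available via a flag) are strictly more damaging on some topologies.
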