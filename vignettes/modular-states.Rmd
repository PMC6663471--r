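---
title: "Detecting modular states in dynamic brain networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting modular states in dynamic brain networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modstates)
```

## The problem and the model

A dynamic functional connectivity analysis produces a tensor
`W[, , t]`, `t = 1..T`: one symmetric weighted network per sliding time
window. The working hypothesis of this package is that the *modular*
organization of these networks — which groups of regions form densely
intraconnected communities — is piecewise stable: the recording visits a
small number of **modular states**, each a set of windows sharing one
modular decomposition. The method makes no assumption about how the
connectivity was computed (PLV, envelope correlation, coherence, ...),
only that each slice is symmetric with a zero diagonal.

The pipeline has three stages.

**1. Per-window consensus decomposition.** Modularity optimization is
stochastic and degenerate: single runs land in different local optima.
Each window is therefore decomposed by an ensemble — by default 200
seeded Louvain runs plus one (deterministic) leading-eigenvector run —
whose node co-assignment counts form an association matrix `A`. Counts
that a permutation null explains (each run's labels shuffled across
nodes, preserving module sizes; pooled off-diagonal counts; `1 - alpha`
quantile) are zeroed, and the surviving matrix is reclustered with
Louvain. If the reclustering runs disagree, the procedure recurses once
on the association matrix of the reclustered ensemble and takes the
majority partition.

**2. Window similarity.** Two partitions are compared by the z-score of
the Rand coefficient: `w` is the number of node pairs co-assigned in
both partitions, standardized by its mean and variance under the
permutation model with fixed module sizes. Both moments are computed
exactly by classifying pairs of co-pairs as identical, node-sharing or
disjoint; the unit tests verify them against exhaustive enumeration of
all node permutations for small `N`. Because a raw z-score is unbounded,
the similarity used downstream is `max(0, z12) / sqrt(z11 * z22)`,
which is 1 exactly when the partitions agree up to relabeling and 0 when
pair agreement is at or below chance. Degenerate partitions (all
singletons, one module) have zero self-score and are assigned
similarity 0.

**3a. Categorical states.** The `T x T` similarity matrix is treated as
a weighted graph over windows and clustered with the same consensus
procedure; each window community is a state, summarized by the consensus
partition of its member windows' affiliations. Because every member
window carries an independent noise realization, spurious co-assignments
cancel at this stage and only the reproducible modular backbone
survives. Windows of background activity typically collect into one
additional community of their own; it matches no reference structure and
is reported as unmatched by the validation tools.

**3b. Consecutive states.** For task data the temporal order matters.
The similarity matrix is converted to an empirical p-value map against a
null of label-permuted partition pairs (one pooled null sample shared by
all entries), thresholded by Benjamini–Hochberg at `fdr_q`,
median-filtered (edge-replicated `median_kernel x median_kernel`
window), and scanned along the diagonal. A segment anchored at `i` with
current extent `j` admits the next window iff the mean of that window's
similarities to all segment windows (both triangles, its self-similarity
counted once — `2(j+1)+1` terms) exceeds the accuracy parameter `a`;
on rejection the segment closes and the rejecting window becomes the
next candidate anchor. Closed segments are kept when they span more
than `j_min` windows.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `runs_per_algorithm` | 200 | Louvain ensemble size per window; the leading-eigenvector method is deterministic and contributes one run. Smaller ensembles (15–50) already stabilize the consensus on networks of a few hundred nodes. |
| `resolution` | 1.0 | Louvain resolution; 1 is classic modularity. |
| `null_alpha` | 0.05 | significance level of the association-matrix pruning. |
| `null_permutations` | 100 | permutation repetitions for the association null. |
| `fdr_q` | 0.05 | BH level for the similarity p-value map. |
| `median_kernel` | 3 | spatial extent (windows) of the similarity smoothing. |
| `accuracy_param` | `"auto"` | segmentation admission threshold in (0,1); `"auto"` = mean of the thresholded, filtered similarity matrix. A high value erases genuine states in a low-similarity matrix, a low value glues distinct ones; the mean adapts to the overall similarity level. |
| `j_min` | 1 | minimal segment length: segments must span *more than* `j_min` windows, so the default only discards single-window segments. Raise it when windows are so short (e.g. millisecond-resolved connectivity) that brief segments are physiologically implausible. |

Every stochastic step derives its seed from one master seed
(`seed + run index`, plus fixed offsets per stage), so whole fits are
bit-reproducible and the caller's RNG state is never modified.

## Signed weights

The simulator adds zero-mean Gaussian noise to the edge weights, so
background windows are zero-mean signed networks. Clipping negative
weights at zero turns such windows into dense all-positive random graphs
on which Louvain finds large, partially run-stable noise communities;
these inflate the pair-counting normalization and destroy the contrast
of the similarity matrix. The package therefore keeps the sign and
optimizes a two-layer signed modularity (positive and negative weight
layers with separate configuration-model null terms, as in the common
brain-connectivity toolbox treatment of signed networks): negative
weights act as repulsion, pure-noise windows fragment into small
unstable modules that the consensus null removes, and windows with a
genuine planted structure keep it. On nonnegative input the objective
reduces exactly to classic weighted modularity. Nonnegativity is still
enforced for tensors read from files (measured connectivity magnitudes);
the simulator opts in to signed weights explicitly, and a
`clip_negative` switch reproduces the clipped variant.

## The simulation scenario

`simulate_dfc()` emulates a standard benchmark for dynamic network
detection: four reference networks over an anatomical parcellation of
221 regions, each activated over a 60-s recording sampled every 0.3 s
(T = 200). The time course of network `j` is
`M_j(t) = f1_j(t) * (a_signal + b_noise * g_j(t))` on its activation
epochs and 0 outside: `f1_j` is a unit-amplitude Hanning window per
epoch, `a_signal = 0.45`, `b_noise = 0.15`, and `g_j` is a unit-variance
AR(1) process (correlation time `b_noise_corr_s = 1` s) modelling the
slow amplitude fluctuation of the active network's time course. The
tensor is `W(t) = sum_j M_j(t) P_j + E(t)` with `E(t)` symmetric
Gaussian edge noise of SD `tensor_noise_std` (0.2–0.5 is the studied
range).

The shipped scenario (an editable JSON fixture,
`extdata/default_scenario.json`) was designed once, as follows, and then
frozen:

* each reference network is a *coarse* modular decomposition of the
  atlas into 2–3 large modules with node membership shuffled
  independently per network, so the four planted partitions are mutually
  near-orthogonal (pairwise normalized z-Rand < 0.01); networks 1–3
  leave ~10% of nodes as background, network 4 covers all nodes;
* within-module weight 0.7, making the peak planted amplitude
  `0.45 * 0.7` roughly 1.6 standard deviations of the baseline edge
  noise — structures are comfortably detectable at epoch centres and
  progressively lost along the Hanning ramps, which is what produces
  temporal-recall values below 1;
* five epochs (networks 1–4 in sequence, plus a repeated short
  activation of network 2 at 57.5–60 s) separated by background gaps.

What the simulation deliberately does **not** model: source leakage and
volume conduction (which correlate neighbouring regions), the spatial
autocorrelation of real parcellations, non-Gaussian connectivity noise,
overlapping window estimates (consecutive simulated windows are
independent given the amplitudes), and gradual state transitions.
Passing the simulation study therefore demonstrates that the estimator
recovers planted modular dynamics under honest noise, not that real
M/EEG state sequences will be recovered at the same accuracy.

## Numerical choices and degenerate inputs

* Association pruning uses strict `>` against the null cutoff; ties are
  zeroed (conservative). The null quantile is pooled over entries rather
  than per-entry — a per-entry null would need far more permutations for
  the same resolution and the pooled version matches the closed-form
  binomial check in the tests.
* Proportional thresholding keeps all edges tied at the cutoff value, so
  it is deterministic, order-independent and idempotent.
* The empirical FDR p-values for tensor edges count null draws strictly
  greater than the observed weight, so a weight never counts as evidence
  against itself; ties between distinct edges have measure zero for
  continuous weights.
* `zrand` returns 0 with a warning when the permutation variance
  vanishes; the similarity matrix forces its diagonal to 1.
* The auto accuracy parameter is clamped just below 1 so that a
  uniformly identical recording (all-ones similarity matrix) yields one
  spanning segment instead of none; an all-zero matrix yields none.
* Segment length uses the strict rule (`length > j_min`); with the
  default `j_min = 1` this drops single-window segments, which also
  removes an artifact of edge-replicated median filtering at the matrix
  corners (the corner diagonal keeps its own replicated value).
* Empty graphs decompose into singletons with a warning; an association
  matrix that is empty after pruning likewise returns singletons.
* State matching maximizes total spatial similarity (exact Hungarian
  assignment) with a 0.01-weight temporal-overlap tiebreak, needed
  because a network that activates twice contributes two truth states
  with identical partitions; detected states below spatial similarity
  0.5 stay unmatched and count toward the false positive rate.

## Validation scale

The packaged checks run the full scenario (N = 221, T = 200) with
ensembles of 15–20 Louvain runs per window, 3 replicates per noise level
(0.2, 0.35, 0.5), and the acceptance script averages 5 replicates at
noise 0.2 with 20-run ensembles; these sizes were chosen as the package's
validation scale and give seed-to-seed standard deviations of a point or
two on the accuracy percentages. The full 200-run ensemble changes the
results only marginally (the consensus has long saturated) and can be
reproduced by passing `consensus_config(runs_per_algorithm = 200)`.

## Known limitations

* Temporal similarity is recall of a true state's windows; a detected
  state that claims extra background windows is not penalized there but
  only through the false positive rate (and only when the claiming state
  matches no reference structure).
* At the upper end of the studied noise range the FDR step lets a small
  number of spurious similarity entries through (that is what q = 0.05
  means), which occasionally yields one short spurious segment in a
  replicate; the five genuine states remain recovered.
* The consecutive scheme cannot represent overlapping or recurring
  states within one segment scan; a recurring structure appears as
  separate segments (intentionally, per the sequential design).
* Categorical clustering assigns *every* window to some community;
  interpretation should focus on communities that match a reference or
  that are temporally coherent.
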