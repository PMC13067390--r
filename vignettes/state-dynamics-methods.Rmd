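---
title: "Methods: two-state dynamic connectivity, group statistics and mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-state dynamic connectivity, group statistics and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcstates)
```

# The analysis model

`dfcstates` implements a resting-state functional-connectivity (FC) pipeline
for studying sex differences in brain integration and segregation, together
with a synthetic-cohort generator so that every stage can be exercised and
validated without access to restricted fMRI data.

## Static connectivity and graph parameters

Static FC between two ROI time series is the Fisher-z transformed Pearson
correlation, $z = \operatorname{atanh}(r)$, with $r$ clipped to
$\pm(1 - 10^{-7})$ so degenerate inputs (perfectly correlated synthetic
columns) cannot produce infinities that would poison downstream clustering.
Self-connections are fixed at 0 and excluded everywhere.

For graph analysis the z-matrix is prepared in the convention of the standard
brain-connectivity tooling: negative weights are set to zero (the weighted
metrics below are defined for nonnegative weights) and the matrix is divided
by its maximum so all weights lie in $[0,1]$. Two parameters are computed:

* **Global efficiency** (integration):
  $E = \frac{1}{n(n-1)} \sum_{i \ne j} 1/d_{ij}$, where $d_{ij}$ is the
  weighted shortest-path length with edge length $1/w$; disconnected pairs
  contribute 0. Max-normalizing weights first puts $E$ in $[0,1]$, the
  magnitude range on which group differences in efficiency are reported.
* **Modularity** (segregation): Newman's weighted
  $Q = \sum_c \left( e_{cc}/W - \gamma\,(a_c/W)^2 \right)$, maximized by the
  Louvain heuristic at resolution $\gamma = 1$ with 20 seeded restarts
  (best Q kept; ties broken by the canonical label sequence). Tests verify
  against exhaustive enumeration of all partitions on graphs of up to 8
  nodes that the restart scheme attains the global optimum there.

No density thresholding or sparsification is applied; the negative-weight
and normalization conventions are the package's own choices, recorded in the
per-run provenance, because the weighted-metric variants in use differ
between toolboxes.

## Sliding-window dynamics and the two-state model

Dynamic FC recomputes the z-matrix in rectangular windows stepped one TR at
a time, giving $n_\text{frames} - w + 1$ windows. The default window is 55
TRs at TR = 0.720 s (39.60 s); the matched companion setting is 40 TRs at TR
= 0.987 s (39.48 s). No taper is applied and no detrending beyond the
correlation's implicit demeaning; the pipeline starts from already
preprocessed time series.

All subjects' window matrices (upper-triangle vectorized) are pooled and
clustered by **k-means with k = 2 under cosine distance** — one group-level
model, so both states share cohort-level centroids. The implementation is
spherical k-means: rows are L2-normalized, centroids are updated as the
renormalized mean, and the best of `n_init = 100` k-means++-style seeded
restarts (tolerance $10^{-6}$, 300 iterations) is kept. Exhaustive
enumeration of all two-partitions on small pools confirms the restart scheme
reaches the global cosine-inertia optimum. Centroids are reported
un-normalized, as the mean of the raw assigned vectors, for
interpretability.

The centroid with the **higher global efficiency is labeled I**
(integrated); the other is S (segregated). The labeling premise — that the
same centroid also has lower modularity — is checked and a warning raised on
disagreement (efficiency decides). Windows are assigned to the
cosine-nearest centroid, with exact ties broken toward S (a documented,
arbitrary convention; ties essentially never occur on real-valued data).

Per subject, four dynamic parameters summarize the state sequence:

* **Prev** — percent of windows in each state; `prev_s + prev_i = 100`
  exactly.
* **MDT** — mean length of maximal constant runs of a state, in seconds.
  Boundary (censored) runs are included by default: excluding them would
  discard most of the data for subjects with long dwellings. A subject that
  never visits a state has no MDT there and is excluded from that
  parameter's group statistics, which is what produces parameter-specific
  group sizes.
* **ITI** — mean spacing between consecutive transitions, in seconds;
  absent with fewer than two transitions. For interior runs the ITI equals
  the mean run duration, so it approximates the mean of the dwell times.
* **Var** — 100 times the mean cosine distance of a subject's state-assigned
  window vectors from the subject's own mean vector for that state (one
  window gives 0). This is our concrete reading of "the extent of the
  within-subject state cloud"; the exact formula used by the original
  toolchain is not published, so the definition is exposed as a module-level
  choice rather than buried.

## Group statistics

Group comparisons (males minus females) report per-sex n, mean, SD and
median, a two-sample t-test, a Mann-Whitney U test, and Cohen's d with a 95%
CI:

* **Student vs Welch**: published tables mix integer and fractional degrees
  of freedom without stating a rule. The default here is data-driven — a
  Brown-Forsythe (median-centered Levene) test at p < 0.05 switches to
  Welch — with an explicit per-comparison override so either variant can be
  reproduced.
* **Sidedness**: directional hypotheses (modularity lower, efficiency
  higher, Prev_S lower, MDT_S lower, Var_I higher in males) are one-sided;
  everything else two-sided; no multiple-comparison correction, the tests
  being treated as independent hypotheses.
* **Cohen's d**: pooled-SD standardized difference; the CI uses the
  normal-approximation standard error
  $\sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}$, which reproduces printed
  interval bounds; a noncentral-t interval is available behind a flag.
* **Mann-Whitney U**: exact when $n_1 n_2 \le 400$ with no ties, otherwise
  the tie-corrected continuity-corrected normal approximation; tests check
  the exact branch against full enumeration of group assignments.
* **Chi-square balance tests**: Pearson goodness-of-fit against an equal sex
  split within a dataset, and an uncorrected Pearson 2x2 test between
  datasets.
* **Reliability of an average**: with single-session ICC $\rho$, averaging
  $m$ sessions gives $m\rho / (1 + (m-1)\rho)$ (at $\rho = 0.5$, $m = 2$:
  0.67).

## Mediation

The mediation stage asks whether sex differences in behavior run through
brain integration (default mediator: Prev_I). Variables are screened by
Pearson correlation with sex and with the mediator, both required to pass a
Bonferroni threshold of $0.05/66$; for a binary sex code the correlation
test is algebraically the pooled t-test, an equivalence asserted in the test
suite. The path model is single-mediator OLS with sex kept on its 1/2
coding and mediator/outcome standardized to variance 1 on the analysis
sample (not re-standardized inside bootstrap resamples):
$a$ from $M \sim \text{sex}$, $(c', b)$ from $Y \sim \text{sex} + M$, and
the total effect $c$ from $Y \sim \text{sex}$, satisfying
$c = c' + ab$ exactly. The indirect effect $ab$ gets a 95% **percentile**
bootstrap CI from 5000 subject resamples (the minimal reading of "bootstrap
samples"; BCa was considered and left out as unspecified), significant when
the CI excludes zero. Resamples with constant sex are redrawn and counted.
No correction is applied across mediation analyses. Coverage of the true
$ab$ is verified by simulation to sit at 95% within 2 points at n = 500.

# The synthetic cohort: what it emulates and what it does not

The generator stands in for restricted fMRI data; no generative model was
ever published for those data, so all distributional choices here are
explicit stand-ins:

* Each subject's frames are zero-mean, unit-variance multivariate Gaussian
  draws whose correlation switches between a block-modular **segregated**
  matrix (within-module r = 0.6, cross-module 0.10) and an **integrated**
  matrix (cross-module 0.45) under a first-order Markov chain. The implied
  matrices are validated positive semi-definite at construction.
* Switch probabilities are sex-specific and were derived once from the
  published group dynamics: stationary segregated-state occupancy 35%
  (males) vs 48% (females) — a ~13 percentage-point gap — with mean
  segregated dwell times near 40 s and 52 s, giving
  $(p_{S\to I}, p_{I\to S})$ = (0.0180, 0.0097) for males and
  (0.0139, 0.0128) for females at TR 0.720 s.
* No within-state autocorrelation is modeled: windows (55 TRs) are long
  relative to BOLD autocorrelation, and the simplest model consistent with
  the assumed covariance switching was preferred. State switches occur at
  frame resolution, so windows spanning a switch have mixed covariance —
  accepted as realistic blur.
* A single global seed is expanded deterministically into per-subject
  streams, so any subject is reproducible in isolation.
* FD series are gamma baseline motion (median ≈ 0.14 mm) plus a controlled
  fraction of spikes ≥ 0.5 mm to exercise the "more than 7.5% of frames"
  exclusion rule exactly at its boundary.
* Behavior follows the linear mediation model with the subject's true
  integrated-state occupancy available as mediator.

Because the generator is Gaussian, stationary-within-state and
autocorrelation-free, passing tests demonstrate that the pipeline recovers
planted structure under these idealized conditions — not that real BOLD
data satisfy them. In particular the within-state dispersion (Var) of
synthetic windows is far smaller than in real data, and no claim about
empirical Var scales is made or tested.

# Numerical choices and degenerate inputs

* Correlations are clipped before `atanh`; constant ROI columns are rejected
  by name at the static stage, and a window-constant column inside one
  sliding window yields a 0 correlation for that window.
* k-means rejects a pool with fewer than two distinct vectors; empty
  clusters are refilled with the worst-fit point.
* State labeling rejects centroids whose efficiencies agree to $10^{-12}$.
* The FD rule is strictly "more than": a spike fraction of exactly 7.5%
  passes.
* All stochastic steps (subject simulation, Louvain restarts, k-means
  seeding, bootstrap) are seeded; identical configurations reproduce
  identical outputs bitwise.

# Problem sizes used in validation

Test and acceptance runs use deliberately scaled-down cohorts chosen as the
smallest sizes at which the planted effects are comfortably identifiable:
8-20 ROIs in 2-4 modules, 250-1200 frames, 8-80 subjects, and the
well-separated covariance regime (cross-module 0.05 vs 0.45). The headline
recovery checks are: Spearman correlation > 0.9 between recovered and
generative segregated-state occupancy across 40 subjects; the planted
~13-point sex gap in Prev_S recovered with the planted sign in at least 95%
of 40 seeded 80-subject cohorts (450 frames each); and bootstrap CI coverage
within 2 points of 95% over 500 replicates at n = 500 (1000 resamples per
replicate — the coverage simulation's depth, distinct from the 5000-resample
analysis default).

# Known limitations

* The modularity maximization is heuristic; optimality is only guaranteed
  (and only checked) on small graphs.
* The Var definition and the censored-run convention for MDT are plausible
  readings of under-specified published procedures; both are flagged
  configurable rather than claimed authoritative.
* The mediation model is single-mediator OLS with percentile bootstrap: no
  latent variables, no robust standard errors, no moderated mediation.
* The pipeline neither ingests neuroimaging volume formats nor performs any
  preprocessing; input is parcellated time series in delimited text.
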