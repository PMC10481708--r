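---
title: "Topological analysis of functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological analysis of functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnc)
```

## The model

Resting-state fMRI yields, after standard preprocessing, one averaged signal
per brain region — here the 90 cerebral regions of the AAL atlas. Static
functional connectivity between regions $i$ and $j$ is the sample Pearson
correlation $m_{ij} = \mathrm{corr}(P_i, P_j)$ of their time courses, and the
brain network is turned into a finite metric-like space by

$$ d(P_i, P_j) \;=\; 1 - \mathrm{corr}(P_i, P_j). $$

Strongly coupled regions are close, uncorrelated regions sit at distance 1,
anti-correlated regions at 2. Note $1-r$ need not satisfy the triangle
inequality; nothing in this package assumes it does.

On this space we build the Vietoris–Rips complex $VR(Z, \delta)$: every
region is a vertex, an edge $[ab]$ enters when $d(a,b) \le \delta$, and a
higher simplex enters when all of its edges have. Sweeping
$\delta \in [0, t_{max}]$ gives a nested filtration, and persistent homology
tracks its topological features across all scales at once: $\beta_0(\delta)$
counts connected branches, $\beta_1(\delta)$ counts independent loops. Each
feature is a Betti interval $[\delta_{birth}, \delta_{death})$ — it exists
for $\delta_{birth} \le \delta < \delta_{death}$ — and the interval set is
the barcode.

The package's feature of interest is the **functional connectivity neural
circuit (FCNC)**: a 1-dimensional cycle of the brain's VR complex, localized
by the representative cycle stored when its class is born. From the barcodes
we derive, per scan and threshold, the number of circuits each region
participates in, and the number of circuits of a given length (edge count).
Two groups of scans are then compared feature-by-feature with two-sided
Mann–Whitney $U$ tests plus Benjamini–Hochberg FDR, and curve-wise with
two-sample Kolmogorov–Smirnov tests on pooled Betti numbers.

## Parameters that matter

* `d_max = 2` — simplices up to triangles. Triangles are what fill loops;
  without them $\beta_1$ would only ever grow. Dimensions above 2 would only
  matter for $\beta_2$, which is out of scope.
* `t_max = 0.9` (dimensionless distance) — the filtration stops at $d = 0.9$,
  i.e. only pairs with $r \ge 0.1$ ever connect. Negative and near-zero
  correlations therefore never form edges, which is this pipeline's implicit
  handling of negative correlation. Loops still open at `t_max` are reported
  with `death = Inf` (right-censored), not discarded.
* `divisions = 450` — resolution of the reported Betti curves
  (grid step $0.9/450 = 0.002$). The grid is purely a sampling device:
  filtration values of simplices and barcode endpoints are exact pairwise
  distances, never snapped to the grid.
* FCNC thresholds `0.7, 0.8, 0.9` — the circuit census is taken cumulatively
  at these three scales (see below).
* `medium_length = 8` — "medium" circuit length is a configuration
  parameter, not an inferred quantity; 8 is a sensible default for 90-node
  correlation networks, and the right value is dataset-dependent.
* `alpha = 0.05` with BH-FDR q-values.

## Interpretive choices

**Cumulative births, zero-length bars.** The FCNC set at threshold $\delta$
is every dim-1 interval with $birth \le \delta$, regardless of death. Counts
are then non-decreasing in $\delta$ and typically saturate between 0.8 and
0.9 — the qualitative signature such per-region count tables show — whereas
"alive at $\delta$" counts fall again as holes fill. By default the census
skips bars of zero persistence: a cycle-closing edge that is itself the
longest edge of some triangle is filled at the very value where it was born,
and in dense correlation graphs these instantly-filled cycles outnumber
genuine circuits by an order of magnitude (a 90-region scan routinely has
~1,700 dim-1 births but only ~100–200 with positive persistence). Treating
zero-length bars as noise keeps per-region counts on a meaningful scale;
`include_zero = TRUE` restores the literal count.

**Representatives.** A class's representative is the reduced-column cycle at
birth — the standard output of the reduction, with deterministic tie-breaks
(equal filtration values are ordered by dimension, then lexicographically by
vertices), so reruns give identical representatives. It is *not* a shortest
cycle; shortest-cycle tightening is deliberately out of scope. Per-region
circuit counts inherit this convention, and early short edges are reused by
many representatives, concentrating counts on tightly coupled regions. Any
localization of a homology class involves such a choice; this package
isolates it behind `extract_fcnc()`.

**FDR family.** `compare_groups()` defaults to correcting each feature
within its own three thresholds (`m = 3`), which is the convention that
reproduces published per-region q-value triples from their p-values. For
whole-brain discovery — "is *any* region flagged?" across 90 regions — that
family is too small: under a complete null the chance that some region
somewhere clears `q < 0.05` approaches certainty. The recovery and type-I
analyses therefore use `fdr_scope = "global"`, pooling all features and
thresholds into one BH family, which under the complete null keeps the
probability of any rejection near $\alpha$. Both scopes are exposed; the
choice is reported with the results.

## The synthetic generator

Real scans are replaced by a generator whose ground truth is known exactly.
Each scan is an independent multivariate normal time series
($n_{t} = 127$ time points by default, matching a 137-volume acquisition
minus 10 discarded volumes; 90 regions) with unit-variance margins,
a uniform background correlation (default 0.1), and planted "cycles": rings
of regions whose *ring-adjacent* pairs correlate at `within_cycle_corr`
(default 0.8). Adjacency-only correlation is the point — correlating all
pairs within the ring would create a filled clique (no hole), while a ring
of short edges with long chords is a genuine $\beta_1 = 1$ structure by
construction.

A ring of high adjacent correlation over a low background is generally not
positive semidefinite as written (the alternating-sign vector around an even
ring has negative eigenvalue), so the target is projected to the nearest PSD
correlation matrix by eigenvalue clipping at $10^{-10}$ and renormalization.
The projection moderates the requested values — adjacency 0.8 over
background 0.1 lands near 0.66 — but preserves the planted topology: ring
edges sit at population distance $\approx 0.34$, chords at $\ge 0.83$, so
the hole is born early and dies late. `target_covariance()` exposes the
projected population matrix so tests can assert against the truth actually
simulated.

What the generator does *not* emulate: hemodynamics, autocorrelated BOLD
noise, spatial smoothness, motion artifacts, and within-group heterogeneity
(one covariance per group). Passing tests therefore demonstrate that the
topological and statistical machinery is correct and sensitive under
idealized noise, not that any particular clinical effect is detectable in
real data.

## Numerical choices

* Triangle filtration values are `max()` of the stored edge values — asserted
  exact, no recomputation drift.
* The boundary-matrix reduction runs over GF(2) with sparse
  sorted-index columns (symmetric difference as column addition), in C++;
  at 90 regions a scan reduces in ~0.15 s (≈1,800 edges, ≈13,000
  triangles).
* Betti curves follow the half-open convention $birth \le \delta < death$,
  so zero-length bars cancel out of the curves identically.
* $\beta_0$ at $\delta = 0$ equals the region count whenever off-diagonal
  distances are positive and distinct (sample correlations are, almost
  surely).
* Degenerate inputs fail loudly: zero-variance regions name themselves in
  the error, streams are validated for filtration order and face closure,
  fully tied samples return $p = 1$ rather than NaN.

## Verification strategy and problem sizes

Three independent routes to the same quantities are cross-checked
exhaustively at small scale: the persistence reduction, a Smith-normal-form
style GF(2) rank computation on the full boundary matrices
(`homology_ranks_bruteforce()`), and graph connected components via igraph
(`connected_components_at()`). The test suite compares all three exactly on
200 random 10–15-point instances at five thresholds each, checks
representative cycles for even GF(2) vertex incidence and birth-consistent
edges, and pins closed-form fixtures (unit square: one loop on
$[1, \sqrt 2)$; regular 10-gon: exactly one persistent loop). Statistical
components are checked against enumeration (all $\binom{n}{n_1}$ labelings
for the $U$ test), a first-principles step-up implementation for BH, ECDF
sweeps for KS, and published q-value triples for the within-family
convention. The end-to-end recovery analysis uses 20 replicates of 20 vs 20
scans with one planted 6-ring (200 time points) — sizes chosen to make the
planted effect clearly detectable while keeping a full suite run in a few
minutes on one core.

## Known limitations

* Per-region counts depend on the representative convention (above); a
  different reduction order would shift counts between members of the same
  homology class.
* The K-S comparison pools Betti values across grid points and scans, so its
  nominal p-value ignores within-scan dependence across the grid; it is a
  descriptive distributional comparison, as is conventional.
* Scans, not subjects, are the sampling unit; repeated scans of one subject
  violate independence and are not modeled.
* $1-r$ is not a metric; VR persistence is well defined regardless, but
  metric-space stability theorems do not directly apply.
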