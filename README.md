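# fcnc

Topological analysis of brain functional connectivity networks: from
region-averaged resting-state fMRI signals to persistent homology, circuit
features, and two-group statistics.

## What it does, and for whom

Functional connectivity studies summarize a resting-state scan as the matrix
of Pearson correlations $m_{ij} = \mathrm{corr}(P_i, P_j)$ between the
averaged time courses of brain regions (here the 90 cerebral AAL regions).
Graph-theoretic analyses of such matrices require choosing a single edge
threshold; topological data analysis removes that choice by examining the
whole family of graphs at once. With the distance

$$ d(P_i, P_j) = 1 - \mathrm{corr}(P_i, P_j), $$

the Vietoris–Rips complex $VR(Z,\delta)$ contains an edge wherever
$d \le \delta$ and a triangle wherever all three edges are present. Sweeping
$\delta$ up to $t_{max} = 0.9$ yields a filtration whose persistent homology
records every connected branch ($\beta_0$) and every loop ($\beta_1$) as a
birth–death interval. This package computes those barcodes by GF(2)
boundary-matrix reduction **with representative cycles**, so each
1-dimensional class — a *functional connectivity neural circuit* (FCNC) —
is localized to actual regions and edges. Per scan and threshold it then
counts, for every region, the circuits passing through it, and the number of
circuits of a given length; two groups of scans (e.g. patients vs controls)
are compared by two-sided Mann–Whitney $U$ tests with Benjamini–Hochberg
FDR, and their Betti curves by two-sample Kolmogorov–Smirnov tests.

It is intended for methods researchers working with ROI-level rsfMRI
exports (any delimited table of time points × labeled regions) and ships a
synthetic-data generator that plants correlation rings with known
1-dimensional homology, so the entire pipeline is testable without clinical
data.

## Worked example

```r
library(fcnc)

# two groups of scans, group A carries a planted 6-ring of correlated regions
cfg <- simulation_config(n_scans_a = 5, n_scans_b = 5,
                         planted_cycles_a = list(1:6),
                         n_timepoints = 200, seed = 42)
res <- run_pipeline(run_config(input = "synthetic", sim = cfg,
                               out_dir = "run1", seed = 42))

# one scan's topology by hand
ts <- generate_group_timeseries(cfg)$a[[1]]
d  <- corr_to_distance(pearson_fc(ts))
bc <- reduce_boundary_matrix(build_simplex_stream(d))
bc
#> <barcode> 90 dim-0 intervals; 1741 dim-1 intervals (182 with positive persistence)

cv <- betti_curve(bc)
cv$beta0[1]          # connected branches at delta = 0: one per region
#> [1] 90

rec <- extract_fcnc(bc, 0.7)       # circuits born by delta = 0.7
region_counts(rec, 90)[1:8]        # the planted ring regions 1..6 light up
#> [1] 1 1 1 1 1 1 0 0

subset(res$comparison, significant & feature_type == "region")[,
  c("feature", "threshold", "mean_a", "mean_b", "p_value", "q_value")]
```

The numbers mean: at $\delta = 0$ every region is its own component
(`beta0 = 90`, the curves' universal starting point); of this scan's ~1,700
loop births only 182 have positive persistence, and exactly one circuit
exists by $\delta = 0.7$ — the planted ring, touching regions 1–6 once
each. The comparison table lists region/threshold cells whose group
difference survives FDR, with group means and the Mann–Whitney p and
BH q-values; on planted-ring data the flagged regions are ring members.

A thin CLI over the same functions is installed at
`system.file("cli", "fcnc-cli.R", package = "fcnc")` with subcommands
`simulate`, `run`, `persistence`, and `stats`.

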