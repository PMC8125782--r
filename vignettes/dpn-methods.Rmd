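---
title: "Drug prescription networks: models, thresholds and design choices"
author: "dpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug prescription networks: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpnet)
```

## The model and its assumptions

A drug prescription network (DPN) treats a cohort's dispensation history as
a graph. Fix an ATC level $L \in \{1,\dots,5\}$ and project every dispensed
level-5 code to its level-$L$ prefix. The network's nodes are the distinct
codes observed; node $i$ carries $P_i$, the number of *patients* (not
prescriptions) with at least one dispensation of $i$ during the observation
window. An edge joins $i$ and $j$ whenever at least one patient received
both, weighted by the co-prescribed patient count $C_{ij}$. Three modelling
assumptions are baked in:

* **Window co-occurrence.** Two drugs are "co-prescribed" if the same
  patient received both at any time inside the window; no temporal overlap
  of the two treatments is required. This is the weakest, most inclusive
  reading; a stricter overlap rule would only remove edges.
* **Patient counts, not event counts.** Repeat dispensations never inflate
  $P_i$ or $C_{ij}$; they only matter for the demography of prescription
  volumes.
* **Isolates are real.** A drug dispensed to patients who received nothing
  else is a degree-0 node. It stays in the graph, and enters $N$, the
  density denominator and all averages, because its presence is a genuine
  feature of the prescribing pattern.

Because the five ATC levels are nested by code prefix, coarsening the level
can only merge nodes: $N(L) \le N(L')$ for $L < L'$. The package verifies
this monotonicity property on every simulated cohort.

## The structural panel

For each network we report $N$, $\ln N$, $E$, density $d = 2E/(N(N-1))$,
and the mean and coefficient of variation (CV% = 100·SD/mean, population
SD by default, sample SD on request) of three node metrics: degree $k_i$,
Freeman betweenness $b_i$ (unnormalised, geodesic ties split equally) and
closeness $Cl_i = 1/\sum_j d(i,j)$ over reachable $j$, with $Cl_i = 0$ for
isolates. Newman's assortativity $r$ is the Pearson correlation of degrees
over the $2E$ oriented edge ends; for regular graphs (zero degree variance,
e.g. a complete network) it is reported as `NA` rather than 0 or an error,
since the correlation is genuinely undefined there. The random-graph
heuristics "$\bar k > 1$: a giant component exists" and
"$\bar k > \ln N$: it spans the network" are reported *alongside* the true
component decomposition, because on structured graphs the heuristics can
disagree with the ground truth (two disjoint triangles have $\bar k = 2$).

**Edge lengths for weighted centralities.** Betweenness and closeness need
an edge-length convention, and none is canonical for co-prescription
weights. The default treats the raw weight $C_{ij}$ as a traversal cost
(the convention of common network toolchains when a weight attribute is
present), with `inverse-cij` (length $1/C_{ij}$: strong co-prescription =
short) and `unweighted` as explicit alternatives. The choice is recorded in
every summary row; degree, density and assortativity do not depend on it.

## φ thresholding and φ~max~

For an edge with counts $(n, P_i, P_j, C_{ij})$ the φ coefficient is the
Pearson correlation of the two binary patient indicators:
$$\phi_{ij} = \frac{n\,C_{ij} - P_i P_j}
{\sqrt{P_i (n-P_i)\, P_j (n-P_j)}}.$$
It is undefined when a drug reaches every patient ($P_i \in \{0, n\}$);
such edges are dropped from the φ analysis with a warning. Thresholding at
φ\* keeps edges with $\phi_{ij} \ge \phi^*$; negative-φ edges are thus
removed by any non-negative threshold without special handling.

The retention analysis evaluates, over a grid of φ\* values, the fraction
of *connected* nodes (degree ≥ 1 — not "in the largest component", which
would conflate thresholding with percolation) and of surviving edges,
relative to the unthresholded counts. Defaults: 50 log-spaced grid points
on $[10^{-5}, 1]$. Each curve is fitted by least squares with a decaying
logistic $A / (1 + \exp((x - x_0)/s))$ in $x = \log_{10}\phi^*$ — a
logistic in raw φ cannot follow a decay spanning five decades — with the
asymptote fixed at $A = 1$ by default. The fit uses a Levenberg–Marquardt
least-squares routine on the explicit residual function with three starting
widths (5%, 15% and 40% of the grid span), keeping the best optimum; the
`converged` flag is honest, and a non-converged fit yields `phi_max = NA`
with a warning rather than a silently bad number.

φ~max~ is the φ\* maximising the gap between the fitted node and edge
curves, located by a 2,000-point log-grid scan followed by local
golden-section refinement (tolerance $10^{-10}$ on the log scale, making
the estimate invariant to the user's grid spacing to well below $10^{-4}$).
When the two fits are identical or the gap is nowhere positive, φ~max~ is
`NA` with a diagnostic message. For two logistics of equal width the gap is
symmetric about the midpoint of their midpoints, which gives the
closed-form check used in the tests: $x_0 = -1$ and $x_0 = -2$ imply
$\phi_{max} = 10^{-1.5}$.

## Stratified layers and their comparison

The cohort is split into sex × age strata (default 0–21, 22–64, 65+, the
six-group design typical of drug-utilisation studies; age is computed once
at the final day of the observation window because a single static age
pyramid is reported). Each stratum's DPN is binarised over the *union*
node universe of the layers being compared — codes absent from a stratum
become all-zero rows, so matrices of compared layers always share an index.

Entry $(i, j)$ of the cross-layer matrix is the Euclidean distance between
the adjacency row of code $i$ in one layer and code $j$ in the other; for
binary rows the squared distance is exactly the Hamming distance, an
integer. This row-profile reading is the one consistent with an
$N \times N$ matrix carrying ATC codes on both axes while comparing two
different populations; it is isolated in `layerDistance()` so an
alternative multiplex distance could be swapped in. Note that for two
*different* layers the cross matrix need not be symmetric
($d(A_i, B_j) \ne d(A_j, B_i)$ in general); since the ward.D2 step requires
a symmetric input (and errors otherwise), `compareLayers()` symmetrises an
asymmetric cross matrix as $(D + D^\top)/2$ and records that it did so in
the result object.

Clustering uses the ward.D2 linkage — squared distances inside the
Lance–Williams update, square-rooted merge heights, which guarantees
monotone heights (no dendrogram inversions) — and the package's tests pin
the implementation to a naive $O(n^3)$ Lance–Williams reference via
cophenetic matrices. The number of clusters to extract is a user parameter;
when unspecified it is chosen to maximise the mean silhouette width over
$k = 2..\min(10, n-1)$, and the chosen $k$ is reported with its silhouette
value so the user can judge whether the partition is meaningful.

## What the synthetic generator does (and does not) emulate

`generateRecords()` draws cohorts with: female fraction 0.547; age-stratum
patient weights (0.119, 0.500, 0.381) for 0–21 / 22–64 / 65+; per-stratum
Poisson mean prescription counts (3.03, 9.03, 26.58), derived so the
stratum shares of prescriptions are 2.4% / 30.1% / 67.5% at an overall
mean of 15 dispensations per patient — the demographic profile of a
one-year administrative cohort from a local health unit. Drug popularity is
Zipf with exponent 1.3 over an 800-code level-5 catalog, reproducing the
observed extremes (one dominant drug; a long tail of drugs dispensed to a
single patient). The catalog is assembled from small per-group component
pools so that projecting to coarser ATC levels genuinely merges codes and
all 14 anatomical groups appear.

Non-random co-prescription is planted as **modules**: by default three
disjoint sets of 4 codes, each with membership rate 0.08 and within-member
draw probability 0.75, taken from the popularity tail so the plant is not
confounded with popularity. Members receive module codes as additional
dispensations, which creates strong positive within-module φ against a
φ ≈ 0 background — the known contrast the φ~max~ recovery tests rely on.
A module plant (rather than a full dependence copula) was chosen because
the thresholding stage only needs a controlled positive/negative
association contrast.

What the generator does **not** emulate: temporal structure within the
window (refill cycles, seasonality), pharmacologically coherent regimens,
dose, prescriber effects, and the correlation between age and *which*
drugs are taken. Passing tests on this generator therefore demonstrate
correctness of the computations and recoverability of planted structure —
not that any particular clinical pattern will appear in real data.

## Numerical choices and degenerate inputs

* Problem sizes: unit tests use cohorts of 120–1,500 patients and graphs of
  3–50 nodes; oracle checks run brute-force geodesic enumeration on ≤ 7
  nodes, exhaustive φ validation to $n = 30$, and 12-point linkage
  matrices. The acceptance script uses a 3,000-patient cohort. These sizes
  were chosen as the smallest at which every qualitative fingerprint of the
  method (complete level-1 network, heavy popularity tail, disassortativity)
  is stable across seeds.
* Dates are ISO-8601 only; records failing date, ATC or mandatory-field
  validation are counted per rule and excluded, mirroring the
  "incomplete/ambiguous" exclusion practice for administrative records.
* Empty inputs degrade gracefully: a header-only file gives a zero report;
  a cohort emptied by filtering yields an empty-outputs manifest; density
  and assortativity raise explicit undefined-metric errors below their
  minimum support ($N < 2$, $E = 0$).
* All randomness flows from one seed (`set.seed()` before generation, or
  `runConfig(seed = )` for the pipeline); re-running a pipeline
  configuration reproduces every artifact byte-for-byte.

## Known limitations

* φ~max~ depends on the logistic parameterisation; with strongly
  non-logistic retention curves the fitted gap maximum can drift from the
  empirical one. The fitted parameters, RSS and convergence flags are
  exported so this is auditable.
* The mean-degree giant-component criteria are Erdős–Rényi heuristics and
  are reported as such, next to the true component sizes.
* Cross-layer distances compare neighbourhood profiles only; they do not
  test significance (no Mantel-style permutation machinery is included),
  and the silhouette-based default for $k$ is a convenience, not an
  inferential claim.
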