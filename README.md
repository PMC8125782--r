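# dpnet — drug co-prescription networks from ATC-coded records

`dpnet` analyses patient-level drug dispensation records — the kind of
administrative data local health units and insurers hold — through the lens
of **drug prescription networks (DPNs)**. It is aimed at pharmacoepidemiologists
and health-data scientists who want to study poly-pharmacy patterns as a
graph rather than as a flat frequency table.

## The model

Every dispensed drug carries an ATC (Anatomical Therapeutic Chemical) code
with five nested levels — from the anatomical main group (1 letter, e.g. `J`)
down to the chemical substance (7 characters, e.g. `J01CR02`). At a fixed
level *L*, the DPN is the undirected weighted graph with

* **nodes**: the ATC codes observed in the cohort, weighted by
  *P<sub>i</sub>* = number of distinct patients prescribed drug *i*;
* **edges**: pairs of codes co-prescribed to at least one common patient,
  weighted by *C<sub>ij</sub>* = number of distinct patients prescribed both.

One cohort therefore yields five networks (ATCL1–ATCL5) whose structure is
summarised by density *d* = 2E/(N(N−1)), degree *k*, betweenness *b* and
closeness *Cl* centralities (means with CV%), and Newman's degree
assortativity *r*.

The central statistic is the **φ coefficient** of each edge — the Pearson
correlation of the two binary patient-indicator vectors:

φ<sub>ij</sub> = (n·C<sub>ij</sub> − P<sub>i</sub>P<sub>j</sub>) /
√(P<sub>i</sub>(n−P<sub>i</sub>)·P<sub>j</sub>(n−P<sub>j</sub>))

Thresholding the network at increasing φ\* strips the "weak" edges (small
C<sub>ij</sub> relative to P<sub>i</sub>, P<sub>j</sub>) first. The fractions
of connected nodes and surviving edges, as functions of φ\*, are fitted with
logistic curves in log<sub>10</sub> φ\*; **φ<sub>max</sub>** — the φ\* value
maximising the gap between the two fitted curves — is a principled threshold
that exposes the network's modular core.

Finally, sex-by-age strata of the cohort give layer-specific binary networks
over a common node universe; cross-layer Euclidean distance matrices between
adjacency row profiles, clustered with ward.D2 linkage, quantify how
prescription structure differs between, say, elderly women and elderly men.

Since real dispensation records are rarely shareable, the package ships a
synthetic record generator (`simConfig()` / `generateRecords()`) that
emulates their statistical structure: a slight female majority, three age
strata with the elderly receiving most prescriptions, Zipf-like drug
popularity and planted co-prescription modules with known φ contrast.

## Worked example

```r
library(dpnet)
set.seed(42)
sim <- generateRecords(simConfig(n_patients = 1000))
records <- filterBirthYear(sim$records)$records

dpn <- buildDPN(buildIncidence(records, level = 2))
dpn
#> DPN at ATC level 2: 112 nodes, 4410 edges (cohort n = 997)
#>   most prescribed: A01 (Pi=906), B03 (Pi=733), C04 (Pi=555)

round(networkSummary(dpn)[, c("N","lnN","E","d","k_mean","k_cv_pct","r")], 3)
#>     N   lnN    E     d k_mean k_cv_pct      r
#> 1 112 4.718 4410 0.709  78.75   30.046 -0.251

d5 <- buildDPN(buildIncidence(records, level = 5))
curve <- fitRetention(retentionCurve(d5))
sprintf("phi_max (ATCL5) = %.3f", phiMaxOf(curve))
#> [1] "phi_max (ATCL5) = 0.177"
```

Reading the output: the level-2 network is dense (*d* = 0.709 — co-prescription
is the norm, not the exception), every node sits in one giant component, and
*r* = −0.251 is disassortative: broadly co-prescribed drug classes attach
preferentially to narrowly used ones. Thresholding the level-5 network at
φ<sub>max</sub> = 0.177 keeps only strongly associated drug pairs — in this
simulated cohort, exactly the planted co-prescription modules.

`runPipeline(runConfig(...))` runs the whole chain (ingest → five DPNs →
metric table → φ analysis → stratified comparison) and writes
GraphML/CSV/JSON artifacts plus a reproducibility manifest;
`inst/cli/dpnet.R` exposes the same stages as shell subcommands
(`simulate`, `build`, `metrics`, `phi`, `compare`, `run-all`).

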