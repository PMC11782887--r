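---
title: "Finding disease-specific inter-tissue communicators by network propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding disease-specific inter-tissue communicators by network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itcrank)
options(itcrank.quiet = TRUE)
```

## The problem

Many diseases are not cell-autonomous: protein ligands and receptors carry
signals between tissues, and a communicator that is innocuous in most
contexts can be a driver in one disease. `itcrank` ranks the entries of a
ligand/receptor catalog ("inter-tissue communicators", ITCs) by how much
influence each exerts on a disease's known genes through a molecular
interaction network, and then asks for which diseases that influence is an
outlier. The package also ships the two validation harnesses used to probe
such rankings — diagnostic prediction from plasma proteomes and
perturbation inference from downstream transcription-factor signatures —
and seeded synthetic-fixture generators so that every stage is testable
without any external database.

## The model

**Network.** Typed edge tables (protein–protein, TF–target, miRNA–target)
are integrated into one heterogeneous network; protein complexes enter as
single nodes with `::`-joined, sorted member ids. Self-loops are dropped,
multi-layer duplicates of a node pair count once, and all edges carry
weight 1 — the sources are curated interaction catalogs that provide no
comparable weights. By default every layer is symmetrized
(`undirected_all`); keeping regulatory direction (`as_declared`) is a
config away. We default to undirected propagation because it is the common
convention for walk-based gene prioritization and maximizes reachability
from communicator seeds; whether regulatory direction should constrain
propagation is genuinely open, so both policies are exposed.

**Random walk with restart.** With `W` the column-normalized adjacency and
`r` the restart probability,

$$p_{t+1} = (1-r)\,W\,p_t + r\,p_0,$$

iterated from the single-seed indicator `p_0` until the L1 change falls
below `tol`. The fixed point `p` measures seed-to-node relevance. The L1
norm is the natural one for probability vectors and gives the clean
geometric bound: the map contracts with factor `(1-r)`, so at most
`log(tol)/log(1-r) + 1` iterations are ever needed. A dense closed-form
solver for `(I-(1-r)W)\,p = r\,e_{seed}` (guarded to 2,000 nodes) serves
as an independent oracle in the tests. Dangling columns (nodes with no
out-mass) default to a uniform jump, which preserves column-stochasticity
without trapping mass; a self-loop policy is available.

**Significance threshold.** Raw walk probabilities reflect topology, not
biology. The minimum value worth interpreting is calibrated by comparing
within-pathway walk values against size-matched uniformly random node
sets: per pathway set the median over all ordered seed→member pair values
is recorded, the same is done for a random set of equal size, and the
threshold is the exact maximum of the random-set medians. We pool pairwise
values per set before taking the median (rather than taking per-seed
medians first) because the calibration compares set-level cohesion; the
alternative reading is noted as ambiguous and the pooled version is the
one implemented. Random genes are drawn from all network nodes with no
exclusions.

**Communicator scoring and selection.** Each catalog entry seeds one walk;
its influence on a disease is the sum of walk probabilities at the
disease's genes, counting only values strictly above the threshold.
Because hub-like disease genes receive large probabilities from *any*
seed, the raw sum is divided by the mean of the same quantity over a
size-matched set of uniformly random seeds (one draw per run by default;
`n_baseline_repeats` averages several). If a baseline is exactly zero the
smallest positive random sum stands in for it, and a disease whose random
sums are all zero is flagged unusable — division by zero must be defined
somehow, and this choice keeps the disease's ranking well-defined without
inventing signal. Diseases enter only with at least 10 genes in the
network, applied after intersection because scores are only computable on
mapped genes.

Per communicator, the normalized scores across diseases form a profile on
which modified Z-scores are computed:

$$\mathrm{modZ}_i = 0.6745\,\frac{x_i - \mathrm{med}(x)}{\mathrm{MAD}(x)},$$

with the mean absolute deviation (constant 1.2533 in the denominator)
taking over when the MAD is zero — score rows are frequently zero-heavy,
so the fallback is exercised routinely, and a fully constant row scores 0
everywhere. A (communicator, disease) pair is selected when its modZ
strictly exceeds 5. Note a structural property of the fallback: with `n`
diseases of which a single one is nonzero, the modZ of the outlier is
`0.6745 n / 1.2533` regardless of its magnitude, so single-spike rows can
only clear the cutoff once roughly ten diseases are scored — selection is
meaningful only against a reasonably wide disease panel.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `restart_prob` | 0.15 | probability of returning to the seed each step (community standard) |
| `tol` | 1e-10 | L1 convergence tolerance of the walk |
| `modz_cutoff` | 5 | outlier cutoff for disease specificity |
| `min_disease_genes` | 10 | disease admission rule after network intersection |
| `max_missing_per_donor` | 150 | proteome filter: donors dropped above this missing count |
| `max_missing_per_protein` | 740 | proteome filter: proteins dropped above this missing count (on surviving donors) |
| `split_ratio`, `folds`, `repeats` | 0.7, 10, 5 | stratified hold-out split and repeated CV geometry |
| `min_cluster`, `min_avg_corr` | 3, 0.4 | cell-line cluster admission for perturbation inference |
| `n_random_sets` | 100 | random communicator sets behind the fold test |

## Validation harness 1: diagnostic prediction

Donor×protein tables are filtered in a fixed order — donors first, then
proteins on the surviving donors, then per-protein median imputation from
the remaining donors — because the order changes the outcome (a donor can
be rescued by dropping a sparse protein first; the fixed order is asserted
by a toy case in the tests). Three feature conditions are compared per
disease: the disease's specific communicators, an equal number of random
measured proteins (excluding those communicators), and the disease's raw
known genes; a condition with no measured feature is carried at chance
level (AUROC 0.5, AUPRC equal to prevalence). Models are gradient-boosted
trees (xgboost, binary logistic) with the positive-class weight set to the
negative/positive ratio; all other hyperparameters stay at library
defaults and are echoed in the result attributes, since no tuning protocol
is part of the method. Every CV model is evaluated on the same held-out
test set — the CV varies the training subsample, the test set stays fixed
— and the AUPRC baseline is the test-set prevalence exactly. Across
diseases, conditions are compared by a one-sided paired Wilcoxon
signed-rank test on per-disease medians (AUPRC first reduced by its
per-disease baseline); the test is a package choice, picked for being
nonparametric and paired. Random proteins are drawn once per disease, not
per CV repeat; per-repeat resampling is available by re-seeding
`assemble_features`.

## Validation harness 2: perturbation inference

Perturbation signatures pass a fixed filter order: exemplar flag, max-TAS
de-duplication within (perturbagen, cell line, type), allowed types
(over-expression, knock-down), required time (96 h), excluded cell lines.
Communicators map to downstream transcription factors by directed
reachability in a pathway graph (receptors directly, ligands through
their paired receptors), and a communicator's inferred signature in a
cell line is the elementwise sum of its TFs' signatures there. Input
effect values are taken as already standardized (level-5-style scores); an
optional per-signature z-scaling is available but off by default.

Because signatures from unrelated cell lines cancel, each disease first
selects a coherent cell-line cluster: Pearson correlations between cell
lines at the disease-gene rows (pairing matched perturbagen/type columns;
unmatched perturbagens are excluded since correlation is only meaningful
on aligned perturbations), average-linkage hierarchical clustering on
`1 - corr`, and the largest cluster of ≥3 lines with mean pairwise
correlation > 0.4 wins, ties broken by higher mean correlation; no
qualifying cluster discards the disease. Average linkage is a package
choice — the selection rule only requires "clustering by similarity".
The disease score averages absolute signature values across the selected
lines, sums them over the disease-specific communicators at the disease
genes, and averages over genes; it is positively homogeneous of degree 1
in the signature values. The score is compared to 100 seeded size-matched
random communicator sets (excluding the disease set), and the fold values
are tested against 1 by a one-sample t-test — two-sided by default, with
a one-sided option, since the sidedness is not dictated by the method.
Over-expression and knock-down are analyzed separately end-to-end.

## What the synthetic fixtures emulate — and what they do not

All generators flow from a single explicit seed (restored on exit), write
the same TSV/GMT formats the pipeline reads, and record their planted
ground truth in a manifest, so recovery tests compare against bookkeeping
rather than re-derivation.

* **Network fixture** (default 500 nodes): a preferential-attachment
  backbone overlaid with 5 planted 20-node modules (within-module edge
  probability 0.25, between 0.01), one module designated disease genes;
  5 planted communicators each get 8 extra edges into that module while
  45 decoys get 8 uniformly placed extra edges, so planted and decoy
  nodes differ only in where their edges point, not in degree. Setting
  the wiring strength to 0 or equalizing the block probabilities produces
  the negative controls.
* **Proteome fixture** (default 200×50, 60 cases): Gaussian proteins,
  cases shifted 3 SD on 5 informative proteins, 2% i.i.d. missingness
  plus one planted high-missingness donor and protein; the manifest's
  post-filter dimensions are computed from the missingness mask by direct
  counting, independent of the filter implementation.
* **Signature fixture** (default 300 genes, 8 cell lines, 12 TF
  perturbagens, both perturbation types): i.i.d. normal effects except
  that 4 cell lines share a latent factor at the disease-gene rows with
  variance share 0.55, and TFs downstream of 3 designated disease
  receptors have disease-gene effects inflated 3×. The latent share is
  set to 0.55 rather than higher on purpose: the selection rule keeps the
  *largest* qualifying cluster, and a much tighter planted block lets a
  barely-correlated fifth line ride along in a superset whose diluted
  mean still clears 0.4 — at 0.55 the block stays comfortably above the
  criterion while a superset would need several-sigma chance
  correlations, keeping the planted truth unambiguous. Metadata decoys
  (a non-exemplar column, a lower-TAS duplicate, an off-time column, an
  excluded cell line) exercise every filter rule.

These fixtures are deliberately minimal: they have the statistical
features the assertions need (modularity, hubness, planted effects,
correlated blocks, missingness) and nothing else. Passing tests therefore
demonstrate that the machinery recovers planted structure under matched
assumptions — they say nothing about curation quality, identifier
mapping, batch structure, or the non-Gaussian noise of real proteomes and
expression signatures.

## Numerical choices and degenerate inputs

* Walk convergence is declared on the L1 norm at 1e-10; the dense oracle
  and the sparse iterative path agree to better than 1e-8 on every tested
  network.
* The planted-communicator recovery experiment scores at threshold 0:
  recovery is a property of normalization and ranking, and censoring has
  its own calibrated criterion; mixing the two would entangle the tests.
* Zero baselines fall back to the smallest positive random sum; diseases
  with no positive random sum at all are dropped, not scored.
* MAD-zero rows use the mean-absolute-deviation fallback described above;
  fully constant rows score 0.
* Random communicator sets that score 0 are redrawn up to 10 times, then
  excluded with a log entry.
* Cluster-selection ties (equal size) go to the higher mean correlation.
* All problem sizes in the tests and the acceptance script are the
  fixture defaults above — 20-seed repetitions for rate-style properties,
  10 seeds for the null diagnosis runs, 100 random sets for fold tests —
  chosen as the smallest sizes at which the planted effects are
  unambiguous against their negative controls.

## Known limitations

* Edge weights, layer-specific walk behavior, and teleport distributions
  other than the single-seed restart are out of scope by design.
* The modified-Z selection needs at least 3 diseases and only becomes
  informative for zero-heavy rows at around 10 diseases (see the fallback
  note above).
* The diagnostic harness does no hyperparameter search and no
  calibration-curve analysis; it is a comparison harness, not a deployed
  classifier.
* Identifier conversion is assumed done upstream: unmapped ids are
  dropped with logged counts, never guessed.
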