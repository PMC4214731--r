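---
title: "Network-based drug-disease association inference: models and design"
author: "netRepurpose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based drug-disease association inference: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netRepurpose)
```

## The inference problem

Drug repositioning by guilt-by-association: if a drug's protein targets sit
close, in a gene/protein interaction network, to the targets of drugs already
known to treat a disease — or to the disease's own susceptibility genes —
the drug is a candidate for that disease. `netRepurpose` quantifies this
closeness on an integrative network (protein-protein interactions, regulatory
links and complex-derived interactions, all treated as undirected), turns it
into a 30-dimensional feature vector per drug-disease pair, and trains
standard classifiers to rank unknown pairs.

## Bounded path scores

All scores are built from three path types between two genes: R0 (the genes
are identical), R1 (a direct edge), R2 (one intermediate gene). An R0 path
scores the base $\omega$, R1 scores $\omega^2$, R2 scores $\omega^3$, and
anything farther scores 0. The default base is fixed at $\omega = 1/6$, the
reciprocal median degree of the integrative network the method was calibrated
on; `pathScoreConfig(mode = "auto")` instead uses $1/\mathrm{medianDegree}$
of the loaded network. For an even number of nodes the median takes the lower
middle value, so the automatic base stays a unit fraction. Distances are
computed by depth-2 truncated search (per-node distance-1 and
exact-distance-2 lists precomputed at load time); no all-pairs matrix is ever
built, so networks of $10^4$ nodes load and query comfortably.

## Adjacency-based inference (3 features)

For two node sets $S_1, S_2$ (drug target sets $T(d)$ or disease gene sets
$T(p)$), every cross pair contributes the score of its bounded shortest path
and the sum is scaled by $|S_1|\,|S_2|$:

$$\mathrm{adj}(S_1,S_2) = \frac{1}{|S_1||S_2|}
  \sum_{x \in S_1}\sum_{y \in S_2} \omega^{\,\mathrm{dist}(x,y)+1}
  \;[\mathrm{dist}(x,y) \le 2].$$

Because each pair contributes at most $\omega$, the attainable range is
$[0, \omega]$, i.e. $[0, 1/6]$ at the default base — the score is left on
this natural scale rather than renormalized. For a pair $(d, p)$, the
drug-side feature is the maximum of $\mathrm{adj}(T(d), T(d'))$ over drugs
$d'$ with a known association to $p$; the disease-side feature is the mirror
image over the known diseases of $d$; the third feature is their weighted
geometric mean $a^{w_1} b^{w_2}$ (equal weights by default, configurable;
zero whenever either side is zero). An empty anchor set scores 0.

**Self-exclusion.** When the scored pair is itself a known association
(every training positive), the pair is removed from the known-association
indexes first — otherwise the drug side would contain the self-comparison
$\mathrm{adj}(T(d), T(d))$ and the feature would encode the label outright.

## Module-distance-based inference (27 features)

The common topological module of two entities at level $v \in \{0,1,2\}$ is
the intersection of the $v$-step network neighborhoods of their node sets;
at $v = 0$ this is simply the shared targets (genes). "Common to two drugs"
is read as shared membership, which is why the intersection — not a union of
induced subgraphs — is used. The distance between a module $M$ and an entity
node set $G$ at path length $k \in \{0,1,2\}$ scores only pairs at distance
*exactly* $k$:

$$\mathrm{mdist}_k(M, G) = \frac{\omega^{k+1}}{|M||G|}
  \sum_{t \in M}\sum_{g \in G} [\mathrm{dist}(t,g) = k].$$

The indicator is per pair, not per path: counting distinct length-$k$ walks
would be unbounded and break the scaling. An empty module scores 0. For a
pair $(d, p)$, the d-module feature at $(v,k)$ maximizes
$\mathrm{mdist}_k(\mathrm{module}(T(d), T(d'), v),\, T(p))$ over the known
drugs $d'$ of $p$; the p-module feature mirrors this over the known diseases
of $d$ with the drug's target set as $G$; the combined feature is the same
geometric mean as above. The $3 \times 3$ grid of $(v, k)$ times three
methods gives 27 features; with the 3 adjacency features the canonical
30-name schema of `featureNames()` (version `netRepurpose-features/1`).
Expansion happens before intersection; both module scores are oriented as
similarities (larger = closer), and the classifier learns any sign.

## Training protocol

Positives are the known associations. Negatives are drawn uniformly without
replacement from the drugs x diseases of the positive set, minus the
positives, at equal size — balanced by construction. Evaluation is 10-fold
cross-validation repeated 10 times, each repeat with a *fresh* negative
sample; folds are stratified by label (the source protocol separates
"arbitrarily"; stratification merely avoids degenerate single-class folds at
small n). A repeat's AUC is the mean of its fold AUCs (pooling held-out
scores instead is available via `pooled = TRUE`), and the grand mean averages
the repeats. AUC is the Mann-Whitney statistic with midrank ties, exactly
trapezoidal ROC integration. Backends: `rpart` (C4.5-style tree),
`randomForest`, and `nnet` (single hidden layer, size 8 — roughly the
(attributes + classes)/2 heuristic — decay 5e-4, 200 iterations); all other
hyperparameters are library defaults, and every stochastic step derives its
seed from the master seed.

By default only the evaluated pair itself is excluded from the
known-association indexes during feature computation; `strictCV = TRUE`
additionally recomputes each fold's features with all of that fold's
positives unknown. The default mirrors the most literal reading of the
source protocol; strict mode is the conservative alternative.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `base` | 1/6 (fixed) | R0 path score; `auto` = 1/medianDegree |
| `allowedLengths` | 0,1,2 | path types allowed to score (ablation) |
| `combineWeights` | 0.5/0.5 | geometric-mean weights |
| `v`, `k` grids | 0..2 x 0..2 | module scope and path-length grid |
| `folds`, `repeats` | 10, 10 | cross-validation shape |
| `threshold` | 0.5 | predicted-positive cutoff for ranking |
| `strictCV` | off | fold-level association exclusion |

## The synthetic benchmark

Real inputs (curated interactomes, drug-target and disease-gene catalogs)
cannot ship with the package, so `benchmarkSpec()` /
`simulateBenchmark()` generate self-contained data with a *planted*
proximity signal. Defaults: 500-node preferential-attachment network
targeting median degree 6 (the attachment parameter is chosen by probing
candidates on the actual node count and keeping the closest median — a
documented heuristic), 60 drugs with 2-5 targets, 20 diseases with 2-6
susceptibility genes, 200 known associations, signal 0.8, generator seed 1.

Design choices worth spelling out:

* **Disease modules** are a random seed node plus sampled neighbors —
  connected-ish neighborhoods, like clustered disease genes.
* **Planting is per pair.** The signal parameter `s` is the probability that
  a positive pair's drug carries a target within distance 1 of *that*
  disease's gene module. Target slots cycle round-robin over the drug's
  positive diseases, and a drug treating many diseases gets at least one
  slot per disease (capped at the size-range maximum) — multi-indication
  drugs having more targets is itself realistic polypharmacology. A pooled
  union-of-diseases draw would dilute the per-pair probability by the
  number of diseases treated.
* **Quasi-regular positives.** Known associations are assigned by a random
  near-regular bipartite pairing, so every drug and disease carries an
  almost equal number of positives. With uniformly sampled positives,
  high-frequency entities are over-represented among positives relative to
  uniformly sampled negatives, and the max-over-anchors features are
  monotone in anchor count — the classifier would then read entity
  frequency instead of network proximity. Near-constant counts remove that
  channel. Real association catalogs are heavy-tailed, so this is a
  deliberate idealization for benchmarking.
* **Fingerprints** are independent random bitsets: structure-blind by
  construction, so the Tanimoto screen on synthetic predictions reports
  essentially zero chemical similarity.

What passing tests on this benchmark do *not* show: performance on real
pharmacological networks (pathway structure, signed regulation, heavy-tailed
association counts, literature bias in curation are all absent), and
absolute AUCs are not comparable to values obtained on curated databases.

**A known residual artifact.** Even at signal 0, repeated CV on the
benchmark yields an AUC near 0.64 rather than 0.50. The cause is the
self-exclusion policy itself: a positive pair always has exactly one fewer
known-partner anchor than an equally-counted negative, and a maximum over
$n-1$ draws is stochastically smaller than over $n$. With only ~3
disease-side anchors per drug the difference is learnable. A matched random
exclusion for negatives removes the effect (verified experimentally), but
would depart from the protocol implemented here, where negatives' indexes
are untouched. Random negative sets being slightly optimistic is an
acknowledged property of this family of protocols; the null-signal run
quantifies it.

## Numerical and degenerate-input conventions

* Unreachable (distance > 2) is the `NA_integer_` sentinel; it scores 0.
* Empty anchor sets and empty modules score 0; the geometric mean is 0 when
  either side is 0.
* Duplicate table rows are deduplicated silently; self-loop edges are
  dropped; duplicate edges merge with the union of their source tags.
* Even-count medians take the lower middle value.
* Ties in AUC count one half (midranks).
* The one-sided Fisher test is the upper hypergeometric tail, computed in
  log space, strict Tanimoto inequality at the 0.7 screen.

## Problem sizes used by the test suite

Unit and property tests run on graphs of up to 200 nodes with exhaustive
oracles (full BFS, brute-force pair enumeration, hypergeometric
enumeration). Statistical tests use the reference 500-node benchmark with
10x10-fold cross-validation, and the ablation comparison averages 5
evaluation seeds at 2 repeats each with feature matrices shared across the
three arms, making the comparison paired. These sizes were chosen so the
whole suite completes on a single CPU in minutes while keeping every
statistical check at the reference conditions.
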