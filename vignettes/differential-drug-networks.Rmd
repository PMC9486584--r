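---
title: "Differential multi-omics networks for drug response prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential multi-omics networks for drug response prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugdiffnet)
```

## The model

`drugdiffnet` predicts *differential* drug response between two sample
groups ("conditions") from unmatched multi-omics abundance data. The
underlying assumption is pharmacological: drugs act predominantly by
binding their targets and disturbing the targets' interactions with other
molecules, so the interactions *around* a drug's targets — and how they
differ between conditions — carry the signal for differential response.
Abundance correlation is used as a proxy for interaction strength, which
is the method's central modelling assumption and its main caveat:
correlation networks capture co-regulation, not physical binding.

The pipeline is:

1. per layer and condition, a complete Spearman correlation network over
   features, using pairwise-complete observations;
2. hard-threshold reduction keeping the largest-|weight| edges;
3. assembly of layers into one heterogeneous network per condition, with
   prior-knowledge connector edges between layers;
4. replacement of edge weights by **integrated interaction scores**

   $$s_{u,v} = \sum_{l=1}^{L} \frac{1}{|P_l(u,v)|}
     \sum_{k \in P_l(u,v)} \prod_{e \in k} w(e),$$

   where $P_l(u,v)$ is the set of simple paths of exactly $l$ edges
   between $u$ and $v$;
5. edge-wise contrast $d = s_A - s_B$ into a differential network
   (zero-filled for condition-specific edges);
6. per-drug scores $|\,\mathrm{mean}\; d\,|$ (or median) over the union
   of edges incident to the drug's targets, ranked descending.

The length-1 "path" is the direct edge itself, so $L = 1$ leaves weights
unchanged, and with all $|w| \le 1$ every score satisfies
$|s_{u,v}| \le L$. Paths are *simple* (no repeated node): allowing
revisits would count walks, whose number grows without bound and would
break that range; the bound is therefore part of the score's definition,
not an afterthought. Each geometrically distinct path is counted once
regardless of traversal direction, and a length with no paths contributes
0 rather than a 0/0 average.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| correlation `method` | `"spearman"` | rank-based, robust to outliers and monotone nonlinearity in abundances |
| `min_pairs` | 5 | minimal pairwise-complete observations per edge; below it, the correlation is too unstable and the pair gets no edge |
| reduction `method` | — | `average_degree` / `density` give direct size control; `scale_free` targets the topology many biological networks approximate |
| `r2_target` | 0.8 | minimal signed scale-free fit R²; relaxed in steps of 0.05 (with a warning) when the two conditions admit no common qualifying cut pair |
| `threshold_grid` | 0.1–0.9 by 0.02 | candidate |w| cuts for the scale-free search |
| `max_path_length` (L) | 3 | path horizon of the integration; length-3 paths already cross two layers of connectors, and enumeration cost grows as degree^(L−1) |
| `restrict_to_targets` | `TRUE` | compute integrated scores only for target-incident edges — the only edges drug scoring reads |
| `aggregator` | `"mean"` | per-drug aggregation of incident differentials; `median` is robust to a single extreme edge |
| `gt_threshold` | 0.01 | ground-truth p-value binarization for ROC analysis |

Scale-free fitting regresses $\log_{10} p(k)$ on $\log_{10} k$ over raw
occupied degree bins (no log-binning); the R² is sign-flipped when the
slope is positive, so a *rising* degree distribution can never qualify as
scale-free. Harmonization selects, among grid cut pairs where both
conditions reach the target fit, the pair with the most similar edge
counts — a deliberate guard against size imbalance biasing the
differential network. These harmonization rules (grid, target, relaxation
step) are package design choices, exposed as arguments rather than fixed
constants.

## Conventions and numerical choices

* **"More than X%" filters are strict.** `filter_zero_fraction()` (default
  0.9) and `filter_missing_fraction()` (default 0.2) drop a feature only
  when its fraction strictly exceeds the threshold; boundary features are
  kept. Zeros and missing values are distinct concepts with separate
  filters, and filtering is per condition — each condition's network is
  built on its own surviving features.
* **Ties at a reduction cut are all kept.** When the count-implied cut
  falls inside a block of equal |weights|, every tied edge is retained
  (slightly exceeding the target count) so the result is deterministic
  and independent of input order.
* **Zero-variance features** produce no edges rather than NaN weights;
  undefined correlations are simply absent.
* **Edges without a computed integrated score** (outside the
  target-incident set when restriction is on) retain their raw
  correlation weight and are flagged; they flow into the differential
  network for completeness but never into drug scores, whose incidence
  definition touches only computed edges.
* **Unscored drugs** (no edge incident to any mapped target) are reported
  explicitly instead of dropped, so evaluation can align drug sets.
  Rank ties are broken lexicographically by drug identifier.
* **Mann–Whitney ground truth** uses the exact two-sided p-value for
  tie-free groups of at most 10 each, and the tie-corrected normal
  approximation otherwise; a fully tied comparison (zero rank variance)
  is assigned p = 1. The exact branch is validated against complete
  enumeration of group assignments in the test suite.
* **ROC conventions.** Curves are built over descending predicted score;
  tied scores collapse into one diagonal segment, making the curve
  order-independent. The partial AUC is the *unnormalized* trapezoid area
  over false positive rates in [0, 0.1] — hence 0.1²/2 = 0.005 for an
  uninformative ranking and 0.1 for a perfect one, two analytic anchors
  the acceptance script recomputes.
* **Connector weights** are used as given; values outside [−1, 1] only
  warn, because they void the ±L score bound but may still be meaningful
  to the caller.

## What the synthetic generator emulates

`fixture_spec()` describes a two-condition dataset with block-correlated
features: each layer's features split into blocks, features of a block
load on a shared per-sample latent factor with loading $\sqrt{\rho}$, so
the within-block correlation is exactly $\rho$ (default 0.7). The factor
is shared across layers, mimicking the mRNA → protein → phosphosite
correspondence that same-name connectors exploit. In condition B the
perturbed blocks (default 5 of 10) use $\rho - \delta$ (default
$\delta = 0.6$) — the planted differential signal. Drugs target protein
features inside (differential drugs) or outside (null drugs) the
perturbed blocks; differential drugs additionally get a 3-SD sensitivity
shift in condition A with 10 replicates per condition, which gives the
Mann–Whitney ground truth high power at the 0.01 threshold. Five percent
of abundance entries are removed completely at random to exercise
pairwise-complete correlation. All randomness descends from one seed
(omics: seed, drugs: seed + 1, connectors: seed + 2), so any sub-table is
individually reproducible.

The default sizes — 3 layers × 300 features, 40 samples per condition,
50 drugs × 3 targets — keep a full pipeline run in the tens of seconds
while leaving room for 10 blocks with ~30 features each. Pipeline runs on
these fixtures use average-degree reduction (target 10): the block
design's degree distribution is intentionally far from scale-free
(within-block degrees cluster tightly), so forcing the scale-free
criterion there would test its relaxation path, not its purpose. The
scale-free machinery is instead validated on degree histograms with known
exact fits and on random graphs.

What passing these tests shows: the machinery — correlation, reduction,
assembly, path integration, differentials, scoring, evaluation — is
internally correct and recovers a planted covariance-structure signal.
What it does not show: performance on real tumor data, where abundance
distributions are heavy-tailed and zero-inflated, missingness is
informative, correlation blocks are not clean-cut, drug-target annotation
is incomplete, and cell-line ground truth only imperfectly reflects
patient response. The generator deliberately does not model
overdispersion, batch effects, or realistic marginals.

## Known limitations

* Correlation is symmetric and undirected; regulatory direction and
  sign-specific mechanisms are invisible.
* The differential score has no null model, so drug scores are a ranking,
  not a significance statement.
* Prediction quality is bounded by drug-target annotation quality:
  unannotated or mis-annotated targets propagate directly to the score.
* Path enumeration is exact but exponential in L; L beyond 3–4 on dense
  networks becomes expensive, which is why target-incident restriction is
  the default.
* Connector weights are taken as given; deriving them from interaction
  databases (scaling, evidence weighting) is out of scope.
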