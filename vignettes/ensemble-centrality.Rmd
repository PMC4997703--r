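---
title: "Ensemble centrality over co-expression-thresholded interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble centrality over co-expression-thresholded interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EnPIN)
```

## The model

Essential-protein prediction from a protein-protein interaction network
(PIN) usually ranks proteins by a centrality measure and takes the top *n*
as candidates. EnPIN treats that single ranking as one vote among many. Two
assumptions drive the design: (a) essential proteins tend to be co-expressed
with some of their interaction partners, and (b) interactions joining two
highly co-expressed proteins matter more for essentiality than interactions
joining uncorrelated ones. Under these assumptions, deleting weakly
co-expressed edges should *concentrate* the network around
essentiality-relevant structure, and centrality computed on the pruned
networks should be more informative — at the price of losing whatever true
signal the deleted edges carried. The ensemble keeps both: it scores every
protein on the original network *and* on a series of progressively pruned
ones, then combines the scores so that heavily pruned, high-confidence
networks dominate without the original network's evidence being discarded.

Formally, each edge gets the Pearson correlation coefficient (PCC) of its
endpoints' expression profiles. A threshold schedule thr₁ < … < thrₘ
produces member networks; member *i* keeps edge *e* iff |w(e)| ≥ thrᵢ
(absolute strategy) or w(e) ≥ thrᵢ (uniform strategy). Each member is scored
with one base measure — DC, BC, CC, EC or SC — zero-degree proteins are
masked to 0, columns are divided by their maximum, and the final score is
the weighted vote fs(j) = Σᵢ s(j,i)·wᵢ with non-decreasing positive
weights, w₁ = 1 for the original network.

## Parameters that matter

- **Threshold schedule** (unitless PCC cutoffs). Absolute default
  0, 0.1, …, 0.8, 0.9, 0.91, …, 0.95 (m = 15): the dense sampling above 0.9
  deliberately over-represents the near-clique co-expression regime, where
  centrality measures are at their most informative. Uniform default
  −0.7, …, 0.8, 0.9, 0.91, 0.92 (m = 19); its negative thresholds barely
  change the network and mostly serve as flat-weight padding. Both are
  user-overridable; the right range depends on the organism and the
  expression compendium's dynamic range.
- **Voting weights.** `w4` (1, 2, 3, 5, …, 987; each weight the sum of its
  two predecessors) is the default: the vote is dominated by the
  highest-threshold networks while every earlier network still contributes.
  `w1` (flat) is the bagging-style baseline, `w2` a linear ramp, `w3` a
  prior-guided ramp that treats the first eight networks (thresholds ≤ 0.7)
  as exchangeable. Rescaling a weight vector by any positive constant
  provably leaves the ranking unchanged, so only the weight *profile*
  matters.
- **Base measure.** DC, EC and SC are local/spectral and cheap; BC and CC
  are global shortest-path measures, noticeably more sensitive to spurious
  edges — which is precisely why they gain the most from pruning.
- **PCC-threshold baseline cutoff** (0.75): the weight at which essential
  and nonessential proteins' co-expression distributions begin to separate;
  also the default cutoff for the IBEP (interaction-between-essential-
  proteins) fraction.

## Numerical choices

- **Retention is ≥ thr** (delete strictly below). This makes thr = 0 under
  the absolute strategy reproduce the original PIN exactly — the anchor the
  weight convention w₁ = 1 presumes.
- **Zero-variance expression ⇒ PCC = 0.** Proteins without expression data
  are zero-filled; a constant profile carries no co-expression evidence, so
  its edges get weight 0 and survive only in low-threshold members. The
  alternative (NA) would silently shrink the edge set.
- **Zero-degree mask before normalization, for every measure.** Only
  proteins that still have interactions in a member can earn a score there.
  SC is the one measure whose mathematical value for an isolated node is
  positive (exp(A)₍ᵥᵥ₎ = 1); without the mask, every stranded protein would
  get the same positive floor in every sparse member, and the heavily
  weighted sparse columns would drown the signal. All-zero columns are left
  as zeros rather than 0/0.
- **Closeness on disconnected graphs** uses the Wasserman–Faust component
  scaling (|R|/(n−1)) · (|R|/Σd), so a tight two-node component does not
  outrank the giant component's core; isolated proteins score 0.
- **Eigenvector centrality on disconnected graphs** is computed per
  connected component; the dominant component is the one with the largest
  leading eigenvalue, and an exact tie is broken toward the component
  containing the lexicographically smallest protein id. The tie rule is not
  cosmetic: thresholding can leave several spectrally identical modules
  (e.g. same-size cliques), and without a deterministic rule the ranking
  would depend on LAPACK's arbitrary choice of basis.
- **Ties in the final ranking** are broken by ascending protein id, with
  scores compared at 12 significant digits — spectrally equivalent proteins
  can differ by an ulp after an eigendecomposition, and that noise should
  not override the deterministic order. A seeded random tie mode is
  available for studying tie sensitivity.
- **Betweenness is unnormalized** (raw pair-count form): the per-member
  max-normalization removes scale anyway, and only order enters the vote.
- **Node strength sums raw, signed PCCs** (an `abs.weights` switch is
  provided). Signed weights keep anti-correlated partners from inflating a
  protein's apparent co-expression support; the same convention feeds the
  PCC-weighted baseline, whose EC/SC operate on the signed weighted
  adjacency.

## The synthetic benchmark

`syntheticSpec()` defaults describe the standard benchmark: 300 proteins
with 36 expression samples (the size of the classical yeast compendium),
12 planted essential modules of 5 proteins each, 20 decoy hubs of degree
25, an Erdős–Rényi background of mean degree 4, and a within-module
expression correlation target of 0.9. Modules are cliques whose members
share a standard-normal latent profile plus N(0, σ) noise with
σ = √(1/r − 1), the closed form that makes the expected pairwise member
correlation equal the target r. Decoy hubs are the adversarial ingredient:
they have top-decile degree but uncorrelated neighbourhoods, so plain
degree ranking promotes them while the ensemble discards their edges at the
first threshold. Generation is deterministic per seed, with the RNG stream
consumed in a fixed order (topology, then expression), so adding parameters
later cannot silently shift existing fixtures.

What passing on this benchmark shows — and does not. The generator
reproduces the *mechanism* the framework exploits (co-expressed essential
modules, uncorrelated hubs). It does not reproduce yeast's degree
distribution, overlapping complexes, correlated noise between samples,
false-negative interactions, or essential proteins *outside* co-expressed
modules. Recovery of all 60 planted essentials here is a statement about
the mechanism, not a forecast of counts on DIP- or BioGRID-scale data,
where database version alone moves every number.

## Problem sizes and runtime

The test suite exercises exact oracles (brute-force shortest-path
enumeration, truncated matrix-exponential series, shifted power iteration,
hand BFS) on 200 random graphs of ≤ 7 nodes, and runs the full pipeline on
ten replicate 300-protein benchmarks; the whole suite completes in well
under a minute on one core. Dense eigendecompositions bound the practical
scale of EC/SC to a few thousand proteins per network; DC/BC/CC go further
via igraph's C implementations. All measures are exact — no sampled
betweenness — since interactome-scale graphs remain tractable.

## Known limitations

- Identifier harmonisation between interaction databases and expression
  data is out of scope; inputs are assumed to share one namespace.
- One base measure per ensemble; combining different measures into a single
  vote is deliberately not offered.
- KS p-values are not computed in-package (the D statistic is); feed the
  samples to `stats::ks.test` if a p-value is needed for reporting.
- The uniform strategy's printed default schedule starts at −0.7 regardless
  of the data's actual minimum PCC; the printed list is taken as
  authoritative and negative thresholds are simply identity members when
  minPCC > thr.
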