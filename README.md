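# EnPIN

Essential proteins — those whose loss is lethal — are enriched among highly
connected nodes of protein-protein interaction networks (PINs), the
"centrality-lethality" rule. But plain centrality rankings are easily fooled:
interaction screens are noisy, and many hubs owe their degree to spurious or
condition-irrelevant contacts. EnPIN implements an ensemble framework that
sharpens any base centrality measure with gene-expression evidence, for
researchers prioritising knockout or essentiality candidates from an
interactome plus an expression compendium.

## The method

Given a PIN *G(V, E)* and an expression matrix, the framework runs four
steps:

1. **Data partition.** Each interaction gets a co-expression weight: the
   Pearson correlation coefficient (PCC) between its endpoints' expression
   profiles. A series of *m* networks is generated by deleting edges below
   each threshold of a schedule — either *|PCC| ≥ thr* ("absolute",
   default thr = 0, 0.1, …, 0.8, 0.9, 0.91, …, 0.95, so *m* = 15) or signed
   *PCC ≥ thr* ("uniform", thr = −0.7, …, 0.8, 0.9, 0.91, 0.92, *m* = 19).
   Nodes are never removed.
2. **Grading.** Every protein is scored on every member network with a base
   centrality measure — degree (DC), betweenness (BC), closeness (CC),
   eigenvector (EC) or subgraph (SC) centrality. Zero-degree proteins score
   0, and each network's scores are divided by their maximum.
3. **Integrating.** Scores are combined by weighted voting,

   *fs(j) = Σᵢ s(j, i) · wᵢ*,

   with non-decreasing weights so high-threshold networks — whose surviving
   edges join strongly co-expressed proteins — dominate. The default is the
   Fibonacci-style "dominant" vector w4 = {1, 2, 3, 5, …, 610, 987};
   w1 (flat), w2 (1..15) and w3 (prior-guided) are also provided.
4. **Ranking.** Proteins are sorted by *fs*, descending; the leading *n*
   are the essentiality candidates.

The package also ships the two single-network baselines (PCC-threshold at
0.75 and the signed PCC-weighted network, the latter restricted to DC/EC/SC
since BC and CC require positive weights), the evaluation battery (top-*n*
essential counts, pairwise/multi-way ranking overlaps, low-degree analysis,
node strength, union-top-*n* score correlation, co-expression weight
distributions with the two-sample KS statistic), and a seeded synthetic
benchmark generator with planted co-expressed essential modules and decoy
hubs.

## Worked example

```r
library(EnPIN)

syn  <- generateSynthetic(syntheticSpec(seed = 1))   # 300 proteins, 36 samples
dc   <- rankProteins(centralityScores(syn$network, "DC"))
endc <- runEnsemble(syn$network, syn$expression, measure = "DC")

essentialInTop(dc,   syn$essential, 60)   # 0
essentialInTop(endc, syn$essential, 60)   # 60

corr <- edgeCorrelations(syn$network, attachMissing(syn$network, syn$expression))
lowDegreeAnalysis(endc, dc, syn$network, corr, syn$essential, 60)
```

On this benchmark plain degree centrality finds 0 of the 60 planted
essential proteins in its top 60 — the 20 decoy hubs and their partners
crowd them out — while the dominant-weighted degree ensemble (EnDC) finds
all 60. The low-degree analysis shows why: the ensemble's picks average
degree 4.0 against 15.3 for DC's picks, all 60 lie below DC's minimal
top-60 degree of 9 (`low_degree_count = 60`), yet their average node
strength is 3.62 versus −0.10 — they are weakly connected but strongly
co-expressed with their partners.

Real data come in as plain text: `readNetwork()` (two-column edge list,
`#` comments, self-loops and duplicates dropped), `readExpression()`
(TSV with a sample-label header), `readEssentialSet()` (one id per line);
proteins without expression data are zero-filled by `attachMissing()`.
`writeRanking()` emits an annotated TSV. A thin command-line wrapper lives
at `inst/scripts/enpin.R`.

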