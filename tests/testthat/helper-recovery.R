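# The standard synthetic-recovery experiment: for each seed, generate the
# default benchmark, rank with the three local base measures and their
# absolute-strategy dominant-weight ensembles, and collect top-60 recovery,
# pairwise essential overlaps, and degree statistics.
runRecoveryExperiment <- function(seeds, n_top = 60) {
  res <- lapply(seeds, function(s) {
    syn <- generateSynthetic(syntheticSpec(seed = s))
    deg <- igraph::degree(syn$network)
    base <- lapply(c(DC = "DC", EC = "EC", SC = "SC"), function(m) {
      sc <- centralityScores(syn$network, m)
      sc[deg == 0] <- 0
      rankProteins(sc)
    })
    ens <- lapply(c(DC = "DC", EC = "EC", SC = "SC"), function(m)
      runEnsemble(syn$network, syn$expression, m, "absolute",
                  weights = namedWeights("w4")))
    tops <- function(ranks) vapply(ranks, essentialInTop,
                                   numeric(1), essential = syn$essential,
                                   n = n_top)
    pairMean <- function(ranks) {
      prs <- utils::combn(names(ranks), 2, simplify = FALSE)
      mean(vapply(prs, function(p)
        pairwiseOverlap(ranks[[p[1]]], ranks[[p[2]]],
                        syn$essential, n_top)$essential_overlap,
        numeric(1)))
    }
    expr <- attachMissing(syn$network, syn$expression)
    corr <- edgeCorrelations(syn$network, expr)
    ld <- lowDegreeAnalysis(ens$DC, base$DC, syn$network, corr,
                            syn$essential, n_top)
    list(base_top = tops(base), ens_top = tops(ens),
         base_pair = pairMean(base), ens_pair = pairMean(ens),
         low_degree = ld)
  })
  list(
    base_top = t(vapply(res, `[[`, numeric(3), "base_top")),
    ens_top = t(vapply(res, `[[`, numeric(3), "ens_top")),
    base_pair = vapply(res, `[[`, numeric(1), "base_pair"),
    ens_pair = vapply(res, `[[`, numeric(1), "ens_pair"),
    ens_avg_degree = vapply(res, function(r) r$low_degree$ens_avg_degree,
                            numeric(1)),
    base_avg_degree = vapply(res, function(r) r$low_degree$base_avg_degree,
                             numeric(1)),
    low_degree_count = vapply(res, function(r) r$low_degree$low_degree_count,
                              numeric(1)),
    low_degree_essential = vapply(res,
      function(r) r$low_degree$low_degree_essential_count, numeric(1)))
}
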