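#' Number of true essential proteins among the top-n candidates
#'
#' @param rank an [EssentialRanking-class].
#' @param essential character vector of reference essential ids.
#' @param n number of leading candidates to take.
#' @return integer count, at most \code{min(n, |essential|)}.
#' @export
essentialInTop <- function(rank, essential, n) {
  if (n < 1L) stop("n must be >= 1")
  sum(topProteins(rank, n) %in% essential)
}

#' Overlap between the top-n sets of two rankings
#'
#' @param rankA,rankB [EssentialRanking-class] objects covering >= n
#'   proteins.
#' @param essential character vector of reference essential ids.
#' @param n top-set size (conventionally 100).
#' @return list with \code{overlap} (|topA intersect topB|) and
#'   \code{essential_overlap} (true essentials within the overlap).
#' @export
pairwiseOverlap <- function(rankA, rankB, essential, n) {
  common <- intersect(topProteins(rankA, n), topProteins(rankB, n))
  list(overlap = length(common),
       essential_overlap = sum(common %in% essential))
}

#' Overlap among the top-n sets of several rankings
#'
#' @param ranks list of >= 2 [EssentialRanking-class] objects.
#' @param essential character vector of reference essential ids.
#' @param n top-set size.
#' @return list with \code{overlap} and \code{essential_overlap} for the
#'   intersection of all top-n sets.
#' @export
multiOverlap <- function(ranks, essential, n) {
  if (length(ranks) < 2L) stop("need at least two rankings")
  tops <- lapply(ranks, topProteins, n = n)
  common <- Reduce(intersect, tops)
  list(overlap = length(common),
       essential_overlap = sum(common %in% essential))
}

#' Low-degree analysis of an ensemble ranking against its base measure
#'
#' Contrasts the ensemble method's top-n picks against the original-network
#' hubs favored by its base centrality measure. The minimal degree is taken
#' over the base measure's top n in the ORIGINAL network; a pick of the
#' ensemble is "low-degree" when its original-network degree falls below
#' that minimum — such proteins are invisible to the base measure but can be
#' promoted by strong co-expression. Also reports average/minimal degree and
#' average node strength over each method's top n.
#'
#' @param ensRank,baseRank [EssentialRanking-class] objects covering >= n
#'   proteins (ensemble method and base centrality measure).
#' @param net the ORIGINAL igraph PIN (degrees and strengths always refer to
#'   it, never to a thresholded member).
#' @param corr an [EdgeCorrelations-class] on \code{net}.
#' @param essential character vector of reference essential ids.
#' @param n top-set size.
#' @return list with fields \code{ens_avg_degree}, \code{ens_min_degree},
#'   \code{base_avg_degree}, \code{base_min_degree},
#'   \code{low_degree_count}, \code{low_degree_essential_count},
#'   \code{ens_avg_strength}, \code{base_avg_strength}.
#' @export
lowDegreeAnalysis <- function(ensRank, baseRank, net, corr, essential, n) {
  deg <- igraph::degree(net)
  strength <- nodeStrength(net, corr)
  topE <- topProteins(ensRank, n)
  topB <- topProteins(baseRank, n)
  base_min <- min(deg[topB])
  low <- topE[deg[topE] < base_min]
  stopifnot(!any(low %in% topB))  # low-degree picks cannot be base hubs
  list(ens_avg_degree = mean(deg[topE]),
       ens_min_degree = min(deg[topE]),
       base_avg_degree = mean(deg[topB]),
       base_min_degree = base_min,
       low_degree_count = length(low),
       low_degree_essential_count = sum(low %in% essential),
       ens_avg_strength = mean(strength[topE]),
       base_avg_strength = mean(strength[topB]))
}

#' Score correlation of two methods over the union of their top-n sets
#'
#' Pearson correlation between two methods' final scores, computed over the
#' union of their top-n protein sets.
#'
#' @param scoresA,scoresB named numeric final-score vectors covering the
#'   union of both top-n sets.
#' @param rankA,rankB the corresponding [EssentialRanking-class] objects.
#' @param n top-set size.
#' @return numeric(1) correlation.
#' @export
unionTopCorrelation <- function(scoresA, scoresB, rankA, rankB, n) {
  u <- union(topProteins(rankA, n), topProteins(rankB, n))
  if (length(u) < 2L) stop("union of top sets has fewer than 2 proteins")
  if (anyNA(scoresA[u]) || anyNA(scoresB[u]))
    stop("score maps do not cover the union of top sets")
  pcc(scoresA[u], scoresB[u])
}

#' PCC-threshold baseline: one network, one hard cutoff
#'
#' Ranks proteins by a base centrality measure applied to the single network
#' obtained by deleting every interaction with |PCC| below the cutoff
#' (default 0.75 — the weight at which essential and nonessential proteins
#' start showing different co-expression distributions). Zero-degree
#' proteins score 0.
#'
#' @param net an igraph PIN.
#' @param corr an [EdgeCorrelations-class] on \code{net}.
#' @param measure one of "DC", "BC", "CC", "EC", "SC".
#' @param thr absolute PCC cutoff.
#' @return an [EssentialRanking-class].
#' @export
pccThresholdBaseline <- function(net, corr, measure = MEASURES, thr = 0.75) {
  measure <- match.arg(measure)
  g <- filterByCorrelation(net, corr, thr, "absolute")
  s <- centralityScores(g, measure)
  s[igraph::degree(g) == 0L] <- 0
  rankProteins(s)
}

#' PCC-weighted baseline: centrality on the signed-weighted original PIN
#'
#' Ranks proteins by [weightedCentrality()] on the original network with
#' each interaction weighted by its signed PCC. Restricted to DC, EC and SC.
#'
#' @param net an igraph PIN.
#' @param corr an [EdgeCorrelations-class] on \code{net}.
#' @param measure one of "DC", "EC", "SC".
#' @return an [EssentialRanking-class].
#' @export
pccWeightedBaseline <- function(net, corr, measure) {
  rankProteins(weightedCentrality(net, corr, measure))
}
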