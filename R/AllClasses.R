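#' @import methods
#' @importFrom stats cor sd quantile rnorm runif setNames
#' @importFrom utils read.table write.table head
NULL

setOldClass("igraph")

# Canonical key for an unordered protein pair. Ids come from
# whitespace-delimited files, so "\t" can never occur inside an id.
edgeKey <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\t")
}

#' EdgeCorrelations: per-edge co-expression weights of a PIN
#'
#' Holds one Pearson correlation coefficient (PCC) per edge of the network it
#' was computed from, together with the extreme values \code{maxPCC} and
#' \code{minPCC}. Weights are keyed by unordered protein pair.
#'
#' @slot edges data.frame with columns \code{u}, \code{v}, \code{weight}; one
#'   row per edge, each weight in \code{[-1, 1]}.
#' @slot maxPCC,minPCC numeric(1), the extreme weights (\code{NA} when the
#'   edge set is empty).
#'
#' @seealso [edgeCorrelations()] which constructs this class,
#'   [edgeWeights()], [nodeStrength()]
#' @exportClass EdgeCorrelations
setClass("EdgeCorrelations",
  representation(edges = "data.frame", maxPCC = "numeric", minPCC = "numeric"))

setValidity("EdgeCorrelations", function(object) {
  ed <- object@edges
  if (!all(c("u", "v", "weight") %in% names(ed)))
    return("edges must have columns u, v, weight")
  if (nrow(ed) > 0L) {
    if (any(!is.finite(ed$weight)) || any(ed$weight < -1 - 1e-12) ||
        any(ed$weight > 1 + 1e-12))
      return("weights must be finite and lie in [-1, 1]")
    if (any(ed$u == ed$v)) return("self-loop in correlation map")
    if (anyDuplicated(edgeKey(ed$u, ed$v)))
      return("duplicate edge in correlation map")
    if (abs(object@maxPCC - max(ed$weight)) > 1e-12 ||
        abs(object@minPCC - min(ed$weight)) > 1e-12)
      return("maxPCC/minPCC inconsistent with weights")
  }
  TRUE
})

#' NetworkSeries: thresholded series of PINs
#'
#' The result of the data-partition step: the base network plus the ordered
#' list of member networks obtained by deleting edges below each threshold.
#' All members share the base node set; edge sets are nested non-increasing.
#'
#' @slot base igraph, the original PIN.
#' @slot strategy "absolute" (keep |PCC| >= thr) or "uniform" (keep
#'   signed PCC >= thr).
#' @slot thresholds strictly increasing numeric vector thr_1..thr_m.
#' @slot members list of igraph, one per threshold.
#'
#' @seealso [buildSeries()], [seriesMembers()], [thresholds()]
#' @exportClass NetworkSeries
setClass("NetworkSeries",
  representation(base = "igraph", strategy = "character",
                 thresholds = "numeric", members = "list"))

setValidity("NetworkSeries", function(object) {
  if (!object@strategy %in% c("absolute", "uniform"))
    return("strategy must be 'absolute' or 'uniform'")
  m <- length(object@thresholds)
  if (length(object@members) != m)
    return("members and thresholds lengths differ")
  if (m > 1L && any(diff(object@thresholds) <= 0))
    return("thresholds must be strictly increasing")
  base_nodes <- sort(igraph::V(object@base)$name)
  prev_ecount <- Inf
  for (g in object@members) {
    if (!identical(sort(igraph::V(g)$name), base_nodes))
      return("member node set differs from base node set")
    if (igraph::ecount(g) > prev_ecount)
      return("member edge counts must be non-increasing")
    prev_ecount <- igraph::ecount(g)
  }
  TRUE
})

#' ScoreMatrix: normalized per-network centrality scores
#'
#' Protein-by-network matrix of max-normalized centrality scores s(j, i): the
#' grading step applied to a [NetworkSeries-class]. Every column is either
#' all-zero (an edgeless member) or attains maximum exactly 1.
#'
#' @slot scores numeric matrix, rows = proteins, one column per member.
#' @slot measure the base centrality measure ("DC", "BC", "CC", "EC", "SC").
#' @slot thresholds the series thresholds labelling the columns.
#'
#' @seealso [gradeSeries()], [integrateScores()]
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
  representation(scores = "matrix", measure = "character",
                 thresholds = "numeric"))

setValidity("ScoreMatrix", function(object) {
  s <- object@scores
  if (ncol(s) != length(object@thresholds))
    return("column count must match thresholds length")
  if (is.null(rownames(s))) return("scores must have protein rownames")
  if (any(!is.finite(s)) || any(s < 0)) return("scores must be finite and >= 0")
  cmax <- if (nrow(s)) apply(s, 2L, max) else numeric(ncol(s))
  bad <- cmax > 0 & abs(cmax - 1) > 1e-9
  if (any(bad))
    return("every nonzero column must have maximum exactly 1")
  TRUE
})

#' EssentialRanking: proteins ordered by final essentiality score
#'
#' Proteins sorted by descending final score fs(j); exact ties are broken by
#' ascending protein id so reruns are reproducible.
#'
#' @slot table data.frame with columns \code{protein} (character) and
#'   \code{score} (numeric, non-increasing).
#'
#' @seealso [rankProteins()], [runEnsemble()], [topProteins()]
#' @exportClass EssentialRanking
setClass("EssentialRanking", representation(table = "data.frame"))

setValidity("EssentialRanking", function(object) {
  tb <- object@table
  if (!all(c("protein", "score") %in% names(tb)))
    return("table must have columns protein, score")
  if (anyDuplicated(tb$protein)) return("duplicate protein in ranking")
  if (nrow(tb) > 1L && any(diff(tb$score) > 1e-12))
    return("scores must be non-increasing")
  TRUE
})
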