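#' @describeIn EdgeCorrelations-class named numeric vector of weights; names
#'   are tab-joined sorted id pairs
#' @export
setMethod("edgeWeights", "EdgeCorrelations", function(x) {
  setNames(x@edges$weight, edgeKey(x@edges$u, x@edges$v))
})

#' @describeIn EdgeCorrelations-class maximal PCC over the edges
#' @export
setMethod("maxPCC", "EdgeCorrelations", function(x) x@maxPCC)

#' @describeIn EdgeCorrelations-class minimal PCC over the edges
#' @export
setMethod("minPCC", "EdgeCorrelations", function(x) x@minPCC)

setMethod("show", "EdgeCorrelations", function(object) {
  cat("EdgeCorrelations with", nrow(object@edges), "edge weights\n")
  if (nrow(object@edges))
    cat(sprintf("  minPCC = %.4f, maxPCC = %.4f\n",
                object@minPCC, object@maxPCC))
})

#' @describeIn NetworkSeries-class list of member igraph networks
#' @export
setMethod("seriesMembers", "NetworkSeries", function(x) x@members)

#' @describeIn NetworkSeries-class the threshold vector thr_1..thr_m
#' @export
setMethod("thresholds", "NetworkSeries", function(x) x@thresholds)

setMethod("length", "NetworkSeries", function(x) length(x@members))

setMethod("show", "NetworkSeries", function(object) {
  cat(sprintf("NetworkSeries (%s thresholding): m = %d member PINs\n",
              object@strategy, length(object@members)))
  cat(sprintf("  base: %d proteins, %d interactions\n",
              igraph::vcount(object@base), igraph::ecount(object@base)))
  ec <- vapply(object@members, igraph::ecount, numeric(1))
  cat("  member edge counts:", paste(ec, collapse = " "), "\n")
})

#' @describeIn ScoreMatrix-class the protein-by-network score matrix
#' @export
setMethod("scoreValues", "ScoreMatrix", function(x) x@scores)

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d proteins x %d PINs (measure %s)\n",
              nrow(object@scores), ncol(object@scores), object@measure))
})

setMethod("dim", "ScoreMatrix", function(x) dim(x@scores))

#' @describeIn EssentialRanking-class ids of the n top-ranked proteins
#' @export
setMethod("topProteins", "EssentialRanking", function(x, n) {
  if (n > nrow(x@table))
    stop("n = ", n, " exceeds ranking length ", nrow(x@table))
  x@table$protein[seq_len(n)]
})

#' @describeIn EssentialRanking-class named vector of final scores fs(j)
#' @export
setMethod("finalScores", "EssentialRanking", function(x) {
  setNames(x@table$score, x@table$protein)
})

setMethod("length", "EssentialRanking", function(x) nrow(x@table))

setMethod("show", "EssentialRanking", function(object) {
  cat("EssentialRanking of", nrow(object@table), "proteins\n")
  print(head(object@table, 5L))
  if (nrow(object@table) > 5L) cat("  ...\n")
})

#' @export
#' @method as.data.frame EssentialRanking
as.data.frame.EssentialRanking <- function(x, ...) x@table

setMethod("as.data.frame", "EssentialRanking",
          function(x, ...) as.data.frame.EssentialRanking(x, ...))
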