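#' @rdname EdgeCorrelations-class
#' @param x an object
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname EdgeCorrelations-class
#' @export
setGeneric("maxPCC", function(x) standardGeneric("maxPCC"))

#' @rdname EdgeCorrelations-class
#' @export
setGeneric("minPCC", function(x) standardGeneric("minPCC"))

#' @rdname NetworkSeries-class
#' @param x an object
#' @export
setGeneric("seriesMembers", function(x) standardGeneric("seriesMembers"))

#' @rdname NetworkSeries-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname ScoreMatrix-class
#' @param x an object
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname EssentialRanking-class
#' @param x an object
#' @param n number of leading proteins
#' @export
setGeneric("topProteins", function(x, n) standardGeneric("topProteins"))

#' @rdname EssentialRanking-class
#' @export
setGeneric("finalScores", function(x) standardGeneric("finalScores"))
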