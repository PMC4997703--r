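#' Default threshold schedules for the two thresholding strategies
#'
#' The absolute strategy uses thr = 0, 0.1, ..., 0.8, 0.9, 0.91, ..., 0.95
#' (m = 15 networks; the dense sampling above 0.9 is deliberate — those
#' networks retain mostly edges between highly co-expressed proteins). The
#' uniform (signed) strategy uses thr = -0.7, -0.6, ..., 0.8, 0.9, 0.91,
#' 0.92 (m = 19). Both schedules are overridable in [buildSeries()];
#' threshold choice is organism- and dataset-dependent.
#'
#' @param strategy "absolute" or "uniform".
#' @return strictly increasing numeric vector of thresholds.
#' @export
defaultSchedule <- function(strategy = c("absolute", "uniform")) {
  strategy <- match.arg(strategy)
  if (strategy == "absolute")
    c(seq(0, 0.8, by = 0.1), seq(0.9, 0.95, by = 0.01))
  else
    c(seq(-0.7, 0.8, by = 0.1), seq(0.9, 0.92, by = 0.01))
}

#' Delete weakly co-expressed interactions from a PIN
#'
#' Returns the network retaining edge e iff its co-expression weight passes
#' the threshold: \code{|weight| >= thr} under the absolute strategy,
#' signed \code{weight >= thr} under the uniform strategy. Deletion is
#' strict-below so thr = 0 under the absolute strategy reproduces the
#' original PIN exactly. Nodes are never removed; proteins that lose all
#' interactions remain as zero-degree vertices (and will receive zero
#' centrality scores downstream).
#'
#' @param net an igraph PIN.
#' @param corr an [EdgeCorrelations-class] covering every edge of \code{net}.
#' @param thr the threshold (\code{>= 0} for "absolute").
#' @param strategy "absolute" or "uniform".
#' @return an igraph with the same vertex set and the filtered edge set.
#' @export
filterByCorrelation <- function(net, corr, thr,
                                strategy = c("absolute", "uniform")) {
  strategy <- match.arg(strategy)
  if (strategy == "absolute" && thr < 0)
    stop("absolute thresholds must be >= 0")
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) return(net)
  w <- edgeWeights(corr)[edgeKey(el[, 1L], el[, 2L])]
  if (anyNA(w))
    stop("correlation map is missing a weight for an edge of the network")
  keep <- if (strategy == "absolute") abs(w) >= thr else w >= thr
  igraph::delete_edges(net, which(!keep))
}

#' Build the thresholded series of PINs (data partition)
#'
#' Applies [filterByCorrelation()] at each threshold of the schedule,
#' producing the ordered series of m networks that the ensemble scores. With
#' an increasing schedule the member edge sets are nested non-increasing by
#' construction; node sets never change.
#'
#' @param net the original igraph PIN.
#' @param corr an [EdgeCorrelations-class] on \code{net}.
#' @param strategy "absolute" or "uniform".
#' @param schedule threshold vector; default [defaultSchedule()] for the
#'   strategy.
#' @return a [NetworkSeries-class].
#' @export
buildSeries <- function(net, corr, strategy = c("absolute", "uniform"),
                        schedule = defaultSchedule(strategy)) {
  strategy <- match.arg(strategy)
  if (length(schedule) == 0L) stop("schedule must be non-empty")
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  members <- lapply(schedule, function(thr)
    filterByCorrelation(net, corr, thr, strategy))
  new("NetworkSeries", base = net, strategy = strategy,
      thresholds = as.numeric(schedule), members = members)
}
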