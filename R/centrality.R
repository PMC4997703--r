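MEASURES <- c("DC", "BC", "CC", "EC", "SC")

# Signed weighted adjacency matrix of net under corr, protein names on dims.
weightedAdjacency <- function(net, corr, abs.weights = FALSE) {
  nodes <- igraph::V(net)$name
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ed <- corr@edges
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el)) {
    w <- edgeWeights(corr)[edgeKey(el[, 1L], el[, 2L])]
    if (anyNA(w))
      stop("correlation map is missing a weight for an edge of the network")
    if (abs.weights) w <- abs(w)
    A[cbind(el[, 1L], el[, 2L])] <- w
    A[cbind(el[, 2L], el[, 1L])] <- w
  }
  A
}

# Principal eigenvector of a symmetric matrix restricted to graph components.
# The dominant component is the one attaining the maximal leading eigenvalue;
# exact ties are broken toward the component holding the lexicographically
# smallest protein id, so e.g. spectrally identical cliques rank
# deterministically. Nodes outside the dominant component score 0.
principalComponentEigenvector <- function(net, A) {
  nodes <- rownames(A)
  out <- setNames(numeric(length(nodes)), nodes)
  if (length(nodes) == 0L) return(out)
  comp <- igraph::components(net)
  memb <- split(nodes, comp$membership[nodes])
  lead <- lapply(memb, function(ids) {
    if (length(ids) == 1L) return(list(lambda = 0, vec = setNames(1, ids)))
    e <- eigen(A[ids, ids, drop = FALSE], symmetric = TRUE)
    v <- e$vectors[, 1L]
    if (sum(v) < 0) v <- -v
    list(lambda = e$values[1L], vec = setNames(v, ids))
  })
  lambdas <- vapply(lead, `[[`, numeric(1), "lambda")
  top <- max(lambdas)
  if (top <= 1e-12) return(out)  # edgeless graph: every protein scores 0
  tied <- which(lambdas >= top - 1e-9)
  firsts <- vapply(tied, function(i) min(memb[[i]]), character(1))
  pick <- tied[order(firsts)][1L]
  v <- lead[[pick]]$vec
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  out[names(v)] <- v
  out
}

# diag(expm(A)) for symmetric A via eigendecomposition.
expmDiag <- function(A) {
  if (nrow(A) == 0L) return(setNames(numeric(0), character(0)))
  e <- eigen(A, symmetric = TRUE)
  setNames(drop((e$vectors^2) %*% exp(e$values)), rownames(A))
}

#' Base centrality scores of every protein in a PIN
#'
#' Computes one of the five base centrality measures on an unweighted,
#' undirected PIN:
#' \describe{
#'   \item{DC}{degree — number of interaction partners.}
#'   \item{BC}{betweenness — for each protein, the sum over unordered pairs
#'     \eqn{\{s,t\}} of the fraction of shortest s-t paths passing through
#'     it; unnormalized (the downstream per-network max-normalization
#'     removes scale anyway).}
#'   \item{CC}{closeness — reciprocal average shortest distance to reachable
#'     proteins, with Wasserman-Faust component scaling
#'     \eqn{(|R|/(n-1)) \cdot (|R|/\sum d)} so proteins in small components
#'     are not inflated; isolated proteins score 0.}
#'   \item{EC}{eigenvector — nonnegative principal eigenvector (unit
#'     Euclidean norm) of the adjacency matrix; on a disconnected network,
#'     proteins outside the spectrally dominant component score 0, with an
#'     exact tie between components broken toward the one holding the
#'     lexicographically smallest id.}
#'   \item{SC}{subgraph — weighted count of closed walks through the
#'     protein, \eqn{[\exp(A)]_{vv}}, shorter walks weighted more; an
#'     isolated protein scores 1 (the length-0 walk).}
#' }
#'
#' @param net an igraph PIN.
#' @param measure one of "DC", "BC", "CC", "EC", "SC".
#' @return named numeric vector over all proteins of \code{net}.
#' @export
centralityScores <- function(net, measure = MEASURES) {
  measure <- match.arg(measure)
  nodes <- igraph::V(net)$name
  switch(measure,
    DC = igraph::degree(net),
    BC = igraph::betweenness(net, directed = FALSE, weights = NA),
    CC = closenessWF(net),
    EC = principalComponentEigenvector(
      net, as.matrix(igraph::as_adjacency_matrix(net, type = "both"))),
    SC = setNames(igraph::subgraph_centrality(net, diag = TRUE), nodes))
}

# Wasserman-Faust closeness on possibly disconnected graphs.
closenessWF <- function(net) {
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  out <- setNames(numeric(n), nodes)
  if (n <= 1L) return(out)
  d <- igraph::distances(net)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r > 0L)
      out[i] <- (r / (n - 1)) * (r / sum(reach))
  }
  out
}

#' Centrality on the PCC-weighted PIN
#'
#' Applies a centrality measure to the original PIN with each interaction
#' weighted by its signed co-expression PCC. Only DC, EC and SC admit signed
#' weights: DC becomes node strength (sum of incident signed weights), EC
#' the eigenvector of the largest eigenvalue of the signed weighted
#' adjacency, and SC the diagonal of its matrix exponential. BC and CC are
#' shortest-path measures and can only be applied in graphs with positive
#' edge weights, so requesting them is an error.
#'
#' @param net an igraph PIN.
#' @param corr an [EdgeCorrelations-class] covering the edges of \code{net}.
#' @param measure one of "DC", "EC", "SC".
#' @param abs.weights use |PCC| instead of signed PCC.
#' @return named numeric vector of weighted scores.
#' @export
weightedCentrality <- function(net, corr, measure, abs.weights = FALSE) {
  if (measure %in% c("BC", "CC"))
    stop("BC and CC can only be applied in graphs with positive edge ",
         "weights; the PCC-weighted PIN carries signed weights")
  measure <- match.arg(measure, c("DC", "EC", "SC"))
  A <- weightedAdjacency(net, corr, abs.weights = abs.weights)
  switch(measure,
    DC = rowSums(A),
    EC = {
      if (nrow(A) == 0L) setNames(numeric(0), character(0))
      else {
        e <- eigen(A, symmetric = TRUE)
        v <- e$vectors[, 1L]
        if (v[which.max(abs(v))] < 0) v <- -v
        setNames(v, rownames(A))
      }
    },
    SC = expmDiag(A))
}
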