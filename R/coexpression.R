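#' Pearson correlation with the zero-variance convention
#'
#' Sample Pearson correlation between two expression profiles. When either
#' profile has zero variance (notably the all-zero rows inserted for
#' proteins without expression data) the correlation is defined as 0 —
#' "no co-expression evidence" — rather than NA. The result is clamped to
#' \code{[-1, 1]} against rounding overshoot.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return numeric(1) in \code{[-1, 1]}.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("profiles must have length >= 2")
  if (sd(x) == 0 || sd(y) == 0) return(0)
  r <- cor(x, y)
  max(-1, min(1, r))
}

#' Co-expression weights for every edge of a PIN
#'
#' Computes the Pearson correlation coefficient between the expression
#' profiles of the two endpoints of every edge — the edge's co-expression
#' weight. Profiles are standardized once per protein, so zero-variance rows
#' standardize to zero and their edges get weight 0 automatically.
#'
#' @param net an igraph PIN.
#' @param expr numeric expression matrix covering every node of \code{net}
#'   (apply [attachMissing()] first).
#' @return an [EdgeCorrelations-class].
#' @export
edgeCorrelations <- function(net, expr) {
  nodes <- igraph::V(net)$name
  absent <- setdiff(nodes, rownames(expr))
  if (length(absent))
    stop("expression matrix lacks ", length(absent),
         " network protein(s), e.g. ", absent[1L],
         "; apply attachMissing() first")
  if (ncol(expr) < 2L) stop("need >= 2 samples to compute correlations")
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) {
    return(new("EdgeCorrelations",
               edges = data.frame(u = character(0), v = character(0),
                                  weight = numeric(0)),
               maxPCC = NA_real_, minPCC = NA_real_))
  }
  used <- unique(c(el[, 1L], el[, 2L]))
  m <- expr[used, , drop = FALSE]
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  w <- rowSums(z[el[, 1L], , drop = FALSE] * z[el[, 2L], , drop = FALSE]) /
    (ncol(expr) - 1L)
  w <- pmax(-1, pmin(1, w))
  new("EdgeCorrelations",
      edges = data.frame(u = el[, 1L], v = el[, 2L], weight = unname(w),
                         stringsAsFactors = FALSE),
      maxPCC = max(w), minPCC = min(w))
}

#' Node strength in the PCC-weighted PIN
#'
#' The strength of a protein is the sum of the raw (signed) co-expression
#' weights over its incident edges; isolated proteins have strength 0. Set
#' \code{abs.weights = TRUE} to sum absolute weights instead.
#'
#' @param net an igraph PIN.
#' @param corr an [EdgeCorrelations-class] computed on \code{net}.
#' @param v optional character vector of protein ids; default all nodes.
#' @param abs.weights sum |PCC| instead of signed PCC.
#' @return named numeric vector of strengths.
#' @export
nodeStrength <- function(net, corr, v = igraph::V(net)$name,
                         abs.weights = FALSE) {
  nodes <- igraph::V(net)$name
  unknown <- setdiff(v, nodes)
  if (length(unknown)) stop("unknown node: ", unknown[1L])
  ed <- corr@edges
  w <- if (abs.weights) abs(ed$weight) else ed$weight
  s <- setNames(numeric(length(nodes)), nodes)
  if (nrow(ed)) {
    inc <- tapply(c(w, w), c(ed$u, ed$v), sum)
    s[names(inc)] <- inc
  }
  s[v]
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The sup-norm distance D between the empirical distribution functions of
#' two samples, used to contrast co-expression weight (or node strength)
#' distributions of essential versus nonessential proteins. Only the D
#' statistic is computed; p-values, which serve as a qualitative gate in the
#' distributional analyses, are left to downstream reporting.
#'
#' @param a,b non-empty numeric samples.
#' @return numeric(1) in \code{[0, 1]}.
#' @export
ksStatistic <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("samples must be non-empty")
  pooled <- sort(unique(c(a, b)))
  Fa <- vapply(pooled, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pooled, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

#' Co-expression weight samples for essential vs nonessential proteins
#'
#' Pools, per protein class, the PCC weights of the edges incident to the
#' proteins of that class. Pooling is per protein: an edge joining an
#' essential to a nonessential protein contributes its weight to both
#' samples, and an edge joining two essential proteins contributes twice to
#' the essential sample.
#'
#' @param net an igraph PIN.
#' @param corr an [EdgeCorrelations-class] on \code{net}.
#' @param essential character vector of essential protein ids.
#' @return list with numeric components \code{essential} and
#'   \code{nonessential}.
#' @export
weightDistributions <- function(net, corr, essential) {
  ed <- corr@edges
  endpoint <- c(ed$u, ed$v)
  w <- c(ed$weight, ed$weight)
  is_ess <- endpoint %in% essential
  list(essential = w[is_ess], nonessential = w[!is_ess])
}

#' Fraction of interactions between essential proteins above a weight cutoff
#'
#' The proportion of all edges whose two endpoints are both essential
#' (IBEPs) and whose co-expression weight exceeds \code{cutoff}, relative to
#' the total number of edges.
#'
#' @param net an igraph PIN with at least one edge.
#' @param corr an [EdgeCorrelations-class] on \code{net}.
#' @param essential character vector of essential protein ids.
#' @param cutoff weight cutoff in \code{[0, 1]} (default 0.75).
#' @return numeric(1) fraction in \code{[0, 1]}.
#' @export
ibepFraction <- function(net, corr, essential, cutoff = 0.75) {
  ed <- corr@edges
  if (nrow(ed) == 0L) stop("network has no edges")
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  hit <- ed$u %in% essential & ed$v %in% essential & ed$weight > cutoff
  sum(hit) / nrow(ed)
}
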