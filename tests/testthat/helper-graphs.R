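# Small named graphs and independent centrality oracles used across tests.
# Oracles deliberately avoid the code paths they check: brute-force path
# enumeration for betweenness, hand BFS for distances, truncated power
# series for subgraph centrality, shifted power iteration for the
# eigenvector measure.

mkGraph <- function(nodes, edges = NULL) {
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

triangleGraph <- function() mkGraph(c("a", "b", "c"),
                                    rbind(c("a","b"), c("b","c"), c("a","c")))
pathGraph3 <- function() mkGraph(c("a", "b", "c"),
                                 rbind(c("a","b"), c("b","c")))
starGraph <- function(leaves = 4) {
  lv <- paste0("l", seq_len(leaves))
  mkGraph(c("hub", lv), cbind("hub", lv))
}

randomGraph <- function(n, p = 0.4) {
  nodes <- sprintf("n%02d", seq_len(n))
  if (n < 2) return(mkGraph(nodes))
  pairs <- t(utils::combn(nodes, 2))
  mkGraph(nodes, pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE])
}

# Random correlation map over the edges of g.
randomCorr <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- stats::runif(nrow(el), -1, 1)
  methods::new("EdgeCorrelations",
               edges = data.frame(u = el[, 1], v = el[, 2], weight = w,
                                  stringsAsFactors = FALSE),
               maxPCC = if (nrow(el)) max(w) else NA_real_,
               minPCC = if (nrow(el)) min(w) else NA_real_)
}

adjMatrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
}

# Hand-rolled BFS distances from one source.
bfsDistances <- function(g, src) {
  nodes <- igraph::V(g)$name
  nbr <- lapply(igraph::adjacent_vertices(g, nodes), function(v) v$name)
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  d[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
    nxt <- nxt[!is.finite(d[nxt])]
    d[nxt] <- d[frontier[1]] + 1
    frontier <- nxt
  }
  d
}

# Count shortest s-t paths and how many pass through each interior node,
# by exhaustive depth-first enumeration (fine for n <= 7).
oracleBetweenness <- function(g) {
  nodes <- igraph::V(g)$name
  nbr <- lapply(igraph::adjacent_vertices(g, nodes), function(v) v$name)
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  if (length(nodes) < 3) return(bc)
  for (si in seq_along(nodes)) for (ti in seq_len(si - 1)) {
    s <- nodes[si]; t <- nodes[ti]
    d <- bfsDistances(g, s)
    if (!is.finite(d[t])) next
    paths <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) { paths[[length(paths) + 1]] <<- path; return() }
      if (length(path) - 1 >= d[t]) return()
      for (x in nbr[[last]])
        if (!(x %in% path) && d[x] == length(path)) walk(c(path, x))
    }
    # restrict enumeration to shortest paths via BFS levels from s
    walk(s)
    sigma <- length(paths)
    interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(interior)) {
      tab <- table(interior)
      bc[names(tab)] <- bc[names(tab)] + as.numeric(tab) / sigma
    }
  }
  bc
}

# Truncated closed-walk series for subgraph centrality.
oracleSubgraph <- function(g, kmax = 25) {
  A <- adjMatrix(g)
  n <- nrow(A)
  acc <- diag(1, n)
  Ak <- diag(1, n)
  for (k in seq_len(kmax)) {
    Ak <- Ak %*% A
    acc <- acc + Ak / factorial(k)
  }
  stats::setNames(diag(acc), rownames(A))
}

# Shifted power iteration, run per connected component; the dominant
# component is the one with the largest Rayleigh quotient, ties broken
# toward the component holding the smallest node id.
oracleEigenvector <- function(g, tol = 1e-13, maxit = 200000) {
  nodes <- igraph::V(g)$name
  out <- stats::setNames(numeric(length(nodes)), nodes)
  comp <- igraph::components(g)
  groups <- split(nodes, comp$membership[nodes])
  res <- lapply(groups, function(ids) {
    if (length(ids) == 1) return(list(lambda = 0, v = stats::setNames(1, ids)))
    A <- adjMatrix(g)[ids, ids]
    shift <- length(ids) + 1
    x <- rep(1 / sqrt(length(ids)), length(ids))
    for (it in seq_len(maxit)) {
      y <- drop(A %*% x) + shift * x
      y <- y / sqrt(sum(y^2))
      if (max(abs(y - x)) < tol) break
      x <- y
    }
    list(lambda = drop(x %*% A %*% x), v = stats::setNames(x, ids))
  })
  lam <- vapply(res, `[[`, numeric(1), "lambda")
  if (max(lam) <= 1e-9) return(out)
  tied <- which(lam >= max(lam) - 1e-9)
  pick <- tied[order(vapply(tied, function(i) min(groups[[i]]), character(1)))][1]
  v <- res[[pick]]$v
  out[names(v)] <- v / sqrt(sum(v^2))
  out
}

oracleClosenessWF <- function(g) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  cc <- stats::setNames(numeric(n), nodes)
  if (n <= 1) return(cc)
  for (v in nodes) {
    d <- bfsDistances(g, v)[setdiff(nodes, v)]
    reach <- d[is.finite(d)]
    if (length(reach))
      cc[v] <- (length(reach) / (n - 1)) * (length(reach) / sum(reach))
  }
  cc
}

# Textbook Pearson formula, written out.
oraclePearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2)) * sqrt(sum(dy^2))
  if (den == 0) 0 else sum(dx * dy) / den
}

# Brute-force two-sample KS D on a fine evaluation grid.
oracleKS <- function(a, b) {
  grid <- sort(c(a, b))
  max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

edgeKeyFor <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "\t")

writeTempLines <- function(lines) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, f)
  f
}
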