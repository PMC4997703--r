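#' Grade a network series: per-member centrality scores, max-normalized
#'
#' Scores every protein on every member network with the chosen base
#' centrality measure, masks proteins of degree 0 in that member to score 0
#' (a protein that has lost all its interactions at a threshold carries no
#' evidence there — this also applies to SC, whose mathematical value for an
#' isolated protein is 1), then divides each column by its maximum so scores
#' from differently sized networks are comparable. All-zero columns (an
#' edgeless member) are left as zeros.
#'
#' @param series a [NetworkSeries-class].
#' @param measure one of "DC", "BC", "CC", "EC", "SC".
#' @return a [ScoreMatrix-class], proteins x members.
#' @export
gradeSeries <- function(series, measure = MEASURES) {
  measure <- match.arg(measure)
  nodes <- igraph::V(series@base)$name
  cols <- lapply(series@members, function(g) {
    s <- centralityScores(g, measure)[nodes]
    s[igraph::degree(g)[nodes] == 0L] <- 0
    mx <- if (length(s)) max(s) else 0
    if (mx > 0) s / mx else s
  })
  sm <- do.call(cbind, cols)
  dimnames(sm) <- list(nodes, NULL)
  new("ScoreMatrix", scores = sm, measure = measure,
      thresholds = series@thresholds)
}

#' Default voting weight vector per thresholding strategy
#'
#' For the absolute strategy the 15-element dominant (Fibonacci-style)
#' vector 1, 2, 3, 5, 8, 13, 21, 34, 55, 89, 144, 233, 377, 610, 987 —
#' each generated network's weight is the sum of its two predecessors', so
#' the vote is dominated by the high-threshold networks whose remaining
#' interactions join highly co-expressed proteins. For the uniform strategy,
#' eight 1s (the negative thresholds, which barely change the network)
#' followed by 2, 3, 5, 8, 13, 21, 34, 55, 89, 144, 233 (19 elements).
#'
#' @param strategy "absolute" or "uniform".
#' @return numeric weight vector matching [defaultSchedule()] in length.
#' @export
defaultWeights <- function(strategy = c("absolute", "uniform")) {
  strategy <- match.arg(strategy)
  fib <- c(1, 2, 3, 5, 8, 13, 21, 34, 55, 89, 144, 233, 377, 610, 987)
  if (strategy == "absolute") fib else c(rep(1, 8), fib[2:12])
}

#' Named voting weight schemes for the 15-network absolute series
#'
#' \describe{
#'   \item{w1}{all ones — unweighted voting baseline.}
#'   \item{w2}{1..15 — gradual advance weighting.}
#'   \item{w3}{eight 1s then 8, 9, 10, 11, 12, 13, 15 — prior-guided
#'     advance weighting (centralities only start gaining above threshold
#'     0.7, so the first eight networks vote equally).}
#'   \item{w4}{1, 2, 3, 5, 8, 13, 21, 34, 55, 89, 144, 233, 377, 610, 987 —
#'     dominant weighting.}
#' }
#'
#' @param name one of "w1", "w2", "w3", "w4".
#' @return numeric vector of length 15.
#' @export
namedWeights <- function(name = c("w1", "w2", "w3", "w4")) {
  name <- match.arg(name)
  switch(name,
    w1 = rep(1, 15),
    w2 = as.numeric(1:15),
    w3 = c(rep(1, 8), 8, 9, 10, 11, 12, 13, 15),
    w4 = defaultWeights("absolute"))
}

#' Combine per-network scores by weighted voting
#'
#' The final score of protein j is \eqn{fs(j) = \sum_{i=1}^{m} s(j,i) w_i}:
#' each member network votes with its normalized centrality scores, weighted
#' by its position in the threshold schedule. Weights must be positive; a
#' decreasing weight vector contradicts the rationale of favoring
#' high-threshold networks and triggers a warning (plateaus are fine).
#'
#' @param sm a [ScoreMatrix-class].
#' @param w numeric weight vector, one weight per member network.
#' @return named numeric vector of final scores fs(j).
#' @export
integrateScores <- function(sm, w) {
  s <- scoreValues(sm)
  if (length(w) != ncol(s))
    stop("weight vector length ", length(w),
         " does not match the ", ncol(s), " member networks")
  if (any(w <= 0)) stop("weights must be positive")
  if (any(diff(w) < 0))
    warning("weight vector is not non-decreasing; ",
            "later (higher-threshold) networks should not vote less")
  drop(s %*% w)
}

#' Rank proteins by final score
#'
#' Descending by score; ties are broken by ascending protein id so repeated
#' runs produce identical rankings. Scores agreeing to 12 significant digits
#' are treated as tied: spectrally equivalent proteins (e.g. members of
#' symmetric modules) can differ by one ulp after an eigendecomposition, and
#' such noise should not outrank the deterministic id order.
#' \code{tie = "random"} instead shuffles tied proteins under the given
#' seed.
#'
#' @param fs named numeric vector of final scores.
#' @param tie "id" (deterministic, default) or "random".
#' @param seed integer seed for \code{tie = "random"}.
#' @return an [EssentialRanking-class].
#' @export
rankProteins <- function(fs, tie = c("id", "random"), seed = 1L) {
  tie <- match.arg(tie)
  ids <- names(fs)
  if (is.null(ids)) stop("final scores must be named by protein id")
  fs <- signif(fs, 12)
  ord <- if (tie == "id") {
    order(-fs, ids, method = "radix")
  } else {
    perm <- withSeed(seed, sample.int(length(fs)))
    order(-fs, perm)
  }
  new("EssentialRanking",
      table = data.frame(protein = ids[ord], score = unname(fs[ord]),
                         stringsAsFactors = FALSE))
}

#' Run the full ensemble framework
#'
#' The four-step pipeline: (1) data partition — compute per-edge
#' co-expression PCCs (zero-filling expression for proteins without data)
#' and generate the thresholded series of networks; (2) grading — score
#' every protein on every member with the base centrality measure and
#' max-normalize per network; (3) integrating — weighted voting across the
#' series; (4) ranking — sort by final score, descending.
#'
#' @param net the original igraph PIN.
#' @param expr numeric expression matrix (rows = proteins); proteins missing
#'   from it are zero-filled via [attachMissing()].
#' @param measure base centrality measure, one of "DC", "BC", "CC", "EC",
#'   "SC".
#' @param strategy "absolute" or "uniform" thresholding.
#' @param schedule threshold vector; defaults to [defaultSchedule()].
#' @param weights voting weights; defaults to [defaultWeights()]. May also
#'   be a name accepted by [namedWeights()].
#' @return an [EssentialRanking-class].
#' @examples
#' syn <- generateSynthetic(syntheticSpec(n_proteins = 60, n_modules = 4,
#'                                        n_decoy_hubs = 4, decoy_degree = 8,
#'                                        seed = 1))
#' r <- runEnsemble(syn$network, syn$expression, measure = "DC")
#' topProteins(r, 5)
#' @export
runEnsemble <- function(net, expr, measure = MEASURES,
                        strategy = c("absolute", "uniform"),
                        schedule = NULL, weights = NULL) {
  measure <- match.arg(measure)
  strategy <- match.arg(strategy)
  if (is.null(schedule)) schedule <- defaultSchedule(strategy)
  if (is.null(weights)) {
    weights <- if (identical(schedule, defaultSchedule(strategy)))
      defaultWeights(strategy) else rep(1, length(schedule))
  } else if (is.character(weights)) {
    weights <- namedWeights(weights)
  }
  expr <- attachMissing(net, expr)
  corr <- edgeCorrelations(net, expr)
  series <- buildSeries(net, corr, strategy, schedule)
  sm <- gradeSeries(series, measure)
  rankProteins(integrateScores(sm, weights))
}

# Evaluate expr under a temporary RNG state seeded with seed.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}
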