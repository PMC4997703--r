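test_that("grading masks zero-degree proteins and max-normalizes per column", {
  tri <- triangleGraph()
  el <- igraph::as_edgelist(tri, names = TRUE)
  corr <- methods::new("EdgeCorrelations",
    edges = data.frame(u = el[, 1], v = el[, 2], weight = c(0.9, 0.2, 0.9)),
    maxPCC = 0.9, minPCC = 0.2)
  series <- buildSeries(tri, corr, "absolute", schedule = c(0))
  sm <- gradeSeries(series, "DC")
  expect_equal(unname(scoreValues(sm)[, 1]), rep(1, 3))  # degree 2 / max 2

  # P4 path, then only its middle edge: hand-computed 4 x 2 DC matrix
  p4 <- mkGraph(c("a", "b", "c", "d"),
                rbind(c("a","b"), c("b","c"), c("c","d")))
  el4 <- igraph::as_edgelist(p4, names = TRUE)
  corr4 <- methods::new("EdgeCorrelations",
    edges = data.frame(u = el4[, 1], v = el4[, 2],
                       weight = c(0.1, 0.8, 0.1)),
    maxPCC = 0.8, minPCC = 0.1)
  series4 <- buildSeries(p4, corr4, "absolute", schedule = c(0, 0.5))
  sm4 <- scoreValues(gradeSeries(series4, "DC"))
  # col 1: degrees (1,2,2,1)/2; col 2: only b-c survives, degrees (0,1,1,0)
  expect_equal(sm4[c("a","b","c","d"), 1], c(0.5, 1, 1, 0.5),
               ignore_attr = TRUE)
  expect_equal(sm4[c("a","b","c","d"), 2], c(0, 1, 1, 0),
               ignore_attr = TRUE)

  # empty member -> all-zero column, left unnormalized
  seriesE <- buildSeries(p4, corr4, "absolute", schedule = c(0, 0.9))
  smE <- scoreValues(gradeSeries(seriesE, "DC"))
  expect_true(all(smE[, 2] == 0))

  # SC of an isolated-in-member protein is masked to 0, not 1
  smSC <- scoreValues(gradeSeries(series4, "SC"))
  expect_equal(smSC[c("a", "d"), 2], c(0, 0), ignore_attr = TRUE)
})

test_that("published weight vectors are reproduced element-for-element", {
  expect_equal(defaultWeights("absolute"),
               c(1, 2, 3, 5, 8, 13, 21, 34, 55, 89, 144, 233, 377, 610, 987))
  expect_equal(defaultWeights("uniform"),
               c(1, 1, 1, 1, 1, 1, 1, 1, 2, 3, 5, 8, 13, 21, 34, 55, 89,
                 144, 233))
  expect_equal(namedWeights("w1"), rep(1, 15))
  expect_equal(namedWeights("w2"), as.numeric(1:15))
  expect_equal(namedWeights("w3"), c(rep(1, 8), 8, 9, 10, 11, 12, 13, 15))
  expect_equal(namedWeights("w4"), defaultWeights("absolute"))
  for (w in list(defaultWeights("absolute"), defaultWeights("uniform"),
                 namedWeights("w1"), namedWeights("w2"), namedWeights("w3"))) {
    expect_true(all(diff(w) >= 0))
    expect_equal(w[1], 1)
  }
  expect_error(namedWeights("w5"))
  expect_error(defaultWeights("geometric"))
})

test_that("integrateScores implements the weighted vote exactly", {
  sm <- new("ScoreMatrix",
            scores = matrix(c(1, 0.5, 0, 1, 0.25, 1), nrow = 3,
                            dimnames = list(c("A", "B", "C"), NULL)),
            measure = "DC", thresholds = c(0, 0.5))
  fs <- integrateScores(sm, c(1, 3))
  expect_equal(unname(fs), c(1 * 1 + 1 * 3, 0.5 + 0.25 * 3, 0 + 1 * 3))

  one <- new("ScoreMatrix",
             scores = matrix(c(1, 0.2), 2, 1,
                             dimnames = list(c("A", "B"), NULL)),
             measure = "DC", thresholds = 0)
  expect_equal(unname(integrateScores(one, 1)), c(1, 0.2))

  expect_error(integrateScores(sm, c(1, 2, 3)), "does not match")
  expect_error(integrateScores(sm, c(1, -1)), "positive")
  expect_warning(integrateScores(sm, c(3, 1)), "non-decreasing")
})

test_that("ranking is descending with deterministic id tie-break", {
  r <- rankProteins(c(A = 2, B = 5, C = 1))
  expect_equal(topProteins(r, 3), c("B", "A", "C"))
  tied <- rankProteins(c(z = 1, a = 1, m = 1))
  expect_equal(topProteins(tied, 3), c("a", "m", "z"))

  withr::with_seed(4, {
    fs <- setNames(runif(1000), sprintf("g%04d", sample(1000)))
    r2 <- rankProteins(fs)
    expect_equal(finalScores(r2), sort(fs, decreasing = TRUE))
  })

  # seeded random tie mode is reproducible
  fs3 <- c(a = 1, b = 1, c = 1, d = 1)
  expect_equal(topProteins(rankProteins(fs3, tie = "random", seed = 9), 4),
               topProteins(rankProteins(fs3, tie = "random", seed = 9), 4))
})

test_that("single-member ensemble collapses to the base measure ranking", {
  syn <- generateSynthetic(syntheticSpec(n_proteins = 80, n_modules = 6,
                                         n_decoy_hubs = 6, decoy_degree = 10,
                                         seed = 7))
  for (m in c("DC", "BC", "CC", "EC", "SC")) {
    ens <- runEnsemble(syn$network, syn$expression, m, "absolute",
                       schedule = 0, weights = 1)
    base <- centralityScores(syn$network, m)
    base[igraph::degree(syn$network) == 0] <- 0
    expect_equal(topProteins(ens, 80), topProteins(rankProteins(base), 80),
                 info = m)
  }
})

test_that("positive rescaling of weights never changes the ranking", {
  syn <- generateSynthetic(syntheticSpec(n_proteins = 60, n_modules = 4,
                                         n_decoy_hubs = 4, decoy_degree = 8,
                                         seed = 3))
  expr <- attachMissing(syn$network, syn$expression)
  corr <- edgeCorrelations(syn$network, expr)
  series <- buildSeries(syn$network, corr, "absolute")
  sm <- gradeSeries(series, "DC")
  w <- defaultWeights("absolute")
  fs1 <- integrateScores(sm, w)
  fs10 <- integrateScores(sm, 10 * w)
  expect_equal(fs10, 10 * fs1, tolerance = 1e-12)
  expect_equal(topProteins(rankProteins(fs1), 60),
               topProteins(rankProteins(fs10), 60))
  # upper bound: fs(j) <= sum(w), equality only for ubiquitous maximizers
  expect_true(all(fs1 <= sum(w) + 1e-9))
})

test_that("normalization is idempotent and zero-degree proteins sort last", {
  syn <- generateSynthetic(syntheticSpec(n_proteins = 60, n_modules = 4,
                                         n_decoy_hubs = 4, decoy_degree = 8,
                                         seed = 5))
  expr <- attachMissing(syn$network, syn$expression)
  corr <- edgeCorrelations(syn$network, expr)
  series <- buildSeries(syn$network, corr, "absolute")
  sm <- scoreValues(gradeSeries(series, "DC"))
  renorm <- apply(sm, 2, function(col) if (max(col) > 0) col / max(col) else col)
  expect_equal(renorm, sm, tolerance = 1e-12)
  cmax <- apply(sm, 2, max)
  expect_true(all(cmax == 0 | abs(cmax - 1) < 1e-12))

  deg <- igraph::degree(syn$network)
  fs <- integrateScores(gradeSeries(series, "DC"), defaultWeights("absolute"))
  if (any(deg == 0)) {
    expect_true(all(fs[deg == 0] == 0))
    r <- rankProteins(fs)
    tb <- as.data.frame(r)
    zero_pos <- which(tb$protein %in% names(deg)[deg == 0])
    pos_pos <- which(tb$score > 0)
    expect_true(min(zero_pos) > max(pos_pos))
  }
})

test_that("runEnsemble is deterministic across repeated runs", {
  syn <- generateSynthetic(syntheticSpec(n_proteins = 60, n_modules = 4,
                                         n_decoy_hubs = 4, decoy_degree = 8,
                                         seed = 7))
  r1 <- runEnsemble(syn$network, syn$expression, "DC")
  r2 <- runEnsemble(syn$network, syn$expression, "DC")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- runEnsemble(syn$network, syn$expression, "DC", weights = "w4")
  expect_identical(as.data.frame(r1), as.data.frame(r3))
})
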