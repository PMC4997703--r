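#' Specification of a synthetic PIN + expression benchmark
#'
#' Describes a seeded synthetic dataset with the statistical structure the
#' ensemble framework exploits: planted co-expressed essential modules
#' (cliques whose members share a latent expression profile), decoy hubs
#' (high-degree nonessential proteins whose neighbors are NOT co-expressed —
#' exactly the proteins that fool plain degree ranking), and an
#' Erdős–Rényi background of nonessential proteins with i.i.d. noise
#' expression.
#'
#' Defaults describe the standard benchmark: 300 proteins, 36 samples (the
#' size of the classical yeast expression compendium), 12 essential modules
#' of 5 proteins, 20 decoy hubs of degree 25, background mean degree 4, and
#' within-module expression correlation 0.9.
#'
#' @param n_proteins total number of proteins.
#' @param n_samples expression samples per protein (>= 3).
#' @param n_modules number of planted essential modules.
#' @param module_size proteins per module (each module is a clique).
#' @param n_decoy_hubs number of decoy hubs.
#' @param decoy_degree partners wired to each decoy hub.
#' @param background_degree mean degree of the Erdős–Rényi background.
#' @param within_module_corr_target expected pairwise expression PCC inside
#'   a module, in (0, 1); sets the member noise via [calibrateNoise()].
#' @param noise_sd member noise standard deviation; default derived from
#'   \code{within_module_corr_target}.
#' @param seed integer RNG seed.
#' @return a \code{synthetic_spec} list.
#' @export
syntheticSpec <- function(n_proteins = 300L, n_samples = 36L,
                          n_modules = 12L, module_size = 5L,
                          n_decoy_hubs = 20L, decoy_degree = 25L,
                          background_degree = 4,
                          within_module_corr_target = 0.9,
                          noise_sd = calibrateNoise(within_module_corr_target),
                          seed = 1L) {
  spec <- list(n_proteins = as.integer(n_proteins),
               n_samples = as.integer(n_samples),
               n_modules = as.integer(n_modules),
               module_size = as.integer(module_size),
               n_decoy_hubs = as.integer(n_decoy_hubs),
               decoy_degree = as.integer(decoy_degree),
               background_degree = background_degree,
               within_module_corr_target = within_module_corr_target,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  if (spec$n_samples < 3L) stop("need at least 3 samples")
  n_mod <- spec$n_modules * spec$module_size
  if (n_mod + spec$n_decoy_hubs > spec$n_proteins)
    stop("modules plus decoy hubs exceed n_proteins")
  if (spec$decoy_degree > spec$n_proteins - n_mod - 1L)
    stop("decoy_degree exceeds the number of available non-module partners")
  if (spec$noise_sd <= 0) stop("noise_sd must be positive")
  class(spec) <- "synthetic_spec"
  spec
}

#' Member noise level for a target within-module correlation
#'
#' Module members emit latent + N(0, sd) noise; two members then correlate
#' at 1 / (1 + sd^2) in expectation, so the sd achieving a target
#' correlation r is \code{sqrt(1/r - 1)}.
#'
#' @param target_corr target pairwise correlation in (0, 1).
#' @return numeric(1) noise standard deviation.
#' @export
calibrateNoise <- function(target_corr) {
  if (target_corr <= 0 || target_corr >= 1)
    stop("target correlation must lie strictly inside (0, 1)")
  sqrt(1 / target_corr - 1)
}

#' Generate a synthetic (network, expression, essential set) triple
#'
#' Deterministic under the spec's seed (Mersenne-Twister, inversion
#' normals); the RNG stream is consumed in a fixed order — topology first
#' (hub wiring, then background edges), then expression (module latent
#' profiles and member noise, then background rows) — so the same seed
#' always yields bit-identical output.
#'
#' Construction: proteins are labelled P001, P002, ... with module members
#' first, then decoy hubs, then background. Each module is a clique and its
#' members form the essential set. Each decoy hub wires to
#' \code{decoy_degree} distinct random non-module partners. Background
#' proteins (neither module member nor hub) are joined by an Erdős–Rényi
#' graph with the requested mean degree. Module members express a shared
#' standard-normal latent profile plus N(0, noise_sd) noise; every other
#' protein expresses i.i.d. standard normal values.
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{network} (igraph), \code{expression} (matrix),
#'   \code{essential} (character vector) and \code{spec}.
#' @export
generateSynthetic <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_proteins
  ids <- sprintf("P%0*d", max(3L, nchar(n)), seq_len(n))
  n_mod <- spec$n_modules * spec$module_size
  module_ids <- ids[seq_len(n_mod)]
  hub_ids <- ids[n_mod + seq_len(spec$n_decoy_hubs)]
  bg_ids <- ids[seq.int(n_mod + spec$n_decoy_hubs + 1L, length.out =
                          n - n_mod - spec$n_decoy_hubs)]
  nonmodule_ids <- c(hub_ids, bg_ids)
  modules <- split(module_ids, rep(seq_len(spec$n_modules),
                                   each = spec$module_size))

  withSeed(spec$seed, {
    # --- topology ---
    clique_edges <- do.call(rbind, lapply(modules, function(m)
      t(utils::combn(m, 2L))))
    hub_edges <- do.call(rbind, lapply(hub_ids, function(h) {
      partners <- sample(setdiff(nonmodule_ids, h), spec$decoy_degree)
      cbind(h, partners)
    }))
    bg_edges <- NULL
    if (length(bg_ids) >= 2L) {
      pairs <- t(utils::combn(bg_ids, 2L))
      p <- spec$background_degree / (length(bg_ids) - 1L)
      bg_edges <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
    }
    el <- rbind(clique_edges, hub_edges, bg_edges)
    el <- el[!duplicated(edgeKey(el[, 1L], el[, 2L])), , drop = FALSE]
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
    g <- igraph::add_edges(g, t(el))

    # --- expression ---
    expr <- matrix(NA_real_, nrow = n, ncol = spec$n_samples,
                   dimnames = list(ids, sprintf("S%02d", seq_len(spec$n_samples))))
    for (m in modules) {
      latent <- rnorm(spec$n_samples)
      for (id in m)
        expr[id, ] <- latent + rnorm(spec$n_samples, sd = spec$noise_sd)
    }
    for (id in nonmodule_ids)
      expr[id, ] <- rnorm(spec$n_samples)

    list(network = g, expression = expr, essential = module_ids,
         spec = spec)
  })
}
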