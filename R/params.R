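#' Algorithm parameters
#'
#' One bag of tunables for the whole pipeline, with defaults.  All distances
#' in Angstrom.
#'
#' Descriptor-pair similarity: `min_elements` aligned elements (central one
#' included) and global Calpha RMSD of the correspondence at most `rmsd_max`
#' are required for two descriptors to count as similar.  `window_rmsd_max`
#' is the per-element candidate filter used during matching.
#'
#' Clique search: graphs up to `exact_limit` nodes use exhaustive
#' branch-and-bound; larger ones the Motzkin-Straus replicator heuristic with
#' `restarts` random initializations, convergence tolerance `replicator_tol`
#' and at most `replicator_iter` iterations.  `profile_restarts` is the
#' (smaller) restart count used for the column-merge clique searches inside
#' profile alignment, which run many times per evolutionary step.
#'
#' Evolutionary algorithm: population cap `pop_max`, mutation probability
#' `p_m` (crossover otherwise), `stall` consecutive non-improving children
#' stop a phase, at most `max_evals` children per phase, `n_trees` stochastic
#' guide trees seed the population, and `identity_max` is the similarity
#' level above which an individual is displaced by a newcomer.
#'
#' Scoring: `lambda_tension` weights the tension penalty against alignment
#' size; `augment_const` scales the `(1 + cos(alpha))/2` factor applied to
#' secondary regions; `min_region` is the smallest region superposed on its
#' own.
#'
#' @param ... overrides of any default listed above (also `d_alpha_max`,
#'   `d_c_max`, `d_diff_min` for the contact criterion, and `min_segments`
#'   for the stage-1 core restriction).
#' @return list of class `msta_params`.
#' @export
msta_params <- function(...) {
  p <- list(
    # contact criterion
    d_alpha_max = 6.5, d_c_max = 8.0, d_diff_min = 0.75,
    # descriptor-pair similarity
    min_elements = 3L, rmsd_max = 2.5, window_rmsd_max = 3.5,
    # clique search
    exact_limit = 25L, restarts = 32L, profile_restarts = 4L,
    replicator_tol = 1e-8, replicator_iter = 10000L, clique_beam = 600L,
    # evolutionary algorithm
    pop_max = 20L, p_m = 0.7, stall = 50L, max_evals = 2000L,
    n_trees = 10L, identity_max = 0.8,
    # scoring
    lambda_tension = 0.05, augment_const = 1.0, min_region = 3L,
    # two-stage protocol
    min_segments = 3L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p$criterion <- contact_criterion(p$d_alpha_max, p$d_c_max, p$d_diff_min)
  class(p) <- "msta_params"
  p
}
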