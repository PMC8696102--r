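# Stochastic guide trees and the steady-state evolutionary refinement.
# A specimen is a binary guide tree whose internal nodes carry the multiple
# alignment of their leaf set; the root alignment is the solution and its
# fitness the specimen's fitness.

tree_leaf <- function(i) list(leaf = i)
is_leaf <- function(node) !is.null(node$leaf)
tree_leaves <- function(node) {
  if (is_leaf(node)) node$leaf else c(tree_leaves(node$left), tree_leaves(node$right))
}

# paths (character vectors of "left"/"right") to all internal nodes / leaves
internal_paths <- function(node, path = character(0)) {
  if (is_leaf(node)) return(list())
  c(list(path),
    internal_paths(node$left, c(path, "left")),
    internal_paths(node$right, c(path, "right")))
}

leaf_paths <- function(node, path = character(0)) {
  if (is_leaf(node)) return(setNames(list(path), node$leaf))
  c(leaf_paths(node$left, c(path, "left")), leaf_paths(node$right, c(path, "right")))
}

# leaf-to-leaf distance matrix (number of tree edges between leaves)
leaf_distances <- function(tree, n) {
  lp <- leaf_paths(tree)
  d <- matrix(0, n, n)
  ids <- as.integer(names(lp))
  for (a in seq_along(lp)) for (b in seq_along(lp)) {
    if (a >= b) next
    p1 <- lp[[a]]; p2 <- lp[[b]]
    k <- 0L
    while (k < length(p1) && k < length(p2) && p1[k + 1L] == p2[k + 1L]) k <- k + 1L
    d[ids[a], ids[b]] <- d[ids[b], ids[a]] <- length(p1) + length(p2) - 2L * k
  }
  d
}

#' Stochastic neighbor-joining guide tree
#'
#' Iteratively joins two clusters, sampling the pair to join with
#' probability proportional to the average similarity of their members
#' (uniformly when all similarities are zero), instead of always taking the
#' most similar pair.  Repeated draws therefore explore different tree
#' topologies, weighted towards the greedy one.
#'
#' @param sim symmetric nonnegative structure similarity matrix (here:
#'   pairwise alignment sizes).
#' @return a binary guide tree; leaves hold structure indices.
#' @export
stochastic_nj <- function(sim) {
  n <- nrow(sim)
  if (n < 2L) stop("need at least 2 structures")
  clusters <- lapply(seq_len(n), tree_leaf)
  members <- as.list(seq_len(n))
  s <- sim; diag(s) <- 0
  while (length(clusters) > 1L) {
    m <- length(clusters)
    pr <- s[upper.tri(s)]
    pick <- if (sum(pr) <= 0) sample.int(length(pr), 1L)
            else sample.int(length(pr), 1L, prob = pr)
    ut <- which(upper.tri(s), arr.ind = TRUE)
    i <- ut[pick, 1L]; j <- ut[pick, 2L]
    joined <- list(left = clusters[[i]], right = clusters[[j]])
    ni <- length(members[[i]]); nj <- length(members[[j]])
    snew <- (ni * s[i, ] + nj * s[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    s <- rbind(cbind(s[keep, keep, drop = FALSE], snew[keep]), c(snew[keep], 0))
    clusters <- c(clusters[keep], list(joined))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
  }
  clusters[[1L]]
}

# flat correspondence tables of the search space linking two disjoint
# leaf sets (fast path for align_profiles)
space_flat <- function(ctx, space, set1, set2) {
  out <- list()
  for (i in set1) for (j in set2) {
    lo <- min(i, j); hi <- max(i, j)
    key <- paste0(lo, "|", hi)
    allowed <- space$allowed[[key]]
    if (length(allowed) == 0L) next
    f <- get_flat(ctx, lo, hi)
    keep <- f$dp %in% allowed
    if (!any(keep)) next
    out[[length(out) + 1L]] <- list(s1 = f$s1, s2 = f$s2, dp = f$dp[keep],
                                    ra = f$ra[keep], rb = f$rb[keep])
  }
  out
}

# recompute the alignment at `path` and at every ancestor up to the root
recompute_path <- function(node, path, ctx, space, params) {
  if (length(path)) {
    node[[path[1L]]] <- recompute_path(node[[path[1L]]], path[-1L], ctx, space, params)
  }
  if (!is_leaf(node)) {
    l <- tree_leaves(node$left); r <- tree_leaves(node$right)
    node$ma <- align_profiles(node$left$ma, node$right$ma,
                              list(), params, flat = space_flat(ctx, space, l, r))
  }
  node
}

#' Progressive alignment along a guide tree
#'
#' Post-order traversal: each leaf holds the trivial alignment of its
#' structure (all singleton columns); each internal node the profile-profile
#' alignment of its children, restricted to the descriptor pairs allowed by
#' the search space.  The root alignment is scored to give the specimen's
#' fitness.
#'
#' @param tree guide tree from [stochastic_nj()].
#' @param ctx an [alignment_context()].
#' @param space a search space (see [initial_space()]).
#' @param params an [msta_params()] list.
#' @return a `specimen`: list with `tree` (alignments attached), `alignment`
#'   (root) and `fitness`.
#' @export
progressive <- function(tree, ctx, space, params = ctx$params) {
  fill <- function(node) {
    if (is_leaf(node)) {
      node$ma <- singleton_alignment(ctx$structures[[node$leaf]])
      return(node)
    }
    node$left <- fill(node$left); node$right <- fill(node$right)
    l <- tree_leaves(node$left); r <- tree_leaves(node$right)
    node$ma <- align_profiles(node$left$ma, node$right$ma,
                              list(), params, flat = space_flat(ctx, space, l, r))
    node
  }
  tree <- fill(tree)
  new_specimen(tree, ctx)
}

new_specimen <- function(tree, ctx) {
  validate_alignment(tree$ma)
  structure(list(tree = tree, alignment = tree$ma, fitness = fitness(tree$ma, ctx),
                 keys = pair_keys(tree$ma)),
            class = "specimen")
}

#' Mutate a specimen
#'
#' Uniformly selects an internal node of the guide tree and recomputes its
#' alignment as a fresh profile-profile alignment of its children, then
#' recomputes every node on the path to the root.  The input is unchanged.
#'
#' @param s a specimen.
#' @param ctx,space,params context, search space, parameters.
#' @return a new specimen.
#' @export
mutate <- function(s, ctx, space, params = ctx$params) {
  paths <- internal_paths(s$tree)
  path <- paths[[sample.int(length(paths), 1L)]]
  new_specimen(recompute_path(s$tree, path, ctx, space, params), ctx)
}

# prune a tree (with alignments) to a leaf subset
prune_tree <- function(node, keep, ctx) {
  if (is_leaf(node)) {
    if (node$leaf %in% keep) return(node) else return(NULL)
  }
  l <- prune_tree(node$left, keep, ctx)
  r <- prune_tree(node$right, keep, ctx)
  if (is.null(l)) return(r)
  if (is.null(r)) return(l)
  node$left <- l; node$right <- r
  node$ma <- subalignment(node$ma, names(ctx$structures)[intersect(tree_leaves(node), keep)])
  node
}

#' Cross two specimens
#'
#' Samples a centroid pair (u, v), u != v, with probability proportional to
#' their leaf distance in the parents' guide trees, grows a subset around u
#' by proximity in the first parent's tree and around v in the second's
#' until the structures are exhausted, extracts the two subalignments and
#' aligns them into the child; the child's tree joins the two pruned
#' subtrees at a new root.
#'
#' @param s1,s2 specimens over the same structure set.
#' @param ctx,space,params context, search space, parameters.
#' @return a new specimen.
#' @export
crossover <- function(s1, s2, ctx, space, params = ctx$params) {
  n <- length(ctx$structures)
  d1 <- leaf_distances(s1$tree, n); d2 <- leaf_distances(s2$tree, n)
  pr <- (d1 + d2)[upper.tri(d1)]
  ut <- which(upper.tri(d1), arr.ind = TRUE)
  pick <- if (sum(pr) <= 0) sample.int(length(pr), 1L)
          else sample.int(length(pr), 1L, prob = pr)
  u <- ut[pick, 1L]; v <- ut[pick, 2L]
  set1 <- u; set2 <- v
  left <- setdiff(seq_len(n), c(u, v))
  turn <- 1L
  while (length(left)) {
    if (turn == 1L) {
      w <- left[order(d1[u, left], left)][1L]; set1 <- c(set1, w)
    } else {
      w <- left[order(d2[v, left], left)][1L]; set2 <- c(set2, w)
    }
    left <- setdiff(left, w)
    turn <- 3L - turn
  }
  nm <- names(ctx$structures)
  sub1 <- subalignment(s1$alignment, nm[sort(set1)])
  sub2 <- subalignment(s2$alignment, nm[sort(set2)])
  ma <- align_profiles(sub1, sub2, list(), params, flat = space_flat(ctx, space, set1, set2))
  t1 <- prune_tree(s1$tree, set1, ctx)
  t2 <- prune_tree(s2$tree, set2, ctx)
  tree <- list(left = t1, right = t2, ma = ma)
  new_specimen(tree, ctx)
}

#' Alignment identity of two specimens
#'
#' Jaccard index of the induced aligned residue-pair sets of the two root
#' alignments, over all structure pairs.
#'
#' @param s1,s2 specimens (or `msta_alignment`s) over one structure set.
#' @return fraction in `[0, 1]` (1 for two empty alignments).
#' @export
specimen_identity <- function(s1, s2) {
  keys_of <- function(s) {
    if (inherits(s, "specimen")) {
      if (!is.null(s$keys)) s$keys else pair_keys(s$alignment)
    } else pair_keys(s)
  }
  k1 <- keys_of(s1); k2 <- keys_of(s2)
  un <- length(union(k1, k2))
  if (un == 0L) return(1)
  length(intersect(k1, k2)) / un
}

#' Steady-state evolutionary refinement
#'
#' Each iteration generates one child (mutation with probability `p_m`,
#' crossover otherwise; parents drawn fitness-proportionally) and applies
#' the elitist insertion rule: the child is added if the population is below
#' its maximal size, or if its fitness exceeds the fitness of the individual
#' most similar to it; on insertion all individuals whose identity to the
#' newcomer exceeds `identity_max` are removed (the newcomer is spared).
#' Stops after `stall` consecutive children that do not improve the
#' best-ever fitness, or after `max_evals` children.
#'
#' @param pop list of specimens (nonempty).
#' @param ctx,space,params context, search space, parameters.
#' @return list: `best` specimen (best ever seen), `pop` final population,
#'   `evals` children generated, `trace` best fitness after each child.
#' @export
steady_state <- function(pop, ctx, space, params = ctx$params) {
  stopifnot(length(pop) > 0L)
  fit <- vapply(pop, `[[`, 0, "fitness")
  best <- pop[[which.max(fit)]]
  evals <- 0L; stall <- 0L; trace <- numeric(0)
  while (evals < params$max_evals && stall < params$stall) {
    fit <- vapply(pop, `[[`, 0, "fitness")
    pr <- fit - min(fit) + (max(fit) - min(fit)) * 0.01 + 1e-9
    child <- if (stats::runif(1) < params$p_m || length(pop) == 1L) {
      mutate(pop[[sample.int(length(pop), 1L, prob = pr)]], ctx, space, params)
    } else {
      ix <- sample.int(length(pop), 2L, replace = TRUE, prob = pr)
      crossover(pop[[ix[1L]]], pop[[ix[2L]]], ctx, space, params)
    }
    evals <- evals + 1L
    insert <- length(pop) < params$pop_max
    if (!insert) {
      ids <- vapply(pop, specimen_identity, 0, s2 = child)
      ms <- which.max(ids)
      insert <- child$fitness > pop[[ms]]$fitness
    }
    if (insert) {
      ids <- vapply(pop, specimen_identity, 0, s2 = child)
      pop <- c(pop[ids <= params$identity_max], list(child))
    }
    if (child$fitness > best$fitness) { best <- child; stall <- 0L } else stall <- stall + 1L
    trace <- c(trace, best$fitness)
  }
  list(best = best, pop = pop, evals = evals, trace = trace)
}

#' Initial search space from the all-vs-all pairwise alignments
#'
#' The space starts constrained to the descriptor pairs actually used by
#' the pairwise alignments; freeing a structure admits every descriptor
#' pair in which one of its descriptors participates.
#'
#' @param ctx an [alignment_context()].
#' @param universe optional list (keyed `"i|j"`) restricting the admissible
#'   descriptor pairs (e.g. the stage-1 core restriction); defaults to all.
#' @return list of class `search_space`: `allowed`, `universe`, `freed`,
#'   `pairwise` (the pairwise alignments), `pair_fitness`.
#' @export
initial_space <- function(ctx, universe = NULL) {
  n <- length(ctx$structures)
  allowed <- list(); pairwise <- list(); pf <- list()
  full_universe <- is.null(universe)
  if (full_universe) universe <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    key <- paste0(i, "|", j)
    pool <- get_pool(ctx, i, j)
    uni <- if (full_universe) seq_along(pool) else universe[[key]]
    pa <- align_pair(ctx$structures[[i]], ctx$structures[[j]], ctx$params,
                     pool = pool[uni])
    pairwise[[key]] <- pa
    allowed[[key]] <- uni[pa$nodes]
    pf[[key]] <- if (nrow(pa$pairs)) fitness(from_pairwise(pa), ctx) else 0
    universe[[key]] <- uni
  }
  structure(list(allowed = allowed, universe = universe, freed = integer(0),
                 pairwise = pairwise, pair_fitness = pf),
            class = "search_space")
}

free_structure <- function(space, s, n) {
  for (j in seq_len(n)) {
    if (j == s) next
    key <- paste0(min(s, j), "|", max(s, j))
    space$allowed[[key]] <- space$universe[[key]]
  }
  space$freed <- sort(c(space$freed, s))
  space
}

#' Evolutionary alignment with gradual extension of the search space
#'
#' Starts by refining the consensus of the pairwise alignments (the search
#' space holds only descriptor pairs those alignments used).  After each
#' converged refinement phase the most under-performing structure -- the one
#' whose summed pairwise-alignment fitness most exceeds its contribution to
#' the best multiple alignment -- is freed (all its descriptor pairs are
#' admitted) and refinement restarts, until every structure is free.
#'
#' @param ctx an [alignment_context()] over >= 3 structures.
#' @param params an [msta_params()] list.
#' @param universe optional admissible-pool restriction (see [initial_space()]).
#' @param seed optional integer seed (sets the RNG).
#' @return list: `best` specimen, `space`, `history` (per-phase best fitness).
#' @export
gradual_extension <- function(ctx, params = ctx$params, universe = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(ctx$structures)
  stopifnot(n >= 3L)
  space <- initial_space(ctx, universe)
  sim <- matrix(0, n, n)
  for (key in names(space$pairwise)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1L]])
    sim[ij[1L], ij[2L]] <- sim[ij[2L], ij[1L]] <- nrow(space$pairwise[[key]]$pairs)
  }
  pop <- lapply(seq_len(params$n_trees), function(k)
    progressive(stochastic_nj(sim), ctx, space, params))
  pop <- pop[seq_len(min(length(pop), params$pop_max))]
  res <- steady_state(pop, ctx, space, params)
  best <- res$best; history <- best$fitness
  while (length(space$freed) < n) {
    unfree <- setdiff(seq_len(n), space$freed)
    contribution <- function(s) {
      others <- names(ctx$structures)[-s]
      best$fitness - fitness(subalignment(best$alignment, others), ctx)
    }
    pair_sum <- function(s) {
      keys <- vapply(setdiff(seq_len(n), s),
                     function(j) paste0(min(s, j), "|", max(s, j)), "")
      sum(unlist(space$pair_fitness[keys]))
    }
    gap <- vapply(unfree, function(s) pair_sum(s) - contribution(s), 0)
    space <- free_structure(space, unfree[which.max(gap)], n)
    res <- steady_state(res$pop, ctx, space, params)
    if (res$best$fitness > best$fitness) best <- res$best
    history <- c(history, best$fitness)
  }
  list(best = best, space = space, history = history)
}

# merge remaining descriptor pairs into an alignment if they overlap it and
# stay consistent; operates on the partition-of-residues column form
extend_alignment <- function(ma, ctx, rest, params = ctx$params) {
  nm <- ma$struct_names
  cols <- ma$cols
  colof <- lapply(seq_along(nm), function(s) {
    v <- cols[, s]; m <- integer(0); m[v[!is.na(v)]] <- which(!is.na(v)); m
  })
  ord <- order(-vapply(rest, function(p) p$size, 0L),
               vapply(rest, function(p) paste(p$a_structure, p$b_structure,
                                              p$a_central, p$b_central), ""))
  for (dp in rest[ord]) {
    u <- match(dp$a_structure, nm); v <- match(dp$b_structure, nm)
    cu <- colof[[u]][dp$corr[, 1L]]; cv <- colof[[v]][dp$corr[, 2L]]
    if (!any(!is.na(cu) & !is.na(cv) & cu == cv)) next   # no overlap
    for (r in seq_len(nrow(dp$corr))) {
      c1 <- cu[r]; c2 <- cv[r]
      if (is.na(c1) || is.na(c2) || c1 == c2) next
      m1 <- !is.na(cols[c1, ]); m2 <- !is.na(cols[c2, ])
      if (any(m1 & m2)) next                             # conflict: skip pair
      cols[c1, m2] <- cols[c2, m2]
      cols[c2, ] <- NA_integer_
      for (s in which(m2)) colof[[s]][cols[c1, s]] <- c1
      cu <- colof[[u]][dp$corr[, 1L]]; cv <- colof[[v]][dp$corr[, 2L]]
    }
  }
  cols <- cols[rowSums(!is.na(cols)) > 0L, , drop = FALSE]
  multiple_alignment(nm, cols)
}

#' Two-stage core alignment and refinement
#'
#' Stage 1 builds an optimal multiple alignment using only descriptor pairs
#' whose correspondence spans at least `min_segments` backbone segments --
#' these capture protein cores but may miss loops and linkers.  Stage 2
#' extends the stage-1 alignment with the remaining descriptor pairs that
#' are consistent with it and overlap it in at least one aligned residue
#' pair.  With two structures the clique-based pairwise aligner replaces the
#' evolutionary stage.  If no descriptor pair passes the stage-1 filter the
#' full pool is used from the start.
#'
#' @param structures list of [structure3d()] (or an existing context via
#'   `ctx`).
#' @param params an [msta_params()] list.
#' @param seed integer seed for all stochastic steps.
#' @param ctx optional prebuilt [alignment_context()] (overrides
#'   `structures`).
#' @return list of class `msta_result`: `alignment`, `fitness`,
#'   `stage1_alignment`, `best` (final specimen or `NULL` for 2 structures),
#'   `seed`.
#' @export
two_stage <- function(structures = NULL, params = msta_params(), seed = 1L,
                      ctx = NULL) {
  if (is.null(ctx)) ctx <- alignment_context(structures, params)
  set.seed(seed)
  n <- length(ctx$structures)
  stopifnot(n >= 2L)
  core_universe <- list(); any_core <- FALSE; n_all <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    key <- paste0(i, "|", j)
    pool <- get_pool(ctx, i, j)
    nseg <- vapply(pool, `[[`, 0L, "n_segments")
    core_universe[[key]] <- which(nseg >= params$min_segments)
    any_core <- any_core || length(core_universe[[key]]) > 0L
    n_all <- n_all + length(pool)
  }
  if (!any_core) core_universe <- NULL    # degenerate: no core pairs at all
  if (n == 2L) {
    pool <- get_pool(ctx, 1L, 2L)
    uni <- if (is.null(core_universe)) seq_along(pool) else core_universe[["1|2"]]
    pa <- align_pair(ctx$structures[[1L]], ctx$structures[[2L]], params, pool = pool[uni])
    stage1 <- align_profiles(singleton_alignment(ctx$structures[[1L]]),
                             singleton_alignment(ctx$structures[[2L]]),
                             pool[uni][pa$nodes], params)
    best <- NULL
    rest_idx <- setdiff(seq_along(pool), uni)
    final <- extend_alignment(stage1, ctx, pool[rest_idx], params)
  } else {
    ge <- gradual_extension(ctx, params, universe = core_universe)
    best <- ge$best
    stage1 <- best$alignment
    rest <- list()
    for (key in names(ge$space$universe)) {
      ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1L]])
      pool <- get_pool(ctx, ij[1L], ij[2L])
      rest <- c(rest, pool[setdiff(seq_along(pool), ge$space$universe[[key]])])
    }
    final <- extend_alignment(stage1, ctx, rest, params)
  }
  structure(list(alignment = final, fitness = fitness(final, ctx),
                 stage1_alignment = stage1, best = best, seed = seed),
            class = "msta_result")
}

#' @export
print.msta_result <- function(x, ...) {
  cat(sprintf("msta_result: %d structures, %d aligned columns, fitness %.2f\n",
              length(x$alignment$struct_names),
              sum(rowSums(!is.na(x$alignment$cols)) >= 2L), x$fitness))
  invisible(x)
}
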