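# Maximum-weight clique search on descriptor-pair consistency graphs.
# Small graphs are solved exactly by branch-and-bound; larger ones by a
# replicator-dynamics heuristic built on the Motzkin-Straus correspondence
# between maximum cliques and maxima of x'Ax over the probability simplex.

is_clique <- function(adj, v) {
  if (length(v) <= 1L) return(TRUE)
  sub <- adj[v, v, drop = FALSE]
  all(sub[upper.tri(sub)])
}

#' Exact maximum-weight clique (branch-and-bound)
#'
#' Exhaustive depth-first search with a remaining-weight bound.  The first
#' maximum found in increasing-vertex-order exploration is kept, which makes
#' the result the lexicographically smallest among maximum-weight cliques.
#'
#' @param adj symmetric logical adjacency matrix (no self loops).
#' @param w node weights (default 1).
#' @param limit refuse graphs larger than this (the heuristic exists for
#'   those); default 25.
#' @return integer vector of clique node indices.
#' @export
max_clique_exact <- function(adj, w = rep(1, nrow(adj)), limit = 25L) {
  n <- nrow(adj)
  if (n == 0L) return(integer(0))
  if (n > limit) stop("graph exceeds the exact-search limit (", limit, " nodes)")
  best <- integer(0); best_w <- -Inf
  expand <- function(cur, cur_w, cand) {
    if (cur_w + sum(w[cand]) <= best_w) return()
    if (length(cand) == 0L) {
      if (cur_w > best_w) { best <<- cur; best_w <<- cur_w }
      return()
    }
    for (k in seq_along(cand)) {
      v <- cand[k]
      rest <- cand[-seq_len(k)]
      if (cur_w + w[v] + sum(w[rest]) <= best_w) break
      expand(c(cur, v), cur_w + w[v], rest[adj[v, rest]])
    }
    if (cur_w > best_w) { best <<- cur; best_w <<- cur_w }
  }
  expand(integer(0), 0, seq_len(n))
  sort(best)
}

# greedy completion: add vertices adjacent to the whole clique, heaviest first
greedy_complete <- function(adj, w, clique) {
  n <- nrow(adj)
  ok <- if (length(clique)) {
    which(colSums(adj[clique, , drop = FALSE]) == length(clique))
  } else seq_len(n)
  for (v in ok[order(-w[ok], ok)]) {
    if (all(adj[v, clique]) || length(clique) == 0L) clique <- c(clique, v)
  }
  sort(clique)
}

#' Heuristic maximum-weight clique (Motzkin-Straus replicator dynamics)
#'
#' Maximizes `x' A x` over the probability simplex by replicator iterations
#' `x <- x * (A x) / (x' A x)`; by the Motzkin-Straus theorem the strict
#' local maxima are uniform distributions over maximal cliques.  The support
#' of the converged point is peeled to a clique (dropping low-support
#' vertices with missing neighbors) and greedily completed by weight.  The
#' best clique over `restarts` randomized initializations (the first restart
#' is a deterministic weight-greedy start) is returned; the result is always
#' a clique.
#'
#' @param adj symmetric logical adjacency matrix.
#' @param w node weights.
#' @param restarts number of initializations.
#' @param tol convergence tolerance on the iterate.
#' @param max_iter iteration cap per restart.
#' @param eval_fn optional function scoring a candidate clique (e.g. exact
#'   union size of the correspondences); defaults to the sum of node weights.
#' @return integer vector of clique node indices.
#' @export
max_clique_heuristic <- function(adj, w = rep(1, nrow(adj)), restarts = 32L,
                                 tol = 1e-8, max_iter = 10000L, eval_fn = NULL) {
  n <- nrow(adj)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  if (is.null(eval_fn)) eval_fn <- function(cl) sum(w[cl])
  a <- matrix(as.numeric(adj), n, n); diag(a) <- 0
  # maximal clique grown along a vertex order
  grow <- function(ord) {
    cl <- integer(0)
    for (v in ord) if (all(adj[v, cl])) cl <- c(cl, v)
    sort(cl)
  }
  best <- integer(0); best_w <- -Inf
  consider <- function(cl) {
    cw <- eval_fn(cl)
    if (cw > best_w) { best <<- cl; best_w <<- cw }
  }
  # deterministic starts: global weight-greedy plus greedy seeded at each of
  # the heaviest vertices
  wo <- order(-w, seq_len(n))
  consider(grow(wo))
  for (v in head(wo, 20L)) consider(grow(c(v, setdiff(wo, v))))
  for (r in seq_len(max(0L, restarts - 1L))) {
    g <- stats::rgamma(n, shape = 1)
    x <- (1 / n + g / sum(g)) / 2
    sig <- ""
    for (it in seq_len(max_iter)) {
      ax <- as.numeric(a %*% x)
      q <- sum(x * ax)
      if (q <= 0) break
      xn <- x * ax / q
      if (max(abs(xn - x)) < tol) { x <- xn; break }
      x <- xn
      # clique extraction depends on the support order only: stop once the
      # leading order is stable between checkpoints
      if (it %% 25L == 0L) {
        s2 <- paste(utils::head(order(-x), 50L), collapse = ",")
        if (identical(s2, sig)) break
        sig <- s2
      }
    }
    # extract cliques along decreasing support, plain and weight-biased
    consider(greedy_complete(adj, w, grow(order(-x, seq_len(n)))))
    consider(greedy_complete(adj, w, grow(order(-x * w, seq_len(n)))))
  }
  best
}

# dispatch: exact for small graphs, heuristic otherwise
best_clique <- function(adj, w, params = msta_params(), restarts = params$restarts) {
  n <- nrow(adj)
  if (n == 0L) return(integer(0))
  if (n <= params$exact_limit) max_clique_exact(adj, w, limit = params$exact_limit)
  else max_clique_heuristic(adj, w, restarts = restarts,
                            tol = params$replicator_tol, max_iter = params$replicator_iter)
}

#' Minimal-loss conflict resolution
#'
#' Given a conflict relation among selected nodes (descriptor pairs or
#' column merges), finds the node subset whose removal clears every conflict
#' while losing the least total alignment size; ties are broken by removing
#' fewer nodes, then by the lexicographically smallest removal set.  Each
#' connected component of the conflict graph is solved independently and
#' exactly (exhaustive bitmask search); components beyond 16 nodes fall back
#' to a greedy cover with a warning.
#'
#' @param conflicts symmetric logical matrix; `TRUE` where two nodes conflict.
#' @param sizes per-node alignment-size contribution.
#' @return integer indices of the retained nodes.
#' @export
resolve_conflicts <- function(conflicts, sizes = rep(1, nrow(conflicts))) {
  n <- nrow(conflicts)
  if (n == 0L) return(integer(0))
  diag(conflicts) <- FALSE
  if (!any(conflicts)) return(seq_len(n))
  g <- igraph::graph_from_adjacency_matrix(conflicts, mode = "undirected")
  comp <- igraph::components(g)
  removed <- integer(0)
  for (ci in seq_len(comp$no)) {
    verts <- which(comp$membership == ci)
    m <- length(verts)
    if (m == 1L) next
    sub <- conflicts[verts, verts, drop = FALSE]
    ed <- which(sub & upper.tri(sub), arr.ind = TRUE)
    if (m <= 16L) {
      masks <- 0:(2^m - 1)
      valid <- rep(TRUE, length(masks))
      for (e in seq_len(nrow(ed)))
        valid <- valid & bitwAnd(masks, bitwOr(2^(ed[e, 1L] - 1L), 2^(ed[e, 2L] - 1L))) != 0
      loss <- cnt <- lex <- numeric(length(masks))
      for (b in seq_len(m)) {
        inb <- bitwAnd(masks, 2^(b - 1L)) != 0
        loss <- loss + inb * sizes[verts[b]]
        cnt <- cnt + inb
        lex <- lex + inb * 2^(m - b)
      }
      cand <- which(valid)
      cand <- cand[order(loss[cand], cnt[cand], lex[cand])][1L]
      rem <- verts[bitwAnd(masks[cand], 2^(seq_len(m) - 1L)) != 0]
    } else {
      warning("conflict component of ", m, " nodes: greedy resolution")
      rem <- integer(0)
      while (nrow(ed)) {
        deg <- tabulate(c(ed[, 1L], ed[, 2L]), nbins = m)
        pick <- order(-deg / sizes[verts], seq_len(m))[1L]
        rem <- c(rem, verts[pick])
        ed <- ed[ed[, 1L] != pick & ed[, 2L] != pick, , drop = FALSE]
      }
    }
    removed <- c(removed, rem)
  }
  setdiff(seq_len(n), removed)
}
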