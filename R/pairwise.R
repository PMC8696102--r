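# Pairwise structure alignment as the largest consistent ensemble of
# descriptor pairs: build the consistency graph, search for a maximum-weight
# clique, resolve residual conflicts, and take the union of correspondences.

#' Are two descriptor pairs consistent?
#'
#' Two descriptor pairs over the same structure pair are consistent when the
#' union of their correspondences is still injective in both directions --
#' no residue of either structure is mapped to two different partners.
#' Geometric agreement is deliberately not required: flexibility and
#' permutations are scored later, not forbidden here.
#'
#' @param p,q `descriptor_pair` objects over the same structure pair.
#' @return logical.
#' @export
consistent <- function(p, q) {
  if (!identical(c(p$a_structure, p$b_structure), c(q$a_structure, q$b_structure)))
    stop("descriptor pairs must be over the same structure pair")
  m <- rbind(p$corr, q$corr)
  m <- m[!duplicated(m), , drop = FALSE]
  !anyDuplicated(m[, 1L]) && !anyDuplicated(m[, 2L])
}

# consistency adjacency matrix over a pool of descriptor pairs (one
# structure pair, common orientation).  TRUE = consistent.
consistency_graph <- function(pool, na_res, nb_res) {
  k <- length(pool)
  conflict <- matrix(FALSE, k, k)
  mark <- function(residue_of, partner_of) {
    # nodes sharing a residue with different partners conflict
    byres <- split(seq_along(residue_of), residue_of)
    for (grp in byres) {
      if (length(grp) < 2L) next
      node <- node_id[grp]; val <- partner_of[grp]
      bad <- outer(val, val, "!=")
      if (any(bad)) {
        ij <- which(bad, arr.ind = TRUE)
        conflict[cbind(node[ij[, 1L]], node[ij[, 2L]])] <<- TRUE
      }
    }
  }
  all_a <- unlist(lapply(pool, function(p) p$corr[, 1L]))
  all_b <- unlist(lapply(pool, function(p) p$corr[, 2L]))
  node_id <- rep(seq_len(k), vapply(pool, function(p) nrow(p$corr), 0L))
  mark(all_a, all_b)
  mark(all_b, all_a)
  diag(conflict) <- FALSE
  adj <- !conflict
  diag(adj) <- FALSE
  adj
}

#' Pairwise alignment of two structures
#'
#' Computes all similar descriptor pairs, builds the consistency graph with
#' node weight equal to the correspondence size, selects a maximum-weight
#' clique ([max_clique_exact()] for small graphs, [max_clique_heuristic()]
#' otherwise, candidate cliques compared by the exact size of the union
#' correspondence), clears any residual conflicts with
#' [resolve_conflicts()], and returns the union of the selected
#' correspondences.  No global superposition is imposed, so hinge-bent
#' domains and circular permutations align in full.
#'
#' @param sa,sb [structure3d()] objects.
#' @param params an [msta_params()] list.
#' @param pool optional precomputed descriptor-pair list for this pair.
#' @return object of class `pairwise_alignment`: `structure_a`,
#'   `structure_b`, `pairs` (m x 2 ordinal matrix), `support` (descriptor
#'   pairs backing each residue pair), `nodes` (indices of the selected
#'   descriptor pairs in `pool`).  Empty alignment when no descriptor pair
#'   passes the similarity thresholds.
#' @export
align_pair <- function(sa, sb, params = msta_params(), pool = NULL) {
  if (is.null(pool)) pool <- all_descriptor_pairs(sa, sb, params)
  empty <- function() structure(
    list(structure_a = sa$name, structure_b = sb$name,
         pairs = matrix(integer(), 0L, 2L), support = integer(0), nodes = integer(0)),
    class = "pairwise_alignment")
  if (length(pool) == 0L) return(empty())
  # orient every node a -> b = sa -> sb
  pool <- lapply(pool, function(p) {
    if (identical(p$a_structure, sa$name)) p
    else {
      p$corr <- p$corr[, 2:1, drop = FALSE]
      p[c("a_structure", "b_structure", "a_central", "b_central")] <-
        p[c("b_structure", "a_structure", "b_central", "a_central")]
      p
    }
  })
  # beam: clique search runs on the heaviest nodes only (the correspondence
  # size is the objective, so light nodes rarely enter the maximum)
  sub <- seq_along(pool)
  w_all <- vapply(pool, function(p) p$size, 0L)
  if (length(pool) > params$clique_beam)
    sub <- sort(order(-w_all, seq_along(pool))[seq_len(params$clique_beam)])
  pool <- pool[sub]
  adj <- consistency_graph(pool, sa$n, sb$n)
  w <- w_all[sub]
  union_size <- function(cl) {
    m <- unique(do.call(rbind, lapply(pool[cl], function(p) p$corr)))
    nrow(m)
  }
  n <- length(pool)
  cl <- if (n <= params$exact_limit) {
    max_clique_exact(adj, w, limit = params$exact_limit)
  } else {
    max_clique_heuristic(adj, w, restarts = params$restarts,
                         tol = params$replicator_tol,
                         max_iter = params$replicator_iter, eval_fn = union_size)
  }
  if (length(cl) == 0L) return(empty())
  cl <- cl[resolve_conflicts(!adj[cl, cl, drop = FALSE],
                             vapply(pool[cl], function(p) p$size, 0L))]
  allp <- do.call(rbind, lapply(pool[cl], function(p) p$corr))
  key <- paste(allp[, 1L], allp[, 2L])
  support <- as.integer(table(key)[match(unique(key), names(table(key)))])
  pairs <- allp[!duplicated(key), , drop = FALSE]
  o <- order(pairs[, 1L])
  pairs <- pairs[o, , drop = FALSE]; support <- support[o]
  if (anyDuplicated(pairs[, 1L]) || anyDuplicated(pairs[, 2L]))
    stop("internal error: pairwise alignment is not injective")
  structure(list(structure_a = sa$name, structure_b = sb$name,
                 pairs = unname(pairs), support = support, nodes = sub[cl]),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment %s ~ %s: %d residue pairs from %d descriptor pairs\n",
              x$structure_a, x$structure_b, nrow(x$pairs), length(x$nodes)))
  invisible(x)
}
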