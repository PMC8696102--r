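# Multiple alignments as column sets.  A column maps a subset of structures
# to exactly one residue each; two residues of one structure may never share
# a column, and a (structure, residue) appears in at most one column.

#' Construct a multiple alignment
#'
#' @param struct_names character vector of member structure names.
#' @param cols k x S integer matrix (NA = structure absent from column);
#'   columns of the matrix are structures (named), rows are alignment columns.
#' @return object of class `msta_alignment`.
#' @export
multiple_alignment <- function(struct_names, cols) {
  cols <- matrix(as.integer(cols), ncol = length(struct_names),
                 dimnames = list(NULL, struct_names))
  ma <- structure(list(struct_names = struct_names, cols = cols),
                  class = "msta_alignment")
  validate_alignment(ma)
  ma
}

#' Check multiple-alignment invariants
#'
#' Stops unless every column is non-empty and no (structure, residue) occurs
#' twice across columns.  Called internally after every profile alignment.
#'
#' @param ma an alignment.
#' @return `ma`, invisibly.
#' @export
validate_alignment <- function(ma) {
  cols <- ma$cols
  if (nrow(cols) && any(rowSums(!is.na(cols)) == 0L)) stop("empty alignment column")
  for (s in seq_len(ncol(cols))) {
    v <- cols[, s]
    if (anyDuplicated(v[!is.na(v)])) stop("residue of structure '",
                                          ma$struct_names[s], "' in two columns")
  }
  invisible(ma)
}

#' @export
print.msta_alignment <- function(x, ...) {
  multi <- sum(rowSums(!is.na(x$cols)) >= 2L)
  cat(sprintf("msta_alignment: %d structures, %d columns (%d aligned)\n",
              length(x$struct_names), nrow(x$cols), multi))
  invisible(x)
}

# every residue of every structure as a singleton column (leaf alignment)
singleton_alignment <- function(s) {
  multiple_alignment(s$name, matrix(seq_len(s$n), ncol = 1L))
}

#' Multiple alignment from a pairwise alignment
#'
#' @param pa a `pairwise_alignment` from [align_pair()].
#' @return two-structure `msta_alignment`, one column per aligned pair.
#' @export
from_pairwise <- function(pa) {
  multiple_alignment(c(pa$structure_a, pa$structure_b), pa$pairs)
}

# number of aligned residue pairs induced by the columns (within-column pairs)
aligned_pair_count <- function(ma) {
  k <- rowSums(!is.na(ma$cols))
  sum(k * (k - 1L) / 2)
}

# canonical string keys of all induced residue pairs (structure names, so
# the result is invariant to structure and column order)
pair_keys <- function(ma) {
  cols <- ma$cols
  nm <- ma$struct_names
  ns <- length(nm)
  if (ns < 2L) return(character(0))
  out <- vector("list", ns * (ns - 1L) / 2L)
  k <- 0L
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
    k <- k + 1L
    rows <- !is.na(cols[, a]) & !is.na(cols[, b])
    if (!any(rows)) next
    k1 <- paste0(nm[a], "|", cols[rows, a])
    k2 <- paste0(nm[b], "|", cols[rows, b])
    sw <- k1 > k2
    out[[k]] <- paste0(ifelse(sw, k2, k1), "||", ifelse(sw, k1, k2))
  }
  unlist(out)
}

#' Restrict an alignment to a subset of structures
#'
#' @param ma an alignment.
#' @param structs structure names to keep.
#' @return alignment over `structs`; columns that lose all members are dropped.
#' @export
subalignment <- function(ma, structs) {
  keep <- match(structs, ma$struct_names)
  if (anyNA(keep)) stop("unknown structure in subalignment request")
  cols <- ma$cols[, keep, drop = FALSE]
  cols <- cols[rowSums(!is.na(cols)) > 0L, , drop = FALSE]
  multiple_alignment(structs, cols)
}

#' Detect transitive conflicts among pairwise alignments
#'
#' Builds the union graph of residue equivalences asserted by a set of
#' pairwise alignments over three or more structures and reports every
#' connected component that ties together two distinct residues of one
#' structure -- such components cannot be realized as columns of a single
#' multiple alignment.
#'
#' @param pas list of `pairwise_alignment` objects over a common structure set.
#' @return object of class `conflict_report`: list with `conflicts`, a list
#'   of data frames (structure, residue) giving each offending component
#'   (the witnessing transitive chain is the component itself).
#' @export
detect_conflicts <- function(pas) {
  edges <- do.call(rbind, lapply(pas, function(pa) {
    cbind(paste0(pa$structure_a, "|", pa$pairs[, 1L]),
          paste0(pa$structure_b, "|", pa$pairs[, 2L]))
  }))
  if (is.null(edges) || nrow(edges) == 0L)
    return(structure(list(conflicts = list()), class = "conflict_report"))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  conflicts <- list()
  for (ci in which(comp$csize >= 2L)) {
    verts <- names(comp$membership)[comp$membership == ci]
    parts <- do.call(rbind, strsplit(verts, "|", fixed = TRUE))
    if (anyDuplicated(parts[, 1L])) {
      df <- data.frame(structure = parts[, 1L], residue = as.integer(parts[, 2L]))
      conflicts[[length(conflicts) + 1L]] <- df[order(df$structure, df$residue), ]
    }
  }
  structure(list(conflicts = conflicts), class = "conflict_report")
}

# flat correspondence tables from an explicit descriptor-pair list
flat_from_pool <- function(pool) {
  if (length(pool) == 0L) return(list())
  keys <- vapply(pool, function(p) paste(p$a_structure, p$b_structure), "")
  lapply(split(seq_along(pool), keys), function(ix) {
    corr <- lapply(pool[ix], `[[`, "corr")
    sizes <- vapply(corr, nrow, 0L)
    list(s1 = pool[[ix[1L]]]$a_structure, s2 = pool[[ix[1L]]]$b_structure,
         dp = rep(seq_along(ix), sizes),
         ra = unlist(lapply(corr, function(m) m[, 1L])),
         rb = unlist(lapply(corr, function(m) m[, 2L])))
  })
}

# beam pruning of merge candidates: per left column and per right column keep
# the `beam` best-scoring candidates
prune_candidates <- function(c1, c2, score, beam = 3L) {
  keep <- rep(FALSE, length(score))
  for (side in list(c1, c2)) {
    o <- order(side, -score)
    r <- unlist(lapply(split(seq_along(o), side[o]), function(ix) ix[seq_len(min(beam, length(ix)))]))
    keep[o[sort(r)]] <- TRUE
  }
  which(keep)
}

#' Align two multiple alignments (profile-profile)
#'
#' Candidate merges of a column of `ma1` with a column of `ma2` are generated
#' from the descriptor pairs in `pool` that link a residue of one to a
#' residue of the other; each candidate is scored by (number of supporting
#' descriptor pairs) x (number of residue pairs newly co-aligned).  A maximal
#' consistent set of merges (no column used twice) is selected by maximum
#' weight clique search on the candidate consistency graph, then passed
#' through [resolve_conflicts()].  Unmerged columns of both inputs are kept
#' unchanged, so the restriction of the result to either input's structures
#' reproduces that input.
#'
#' @param ma1,ma2 alignments over disjoint structure sets.
#' @param pool list of `descriptor_pair` objects linking the two sides (pairs
#'   involving other structures are ignored).
#' @param params an [msta_params()] list.
#' @param flat optional list of flat correspondence tables (see `get_flat`);
#'   when given, `pool` is ignored (internal fast path).
#' @return merged `msta_alignment` over the union structure set.
#' @export
align_profiles <- function(ma1, ma2, pool, params = msta_params(), flat = NULL) {
  s1 <- ma1$struct_names; s2 <- ma2$struct_names
  if (length(intersect(s1, s2))) stop("structure sets must be disjoint")
  colof <- function(ma) {
    lapply(seq_along(ma$struct_names), function(s) {
      v <- ma$cols[, s]
      m <- integer(0)
      if (any(!is.na(v))) m[v[!is.na(v)]] <- which(!is.na(v))
      m
    })
  }
  co1 <- setNames(colof(ma1), s1); co2 <- setNames(colof(ma2), s2)
  if (is.null(flat)) flat <- flat_from_pool(pool)
  lk <- function(m, idx) {
    out <- rep(NA_integer_, length(idx))
    ok <- idx <= length(m)
    out[ok] <- m[idx[ok]]
    out
  }
  c1 <- c2 <- integer(0); dpid <- integer(0); off <- 0L
  for (e in flat) {
    if (e$s1 %in% s1 && e$s2 %in% s2) {
      u <- e$s1; v <- e$s2; ra <- e$ra; rb <- e$rb
    } else if (e$s2 %in% s1 && e$s1 %in% s2) {
      u <- e$s2; v <- e$s1; ra <- e$rb; rb <- e$ra
    } else next
    q1 <- lk(co1[[u]], ra); q2 <- lk(co2[[v]], rb)
    ok <- !is.na(q1) & !is.na(q2)
    if (any(ok)) {
      c1 <- c(c1, q1[ok]); c2 <- c(c2, q2[ok]); dpid <- c(dpid, e$dp[ok] + off)
    }
    off <- off + max(e$dp, 0L)
  }
  # one vote per descriptor pair and candidate merge
  dd <- !duplicated(paste(dpid, c1, c2))
  c1 <- c1[dd]; c2 <- c2[dd]; dpid <- dpid[dd]
  if (length(c1) == 0L) {
    cols <- rbind(cbind(ma1$cols, matrix(NA_integer_, nrow(ma1$cols), length(s2))),
                  cbind(matrix(NA_integer_, nrow(ma2$cols), length(s1)), ma2$cols))
    return(multiple_alignment(c(s1, s2), cols))
  }
  key <- paste(c1, c2)
  first <- !duplicated(key)
  support <- as.integer(table(factor(key, levels = key[first])))
  uc1 <- c1[first]; uc2 <- c2[first]
  sz1 <- rowSums(!is.na(ma1$cols)); sz2 <- rowSums(!is.na(ma2$cols))
  score <- as.numeric(support) * sz1[uc1] * sz2[uc2]
  sel <- prune_candidates(uc1, uc2, score)
  uc1 <- uc1[sel]; uc2 <- uc2[sel]; score <- score[sel]
  # deterministic candidate order for the clique machinery
  o <- order(uc1, uc2)
  uc1 <- uc1[o]; uc2 <- uc2[o]; score <- score[o]
  adj <- outer(uc1, uc1, "!=") & outer(uc2, uc2, "!=")
  cl <- best_clique(adj, score, params, restarts = params$profile_restarts)
  cl <- cl[resolve_conflicts(!adj[cl, cl, drop = FALSE], score[cl])]
  mc1 <- uc1[cl]; mc2 <- uc2[cl]
  merged <- cbind(ma1$cols[mc1, , drop = FALSE], ma2$cols[mc2, , drop = FALSE])
  rest1 <- setdiff(seq_len(nrow(ma1$cols)), mc1)
  rest2 <- setdiff(seq_len(nrow(ma2$cols)), mc2)
  cols <- rbind(merged,
                cbind(ma1$cols[rest1, , drop = FALSE],
                      matrix(NA_integer_, length(rest1), length(s2))),
                cbind(matrix(NA_integer_, length(rest2), length(s1)),
                      ma2$cols[rest2, , drop = FALSE]))
  multiple_alignment(c(s1, s2), cols)
}
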