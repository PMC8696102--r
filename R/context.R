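# Shared precomputation for a set of structures being aligned: contact
# matrices, element validity, descriptors, descriptor-pair pools per
# structure pair, and a memo table for contact tensions.  Everything
# downstream (pairwise alignment, the evolutionary algorithm, scoring) works
# against this context, so nothing is recomputed across seeds or iterations.

#' Build an alignment context
#'
#' @param structures list of [structure3d()] objects (unique names).
#' @param params an [msta_params()] list.
#' @param pools optionally precomputed descriptor-pair pools (named
#'   `"i|j"` by structure index, i < j), e.g. to share across runs.
#' @return an environment of class `msta_context` with fields `structures`,
#'   `params`, `cm` (contact matrices), `valid` (element validity), `descs`
#'   (descriptor lists), `pools` and `tension_memo`.
#' @export
alignment_context <- function(structures, params = msta_params(), pools = NULL) {
  nm <- vapply(structures, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("structure names must be unique")
  names(structures) <- nm
  ctx <- new.env(parent = emptyenv())
  ctx$structures <- structures
  ctx$params <- params
  ctx$cm <- lapply(structures, contact_matrix, criterion = params$criterion)
  ctx$valid <- lapply(structures, element_valid)
  ctx$descs <- lapply(structures, all_descriptors, criterion = params$criterion)
  ctx$pools <- if (is.null(pools)) list() else pools
  ctx$tension_memo <- new.env(parent = emptyenv())
  class(ctx) <- "msta_context"
  ctx
}

# descriptor-pair pool for structure indices i < j, computed on first use
get_pool <- function(ctx, i, j) {
  if (i > j) stop("internal: pool indices must be ordered")
  key <- paste0(i, "|", j)
  if (is.null(ctx$pools[[key]])) {
    ctx$pools[[key]] <- all_descriptor_pairs(
      ctx$structures[[i]], ctx$structures[[j]], ctx$params,
      ctx$descs[[i]], ctx$descs[[j]])
  }
  ctx$pools[[key]]
}

# flat correspondence table of a pool: one row per residue pair, columns
# dp (pool index), ra (ordinal in structure i), rb (ordinal in structure j).
# Cached; align_profiles consumes these to avoid per-descriptor-pair loops.
get_flat <- function(ctx, i, j) {
  key <- paste0(i, "|", j)
  if (is.null(ctx$flats)) ctx$flats <- list()
  if (is.null(ctx$flats[[key]])) {
    pool <- get_pool(ctx, i, j)
    nm_i <- names(ctx$structures)[i]
    corr <- lapply(pool, function(p)
      if (identical(p$a_structure, nm_i)) p$corr else p$corr[, 2:1, drop = FALSE])
    sizes <- vapply(corr, nrow, 0L)
    ctx$flats[[key]] <- list(
      s1 = nm_i, s2 = names(ctx$structures)[j],
      dp = rep(seq_along(pool), sizes),
      ra = unlist(lapply(corr, function(m) m[, 1L])),
      rb = unlist(lapply(corr, function(m) m[, 2L])))
  }
  ctx$flats[[key]]
}

# index of a structure name in the context
struct_index <- function(ctx, name) {
  i <- match(name, names(ctx$structures))
  if (is.na(i)) stop("unknown structure: ", name)
  i
}
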