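# Descriptor-pair alignment: residue-level correspondence between two
# similar descriptors from two structures.  A descriptor pair is the
# elementary building block of every alignment computed by this package.

# 5-residue window ordinals for element centers
win_idx <- function(centers) {
  cbind(centers - 2L, centers - 1L, centers, centers + 1L, centers + 2L)
}

# flattened (k x 15) window coordinates
win_coords <- function(ca, idx) {
  do.call(cbind, lapply(seq_len(ncol(idx)), function(k) ca[idx[, k], , drop = FALSE]))
}

# greedy element matching under a fixed rigid transform of b onto a.
# Returns element-match matrix and residue maps; the central match is forced.
greedy_elements <- function(ea, eb, idx_a, idx_b, fa, fbt, ca_ord, cb_ord,
                            na_res, nb_res, wmax) {
  d2 <- matrix(rowSums(fa^2), length(ea), length(eb)) +
    matrix(rowSums(fbt^2), length(ea), length(eb), byrow = TRUE) -
    2 * fa %*% t(fbt)
  cost <- sqrt(pmax(d2, 0) / 5)
  ic <- which(ea == ca_ord); jc <- which(eb == cb_ord)
  map_ab <- rep(NA_integer_, na_res); map_ba <- rep(NA_integer_, nb_res)
  used_a <- logical(length(ea)); used_b <- logical(length(eb))
  matches <- matrix(integer(), 0L, 2L)
  accept <- function(i, j) {
    wa <- idx_a[i, ]; wb <- idx_b[j, ]
    ok <- all((is.na(map_ab[wa]) | map_ab[wa] == wb) &
              (is.na(map_ba[wb]) | map_ba[wb] == wa))
    if (!ok) return(FALSE)
    map_ab[wa] <<- wb; map_ba[wb] <<- wa
    used_a[i] <<- TRUE; used_b[j] <<- TRUE
    matches <<- rbind(matches, c(i, j))
    TRUE
  }
  accept(ic, jc)
  cand <- which(cost <= wmax, arr.ind = TRUE)
  if (nrow(cand)) {
    cand <- cand[order(cost[cand], cand[, 1L], cand[, 2L]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      if (!used_a[i] && !used_b[j]) accept(i, j)
    }
  }
  list(matches = matches, map_ab = map_ab)
}

# residue correspondence (k x 2) implied by a set of element matches
corr_from_matches <- function(matches, idx_a, idx_b, na_res, nb_res) {
  map_ab <- rep(NA_integer_, na_res); map_ba <- rep(NA_integer_, nb_res)
  for (r in seq_len(nrow(matches))) {
    wa <- idx_a[matches[r, 1L], ]; wb <- idx_b[matches[r, 2L], ]
    ok <- (is.na(map_ab[wa]) | map_ab[wa] == wb) & (is.na(map_ba[wb]) | map_ba[wb] == wa)
    if (all(ok)) { map_ab[wa] <- wb; map_ba[wb] <- wa }
  }
  ia <- which(!is.na(map_ab))
  cbind(a = ia, b = map_ab[ia])
}

# number of maximal consecutive runs in a sorted integer vector
n_runs <- function(x) if (length(x) == 0L) 0L else sum(c(TRUE, diff(sort(x)) != 1L))

# descriptor segments represented in a set of corresponded ordinals (element
# windows never span two segments, so any overlap means a matched element)
segments_covered <- function(segments, ordinals) {
  sum(vapply(segments, function(r) any(r[1L]:r[2L] %in% ordinals), TRUE))
}

#' Align two local descriptors
#'
#' Searches for the largest residue-level correspondence between two
#' descriptors from different structures such that (i) the central elements
#' correspond position-by-position, (ii) at least `min_elements` whole
#' elements (central one included) are aligned center-to-center in forward
#' orientation, and (iii) a single rigid superposition of all corresponded
#' Calpha atoms has RMSD at most `rmsd_max`.  The correspondence may permute
#' segments (no sequence-order constraint across elements) but is monotone
#' within each element.
#'
#' Matching is an iterated closest-element procedure: the central elements
#' anchor an initial superposition, elements are greedily paired by window
#' RMSD under the current transform subject to residue injectivity, the
#' transform is refit on all corresponded atoms and matching repeated; if the
#' final RMSD exceeds `rmsd_max` the worst-fitting elements are peeled off.
#'
#' @param da,db descriptors from [build_descriptor()].
#' @param sa,sb their parent [structure3d()] objects.
#' @param params an [msta_params()] list.
#' @return a `descriptor_pair` (list with `corr` k x 2 ordinal matrix,
#'   `rmsd`, `n_elements`, `n_segments` -- the number of the first
#'   descriptor's segments entirely covered by the correspondence -- `size`,
#'   central ordinals) or `NULL` when the descriptors are not similar.
#' @export
align_descriptors <- function(da, db, sa, sb, params = msta_params()) {
  if (is.null(da) || is.null(db)) return(NULL)
  if (identical(sa$name, sb$name)) stop("descriptors must come from different structures")
  # canonical orientation so that (a,b) and (b,a) give inverse correspondences
  if (order(c(paste0(sa$name, "\r", da$central), paste0(sb$name, "\r", db$central)))[1L] == 2L) {
    sw <- align_descriptors(db, da, sb, sa, params)
    if (is.null(sw)) return(NULL)
    sw$corr <- sw$corr[, 2:1, drop = FALSE]; colnames(sw$corr) <- c("a", "b")
    sw[c("a_central", "b_central", "a_structure", "b_structure")] <-
      sw[c("b_central", "a_central", "b_structure", "a_structure")]
    sw$n_segments <- segments_covered(da$segments, sw$corr[, 1L])
    return(sw)
  }
  ea <- da$element_centers; eb <- db$element_centers
  if (length(ea) < params$min_elements || length(eb) < params$min_elements) return(NULL)
  idx_a <- win_idx(ea); idx_b <- win_idx(eb)
  wa0 <- win_idx(da$central)[1L, ]; wb0 <- win_idx(db$central)[1L, ]
  sup <- superpose(sa$ca[wa0, ], sb$ca[wb0, ])
  if (sup$rmsd > params$rmsd_max) return(NULL)
  fa <- win_coords(sa$ca, idx_a)
  res <- NULL
  for (it in 1:2) {
    bt <- apply_superposition(sup, sb$ca)
    res <- greedy_elements(ea, eb, idx_a, idx_b, fa, win_coords(bt, idx_b),
                           da$central, db$central, sa$n, sb$n, params$window_rmsd_max)
    corr <- corr_from_matches(res$matches, idx_a, idx_b, sa$n, sb$n)
    sup <- superpose(sa$ca[corr[, 1L], , drop = FALSE], sb$ca[corr[, 2L], , drop = FALSE])
  }
  matches <- res$matches
  # peel worst elements while the global fit is too loose
  repeat {
    if (nrow(matches) < params$min_elements) return(NULL)
    corr <- corr_from_matches(matches, idx_a, idx_b, sa$n, sb$n)
    sup <- superpose(sa$ca[corr[, 1L], , drop = FALSE], sb$ca[corr[, 2L], , drop = FALSE])
    if (sup$rmsd <= params$rmsd_max) break
    bt <- apply_superposition(sup, sb$ca)
    dev <- vapply(seq_len(nrow(matches)), function(r) {
      wa <- idx_a[matches[r, 1L], ]; wb <- idx_b[matches[r, 2L], ]
      mean(rowSums((sa$ca[wa, ] - bt[wb, ])^2))
    }, 0)
    ic <- which(ea[matches[, 1L]] == da$central)
    dev[ic] <- -Inf                 # never peel the central match
    matches <- matches[-which.max(dev), , drop = FALSE]
  }
  structure(list(
    a_structure = sa$name, b_structure = sb$name,
    a_central = da$central, b_central = db$central,
    corr = corr, rmsd = sup$rmsd, size = nrow(corr),
    n_elements = nrow(matches),
    n_segments = segments_covered(da$segments, corr[, 1L])),
    class = "descriptor_pair")
}

#' All similar descriptor pairs between two structures
#'
#' Builds every descriptor of both structures and returns the aligned pairs
#' that pass the similarity thresholds, ordered by the two central ordinals.
#'
#' @param sa,sb [structure3d()] objects.
#' @param params an [msta_params()] list.
#' @param descs_a,descs_b optional precomputed descriptor lists
#'   (from `all_descriptors`), to avoid recomputation across calls.
#' @return list of `descriptor_pair` objects (possibly empty).
#' @export
all_descriptor_pairs <- function(sa, sb, params = msta_params(),
                                 descs_a = NULL, descs_b = NULL) {
  if (is.null(descs_a)) descs_a <- all_descriptors(sa, params$criterion)
  if (is.null(descs_b)) descs_b <- all_descriptors(sb, params$criterion)
  out <- vector("list", 0L)
  for (i in seq_along(descs_a)) {
    da <- descs_a[[i]]
    if (is.null(da) || length(da$element_centers) < params$min_elements) next
    for (j in seq_along(descs_b)) {
      db <- descs_b[[j]]
      if (is.null(db) || length(db$element_centers) < params$min_elements) next
      dp <- align_descriptors(da, db, sa, sb, params)
      if (!is.null(dp)) out[[length(out) + 1L]] <- dp
    }
  }
  out
}
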