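# Tension-based alignment quality.  For every pair of aligned residues in
# contact in at least one of the two structures, the RMSD of the two
# five-residue backbone elements is computed; these are averaged per
# residue, squared, averaged per structure pair and over the alignment.
# Low tension means the local environments agree; it is the elastic strain
# left when the alignment is treated as a set of springs.

#' Aligned residue pairs in contact
#'
#' For each structure pair and each pair of alignment columns containing
#' both structures, emits the column pair when the two residues are in
#' contact in at least one of the two structures.
#'
#' @param ma an `msta_alignment`.
#' @param ctx an [alignment_context()].
#' @return data frame with columns `si`, `sj` (structure indices), `col1`,
#'   `col2` (row indices of `ma$cols`).
#' @export
contact_pairs <- function(ma, ctx) {
  out <- list()
  idx <- match(ma$struct_names, names(ctx$structures))
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (a >= b) next
    rows <- which(!is.na(ma$cols[, a]) & !is.na(ma$cols[, b]))
    if (length(rows) < 2L) next
    ri <- ma$cols[rows, a]; rj <- ma$cols[rows, b]
    m <- ctx$cm[[idx[a]]][ri, ri, drop = FALSE] | ctx$cm[[idx[b]]][rj, rj, drop = FALSE]
    hit <- which(m & upper.tri(m), arr.ind = TRUE)
    if (nrow(hit))
      out[[length(out) + 1L]] <- data.frame(si = idx[a], sj = idx[b],
                                            col1 = rows[hit[, 1L]], col2 = rows[hit[, 2L]])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(si = integer(0), sj = integer(0), col1 = integer(0), col2 = integer(0))
}

#' Element RMSD of one aligned contact
#'
#' Superposes the union of the two contact residues' 5-residue backbone
#' elements (Calpha, up to 10 points; duplicated correspondences from
#' overlapping windows are counted once) of structure `sj` onto structure
#' `si` and returns the RMSD.  Memoized in the context.
#'
#' @param ctx an [alignment_context()].
#' @param si,sj structure indices.
#' @param ri1,ri2 contact residue ordinals in structure `si`.
#' @param rj1,rj2 their aligned partners in structure `sj`.
#' @return RMSD in Angstrom, or `NA` if any element is invalid.
#' @export
contact_tension <- function(ctx, si, sj, ri1, ri2, rj1, rj2) {
  key <- paste(si, sj, ri1, ri2, rj1, rj2)
  hit <- ctx$tension_memo[[key]]
  if (!is.null(hit)) return(hit)
  if (!ctx$valid[[si]][ri1] || !ctx$valid[[si]][ri2] ||
      !ctx$valid[[sj]][rj1] || !ctx$valid[[sj]][rj2]) return(NA_real_)
  ii <- c((ri1 - 2L):(ri1 + 2L), (ri2 - 2L):(ri2 + 2L))
  jj <- c((rj1 - 2L):(rj1 + 2L), (rj2 - 2L):(rj2 + 2L))
  keep <- !duplicated(paste(ii, jj))
  val <- superpose(ctx$structures[[si]]$ca[ii[keep], , drop = FALSE],
                   ctx$structures[[sj]]$ca[jj[keep], , drop = FALSE])$rmsd
  ctx$tension_memo[[key]] <- val
  val
}

#' Tension of a multiple alignment
#'
#' Per structure pair, contact element-RMSDs are averaged for each aligned
#' residue over all its contacts, the per-residue means are squared and
#' averaged over residues with at least one contact; the total is the mean
#' over structure pairs with at least one contributing residue.  Contacts
#' whose residues lack a valid element in either structure are skipped.
#'
#' @param ma an `msta_alignment`.
#' @param ctx an [alignment_context()].
#' @return list of class `tension_result`: `per_pair` (named, Angstrom^2),
#'   `total` (Angstrom^2), `n_contacts`.
#' @export
tension <- function(ma, ctx) {
  cp <- contact_pairs(ma, ctx)
  per_pair <- numeric(0)
  n_used <- 0L
  for (key in unique(paste(cp$si, cp$sj))) {
    sub <- cp[paste(cp$si, cp$sj) == key, , drop = FALSE]
    si <- sub$si[1L]; sj <- sub$sj[1L]
    ai <- match(names(ctx$structures)[si], ma$struct_names)
    aj <- match(names(ctx$structures)[sj], ma$struct_names)
    tv <- vapply(seq_len(nrow(sub)), function(r) {
      c1 <- sub$col1[r]; c2 <- sub$col2[r]
      contact_tension(ctx, si, sj, ma$cols[c1, ai], ma$cols[c2, ai],
                      ma$cols[c1, aj], ma$cols[c2, aj])
    }, 0)
    ok <- !is.na(tv)
    if (!any(ok)) next
    n_used <- n_used + sum(ok)
    # per-residue mean over incident contacts (a residue = an aligned column)
    res <- c(sub$col1[ok], sub$col2[ok])
    val <- c(tv[ok], tv[ok])
    per_res <- vapply(split(val, res), mean, 0)
    per_pair[paste(names(ctx$structures)[si], names(ctx$structures)[sj], sep = "~")] <-
      mean(per_res^2)
  }
  structure(list(per_pair = per_pair,
                 total = if (length(per_pair)) mean(per_pair) else 0,
                 n_contacts = n_used),
            class = "tension_result")
}

#' Decompose one structure pair's alignment into contact-connected regions
#'
#' Vertices are the aligned residue pairs of one structure pair; edges join
#' pairs whose residues are in contact in either structure.  Each connected
#' component (region) carries the rotation of its own least-squares
#' superposition; regions smaller than `min_region` pairs reuse the largest
#' region's rotation and are flagged.
#'
#' @param ma an `msta_alignment`.
#' @param ctx an [alignment_context()].
#' @param name_a,name_b structure names of the pair.
#' @return list of regions: `rows` (row indices in `ma$cols`), `pairs`
#'   (m x 2 ordinals), `size`, `rotation`, `reused` (logical).
#' @export
region_decomposition <- function(ma, ctx, name_a, name_b) {
  a <- match(name_a, ma$struct_names); b <- match(name_b, ma$struct_names)
  si <- struct_index(ctx, name_a); sj <- struct_index(ctx, name_b)
  rows <- which(!is.na(ma$cols[, a]) & !is.na(ma$cols[, b]))
  if (length(rows) == 0L) return(list())
  ri <- ma$cols[rows, a]; rj <- ma$cols[rows, b]
  m <- ctx$cm[[si]][ri, ri, drop = FALSE] | ctx$cm[[sj]][rj, rj, drop = FALSE]
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(m, mode = "undirected"))
  regions <- lapply(seq_len(comp$no), function(k) {
    sel <- which(comp$membership == k)
    list(rows = rows[sel], pairs = cbind(ri[sel], rj[sel]), size = length(sel),
         rotation = NULL, reused = FALSE)
  })
  sizes <- vapply(regions, `[[`, 0L, "size")
  span <- vapply(regions, function(r) diff(range(r$pairs[, 1L])), 0L)
  first <- vapply(regions, function(r) min(r$pairs[, 1L]), 0L)
  regions <- regions[order(-sizes, -span, first)]
  for (k in seq_along(regions)) {
    r <- regions[[k]]
    if (r$size >= max(3L, ctx$params$min_region)) {
      regions[[k]]$rotation <- superpose(
        ctx$structures[[si]]$ca[r$pairs[, 1L], , drop = FALSE],
        ctx$structures[[sj]]$ca[r$pairs[, 2L], , drop = FALSE])$rotation
    } else {
      regions[[k]]$rotation <- regions[[1L]]$rotation
      regions[[k]]$reused <- TRUE
    }
  }
  regions
}

#' Rotation-augmented size of a region decomposition
#'
#' The largest region counts in full; every other region counts its size
#' times `constant * (1 + cos(alpha)) / 2`, where `alpha` is the angle
#' between its superposition rotation and the largest region's.  Regions
#' rotated coherently are thus counted fully, regions requiring an opposite
#' rotation not at all.
#'
#' @param regions result of [region_decomposition()] (already sorted largest
#'   first, largest-first ties broken by residue span then position).
#' @param constant proportionality constant of the augmentation factor.
#' @return numeric score (<= total pair count).
#' @export
augmented_size <- function(regions, constant = 1.0) {
  if (length(regions) == 0L) return(0)
  score <- regions[[1L]]$size
  if (length(regions) > 1L) for (k in 2:length(regions)) {
    r <- regions[[k]]
    alpha <- if (r$reused) 0 else rotation_angle(regions[[1L]]$rotation, r$rotation)
    score <- score + r$size * constant * (1 + cos(alpha)) / 2
  }
  score
}

#' Fitness of a multiple alignment
#'
#' Sum over structure pairs of the rotation-augmented region sizes, minus
#' `lambda_tension` times the total tension times the number of aligned
#' residue pairs.  Higher is better; deterministic.
#'
#' @param ma an `msta_alignment`.
#' @param ctx an [alignment_context()].
#' @return numeric score.
#' @export
fitness <- function(ma, ctx) {
  if (nrow(ma$cols) == 0L) return(0)
  size_term <- 0
  nm <- ma$struct_names
  if (length(nm) > 1L) for (a in seq_along(nm)) for (b in seq_along(nm)) {
    if (a >= b) next
    regions <- region_decomposition(ma, ctx, nm[a], nm[b])
    size_term <- size_term + augmented_size(regions, ctx$params$augment_const)
  }
  size_term - ctx$params$lambda_tension * tension(ma, ctx)$total * aligned_pair_count(ma)
}

#' Plain-text score report
#'
#' Per-pair tension, region table (size, angle to the largest region,
#' augmentation factor) and total fitness, as tab-separated lines.
#'
#' @param ma an `msta_alignment`.
#' @param ctx an [alignment_context()].
#' @return character vector of report lines.
#' @export
score_report <- function(ma, ctx) {
  tn <- tension(ma, ctx)
  lines <- c("pair\ttension_A2", sprintf("%s\t%.4f", names(tn$per_pair), tn$per_pair),
             "", "pair\tregion\tsize\talpha_deg\tfactor")
  nm <- ma$struct_names
  for (a in seq_along(nm)) for (b in seq_along(nm)) {
    if (a >= b) next
    regions <- region_decomposition(ma, ctx, nm[a], nm[b])
    for (k in seq_along(regions)) {
      alpha <- if (k == 1L || regions[[k]]$reused) 0
               else rotation_angle(regions[[1L]]$rotation, regions[[k]]$rotation)
      lines <- c(lines, sprintf("%s~%s\t%d\t%d\t%.1f\t%.3f", nm[a], nm[b], k,
                                regions[[k]]$size, alpha * 180 / pi, (1 + cos(alpha)) / 2))
    }
  }
  c(lines, "", sprintf("total_tension_A2\t%.6f", tn$total),
    sprintf("aligned_pairs\t%d", aligned_pair_count(ma)),
    sprintf("fitness\t%.4f", fitness(ma, ctx)))
}
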