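#' Residue contact criterion
#'
#' Two residues are in contact when their Calpha atoms are within
#' `d_alpha_max`, or when their side-chain geometric centers are within
#' `d_c_max` and at least `d_diff_min` closer than the Calpha atoms
#' (side chains pointing towards each other).  Defaults: d_alpha <= 6.5 A, or
#' d_C <= 8 A with d_alpha - d_C >= 0.75 A.
#'
#' @param d_alpha_max Calpha-Calpha cutoff (Angstrom).
#' @param d_c_max side-chain-center cutoff (Angstrom).
#' @param d_diff_min minimum d_alpha - d_C excess (Angstrom).
#' @return list of class `contact_criterion`.
#' @export
contact_criterion <- function(d_alpha_max = 6.5, d_c_max = 8.0, d_diff_min = 0.75) {
  stopifnot(d_alpha_max > 0, d_c_max > 0, d_diff_min > 0)
  structure(list(d_alpha_max = d_alpha_max, d_c_max = d_c_max,
                 d_diff_min = d_diff_min), class = "contact_criterion")
}

# n x n logical contact matrix for a structure (no self-contacts)
contact_matrix <- function(s, criterion = contact_criterion()) {
  da <- as.matrix(stats::dist(s$ca))
  dc <- as.matrix(stats::dist(s$sc))
  m <- da <= criterion$d_alpha_max | (dc <= criterion$d_c_max & da - dc >= criterion$d_diff_min)
  diag(m) <- FALSE
  m
}

#' Residues in contact with a central residue
#'
#' @param s a [structure3d()].
#' @param center residue ordinal (1-based).
#' @param criterion a [contact_criterion()].
#' @return sorted integer vector of residue ordinals in contact with `center`.
#' @export
find_contacts <- function(s, center, criterion = contact_criterion()) {
  stopifnot(center >= 1L, center <= s$n)
  da <- sqrt(colSums((t(s$ca) - s$ca[center, ])^2))
  dc <- sqrt(colSums((t(s$sc) - s$sc[center, ])^2))
  hit <- da <= criterion$d_alpha_max |
    (dc <= criterion$d_c_max & da - dc >= criterion$d_diff_min)
  hit[center] <- FALSE
  which(hit)
}

# TRUE for ordinals whose 5-residue window (center +/- 2) stays inside one chain
element_valid <- function(s) {
  n <- s$n
  ok <- rep(FALSE, n)
  if (n >= 5L) {
    idx <- 3:(n - 2L)
    ok[idx] <- s$chain[idx - 2L] == s$chain[idx] & s$chain[idx + 2L] == s$chain[idx]
  }
  ok
}

#' Merge overlapping elements into segments
#'
#' Elements are 5-residue backbone windows centered on contact residues; any
#' overlapping (or touching) windows are concatenated.  The result is the
#' list of maximal runs of consecutive ordinals covered by at least one
#' element, split at chain boundaries.
#'
#' @param centers integer vector of element-center ordinals.
#' @param chain character vector of per-residue chain ids (defines breaks).
#' @return list of integer ranges `c(start, end)`, sorted and disjoint.
#' @export
merge_elements <- function(centers, chain = NULL) {
  centers <- sort(unique(centers))
  if (length(centers) == 0L) return(list())
  # windows merge only when they share a residue; adjacent but disjoint
  # windows remain separate segments
  segs <- list()
  start <- centers[1L] - 2L; end <- centers[1L] + 2L
  for (c in centers[-1L]) {
    overlap <- (c - 2L) <= end
    if (!is.null(chain) && chain[c] != chain[start]) overlap <- FALSE
    if (overlap) end <- c + 2L
    else { segs[[length(segs) + 1L]] <- c(start, end); start <- c - 2L; end <- c + 2L }
  }
  segs[[length(segs) + 1L]] <- c(start, end)
  segs
}

#' Build the local descriptor of a residue
#'
#' The descriptor of a central residue consists of the residues in contact
#' with it; around the center and every contact residue a 5-residue element
#' (two sequential neighbors on each side) is built, and overlapping elements
#' are merged into continuous segments.  Contact residues too close to a
#' chain terminus to carry a full element are dropped.  If the central
#' element itself is invalid the residue has no descriptor.
#'
#' @param s a [structure3d()].
#' @param center residue ordinal.
#' @param criterion a [contact_criterion()].
#' @param cm optional precomputed [contact_matrix] (internal speed-up).
#' @param valid optional precomputed element-validity vector.
#' @return a `descriptor` (list with `structure`, `central`, `contacts`,
#'   `element_centers`, `segments`, `members`) or `NULL`.
#' @export
build_descriptor <- function(s, center, criterion = contact_criterion(),
                             cm = NULL, valid = NULL) {
  if (is.null(valid)) valid <- element_valid(s)
  if (!valid[center]) return(NULL)
  contacts <- if (is.null(cm)) find_contacts(s, center, criterion) else which(cm[center, ])
  contacts <- contacts[valid[contacts]]
  centers <- sort(unique(c(center, contacts)))
  segments <- merge_elements(centers, s$chain)
  members <- sort(unique(unlist(lapply(segments, function(r) r[1L]:r[2L]))))
  structure(list(structure = s$name, central = center, contacts = contacts,
                 element_centers = centers, segments = segments, members = members),
            class = "descriptor")
}

# all descriptors of a structure (NULL entries for invalid centers)
all_descriptors <- function(s, criterion = contact_criterion()) {
  cm <- contact_matrix(s, criterion)
  valid <- element_valid(s)
  lapply(seq_len(s$n), function(i)
    if (valid[i]) build_descriptor(s, i, criterion, cm = cm, valid = valid) else NULL)
}

#' @export
print.descriptor <- function(x, ...) {
  cat(descriptor_report(x), sep = "\n")
  invisible(x)
}

#' Plain-text report of a descriptor
#'
#' Stable diagnostic listing of the central residue, its contacts and the
#' merged segment ranges (by residue ordinal).
#'
#' @param d a descriptor.
#' @param s optional [structure3d()]; when given, ordinals are reported in
#'   PDB numbering (`chain:resno`).
#' @return character vector of report lines.
#' @export
descriptor_report <- function(d, s = NULL) {
  lab <- function(i) {
    if (is.null(s)) as.character(i)
    else paste0(s$chain[i], ":", s$resno[i], ifelse(s$icode[i] == "", "", s$icode[i]))
  }
  segs <- vapply(d$segments, function(r) paste0(lab(r[1L]), "-", lab(r[2L])), "")
  c(sprintf("descriptor %s / center %s", d$structure, lab(d$central)),
    sprintf("contacts (%d): %s", length(d$contacts),
            paste(vapply(d$contacts, lab, ""), collapse = " ")),
    sprintf("segments (%d): %s", length(d$segments), paste(segs, collapse = " ")))
}
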