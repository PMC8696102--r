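# Synthetic structure families with known ground truth.  Chains are built
# from ideal secondary-structure blocks laid out as a packed bundle so that
# every stage of the pipeline (contacts, descriptors, cliques, the
# evolutionary refinement, scoring) can be exercised without external data.

rot_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c + s * ux + (1 - c) * tcrossprod(u)
}

#' Build an idealized protein chain
#'
#' Secondary-structure blocks are laid out as a packed bundle: each helix or
#' strand occupies a slot on a 9.5 A square grid (slots snake through the
#' grid so consecutive blocks pack against each other and every block
#' touches two or three neighbors, as in real helix bundles), running
#' alternately up and down in z; loop blocks connect consecutive slots with
#' a smooth arc.
#' Helices use 1.5 A rise, 100 degrees per residue, 2.3 A radius (consecutive
#' Calpha ~3.8 A apart); strands 3.4 A rise with a +/-0.5 A alternating
#' lateral offset.  Pseudo side-chain centers are placed 1.5 A outward along
#' the local curvature bisector.  Deterministic for a given architecture and
#' seed (the seed only sets helix phases).
#'
#' @param architecture list of blocks, each `list(type, len)` with type
#'   `"helix"`, `"strand"`, `"loop"` or `"linker"`.  A linker behaves like a
#'   loop but skips one column slot, separating the flanking blocks by two
#'   column widths (19 A) so the two sides share no contacts -- a true
#'   two-domain layout.
#' @param seed integer seed.
#' @param name structure label.
#' @return a [structure3d()] with chain "A" and residues numbered from 1.
#' @export
make_chain <- function(architecture, seed = 1L, name = "chain") {
  withr_seed <- .Random.seed_exists()
  set.seed(seed)
  types <- vapply(architecture, `[[`, "", "type")
  lens <- vapply(architecture, function(b) as.integer(b$len), 0L)
  stopifnot(all(types %in% c("helix", "strand", "loop", "linker")), sum(lens) >= 10L)
  phases <- stats::runif(length(types), 0, 2 * pi)
  # grid slot for secondary block k: snake through a 2-row grid so that
  # consecutive blocks stay adjacent and the bundle is compact
  slot_xy <- function(k) {
    cx <- k %/% 2L
    cy <- if (cx %% 2L == 0L) k %% 2L else 1L - k %% 2L
    c(9.5 * cx, 9.5 * cy)
  }
  slot <- -1L; zdir <- 1; zend <- 0
  coords <- vector("list", length(types))
  for (bi in seq_along(types)) {
    L <- lens[bi]
    if (!types[bi] %in% c("loop", "linker")) {
      slot <- slot + 1L
      if (bi > 1L && types[bi - 1L] == "linker") slot <- slot + 3L
      zdir <- if (slot %% 2L == 0L) 1 else -1
      xy <- slot_xy(slot)
      i <- seq_len(L)
      if (types[bi] == "helix") {
        ang <- phases[bi] + (i - 1L) * 100 * pi / 180
        xyz <- cbind(xy[1L] + 2.3 * cos(ang), xy[2L] + 2.3 * sin(ang),
                     zend + zdir * 1.5 * (i - 1L))
      } else {
        xyz <- cbind(xy[1L], xy[2L] + 0.5 * (-1)^i, zend + zdir * 3.4 * (i - 1L))
      }
      zend <- xyz[L, 3L]
      coords[[bi]] <- xyz
    }
  }
  # loops: smooth arcs between the flanking block endpoints
  for (bi in which(types %in% c("loop", "linker"))) {
    L <- lens[bi]
    a <- if (bi > 1L) coords[[bi - 1L]][lens[bi - 1L], ] else c(-4, 0, 0)
    b <- if (bi < length(types)) coords[[bi + 1L]][1L, ] else a + c(4, 0, 0)
    d <- b - a
    bulge <- max(1, (3.8 * (L + 1L) - sqrt(sum(d^2))) / 2)
    t <- seq_len(L) / (L + 1L)
    coords[[bi]] <- cbind(a[1L] + t * d[1L],
                          a[2L] + t * d[2L] + sin(pi * t) * bulge,
                          a[3L] + t * d[3L])
  }
  ca <- do.call(rbind, coords)
  n <- nrow(ca)
  # pseudo side-chain centers: 1.5 A along the curvature bisector
  sc <- ca
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    v <- ca[i, ] - (ca[lo, ] + ca[hi, ]) / 2
    if (sqrt(sum(v^2)) < 0.1) v <- c(0, 1, 0)
    sc[i, ] <- ca[i, ] + 1.5 * v / sqrt(sum(v^2))
  }
  aa <- rep(strsplit("ARNDCQEHILKMFPSTWYV", "")[[1L]], length.out = n)
  if (withr_seed$had) assign(".Random.seed", withr_seed$seed, envir = globalenv())
  structure3d(name = name, chain = rep("A", n), resno = seq_len(n),
              aa = aa, ca = ca, sc = sc)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    list(had = TRUE, seed = get(".Random.seed", envir = globalenv()))
  else list(had = FALSE)
}

#' Two-domain template architecture
#'
#' Two packed three-helix domains joined by a 4-residue inter-domain linker;
#' 60 residues in total.  Three helices per domain give every domain an
#' internal core whose descriptors span three or more backbone segments --
#' needed for the stage-1 core restriction to anchor each structure even
#' when a hinge motion breaks the inter-domain interface.  The two domains
#' have deliberately different helix lengths (8/8/8 vs 10/6/8) so that, as
#' in real two-domain proteins, the domains are not interchangeable and a
#' circular permutation has a unique correct alignment.
#' @return architecture list for [make_chain()].
#' @export
two_domain_architecture <- function() {
  h <- function(n) list(type = "helix", len = n)
  l <- function(n) list(type = "loop", len = n)
  list(h(8), l(2), h(8), l(2), h(8),      # domain 1: residues 1-28
       l(4),                              # linker: 29-32
       h(10), l(2), h(6), l(2), h(8))     # domain 2: 33-60
}

#' Specification of a synthetic structure family
#'
#' @param architecture block list for [make_chain()]; default two-domain.
#' @param n_copies number of structures in the family.
#' @param noise_sigma Gaussian coordinate noise per atom (Angstrom).
#' @param permuted_copies indices of copies receiving a circular permutation.
#' @param cut 1-based ordinal where permuted copies start (their first
#'   residue is template residue `cut`).
#' @param hinged_copies indices of copies receiving a hinge rotation.
#' @param hinge_pivot ordinal of the hinge pivot; residues beyond it rotate.
#' @param hinge_angle hinge angle in degrees.
#' @param seed integer seed.
#' @return list of class `family_spec`.
#' @export
family_spec <- function(architecture = two_domain_architecture(), n_copies = 5L,
                        noise_sigma = 0.3, permuted_copies = integer(0), cut = 31L,
                        hinged_copies = integer(0), hinge_pivot = 30L,
                        hinge_angle = 45, seed = 1L) {
  n <- sum(vapply(architecture, function(b) as.integer(b$len), 0L))
  stopifnot(noise_sigma >= 0, cut > 1L, cut <= n, hinge_pivot > 1L, hinge_pivot < n)
  structure(list(architecture = architecture, n_copies = as.integer(n_copies),
                 noise_sigma = noise_sigma, permuted_copies = as.integer(permuted_copies),
                 cut = as.integer(cut), hinged_copies = as.integer(hinged_copies),
                 hinge_pivot = as.integer(hinge_pivot), hinge_angle = hinge_angle,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate a structure family with ground truth
#'
#' Copies of the template receive, in this order: an optional hinge rotation
#' of all residues beyond the pivot (rigid rotation about the y axis through
#' the pivot Calpha), independent Gaussian noise on every atom, and an
#' optional circular permutation, implemented as a renumbering at the cut
#' point with both halves preserved (geometry untouched).  The ground truth
#' maps every template residue across all copies, respecting permutations:
#' residue at position p of a permuted copy corresponds to template ordinal
#' `((p - 1 + cut - 1) mod n) + 1`.
#'
#' @param spec a [family_spec()].
#' @return list with `structures` (list of [structure3d()], names "S1".."Sk"),
#'   `truth` (ground-truth `msta_alignment`, full columns) and `template`.
#' @export
make_family <- function(spec) {
  template <- make_chain(spec$architecture, seed = spec$seed, name = "template")
  n <- template$n
  set.seed(spec$seed + 7L)
  structures <- vector("list", spec$n_copies)
  truth_cols <- matrix(NA_integer_, n, spec$n_copies)
  for (k in seq_len(spec$n_copies)) {
    ca <- template$ca; sc <- template$sc
    if (k %in% spec$hinged_copies) {
      r <- rot_about(c(0, 1, 0), spec$hinge_angle * pi / 180)
      pivot <- ca[spec$hinge_pivot, ]
      mov <- (spec$hinge_pivot + 1L):n
      ca[mov, ] <- sweep(sweep(ca[mov, , drop = FALSE], 2L, pivot) %*% t(r), 2L, pivot, "+")
      sc[mov, ] <- sweep(sweep(sc[mov, , drop = FALSE], 2L, pivot) %*% t(r), 2L, pivot, "+")
    }
    if (spec$noise_sigma > 0) {
      ca <- ca + matrix(stats::rnorm(3 * n, 0, spec$noise_sigma), n, 3L)
      sc <- sc + matrix(stats::rnorm(3 * n, 0, spec$noise_sigma), n, 3L)
    }
    ord <- seq_len(n)
    if (k %in% spec$permuted_copies) ord <- c(spec$cut:n, seq_len(spec$cut - 1L))
    structures[[k]] <- structure3d(name = paste0("S", k), chain = rep("A", n),
                                   resno = seq_len(n), aa = template$aa[ord],
                                   ca = ca[ord, , drop = FALSE], sc = sc[ord, , drop = FALSE])
    truth_cols[ord, k] <- seq_len(n)
  }
  names(structures) <- vapply(structures, function(s) s$name, "")
  truth <- multiple_alignment(names(structures), truth_cols)
  list(structures = structures, truth = truth, template = template)
}

#' Benchmark family: the standard recovery study conditions
#'
#' Five copies of the 60-residue two-domain template with 0.3 A coordinate
#' noise per atom, one circularly permuted copy (cut at the domain boundary)
#' and one copy hinge-rotated by 45 degrees at the linker.
#'
#' @param seed integer seed for the family geometry.
#' @return a [family_spec()].
#' @export
benchmark_family_spec <- function(seed = 101L) {
  family_spec(n_copies = 5L, noise_sigma = 0.3, permuted_copies = 2L,
              cut = 31L, hinged_copies = 3L, hinge_pivot = 30L,
              hinge_angle = 45, seed = seed)
}

#' Desk-scale run configuration
#'
#' The [msta_params()] configuration used for the recovery studies shipped
#' with the package: a reduced evolutionary schedule (4 guide trees,
#' population 8, 40 children per phase, stall 10) and a lighter clique
#' search (8 replicator restarts, 1 for profile merges).  See the methods
#' vignette for the rationale.
#'
#' @param ... overrides passed on to [msta_params()].
#' @return an [msta_params()] list.
#' @export
benchmark_params <- function(...) {
  msta_params(n_trees = 4L, pop_max = 8L, max_evals = 40L, stall = 10L,
              restarts = 8L, profile_restarts = 1L, ...)
}

#' Write a family to a directory
#'
#' Emits one PDB file per copy and the ground-truth alignment in FASTA.
#' @param fam result of [make_family()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_family <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in fam$structures) write_structure(s, file.path(dir, paste0(s$name, ".pdb")))
  write_alignment_fasta(fam$truth, fam$structures, file.path(dir, "truth.fasta"))
  invisible(dir)
}
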