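#' @importFrom stats rnorm runif setNames aggregate
#' @importFrom utils head tail combn write.table
NULL

#' Protein structure as an ordered residue list
#'
#' A `structure3d` object holds, for one or more chains of a protein, the
#' ordered list of residues with their Calpha coordinates and the geometric
#' centers of their side chains.  It is the geometric substrate for local
#' descriptor construction: contacts are evaluated between Calpha atoms and
#' side-chain centers, and five-residue backbone windows (elements) are taken
#' along the residue order, never across a chain break.
#'
#' @param name label for the structure.
#' @param chain character vector of chain identifiers, one per residue.
#' @param resno integer vector of PDB residue numbers.
#' @param icode character vector of insertion codes ("" when absent).
#' @param aa one-letter amino-acid codes.
#' @param ca n x 3 matrix of Calpha coordinates (Angstrom).
#' @param sc n x 3 matrix of side-chain geometric centers; for glycine or a
#'   residue with no resolved side-chain heavy atoms this equals the Calpha
#'   position.
#'
#' @return An object of class `structure3d` with fields `name`, `chain`,
#'   `resno`, `icode`, `aa`, `ca`, `sc` and `n` (residue count).  Residues are
#'   indexed by 1-based ordinal position throughout the package; user-facing
#'   output uses the PDB numbering.
#' @export
structure3d <- function(name, chain, resno, icode = NULL, aa = NULL, ca, sc = NULL) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  stopifnot(ncol(ca) == 3L, length(chain) == n, length(resno) == n)
  if (is.null(icode)) icode <- rep("", n)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(sc)) sc <- ca
  sc <- as.matrix(sc)
  stopifnot(all(is.finite(ca)), all(is.finite(sc)))
  id <- paste(chain, resno, icode, sep = "|")
  if (anyDuplicated(id)) stop("duplicate residue identifiers (chain, resno, icode)")
  obj <- list(name = name, chain = as.character(chain), resno = as.integer(resno),
              icode = as.character(icode), aa = as.character(aa),
              ca = unname(ca), sc = unname(sc), n = n)
  class(obj) <- "structure3d"
  obj
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d '%s': %d residues, chains %s\n",
              x$name, x$n, paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' Geometric center of a side chain
#'
#' Unweighted mean of the side-chain heavy-atom coordinates.  Backbone atoms
#' (N, CA, C, O, OXT) and hydrogens are excluded.  A residue with no
#' side-chain heavy atoms (glycine, or unresolved side chain) falls back to
#' the Calpha position so that every residue stays contact-evaluable.
#'
#' @param elety atom names (PDB `elety`), parallel to `xyz` rows.
#' @param xyz k x 3 coordinate matrix for the residue's atoms.
#' @param ca Calpha coordinate (length-3), the fallback.
#' @return length-3 numeric coordinate.
#' @export
sidechain_center <- function(elety, xyz, ca) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  backbone <- c("N", "CA", "C", "O", "OXT")
  elety <- trimws(elety)
  keep <- !(elety %in% backbone) & !grepl("^[0-9]*[HD]", elety)
  if (!any(keep)) return(as.numeric(ca))
  colMeans(xyz[keep, , drop = FALSE])
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (plus HETATM records of modified amino acids such as
#' MSE) with bio3d, resolves alternate locations to the highest-occupancy
#' conformer (ties broken by file order), keeps the first MODEL only, and
#' skips residues without a Calpha atom (with a warning).  Side-chain centers
#' are computed with [sidechain_center()].
#'
#' @param path PDB file.
#' @param chains optional character vector restricting to these chain ids.
#' @param name label for the structure; defaults to the file base name.
#' @return a [structure3d()] object; residues in file order.
#' @export
read_structure <- function(path, chains = NULL, name = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  if (is.null(name)) name <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  at <- at[(at$type == "ATOM" | aa1 != "X") & aa1 != "X", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no amino-acid residues in selection")
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  rid <- paste(at$chain, at$resno, at$insert, sep = "|")
  # altloc: per (residue, atom name) keep highest occupancy, first on tie
  at$o[is.na(at$o)] <- 1
  key <- paste(rid, trimws(at$elety))
  ord <- order(factor(key, levels = unique(key)), -at$o)
  at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "|"), unique(rid))), , drop = FALSE]

  rid <- paste(at$chain, at$resno, at$insert, sep = "|")
  urid <- unique(rid)
  rows <- split(seq_len(nrow(at)), factor(rid, levels = urid))
  ca_list <- sc_list <- vector("list", length(urid))
  keep <- logical(length(urid))
  meta <- matrix("", length(urid), 4L)
  for (i in seq_along(urid)) {
    ri <- rows[[i]]
    sub <- at[ri, , drop = FALSE]
    ica <- which(trimws(sub$elety) == "CA")
    if (length(ica) == 0L) next
    keep[i] <- TRUE
    ca <- c(sub$x[ica[1L]], sub$y[ica[1L]], sub$z[ica[1L]])
    ca_list[[i]] <- ca
    sc_list[[i]] <- sidechain_center(sub$elety, cbind(sub$x, sub$y, sub$z), ca)
    meta[i, ] <- c(sub$chain[1L], sub$resno[1L], sub$insert[1L],
                   suppressWarnings(bio3d::aa321(sub$resid[1L])))
  }
  if (any(!keep)) warning(sum(!keep), " residue(s) without a CA atom skipped")
  if (!any(keep)) stop("empty structure: no residue with a CA atom")
  structure3d(name = name,
              chain = meta[keep, 1L], resno = as.integer(meta[keep, 2L]),
              icode = meta[keep, 3L], aa = meta[keep, 4L],
              ca = do.call(rbind, ca_list[keep]), sc = do.call(rbind, sc_list[keep]))
}

#' Write a structure to a PDB file
#'
#' Emits one CA atom per residue plus a CB pseudo-atom at the side-chain
#' center whenever it differs from the Calpha position, so that a written
#' structure read back with [read_structure()] reproduces residue identities,
#' order, Calpha coordinates and side-chain centers.
#'
#' @param s a [structure3d()] object.
#' @param path output file.
#' @param xyz optional n x 3 replacement Calpha coordinates (e.g. after
#'   superposition); side-chain centers are displaced by the same offset.
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path, xyz = NULL) {
  ca <- if (is.null(xyz)) s$ca else as.matrix(xyz)
  sc <- if (is.null(xyz)) s$sc else s$sc + (ca - s$ca)
  has_sc <- rowSums((s$sc - s$ca)^2) > 1e-12
  nat <- s$n + sum(has_sc)
  resid3 <- bio3d::aa123(ifelse(s$aa %in% rownames(bio3d::aa.table), s$aa, "A"))
  resid3[s$aa == "G"] <- "GLY"
  ord <- rep(seq_len(s$n), 1L + has_sc)
  elety <- unlist(lapply(seq_len(s$n), function(i) if (has_sc[i]) c("CA", "CB") else "CA"))
  xyzmat <- matrix(0, nat, 3L)
  xyzmat[elety == "CA", ] <- ca
  if (any(has_sc)) xyzmat[elety == "CB", ] <- sc[has_sc, , drop = FALSE]
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyzmat)),
                   resno = s$resno[ord], resid = resid3[ord],
                   chain = s$chain[ord], insert = ifelse(s$icode[ord] == "", NA, s$icode[ord]),
                   elety = elety, eleno = seq_len(nat))
  invisible(path)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R b + t` onto `a`.  Reflections are excluded by the usual determinant
#' correction of the SVD solution.
#'
#' @param a,b equal-size m x 3 coordinate matrices, m >= 3.
#' @return list of class `superposition` with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd` (Angstrom).
#' @export
superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in length")
  if (nrow(a) < 3L) stop("need at least 3 points")
  ma <- colMeans(a); mb <- colMeans(b)
  ac <- sweep(a, 2L, ma); bc <- sweep(b, 2L, mb)
  h <- crossprod(bc, ac)           # 3x3
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ma - as.numeric(r %*% mb)
  fit <- sweep(bc %*% t(r), 2L, ma, "+")
  rmsd <- sqrt(mean(rowSums((fit - a)^2)))
  out <- list(rotation = r, translation = tr, rmsd = rmsd)
  class(out) <- "superposition"
  out
}

#' Apply a superposition to coordinates
#' @param sup a `superposition` from [superpose()].
#' @param x m x 3 coordinates.
#' @return transformed m x 3 coordinates.
#' @export
apply_superposition <- function(sup, x) {
  sweep(as.matrix(x) %*% t(sup$rotation), 2L, sup$translation, "+")
}

#' Angle between two rotations
#'
#' Rotation angle of the relative rotation `r1 %*% t(r2)`, from its trace.
#' Symmetric in its arguments; used to discount alignment regions whose
#' superposition rotations disagree.
#'
#' @param r1,r2 proper 3 x 3 rotation matrices.
#' @return angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(r1, r2) {
  check_rot <- function(r) {
    if (max(abs(crossprod(r) - diag(3))) > 1e-6 || det(r) < 0)
      stop("input is not a proper rotation matrix")
  }
  check_rot(r1); check_rot(r2)
  rel <- r1 %*% t(r2)
  acos(min(1, max(-1, (sum(diag(rel)) - 1) / 2)))
}
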