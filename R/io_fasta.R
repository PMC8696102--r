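# FASTA alignment output and reference-alignment input.  Aligned residues
# are written in upper case, unaligned residues in lower case in their own
# insertion columns, gaps as '-'.  Column order: aligned columns are sorted
# by the residue ordinal of the lowest-index structure present (stable);
# blocks that a circular permutation makes sequentially incompatible are
# thus emitted in master-structure order.  Unaligned residues follow their
# within-structure predecessor.  The layout is deterministic.

#' Write a multiple alignment as FASTA
#'
#' @param ma an `msta_alignment`.
#' @param structures named list of [structure3d()] providing sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_alignment_fasta <- function(ma, structures, path) {
  nm <- ma$struct_names
  ns <- length(nm)
  aligned <- which(rowSums(!is.na(ma$cols)) >= 2L)
  lead <- apply(ma$cols[aligned, , drop = FALSE], 1L, function(r) {
    s <- which(!is.na(r))[1L]; c(s, r[s])
  })
  ord <- if (length(aligned)) aligned[order(lead[1L, ], lead[2L, ])] else integer(0)
  k <- length(ord)
  slots <- vector("list", k + 1L)      # insertion residues after each column
  for (g in seq_len(k + 1L)) slots[[g]] <- matrix(NA_integer_, 0L, 2L)
  for (s in seq_len(ns)) {
    res_aligned <- ma$cols[ord, s]
    n <- structures[[nm[s]]]$n
    in_col <- rep(NA_integer_, n)
    in_col[res_aligned[!is.na(res_aligned)]] <- which(!is.na(res_aligned))
    for (r in seq_len(n)) {
      if (!is.na(in_col[r])) next
      # place after the column holding this structure's predecessor residue
      pred <- if (r > 1L) max(which(!is.na(in_col[seq_len(r - 1L)])), 0L) else 0L
      g <- if (pred > 0L) in_col[pred] + 1L else 1L
      slots[[g]] <- rbind(slots[[g]], c(s, r))
    }
  }
  width <- k + sum(vapply(slots, nrow, 0L))
  ali <- matrix("-", ns, width)
  col <- 0L
  for (g in seq_len(k + 1L)) {
    ins <- slots[[g]]
    if (nrow(ins)) {
      ins <- ins[order(ins[, 1L], ins[, 2L]), , drop = FALSE]
      for (r in seq_len(nrow(ins))) {
        col <- col + 1L
        s <- ins[r, 1L]
        ali[s, col] <- tolower(structures[[nm[s]]]$aa[ins[r, 2L]])
      }
    }
    if (g <= k) {
      col <- col + 1L
      for (s in seq_len(ns)) {
        res <- ma$cols[ord[g], s]
        if (!is.na(res)) ali[s, col] <- toupper(structures[[nm[s]]]$aa[res])
      }
    }
  }
  bio3d::write.fasta(seqs = ali, ids = nm, file = path)
  invisible(path)
}

#' Read a multiple alignment from FASTA
#'
#' Record ids must name the structures.  Every letter consumes the next
#' residue of its structure; columns with at least two upper-case letters
#' become alignment columns (lower-case letters are unaligned insertions, as
#' written by [write_alignment_fasta()]).
#'
#' @param path FASTA alignment.
#' @param structures named list of [structure3d()].
#' @return an `msta_alignment`.
#' @export
read_alignment_fasta <- function(path, structures) {
  fa <- bio3d::read.fasta(path)
  nm <- fa$id
  missing <- setdiff(nm, names(structures))
  if (length(missing)) stop("alignment names not among structures: ",
                            paste(missing, collapse = ", "))
  ali <- fa$ali
  width <- ncol(ali)
  cols <- matrix(NA_integer_, width, length(nm), dimnames = list(NULL, nm))
  upper <- matrix(FALSE, width, length(nm))
  for (s in seq_along(nm)) {
    lets <- ali[s, ]
    isres <- lets != "-" & lets != "."
    cols[isres, s] <- cumsum(isres)[isres]
    upper[, s] <- isres & lets == toupper(lets)
  }
  cols[!upper] <- NA_integer_
  keep <- rowSums(!is.na(cols)) >= 2L
  multiple_alignment(nm, cols[keep, , drop = FALSE])
}

#' Write aligned residue ranges
#'
#' Per structure, the aligned residues are grouped into maximal consecutive
#' blocks and written as `chain:start-end` lists (PDB numbering), one
#' tab-separated line per structure.
#'
#' @param ma an `msta_alignment`.
#' @param structures named list of [structure3d()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_residue_ranges <- function(ma, structures, path) {
  aligned <- rowSums(!is.na(ma$cols)) >= 2L
  lines <- vapply(seq_along(ma$struct_names), function(s) {
    st <- structures[[ma$struct_names[s]]]
    res <- sort(ma$cols[aligned, s])
    res <- res[!is.na(res)]
    if (length(res) == 0L) return(paste0(ma$struct_names[s], "\t"))
    grp <- cumsum(c(TRUE, diff(res) != 1L | st$chain[res[-1L]] != st$chain[res[-length(res)]]))
    blocks <- vapply(split(res, grp), function(b) {
      sprintf("%s:%d-%d", st$chain[b[1L]], st$resno[b[1L]], st$resno[b[length(b)]])
    }, "")
    paste0(ma$struct_names[s], "\t", paste(blocks, collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
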