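# Alignment quality relative to a reference: Q_C, the fraction of reference
# columns reproduced in full, and Q_P, the fraction of reference residue
# pairs reproduced; plus Dolan-More performance profiles for aggregating
# accuracies of several methods over a benchmark.

#' Fraction of correctly aligned columns (Q_C)
#'
#' A reference column (which must contain every structure) counts as correct
#' only when its complete structure-to-residue mapping appears inside a
#' single column of the test alignment.  The stricter of the two measures:
#' partial credit belongs to [qp()].
#'
#' @param test,ref `msta_alignment`s over the same structure set; `ref`
#'   columns must be full.
#' @return percentage in `[0, 100]`.
#' @export
qc <- function(test, ref) {
  if (!setequal(test$struct_names, ref$struct_names))
    stop("test and reference alignments are over different structure sets")
  if (nrow(ref$cols) == 0L) return(NA_real_)
  if (any(is.na(ref$cols))) stop("reference columns must contain every structure")
  ord <- match(ref$struct_names, test$struct_names)
  tkey <- apply(test$cols[, ord, drop = FALSE], 1L, paste, collapse = ",")
  full <- rowSums(!is.na(test$cols)) == length(test$struct_names)
  rkey <- apply(ref$cols, 1L, paste, collapse = ",")
  100 * sum(rkey %in% tkey[full]) / nrow(ref$cols)
}

#' Fraction of correctly aligned residue pairs (Q_P)
#'
#' The lenient measure: the share of residue pairs induced by the reference
#' columns that the test alignment also aligns.
#'
#' @param test,ref `msta_alignment`s over the same structure set.
#' @return percentage in `[0, 100]`.
#' @export
qp <- function(test, ref) {
  if (!setequal(test$struct_names, ref$struct_names))
    stop("test and reference alignments are over different structure sets")
  rk <- pair_keys(ref)
  if (length(rk) == 0L) return(NA_real_)
  100 * length(intersect(rk, pair_keys(test))) / length(rk)
}

#' Per-case accuracy ratios
#'
#' For each benchmark case, every method's accuracy is divided by the best
#' accuracy any method achieved on that case.  Failed runs count as accuracy
#' 0; an all-zero case yields ratio 0 for everyone, with a warning.
#'
#' @param records data frame with columns `method`, `case`, `accuracy` and
#'   optionally `failed` (logical).
#' @return the input with an added `ratio` column.
#' @export
accuracy_ratio <- function(records) {
  acc <- records$accuracy
  if (!is.null(records$failed)) acc[records$failed] <- 0
  best <- stats::ave(acc, records$case, FUN = max)
  ratio <- ifelse(best > 0, acc / best, 0)
  if (any(best <= 0)) warning("case(s) where every method scored 0: ratios set to 0")
  records$ratio <- ratio
  records
}

#' Dolan-More performance profiles
#'
#' For each method, `rho(alpha)` is the fraction of cases whose accuracy
#' ratio is at least `alpha`: the probability that the method performs no
#' worse than the per-case best by the given factor.  Profiles are
#' non-increasing step functions with `rho(0)` the fraction of non-failed
#' cases.
#'
#' @param records output of [accuracy_ratio()].
#' @param alphas grid of ratio thresholds (default 0..1 step 0.01).
#' @return data frame (method, alpha, rho) plus attribute `auc`, the
#'   trapezoid area under each curve.
#' @export
performance_profile <- function(records, alphas = seq(0, 1, by = 0.01)) {
  ok <- if (is.null(records$failed)) rep(TRUE, nrow(records)) else !records$failed
  records$.ok <- ok
  out <- do.call(rbind, lapply(split(records, records$method), function(sub) {
    rho <- vapply(alphas, function(a) mean(sub$ratio >= a & sub$.ok), 0)
    data.frame(method = sub$method[1L], alpha = alphas, rho = rho)
  }))
  rownames(out) <- NULL
  auc <- vapply(split(out, out$method), function(sub) {
    sum(diff(sub$alpha) * (head(sub$rho, -1L) + tail(sub$rho, -1L)) / 2)
  }, 0)
  attr(out, "auc") <- auc
  out
}
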