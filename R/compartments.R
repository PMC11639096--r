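## A/B compartment annotation: eigenvectors 1-3 of the Pearson correlation
## matrix, selected and sign-oriented by bp-Jaccard against a reference
## active-chromatin track, so that positive values mark type A.

#' Leading eigenvectors of the Pearson matrix
#'
#' Principal components of the correlation matrix: columns are centered and
#' the top right singular vectors taken, ordered by descending singular
#' value.  Each eigenvector has unit norm over unmasked bins; masked bins
#' carry `NA`.
#'
#' @param pearson Correlation matrix from [pearson_matrix()].
#' @param k Number of components (default 3).
#' @return List with `vectors` (`n_bins x k`, `NA` on masked bins) and
#'   `values` (variance explained per component).
#' @export
top_eigenvectors <- function(pearson, k = 3L) {
  n <- nrow(pearson)
  ok <- which(rowSums(!is.na(pearson)) > 0)
  if (length(ok) < k) stop("k exceeds unmasked rank")
  X <- pearson[ok, ok, drop = FALSE]
  X[is.na(X)] <- 0
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = k)
  V <- matrix(NA_real_, n, k)
  V[ok, ] <- sv$v[, seq_len(k), drop = FALSE]
  list(vectors = V, values = sv$d[seq_len(k)]^2 / (length(ok) - 1))
}

#' Basepair Jaccard similarity of two interval sets
#'
#' `(bp of intersection) / (bp of union)`; 0 when the union is empty.
#' Overlapping intervals within one set are merged first (with a warning,
#' mirroring the behavior of interval tooling on unmerged input).
#'
#' @param a,b Data frames with `start`, `end` (0-based half-open) on one
#'   chromosome.
#' @return Numeric scalar in [0, 1].
#' @export
interval_jaccard <- function(a, b) {
  ra <- .merged_iranges(a, "setA")
  rb <- .merged_iranges(b, "setB")
  inter <- sum(IRanges::width(IRanges::intersect(ra, rb)))
  uni <- sum(IRanges::width(IRanges::union(ra, rb)))
  if (uni == 0) 0 else inter / uni
}

.merged_iranges <- function(df, label) {
  if (!nrow(df)) return(IRanges::IRanges())
  r <- IRanges::IRanges(start = df$start + 1L, end = df$end)  # to 1-based
  m <- IRanges::reduce(r)
  if (sum(IRanges::width(m)) < sum(IRanges::width(r)))
    warning(sprintf("overlapping intervals in %s merged", label))
  m
}

#' Select and orient the compartment eigenvector
#'
#' For each of the first `k` eigenvectors and each sign, bins where the
#' signed vector exceeds `threshold` are merged into intervals and
#' Jaccard-scored against the reference track; the (eigenvector, sign) pair
#' with the highest Jaccard wins (ties: lower eigenvector index, then
#' positive sign).  The returned track is the signed winner, so positive
#' values mark type A compartmentalization.
#'
#' @param eigs Result of [top_eigenvectors()].
#' @param reference Data frame `chrom`/`start`/`end` of active intervals.
#' @param chrom,bin_size Coordinates of the bins.
#' @param threshold Sign-split threshold (default 0).
#' @return List with `track` (oriented per-bin values), `selected`
#'   (eigenvector index), `sign`, `jaccard` (3 x 2 matrix of scores), and
#'   `a_intervals` / `b_intervals` data frames.
#' @export
select_and_orient <- function(eigs, reference, chrom, bin_size,
                              threshold = 0) {
  V <- eigs$vectors
  k <- ncol(V)
  J <- matrix(0, k, 2, dimnames = list(paste0("eig", seq_len(k)),
                                       c("pos", "neg")))
  for (e in seq_len(k)) for (si in 1:2) {
    s <- c(1, -1)[si]
    ints <- bins_to_intervals(s * V[, e] > threshold, chrom, bin_size)
    J[e, si] <- interval_jaccard(ints, reference)
  }
  if (all(J == 0)) stop("reference uninformative: all six Jaccards are zero")
  best <- which(J == max(J), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  s <- c(1, -1)[best[2]]
  track <- s * V[, best[1]]
  list(track = track, selected = unname(best[1]), sign = s, jaccard = J,
       a_intervals = bins_to_intervals(track > threshold, chrom, bin_size),
       b_intervals = bins_to_intervals(track <= threshold & !is.na(track),
                                       chrom, bin_size))
}

#' Full compartment call from a raw contact matrix
#'
#' Balance, O/E, Pearson, eigenvectors, then select/orient against the
#' reference.
#'
#' @param cm A [contact_matrix()].
#' @param reference Reference active intervals (data frame).
#' @param ... Passed to [balance()].
#' @return As [select_and_orient()].
#' @export
call_compartments <- function(cm, reference, ...) {
  bal <- balance(cm, ...)
  oe <- observed_over_expected(bal)
  P <- pearson_matrix(oe)
  eig <- top_eigenvectors(P, 3L)
  select_and_orient(eig, reference, cm$chrom, cm$bin_size)
}
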