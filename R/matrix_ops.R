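## Normalization and expected models shared by all feature extractors.
## Balancing is iterative proportional fitting to equal row sums -- the same
## fixed-point family as the scaling normalizations used on Hi-C maps, fully
## specified and desk-scale.

#' Balance a contact matrix by iterative proportional fitting
#'
#' Masks bins with fewer than `min_nnz` nonzero raw entries (and all-zero
#' bins), then iterates `b_i <- b_i / sqrt(rowsum_i / target)` until all
#' unmasked row sums agree with their mean to relative tolerance `tol`.
#' The balanced matrix satisfies `balanced(i,j) = raw(i,j) * b_i * b_j`.
#'
#' @param cm A [contact_matrix()] or a dense symmetric non-negative matrix.
#' @param tol Relative row-sum tolerance.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   last residual.
#' @param min_nnz Sparse-bin mask threshold (nonzero entries per row).
#' @return Object of class `balanced_matrix`: list with `matrix` (dense,
#'   `NA` rows/cols on masked bins), `bias`, `mask` (logical, TRUE =
#'   masked), `bin_size`, `chrom`.
#' @export
balance <- function(cm, tol = 1e-8, max_iter = 1000L, min_nnz = 10L) {
  if (inherits(cm, "contact_matrix")) {
    M <- as_dense(cm); chrom <- cm$chrom; bin_size <- cm$bin_size
  } else {
    M <- cm; chrom <- NA_character_; bin_size <- NA_integer_
    stopifnot(nrow(M) == ncol(M))
    if (any(M < 0)) stop("matrix must be non-negative")
  }
  n <- nrow(M)
  nnz <- rowSums(M != 0)
  mask <- nnz < min_nnz | rowSums(M) == 0
  b <- rep(1, n)
  b[mask] <- NA_real_
  act <- which(!mask)
  if (!length(act)) stop("all bins masked")
  A <- M[act, act, drop = FALSE]
  bb <- rep(1, length(act))
  resid <- Inf
  for (it in seq_len(max_iter)) {
    rs <- as.numeric((A %*% bb) * bb)
    target <- mean(rs)
    resid <- max(abs(rs - target)) / target
    if (resid <= tol) break
    bb <- bb / sqrt(rs / target)
  }
  if (resid > tol)
    stop(sprintf("balancing did not converge in %d iterations (residual %.3g)",
                 max_iter, resid))
  b[act] <- bb
  Mb <- M * outer(b, b)
  Mb[mask, ] <- NA_real_
  Mb[, mask] <- NA_real_
  structure(list(matrix = Mb, bias = b, mask = mask, chrom = chrom,
                 bin_size = bin_size, n_bins = n),
            class = "balanced_matrix")
}

#' @export
print.balanced_matrix <- function(x, ...) {
  cat(sprintf("balanced_matrix: %d bins (%d masked)\n", x$n_bins,
              sum(x$mask)))
  invisible(x)
}

#' Mean balanced contact by bin distance
#'
#' @param bal A [balance()] result.
#' @return Object of class `expected_profile`: numeric `e` of length
#'   `n_bins` where `e[d+1]` is the mean over unmasked pairs at distance
#'   `d`; distances with no observations are `NA`.
#' @export
expected_by_distance <- function(bal) {
  M <- bal$matrix
  n <- nrow(M)
  e <- rep(NA_real_, n)
  for (d in 0:(n - 1L)) {
    v <- M[cbind(1:(n - d), (1 + d):n)]
    v <- v[!is.na(v)]
    if (length(v)) e[d + 1L] <- mean(v)
  }
  structure(list(e = e, n_bins = n), class = "expected_profile")
}

#' Observed-over-expected transform
#'
#' @param bal A [balance()] result.
#' @param expected An [expected_by_distance()] profile.
#' @param mode `"ratio"` for O/E (undefined where `e(d) == 0`), or
#'   `"difference"` for O-E.
#' @return Dense matrix; masked bins and undefined entries are `NA`.
#' @export
observed_over_expected <- function(bal, expected = expected_by_distance(bal),
                                   mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  n <- bal$n_bins
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(expected$e[D + 1L], n, n)
  if (mode == "ratio") {
    out <- bal$matrix / E
    out[!is.na(E) & E == 0] <- NA_real_
  } else {
    out <- bal$matrix - E
  }
  out
}

#' Pearson correlation matrix of O/E rows
#'
#' `r(i, j)` is the Pearson correlation of rows i and j of the O/E matrix
#' over unmasked columns; rows with zero variance are masked; the diagonal
#' is 1.
#'
#' @param oe O/E ratio matrix (with `NA` on masked bins).
#' @return Dense correlation matrix with `NA` rows/cols for masked or
#'   zero-variance bins.
#' @export
pearson_matrix <- function(oe) {
  n <- nrow(oe)
  ok <- which(colSums(!is.na(oe)) > 0)
  X <- oe[ok, ok, drop = FALSE]
  v <- apply(X, 1, var, na.rm = TRUE)
  keep <- ok[is.finite(v) & v > 0]
  R <- matrix(NA_real_, n, n)
  if (length(keep) >= 2) {
    sub <- oe[keep, keep, drop = FALSE]
    R[keep, keep] <- suppressWarnings(cor(t(sub),
                                          use = "pairwise.complete.obs"))
    R[cbind(keep, keep)] <- 1
  }
  R
}

#' Sum counts into coarser bins
#'
#' @param cm A [contact_matrix()].
#' @param factor Integer rebinning factor (new bin size = `factor *
#'   bin_size`).
#' @return A [contact_matrix()] at the coarser resolution.
#' @export
rebin_contacts <- function(cm, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(cm)
  n2 <- as.integer(ceiling(cm$n_bins / factor))
  df <- cm$counts
  contact_matrix(cm$chrom, cm$bin_size * factor, n2,
                 i = df$i %/% factor, j = df$j %/% factor, count = df$count)
}
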