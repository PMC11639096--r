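## Contact-domain (TAD) calling via an arrowhead-style transform and corner
## score, with cross-cohort union re-scoring.  The corner score is a fully
## specified stand-in for Arrowhead's block score: it exercises the same
## transform and recovers planted domains, but is not bit-compatible with
## the original dynamic program.

#' Arrowhead transform at one pixel
#'
#' `A(i, i+d) = (M(i, i-d) - M(i, i+d)) / (M(i, i-d) + M(i, i+d))` on the
#' balanced matrix: positive when contacts upstream of `i` at distance `d`
#' exceed those downstream.  Returns `NA` (not an error) when either pixel
#' is out of range or masked, and 0 when both pixels are 0.
#'
#' @param bal A [balance()] result.
#' @param i Bin index (1-based).
#' @param d Distance in bins (`d >= 1`).
#' @return Value in `[-1, 1]` or `NA`.
#' @export
arrowhead_transform <- function(bal, i, d) {
  A <- arrowhead_matrix_cpp(bal$matrix, as.integer(d))
  A[i, d + 1L]
}

#' Corner score of a candidate domain
#'
#' For candidate `[a, b]` (1-based inclusive bins), the mean arrowhead value
#' over pixels whose mirror lies inside the domain but whose forward pixel
#' crosses `b`, minus the mean over pixels inside the domain whose mirror
#' crosses `a`.  A true domain scores high because contacts inside the
#' triangle exceed those crossing its edges.  Undefined pixels are skipped;
#' the score is `NA` when either pixel set is empty.
#'
#' @param bal A [balance()] result.
#' @param a,b Domain bounds, 1-based inclusive bins, `a < b`.
#' @return Score in `[-2, 2]` or `NA`.
#' @export
corner_score <- function(bal, a, b) {
  stopifnot(a < b)
  corner_score_cpp(bal$matrix, a - 1L, b - 1L)
}

#' Call contact domains on one balanced matrix
#'
#' Scores all candidates with `L_min <= b - a <= L_max` by [corner_score()],
#' keeps `S >= theta`, then selects greedily by descending score (ties:
#' smaller `(a, b)` lexicographically).  A survivor may be nested inside an
#' accepted domain but may not partially overlap one.
#'
#' @param bal A [balance()] result.
#' @param theta Score threshold (default 0.2).
#' @param L_min,L_max Candidate length bounds in bins.
#' @return Data frame with `a`, `b` (1-based inclusive bins), `start`, `end`
#'   (bp, half-open), `score`, `resolution` (bp).
#' @export
call_domains <- function(bal, theta = 0.2, L_min = 3L, L_max = 100L) {
  n <- bal$n_bins
  sc <- corner_scan_cpp(bal$matrix, as.integer(L_min),
                        as.integer(min(L_max, n - 1L)))
  keep <- which(!is.na(sc[, 3]) & sc[, 3] >= theta)
  empty <- data.frame(a = integer(), b = integer(), start = integer(),
                      end = integer(), score = numeric(),
                      resolution = integer())
  if (!length(keep)) return(empty)
  a <- as.integer(sc[keep, 1]) + 1L
  b <- as.integer(sc[keep, 2]) + 1L
  S <- sc[keep, 3]
  ord <- order(-S, a, b)
  a <- a[ord]; b <- b[ord]; S <- S[ord]
  acc_a <- integer(); acc_b <- integer(); acc_s <- numeric()
  for (q in seq_along(a)) {
    if (length(acc_a)) {
      ov <- acc_a <= b[q] & a[q] <= acc_b
      nested <- (acc_a >= a[q] & acc_b <= b[q]) | (a[q] >= acc_a & b[q] <= acc_b)
      if (any(ov & !nested)) next
      if (any(acc_a == a[q] & acc_b == b[q])) next
    }
    acc_a <- c(acc_a, a[q]); acc_b <- c(acc_b, b[q]); acc_s <- c(acc_s, S[q])
  }
  ord2 <- order(acc_a, acc_b)
  data.frame(a = acc_a[ord2], b = acc_b[ord2],
             start = (acc_a[ord2] - 1L) * bal$bin_size,
             end = acc_b[ord2] * bal$bin_size,
             score = acc_s[ord2],
             resolution = bal$bin_size)
}

#' Call domains at several resolutions and merge
#'
#' Rebins the raw matrix to each requested resolution (which must be an
#' integer multiple of the native bin size), balances, calls domains, and
#' merges the per-resolution calls by bp coordinates, keeping the higher
#' score among duplicates.
#'
#' @param cm A [contact_matrix()] of raw counts.
#' @param resolutions Bin sizes (bp) to call at.
#' @param theta,L_min,L_max Passed to [call_domains()].
#' @param ... Passed to [balance()].
#' @return Data frame as [call_domains()], bp-sorted.
#' @export
call_domains_multi <- function(cm, resolutions = c(5e4, 1e5), theta = 0.2,
                               L_min = 3L, L_max = 100L, ...) {
  calls <- list()
  for (res in resolutions) {
    if (res %% cm$bin_size != 0)
      stop("resolution must be a multiple of the native bin size")
    bal <- balance(rebin_contacts(cm, res %/% cm$bin_size), ...)
    calls[[as.character(res)]] <- call_domains(bal, theta, L_min, L_max)
  }
  all <- do.call(rbind, calls)
  if (!nrow(all)) return(all)
  all <- all[order(all$start, all$end, -all$score), ]
  all[!duplicated(all[, c("start", "end")]), ]
}

#' Union of domain calls across samples
#'
#' Deduplicates pooled calls by `(start, end, resolution)` and records which
#' samples contributed each entry.
#'
#' @param calls Named list of per-sample [call_domains()] data frames.
#' @return Data frame of unique intervals with a `samples` provenance
#'   column.
#' @export
domain_union <- function(calls) {
  pooled <- do.call(rbind, lapply(names(calls), function(id) {
    df <- calls[[id]]
    if (!nrow(df)) return(NULL)
    df$sample <- id
    df
  }))
  if (is.null(pooled))
    return(data.frame(a = integer(), b = integer(), start = integer(),
                      end = integer(), resolution = integer(),
                      samples = character()))
  key <- paste(pooled$start, pooled$end, pooled$resolution)
  prov <- tapply(pooled$sample, key, function(s)
    paste(sort(unique(s)), collapse = ","))
  uniq <- pooled[!duplicated(key), c("a", "b", "start", "end", "resolution")]
  uniq$samples <- as.character(prov[paste(uniq$start, uniq$end,
                                          uniq$resolution)])
  uniq[order(uniq$start, uniq$end), ]
}

#' Re-score one sample at the domain union
#'
#' Evaluates [corner_score()] at every union interval for this sample --
#' the feature-list/control-list style union re-scoring that turns
#' per-sample calls into a common cohort feature space.
#'
#' @param bal A [balance()] result at the union's resolution.
#' @param union Data frame with `a`, `b` columns (1-based bins).
#' @return Numeric score per union entry (`NA` where undefined).
#' @export
rescore_domains <- function(bal, union) {
  if (!nrow(union)) return(numeric(0))
  vapply(seq_len(nrow(union)), function(r) {
    a <- union$a[r]; b <- union$b[r]
    if (b > bal$n_bins || a < 1) return(NA_real_)
    corner_score_cpp(bal$matrix, a - 1L, b - 1L)
  }, numeric(1))
}
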