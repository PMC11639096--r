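## Focal loop calling: each candidate pixel is tested against four local
## expected models (donut ring, lower-left quadrant, horizontal and
## vertical stripes) under a Poisson upper-tail test, with BH correction
## within log-spaced distance strata per neighborhood.  Balanced counts are
## treated directly as Poisson rates (consistent with the Poisson contact
## simulator); enrichment thresholds follow donut-filter convention.

#' Local expected models at candidate pixels
#'
#' For each neighborhood N (excluding the inner p-box),
#' `lambda_N = e(|i-j|) * sum_N(M) / sum_N(e)`, with masked pixels excluded
#' from both sums.
#'
#' @param bal A [balance()] result.
#' @param expected An [expected_by_distance()] profile.
#' @param i,j Equal-length 1-based bin indices with `j > i`.
#' @param p Inner exclusion half-width (default 2).
#' @param w Neighborhood half-width (default 5).
#' @return Data frame `i`, `j`, `obs`, `lam_donut`, `lam_ll`, `lam_h`,
#'   `lam_v` (`NA` where a neighborhood is fully masked).
#' @export
local_expecteds <- function(bal, expected, i, j, p = 2L, w = 5L) {
  stopifnot(length(i) == length(j), all(j - i > w))
  st <- loop_stats_cpp(bal$matrix, expected$e, as.integer(i - 1L),
                       as.integer(j - 1L), as.integer(p), as.integer(w))
  data.frame(i = i, j = j, obs = st[, 1], lam_donut = st[, 2],
             lam_ll = st[, 3], lam_h = st[, 4], lam_v = st[, 5])
}

#' Poisson upper-tail loop test
#'
#' `p = P(X >= round(observed))` for `X ~ Poisson(lambda)`.
#'
#' @param observed Observed balanced count(s).
#' @param lambda Expected rate(s); `lambda <= 0` gives `NA`.
#' @return P-value(s).
#' @export
loop_test <- function(observed, lambda) {
  k <- round(observed)
  p <- ppois(k - 1, lambda, lower.tail = FALSE)
  p[!is.finite(lambda) | lambda <= 0] <- NA_real_
  p
}

#' Call loops on one balanced matrix
#'
#' Tests all pixels with `d_min <= j - i <= d_max`; BH-adjusts within
#' log2-spaced distance strata separately per neighborhood; keeps pixels
#' with all four `q <= fdr` and `observed >= enrich_N * lambda_N`; merges
#' 8-connected surviving pixels into one call at the maximum-observed
#' pixel.
#'
#' @param bal A [balance()] result.
#' @param expected An [expected_by_distance()] profile.
#' @param p,w Neighborhood geometry (defaults (2, 5); use (1, 3) at coarse
#'   bins).
#' @param fdr BH threshold per neighborhood (default 0.1).
#' @param enrich Enrichment thresholds for (donut, lower-left, horizontal,
#'   vertical).
#' @param d_min,d_max Candidate distance range in bins.
#' @return Data frame with anchor bins/bp, observed value, the four
#'   lambdas, q-values, cluster size, and `resolution`.
#' @export
call_loops <- function(bal, expected = expected_by_distance(bal),
                       p = 2L, w = 5L, fdr = 0.1,
                       enrich = c(1.75, 1.75, 1.5, 1.5),
                       d_min = w + 1L, d_max = min(bal$n_bins - 1L, 200L)) {
  n <- bal$n_bins
  cand <- do.call(rbind, lapply(d_min:d_max, function(d) {
    ii <- seq_len(n - d)
    cbind(ii, ii + d)
  }))
  st <- local_expecteds(bal, expected, cand[, 1], cand[, 2], p = p, w = w)
  lam <- as.matrix(st[, c("lam_donut", "lam_ll", "lam_h", "lam_v")])
  ok <- !is.na(st$obs) & rowSums(is.na(lam)) == 0
  st <- st[ok, , drop = FALSE]; lam <- lam[ok, , drop = FALSE]
  empty <- data.frame(i = integer(), j = integer(), start1 = integer(),
                      end1 = integer(), start2 = integer(), end2 = integer(),
                      obs = numeric(), lam_donut = numeric(),
                      lam_ll = numeric(), lam_h = numeric(),
                      lam_v = numeric(), q_donut = numeric(),
                      q_ll = numeric(), q_h = numeric(), q_v = numeric(),
                      cluster_size = integer(), resolution = integer())
  if (!nrow(st)) return(empty)
  stratum <- floor(log2(st$j - st$i))
  q <- matrix(NA_real_, nrow(st), 4)
  for (k in 1:4) {
    pv <- loop_test(st$obs, lam[, k])
    for (s in unique(stratum)) {
      sel <- stratum == s & !is.na(pv)
      if (any(sel)) q[sel, k] <- p.adjust(pv[sel], method = "BH")
    }
  }
  enr_ok <- st$obs >= lam[, 1] * enrich[1] & st$obs >= lam[, 2] * enrich[2] &
    st$obs >= lam[, 3] * enrich[3] & st$obs >= lam[, 4] * enrich[4]
  pass <- rowSums(q <= fdr, na.rm = TRUE) == 4 & rowSums(is.na(q)) == 0 &
    enr_ok
  hits <- which(pass)
  if (!length(hits)) return(empty)
  hi <- st$i[hits]; hj <- st$j[hits]
  comp <- .connected_components(hi, hj)
  out <- do.call(rbind, lapply(split(seq_along(hits), comp), function(members) {
    hh <- hits[members]
    best <- hh[which.max(st$obs[hh])]
    r <- match(best, hits)
    data.frame(i = st$i[best], j = st$j[best],
               obs = st$obs[best],
               lam_donut = lam[best, 1], lam_ll = lam[best, 2],
               lam_h = lam[best, 3], lam_v = lam[best, 4],
               q_donut = q[best, 1], q_ll = q[best, 2],
               q_h = q[best, 3], q_v = q[best, 4],
               cluster_size = length(members))
  }))
  out$start1 <- (out$i - 1L) * bal$bin_size
  out$end1 <- out$i * bal$bin_size
  out$start2 <- (out$j - 1L) * bal$bin_size
  out$end2 <- out$j * bal$bin_size
  out$resolution <- bal$bin_size
  rownames(out) <- NULL
  out[order(out$i, out$j), ]
}

## 8-connected components over pixel coordinates (simple BFS; call sets are
## small after filtering)
.connected_components <- function(i, j) {
  m <- length(i)
  comp <- rep(0L, m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      q0 <- queue[1]; queue <- queue[-1]
      nb <- which(comp == 0L & abs(i - i[q0]) <= 1L & abs(j - j[q0]) <= 1L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Call loops at several resolutions and merge
#'
#' Calls per resolution, then merges by anchor-bp overlap keeping the
#' finer-resolution call.
#'
#' @param cm A [contact_matrix()] of raw counts.
#' @param resolutions Bin sizes (bp), finest first.
#' @param geometry Named list mapping resolution to `c(p, w)`; defaults to
#'   (2, 5) at the finest and (1, 3) elsewhere.
#' @param ... Passed to [call_loops()].
#' @return Data frame as [call_loops()].
#' @export
call_loops_multi <- function(cm, resolutions = c(cm$bin_size),
                             geometry = NULL, ...) {
  resolutions <- sort(resolutions)
  calls <- list()
  for (ri in seq_along(resolutions)) {
    res <- resolutions[ri]
    if (res %% cm$bin_size != 0)
      stop("resolution must be a multiple of the native bin size")
    bal <- balance(rebin_contacts(cm, res %/% cm$bin_size))
    pw <- if (!is.null(geometry) && !is.null(geometry[[as.character(res)]]))
      geometry[[as.character(res)]]
    else if (ri == 1L) c(2L, 5L) else c(1L, 3L)
    calls[[ri]] <- call_loops(bal, p = pw[1], w = pw[2], ...)
  }
  merged <- calls[[1]]
  if (length(calls) > 1) {
    for (ri in 2:length(calls)) {
      co <- calls[[ri]]
      if (!nrow(co)) next
      if (nrow(merged)) {
        dup <- vapply(seq_len(nrow(co)), function(r) {
          any(co$start1[r] < merged$end1 & merged$start1 < co$end1 &
                co$start2[r] < merged$end2 & merged$start2 < co$end2)
        }, logical(1))
        co <- co[!dup, , drop = FALSE]
      }
      merged <- rbind(merged, co)
    }
  }
  merged[order(merged$start1, merged$start2), ]
}

#' Union of loop calls across samples
#'
#' @param calls Named list of per-sample [call_loops()] data frames at a
#'   common resolution.
#' @return Data frame of unique `(i, j)` pixels with provenance.
#' @export
loop_union <- function(calls) {
  pooled <- do.call(rbind, lapply(names(calls), function(id) {
    df <- calls[[id]]
    if (!nrow(df)) return(NULL)
    data.frame(i = df$i, j = df$j, resolution = df$resolution, sample = id)
  }))
  if (is.null(pooled))
    return(data.frame(i = integer(), j = integer(), resolution = integer(),
                      samples = character()))
  key <- paste(pooled$i, pooled$j, pooled$resolution)
  prov <- tapply(pooled$sample, key, function(s)
    paste(sort(unique(s)), collapse = ","))
  uniq <- pooled[!duplicated(key), c("i", "j", "resolution")]
  uniq$samples <- as.character(prov[paste(uniq$i, uniq$j, uniq$resolution)])
  uniq[order(uniq$i, uniq$j), ]
}

#' Re-score one sample at the loop union
#'
#' Reports observed, the four lambdas, and the donut observed/expected
#' ratio at every union pixel, with no thresholding -- the
#' specified-loop-list style re-scoring.
#'
#' @param bal A [balance()] result.
#' @param expected An [expected_by_distance()] profile.
#' @param union A [loop_union()] data frame.
#' @param p,w Neighborhood geometry.
#' @return Data frame with per-pixel statistics and `oe_donut`.
#' @export
rescore_loops <- function(bal, expected, union, p = 2L, w = 5L) {
  if (!nrow(union))
    return(data.frame(i = integer(), j = integer(), obs = numeric(),
                      lam_donut = numeric(), lam_ll = numeric(),
                      lam_h = numeric(), lam_v = numeric(),
                      oe_donut = numeric()))
  st <- local_expecteds(bal, expected, union$i, union$j, p = p, w = w)
  st$oe_donut <- st$obs / st$lam_donut
  st
}

#' Promoter annotation of loop anchors
#'
#' An anchor is promoter-anchored when its bp interval overlaps any
#' promoter by at least 1 bp.
#'
#' @param loops A loop-call data frame with `start1`/`end1`/`start2`/`end2`.
#' @param promoters Data frame `chrom`/`start`/`end` of promoter intervals.
#' @return List with `fraction` (promoter-anchored anchors over all
#'   anchors; `NA` for an empty loop list) and `anchors` (per-anchor data
#'   frame with a logical `in_promoter`).
#' @export
annotate_anchors <- function(loops, promoters) {
  if (!nrow(loops)) return(list(fraction = NA_real_, anchors = NULL))
  anchors <- data.frame(
    loop = rep(seq_len(nrow(loops)), 2L),
    side = rep(c(1L, 2L), each = nrow(loops)),
    start = c(loops$start1, loops$start2),
    end = c(loops$end1, loops$end2))
  ra <- IRanges::IRanges(start = anchors$start + 1L, end = anchors$end)
  rp <- IRanges::reduce(IRanges::IRanges(start = promoters$start + 1L,
                                         end = promoters$end))
  anchors$in_promoter <- IRanges::overlapsAny(ra, rp)
  list(fraction = mean(anchors$in_promoter), anchors = anchors)
}
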