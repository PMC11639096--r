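## Structural-variant inference from contact maps: per-bin coverage and
## copy-number segments, and a block-enrichment ("butterfly") scanner for
## translocation/inversion/duplication-like signatures.  The detector is an
## explicit operationalization of the visual pattern: rectangular O/E
## enrichment off the diagonal with a sharp corner at the breakpoints.

#' Per-bin coverage and copy-number segments
#'
#' Coverage is the raw row sum, normalized by the per-bin cohort median
#' when a cohort is supplied and by the sample median otherwise.  Segments
#' are maximal runs of at least `min_run` bins with normalized coverage
#' above `1 + delta` (gain) or below `1 - delta` (loss); normalized
#' coverage below 0.1 marks a deep deletion.
#'
#' @param cm A [contact_matrix()].
#' @param cohort Optional list of cohort [contact_matrix()] objects used
#'   for the per-bin reference median.
#' @param delta Gain/loss threshold (default 0.5).
#' @param min_run Minimum segment length in bins (default 5).
#' @return List with `coverage` (raw), `normalized`, and `segments` (data
#'   frame `start_bin`, `end_bin`, `type`, `mean_cov`).
#' @export
coverage_track <- function(cm, cohort = NULL, delta = 0.5, min_run = 5L) {
  cov <- rowSums(as_dense(cm))
  if (!is.null(cohort) && length(cohort) >= 2) {
    ref <- apply(vapply(cohort, function(s) rowSums(as_dense(s)),
                        numeric(cm$n_bins)), 1, median)
    ref[ref == 0] <- NA_real_
    norm <- cov / ref
  } else {
    norm <- cov / median(cov[cov > 0])
  }
  lab <- ifelse(is.na(norm), "na",
                ifelse(norm < 0.1, "deep_deletion",
                       ifelse(norm < 1 - delta, "loss",
                              ifelse(norm > 1 + delta, "gain", "neutral"))))
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("gain", "loss", "deep_deletion") &
    r$lengths >= min_run
  segs <- data.frame(start_bin = starts[keep], end_bin = ends[keep],
                     type = r$values[keep])
  segs$mean_cov <- vapply(seq_len(nrow(segs)), function(s)
    mean(norm[segs$start_bin[s]:segs$end_bin[s]], na.rm = TRUE), numeric(1))
  list(coverage = cov, normalized = norm, segments = segs)
}

## mean of O/E over each k x k window via summed-area tables, NA-aware;
## entry (r, c) of the result is the window whose top-left pixel is (r, c)
.window_means <- function(X, k) {
  nr <- nrow(X); nc <- ncol(X)
  if (nr < k || nc < k) return(NULL)
  X0 <- X; X0[is.na(X0)] <- 0
  C <- (!is.na(X)) * 1
  sat0 <- function(M) {           # zero-padded summed-area table
    S <- apply(M, 2, cumsum)
    S <- t(apply(S, 1, cumsum))
    rbind(0, cbind(0, S))
  }
  Z <- sat0(X0); Zc <- sat0(C)
  ir <- seq_len(nr - k + 1L); ic <- seq_len(nc - k + 1L)
  box <- function(S) {
    out <- S[ir + k, ic + k, drop = FALSE] - S[ir, ic + k, drop = FALSE] -
      S[ir + k, ic, drop = FALSE] + S[ir, ic, drop = FALSE]
    out
  }
  sumV <- box(Z); sumC <- box(Zc)
  m <- sumV / sumC
  m[sumC == 0] <- NA_real_
  list(mean = m, count = sumC)
}

#' Butterfly scan for structural-variant blocks
#'
#' Slides a `k x k` window over the O/E matrix (restricted to pixel
#' distances above `d_min` bp for cis maps), flags windows whose mean O/E
#' exceeds `enrich_min` and whose raw support passes `min_count`, merges
#' overlapping candidate windows into blocks, localizes each block's
#' breakpoints at its most intense corner, and classifies the call.
#'
#' @param oe O/E ratio matrix (cis) or a raw-scaled trans block.
#' @param bin_size Bin size in bp.
#' @param d_min Minimum pixel distance (bp) for cis candidates (default
#'   2 Mb).
#' @param k Window size in bins (default 5).
#' @param enrich_min Minimum window mean O/E (default 3).
#' @param min_count Minimum summed raw counts in the window, evaluated on
#'   `raw` when given (guards against single-read O/E spikes in sparse
#'   far-cis pixels).
#' @param raw Optional raw count matrix aligned with `oe`.
#' @param trans Set TRUE for an inter-chromosomal block (no distance gate,
#'   all calls translocation-like).
#' @param coverage Optional [coverage_track()] result used to promote calls
#'   overlapping gain segments to duplication-like.
#' @return Data frame of calls: `bp1_bin`, `bp2_bin`, `type`, `enrichment`,
#'   `support_pixels`, block bounds.
#' @export
butterfly_scan <- function(oe, bin_size, d_min = 2e6, k = 5L,
                           enrich_min = 3, min_count = 25, raw = NULL,
                           trans = FALSE, coverage = NULL) {
  n <- nrow(oe)
  empty <- data.frame(bp1_bin = integer(), bp2_bin = integer(),
                      type = character(), enrichment = numeric(),
                      support_pixels = integer(), row1 = integer(),
                      row2 = integer(), col1 = integer(), col2 = integer())
  if (n < k) return(empty)
  wm <- .window_means(oe, k)
  if (is.null(wm)) return(empty)
  M <- wm$mean
  cnt_ok <- TRUE
  if (!is.null(raw)) {
    wr <- .window_means(raw, k)
    cnt_ok <- !is.na(wr$mean) & wr$mean * wr$count >= min_count
  }
  m <- nrow(M)
  ri <- row(M); ci <- col(M)
  keep <- !is.na(M) & M > enrich_min & cnt_ok
  if (!trans) {
    dist_bp <- (abs(ci - ri)) * bin_size   # window top-left corner distance
    keep <- keep & dist_bp > d_min & ci > ri   # upper triangle only
  }
  hits <- which(keep)
  if (!length(hits)) return(empty)
  hi <- ri[hits]; hj <- ci[hits]
  ## merge windows whose extents overlap (within k bins)
  comp <- rep(0L, length(hits)); cur <- 0L
  for (s in seq_along(hits)) {
    if (comp[s]) next
    cur <- cur + 1L; queue <- s; comp[s] <- cur
    while (length(queue)) {
      q0 <- queue[1]; queue <- queue[-1]
      nb <- which(comp == 0L & abs(hi - hi[q0]) <= k & abs(hj - hj[q0]) <= k)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  out <- do.call(rbind, lapply(split(seq_along(hits), comp), function(mem) {
    r1 <- min(hi[mem]); r2 <- max(hi[mem]) + k - 1L
    c1 <- min(hj[mem]); c2 <- max(hj[mem]) + k - 1L
    ## breakpoint = sharp corner of the discontinuity.  Each wing of the
    ## block decays away from the breakpoint, so the block's marginal O/E
    ## profiles peak exactly at the breakpoint rows/columns (both wings of
    ## a butterfly contribute to the same peak row and column).
    sub <- oe[r1:r2, c1:c2, drop = FALSE]
    rp <- rowMeans(sub, na.rm = TRUE); cp <- colMeans(sub, na.rm = TRUE)
    best <- c(r1 + which.max(rp) - 1L, c1 + which.max(cp) - 1L)
    enr <- max(M[cbind(hi[mem], hj[mem])])
    ## classification by quadrant geometry around the breakpoint corner:
    ## reciprocal translocation wings occupy the up-right and down-left
    ## quadrants (regions flanking both breakpoints outward), inversion
    ## wings the up-left and down-right quadrants (reversed decay at the
    ## span's ends); a coverage gain overlapping a breakpoint promotes the
    ## call to duplication-like (junction block of a tandem duplication).
    type <- "translocation-like"
    if (!trans) {
      qm <- function(rs, cs) {
        rs <- rs[rs >= 1 & rs <= n]; cs <- cs[cs >= 1 & cs <= n]
        if (!length(rs) || !length(cs)) return(1)
        v <- mean(oe[rs, cs], na.rm = TRUE)
        if (is.na(v)) 1 else v
      }
      rA <- (best[1] - k):(best[1] - 1L); rB <- (best[1] + 1L):(best[1] + k)
      cA <- (best[2] - k):(best[2] - 1L); cB <- (best[2] + 1L):(best[2] + k)
      tra_sig <- min(qm(rA, cB), qm(rB, cA))   # UR, DL
      inv_sig <- min(qm(rA, cA), qm(rB, cB))   # UL, DR
      if (inv_sig > tra_sig) type <- "inversion-like"
      if (!is.null(coverage) && nrow(coverage$segments)) {
        gains <- coverage$segments[coverage$segments$type == "gain", ]
        in_gain <- function(bin) any(gains$start_bin - 1L <= bin &
                                       bin <= gains$end_bin + 1L)
        if (nrow(gains) && (in_gain(best[1]) || in_gain(best[2])))
          type <- "duplication-like"
      }
    }
    data.frame(bp1_bin = min(best), bp2_bin = max(best), type = type,
               enrichment = enr, support_pixels = length(mem),
               row1 = r1, row2 = r2, col1 = c1, col2 = c2)
  }))
  rownames(out) <- NULL
  out[order(out$bp1_bin, out$bp2_bin), ]
}

#' Recurrent SVs across a cohort
#'
#' Clusters calls whose loci reciprocally overlap by at least 1 bin across
#' samples (both breakpoint neighborhoods, half-width `pad` bins) and
#' reports clusters supported by at least `min_samples` distinct samples.
#'
#' @param calls Named list (by sample) of [butterfly_scan()] data frames.
#' @param min_samples Minimum distinct supporting samples (default 2).
#' @param pad Breakpoint neighborhood half-width in bins (default 2).
#' @return Data frame of recurrent clusters: representative breakpoints,
#'   `type`, `n_samples`, `samples`.
#' @export
recurrent_svs <- function(calls, min_samples = 2L, pad = 2L) {
  pooled <- do.call(rbind, lapply(names(calls), function(id) {
    df <- calls[[id]]
    if (is.null(df) || !nrow(df)) return(NULL)
    df$sample <- id
    df
  }))
  empty <- data.frame(bp1_bin = integer(), bp2_bin = integer(),
                      type = character(), n_samples = integer(),
                      samples = character())
  if (is.null(pooled) || !nrow(pooled)) return(empty)
  m <- nrow(pooled)
  ov <- function(a, b) {
    abs(pooled$bp1_bin[a] - pooled$bp1_bin[b]) <= 2L * pad &&
      abs(pooled$bp2_bin[a] - pooled$bp2_bin[b]) <= 2L * pad
  }
  comp <- rep(0L, m); cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s]) next
    cur <- cur + 1L; queue <- s; comp[s] <- cur
    while (length(queue)) {
      q0 <- queue[1]; queue <- queue[-1]
      nb <- which(comp == 0L)
      nb <- nb[vapply(nb, ov, logical(1), b = q0)]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(m), comp), function(mem) {
    ids <- unique(pooled$sample[mem])
    data.frame(bp1_bin = round(median(pooled$bp1_bin[mem])),
               bp2_bin = round(median(pooled$bp2_bin[mem])),
               type = names(sort(table(pooled$type[mem]),
                                 decreasing = TRUE))[1],
               n_samples = length(ids),
               samples = paste(sort(ids), collapse = ","))
  }))
  out <- out[out$n_samples >= min_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}
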