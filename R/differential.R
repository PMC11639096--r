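## Differential boundary testing between subgroups, a Welch-t differential
## expression stand-in on log2-CPM, and boundary-gene association
## (relative distance, closest up/downstream boundary, 1-Mb window
## assignment).

#' Two-sided Welch t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#' Degenerate inputs follow fixed conventions: zero variance in both groups
#' with equal means gives `p = 1`; zero variance with unequal means gives
#' `p = 0` (flagged by `t = +/-Inf`).
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_two_sided <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  vx <- var(x); vy <- var(y)
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = nx + ny - 2, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = nx + ny - 2, p = 0))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up: `padj_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1, order
#' restored.
#'
#' @param pvals P-values in [0, 1] (`NA` allowed, passed through).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Differential boundary testing between two subgroups
#'
#' Tests every position defined (non-missing) in at least 2 samples per
#' group with a two-sided Welch t, BH-adjusts across all tested positions,
#' and summarizes the significant count and percentage (rounded to one
#' decimal).
#'
#' @param x Samples x positions feature matrix (standardized boundary
#'   scores).
#' @param metadata Data frame with `sample_id` and `subgroup` matching the
#'   rows of `x`.
#' @param groupA,groupB Subgroup labels to contrast; the reported
#'   `z_diff` is `mean(groupA) - mean(groupB)`.
#' @param alpha Significance threshold on `padj` (default 0.05).
#' @return List with `results` (per-position data frame: position,
#'   group means, `z_diff`, `t`, `p`, `padj`, `significant`) and `summary`
#'   (tested, significant, percent).
#' @export
differential_boundaries <- function(x, metadata, groupA, groupB,
                                    alpha = 0.05) {
  for (g in c(groupA, groupB))
    if (!g %in% metadata$subgroup) stop("group absent from metadata: ", g)
  ia <- metadata$sample_id[metadata$subgroup == groupA]
  ib <- metadata$sample_id[metadata$subgroup == groupB]
  xa <- x[ia, , drop = FALSE]; xb <- x[ib, , drop = FALSE]
  testable <- colSums(!is.na(xa)) >= 2 & colSums(!is.na(xb)) >= 2
  pos <- which(testable)
  res <- do.call(rbind, lapply(pos, function(cl) {
    w <- welch_t_two_sided(xa[, cl], xb[, cl])
    data.frame(position = colnames(x)[cl],
               mean_a = mean(xa[, cl], na.rm = TRUE),
               mean_b = mean(xb[, cl], na.rm = TRUE),
               t = w$t, p = w$p)
  }))
  if (is.null(res)) stop("no testable positions")
  res$z_diff <- res$mean_a - res$mean_b
  res$padj <- bh_adjust(res$p)
  res$significant <- !is.na(res$padj) & res$padj < alpha
  list(results = res,
       summary = diffbound_summary(sum(res$significant), nrow(res)))
}

#' Differential-boundary summary arithmetic
#'
#' @param n_significant,n_tested Counts of significant and tested
#'   boundaries.
#' @return List with `tested`, `significant`, and `percent` (100 x
#'   significant / tested, rounded to 1 decimal).
#' @export
diffbound_summary <- function(n_significant, n_tested) {
  list(tested = n_tested, significant = n_significant,
       percent = round(100 * n_significant / n_tested, 1))
}

#' Differential expression stand-in on log2-CPM
#'
#' Library-size-normalized counts are transformed to
#' `log2((count + 0.5) / libsize * 1e6)` and each gene is tested with a
#' two-sided Welch t between the groups; BH adjustment across genes.  This
#' is a documented stand-in for moderated-variance pipelines.
#'
#' @param counts Genes x samples integer matrix.
#' @param metadata Data frame with `sample_id`, `subgroup`.
#' @param groupA,groupB Labels to contrast (log2 fold-change is A minus B).
#' @param alpha Significance threshold on `padj`.
#' @return Data frame `gene`, `log2fc`, `t`, `p`, `padj`, `significant`.
#' @export
de_genes <- function(counts, metadata, groupA, groupB, alpha = 0.05) {
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero)) {
    warning("excluding sample(s) with zero library size: ",
            paste(colnames(counts)[zero], collapse = ", "))
    counts <- counts[, !zero, drop = FALSE]
    lib <- lib[!zero]
  }
  logcpm <- log2(t((t(counts) + 0.5) / lib * 1e6))
  ia <- intersect(metadata$sample_id[metadata$subgroup == groupA],
                  colnames(counts))
  ib <- intersect(metadata$sample_id[metadata$subgroup == groupB],
                  colnames(counts))
  res <- do.call(rbind, lapply(seq_len(nrow(counts)), function(g) {
    a <- logcpm[g, ia]; b <- logcpm[g, ib]
    if (all(counts[g, ] == 0)) return(NULL)   # undefined, excluded
    w <- welch_t_two_sided(a, b)
    data.frame(gene = rownames(counts)[g], log2fc = mean(a) - mean(b),
               t = w$t, p = w$p)
  }))
  res$padj <- bh_adjust(res$p)
  res$significant <- !is.na(res$padj) & res$padj < alpha
  res
}

#' Relative distance of genes to their flanking boundaries
#'
#' Each gene midpoint `g` with flanking boundaries `b_left <= g <= b_right`
#' scores `r = min(g - b_left, b_right - g) / (b_right - b_left)`, in
#' [0, 0.5]; genes outside the boundary span are excluded.  Under
#' independence `r` is uniform on [0, 0.5].
#'
#' @param gene_mid Gene midpoints in bp.
#' @param boundaries Boundary positions in bp (at least 2).
#' @return List with `reldist` (per included gene), `included` (indices),
#'   and `histogram` (10 bins of width 0.05 with observed fraction and the
#'   uniform expectation 0.1).
#' @export
reldist <- function(gene_mid, boundaries) {
  if (length(boundaries) < 2L) stop("need at least 2 boundaries")
  b <- sort(boundaries)
  inside <- which(gene_mid >= b[1] & gene_mid <= b[length(b)])
  r <- vapply(gene_mid[inside], function(g) {
    iv <- findInterval(g, b)
    iv <- min(max(iv, 1L), length(b) - 1L)
    bl <- b[iv]; br <- b[iv + 1L]
    min(g - bl, br - g) / (br - bl)
  }, numeric(1))
  breaks <- seq(0, 0.5, by = 0.05)
  h <- hist(r, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  list(reldist = r, included = inside,
       histogram = data.frame(lo = head(breaks, -1), hi = breaks[-1],
                              observed = h$counts / max(1, length(r)),
                              expected = 0.1))
}

#' Closest upstream and downstream boundary per gene
#'
#' Upstream: nearest boundary at or before the gene start (signed distance
#' `boundary - start <= 0`); downstream: nearest at or after the gene end.
#' A boundary inside the gene body counts as distance 0 on both sides.
#' Missing side gives `NA`.
#'
#' @param genes Data frame with `start`, `end` (bp).
#' @param boundaries Boundary positions in bp.
#' @return Data frame `upstream`, `upstream_dist`, `downstream`,
#'   `downstream_dist`, one row per gene.
#' @export
closest_boundaries <- function(genes, boundaries) {
  b <- sort(boundaries)
  out <- data.frame(upstream = rep(NA_real_, nrow(genes)),
                    upstream_dist = NA_real_,
                    downstream = NA_real_, downstream_dist = NA_real_)
  for (g in seq_len(nrow(genes))) {
    s <- genes$start[g]; e <- genes$end[g]
    inside <- b[b >= s & b <= e]
    if (length(inside)) {
      out$upstream[g] <- out$downstream[g] <- inside[1]
      out$upstream_dist[g] <- out$downstream_dist[g] <- 0
      next
    }
    up <- b[b <= s]
    if (length(up)) {
      out$upstream[g] <- max(up)
      out$upstream_dist[g] <- max(up) - s
    }
    dn <- b[b >= e]
    if (length(dn)) {
      out$downstream[g] <- min(dn)
      out$downstream_dist[g] <- min(dn) - e
    }
  }
  out
}

#' Assign each gene its most significant boundary within a window
#'
#' Among boundaries within `window` bp of the gene span, returns the one
#' with minimal `padj` (ties: smaller `p`, then nearer, then smaller
#' coordinate); `NA` when none is in range.
#'
#' @param genes Data frame with `start`, `end`.
#' @param boundary_results Data frame with `bp`, `p`, `padj`.
#' @param window Window in bp (default 1 Mb).
#' @return Data frame `boundary_bp`, `padj`, one row per gene.
#' @export
window_assign <- function(genes, boundary_results, window = 1e6) {
  out <- data.frame(boundary_bp = rep(NA_real_, nrow(genes)),
                    padj = NA_real_)
  for (g in seq_len(nrow(genes))) {
    s <- genes$start[g]; e <- genes$end[g]
    d <- ifelse(boundary_results$bp < s, s - boundary_results$bp,
                ifelse(boundary_results$bp > e, boundary_results$bp - e, 0))
    in_win <- which(d <= window)
    if (!length(in_win)) next
    cand <- boundary_results[in_win, ]
    cand$dist <- d[in_win]
    ord <- order(cand$padj, cand$p, cand$dist, cand$bp)
    out$boundary_bp[g] <- cand$bp[ord[1]]
    out$padj[g] <- cand$padj[ord[1]]
  }
  out
}

#' DE genes whose nearest boundary is differential
#'
#' Counts differentially expressed genes whose closest upstream or
#' downstream boundary belongs to the significantly differential set.
#'
#' @param de Data frame from [de_genes()] restricted or not; must carry
#'   `gene`, `significant`.
#' @param genes Gene positions (`gene`, `start`, `end`), superset of `de`.
#' @param all_boundaries All tested boundary positions (bp).
#' @param diff_boundaries Significantly differential boundary positions
#'   (bp).
#' @return List with `count` and `table` (per-DE-gene up/down flags).
#' @export
count_de_near_differential <- function(de, genes, all_boundaries,
                                       diff_boundaries) {
  sig <- de$gene[de$significant]
  if (!length(sig)) return(list(count = 0L, table = NULL))
  gd <- genes[match(sig, genes$gene), ]
  cb <- closest_boundaries(gd, all_boundaries)
  up_diff <- !is.na(cb$upstream) & cb$upstream %in% diff_boundaries
  dn_diff <- !is.na(cb$downstream) & cb$downstream %in% diff_boundaries
  tab <- data.frame(gene = sig, upstream_differential = up_diff,
                    downstream_differential = dn_diff)
  list(count = sum(up_diff | dn_diff), table = tab)
}
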