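## Multi-view subgroup discrimination: feature filtering, per-view
## distances, similarity network fusion, spectral clustering, concordance
## networks, and consensus NMF.  Continuous views (boundary scores,
## compartment eigenvectors) enter via squared Euclidean distances;
## call-based views (domains, loops) via Jaccard distances on binary
## presence vectors over the cohort union.

#' Fusion configuration
#'
#' @param K Neighbors for affinity and sparse kernels (default 20; clamped
#'   to `n - 2` with a warning on small cohorts).
#' @param sigma Kernel width multiplier (default 0.3).
#' @param T Diffusion iterations (default 16).
#' @param C Clusters for the concordance computation (default 2).
#' @param variance_keep Fraction of columns kept by variance (default 0.40).
#' @param max_missing Maximum per-column missing fraction (default 0.05).
#' @return List of class `fusion_config`.
#' @export
fusion_config <- function(K = 20L, sigma = 0.3, T = 16L, C = 2L,
                          variance_keep = 0.40, max_missing = 0.05) {
  stopifnot(T >= 1L, variance_keep > 0, variance_keep <= 1)
  structure(list(K = as.integer(K), sigma = sigma, T = as.integer(T),
                 C = as.integer(C), variance_keep = variance_keep,
                 max_missing = max_missing), class = "fusion_config")
}

#' Filter a continuous feature matrix
#'
#' Keeps positions where fewer than `max_missing` of samples are undefined,
#' then the top `variance_keep` fraction by cross-sample variance (ties at
#' the cutoff kept); remaining missing values are column-mean imputed.
#'
#' @param x Samples x positions matrix with `NA` for undefined scores.
#' @param config A [fusion_config()].
#' @return Filtered, imputed matrix.
#' @export
filter_features <- function(x, config = fusion_config()) {
  missing_frac <- colMeans(is.na(x))
  x <- x[, missing_frac < config$max_missing, drop = FALSE]
  if (!ncol(x)) stop("no positions survive the missingness filter")
  v <- apply(x, 2, var, na.rm = TRUE)
  v[is.na(v)] <- 0
  k <- floor(config$variance_keep * ncol(x))
  if (k < 1L) k <- 1L
  cutoff <- sort(v, decreasing = TRUE)[k]
  x <- x[, v >= cutoff, drop = FALSE]
  if (!ncol(x)) stop("no positions survive the variance filter")
  for (cl in which(colSums(is.na(x)) > 0)) {
    m <- mean(x[, cl], na.rm = TRUE)
    x[is.na(x[, cl]), cl] <- m
  }
  x
}

#' Squared Euclidean distances between samples
#'
#' @param x Filtered samples x positions matrix (no missing values).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_continuous <- function(x) {
  D <- as.matrix(dist(x, method = "euclidean"))^2
  dimnames(D) <- list(rownames(x), rownames(x))
  D
}

#' Jaccard distances between binary call profiles
#'
#' `1 - |A intersect B| / |A union B|` on each pair of samples' call sets;
#' two empty sets have distance 0 by convention.
#'
#' @param x Samples x features binary (0/1) matrix.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_binary <- function(x) {
  stopifnot(all(x %in% c(0, 1)))
  x <- as.matrix(x)
  inter <- x %*% t(x)
  size <- rowSums(x)
  uni <- outer(size, size, "+") - inter
  D <- 1 - ifelse(uni == 0, 1, inter / uni)
  diag(D) <- 0
  dimnames(D) <- list(rownames(x), rownames(x))
  D
}

#' Scaled exponential affinity kernel
#'
#' `mu_s` is the mean of the K smallest off-diagonal distances from sample
#' s; the pairwise bandwidth is `eps_st = (mu_s + mu_t + D_st) / 3`; and
#' `W_st = (2 pi (sigma eps_st)^2)^(-1/2) exp(-D_st^2 / (2 (sigma
#' eps_st)^2))`, symmetrized as `(W + t(W)) / 2`.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param config A [fusion_config()].
#' @return Symmetric affinity matrix.
#' @export
affinity_matrix <- function(D, config = fusion_config()) {
  n <- nrow(D)
  K <- config$K
  if (K >= n) stop("K must be smaller than the number of samples")
  if (K > n - 2L) {
    warning("K clamped to n - 2 for small cohort")
    K <- n - 2L
  }
  mu <- vapply(seq_len(n), function(s) {
    mean(sort(D[s, -s])[seq_len(K)])
  }, numeric(1))
  eps <- (outer(mu, mu, "+") + D) / 3
  if (any(eps == 0)) stop("degenerate distances: zero kernel bandwidth")
  se <- config$sigma * eps
  W <- exp(-D^2 / (2 * se^2)) / sqrt(2 * pi * se^2)
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(D)
  W
}

## Full kernel: off-diagonal rows sum to 1/2, diagonal 1/2.
.full_kernel <- function(W) {
  n <- nrow(W)
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

## Sparse KNN kernel: row-normalized over each sample's K nearest neighbors.
.sparse_kernel <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ord <- order(W[s, -s], decreasing = TRUE)
    nb <- (seq_len(n)[-s])[ord[seq_len(K)]]
    S[s, nb] <- W[s, nb]
  }
  S / rowSums(S)
}

#' Similarity network fusion
#'
#' Cross-diffusion of per-view affinities: each view's full kernel is
#' propagated through its sparse KNN kernel against the average of the
#' other views for `T` rounds, re-symmetrized and re-normalized each round;
#' the fused network is the renormalized average of the diffused kernels.
#' With a single view the fused network is that view's full kernel.
#'
#' @param W_list List of symmetric affinity matrices over the same samples.
#' @param config A [fusion_config()].
#' @return Object of class `fused_network`: list with `fused` (the fused
#'   kernel; off-diagonal entries in [0, 0.5]), `P_views` (diffused
#'   kernels), and `config`.
#' @export
snf_fuse <- function(W_list, config = fusion_config()) {
  m <- length(W_list)
  stopifnot(m >= 1)
  n <- nrow(W_list[[1]])
  ids <- rownames(W_list[[1]])
  for (W in W_list)
    if (nrow(W) != n || !identical(rownames(W), ids))
      stop("affinity matrices have mismatched sample sets")
  K <- min(config$K, n - 2L)
  P <- lapply(W_list, .full_kernel)
  if (m > 1) {
    S <- lapply(W_list, .sparse_kernel, K = K)
    for (it in seq_len(config$T)) {
      P_new <- vector("list", m)
      for (v in seq_len(m)) {
        others <- Reduce(`+`, P[-v]) / (m - 1)
        Q <- S[[v]] %*% others %*% t(S[[v]])
        Q <- (Q + t(Q)) / 2
        P_new[[v]] <- .full_kernel(Q)
      }
      P <- P_new
    }
  }
  if (m == 1) {
    fused <- P[[1]]                     # single view: its full kernel
  } else {
    fused <- Reduce(`+`, P) / m
    fused <- .full_kernel((fused + t(fused)) / 2)
  }
  dimnames(fused) <- list(ids, ids)
  structure(list(fused = fused, P_views = P, config = config),
            class = "fused_network")
}

#' Distance derived from a fused network
#'
#' `dist(s, t) = 0.5 - similarity` off the diagonal, 0 on it.  The
#' row-normalized kernel can be slightly asymmetric, so the similarity is
#' symmetrized before conversion; the result is a symmetric dissimilarity
#' but not guaranteed to be a metric.
#'
#' @param fused A `fused_network` or its fused kernel matrix.
#' @return Symmetric distance matrix with values in [0, 0.5].
#' @export
fused_distance <- function(fused) {
  Pbar <- if (inherits(fused, "fused_network")) fused$fused else fused
  D <- 0.5 - (Pbar + t(Pbar)) / 2
  diag(D) <- 0
  pmin(pmax(D, 0), 0.5)
}

#' Two-dimensional embedding of a distance matrix
#'
#' Neighborhood-preserving 2-D coordinates for visualization.  The backend
#' is pluggable; the default is classical multidimensional scaling, which
#' is deterministic (the seed argument is accepted for interface stability
#' and used only to break exact ties).  No quantitative result in the
#' package depends on these coordinates.
#'
#' @param D Symmetric distance matrix.
#' @param seed Integer seed.
#' @return n x 2 coordinate matrix.
#' @export
embed_2d <- function(D, seed = 1L) {
  n <- nrow(D)
  if (n == 1L)
    return(matrix(0, 1, 2, dimnames = list(rownames(D), c("x", "y"))))
  co <- suppressWarnings(cmdscale(as.dist(D), k = min(2L, n - 1L)))
  if (ncol(co) < 2L) co <- cbind(co, 0)
  .set_rng(seed)
  co <- co + matrix(runif(length(co), -1e-12, 1e-12), nrow(co))
  colnames(co) <- c("x", "y")
  co
}

#' Normalized-cut spectral clustering of an affinity matrix
#'
#' Top-C eigenvectors of the symmetrically normalized affinity, rows
#' normalized to unit length, then k-means with a fixed seed.
#'
#' @param W Symmetric non-negative affinity matrix.
#' @param C Number of clusters.
#' @param seed Seed for k-means initialization.
#' @return Integer cluster labels named by sample.
#' @export
spectral_cluster <- function(W, C, seed = 1L) {
  n <- nrow(W)
  if (C >= n) return(setNames(seq_len(n), rownames(W)))
  d <- rowSums(W)
  d[d == 0] <- 1e-12
  Ds <- 1 / sqrt(d)
  Lsym <- t(W * Ds) * Ds
  eig <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  U <- eig$vectors[, seq_len(C), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U <- U / norms
  .set_rng(seed)
  km <- kmeans(U, centers = C, nstart = 50L, iter.max = 100L)
  setNames(km$cluster, rownames(W))
}

#' Normalized mutual information between two partitions
#'
#' `I(a; b) / sqrt(H(a) H(b))`; 1 for identical partitions up to
#' relabeling; defined as 1 when both entropies are 0 and 0 when exactly
#' one is.
#'
#' @param a,b Equal-length label vectors.
#' @return Value in [0, 1].
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  Ha <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  Hb <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  EP <- outer(pi_, pj_)
  I <- sum(ifelse(pij > 0, pij * log(pij / EP), 0))
  max(0, min(1, I / sqrt(Ha * Hb)))
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Equal-length label vectors.
#' @return ARI (1 for identical partitions, ~0 at random).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Concordance network between views and the fused network
#'
#' Clusters every network (each view plus the fused one) with
#' [spectral_cluster()] at `C` groups, then reports pairwise NMI between
#' the partitions; distance is `1 - concordance`.
#'
#' @param W_views Named list of per-view affinity (or kernel) matrices.
#' @param fused Fused kernel matrix (or `fused_network`).
#' @param config A [fusion_config()] (supplies `C`).
#' @param seed Clustering seed.
#' @return List with `concordance` (symmetric matrix, unit diagonal),
#'   `distance` (`1 - concordance`), and `labels` per network.
#' @export
concordance_network <- function(W_views, fused, config = fusion_config(),
                                seed = 1L) {
  Pbar <- if (inherits(fused, "fused_network")) fused$fused else fused
  nets <- c(W_views, list(fused = Pbar))
  labels <- lapply(nets, spectral_cluster, C = config$C, seed = seed)
  m <- length(nets)
  conc <- matrix(1, m, m, dimnames = list(names(nets), names(nets)))
  for (u in seq_len(m - 1)) for (v in (u + 1):m) {
    conc[u, v] <- conc[v, u] <- nmi(labels[[u]], labels[[v]])
  }
  list(concordance = conc, distance = 1 - conc, labels = labels)
}

## one multiplicative-update NMF run, Frobenius objective
.nmf_run <- function(X, k, iters, floor_val, seed) {
  .set_rng(seed)
  f <- nrow(X); s <- ncol(X)
  W <- matrix(runif(f * k, floor_val, 1), f, k)
  H <- matrix(runif(k * s, floor_val, 1), k, s)
  for (it in seq_len(iters)) {
    H <- H * (t(W) %*% X) / pmax(t(W) %*% W %*% H, floor_val)
    W <- W * (X %*% t(H)) / pmax(W %*% H %*% t(H), floor_val)
    H[H < floor_val] <- floor_val
    W[W < floor_val] <- floor_val
  }
  list(W = W, H = H)
}

#' Consensus NMF clustering with silhouettes
#'
#' The samples x features matrix is shifted non-negative by subtracting its
#' global minimum and transposed to features x samples; `n_runs` rank-`k`
#' factorizations (multiplicative Frobenius updates, 500 iterations, 1e-9
#' floor, per-run random initialization) each label samples by the argmax
#' of their `H` column; the consensus matrix holds co-clustering fractions;
#' final labels cut an average-linkage tree on `1 - consensus` at `k`; and
#' silhouette widths are computed on `1 - consensus`.
#'
#' @param x Samples x features continuous matrix (no missing values).
#' @param k Factorization rank / cluster count (default 3).
#' @param n_runs Number of restarts (default 30).
#' @param iters Multiplicative-update iterations per run.
#' @param seed Master seed; run r uses `derive_seed(seed, r)`.
#' @return List with `labels` (named integer vector), `consensus`,
#'   `silhouette` (per-sample width), and `run_labels`.
#' @export
nmf_consensus <- function(x, k = 3L, n_runs = 30L, iters = 500L, seed = 1L) {
  if (k > nrow(x)) stop("k exceeds the number of samples")
  X <- t(x - min(x))                        # features x samples, non-negative
  if (any(X < 0)) stop("internal error: negative entries after shift")
  n <- ncol(X)
  run_labels <- matrix(0L, n_runs, n)
  for (r in seq_len(n_runs)) {
    fit <- .nmf_run(X, k, iters, 1e-9, derive_seed(seed, r))
    run_labels[r, ] <- apply(fit$H, 2, which.max)
  }
  M <- matrix(0, n, n)
  for (r in seq_len(n_runs))
    M <- M + outer(run_labels[r, ], run_labels[r, ], "==")
  M <- M / n_runs
  dimnames(M) <- list(rownames(x), rownames(x))
  hc <- hclust(as.dist(1 - M), method = "average")
  labels <- cutree(hc, k = k)
  sil <- .silhouette_from_dist(1 - M, labels)
  list(labels = labels, consensus = M, silhouette = sil,
       run_labels = run_labels)
}

## silhouette widths from a distance matrix (singleton clusters get 0)
.silhouette_from_dist <- function(D, labels) {
  n <- length(labels)
  vapply(seq_len(n), function(s) {
    own <- labels == labels[s]
    if (sum(own) == 1L) return(0)
    a <- mean(D[s, own & seq_len(n) != s])
    b <- min(vapply(setdiff(unique(labels), labels[s]), function(cl) {
      mean(D[s, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}
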