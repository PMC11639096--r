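test_that("feature filtering applies missingness and variance rules", {
  set.seed(5)
  x <- matrix(rnorm(20 * 100), 20, 100)
  x[1:2, 1:10] <- NA                  # 10 columns with 10% missing
  rownames(x) <- paste0("s", 1:20)
  f <- filter_features(x)
  expect_equal(ncol(f), 36L)          # 90 survive, floor(0.4 * 90) = 36
  expect_false(anyNA(f))

  ## sporadic missingness below 5% is mean-imputed
  x2 <- matrix(rnorm(40 * 50), 40, 50)
  x2[1, 7] <- NA
  f2 <- filter_features(x2)
  if ("7" %in% colnames(f2)) expect_false(anyNA(f2))

  ## constant columns are dropped by the variance rule
  x3 <- cbind(matrix(rnorm(20 * 30), 20, 30), matrix(1, 20, 10))
  f3 <- filter_features(x3)
  expect_true(all(apply(f3, 2, var) > 0))
  expect_error(filter_features(matrix(NA_real_, 5, 4)), "missingness")
})

test_that("continuous and binary distances match brute-force oracles", {
  expect_equal(distance_continuous(rbind(c(0, 0), c(3, 4)))[1, 2], 25)
  set.seed(6)
  x <- matrix(rnorm(35), 5, 7)
  D <- distance_continuous(x)
  for (s in 1:5) for (t in 1:5)
    expect_equal(D[s, t], sum((x[s, ] - x[t, ])^2), tolerance = 1e-12)

  b <- rbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1), c = c(0, 0, 0, 0),
             d = c(0, 0, 0, 0))
  Db <- distance_binary(b)
  expect_equal(Db["a", "b"], 0.5)     # {1,2,3} vs {2,3,4}
  expect_equal(Db["c", "d"], 0)       # both empty -> 0
  expect_equal(Db["a", "c"], 1)       # disjoint, one empty... union nonempty
  expect_equal(diag(Db), setNames(rep(0, 4), rownames(b)))
})

test_that("affinity kernel matches its formula and is monotone", {
  set.seed(7)
  x <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(paste0("s", 1:4), NULL))
  D <- distance_continuous(x)
  cfg <- fusion_config(K = 2)
  W <- affinity_matrix(D, cfg)
  ## brute-force recomputation
  for (s in 1:4) for (t in 1:4) {
    mus <- mean(sort(D[s, -s])[1:2]); mut <- mean(sort(D[t, -t])[1:2])
    e1 <- (mus + mut + D[s, t]) / 3
    w_st <- exp(-D[s, t]^2 / (2 * (0.3 * e1)^2)) / sqrt(2 * pi * (0.3 * e1)^2)
    ## symmetrized
    expect_equal(W[s, t], (w_st + w_st) / 2, tolerance = 1e-12)
  }
  expect_error(affinity_matrix(D, fusion_config(K = 4)), "smaller")
  expect_warning(affinity_matrix(D, fusion_config(K = 3)), "clamped")

  ## duplicated samples get the row-maximal affinity
  x2 <- rbind(x, s5 = x[1, ])
  W2 <- affinity_matrix(distance_continuous(x2), cfg)
  expect_equal(unname(which.max(W2[5, -5])), 1L)
})

test_that("SNF fusion keeps kernels row-stochastic and fuses planted structure", {
  set.seed(8)
  grp <- rep(1:3, each = 6)
  mk_view <- function(shift) {
    x <- matrix(rnorm(18 * 40), 18, 40,
                dimnames = list(paste0("s", 1:18), NULL))
    for (g in 1:3) x[grp == g, (g - 1) * 8 + 1:8] <-
        x[grp == g, (g - 1) * 8 + 1:8] + shift
    affinity_matrix(distance_continuous(x), fusion_config(K = 5))
  }
  W1 <- mk_view(2.5); W2 <- mk_view(2.5)
  cfg <- fusion_config(K = 5, T = 16)
  ## single view: fused equals that view's full kernel
  f1 <- snf_fuse(list(W1), cfg)
  expect_equal(f1$fused, topohic:::.full_kernel(W1), tolerance = 1e-12)
  ## fused kernel invariants
  fn <- snf_fuse(list(W1, W2), cfg)
  P <- fn$fused
  expect_equal(unname(diag(P)), rep(0.5, 18))
  off <- P; diag(off) <- 0
  expect_equal(unname(rowSums(off)), rep(0.5, 18), tolerance = 1e-10)
  expect_true(all(off >= 0 & off <= 0.5 + 1e-12))
  ## planted 3-group structure is recovered exactly
  lab <- spectral_cluster(P, 3, seed = 2)
  expect_equal(adjusted_rand_index(lab, grp), 1)
  ## mismatched sample sets error
  W3 <- W2; rownames(W3)[1] <- "zz"
  expect_error(snf_fuse(list(W1, W3), cfg), "mismatch")
})

test_that("fused distance is 0.5 - similarity on [0, 0.5]", {
  set.seed(9)
  W <- affinity_matrix(distance_continuous(
    matrix(rnorm(50), 10, 5, dimnames = list(paste0("s", 1:10), NULL))),
    fusion_config(K = 3))
  fn <- snf_fuse(list(W), fusion_config(K = 3))
  D <- fused_distance(fn)
  expect_equal(unname(diag(D)), rep(0, 10))
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 0.5))
  expect_equal(D[1, 2], 0.5 - (fn$fused[1, 2] + fn$fused[2, 1]) / 2)
})

test_that("2-D embedding is deterministic and separates planted groups", {
  set.seed(10)
  pts <- rbind(matrix(rnorm(16), 8, 2), matrix(rnorm(16, 8), 8, 2),
               matrix(rnorm(16, 16), 8, 2))
  D <- as.matrix(dist(pts))
  c1 <- embed_2d(D, seed = 4)
  c2 <- embed_2d(D, seed = 4)
  expect_identical(c1, c2)
  km <- kmeans(c1, 3, nstart = 20)
  expect_gte(adjusted_rand_index(km$cluster, rep(1:3, each = 8)), 0.9)
  expect_equal(dim(embed_2d(matrix(0, 1, 1), seed = 1)), c(1L, 2L))
})

test_that("spectral clustering recovers block structure and handles C = n", {
  B <- matrix(0.01, 12, 12)
  B[1:6, 1:6] <- 1; B[7:12, 7:12] <- 1
  diag(B) <- 1
  lab <- spectral_cluster(B, 2, seed = 3)
  expect_equal(adjusted_rand_index(lab, rep(1:2, each = 6)), 1)
  expect_length(unique(spectral_cluster(B, 12, seed = 3)), 12L)
})

test_that("NMI follows its entropy definition", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(nmi(c(1, 1, 1), c(1, 1, 1)), 1)   # both entropies zero
  expect_equal(nmi(c(1, 1, 1), c(1, 2, 1)), 0)   # exactly one zero
  expect_error(nmi(1:3, 1:4), "length")
  ## direct entropy computation oracle on a random pair
  set.seed(11)
  a <- sample(1:3, 40, TRUE); b <- sample(1:2, 40, TRUE)
  tab <- table(a, b) / 40
  pa <- rowSums(tab); pb <- colSums(tab)
  I <- sum(tab * log(tab / outer(pa, pb)), na.rm = TRUE)
  expect_equal(nmi(a, b),
               max(0, I / sqrt(-sum(pa * log(pa)) * -sum(pb * log(pb)))),
               tolerance = 1e-12)
})

test_that("concordance network ranks a structured view above noise", {
  set.seed(12)
  grp <- rep(1:2, each = 8)
  xs <- matrix(rnorm(16 * 30), 16, 30,
               dimnames = list(paste0("s", 1:16), NULL))
  xs[grp == 2, 1:10] <- xs[grp == 2, 1:10] + 4
  xn <- matrix(rnorm(16 * 30), 16, 30,
               dimnames = list(paste0("s", 1:16), NULL))
  cfg <- fusion_config(K = 4, C = 2)
  Ws <- affinity_matrix(distance_continuous(xs), cfg)
  Wn <- affinity_matrix(distance_continuous(xn), cfg)
  fn <- snf_fuse(list(structured = Ws, noise = Wn), cfg)
  cn <- concordance_network(list(structured = Ws, noise = Wn), fn, cfg)
  expect_equal(diag(cn$concordance), rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(cn$concordance, t(cn$concordance))
  expect_gt(cn$concordance["structured", "fused"],
            cn$concordance["noise", "fused"])
  expect_equal(cn$distance, 1 - cn$concordance)
})

test_that("consensus NMF clusters planted groups with confident silhouettes", {
  set.seed(13)
  grp <- rep(1:3, each = 6)
  x <- matrix(rnorm(18 * 40), 18, 40,
              dimnames = list(paste0("s", 1:18), NULL))
  for (g in 1:3) x[grp == g, (g - 1) * 10 + 1:10] <-
      x[grp == g, (g - 1) * 10 + 1:10] + 3
  nm <- nmf_consensus(x, k = 3, n_runs = 10, seed = 5)
  expect_equal(adjusted_rand_index(nm$labels, grp), 1)
  expect_true(all(nm$silhouette > 0.5))
  ## single run: binary consensus
  nm1 <- nmf_consensus(x, k = 3, n_runs = 1, seed = 5)
  expect_true(all(nm1$consensus %in% c(0, 1)))
  ## duplicated rows always co-cluster
  xd <- rbind(x, dup = x[1, ])
  nmd <- nmf_consensus(xd, k = 3, n_runs = 8, seed = 5)
  expect_equal(nmd$consensus["s1", "dup"], 1)
  expect_error(nmf_consensus(x[1:2, ], k = 3), "exceeds")
})
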