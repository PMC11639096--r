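test_that("Welch t matches the reference implementation", {
  w <- welch_t_two_sided(1:5, 2:6)
  expect_equal(w$t, -1)
  expect_equal(welch_t_two_sided(c(1, 2, 3), c(1, 2, 3))$p, 1)
  ## degenerate variance conventions
  expect_equal(welch_t_two_sided(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t_two_sided(c(2, 2), c(3, 3))$p, 0)
  ## high-precision oracle on random inputs
  set.seed(14)
  for (r in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), sd = 2)
    ref <- t.test(x, y)
    w <- welch_t_two_sided(x, y)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
  }
})

test_that("BH adjustment matches a hand-rolled step-up", {
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    run <- Inf
    for (q in m:1) {
      run <- min(run, m * p[o[q]] / q)
      adj[o[q]] <- min(1, run)
    }
    adj
  }
  set.seed(15)
  for (r in 1:10) {
    p <- runif(sample(5:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  ## monotone in p-order
  p <- runif(30)
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= -1e-15))
})

test_that("differential boundary testing summarizes counts and controls the null", {
  ## printed-count arithmetic
  expect_equal(diffbound_summary(2803, 13885)$percent, 20.2)
  expect_equal(diffbound_summary(1486, 13885)$percent, 10.7)

  meta <- data.frame(sample_id = paste0("s", 1:21),
                     subgroup = rep(c("G3", "G4"), c(8, 13)))
  set.seed(16)
  fr <- vapply(1:40, function(r) {
    x <- matrix(rnorm(21 * 200), 21, 200,
                dimnames = list(meta$sample_id, seq_len(200) * 5e4))
    db <- differential_boundaries(x, meta, "G3", "G4")
    db$summary$significant / db$summary$tested
  }, numeric(1))
  expect_lte(mean(fr), 0.05 + 2 * sqrt(0.05 / 200))
  ## positions defined in < 2 samples per group are not tested
  x <- matrix(rnorm(21 * 10), 21, 10,
              dimnames = list(meta$sample_id, seq_len(10) * 5e4))
  x[meta$subgroup == "G3", 3] <- NA
  db <- differential_boundaries(x, meta, "G3", "G4")
  expect_equal(db$summary$tested, 9L)
  expect_error(differential_boundaries(x, meta, "G3", "WNT"), "absent")
})

test_that("the DE stand-in is calibrated and powered as stated", {
  spec <- cohort_spec(seed = 17)
  co <- simulate_cohort(spec, contacts = FALSE)
  meta <- co$metadata
  de <- de_genes(co$expression, meta, "G4", "G3")
  planted <- spec$de_genes$gene
  expect_gt(mean(de$significant[de$gene %in% planted]), 0.9)
  expect_lt(mean(de$significant[!de$gene %in% planted]), 0.05)
  ## all-zero gene is excluded
  cnt <- co$expression
  cnt[5, ] <- 0L
  de2 <- de_genes(cnt, meta, "G4", "G3")
  expect_false(rownames(cnt)[5] %in% de2$gene)
  ## zero library size excluded with warning
  cnt2 <- co$expression
  cnt2[, 3] <- 0L
  expect_warning(de_genes(cnt2, meta, "G4", "G3"), "zero library")
})

test_that("reldist is exact on anchors and uniform under independence", {
  b <- c(0, 1000)
  expect_equal(reldist(0, b)$reldist, 0)
  expect_equal(reldist(500, b)$reldist, 0.5)
  expect_error(reldist(10, 100), "2 boundaries")
  set.seed(18)
  bnd <- sort(runif(50, 0, 25e6))
  g <- runif(1000, min(bnd), max(bnd))
  rd <- reldist(g, bnd)
  expect_true(all(rd$reldist >= 0 & rd$reldist <= 0.5))
  ks <- suppressWarnings(ks.test(rd$reldist, function(x) punif(x, 0, 0.5)))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sum(rd$histogram$observed), 1, tolerance = 1e-12)
  expect_equal(rd$histogram$expected, rep(0.1, 10))
})

test_that("closest boundary queries follow the stated conventions", {
  genes <- data.frame(start = c(100, 100, 10), end = c(200, 200, 40))
  cb <- closest_boundaries(genes[1, ], c(50, 500))
  expect_equal(cb$upstream, 50)
  expect_equal(cb$upstream_dist, -50)
  expect_equal(cb$downstream, 500)
  expect_equal(cb$downstream_dist, 300)
  ## boundary inside the gene body: distance 0 both sides
  cb2 <- closest_boundaries(genes[2, ], c(150, 500))
  expect_equal(cb2$upstream_dist, 0)
  expect_equal(cb2$downstream_dist, 0)
  ## gene before all boundaries: upstream missing
  cb3 <- closest_boundaries(genes[3, ], c(50, 500))
  expect_true(is.na(cb3$upstream))
  expect_equal(cb3$downstream, 50)
})

test_that("window assignment picks the most significant boundary in range", {
  genes <- data.frame(start = 5e6, end = 5.01e6)
  br <- data.frame(bp = c(4.5e6, 5.5e6, 7e6), p = c(0.15, 0.005, 1e-6),
                   padj = c(0.2, 0.01, 1e-4))
  wa <- window_assign(genes, br, window = 1e6)
  expect_equal(wa$boundary_bp, 5.5e6)     # 7e6 is out of range
  expect_true(is.na(window_assign(genes, br[3, , drop = FALSE])$boundary_bp))
  ## brute-force oracle on random fixtures
  set.seed(19)
  for (r in 1:10) {
    gs <- sort(runif(2, 0, 2e7)); gdf <- data.frame(start = gs[1], end = gs[2])
    brr <- data.frame(bp = runif(30, 0, 2.5e7), p = runif(30),
                      padj = runif(30))
    got <- window_assign(gdf, brr, window = 1e6)
    d <- ifelse(brr$bp < gs[1], gs[1] - brr$bp,
                ifelse(brr$bp > gs[2], brr$bp - gs[2], 0))
    cand <- which(d <= 1e6)
    if (!length(cand)) {
      expect_true(is.na(got$boundary_bp))
    } else {
      best <- cand[order(brr$padj[cand], brr$p[cand], d[cand],
                         brr$bp[cand])][1]
      expect_equal(got$boundary_bp, brr$bp[best])
    }
  }
})

test_that("DE-near-differential counting matches planted adjacency", {
  spec <- default_spec()
  genes <- spec$genes
  all_b <- spec$boundary_bin * spec$bin_size
  diff_b <- spec$boundary_bin[spec$diff_boundaries] * spec$bin_size
  de <- data.frame(gene = genes$gene,
                   significant = genes$gene %in% spec$de_genes$gene)
  got <- count_de_near_differential(de, genes, all_b, diff_b)
  ## every planted DE gene sits next to a differential boundary
  expect_equal(got$count, nrow(spec$de_genes))
  expect_lte(got$count, sum(de$significant))
  none <- count_de_near_differential(
    data.frame(gene = character(), significant = logical()),
    genes, all_b, diff_b)
  expect_equal(none$count, 0L)
})
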