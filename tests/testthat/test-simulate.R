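# The generator's contract: stated Poisson mean structure, determinism, and
# planted-truth consistency.

test_that("contact simulation is deterministic and totals match L", {
  spec <- default_spec()
  a <- simulate_contact_map(spec, "G3", 7)
  b <- simulate_contact_map(spec, "G3", 7)
  expect_identical(a$cm$counts, b$cm$counts)
  tot <- vapply(1:5, function(s)
    sum(simulate_contact_map(spec, "SHH", 40 + s)$cm$counts$count),
    numeric(1))
  expect_true(all(abs(tot / spec$library_size - 1) < 0.02))
})

test_that("structure-free decay matches the (1+d)^-alpha profile", {
  spec <- cohort_spec(seed = 2, tau = 0, compartment_contrast = 0,
                      loop_amp = 0)
  ## pool several seeds so per-diagonal Monte-Carlo error is small
  n <- spec$n_bins
  dd <- c(1L, 5L, 20L)
  sums <- matrix(0, length(dd), 5)
  for (s in 1:5) {
    M <- as_dense(simulate_contact_map(spec, "G3", 300 + s)$cm)
    for (q in seq_along(dd))
      sums[q, s] <- mean(M[cbind(1:(n - dd[q]), (1 + dd[q]):n)])
  }
  mu <- contact_mu(spec, "G3")
  for (q in seq_along(dd)) {
    expmean <- mean(mu[cbind(1:(n - dd[q]), (1 + dd[q]):n)])
    se <- sd(sums[q, ]) / sqrt(5)
    expect_lt(abs(mean(sums[q, ]) - expmean), max(3 * se, 1e-8))
  }
  ## profile follows the power law: ratio test on the expected matrix
  expect_equal(mu[1, 21] / mu[1, 11], (21 / 11)^(-1), tolerance = 1e-10)
})

test_that("boundary strength acts as specified on cross-TAD means", {
  ## beta = 1 suppresses the TAD term to baseline: cross/within = 1/(1+tau)
  spec <- cohort_spec(seed = 1, compartment_contrast = 0, loop_amp = 0)
  spec$beta[, ] <- 1
  mu <- contact_mu(spec, "G3")
  bb <- spec$boundary_bin
  within <- c(); cross <- c()
  for (i in seq_len(spec$n_bins - 2)) {
    nb <- sum(bb >= i & bb < i + 2)
    if (nb == 0) within <- c(within, mu[i, i + 2])
    if (nb == 1) cross <- c(cross, mu[i, i + 2])
  }
  expect_equal(mean(cross) / mean(within), 1 / (1 + spec$tau),
               tolerance = 1e-10)

  ## beta = 0 makes the boundary statistically invisible in the mean
  spec0 <- cohort_spec(seed = 1, compartment_contrast = 0, loop_amp = 0)
  spec0$beta[, ] <- 0
  mu0 <- contact_mu(spec0, "G3")
  cross0 <- c(); within0 <- c()
  for (i in seq_len(spec0$n_bins - 2)) {
    nb <- sum(spec0$boundary_bin >= i & spec0$boundary_bin < i + 2)
    if (nb == 0) within0 <- c(within0, mu0[i, i + 2])
    if (nb == 1) cross0 <- c(cross0, mu0[i, i + 2])
  }
  expect_equal(mean(cross0) / mean(within0), 1, tolerance = 1e-10)
})

test_that("planted beta=0 boundary is invisible to the boundary score", {
  ## score distribution at the beta=0 position matches null positions
  spec <- two_tad_world(beta = 0)
  z_at <- c()
  for (s in 1:12) {
    sim <- simulate_contact_map(spec, "SHH", 800 + s)
    tr <- boundary_scores(balance(sim$cm))
    z_at <- c(z_at, tr$combined[100])
  }
  null_pool <- c()
  for (s in 1:12) {
    sim <- simulate_contact_map(spec, "SHH", 900 + s)
    tr <- boundary_scores(balance(sim$cm))
    null_pool <- c(null_pool, tr$combined[c(40, 60, 150, 170)])
  }
  ks <- suppressWarnings(ks.test(z_at, null_pool))
  expect_gt(ks$p.value, 0.01)
})

test_that("expression simulation plants fold-changes where stated", {
  spec <- default_spec()
  expect_identical(simulate_expression(spec, "G4", 5),
                   simulate_expression(spec, "G4", 5))
  ## null genes: group means agree within sampling error
  null_genes <- setdiff(spec$genes$gene, spec$de_genes$gene)
  m3 <- rowMeans(vapply(1:25, function(s)
    simulate_expression(spec, "G3", 1000 + s), numeric(nrow(spec$genes))))
  m4 <- rowMeans(vapply(1:25, function(s)
    simulate_expression(spec, "G4", 2000 + s), numeric(nrow(spec$genes))))
  ratio <- m4[null_genes] / m3[null_genes]
  expect_lt(abs(median(ratio) - 1), 0.1)
  ## planted genes: fold ~ de_fold in the affected group
  g4_up <- spec$de_genes$gene[spec$de_genes$group == "G4"]
  expect_gt(median(m4[g4_up] / m3[g4_up]), spec$de_genes$fold[1] * 0.6)
})

test_that("reference track tiles A bins and degrades with label noise", {
  spec <- default_spec()
  ref <- simulate_reference_track(spec, epsilon = 0)
  truthA <- bins_to_intervals(spec$compartments == "A", spec$chrom,
                              spec$bin_size)
  expect_equal(ref, truthA)
  expect_equal(interval_jaccard(ref, truthA), 1)
  ## epsilon = 0.5: flipping half the bins drives Jaccard towards the
  ## random-overlap level; closed form for half A-bins flipped out and half
  ## B-bins flipped in: intersection ~ A/2, union ~ 3A/2 -> 1/3
  refs <- vapply(1:20, function(s)
    interval_jaccard(simulate_reference_track(spec, epsilon = 0.5,
                                              seed = 100 + s), truthA),
    numeric(1))
  expect_lt(abs(mean(refs) - 1 / 3), 0.06)

  ## alternating 10-bin blocks give intervals of exactly 10 * bin_size
  sp <- cohort_spec(seed = 4, compartment_block_len = 10 * 5e4)
  r10 <- simulate_reference_track(sp, epsilon = 0)
  expect_true(all((r10$end - r10$start) == 10 * 5e4))
})

test_that("TAD validation rejects partial overlaps", {
  spec <- cohort_spec(seed = 1, tads = data.frame(start_bin = c(10L, 20L),
                                                  end_bin = c(30L, 40L)))
  expect_error(contact_mu(spec, "SHH"), "partial overlap")
})

test_that("SV operators reshape the expected matrix as stated", {
  spec <- cohort_spec(seed = 2, tau = 0, compartment_contrast = 0,
                      loop_amp = 0)
  mu <- contact_mu(spec, "G3")
  ## duplication doubles rows/cols (frac = 1) outside the junction block
  d <- apply_sv(mu, list(type = "dup", start_bin = 101L, end_bin = 140L,
                         frac = 1), alpha = 1)
  expect_equal(d[120, 300] / mu[120, 300], 2, tolerance = 1e-12)
  expect_equal(d[300, 400], mu[300, 400])
  ## inversion at frac = 1 permutes indices within the span
  v <- apply_sv(mu, list(type = "inv", start_bin = 101L, end_bin = 140L,
                         frac = 1), alpha = 1)
  expect_equal(v[101, 300], mu[140, 300], tolerance = 1e-12)
  ## translocation adds a butterfly block peaked at the breakpoints
  tr <- apply_sv(mu, list(type = "tra", bp1_bin = 100L, bp2_bin = 400L,
                          frac = 0.5), alpha = 1)
  added <- tr - mu
  expect_equal(unname(which(added[, 400] == max(added[, 400]))[1]), 100L)
  expect_gt(added[100, 400], added[80, 420])
  expect_lt(added[300, 350], added[100, 400] / 50)  # far from the corner
})
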