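test_that("arrowhead transform hits its fixed points and range", {
  bal <- balance(matrix(1, 40, 40), min_nnz = 1)
  expect_equal(arrowhead_transform(bal, 20, 5), 0)   # equal pixels -> 0

  ## M*(i, i+d) = 0, M*(i, i-d) > 0 -> +1
  Z <- matrix(1, 40, 40)
  Z[20, 25] <- 0; Z[25, 20] <- 0
  expect_equal(topohic:::arrowhead_matrix_cpp(Z, 5)[20, 6], 1)

  ## out of range -> NA flag, both-zero -> 0, |A| <= 1 on random matrices
  expect_true(is.na(topohic:::arrowhead_matrix_cpp(Z, 5)[2, 6]))
  Z2 <- matrix(0, 10, 10)
  expect_equal(topohic:::arrowhead_matrix_cpp(Z2, 3)[5, 4], 0)
  set.seed(8)
  R <- matrix(runif(900), 30, 30); R <- R + t(R)
  A <- topohic:::arrowhead_matrix_cpp(R, 10)
  expect_true(all(abs(A) <= 1, na.rm = TRUE))
})

test_that("corner score peaks at planted domains and is scale invariant", {
  spec <- three_tad_world()
  mu <- contact_mu(spec, "SHH")
  bal <- balance(mu, min_nnz = 1)
  sc <- topohic:::corner_scan_cpp(bal$matrix, 3L, 40L)
  df <- data.frame(a = sc[, 1] + 1, b = sc[, 2] + 1, S = sc[, 3])
  for (r in 1:3) {
    a0 <- spec$tads$start_bin[r]; b0 <- spec$tads$end_bin[r]
    at <- df$S[df$a == a0 & df$b == b0]
    ## the planted (a, b) outranks every locally shifted candidate
    shifted <- abs(df$a - a0) <= 6 & abs(df$b - b0) <= 6 &
      (abs(df$a - a0) >= 2 | abs(df$b - b0) >= 2)
    expect_gt(at, max(df$S[shifted], na.rm = TRUE))
  }
  ## uniform matrix: S ~ 0 everywhere
  balu <- balance(matrix(2, 60, 60), min_nnz = 1)
  scu <- topohic:::corner_scan_cpp(balu$matrix, 3L, 30L)
  expect_true(all(abs(scu[, 3]) < 1e-12, na.rm = TRUE))
  ## global scaling leaves the score unchanged (ratio form)
  s1 <- corner_score(bal, 41, 60)
  bal2 <- bal; bal2$matrix <- bal$matrix * 7.3
  expect_equal(corner_score(bal2, 41, 60), s1, tolerance = 1e-12)
})

test_that("call_domains recovers planted TADs and forbids partial overlap", {
  spec <- three_tad_world()
  hits <- 0L
  for (s in 1:6) {
    sim <- simulate_contact_map(spec, "SHH", 300 + s)
    dc <- call_domains(balance(sim$cm), L_max = 40)
    hits <- hits + sum(vapply(1:3, function(r)
      any(abs(dc$a - spec$tads$start_bin[r]) <= 1 &
            abs(dc$b - spec$tads$end_bin[r]) <= 1), logical(1)))
    ## no partial overlaps among accepted calls
    for (q in seq_len(nrow(dc))) {
      ov <- dc$a <= dc$b[q] & dc$a[q] <= dc$b
      nested <- (dc$a >= dc$a[q] & dc$b <= dc$b[q]) |
        (dc$a[q] >= dc$a & dc$b[q] <= dc$b)
      expect_true(all(!ov | nested))
    }
  }
  expect_gte(hits, 17L)               # >= 17/18 planted corners recovered

  ## theta above the maximum score gives an empty call set
  sim <- simulate_contact_map(spec, "SHH", 311)
  expect_equal(nrow(call_domains(balance(sim$cm), theta = 10)), 0L)
})

test_that("nested domains are both callable", {
  spec <- cohort_spec(seed = 6, chrom_length = 100 * 5e4, loop_amp = 0,
                      compartment_contrast = 0,
                      tads = data.frame(start_bin = c(21L, 30L),
                                        end_bin = c(70L, 45L)))
  found_parent <- 0L; found_child <- 0L
  for (s in 1:5) {
    sim <- simulate_contact_map(spec, "SHH", 410 + s)
    dc <- call_domains(balance(sim$cm), theta = 0.1, L_max = 60)
    found_parent <- found_parent +
      any(abs(dc$a - 21) <= 1 & abs(dc$b - 70) <= 1)
    found_child <- found_child +
      any(abs(dc$a - 30) <= 1 & abs(dc$b - 45) <= 1)
  }
  expect_gte(found_parent, 4L)
  expect_gte(found_child, 4L)
})

test_that("detection strength is monotone in tau", {
  means <- vapply(c(0.25, 0.5, 1.0), function(tau) {
    spec <- three_tad_world(tau = tau)
    mean(vapply(1:5, function(s) {
      bal <- balance(simulate_contact_map(spec, "SHH", 500 + s)$cm)
      mean(vapply(1:3, function(r)
        corner_score(bal, spec$tads$start_bin[r], spec$tads$end_bin[r]),
        numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("union rescoring reproduces own scores and flags absent TADs", {
  specA <- three_tad_world(seed = 21)
  ## sample B lacks the middle TAD
  specB <- cohort_spec(seed = 21, chrom_length = 100 * 5e4, loop_amp = 0,
                       compartment_contrast = 0,
                       tads = data.frame(start_bin = c(11L, 71L),
                                         end_bin = c(25L, 88L)))
  balA <- balance(simulate_contact_map(specA, "SHH", 601)$cm)
  balB <- balance(simulate_contact_map(specB, "SHH", 602)$cm)
  callsA <- call_domains(balA, L_max = 40)
  callsB <- call_domains(balB, L_max = 40)
  u <- domain_union(list(A = callsA, B = callsB))
  expect_false(any(duplicated(u[, c("start", "end", "resolution")])))
  ## rescoring a sample at its own calls reproduces the call scores
  reA <- rescore_domains(balA, callsA)
  expect_equal(reA, callsA$score, tolerance = 1e-12)
  ## the TAD only A has scores much lower in B
  mid <- which(u$a == 41 & u$b == 60)
  if (length(mid)) {
    sB <- rescore_domains(balB, u[mid, , drop = FALSE])
    sA <- rescore_domains(balA, u[mid, , drop = FALSE])
    expect_gt(sA, sB + 0.1)
  }
  ## provenance lists contributing samples
  both <- u$samples[match(paste(11, 25), paste(u$a, u$b))]
  if (!is.na(both)) expect_match(both, "A")
})

test_that("multi-resolution calling merges by bp keeping the best score", {
  spec <- three_tad_world(seed = 31)
  cm <- simulate_contact_map(spec, "SHH", 701)$cm
  multi <- call_domains_multi(cm, resolutions = c(5e4, 1e5), L_max = 40)
  expect_false(any(duplicated(multi[, c("start", "end")])))
  expect_true(all(multi$resolution %in% c(5e4, 1e5)))
  expect_error(call_domains_multi(cm, resolutions = 7e4), "multiple")
})
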