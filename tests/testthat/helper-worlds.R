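# Shared simulation worlds, memoised so expensive cohort-level fixtures are
# built once per test run.  All fixtures are generated in code; nothing is
# read from disk.

.world_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .world_cache))
    assign(key, force(expr), envir = .world_cache)
  get(key, envir = .world_cache)
}

## The default stated world: 29-sample cohort, 500 bins at 50 kb.
default_spec <- function() memo("spec", cohort_spec(seed = 1))

default_cohort <- function() memo("cohort", simulate_cohort(default_spec()))

cohort_ids <- function() {
  meta <- default_cohort()$metadata
  meta$sample_id[meta$subgroup != "WNT"]
}

cohort_balances <- function() memo("balances", {
  co <- default_cohort()
  lapply(setNames(nm = cohort_ids()), function(id) balance(co$samples[[id]]))
})

cohort_boundary_matrix <- function() memo("bmat", {
  boundary_feature_matrix(lapply(cohort_balances(), boundary_scores))
})

## All four affinity views over the default cohort (boundary, eigenvector,
## domain calls, loop calls), as used by the fusion stage.
cohort_views <- function() memo("views", {
  co <- default_cohort()
  spec <- co$spec
  ids <- cohort_ids()
  bals <- cohort_balances()
  ref <- simulate_reference_track(spec)
  doms <- list(); loops_l <- list(); eigs <- list()
  for (id in ids) {
    bal <- bals[[id]]
    doms[[id]] <- call_domains(bal, L_max = 30)
    ex <- expected_by_distance(bal)
    loops_l[[id]] <- call_loops(bal, ex)
    oe <- observed_over_expected(bal)
    eigs[[id]] <- select_and_orient(top_eigenvectors(pearson_matrix(oe)),
                                    ref, spec$chrom, spec$bin_size)$track
  }
  cfg <- fusion_config()
  du <- domain_union(doms); lu <- loop_union(loops_l)
  dmat <- t(vapply(ids, function(id)
    as.integer(paste(du$a, du$b) %in% paste(doms[[id]]$a, doms[[id]]$b)),
    integer(nrow(du))))
  lmat <- t(vapply(ids, function(id)
    as.integer(paste(lu$i, lu$j) %in%
                 paste(loops_l[[id]]$i, loops_l[[id]]$j)),
    integer(nrow(lu))))
  emat <- do.call(rbind, eigs); rownames(emat) <- ids
  list(
    boundary = affinity_matrix(distance_continuous(
      filter_features(cohort_boundary_matrix(), cfg)), cfg),
    eigen = affinity_matrix(distance_continuous(
      filter_features(emat, cfg)), cfg),
    domain = affinity_matrix(distance_binary(dmat), cfg),
    loop = affinity_matrix(distance_binary(lmat), cfg))
})

cohort_truth_labels <- function() {
  meta <- default_cohort()$metadata
  meta$subgroup[match(cohort_ids(), meta$sample_id)]
}

## Feature-isolated worlds --------------------------------------------------

## Pure decay + Poisson + planted loops: validates the loop caller against a
## background free of other focal corner structures (TAD and compartment
## block corners are genuinely locally enriched and would be flagged by any
## donut filter).
loop_world <- function(seed = 7, loop_amp = 2) {
  cohort_spec(seed = seed, tau = 0, compartment_contrast = 0,
              loop_amp = loop_amp)
}

## Three isolated TADs with gaps, no compartments or loops, on 100 bins.
three_tad_world <- function(seed = 5, tau = 1) {
  s <- cohort_spec(seed = seed, chrom_length = 100 * 5e4, loop_amp = 0,
                   compartment_contrast = 0,
                   tads = data.frame(start_bin = c(11L, 41L, 71L),
                                     end_bin = c(25L, 60L, 88L)))
  s$tau <- tau
  s
}

## One planted boundary between two TADs on a 200-bin toy.
two_tad_world <- function(beta, seed = 5, tau = 1) {
  s <- cohort_spec(seed = seed, chrom_length = 200 * 5e4, loop_amp = 0,
                   compartment_contrast = 0,
                   tads = data.frame(start_bin = c(1L, 101L),
                                     end_bin = c(100L, 200L)))
  s$tau <- tau
  s$boundary_bin <- 100L
  s$beta <- matrix(beta, nrow(s$groups), 1,
                   dimnames = list(s$groups$label, NULL))
  s
}

## Loop-call recovery metrics against planted anchors
loop_recovery <- function(calls, truth, tol = 1L) {
  tp <- sum(vapply(seq_len(nrow(truth)), function(r)
    any(abs(calls$i - truth$a1[r]) <= tol & abs(calls$j - truth$a2[r]) <= tol),
    logical(1)))
  fp <- sum(!vapply(seq_len(nrow(calls)), function(r)
    any(abs(calls$i[r] - truth$a1) <= tol & abs(calls$j[r] - truth$a2) <= tol),
    logical(1)))
  list(recall = tp / nrow(truth),
       precision = if (nrow(calls)) (nrow(calls) - fp) / nrow(calls) else NA)
}

## Rank-based AUC for separating two score sets
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}
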