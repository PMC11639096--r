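## End-to-end orchestration: simulate (or load) a cohort, extract the four
## feature classes per sample, build union feature matrices, fuse, cluster,
## test differential boundaries, associate with expression, and scan for
## SVs.  All stages run from a single config list with one master seed;
## outputs are plain-text tables plus a JSON manifest with per-stage QC.

#' Default pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @return Named list of stage parameter blocks; pass to [run_pipeline()].
#' @export
default_config <- function(outdir = tempfile("topohic_run_"), seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    simulate = list(enabled = TRUE),
    balance = list(tol = 1e-8, max_iter = 1000L, min_nnz = 10L),
    boundaries = list(w_min = 3L, w_max = 10L, z_threshold = 2.0,
                      min_separation = 2L),
    domains = list(theta = 0.2, L_min = 3L, L_max = 30L),
    loops = list(p = 2L, w = 5L, fdr = 0.1,
                 enrich = c(1.75, 1.75, 1.5, 1.5)),
    fusion = list(K = 20L, sigma = 0.3, T = 16L, C = 2L,
                  variance_keep = 0.40, max_missing = 0.05),
    nmf = list(k = 3L, n_runs = 30L),
    contrasts = list(c("SHH", "G3"), c("SHH", "G4"), c("G4", "G3")),
    diff_alpha = 0.05,
    sv = list(d_min = 2e6, k = 5L, enrich_min = 3, min_count = 25),
    exclude_groups = "WNT"
  )
}

#' Run the full pipeline on a (simulated) cohort
#'
#' Sequences balance -> compartments / domains / boundaries / loops ->
#' unions -> feature matrices -> SNF + NMF -> differential boundaries ->
#' expression association -> SV scan, writing TSV/JSON outputs and a
#' manifest with per-stage QC (including the long-range contact fraction,
#' the share of cis contacts beyond 20 kb).
#'
#' @param config List from [default_config()] (possibly modified).
#' @param cohort Optional pre-built cohort from [simulate_cohort()]; when
#'   absent one is simulated from `cohort_spec(seed = config$seed)`.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(package = "topohic",
                   version = as.character(utils::packageVersion("topohic")),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), ts, units = "secs")), 2))
    out
  }

  if (is.null(cohort))
    cohort <- stage("simulate",
                    simulate_cohort(cohort_spec(seed = config$seed)))
  spec <- cohort$spec
  meta <- cohort$metadata
  keep <- !(meta$subgroup %in% config$exclude_groups)
  ids <- meta$sample_id[keep]

  ## per-sample extraction
  bals <- list(); tracks <- list(); dom_calls <- list(); loop_calls <- list()
  eig_tracks <- list(); qc <- list()
  reference <- simulate_reference_track(spec)
  stage("features", {
    for (id in ids) {
      cm <- cohort$samples[[id]]
      df <- cm$counts
      cis_far <- sum(df$count[(df$j - df$i) * cm$bin_size > 2e4])
      qc[[id]] <- list(total = sum(df$count),
                       long_range_fraction = cis_far / sum(df$count))
      bal <- do.call(balance, c(list(cm), config$balance))
      bals[[id]] <- bal
      tracks[[id]] <- boundary_scores(bal, config$boundaries$w_min,
                                      config$boundaries$w_max)
      oe <- observed_over_expected(bal)
      eig_tracks[[id]] <- tryCatch(
        select_and_orient(top_eigenvectors(pearson_matrix(oe)), reference,
                          cm$chrom, cm$bin_size)$track,
        error = function(e) rep(NA_real_, cm$n_bins))
      dom_calls[[id]] <- call_domains(bal, config$domains$theta,
                                      config$domains$L_min,
                                      config$domains$L_max)
      ex <- expected_by_distance(bal)
      loop_calls[[id]] <- call_loops(bal, ex, p = config$loops$p,
                                     w = config$loops$w,
                                     fdr = config$loops$fdr,
                                     enrich = config$loops$enrich)
    }
    NULL
  })
  manifest$qc <- qc

  ## unions and feature matrices
  feats <- stage("feature_matrices", {
    dom_u <- domain_union(dom_calls)
    loop_u <- loop_union(loop_calls)
    bmat <- boundary_feature_matrix(tracks)
    emat <- do.call(rbind, eig_tracks)
    rownames(emat) <- ids
    ## binary presence of each union entry in each sample's call set
    dmat <- if (nrow(dom_u)) {
      t(vapply(ids, function(id)
        as.integer(paste(dom_u$a, dom_u$b) %in%
                     paste(dom_calls[[id]]$a, dom_calls[[id]]$b)),
        integer(nrow(dom_u))))
    } else NULL
    lmat <- if (nrow(loop_u)) {
      t(vapply(ids, function(id)
        as.integer(paste(loop_u$i, loop_u$j) %in%
                     paste(loop_calls[[id]]$i, loop_calls[[id]]$j)),
        integer(nrow(loop_u))))
    } else NULL
    list(boundary = bmat, eigen = emat, domain = dmat, loop = lmat,
         domain_union = dom_u, loop_union = loop_u)
  })

  ## fusion + clustering
  integ <- stage("integrate", {
    cfg <- do.call(fusion_config, config$fusion)
    if (cfg$K > length(ids) - 2L) {
      warning("fusion K clamped to n - 2 for this cohort size")
      cfg$K <- max(1L, length(ids) - 2L)
    }
    views <- list()
    fb <- filter_features(feats$boundary, cfg)
    views$boundary <- affinity_matrix(distance_continuous(fb), cfg)
    fe <- tryCatch(filter_features(feats$eigen, cfg), error = function(e) NULL)
    if (!is.null(fe))
      views$eigen <- affinity_matrix(distance_continuous(fe), cfg)
    if (!is.null(feats$domain) && ncol(feats$domain) > 1)
      views$domain <- affinity_matrix(distance_binary(feats$domain), cfg)
    if (!is.null(feats$loop) && ncol(feats$loop) > 1)
      views$loop <- affinity_matrix(distance_binary(feats$loop), cfg)
    fn <- snf_fuse(views, cfg)
    conc <- concordance_network(views, fn, cfg,
                                seed = derive_seed(config$seed, 21L))
    sc <- spectral_cluster(fn$fused, C = 3L,
                           seed = derive_seed(config$seed, 22L))
    nm <- nmf_consensus(fb, k = config$nmf$k, n_runs = config$nmf$n_runs,
                        seed = derive_seed(config$seed, 23L))
    truthlab <- meta$subgroup[match(ids, meta$sample_id)]
    list(views = views, fused = fn, concordance = conc,
         spectral = sc, nmf = nm,
         ari_spectral = adjusted_rand_index(sc, truthlab),
         ari_nmf = adjusted_rand_index(nm$labels, truthlab),
         filtered_boundary = fb)
  })

  ## differential boundaries + association per contrast
  diffs <- stage("differential", {
    out <- list()
    for (ct in config$contrasts) {
      key <- paste(ct, collapse = "_vs_")
      db <- differential_boundaries(feats$boundary, meta, ct[1], ct[2],
                                    alpha = config$diff_alpha)
      de <- de_genes(cohort$expression[, ids, drop = FALSE], meta,
                     ct[1], ct[2], alpha = config$diff_alpha)
      db$results$bp <- as.numeric(db$results$position)
      sig_bp <- db$results$bp[db$results$significant]
      assoc <- if (length(sig_bp) >= 2) {
        mid <- (spec$genes$start + spec$genes$end) / 2
        rd <- reldist(mid[match(de$gene[de$significant], spec$genes$gene)],
                      sig_bp)
        cn <- count_de_near_differential(de, spec$genes, db$results$bp,
                                         sig_bp)
        list(reldist = rd, near = cn)
      } else NULL
      out[[key]] <- list(boundaries = db, de = de, assoc = assoc)
    }
    out
  })

  ## SV scan
  svs <- stage("sv_scan", {
    calls <- list()
    for (id in ids) {
      oe <- observed_over_expected(bals[[id]])
      cov <- coverage_track(cohort$samples[[id]], cohort$samples[ids])
      calls[[id]] <- butterfly_scan(oe, spec$bin_size,
                                    d_min = config$sv$d_min,
                                    k = config$sv$k,
                                    enrich_min = config$sv$enrich_min,
                                    min_count = config$sv$min_count,
                                    raw = as_dense(cohort$samples[[id]]),
                                    coverage = cov)
    }
    list(calls = calls, recurrent = recurrent_svs(calls))
  })

  ## outputs
  stage("write", {
    write.table(meta, file.path(config$outdir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample = rownames(feats$boundary),
                           feats$boundary, check.names = FALSE),
                file.path(config$outdir, "boundary_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (key in names(diffs)) {
      df <- diffs[[key]]$boundaries$results
      write.table(df[, c("position", "z_diff", "p", "padj")],
                  file.path(config$outdir, paste0("diffbound_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report <- list(
      spectral = as.list(integ$spectral),
      nmf = as.list(integ$nmf$labels),
      silhouette = integ$nmf$silhouette,
      ari_spectral = integ$ari_spectral,
      ari_nmf = integ$ari_nmf)
    jsonlite::write_json(report, file.path(config$outdir, "clusters.json"),
                         auto_unbox = TRUE, digits = NA)
    NULL
  })

  manifest$elapsed_seconds <-
    round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  manifest$parameters <- config[setdiff(names(config), "outdir")]
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(cohort = cohort, features = feats, integration = integ,
                 differential = diffs, svs = svs, manifest = manifest))
}
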