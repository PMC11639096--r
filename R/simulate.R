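## Synthetic Hi-C cohort with planted ground truth.
##
## The generator emulates, at desk scale, the structure of a 29-sample
## medulloblastoma-like cohort: power-law distance decay, a two-state
## compartment checkerboard, TADs whose boundary strengths differ by
## subgroup, focal loops at anchor pairs, Poisson contact noise,
## negative-binomial expression with subgroup effects near selected
## boundaries, and optional planted SVs.

#' Derive a 32-bit child seed from a master seed
#'
#' Lehmer-style mixing; result is always in [1, 2^31 - 2] so it is a valid
#' input to [set.seed()] on every platform.
#'
#' @param seed Master integer seed.
#' @param k Stream index (sample number, stage number, ...).
#' @return Integer scalar.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + k * 16807) %%
               2147483646 + 1)
}

.set_rng <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
}

#' Specify a synthetic Hi-C cohort
#'
#' Defaults describe the study-like world: one 25-Mb chromosome at 50-kb
#' bins (500 bins); subgroups SHH (7), G3 (8), G4 (13), WNT (1); distance
#' decay `(1+d)^-alpha` with `alpha = 1`; alternating 2-Mb A/B compartment
#' blocks with contrast `gamma = 0.3`; TADs tiling the chromosome with
#' within-TAD enrichment `tau = 1`; baseline boundary strength `beta = 0.8`
#' with 10 designated differential boundaries where the weak group drops to
#' `beta = 0.2` (`delta beta = 0.6`): G3 is weak at the first five, G4 at the
#' last five, and WNT shares the SHH pattern.  Ten focal loops of amplitude
#' `loop_amp = 2`; 2e6 expected contacts per sample; 400 genes with
#' NB(mean, dispersion 0.1) expression and 20 four-fold DE genes placed next
#' to the differential boundaries.
#'
#' @param groups Data frame with columns `label` and `n`.
#' @param chrom,chrom_length,bin_size Chromosome name / length / bin size.
#' @param decay_exponent Distance-decay exponent `alpha`.
#' @param compartment_block_len A/B block length in bp.
#' @param compartment_contrast Checkerboard contrast `gamma` in [0, 1);
#'   0 disables compartment structure (feature-isolated worlds).
#' @param tad_len_bins Cycle of TAD lengths (bins) used to tile the
#'   chromosome.
#' @param tau Within-TAD contact enrichment.
#' @param beta_baseline Baseline boundary strength in [0, 1].
#' @param n_diff_boundaries Number of subgroup-differential boundaries.
#' @param beta_weak Strength of a differential boundary in its weak group.
#' @param n_loops,loop_amp,loop_sigma Loop count, amplitude `lambda`, and
#'   Gaussian half-width (bins).
#' @param library_size Expected total contacts `L` per sample.
#' @param n_genes,expr_mean_log,expr_sd_log,dispersion Expression model:
#'   gene count, log-normal base-mean parameters, NB dispersion `phi`.
#' @param n_de_genes Number of DE genes (fold `de_fold` in the group whose
#'   boundary is weak, placed within `de_max_dist` bp of a differential
#'   boundary).
#' @param de_fold,de_max_dist See `n_de_genes`.
#' @param ref_epsilon Fraction of bins label-flipped in the simulated
#'   active-chromatin reference track.
#' @param sv_specs Named list (by sample id or index) of lists of SV specs;
#'   each spec is `list(type = "dup"|"inv"|"tra"|"del", ...)`, see
#'   [apply_sv()].
#' @param tads Optional custom TAD layout (data frame with `start_bin`,
#'   `end_bin`, 1-based inclusive bins; gaps and nesting allowed).  When
#'   given, shared edges between adjacent TADs act as full-strength
#'   boundaries unless `boundary_bin`/`beta` are set on the returned spec;
#'   used by feature-isolated validation worlds.
#' @param seed Master seed for the cohort.
#' @return A `cohort_spec` object carrying the derived bin/TAD/boundary/gene
#'   layout and the planted truth shared by all samples.
#' @export
cohort_spec <- function(groups = data.frame(label = c("SHH", "G3", "G4", "WNT"),
                                            n = c(7L, 8L, 13L, 1L)),
                        chrom = "chrS", chrom_length = 25e6, bin_size = 5e4,
                        decay_exponent = 1.0,
                        compartment_block_len = 2e6,
                        compartment_contrast = 0.3,
                        tad_len_bins = c(12L, 18L, 10L, 15L, 20L, 14L, 8L, 16L),
                        tau = 1.0,
                        beta_baseline = 0.8,
                        n_diff_boundaries = 10L,
                        beta_weak = 0.2,
                        n_loops = 10L, loop_amp = 2.0, loop_sigma = 1.0,
                        library_size = 2e6,
                        n_genes = 400L, expr_mean_log = log(100),
                        expr_sd_log = 0.6, dispersion = 0.1,
                        n_de_genes = 20L, de_fold = 4, de_max_dist = 2e5,
                        ref_epsilon = 0,
                        sv_specs = list(),
                        tads = NULL,
                        seed = 1L) {
  stopifnot(compartment_contrast >= 0, compartment_contrast < 1,
            beta_baseline >= 0, beta_baseline <= 1,
            beta_weak >= 0, beta_weak <= 1, tau >= 0, loop_amp >= 0)
  n_bins <- as.integer(ceiling(chrom_length / bin_size))

  ## compartments: alternating blocks, first block is A
  block <- max(1L, as.integer(round(compartment_block_len / bin_size)))
  comp <- ifelse((((seq_len(n_bins) - 1L) %/% block) %% 2L) == 0L, "A", "B")

  ## TADs tile the chromosome; boundary b sits on the edge after bin end[b].
  ## A custom non-tiling or nested layout can be injected post hoc by
  ## replacing spec$tads (see contact_mu, which validates it).
  lens <- integer(0); tot <- 0L; k <- 0L
  while (tot < n_bins) {
    k <- k + 1L
    l <- tad_len_bins[((k - 1L) %% length(tad_len_bins)) + 1L]
    lens <- c(lens, min(l, n_bins - tot)); tot <- tot + l
  }
  tad_end <- cumsum(lens); tad_start <- c(1L, head(tad_end, -1L) + 1L)
  custom_tads <- !is.null(tads)
  if (!custom_tads)
    tads <- data.frame(start_bin = tad_start, end_bin = tad_end)
  if (custom_tads) {
    ## custom (possibly gapped or nested) layout: shared edges become
    ## full-strength boundaries unless the caller supplies beta afterwards
    bound_bin <- integer(0)
    n_bound <- 0L
  } else {
    n_bound <- nrow(tads) - 1L
    bound_bin <- tad_end[seq_len(n_bound)]   # edge between bin b and b+1
  }

  ## per-group boundary strengths
  labels <- groups$label
  beta <- matrix(beta_baseline, nrow = length(labels), ncol = n_bound,
                 dimnames = list(labels, NULL))
  if (n_bound >= 3L && n_diff_boundaries > 0L) {
    n_diff <- min(n_diff_boundaries, n_bound)
    diff_idx <- unique(round(seq(2, n_bound - 1, length.out = n_diff)))
  } else diff_idx <- integer(0)
  half <- ceiling(length(diff_idx) / 2)
  g3_weak <- diff_idx[seq_len(half)]
  g4_weak <- diff_idx[setdiff(seq_along(diff_idx), seq_len(half))]
  if ("G3" %in% labels) beta["G3", g3_weak] <- beta_weak
  if ("G4" %in% labels) beta["G4", g4_weak] <- beta_weak

  ## loops: anchors inside TADs, 6-14 bins apart
  big <- which(lens >= 10L)
  n_loops <- min(n_loops, length(big))
  loop_a1 <- integer(0); loop_a2 <- integer(0)
  for (q in seq_len(n_loops)) {
    t0 <- big[((q - 1L) %% length(big)) + 1L]
    a1 <- tad_start[t0] + 1L
    a2 <- min(a1 + 5L + 2L * (q %% 5L), tad_end[t0] - 1L)
    loop_a1 <- c(loop_a1, a1); loop_a2 <- c(loop_a2, a2)
  }
  loops <- data.frame(a1 = loop_a1, a2 = loop_a2)

  ## genes: deterministic layout from the master seed
  .set_rng(derive_seed(seed, 777L))
  gene_len <- 1e4
  tss <- sort(round(runif(n_genes, 0, chrom_length - gene_len)))
  base_mean <- rlnorm(n_genes, expr_mean_log, expr_sd_log)
  gene <- sprintf("gene%03d", seq_len(n_genes))
  ## DE genes: relocated next to differential boundaries, fold in weak group
  n_de <- if (length(diff_idx)) min(n_de_genes, n_genes) else 0L
  de_idx <- round(seq(1, n_genes, length.out = n_de))
  de_tab <- data.frame(gene = gene[de_idx], group = character(n_de),
                       fold = rep(de_fold, n_de),
                       boundary = integer(n_de), stringsAsFactors = FALSE)
  if (n_de > 0L) {
    per_b <- ceiling(n_de / length(diff_idx))
    for (q in seq_len(n_de)) {
      b <- diff_idx[((q - 1L) %/% per_b) + 1L]
      bp <- bound_bin[b] * bin_size
      off <- (q %% 2L * 2L - 1L) *
        round(de_max_dist * (0.3 + 0.6 * (q %% 3L) / 2))
      tss[de_idx[q]] <- max(0, min(chrom_length - gene_len, bp + off))
      de_tab$boundary[q] <- b
      de_tab$group[q] <- if (b %in% g3_weak) "G3" else "G4"
    }
  }
  genes <- data.frame(gene = gene, chrom = chrom, start = as.integer(tss),
                      end = as.integer(tss + gene_len))

  structure(list(groups = groups, chrom = chrom,
                 chrom_length = chrom_length, bin_size = as.integer(bin_size),
                 n_bins = n_bins, decay_exponent = decay_exponent,
                 compartment_contrast = compartment_contrast,
                 compartments = comp, tads = tads, tau = tau,
                 boundary_bin = bound_bin, beta = beta,
                 diff_boundaries = diff_idx,
                 g3_weak = g3_weak, g4_weak = g4_weak,
                 loops = loops, loop_amp = loop_amp, loop_sigma = loop_sigma,
                 library_size = library_size,
                 genes = genes, base_mean = base_mean,
                 dispersion = dispersion, de_genes = de_tab,
                 ref_epsilon = ref_epsilon, sv_specs = sv_specs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Expected (noise-free) contact matrix for one subgroup
#'
#' Builds the Poisson mean `mu_ij = L/Z * (1+d)^-alpha * c_ij * t_ij * l_ij`
#' where `d = |i-j|`; `c_ij = 1+gamma` when bins share a compartment label
#' and `1-gamma` otherwise; the TAD term is `1 + tau * prod(1 - beta_b)` over
#' the boundaries spanned by the pair (so a pair inside one TAD gets
#' `1 + tau`, a pair crossing a full-strength boundary falls to the non-TAD
#' baseline 1); and the loop term adds a Gaussian bump of amplitude
#' `loop_amp` at each planted anchor pair.  `Z` normalizes the expected
#' total (upper triangle including the diagonal) to `library_size`.
#'
#' @param spec A [cohort_spec()].
#' @param group Subgroup label (row of `spec$beta`).
#' @return Dense symmetric `n_bins x n_bins` matrix of expected counts.
#' @export
contact_mu <- function(spec, group) {
  n <- spec$n_bins
  idx <- seq_len(n)
  D <- abs(outer(idx, idx, "-"))
  mu <- (1 + D)^(-spec$decay_exponent)

  g <- spec$compartment_contrast
  same <- outer(spec$compartments, spec$compartments, "==")
  mu <- mu * ifelse(same, 1 + g, 1 - g)

  ## TAD term.  Base layer: maximal non-nested TADs; edges shared by
  ## adjacent base TADs carry the per-group strength beta (looked up in
  ## spec$boundary_bin, defaulting to a full boundary), gaps act as
  ## full-strength boundaries, and bins outside all TADs get no enrichment.
  ## Pair (i<j) spans edge e (between bins e and e+1) iff i <= e < j;
  ## cumulative sums over edges give prod(1 - beta) for each pair, so a
  ## within-TAD pair gets 1 + tau and a pair crossing one boundary gets
  ## 1 + tau(1 - beta).  Nested TADs multiply an extra (1 + tau) inside.
  tads <- spec$tads[order(spec$tads$start_bin, -spec$tads$end_bin), ]
  if (any(tads$start_bin > tads$end_bin) || any(tads$start_bin < 1) ||
      any(tads$end_bin > n))
    stop("invalid TAD intervals")
  base_idx <- integer(0); nested_idx <- integer(0); cover_end <- 0L
  for (r in seq_len(nrow(tads))) {
    if (tads$start_bin[r] > cover_end) {
      base_idx <- c(base_idx, r); cover_end <- tads$end_bin[r]
    } else if (tads$end_bin[r] <= cover_end) {
      nested_idx <- c(nested_idx, r)
    } else stop("TAD intervals not sorted/nested-consistent: partial overlap")
  }
  base <- tads[base_idx, , drop = FALSE]
  in_tad <- rep(FALSE, n)
  for (r in seq_len(nrow(base))) in_tad[base$start_bin[r]:base$end_bin[r]] <- TRUE
  beta_g <- spec$beta[group, ]
  edge <- numeric(0); ebeta <- numeric(0)
  if (nrow(base) > 1) for (r in seq_len(nrow(base) - 1L)) {
    e1 <- base$end_bin[r]; s2 <- base$start_bin[r + 1L]
    if (s2 == e1 + 1L) {                       # shared edge
      hit <- match(e1, spec$boundary_bin)
      edge <- c(edge, e1)
      ebeta <- c(ebeta, if (!is.na(hit)) beta_g[hit] else 1)
    } else {                                   # gap: insulate both sides
      edge <- c(edge, e1, s2 - 1L); ebeta <- c(ebeta, 1, 1)
    }
  }
  q <- 1 - ebeta
  nzero <- cumsum(tabulate(edge[q == 0] + 1L, nbins = n))
  clog <- cumsum(`[<-`(numeric(n), edge[q > 0] + 1L, log(q[q > 0])))
  span0 <- outer(nzero, nzero, function(a, b) abs(a - b)) == 0
  prodq <- exp(-abs(outer(clog, clog, "-"))) * span0
  tmat <- 1 + spec$tau * prodq * outer(in_tad, in_tad)
  for (r in nested_idx) {
    sp <- tads$start_bin[r]:tads$end_bin[r]
    tmat[sp, sp] <- tmat[sp, sp] * (1 + spec$tau)
  }
  mu <- mu * tmat

  if (nrow(spec$loops) && spec$loop_amp > 0) {
    s2 <- 2 * spec$loop_sigma^2
    bump <- matrix(0, n, n)
    for (r in seq_len(nrow(spec$loops))) {
      ga <- exp(-(idx - spec$loops$a1[r])^2 / s2)
      gb <- exp(-(idx - spec$loops$a2[r])^2 / s2)
      G <- outer(ga, gb)
      bump <- bump + G + t(G)
    }
    mu <- mu * (1 + spec$loop_amp * bump)
  }
  mu * (spec$library_size / sum(mu[upper.tri(mu, diag = TRUE)]))
}

#' Apply a structural-variant operator to an expected contact matrix
#'
#' Operates on the Poisson mean before sampling.  Types:
#' * `dup`: tandem duplication of `[start_bin, end_bin]` -- doubles the
#'   span's rows and columns and adds a through-junction contact block whose
#'   intensity decays from the (start, end) corner;
#' * `inv`: inversion -- reverses bin order within the span;
#' * `tra`: balanced translocation joining `bp1_bin` to `bp2_bin` -- adds
#'   two elevated off-diagonal wings decaying from the sharp corner at the
#'   breakpoints (the "butterfly");
#' * `del`: deep deletion -- multiplies the span's rows/columns by
#'   `residual` (default 0.02).
#'
#' @param mu Dense symmetric expected matrix.
#' @param sv List with `type` and the fields above; `frac` (default 0.5) is
#'   the clonal fraction scaling added SV contacts.
#' @param alpha Distance-decay exponent used for junction decay.
#' @return Modified dense matrix.
#' @export
apply_sv <- function(mu, sv, alpha = 1.0) {
  n <- nrow(mu)
  frac <- if (is.null(sv$frac)) 0.5 else sv$frac
  scale0 <- mean(diag(mu))            # contact level at distance 0
  if (sv$type == "dup") {
    s <- sv$start_bin; e <- sv$end_bin
    w <- rep(1, n); w[s:e] <- 1 + frac      # extra copy in `frac` of cells
    mu <- mu * outer(w, w)
    ii <- s:e
    dd <- outer(ii - s, e - ii, "+")        # through-junction distance
    J <- frac * scale0 * (1 + dd)^(-alpha)
    mu[ii, ii] <- mu[ii, ii] + J + t(J)
  } else if (sv$type == "inv") {
    s <- sv$start_bin; e <- sv$end_bin
    perm <- seq_len(n); perm[s:e] <- e:s
    full <- mu[perm, perm]
    mu <- (1 - frac) * mu + frac * full
  } else if (sv$type == "tra") {
    p1 <- sv$bp1_bin; p2 <- sv$bp2_bin
    stopifnot(p1 < p2)
    i1 <- 1:p1; j1 <- p2:n
    W1 <- frac * scale0 * (1 + outer(p1 - i1, j1 - p2, "+"))^(-alpha)
    mu[i1, j1] <- mu[i1, j1] + W1
    mu[j1, i1] <- mu[j1, i1] + t(W1)
    i2 <- p1:min(n, p2 - 1L); j2 <- max(1L, p1 + 1L):p2
    W2 <- frac * scale0 * (1 + outer(i2 - p1, rep(0, length(j2)), "+") +
                             outer(rep(0, length(i2)), p2 - j2, "+"))^(-alpha)
    keep <- outer(i2, j2, "<")               # upper triangle only
    W2[!keep] <- 0
    mu[i2, j2] <- mu[i2, j2] + W2
    mu[j2, i2] <- mu[j2, i2] + t(W2)
  } else if (sv$type == "del") {
    s <- sv$start_bin; e <- sv$end_bin
    res <- if (is.null(sv$residual)) 0.02 else sv$residual
    w <- rep(1, n); w[s:e] <- res
    mu <- mu * outer(w, w)
  } else stop("unknown SV type: ", sv$type)
  mu
}

#' Simulate one sample's raw contact matrix
#'
#' Draws Poisson counts around [contact_mu()] for the sample's subgroup,
#' after applying any SV operators.  Deterministic given `sample_seed`.
#'
#' @param spec A [cohort_spec()].
#' @param group Subgroup label.
#' @param sample_seed Integer seed for this sample.
#' @param svs Optional list of SV specs for this sample (see [apply_sv()]).
#' @return List with `cm` (a [contact_matrix()] of raw counts) and `truth`
#'   (planted compartments, TADs, per-boundary strength, loop anchors, SVs).
#' @export
simulate_contact_map <- function(spec, group, sample_seed, svs = NULL) {
  mu <- contact_mu(spec, group)
  if (!is.null(svs)) for (sv in svs)
    mu <- apply_sv(mu, sv, alpha = spec$decay_exponent)
  .set_rng(sample_seed)
  n <- spec$n_bins
  up <- upper.tri(mu, diag = TRUE)
  counts <- rpois(sum(up), mu[up])
  M <- matrix(0, n, n)
  M[up] <- counts
  cm <- dense_to_contacts(M + t(M) - diag(diag(M)), spec$chrom, spec$bin_size)
  truth <- list(compartments = spec$compartments, tads = spec$tads,
                boundary_bin = spec$boundary_bin,
                beta = spec$beta[group, ], loops = spec$loops, svs = svs)
  list(cm = cm, truth = truth)
}

#' Simulate one sample's expression counts
#'
#' Negative-binomial counts with mean `base_mean * fold` and dispersion
#' `phi` (`size = 1/phi`); `fold` differs from 1 only for the planted DE
#' genes in their affected subgroup.
#'
#' @param spec A [cohort_spec()].
#' @param group Subgroup label.
#' @param sample_seed Integer seed.
#' @return Integer vector of counts named by gene.
#' @export
simulate_expression <- function(spec, group, sample_seed) {
  .set_rng(sample_seed)
  fold <- rep(1, nrow(spec$genes))
  hit <- spec$de_genes$group == group
  if (any(hit))
    fold[match(spec$de_genes$gene[hit], spec$genes$gene)] <-
      spec$de_genes$fold[hit]
  mu <- spec$base_mean * fold
  setNames(rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
           spec$genes$gene)
}

#' Simulated active-chromatin reference track
#'
#' Emits the planted A-compartment bins as merged BED intervals, optionally
#' with a fraction `epsilon` of all bins label-flipped -- the stand-in for a
#' reference active-chromatin (H3K27ac-like) track used to orient
#' compartment eigenvectors.
#'
#' @param spec A [cohort_spec()].
#' @param epsilon Flip fraction; defaults to `spec$ref_epsilon`.
#' @param seed Seed for the flips.
#' @return Data frame `chrom`, `start`, `end` of merged A intervals.
#' @export
simulate_reference_track <- function(spec, epsilon = spec$ref_epsilon,
                                     seed = derive_seed(spec$seed, 555L)) {
  lab <- spec$compartments == "A"
  if (epsilon > 0) {
    .set_rng(seed)
    flip <- sample(spec$n_bins, round(epsilon * spec$n_bins))
    lab[flip] <- !lab[flip]
  }
  bins_to_intervals(lab, spec$chrom, spec$bin_size)
}

#' Merge a logical per-bin vector into BED intervals
#'
#' @param flag Logical vector, one entry per bin (`NA` treated as FALSE).
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @return Data frame `chrom`, `start`, `end` of maximal TRUE runs.
#' @export
bins_to_intervals <- function(flag, chrom, bin_size) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(chrom = rep_len(chrom, sum(keep)),
             start = as.integer((starts[keep] - 1L) * bin_size),
             end = as.integer(ends[keep] * bin_size))
}

#' Simulate the full cohort
#'
#' Generates one contact matrix and one expression profile per sample, with
#' per-sample seeds derived from the master seed.  Sample ids are
#' `<label><k>`; metadata mirrors a clinical sample sheet (id, subgroup,
#' sex, biotype).
#'
#' @param spec A [cohort_spec()].
#' @param contacts Set FALSE to skip Hi-C simulation (expression only).
#' @return List with `samples` (named list of [contact_matrix()]),
#'   `expression` (gene x sample integer matrix), `metadata` (data frame),
#'   `truth` (per-sample planted truth), and `spec`.
#' @export
simulate_cohort <- function(spec, contacts = TRUE) {
  meta <- do.call(rbind, lapply(seq_len(nrow(spec$groups)), function(g) {
    data.frame(sample_id = sprintf("%s%02d", spec$groups$label[g],
                                   seq_len(spec$groups$n[g])),
               subgroup = spec$groups$label[g])
  }))
  meta$sex <- rep_len(c("M", "M", "F"), nrow(meta))
  meta$biotype <- c(rep("surgical", nrow(meta) - 1L), "PDX")
  samples <- list(); truth <- list()
  expr <- matrix(0L, nrow(spec$genes), nrow(meta),
                 dimnames = list(spec$genes$gene, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    id <- meta$sample_id[s]
    svs <- NULL
    if (length(spec$sv_specs)) {
      if (!is.null(names(spec$sv_specs))) {
        if (id %in% names(spec$sv_specs)) svs <- spec$sv_specs[[id]]
      } else if (length(spec$sv_specs) >= s) svs <- spec$sv_specs[[s]]
    }
    if (contacts) {
      sim <- simulate_contact_map(spec, meta$subgroup[s],
                                  derive_seed(spec$seed, s), svs = svs)
      samples[[id]] <- sim$cm
      truth[[id]] <- sim$truth
    }
    expr[, s] <- simulate_expression(spec, meta$subgroup[s],
                                     derive_seed(spec$seed, 10000L + s))
  }
  list(samples = samples, expression = expr, metadata = meta,
       truth = truth, spec = spec)
}

#' Promoter intervals for the simulated genes
#'
#' TSS +/- `flank` bp, clipped to the chromosome.
#'
#' @param spec A [cohort_spec()].
#' @param flank Half-width in bp (default 3 kb).
#' @return Data frame `chrom`, `start`, `end`, `name`.
#' @export
promoter_track <- function(spec, flank = 3e3) {
  tss <- spec$genes$start
  data.frame(chrom = spec$chrom,
             start = as.integer(pmax(0, tss - flank)),
             end = as.integer(pmin(spec$chrom_length, tss + flank)),
             name = spec$genes$gene)
}
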