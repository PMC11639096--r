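# topohic

Topological feature extraction and multi-view subgroup discovery from Hi-C
contact maps.

Medulloblastoma and other tumors are classified into molecular subgroups by
transcription and mutation profiles; whether the 3D genome carries the same
signal is a quantitative question about Hi-C-derived features.  `topohic`
implements the full analysis path for binned intra-chromosomal contact
matrices:

* **Matrix models** — iterative-proportional-fitting balancing (equal row
  sums, bias vector `b` with `balanced(i,j) = raw(i,j) b_i b_j`), the
  distance-expected profile `e(d)`, observed/expected transforms, and the
  Pearson correlation map.
* **A/B compartments** — eigenvectors 1–3 of the Pearson matrix, selected
  and sign-oriented by bp-Jaccard against an active-chromatin reference so
  positive values mark type A.
* **Contact domains (TADs)** — an arrowhead-style transform
  `A(i,i+d) = (M(i,i−d) − M(i,i+d)) / (M(i,i−d) + M(i,i+d))` with a corner
  score over candidate triangles, greedy non-partially-overlapping
  selection, and cross-cohort union re-scoring.
* **Boundary (insulation) scores** — at each inter-bin edge, distance-
  matched Mann–Whitney comparisons of within- vs cross-edge contacts,
  Stouffer-combined over distances, maximized over windows of 150–500 kb,
  standardized per sample.
* **Loops** — donut / lower-left / stripe local expected models
  `λ_N = e(d) Σ_N M / Σ_N e` with upper-tail Poisson tests, BH within
  log-spaced distance strata, enrichment gates, pixel-cluster merging, and
  union re-scoring; anchors annotated against promoters.
* **Subgroup discrimination** — per-view squared-Euclidean or Jaccard
  distances, the scaled-exponential affinity kernel (K = 20, σ = 0.3),
  similarity network fusion (T = 16 cross-diffusion rounds), distance
  `0.5 − similarity`, spectral clustering, view-vs-fused concordance
  (NMI at C = 2), and consensus NMF (k = 3) with silhouettes.
* **Differential boundaries and expression association** — two-sided Welch
  t per position with BH `padj`, a Welch-on-log2-CPM differential
  expression stand-in, and BEDTools-style `reldist` / `closest` / 1-Mb
  window association.
* **SV scanning** — coverage-based copy-number segments and a "butterfly"
  block-enrichment scanner that localizes breakpoints at the O/E
  discontinuity corner and flags recurrence across samples.
* **Synthetic cohort** — a generator with planted ground truth: power-law
  distance decay `(1+d)^{-α}`, a compartment checkerboard (contrast γ),
  TADs whose boundary strengths β differ by subgroup, Gaussian loop bumps,
  Poisson contact noise, negative-binomial expression with DE genes near
  differential boundaries, and optional planted SVs.

## Worked example

```r
library(topohic)

spec   <- cohort_spec(seed = 1)          # 7 SHH / 8 G3 / 13 G4 / 1 WNT,
cohort <- simulate_cohort(spec)          # 500 bins of 50 kb, L = 2e6

ids    <- cohort$metadata$sample_id[cohort$metadata$subgroup != "WNT"]
tracks <- lapply(cohort$samples[ids],
                 function(cm) boundary_scores(balance(cm)))
bmat   <- boundary_feature_matrix(tracks)

cfg <- fusion_config()                   # K = 20, sigma = 0.3, T = 16
fb  <- filter_features(bmat, cfg)        # <5% missing, top 40% variance
W   <- affinity_matrix(distance_continuous(fb), cfg)
lab <- spectral_cluster(snf_fuse(list(W), cfg)$fused, C = 3, seed = 11)
adjusted_rand_index(lab, cohort$metadata$subgroup[match(ids, cohort$metadata$sample_id)])
#> [1] 1

db <- differential_boundaries(bmat, cohort$metadata, "G3", "G4")
db$summary
#> $tested
#> [1] 495
#> $significant
#> [1] 48
#> $percent
#> [1] 9.7
```

The ARI of 1 says the boundary-score view alone separates the three planted
subgroups perfectly; the differential summary reports that 9.7% of testable
boundary positions differ between the G3 and G4 analogs at `padj < 0.05`
(48 significant positions out of 495, driven by the 10 planted
differential boundaries plus their neighborhoods).

## Command line

```sh
Rscript inst/cli/topohic.R simulate --outdir sim --seed 3
Rscript inst/cli/topohic.R boundaries --in sim/G301.coo \
    --bin-size 50000 --chrom-length 25000000 > boundaries.bedgraph
Rscript inst/cli/topohic.R pipeline --outdir run1 --seed 1
```

Formats: COO contact text (`chrom i j count`, 0-based upper-triangle
bins), BED3/6, bedGraph (undefined values as `nan`), BEDPE, and a
gene/chrom/start/end + samples counts TSV.  All coordinates are 0-based
half-open.
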