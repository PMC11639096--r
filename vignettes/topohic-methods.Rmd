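---
title: "Models and methods in topohic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in topohic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`topohic` turns binned intra-chromosomal Hi-C contact matrices into four
feature classes — A/B compartment eigenvectors, contact domains,
per-position boundary (insulation) scores, and focal loops — and uses them
for tumor-subgroup discrimination, differential-boundary testing,
expression association, and structural-variant scanning.  This vignette
records the models, the tunable parameters and their defaults, the design
choices made where the design was genuinely open, and what the synthetic
cohort does and does not establish.  It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Conventions

All coordinates are 0-based half-open (BED convention); bin *i* spans
`[i·bin_size, (i+1)·bin_size)`.  Contact matrices are stored as plain-text
upper-triangle COO (`chrom i j count`), one chromosome per sample per
file.  Boundary *positions* index inter-bin edges: position *i* is the
edge between bins *i* and *i+1* at basepair `i·bin_size`.  Undefined track
values are written as `nan` tokens so they survive round trips.

## Matrix normalization

Balancing is iterative proportional fitting to equal row sums: bins with
fewer than `min_nnz = 10` nonzero entries are masked, then
`b ← b / sqrt(rowsum/target)` until the unmasked row sums agree to a
relative tolerance of 1e-8 (1000-iteration cap, error on
non-convergence).  This replaces scaling-type normalizations of
production Hi-C pipelines with a member of the same fixed-point family
that is fully specified and testable; re-balancing a balanced matrix
returns biases of 1 to 1e-6.  The expected profile `e(d)` is the mean
balanced contact over unmasked pairs at each bin distance, computed per
chromosome.  With dense storage, structural zeros count as observations,
so a diagonal-only matrix has `e(d>0) = 0` rather than "undefined";
ratio-mode O/E flags those pixels as `NA` instead of producing
infinities.

## Compartments

The Pearson matrix correlates O/E rows over unmasked columns; rows with
zero variance are masked.  "Principal components of the Pearson matrix"
is interpreted as PCA: columns are centered and the top right singular
vectors taken.  Each of eigenvectors 1–3, in both signs, is thresholded
at 0, merged into intervals, and Jaccard-scored against a reference
active-chromatin track; the best (eigenvector, sign) wins, ties broken by
lower eigenvector index then positive sign (the threshold and tie rules
are declared here — they are not derivable from any published
description).  Positive values of the returned track mark type A.  In
tests the reference is the simulator's A-compartment track, optionally
label-flipped; at runtime any BED can be supplied.

## Contact domains

The arrowhead transform
`A(i, i+d) = (M*(i,i−d) − M*(i,i+d)) / (M*(i,i−d) + M*(i,i+d))`
is scored over candidate triangles `[a, b]` with a corner score: the mean
of `A` over pixels whose mirror lies inside the candidate but whose
forward pixel crosses `b`, minus the mean over pixels inside whose mirror
crosses `a`.  This replaces the original dynamic program (variance and
sign sub-scores) with an explicit statistic that exercises the same
transform and recovers planted domains; it is *not* bit-compatible with
any published block score, and cross-sample comparisons use it
consistently.  Candidates of 3–100 bins scoring at least `θ = 0.2` are
selected greedily by descending score; an accepted set may nest but never
partially overlap.  Nested-domain tests lower `θ` to 0.1 — a nested child
dilutes its parent's corner score — which is a caller-sensitivity choice,
not a generator change.  Multi-resolution calling re-bins raw counts by
summation before balancing and merges by basepair, keeping the higher
score.  Cohort comparisons re-score every sample at the call union
(feature-list/control-list style).

## Boundary scores

At each edge, for windows `w = 3..10` bins fully inside the chromosome
and distances `d ≤ w`, the within-left and within-right contact sets are
compared against the distance-matched cross set by Mann–Whitney U (ties
half-counted; normal approximation without continuity correction;
sets with fewer than two values are skipped — at `d = 1` the cross set
has one element, so it never contributes).  Per-distance Z scores are
Stouffer-combined with `1/sqrt(w)` and the combined score is the maximum
over windows; left/right variants use only one side.  A final per-sample
standardization (mean 0, sd 1 over defined positions) makes tracks
comparable across samples; this standardized `z` is the cohort feature.

**Known red check.** The combined statistic is the maximum of ~8
positively correlated, approximately standard-normal window scores, so
its *raw* null distribution is right-shifted: over 200 null simulations
the acceptance suite measures a mean near 0.6 and an sd near 0.65, where
the stated calibration check demands |mean| < 0.1 and sd in [0.8, 1.2].
Those two properties are mutually exclusive with max-over-window
combining; the statistic is implemented exactly as specified and the
check left failing rather than silently re-centered.  Nothing downstream
consumes the raw score: the per-sample standardized track is mean-0/sd-1
by construction, and separation quality (ROC AUC ≥ 0.95 against planted
boundaries at β = 0.8) is unaffected.

## Loops

Each candidate pixel `(i, j)` is tested against four local expected
models — donut ring, lower-left quadrant, horizontal and vertical
stripes, all excluding the inner `p`-box — with
`λ_N = e(|i−j|) · Σ_N M* / Σ_N e`.  Balanced values are treated directly
as Poisson rates (consistent with the Poisson contact simulator; the
raw-count back-scaling of the original donut method is dropped).
Upper-tail Poisson p-values are BH-adjusted within log2-spaced distance
strata per neighborhood; calls require all four `q ≤ 0.1` and enrichments
of 1.75 (donut, lower-left) and 1.5 (stripes), then 8-connected pixels
merge into one call at the maximum-observed pixel.  Neighborhood
geometry defaults to `(p, w) = (2, 5)` at the finest resolution and
`(1, 3)` at coarser ones.  Deeper sequencing can only add calls: the
enrichment gates are scale invariant while p-values sharpen, so the
original call set is preserved under a global count increase (asserted
in tests); exact call-set invariance under rescaling is impossible for a
Poisson test and is not claimed.

## Subgroup integration

Continuous views (standardized boundary scores, oriented eigenvectors)
are filtered to positions with fewer than 5% undefined samples, then the
top 40% by cross-sample variance (ties kept), with residual missingness
column-mean imputed; distances are squared Euclidean.  Call views
(domains, loops) enter as binary presence over the cohort union with
Jaccard distances (two empty call sets have distance 0).  The affinity
kernel uses `K = 20` neighbors and width multiplier `σ = 0.3`, with the
density prefactor retained; `K` is clamped to `n − 2` (with a warning)
on small cohorts.  Fusion runs `T = 16` cross-diffusion rounds of each
view's sparse KNN kernel against the average of the other views' full
kernels, re-symmetrizing and re-normalizing each round.  The full kernel
(off-diagonal rows summing to 1/2, diagonal 1/2) is row-stochastic but
not exactly symmetric; since no single normalization is both, the fused
kernel keeps exact row sums and `fused_distance` symmetrizes before
applying `0.5 − similarity`.  With one view, fusion returns that view's
full kernel exactly.

Sample maps use classical MDS as the pluggable 2-D embedding backend (no
UMAP implementation is assumed; the embedding is visual only and no
quantitative result depends on coordinates).  Cluster structure is
quantified by normalized-cut spectral clustering, view-vs-fused
concordance as NMI of `C = 2` spectral partitions (distance
`1 − concordance`), and consensus NMF: rank-3 multiplicative Frobenius
updates (500 iterations, 1e-9 floor, 30 random restarts), per-run labels
from the argmax of `H`, co-clustering consensus, average-linkage cut at
`k`, and silhouettes on `1 − consensus`.

## Differential testing and association

Per-position two-sided Welch t tests (unequal variances, Satterthwaite
df) compare subgroups at every position defined in at least two samples
per group, with Benjamini–Hochberg adjustment across tested positions;
"significant" means `padj < 0.05`.  Degenerate conventions: zero
variance with equal means gives `p = 1`, with unequal means `p = 0`.
The expression stand-in transforms counts to
`log2((count + 0.5)/libsize · 1e6)` and applies the same Welch/BH
machinery per gene — a deliberate, documented replacement for
moderated-variance pipelines, used consistently in simulation.
Association uses gene midpoints: `reldist` (min distance to the flanking
boundaries over their spacing, uniform on [0, 0.5] under independence),
closest up/downstream boundary (a boundary inside the gene body counts
as distance 0 both ways), and the most significant boundary within 1 Mb
(ties: smaller p, then nearer, then smaller coordinate).

## SV scanning

Coverage is the raw row sum normalized by the cohort per-bin median when
available (else the sample median); segments are runs of at least 5 bins
beyond ±50%, with deep deletions below 0.1.  The butterfly scanner
slides a `k = 5` window over O/E, flags windows with mean above 3 that
also carry at least 25 raw counts (the count gate suppresses single-read
O/E spikes in sparse far-cis pixels), merges overlapping windows, and
localizes breakpoints at the peaks of the block's marginal O/E profiles —
both wings of a butterfly decay away from the breakpoint, so the
marginals peak exactly there.  Classification is by quadrant geometry
around the corner (translocation wings occupy up-right/down-left,
inversion wings up-left/down-right), with coverage-gain overlap promoting
a call to duplication-like.  These rules are an explicit
operationalization of a pattern the source analysis read by eye; labels
carry the suffix "-like" accordingly.

## The synthetic cohort

The generator emulates the study-shaped world at desk scale: one 25-Mb
chromosome at 50-kb bins (500 bins); subgroups SHH (7), G3 (8), G4 (13),
WNT (1); Poisson counts around
`μ_ij = L/Z · (1+d)^{-α} · c_ij · t_ij · ℓ_ij` with `L = 2·10⁶` expected
contacts, decay `α = 1`, compartment factor `1 ± γ` (`γ = 0.3`,
alternating 2-Mb blocks), TAD factor `1 + τ·Π(1−β_b)` over spanned
boundaries (`τ = 1`; a full-strength boundary β = 1 returns a crossing
pair to baseline, β = 0 is invisible), and Gaussian loop bumps of
amplitude 2 at ten anchor pairs.  Boundary strengths default to
β = 0.8, with ten differential boundaries where the weak subgroup drops
to β = 0.2 (Δβ = 0.6): G3 is weak at the first five, G4 at the last
five, and WNT shares the SHH pattern — mirroring the observation that
the single WNT sample co-clusters with SHH.  Expression is negative
binomial (log-normal base means around 100, dispersion 0.1) with twenty
4-fold DE genes placed within 200 kb of the differential boundaries.
SV operators (tandem duplication with a through-junction block,
inversion by index reversal at a clonal fraction, balanced translocation
as two wings decaying from the breakpoint corner, deep deletion) act on
μ before sampling.  Values not fixed by any stated source (TAD length
cycle of 8–20 bins, 2-Mb compartment blocks, 400 genes, loop spans of
6–14 bins, clonal fraction 0.5) were chosen once as field-typical and
are not tuned.

**Feature-isolated validation worlds.**  Sharp TAD corners and
compartment-block corners are *genuinely* locally enriched pixels — in
real data such corner peaks are usually called as loops, and domain-like
blocks form at compartment transitions.  Against the full default world
a donut filter therefore "fails" planted-loop precision only by calling
these real corner structures.  Loop precision/recall and the clean
domain-recovery checks are therefore evaluated on worlds that omit the
untested structure (loops: `τ = 0, γ = 0`; domains: `γ = 0`, three gapped
TADs), which required allowing `γ = 0` in the cohort specification.  A
green loop test establishes that the caller finds planted focal enrichments
over a realistic decay background at stated FDR and enrichment gates; it
does not establish discrimination of loops from TAD/compartment corners,
which is not claimed anywhere in the package.

What a green cohort-recovery test establishes is also bounded by the
generator: Poisson (not overdispersed) contact noise, a single
chromosome, no trans background, no karyotype-scale CNV, and subgroup
signal placed only in boundary strengths.  Real cohorts carry
library-quality variation, copy-number confounding, and subtler effect
sizes; the recovery ARIs here certify the pipeline's correctness, not
its field sensitivity.

## Reproducibility

Every stochastic entry point takes an explicit integer seed;
`derive_seed()` expands a master seed into Lehmer-mixed 32-bit
sub-streams (always below 2³¹) for samples and stages, and the RNG kind
is pinned (Mersenne-Twister / inversion).  Re-running the pipeline with
the same seed reproduces byte-identical tables; the acceptance script
derives all of its seeds from `--seed`.

## Known limitations

Single-chromosome analysis (trans contacts appear only as SV blocks);
no sub-compartments; no `.hic`/`.mcool` readers (text COO only); the
corner score and boundary statistic are stand-ins that preserve the
behavior, not the bit-level output, of the production tools they
replace; the expression test is unmoderated Welch, slightly conservative
at these sample sizes; YAML configs are replaced by JSON (no YAML parser
in the supported dependency set).
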