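---
title: "Pseudo-bootstrap network analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-bootstrap network analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pbsnet)
```

## The idea

Network analyses of brain imaging data need nodes, and nodes come from a
parcellation of gray matter. No parcellation is canonical: template
atlases impose one fixed, somewhat arbitrary sampling of the cortex on
every subject. `pbsnet` takes the opposite view: treat the parcellation
itself as a resampling device. Generate many random parcellations with
the *same* number of roughly equal-sized, spatially contiguous parcels,
build one network per parcellation, and treat the resulting per-
parcellation global metrics as a pseudo-bootstrap (PBS) sample of the
subject's underlying connectome. The ensemble yields distributions of
global metrics instead of point estimates, a variance decomposition
(how much of the metric variation is due to parcellation, scan
repetition, or subject identity), more reliable test–retest ICCs via
ensemble means, and — perhaps most strikingly — a subject fingerprint
built from nothing but the *mean* functional connectivity traced across
the ensemble.

Node identities are not comparable across parcellations; that is the
premise, not a defect. Only global (whole-network) quantities are
compared across the ensemble, and node-level group comparisons are
deliberately out of scope.

## Random parcellation

### The distance the algorithm grows in

Voxels of the gray-matter mask form a graph: 26-adjacent voxels are
joined by edges weighted 1, √2 or √3 according to whether they share a
face, an edge or only a vertex. The geodesic distance G(i,j) is the
shortest weighted path between voxels *inside the mask* — distances wrap
around sulci rather than cutting across them, which is what makes
Euclidean seed spreading fail on cortex. Distances are in lattice units
(voxel edge = 1); anisotropic voxel sizes are recorded as metadata but
do not enter the metric, since the method is used on resampled,
near-isotropic masks.

Geodesic distance alone still over-allocates voxels to seeds sitting in
densely packed cortex. The local density field
L(i) — the sum of geodesic distances from voxel i to its M nearest mask
voxels, with M = ⌊V/N⌋ the expected parcel size — measures how crowded
the neighbourhood of i is (small L = crowded). The growth metric is

D(i,j) = 2 G(i,j) / (L(i) + L(j)),

so that pairs in dense cortex count as farther apart: seeds spread into
dense regions, and growth is slowed there. The typeset form of this
formula in the source literature is ambiguous (the fraction bar is
lost); the denominator reading is adopted because the text describes the
geodesic distance as *weighted by* local density and the weighting must
shrink distances where density is high for the stated purpose (size
equalisation) to come out.

### Seeds and growth

The first seed is drawn uniformly from the mask (the only random step);
every later seed is placed deterministically at the voxel maximising the
minimum D to all already-placed seeds (farthest-point sampling). Argmax
ties break to the lowest linear voxel index, so one `(mask, N,
rng_seed)` triple always reproduces the same parcellation bit for bit.

Growth is *balanced iterative growing*: regions take turns in label
order, and on its turn a region claims the unassigned frontier voxel
with the smallest D from its seed (D accumulated along the growth tree),
then exposes that voxel's neighbours. A region walled in by its
neighbours drops out of the cycle. Two properties follow by
construction: every parcel is 26-connected (each voxel attaches through
an already-labelled neighbour), and parcel sizes stay nearly equal,
because regions grow at equal *voxel* rates rather than equal distance
rates — the residual size variation comes from early blocking.

This growth schedule was a genuinely open design point. We implemented
the obvious alternative first — simultaneous Dijkstra fronts, i.e.
nearest-seed assignment under D — and found it produces SD/mean size
ratios around 18% on smooth synthetic shells at every scale we tried
(8k–24k voxels, N = 100–500): equal-radius growth simply is not
equal-size growth, and farthest-point seeding alone cannot close the
gap. Balanced growing brings the ratio to 4–6% with IQR/median ≈ 0.06
and NMV ≈ 25–50%, the homogeneity regime the method needs. The Dijkstra
schedule remains available as `method = "dijkstra"`; on a uniform
density field it is exact multi-source Dijkstra and is used as an oracle
in the tests. No Lloyd-style re-seeding is performed — a single
placement + growth pass generates each sample, keeping ensemble members
statistically independent given their first seeds.

Ensembles (`pbs_sample`) use consecutive RNG seeds `base_seed + 0, 1,
…`, so any ensemble is reproducible from one integer.

### Parcel-size statistics

`parcel_size_stats` reports the SD-to-mean ratio (%), the
inter-quartile-range-to-median ratio (type-7 linear-interpolation
quantiles — stated because the IQR targets depend on the quantile
convention), and the normalized maximum variation
NMV = (max − min)/min × 100%.

## Networks per parcellation

**Structural.** A streamline connects parcels (i, j) iff its two
terminal points fall in parcels i and j (nearest-voxel lookup of the two
endpoints only — the simplest defensible endpoint rule; intra-parcel and
off-mask streamlines are excluded and counted). Edge weights follow

w_ij = 2/(n_i + n_j) · Σ_m 1/L_ij^m,

fiber count normalized by node volume, each fiber penalised by its arc
length; pairs with fewer than 10 fibers are zeroed to suppress spurious
tracts. The surrounding literature describes this weight in words as a
count "normalized by mean volume and mean fiber length", which is a
slightly different estimator; both are implemented
(`normalization = "harmonic"` (default) vs `"mean_length"`), the
displayed-formula default winning because it is the formula actually
printed. Tractography itself is out of scope: the package consumes
co-registered streamlines (a plain JSON point-list dialect; no installed
R reader for TRK/TCK exists, so conversion is the caller's job).

**Functional.** Voxel time series are residualised on an intercept plus
confound regressors (motion, white matter, CSF — whatever the caller
supplies) by QR least squares *before* parcel averaging; node series are
the means of member-voxel series; edges are Pearson correlations. The
diagonal is stored as zero so ensemble averages run over distinct pairs;
negative correlations are retained; no Fisher transform is applied
(none is described for the method being implemented). For signed
matrices the graph metrics below use positive weights only, except
strength, which keeps the sign — a convention, flagged as such.

## Global metrics and PBS statistics

Six global metrics per network: mean binary degree, mean strength,
mean weighted clustering (Onnela geometric-mean form on weights scaled
by the maximum), global efficiency (mean inverse shortest path on 1/w
edge costs), modularity (best Newman Q over 20 seeded Louvain restarts
— deterministic given the seed, non-decreasing in restarts), and mean
diversity (Shannon entropy of each node's strength distribution across
the Louvain modules, normalized by log m). Which clustering and
diversity formulations the original analyses used is not documented;
the Onnela and Rubinov–Sporns forms are the standard choices in weighted
brain-network toolkits and are stated here as conventions — published
magnitude tables for these metrics are therefore *not* reproduction
targets, only their qualitative patterns are.

PBS ensemble statistics:

- `pbs_metric_distribution` — per-metric ensemble moments plus a
  Lilliefors normality test (skipped below 20 samples or for constant
  vectors).
- `variance_decomposition` — σ_parcellation (SD across the ensemble,
  scan 1, averaged over subjects), σ_BS = √(mean over subjects of the
  squared difference of the two scans' PBS means), σ_subject (SD across
  subjects of scan-1 PBS means).
- `icc` — ICC(1,1), one-way random effects, (MS_B − MS_W)/(MS_B +
  (k−1)MS_W); negative values are legitimate under this estimator,
  which is why it was chosen over the two-way variants (those are
  available behind `type`).
- `icc_comparison` — ICC of the ensemble means vs the mean of
  per-parcellation ICCs. Averaging removes parcellation noise from the
  within-subject variance, so the former exceeds the latter whenever
  parcellation noise is independent across parcellations; the p-value
  is a one-tailed one-sample t-test of the per-parcellation ICC sample
  against the ICC of means (the paired/one-sample choice is not
  documented in the source analyses; one-sample is used).

## Fingerprinting from the mean-FC vector

Per subject and session, the mean off-diagonal FC of each ensemble
parcellation forms the mean-FC vector (mFCV) — ensemble-length, rank-
ordered, comparable across subjects only because the i-th parcellation
is the same label volume for everyone. Similarity between two mFCVs is
their Pearson correlation ("cross-correlation" in the fingerprinting
literature; a lagged reading is meaningless here because the ensemble
axis is unordered), and each subject in one session is identified as
the argmax-similarity subject of the other session, in both directions.
`accuracy_vs_samples` traces accuracy against sub-ensemble size using
shared without-replacement subsets (≥ 2 samples — a Pearson similarity
needs at least two points; the single-parcellation baseline is instead
`identify_matrix_baseline`, which correlates vectorized upper triangles
of full FC matrices, the classic fingerprinting measure).

## Synthetic data: what it emulates, and what it does not

The generators exist so that every estimator can be validated against
known ground truth ("dial-a-truth"); they are deliberately minimal.

- `synth_mask` — hollow-ellipsoid shells (radius ratios 1 : 1.25 :
  0.85, default thickness 30% of the outer radius) with a smooth
  sinusoidal folding of the surface, bisection-scaled to a target voxel
  count within 5%, largest 26-connected component kept. This emulates
  the closed, curved, variable-density geometry of a cortical sheet —
  not gyral anatomy.
- `synth_streamline_cohort` — a latent connectome on a reference
  parcellation with distance-dependent connection probability and mean
  fiber count (decay length 20% of the mask diameter): geometric
  structure is what survives re-parcellation, as in real connectomes
  where short-range fibers dominate. Subject effects are log-normal
  (a global scale plus a per-pair pattern, SD 0.4, stable across
  scans); scan effects are log-normal (global plus per-pair, SD 0.15);
  counts are Poisson; streamlines are straight two-point polylines with
  endpoints on voxel centres drawn uniformly inside the two parcels.
  The defaults (20 subjects, two scans) were fixed by pilot simulation
  so that the variance decomposition shows σ_parcellation below the
  scan and subject components for the scale-carrying metrics (degree,
  strength, efficiency) — the qualitative pattern reported for real
  cohorts, where the same published tables also show that the
  scale-free partition metrics (clustering, diversity, modularity) do
  not obey the full ordering; the tests assert accordingly.
- `synth_bold_cohort` — per subject, smooth sinusoidal spatial loading
  fields (fixed across sessions: the identity signal) times
  session-specific white temporal factors, plus white noise and
  injected smoothed confound components; sessions are generated lazily
  and reproducibly so large cohorts never sit in memory. Defaults
  (50 subjects, T = 300, 6 factors, unit signal and noise) were fixed
  by a pilot run in which cross-session identification from 400-sample
  mFCVs is essentially perfect and collapses to chance when the signal
  is zeroed. No hemodynamics, no realistic motion, no MR physics.
- `synth_metric_cohort` — draws metric values directly from the
  additive model G = μ + subject + scan + parcellation-noise; the
  estimator-validation workhorse. Note the estimators' population
  values under this model: σ_BS estimates √(2σ_scan² + 2σ_parc²/P) and
  σ_subject estimates √(σ_subj² + σ_scan² + σ_parc²/P); with the
  default P = 50 these inflations are 1–5%, well inside the 15%
  recovery tolerance used in the tests.

Passing tests on these generators show the estimators and the pipeline
are correct and well-calibrated under controlled conditions; they do
not show that real dMRI or BOLD data satisfy those conditions.

## Numerical choices and degenerate inputs

- Exact Dijkstra (binary heap) everywhere; the truncated search for
  L(i) settles nodes in (distance, index) order so the M-nearest set is
  deterministic under ties. All-pairs results on ≤ 300-voxel masks are
  tested against Floyd–Warshall to 1e-10.
- Disconnected masks are reduced to their largest 26-connected
  component with a warning (seed placement across components is
  undefined); unreachable queries return Inf with a warning.
- Empty networks yield all-zero metrics with a warning; degenerate ICC
  tables (zero total variance), zero-variance node series and
  zero-variance mFCVs raise errors naming the offending units.
- Similarity argmax ties (measure-zero generically) break to the lowest
  subject index with a warning.

## Problem sizes used in the checks

The published statistics this package reproduces were computed on
~90k-voxel cortical masks with ensembles of 200–600 parcellations. The
test suite and the acceptance script run the identical estimators at
desk scale, chosen so the whole suite completes on one CPU core in
minutes: a ~15k-voxel shell with 20-trial ensembles at N = 500 and 1000
(and 100 trials at N = 250) for the parcel-size statistics — which are
scale-stable in our measurements from 9k to 24k voxels, provided the
expected parcel size stays above ~15 voxels — and a ~2.2k-voxel shell,
50 subjects, 400 parcellations for the fingerprinting cohort.

## Known limitations

- Surface-based parcellation, sub-voxel geometry and partial-volume
  weighting are out of scope; the mask is a binary lattice.
- Anisotropic voxel dimensions do not enter the distance metric.
- The balanced growth schedule trades the clean "nearest seed under D"
  characterisation for size homogeneity; parcels are contiguous and
  near-equal-sized but not D-Voronoi cells.
- Louvain is a heuristic; Q is the best of 20 seeded restarts, not a
  global optimum (the exhaustive oracle in the tests covers n ≤ 8).
- Fingerprinting assumes the same subjects in both sessions, in the
  same row order.
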