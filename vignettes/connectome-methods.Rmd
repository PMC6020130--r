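---
title: "Methods: from diffusion signal to network statistics"
author: "dtiConnectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from diffusion signal to network statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models each
stage implements, the parameters that matter, what the synthetic data
emulate (and do not), and the numerical decisions taken where the
design was genuinely open.

## The diffusion tensor stage

Each voxel's diffusion-weighted signal is modelled by the
monoexponential tensor law

$$S(\mathbf{g}) = S_0 \exp(-b\,\mathbf{g}^\top D\, \mathbf{g}),$$

with $D$ a symmetric positive 3×3 tensor, $b$ the diffusion weighting
(s/mm²) and $\mathbf{g}$ a unit gradient direction. `fitTensor()`
solves the log-linearized system $\ln S = \ln S_0 - b\,\mathbf{g}^\top
D\,\mathbf{g}$ by ordinary least squares for the six unique tensor
elements plus $\ln S_0$ — the classic DTIFIT-style fit, chosen over
weighted or nonlinear variants because it admits an exact oracle: on
noiseless synthetic data the recovered tensor equals the generating
tensor to machine precision, which the test suite asserts at a 1e-10
relative tolerance.

From the sorted eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$ we
derive axial diffusivity $\mathrm{AD} = \lambda_1$, radial diffusivity
$\mathrm{RD} = (\lambda_2 + \lambda_3)/2$, mean diffusivity
$\mathrm{MD} = \bar\lambda$, and fractional anisotropy

$$\mathrm{FA} = \sqrt{\tfrac{3}{2}}\;
\frac{\lVert \boldsymbol\lambda - \bar\lambda \rVert}
     {\lVert \boldsymbol\lambda \rVert}.$$

Numerical choices: voxels with any non-positive signal are flagged and
excluded rather than silently log-transformed; negative eigenvalues
from noisy fits are floored at $10^{-12}$ mm²/s (keeping FA within
[0, 1]) with a per-voxel `clamped` flag; a gradient scheme whose
design matrix is rank-deficient is an error, not a warning.

### Head-motion quality control

Motion traces carry three translations (mm) and three rotations
(radians). The exclusion rule compares translations in mm directly and
converts rotations to arc displacement at a 50 mm head radius
(displacement = angle × radius) before applying the same 1.5 mm limit.
The "1.5 mm/degree" phrasing common in motion-QC protocols conflates
units; the displacement reading is the only one under which a radius
enters, so it is the one implemented — a trace is excluded iff any
converted parameter *strictly* exceeds 1.5 mm, so a maximum of exactly
1.5 mm is retained. Total intracranial volume, used later as a
covariate, is the sum of grey- and white-matter volumes.

## Streamline tractography

`trackStreamline()` performs Euler integration with a fixed 0.5 mm
step along the principal eigenvector of the tensor field. The six
tensor components are interpolated trilinearly at each point and
re-eigendecomposed, which keeps directions smooth inside bundles while
changing sharply at bundle interfaces; the eigenvector sign is aligned
with the previous step. Termination follows four rules: entering a
voxel with FA below 0.2, a turn between successive steps above 60°,
leaving the trackable mask or grid, or a 2000-step safety cap (the cap
guarantees termination; no other stage depends on it). Tracking runs
in both antipodal directions from each seed and joins the two branches
— the standard convention when a method description does not say
otherwise, recorded here as an assumption.

Whole-brain "exhaustive" seeding launches one streamline from the
centre of every white-matter voxel at or above the FA floor, in sorted
voxel order so runs are reproducible. A von Mises–Fisher jitter of the
step direction (concentration `jitterKappa`, with `samplesPerSeed`
repeats) is available to emulate the spirit of probabilistic
tractography — repeated samples over uncertain fibre directions —
without estimating a posterior over directions, which is out of scope.
With `jitterKappa = 0` tracking is fully deterministic.

`buildConnectome()` marks a streamline as connecting regions $(i, j)$
when its points (at nearest-voxel resolution) intersect both label
regions; a streamline touching three or more regions increments every
touched pair, and each connected pair's edge carries the mean AD over
all voxels visited by its connecting streamlines. Counts matrices are
symmetric with zero diagonal by construction.

## Thresholded graph metrics

Subject networks are compared at equal density via proportional
thresholding: at level $p$ exactly $k = \mathrm{round}(p \cdot
N(N-1)/2)$ strongest edges are retained (round-half-even; ties broken
by lexicographic edge order so results do not depend on sort
stability) and the matrix is binarized. The analysis grid runs from
0.15 to 0.40 in steps of 0.01 — 26 levels.

Nine metrics are computed per network: degree, betweenness centrality,
nodal characteristic path length, clustering coefficient and local
efficiency (nodal); density, global efficiency, degree assortativity
and small-worldness (global). Conventions, where more than one exists
in the literature:

* betweenness is unnormalized (raw shortest-path counts, each
  unordered pair counted once) — the scale on which nodal grand means
  of order 40 arise for 24-node networks;
* nodal path length averages geodesics over *reachable* nodes only,
  with the reachable fraction reported as an attribute; efficiency
  uses $1/\infty = 0$; local efficiency of a node is the global
  efficiency of the subgraph induced by its neighbours, zero below two
  neighbours;
* assortativity on a regular graph (zero degree variance over edges)
  is NaN with a warning rather than an arbitrary number.

Shortest-path and triangle computations go through igraph and a small
dense BFS; the test suite checks all of them against an independent
brute-force oracle that enumerates every simple path on graphs of up
to 8 nodes.

### Null networks and small-worldness

Each network is normalized against 500 degree-preserving nulls built
by Maslov–Sneppen double-edge swaps (10 × E attempted swaps per null;
proposals creating self-loops or duplicate edges are rejected, so the
degree sequence is preserved *exactly*, which the tests assert for
every null). $\gamma$ is mean nodal clustering over the null mean,
$\lambda$ the characteristic path length over the null mean, and
$\sigma = \gamma / \lambda$; $\sigma > 1$ reads as small-world
organization. The swap-and-measure loop is implemented in C++ because
a default run evaluates ~750,000 null networks; an R-level test pins
the C++ statistics to the R metric definitions.

Hubs are nodes with z ≥ 2 on both group-mean degree and group-mean
betweenness. The source analysis reports one hub set per group without
stating the threshold at which nodal means are taken; we average
nodal metrics across the full threshold grid before z-scoring, the
least arbitrary reading, and record it here as a documented choice.

## Inference

Group differences are tested per (metric, node, threshold) cell with a
general linear model — metric ~ group + age + IQ + TIV — and a
Freedman–Lane permutation null: residuals of the covariate-only model
are permuted, added back to the reduced fit, and the full model refit;
the group-term t is the statistic and $p = (1 + \#\{|t^*| \ge
|t|\})/(1 + n_{perm})$ with 1000 permutations, so p is never zero.
Freedman–Lane is the standard scheme for permutation with nuisance
covariates; the group-term t (rather than a raw mean difference) is
adopted where the upstream tooling leaves the statistic unstated.
Internally subjects are processed in sorted-identifier order, making
p-values invariant to row order, and t is invariant to affine
covariate rescaling.

Clinical associations are fitted in patients only (the clinical
instruments are not administered to controls): score ~ metric + age +
IQ + TIV at every (threshold, node, metric) cell. The nine metrics
enter per node — global metrics replicated across the 24 nodes — so a
full scan holds 26 × 24 × 9 = 5,616 cells forming a single FDR family.
Cells whose metric is constant across subjects (density, by the
thresholding contract) carry NA statistics. Both parametric and
permutation p-values are emitted, since either convention is found in
practice; FDR is Benjamini–Hochberg by default with
Benjamini–Yekutieli behind a flag, and group tests are corrected per
metric across their nodes and thresholds.

## The synthetic data

Two generators make the pipeline testable without MRI data.

**Phantoms** (`makePhantom()`) place straight cylindrical bundles with
known anisotropic tensors in an isotropic background (1 × 1 × 2 mm
voxels, b = 1000 s/mm², 32 spherical-Fibonacci directions plus one
b = 0 volume, matching a typical clinical acquisition), with optional
Rician noise — magnitude MRI physics:
$\tilde S = \sqrt{(S + n_1)^2 + n_2^2}$, $n_i \sim N(0, \sigma)$ —
and $\sigma = 0$ allowed so oracles are exact. Bundle end caps become
ROI atlas regions. Phantoms do not emulate crossing fibres, curved
anatomy, eddy currents or susceptibility artefacts; tests passing on
them validate the numerics of fitting, tracking and matrix
construction, not robustness to real-data confounds.

**Cohorts** (`makeCohort()`) are generated directly at the connectome
level — tracking 58 phantoms per replicate would dominate runtime
while exercising no additional code path; one phantom→connectome path
is tested end to end separately. The model: a shared log-normal
baseline weight matrix (meanlog = log 30, sdlog = 0.7 — streamline
counts of a few tens per edge), hub gain 2.5 at the left SMA and right
putamen (elevated strength in both groups), multiplicative log-normal
subject noise (sd 0.35), and rounding to integer counts. Default group
sizes are 28 patients / 30 controls; ages span 8.6–21.8 years, IQ ~
N(115, 13²), TIV ~ N(1.4 × 10⁶, (1.2 × 10⁵)²) mm³; tic-severity scores
(0–100) and premonitory-urge scores (9–36) are drawn for patients only
with means 33 and 20.4.

Planted effects are edge-weight surgery on the target node's incident
edges, because effects are specified at the metric level while the
generator operates on edges:

* the *group effect* (default: betweenness at the left putamen,
  d = 1.2) scales patient incident edges by a factor calibrated
  against the cohort's own between-subject metric spread at the 0.25
  threshold, with refinement iterations so the realized pooled-SD
  effect size lands near the requested d despite the variance the
  scaling itself adds;
* each *clinical effect* (default: positive local-efficiency
  associations with the urge score at two insula nodes, strength 0.6)
  drives a per-patient latent that scales the node's incident edges by
  one metric SD per latent unit; the score then loads on the realized
  standardized metric with weight $r = e/\sqrt{1 + e^2}$ for requested
  strength $e$, plus independent noise, so the planted
  covariate-adjusted association has the requested sign and
  approximate magnitude.

A null cohort (no planted effects) drives the permutation test to its
nominal size, which the acceptance tests verify over 200 replicates.

## Problem sizes and runtime choices

The default run analyses 58 synthetic subjects over 26 thresholds with
500 nulls per (subject, threshold) and 1000 permutations per test —
the full stated analysis — and completes in a few minutes on one CPU.
Unit tests use smaller grids (6 threshold levels, 40 nulls, 99
permutations) where the property under test does not depend on the
ensemble size; oracle comparisons use graphs of ≤ 8 nodes because
exhaustive path enumeration grows factorially. Phantoms in tests are
~24 × 10 × 6 voxels: large enough for ~150-seed corridors, small
enough that the whole suite runs in minutes.

## Known limitations

* Deterministic (optionally jittered) tracking approximates, but is
  not, posterior sampling over fibre directions; streamline counts are
  not probabilistic connectivity indices.
* Registration, eddy/motion image correction, brain extraction and
  voxelwise skeleton statistics are out of scope; inputs are assumed
  aligned.
* Synthetic cohorts plant effects at single nodes with homogeneous
  covariate distributions across groups; they do not model
  site/scanner effects, medication status or comorbidity structure.
* Weighted-graph metric variants, directed networks and community
  detection are not implemented.
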