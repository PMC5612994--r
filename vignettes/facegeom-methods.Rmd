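---
title: "Decoding face familiarity and identity: models, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding face familiarity and identity: models, inference, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facegeom)
```

## The scientific problem

Personally familiar faces are recognized faster and more robustly than
unfamiliar ones. Two kinds of neural information could underlie this:
*identity-independent familiarity* — a signal shared by all familiar faces
regardless of who they are — and *identity-specific* patterns that
distinguish individuals. The two are confounded in any simple
familiar-vs-unfamiliar contrast, because familiar faces are also particular
identities.

`facegeom` implements an analysis strategy that dissociates them in run-wise
fMRI beta patterns:

1. **Familiarity decoding with identity control.** A linear classifier is
   trained to separate familiar from unfamiliar faces using six identities
   (three per class) and tested on the two left-out identities — one familiar,
   one unfamiliar. With 4 + 4 identities this *leave-two-identities-out*
   scheme yields 16 splits. Because test identities never appear in training,
   above-chance accuracy cannot come from memorized identity patterns.
2. **Identity decoding without familiarity leakage.** 4-way identity
   classification is run separately within the familiar and within the
   unfamiliar set (leave-one-run-out over 11 runs, 11 splits) and the two
   accuracy maps are averaged.
3. **Searchlight mapping with permutation + TFCE inference.** Both analyses
   run in a 5-voxel (10 mm) spherical searchlight; group significance comes
   from label-permutation nulls combined with threshold-free cluster
   enhancement.
4. **Second-order representational geometry.** Per region of interest, a
   cross-validated representational dissimilarity matrix (RDM) over the 8
   identities summarizes the local geometry; correlating RDMs *between*
   regions gives a region-by-region distance matrix, embedded with classical
   MDS and tested with a mixed-effects contrast of within- versus
   between-system correlations.

## Feature preparation

Betas are estimated per run (ordinary least squares on boxcar regressors
convolved with a canonical double-gamma HRF, plus nuisance columns), the self
condition is dropped (8 conditions remain), and features are z-scored within
each run, separately per voxel. The order is fixed as *filter, then z-score*:
the classifier's features should be standardized over exactly the 8
conditions it sees. Z-scoring uses the population SD (divide by n) by
default, matching the convention of the Python MVPA toolkits this analysis
style comes from; sample SD is selectable (`sd_type = "sample"`).

CompCor-style noise components are available for the GLM: voxel time series
from a noise mask are residualized on confounds and the first 5 principal
components of the residuals are returned as nuisance regressors.

## The classifier

The classifier is a linear C-SVM (L1 hinge loss). No SVM implementation is
available in the target environment, so the package carries its own solver:
dual coordinate descent on the box-constrained dual with the bias absorbed as
an augmented constant feature, deterministic coordinate shuffling, and
one-vs-one voting (ties to the lowest class label) for the 4-way identity
analyses. The regularization constant follows the "scale C by the data"
convention: `C = c_base / mean ||x||` over the training vectors.

Numerical choices: the solver stops at a projected-gradient tolerance of
1e-3 or 25 epochs, whichever comes first. On planted-signal benchmarks,
searchlight maps computed at 25 versus 200 epochs agreed to 3–4 decimals
while running 8x faster; the cap is a compute-budget choice applied
identically to observed and permutation statistics, so it cannot bias
inference. Degenerate all-constant feature blocks yield chance-level
accuracy with a warning rather than an error, keeping searchlight maps total
over the mask.

## Permutation inference with TFCE

Per subject, the null distribution of the familiarity analysis is the
*exhaustive* set of balanced relabelings of the 8 identities: C(8,4)/2 = 35
permutations, after merging each labeling with its complement (a symmetric
binary classifier scores both identically; this equivalence is verified
empirically in the test suite). The identity analysis uses 20 random
within-run relabelings per subject.

One subtlety is not fixed by the analysis description alone: what happens to
the cross-validation scheme under a permuted labeling. Keeping the veridical
leave-two-identities-out splits would make training unbalanced (up to 4-vs-2)
and many test pairs single-class for every non-veridical labeling — measured
on pure noise, such null accuracies average far below 0.5 while the veridical
labeling (the only balanced one) averages 0.5, which destroys the
exchangeability that permutation inference needs. `facegeom` therefore
rebuilds the leave-two-identities-out scheme from each permuted labeling's
own classes, so every permutation is analyzed exactly like the veridical
labeling (3-vs-3 training, mixed test pairs). With this choice the measured
grand null mean is 0.500, and the family-wise false-positive rate of the
full inference stack measures at its nominal 0.05 over 80 independent
no-signal replicates (`scripts/null_calibration_diagnostic.R`). Note that a
calibration check over a finite replicate batch is itself a binomial draw:
a perfectly calibrated system still exceeds a 10%-of-40 bound about 5% of
the time.

Group inference: accuracy maps are centered at chance (0.5 or 0.25) and
negatives truncated (the test is one-tailed), TFCE-transformed
(`extent^0.5 * height^2`, 6-connectivity, dh = max/100 by default), and
averaged over subjects. The null is built by repeatedly (default 10,000
times) sampling one permutation map per subject and averaging. The default
z construction is FWE-corrected: a voxel's p-value is the fraction of draws
whose *map-wise maximum* TFCE reaches the voxel's observed score, mapped
through the normal quantile — thresholding at z >= 1.65 then controls the
family-wise error at 0.05 one-tailed. The uncorrected per-voxel variants
(rank-based, or (obs − mean)/SD) are exposed as options
(`null_stat = "voxel"`, `z_method`), since both appear in the toolkit family
this procedure comes from; the corrected default is the one consistent with
calling the threshold "corrected for multiple comparisons".

## Representational geometry

**Cross-validated RDMs.** Runs are split into halves (sizes 6/5 for 11 runs;
all C(11,6) = 462 partitions), betas averaged within each half, and the two
half-means Pearson-correlated across an ROI's voxels for all 8 x 8 condition
pairs. The diagonal therefore estimates pattern *reliability* rather than
being fixed at 1. Partition matrices are averaged on the Fisher z scale,
symmetrized by averaging with the transpose (also on the z scale), and mapped
back to correlations. For even run counts the half-size generalizes to
ceiling/floor of n/2 with complement deduplication.

**Inter-ROI distance.** Within subject: 1 minus the Pearson correlation
between vectorized RDMs. The vectorization *includes* the diagonal by
default, because the cross-validated diagonal is informative; a flag excludes
it. Subject matrices are Fisher-averaged into a group matrix.

**Between-subject variant.** When data are functionally aligned across
subjects, RDM correlations are computed across subject pairs (all 55 pairs
for 11 subjects, both directions, Fisher-averaged). The per-ROI reliability
`r_a` is the same quantity with the ROI correlated with itself across
subjects, and the dissimilarity index normalizes by the attainable ceiling:
`D_ab = 1 − r_ab / sqrt(r_a r_b)`. Non-positive reliabilities leave the
index undefined and raise an error naming the ROI — imputing a value here
would silently fabricate geometry.

**MDS and RV.** Classical MDS (double-center −D²/2, eigendecompose, scale
eigenvectors by sqrt eigenvalue) is implemented directly and cross-checked
against `stats::cmdscale` in the tests; negative eigenvalue mass is reported.
The RV coefficient compares two double-centered symmetric matrices by their
normalized trace inner product.

**System contrast.** ROI-pair correlations r_ij (units i = subjects, or
subject pairs for the between-subject variant; j indexes ROI pairs from the
upper triangle) are modeled as

    r_ij = b0 + b1 C_ij + b2 E_ij + z_i

with C_ij = both ROIs in the core system (pooling its ventral, dorsal and
anterior subdivisions), E_ij = both in the extended system, and z_i a random
intercept per unit. b1 and b2 are the contrasts "within core > between" and
"within extended > between". Estimation delegates to `lme4::lmer` (REML);
95% CIs come from a seeded parametric bootstrap (default 1000 draws). For
the usual balanced case — every unit has the identical ROI-pair design — the
REML fixed effects coincide with OLS, so bootstrap refits use an exact OLS
fast path; unbalanced data fall back to `lme4::refit`. Self-pairs (the
diagonal) are excluded from the response set: with 30 ROIs the model sees
C(30,2) = 435 pairs. EV-region pairs and all cross-system pairs form the
"between" baseline.

## The synthetic world

The generator emulates the experiment the analyses assume, so every stage is
testable without scanner data:

* **Design**: 11 runs x 48 trials — 4 trials for each of 9 identities (4
  familiar, 4 unfamiliar, self), 4 blanks, 4 oddballs, 4 buffers (3 at run
  start, 1 at run end); 396 non-oddball identity trials, 44 per identity.
  Each trial shows 3 head views of one identity for 500 ms each. Trial order
  is pseudo-randomized by a seeded greedy search minimizing the deviation of
  the first-order transition-count matrix from uniform — a deterministic,
  testable surrogate for the counterbalancing optimizers used in practice,
  whose exact algorithm is not part of this package's contract.
* **Betas**: beta(run, identity, voxel) = familiarity component (one fixed
  spatial pattern, sign +1 for familiar and −1 for unfamiliar by default; a
  familiar-only additive mode is selectable) + identity component (unique per
  identity, stable across runs) + view component (weighted by the run's
  head-view mixture; since every trial shows all three views the mixture is
  uniform, and the component contributes a condition-shared pattern that
  within-run z-scoring removes — a deliberate, documented consequence) +
  smooth Gaussian noise (FWHM 3 voxels = 6 mm at 2 mm, rescaled to unit SD so
  `noise_sd` keeps its meaning). Components are drawn once per dataset from
  the seed; noise is redrawn per run.
* **Time series** (optional): condition regressors (1.5 s boxcars at 6 s
  onset asynchrony, 10 s fixation at both ends — 154 volumes at TR = 2 s)
  times the betas, plus white noise; the GLM round-trips the betas exactly in
  the noiseless case. Oddball/blank/buffer trials evoke no modeled response,
  matching their exclusion from analysis; realistic responses for them are a
  non-goal.
* **Scale**: the default grid is 24 x 24 x 18 voxels at nominal 2 mm with 20
  simulated subjects — large enough for searchlight and ROI analyses with
  planted structure, small enough that the full pipeline with permutations
  finishes in minutes.

What a green test does *not* establish: the generator has no MRI physics, no
motion, no physiological noise, no spatial autocorrelation beyond smoothing,
and its "regions" are spheres with iid-Gaussian patterns. Passing tests
demonstrate that the *analysis machinery* behaves as specified (controls
identity confounds, calibrated false positives, recoverable geometry), not
that real cortical data have these properties.

## Known limitations and open choices

* Sphere boundaries are inclusive (<=) and voxel-unit Euclidean; the paper
  convention of "5-voxel radius (10 mm)" is pinned by the 515-lattice-point
  oracle. ROI overlap ties are resolved to the earlier ROI in the input list.
* Whether to z-score before or after dropping the self condition, and
  whether the inter-ROI vectorization includes the RDM diagonal, are not
  determined by the analysis description; both are fixed by explicit
  defaults (filter-then-z-score; diagonal included) with flags for the
  alternatives.
* The z-TFCE normalization has two published variants; the FWE-corrected
  max-stat version is the default here because it is the one whose 1.65
  threshold legitimately reads "corrected".
* Searchlight centers outside the mask are skipped, not zero-filled.
* The R API uses 1-based voxel indices; NIfTI affines (0-based convention)
  are converted internally.
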