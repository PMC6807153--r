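---
title: "Active acquisition: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active acquisition: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`activeacq` simulates closed-loop neuroimaging acquisition: every scan is
analysed immediately and the result chooses the next scan. This vignette
is the package's account of the science underneath — the models, the
synthetic data they are exercised on, the numerical decisions, and what
the passing test suite does and does not demonstrate about real data.

## 1. The robust outlier distance

Scenario 1's decision signal is a scalar per scan region: the mean
intensity `x` of the region, scored against the same summary computed for
each of `n` normative subjects `s_1..s_n` under identical acquisition
geometry (same resolution, same field of view — a provenance mismatch is
an error, not a warning):

```
D(x) = median_i |x - s_i| / (1.4826 * median_i |s_i - median(s)|)
```

Both numerator and denominator are robust: the median absolute distance
to the normative subjects, scaled by the normal-consistent median
absolute deviation of the normative summaries. `D` is dimensionless,
invariant under any common positive affine intensity transform applied to
subject and normative sample together, and reduces to a robust z-score —
which makes it comparable across resolutions. Because a one-sentence
verbal definition of such a statistic admits several readings (in
particular, whether a MAD denominator is applied at all), the unscaled
median distance is also exposed (`outlier_distance(..., scale = "raw")`),
and the consistency constant 1.4826 is a parameter.

Two small conventions are fixed deterministically: `split_thirds` divides
the z-axis into three contiguous slabs whose sizes differ by at most one
voxel, assigning remainder slabs to the lowest regions one each (10
slabs → 4/3/3, 14 → 5/5/4); `pick_region` breaks ties toward the lowest
region index. The stop rule `stop_or_continue(score, threshold)` is
boundary-inclusive — at exactly the threshold the loop continues, because
scanning more on ambiguity is the conservative clinical choice. The
threshold default is 3 MAD-units; it is a config scalar with no canonical
value, 3 being the usual robust-outlier convention.

**Small-sample caveat.** With only 7 normative subjects the MAD is the
4th order statistic of 7 deviations and is noisy; all three regions of
one experiment share the same subjects, so their MADs rise and fall
together only insofar as between-subject variation is *common* across
regions. The phantom generator (below) is designed so that this is the
dominant regime, mirroring real structural data where session-level
intensity scaling dwarfs thermal noise in regional means.

## 2. Simulated acquisition

`acquire(truth, voxel_mm, fov)` models scanning as voxel-centre block
averaging: each output voxel is the mean of all ground-truth voxels whose
centres fall in its physical box. This is a crude partial-volume model,
chosen because it preserves regional means exactly (the property the
outlier distance consumes) and because an independent brute-force binning
loop can verify it to machine precision. The simulation only ever samples
*down*: requesting a finer grid than the truth is rejected ("cannot
synthesise detail"). The requested field of view is snapped outward to a
whole number of output voxels (never cropping requested anatomy), on the
output lattice anchored at the truth origin; the snap offset is recorded
on the result. Acquisition is noise-free by default; optional additive
Gaussian noise with SD proportional to `1/sqrt(voxel volume)` can be
enabled to mimic the SNR/resolution trade-off.

The zoom loop re-"acquires" every normative subject at each step's field
of view and resolution. Normative summaries are therefore always matched
to the subject's current geometry; the alternative (scoring against
full-third normative summaries) is not implemented.

## 3. The phantom generator

`make_phantom` builds a 1 mm volume containing a smooth two-shell
ellipsoid — a "cortex" shell (intensity 60) around a brighter
"white-matter" core (100) — on a near-zero background, with semi-axes
0.95 of each half-extent so the brain mask fills ≈45% of the grid.
Spatially correlated noise is Gaussian-smoothed white noise (FWHM 3 mm,
SD 1 intensity unit), so coarse acquisitions average it the way real
partial-volume data behave. Between-subject variability has two
components: a global additive intensity offset (SD 2) and a global
multiplicative gain on the tissue signal (SD 0.001), emulating
scanner/session differences. The offset deliberately dominates: it makes
the between-subject variance of regional summaries uniform across
brain-dense and background-heavy regions, so the per-region MAD
denominators of Section 1 are commensurable. If instead variability were
proportional to local signal (gain-only), near-background regions would
have near-degenerate MADs and their scaled distances would explode — an
instability of the statistic, not of the data.

Lesions are spheres with a smoothstep intensity ramp of width 1.5 mm
centred *on* the nominal radius, so the half-maximum surface of the
change sits exactly at the radius and the voxel count with
|change| > |delta|/2 reproduces (4/3)πr³. The default radius 13.6 mm
gives a 10.6 cm³ sphere, a typical chronic middle-cerebral-artery stroke
lesion volume. Only the lesion *centre* is required to lie inside the
brain mask.

**Problem sizes.** The Scenario-1 experiments use 24 × 24 × 84 mm
phantoms with the lesion centred at (12, 12, 70) — strictly inside the
top z-third. This scaled-down geometry is a deliberate choice: the
lesion-to-third volume ratio (10.6 / 16.1 cm³ ≈ 0.66) is what converts a
"10× the normative summary SD" intensity anomaly into a multiple-SD shift
of the third's *mean*, since the summary shift equals delta × (lesion
volume / region volume). A head-sized phantom with the same lesion would
dilute the shift below the normative spread, and no intensity rescaling
can compensate (the ratio is scale-free). Tests run in seconds at this
size.

## 4. The sequential decision tree

`fit_tree` z-scores each modality on training statistics, then fits a
squared-error regression tree (CART, via `rpart` with competes and
surrogates disabled) whose hyperparameters — maximum depth in [2, 8] and
minimum leaf size in [5, 50] — are tuned by 5-fold cross-validation
driven by the package's GP/expected-improvement engine over the integer
grid (one optimiser, two uses; exhaustive grid search is available as a
flag). The fitted tree is converted to a plain node structure with one
fixed convention: *z < threshold goes left*, z ≥ threshold goes right.
`sequential_predict` walks root-to-leaf, querying an oracle only at
visited nodes and caching answers, so the acquisition list is exactly the
path's distinct modalities and the prediction provably equals the batch
prediction. Leaf values are training-set means, hence always inside the
training age range. Degenerate input (constant ages) yields a single-leaf
tree. An oracle failure mid-path (a failed scan) returns a flagged
partial trace rather than an error.

The worked-example tree shipped in
`inst/extdata/worked_example_tree_synthetic.json` exists to pin the
traversal semantics to three published example paths (leaf ages 77.6,
63.1 and 55.7 years; task-BOLD split at −0.18). Only those paths are
constrained; every other node and threshold is an invented placeholder
and carries `"synthetic": true` in the file.

The all-modality baseline is an RBF support-vector regression tuned by
the same engine over a log₂ cost × gamma grid. It always acquires all
modalities; the comparison of interest is accuracy *per scans acquired*,
not raw accuracy — absolute accuracy of six scalar summaries is
deliberately modest compared with voxelwise brain-age models.

## 5. The factor-ordered modality search

`zscore_table` standardises every subject with *training* means and SDs
only (no leakage). `factor_order` fits a one-factor maximum-likelihood
factor analysis to the training z-matrix, flips the sign so the
largest-magnitude loading is positive, and assigns integer coordinates
1..K in descending loading order; on non-convergence (e.g. duplicated
columns making the correlation singular) it falls back to principal-axis
loadings and records that in `$method`.

`run_search` draws 3 distinct burn-in coordinates uniformly *without*
replacement, fits a GP with squared-exponential kernel (length-scale 1.5
coordinates, unit signal SD, observation noise 10⁻⁴ — a 6-point axis
cannot support marginal-likelihood tuning, so these are fixed,
config-overridable defaults), and takes one expected-improvement sample
(ties toward the lowest coordinate). Observations are noise-free reads of
the subject's z-row. The reported result is the *minimum observed* value
and its modality; the GP-posterior argmin is logged alongside. Reporting
the minimum observed is what makes the 4/6 chance level exact: success
reduces to "the true argmin was among the 4 sampled coordinates".

Two analytic facts anchor the evaluation. First, burn-in without
replacement plus one pick that depends only on burn-in observations gives
success probability exactly 4/6 under a random ordering, for *any*
acquisition rule: given the burn-in, the unsampled modalities are
exchangeable and independent of the pick. (With replacement this breaks,
which is why without-replacement is the right reading.) Second, the
informed ordering helps only through the GP's ability to extrapolate
along the factor axis; after within-modality z-scoring, a one-factor
cohort with uniformly strong loadings collapses to an (approximately)
two-block ±λ step on the axis, which caps the informed success rate well
below 1 — in the package's experiments around 0.75 against the 0.67
chance level, a direction and magnitude consistent with a modest,
K = 6-limited search space. The objective is `min` z by default;
`max` and `absmax` are exposed since the choice is application-dependent.

`evaluate_orderings` re-permutes the axis per subject per repetition for
the random baseline, and repeats the whole assessment (default 100
times) with fresh burn-in seeds; it reports per-repetition success
proportions and mean reported minima for both conditions.

## 6. The cohort generator

`simulate_cohort` draws, for subject *i* and modality *m*,

```
x[i, m] = loadings[m] * f_i + age_slopes[m] * (age_i - mean age) + noise_sd[m] * eps[i, m]
```

with `f` and `eps` standard normal and ages uniform on 18–88 years. It
emulates the two features the scenarios consume — a single shared factor
of cross-subject covariance, and an age trend — and nothing else. Real
multimodal ageing data differ in ways that matter for interpretation:
age effects are nonlinear, noise is heteroscedastic and correlated across
modalities beyond one factor, and ages are not uniform. Passing tests
therefore demonstrate that the machinery (splitting, tuning, traversal,
ordering, search) behaves as specified under a known generative model;
they do not certify accuracy figures on any real cohort, and the
package's synthetic error rates should not be compared against published
brain-age benchmarks.

## 7. Numerical choices and degenerate inputs

* Physical boxes are half-open `[lo, hi)`, 0-based, in mm; fov equality
  and containment use a 10⁻⁶–10⁻⁴ mm tolerance.
* Block-average identity: acquiring at the native resolution over the
  full field of view returns the truth bit-identically.
* MAD = 0 (all normative summaries identical) is signalled as a
  degenerate-normative error instead of returning infinity.
* GP kernel solves use a Cholesky factorisation; a numerically singular
  kernel gets a 10⁻⁸ jitter with a warning. Posterior variances are
  clamped at 0 before the square root.
* Expected improvement uses the closed form with the exact `sd = 0`
  limit `max(0, f_best − mu)`; it is non-negative by construction.
* Tie-breaks are everywhere deterministic (lowest index/coordinate).
* All randomness flows from one master seed through labelled child
  seeds (`child_seed(master, label)`, a 31-bit string hash), so adding an
  operation never perturbs an unrelated stream, and scenario runs are
  byte-reproducible (the manifest hashes verify this).
* Trees serialise to JSON at 17 significant digits, which round-trips
  IEEE doubles losslessly.

## 8. Known limitations

* Acquisition is a mean-preserving block average: no k-space, no bias
  field, no pulse-sequence physics, no oblique orientations, no
  registration — synthetic data are born aligned.
* The outlier statistic is univariate per region; covariance-aware
  multivariate alternatives are out of scope by design.
* The modality axis is a single integer dimension; multi-dimensional or
  continuous modality spaces, and noisy observation models for the
  search, are not implemented.
* With n = 7 normative subjects the MAD denominator is noisy; distances
  of individual clean subjects occasionally exceed the conventional
  threshold of 3, and separation statements are about group order
  statistics, not individual calibration.
* The per-repetition superiority of the informed ordering over the
  random ordering is a ~1.5-sigma effect per repetition at a 120-subject
  holdout; it is decisive across 100 repetitions in aggregate but not in
  (almost) every single repetition — an intrinsic ceiling of a 6-point
  search space sampled 4 times, discussed quantitatively in Section 5.
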