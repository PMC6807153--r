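# activeacq

Closed-loop ("active") acquisition simulation for multimodal neuroimaging.

In conventional MRI studies every participant receives the same battery of
scans, analysed long after the session ends. Active acquisition inverts
this: each scan is analysed as soon as it is acquired, and the result
chooses the *next* scan — its resolution, its field of view, or its
modality — or triggers stopping. `activeacq` implements three such
closed loops as fully tested simulations, together with synthetic-data
generators (brain-like lesion phantoms and one-factor multimodal cohorts)
so that every stage runs without any external data. It is aimed at
methods researchers prototyping adaptive scanning policies and at anyone
who wants a reproducible sandbox for outlier-guided acquisition logic.

## The three scenarios

**Scenario 1 — outlier-guided resolution zoom.** A structural volume is
acquired coarsely (4 mm), split into three equal z-thirds, and each third's
mean intensity x is scored against a normative sample s₁…sₙ by a robust
outlier distance

    D(x) = median_i |x − s_i| / (1.4826 · MAD(s)),    MAD(s) = median_i |s_i − median(s)|

— a robust z-score: median absolute distance to the normative subjects,
scaled by the normal-consistent MAD of the normative summaries. The most
outlying third becomes the next field of view, the resolution doubles
(4 → 2 → 1 mm), and the loop repeats, homing in on focal pathology while
clean subjects can stop after the cheap coarse scan.

**Scenario 2 — sequential modality acquisition.** A regression tree maps
six modality z-summaries (grey-matter volume, white-matter FA, T2
intensity, two DMN connectivity measures, a task-BOLD contrast) to age.
Applied *sequentially*, the tree is an acquisition policy: each internal
node requests one modality, so different individuals receive different —
and usually fewer — scans, while a support-vector-regression baseline
needs all six. Tree hyperparameters are tuned by the same Gaussian-process
/ expected-improvement engine used in Scenario 3.

**Scenario 3 — discovering the most abnormal modality.** Modalities are
placed on an integer axis 1..K ordered by their loadings on a single
factor fitted to normative covariance, so modalities that co-vary sit at
adjacent coordinates. For each new individual, a Gaussian-process
regression over that axis is fed 3 random burn-in samples, then the
expected-improvement rule

    EI(x) = (f_best − μ(x))·Φ(u) + σ(x)·φ(u),   u = (f_best − μ(x)) / σ(x)

picks one more modality, and the minimum observed z-score is reported —
4 of 6 modalities sampled. With a random axis the success probability is
exactly 4/6 ≈ 0.67; the factor-informed axis does better.

## Worked example

```r
library(activeacq)

# Scenario 1: 7 normative phantoms, one patient with a 10.6 cm^3 lesion
norm <- lapply(1:7, function(j) make_phantom(c(24, 24, 84), seed = 100 + j))
summaries <- sapply(norm, function(v)
  sapply(split_thirds(acquire(v, 4)), scan_summary))
delta <- 10 * max(apply(summaries, 1, sd))      # lesion amplitude: 10x normative SD

subject <- add_lesion(make_phantom(c(24, 24, 84), seed = 42),
                      lesion_spec(c(12, 12, 70), radius_mm = 13.6,
                                  intensity_delta = -delta))
zoom <- run_zoom(subject, norm, resolutions_mm = c(4, 2, 1), threshold = 3)
zoom
#> <composite_image: 3 acquisition steps>
#>   step 0 @ 4 mm: distances (0.82, 0.64, 5.12), chose region 2 [CONTINUE]
#>   step 1 @ 2 mm: distances (4.32, 7.32, 3.92), chose region 1 [CONTINUE]
#>   step 2 @ 1 mm: distances (6.01, 7.75, 8.19), chose region 2 [CONTINUE]
```

At 4 mm the top third (region 2, where the lesion sits) is 5.1 MAD-units
from the 7-subject normative sample while the clean thirds stay below 1;
the loop zooms there, re-splits, and ends with a 1 mm scan of a ninth of
the original field of view containing the lesion.

```r
# Scenario 3: factor-ordered search vs a random ordering
co <- simulate_cohort(cohort_spec(600, 6,
        loadings = c(0.95, 0.9, 0.85, -0.85, -0.9, -0.95),
        noise_sd = rep(0.3, 6), seed = 1))
sp <- train_holdout_split(co, 0.2, seed = 1)
zt <- zscore_table(co, sp$train$subjects)
space <- factor_order(zt)
space
#> <search_space (ml): 1=mod_6(0.96) 2=mod_5(0.94) 3=mod_4(0.93)
#>                     4=mod_3(-0.94) 5=mod_2(-0.95) 6=mod_1(-0.95)>

zh <- zt$z[match(sp$holdout$subjects, zt$subjects), , drop = FALSE]
ev <- evaluate_orderings(zh, space, n_reps = 20, seed = 1)
#> informed ordering: 0.766   random ordering: 0.677
```

The informed ordering finds each holdout subject's most abnormal modality
in 76.6% of searches versus 67.7% under random ordering (chance is
4/6 ≈ 0.667), while sampling only 4 of the 6 modalities.

A thin command-line wrapper is provided in `exec/actacq`
(`actacq scenario1|scenario2|scenario3 [--config cfg.yaml] [--seed N] [--out DIR]`);
each run writes its volumes/tables, a JSON trace, the effective YAML
config and a hash manifest, and is byte-reproducible from config + seed.

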