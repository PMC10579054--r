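---
title: "Quantifying heterotopic ossification on NaF PET-CT and testing crossover endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heterotopic ossification on NaF PET-CT and testing crossover endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoquant)
```

## The problem

Fibrodysplasia ossificans progressiva (FOP) progressively replaces muscle
and connective tissue with heterotopic bone. Disease activity is imaged with
¹⁸F-NaF PET — the tracer deposits where bone mineral is actively forming —
co-registered with CT, which shows the ossified result. Trials in this
space therefore carry a two-layer computational core: (i) image-level
quantification of individual HO lesions, and (ii) a patient-level endpoint
and testing layer built on those measurements, often with a
placebo-to-treatment crossover at mid-study so each patient can serve as
their own control. `hoquant` implements both layers and a simulator that
generates inputs with the statistical structure the analysis assumes, so
every rule is exercised by tests without access to patient data.

## Image quantification

**SUV.** A PET voxel's standardized uptake value is its decay-corrected
activity concentration $r$ (kBq/ml) divided by injected dose over body
mass, $\mathrm{SUV} = r/(A_0/M_0)$. `to_suv()` applies this voxelwise and
is idempotent on SUV-flagged volumes. Inputs are assumed decay-corrected
upstream; the package performs no decay correction of its own. The
1 ml ≡ 1 g density convention makes SUV unitless and lets metabolic volumes
in ml read as grams when multiplied by SUV.

**Region statistics.** `region_stats()` reports the region maximum and
arithmetic mean. Masks are plain logical arrays aligned with the volume, so
any reader-drawn or simulated ROI plugs in.

**Metabolic volume.** `metabolic_volume()` keeps lesion voxels with SUV at
or above 40 % of the lesion's SUVmax. Two deliberate choices:

- *Inclusive comparison* (`>=`). With a strict `>` a perfectly uniform
  lesion would segment to nothing; inclusivity makes the uniform case
  return the full lesion, which is the behaviour a reader expects.
- *Connected-component restriction* (default on, 26-neighbour). Whether a
  trial's segmentation kept only the component containing the max voxel or
  took all supra-threshold voxels inside a reader boundary is usually not
  reported; both are supported (`connected =`), with connectivity
  configurable to 6. Tie-breaks for the max voxel use the first voxel in
  array order, making segmentation deterministic.

An exclusion mask (the reader's "not this normotopic bone" stroke) is
subtracted after thresholding; excluding the max voxel itself leaves no
anchor for the threshold and raises an error rather than guessing.

**Peak SUV.** `suv_peak()` is the mean over a 1 ml sphere centred on the
max voxel (EANM-style). Peak SUV feeds no downstream endpoint here, so the
choice of sphere volume is inert; among tied maxima the sphere centres on
the voxel nearest the lesion centroid, again for determinism.

## Lesion classification rules

- `classify_active()`: SUVmax ≥ 3 × the supra-acetabular reference mean,
  boundary inclusive. Monotone in SUVmax, anti-monotone in the reference.
- `select_baseline_lesions()`: up to seven active baseline lesions in
  descending SUVmax, ties broken by larger metabolic volume then lesion id.
  The cap reflects operational limits on how many lesions readers can
  delineate and follow, not a biological claim.
- `detect_new_ct_lesion()`: density strictly above 200 HU — well above
  ~50 HU soft tissue yet below ~800 HU cortical bone, so early mineralizing
  HO is kept — and volume ≥ 1 cm³, the smallest lesion reliably measured on
  low-dose CT. "Density" is the mean HU over the candidate mask; a max-HU
  variant can be built from `region_stats()` on the CT volume if preferred.
- `detect_new_pet_lesion()`: a post-baseline, unmatched lesion is new iff
  active. No volume floor is applied on the PET side: the activity
  criterion is taken as the complete rule.
- `adjudicate()`: dual-reader calls agree or are resolved by an explicit
  adjudicator ruling table; unresolved discrepancies are an error listing
  the keys. Modelling the adjudicator as a ruling table (not a third
  automated reader) matches forced adjudication with readers blinded to the
  outcome. `lesion_match()` pairs calls by Dice overlap > 0.2 with a
  centroid-distance fallback; the threshold is configurable since matching
  procedures are rarely published.

## Endpoints

**TLA** sums SUVmean × metabolic volume over a patient-visit's lesions
(grams); it errors on mixed visits rather than silently pooling.

**TWA percent change.** Percent change is anchored at 0 at week 0; the
time-weighted average over period 1 is the trapezoidal AUC through
$(0,0), (8, pc_8), (28, pc_{28})$ divided by the full 28-week span, which
makes it a weighted mean of the two percent changes
($\tfrac{1}{2}pc_8 + \tfrac{5}{14}pc_{28}$). Missing-scan handling follows
the prespecified rules, which form a mutually exclusive, exhaustive
partition of the four missingness patterns:

| week 8 | week 28 | rule |
|---|---|---|
| present | present | trapezoid as observed |
| missing | present | linear interpolation baseline→28: $pc_8 = \tfrac{8}{28} pc_{28}$ |
| present | missing | carry forward: $pc_{28} = pc_8$ |
| missing | missing | substitute placebo-group means (error if unavailable) |

The divisor is taken as the full 28 weeks in all cases; whether a trial
would shorten it for late dosing is not derivable from public information,
and a constant divisor keeps the TWA comparable across patients.

**Per-period new lesions.** A lesion belongs to the period in which it is
first detected: period 1 at the week-28 scan relative to baseline, period 2
at the week-56 scan relative to week 28. The period sets partition — a
lesion never counts twice. A missing week-56 scan is substituted by the
first available later scan (the pandemic-era rule); this is valid because
ossified lesions persist, though a late substitute scan could in principle
include lesions arising after week 56 — a conservative bias the simulator
does not model. A patient with no usable follow-up scan is excluded from
the modified intent-to-treat set with a logged reason, not imputed.

## The statistical layer

**Exact Wilcoxon signed-rank** (`wilcoxon_signed_rank_exact()`): zeros
dropped (the classic treatment; a Pratt option keeps their ranks), midranks
for ties, statistic = rank sum of positive differences. For n ≤ 25 the
sign-flip null distribution is computed exactly by convolving the doubled
midranks — identical to enumerating all $2^n$ sign vectors, at polynomial
cost — and the two-sided p doubles the smaller inclusive tail, capped at 1.
Above 25 a tie-corrected normal approximation is used with a notice. When
every non-zero difference shares one sign the exact p is $2/2^n$ regardless
of magnitudes; with 9 such differences that is $2/512 = 0.00390625$, which
is why per-patient count comparisons of a suppressed outcome yield
p ≈ 0.0039 independent of the count values.

**McNemar** (`mcnemar_test()`): the default is the uncorrected
$\chi^2=(b-c)^2/(b+c)$ on 1 df. The uncorrected form is the inference that
uniquely reproduces the paired-proportion p-values recomputable from
printed discordant counts (b = 9, c = 0 → 0.0027; b = 8, c = 0 → 0.0047),
and is therefore the default; an exact binomial mode is available and is
never anti-conservative relative to it at min(b, c) = 0.

**Relative risk and rate ratio**: plain quotients with a log-Wald interval
for the RR; degenerate denominators are flagged, never silently dropped.

**Gatekeeping** (`gatekeeping()`): fixed-sequence testing, stop at the
first p ≥ α, later hypotheses reported as untested/descriptive. A blinded
period conventionally runs at α = 0.05 and an open-label crossover period
at a two-sided α = 0.10; both are arguments, not constants.

**Model contracts.** `fit_ancova()` (lm), `fit_repeated_measures()`
(`nlme::gls` with `corSymm` + `varIdent`, i.e. fully unstructured
within-patient covariance, arm contrast at the last visit) and
`fit_count_gee()` (negative-binomial regression with cluster-robust
sandwich errors over patients — a GEE with independence working
correlation) are validated by parameter recovery on simulated cohorts:
zero-noise exactness, interval coverage, type-I error. Their role is to
provide the model-based counterparts of the trial analyses; reproducing any
specific trial's least-squares means would require patient-level data and
is out of scope. When one count group has no events the rate ratio lies on
the boundary of the parameter space; the fit is replaced by a flagged
descriptive result rather than a fragile estimate.

## The simulator: what it emulates, and what it does not

`generate_phantom()` builds PET as background (default SUV 0.5, soft
tissue) plus lesion profiles plus additive Gaussian noise clipped at zero,
and CT as soft tissue (50 HU) with a skeletal reference ellipsoid (800 HU)
and lesions (300 HU) painted in. Lesion profiles are isotropic Gaussians
(support truncated at 3σ) or hard ellipsoids; Gaussians make the 40 %
threshold carve a proper sub-volume, ellipsoids exercise the uniform edge
case. The default 64×64×96 grid at 4 mm quantifies in milliseconds, so
oracle suites can afford dozens of phantoms. Deliberately absent: scanner
physics (attenuation, scatter, reconstruction, partial volume), Poisson
count noise, respiratory motion, inter-timepoint registration error. Tests
passing on these phantoms validate the *rules*, not robustness to scanner
artefacts.

`generate_cohort()` draws a two-arm crossover: 24 placebo / 20 treated;
visits at weeks 0, 8, 28, 56, 76; per-period new-PET-lesion counts negative
binomial with placebo mean 1.19 lesions/patient/period, treated mean
smaller by the rate ratio 0.13, and the placebo arm switching to the
treated rate after week 28. CT counts are a binomial thinning of PET counts
with detection probability 1.13/1.19, preserving both marginal rates and a
strong within-patient PET–CT coupling. Diary flare-up probabilities are
0.708 untreated / 0.35 treated per period (investigator-reported 0.417 /
0.10). Scan missingness is MCAR at 5 % per post-baseline visit — the
pandemic-era mechanism, at a magnitude chosen so substitution logic is
exercised without dominating the data. Values without a public anchor are
explicit stand-ins: NB dispersion 1.0 (variance $\mu + \mu^2$, the moderate
overdispersion typical of per-patient lesion counts), lognormal per-lesion
CT volumes (median 8 cm³) and activities (median 150 g) at the scale of
reported period totals, and percent-change means of +10/+20 % (untreated)
vs −5/−10 % (treated) at weeks 8/28 with SD 30 %. The simulator draws
per-patient counts directly; it does not place per-lesion masks into
phantom volumes, so reader variability and lesion matching across time are
not emulated at cohort scale.

## Numerical and degenerate-input choices

- All RNG flows through a single integer seed per spec object; generation
  restores the caller's RNG state, and equal seeds give byte-identical
  outputs.
- Empty masks, empty analysis sets, non-positive baselines, zero reference
  rates and all-zero difference vectors each produce either a defined
  degenerate result with a flag (p = 1, RR 0) or an error with the
  offending item named — never a silent NA.
- Exact p-values are computed in exact rational arithmetic up to the
  floating division by $2^n$; the 0.00390625 benchmark is reproduced
  identically, not to tolerance.
- Problem sizes in the test suite: 50-phantom oracle sweeps at 16³ voxels,
  5000-patients-per-arm rate recovery, and 2000-replicate size simulation
  of the exact test at n = 22 — together they run in well under a minute.

## Known limitations

- No DICOM ingestion or registration: volumes are assumed co-registered
  NIfTI, metadata in a JSON sidecar.
- The automatic lesion-proposal path is limited to connected components of
  supra-threshold voxels; trials use human readers, and the simulator's
  truth masks stand in for them.
- Safety/adverse-event tabulation, patient-reported instruments and
  biomarker assays are out of scope.
- `fit_count_gee()` uses an independence working correlation; with few,
  highly unbalanced clusters its small-sample behaviour inherits the usual
  sandwich-estimator caveats.
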