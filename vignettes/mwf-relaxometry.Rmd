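---
title: "Myelin water fraction estimation by NNLS T2 relaxometry: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelin water fraction estimation by NNLS T2 relaxometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mwfr)
```

## The signal model

A voxel of brain tissue contains water in several micro-environments that
exchange slowly on the measurement timescale: water trapped between the
lipid bilayers of myelin (T2 roughly 15–40 ms), intra/extracellular water
(roughly 40–200 ms), and free water such as CSF (beyond 1500 ms). A
multi-echo spin-echo acquisition samples the composite decay

$$y(TE_i) = S_0 \sum_j f_j \, e^{-TE_i / T_{2,j}} + \varepsilon_i,$$

at echo times $TE_i$ (here 32 echoes, 10–320 ms in 10 ms steps). The
package recovers a discrete amplitude spectrum $s \ge 0$ over a grid of
candidate T2 values by non-negative least squares,

$$\hat{s} = \arg\min_{s \ge 0} \lVert A s - y \rVert_2^2, \qquad
  A_{ij} = e^{-TE_i / T_{2,j}},$$

and defines the myelin water fraction as the short-window share of the
total spectrum,

$$\mathrm{MWF} = \frac{\sum_{15 \le T_{2,j} < 40} \hat{s}_j}
                      {\sum_{15 \le T_{2,j} \le 2000} \hat{s}_j}.$$

NNLS makes no assumption about the number of pools, only non-negativity,
which is physically necessary for amplitudes. The solver is a
Lawson–Hanson active-set iteration: it terminates at the exact constrained
minimiser, uses no random initialisation, and is therefore
bit-reproducible — the optimality is verified in the test suite against
exhaustive active-set enumeration on small systems and against an
independent NNLS implementation on realistic bases.

### Window conventions

Component windows are half-open, $[lo, hi)$, so the shared 40 ms edge
belongs to the medium window only and no amplitude is counted twice. The
total window $[15, 2000]$ ms is closed, matching the denominator
definition of the MWF. The gap between the medium window (up to 200 ms)
and the long window (beyond 1500 ms) is deliberate: grid points in
(200, 1500] ms count toward the total signal but toward neither labelled
component, and the default simulator places no pool there rather than
guess at intent for that band.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `echo_times` | 10, 20, …, 320 ms | echo train of the acquisition |
| `t2_grid()` | 40 log-spaced points, 15–2000 ms | spectral grid; density is configurable and tests pin the default |
| `short_window` | [15, 40) ms | myelin water |
| `medium_window` | [40, 200) ms | intra/extracellular water |
| `long_window` | (1500, 2000] ms | free water |
| `regularization` | `"none"` | `"chi2_constrained"` enables the smoothed fit |
| `chi2_factor` | 1.02 | misfit inflation of the regularised fit |

### Regularisation

Voxelwise NNLS is noise-sensitive: the myelin and intra/extracellular
columns of $A$ are strongly collinear, so noise can collapse the two pools
into a single peak whose position fluctuates around the 40 ms window
boundary. The `chi2` mode returns the minimum-energy ($\min \lVert s
\rVert_2$) non-negative solution whose misfit equals `chi2_factor` times
the unregularised minimum, located by bisection on a Tikhonov weight
(stacked system $[A; \sqrt{\mu} I]$). With factor 1 it reproduces the
plain fit; with 1.02 it reduces the voxelwise spread of MWF estimates (a
property the tests assert). It is off by default: the energy penalty
favours large-norm (long-T2) basis columns and therefore trades variance
for a downward MWF bias, which matters for ROI means (below).

## Estimating ROI-level MWF

Two estimators are provided, and the distinction is deliberate:

* `fit_mwf_map()` + `roi_stats()` — fit every voxel, then average the MWF
  map over the ROI. This is the map a clinician inspects, but at moderate
  SNR the voxelwise estimates carry a *systematic downward bias* (about
  −0.015 at SNR 100 for a 0.0999-MWF tissue with the default grid) caused
  by the noise-driven pool collapse described above. The bias shrinks
  monotonically as noise falls — the test suite checks this on phantoms
  with common noise seeds — but it does not average away over voxels.
* `roi_spectrum_mwf()` — average the decay curves over the ROI first, fit
  one spectrum. Averaging $N$ voxels raises the effective SNR by
  $\sqrt{N}$, so the fit operates in the near-asymptotic regime where the
  NNLS bias is negligible; with 500+ voxels at SNR 100 the planted MWF is
  recovered to within a few thousandths. This classical region-based
  multi-component analysis is the package's preferred ROI estimator for
  parameter recovery, and the one the acceptance script reports as
  `nawm_mwf` / `lesion_mwf` (the map-based means are reported alongside,
  unadjusted, as `map_*`).

The MWF ratio (lesion mean over NAWM mean) then indexes myelin disruption
inside lesions while normalising between-subject differences in NAWM
myelin content.

## What the phantom generator emulates — and what it does not

`make_phantom()` builds a cuboid of three-pool NAWM (myelin water 20 ms,
intra/extracellular 80 ms, free water 2000 ms — values placed centrally in
the short/medium/long windows, since only window bounds are conventional)
carrying spherical lesions with a lower myelin fraction. Defaults plant
NAWM MWF 0.0999 and lesion MWF 0.080 in three radius-6 blobs (~2800
voxels, ~11 cm³ total — a moderate-to-high lesion load for a
relapsing-remitting cohort, and enough voxels that region-averaged
estimates are stable). Noise is additive Gaussian by default, with a
Rician option (magnitude of signal plus complex Gaussian noise) for
magnitude-MRI realism; at SNR ≥ 50 the Rician magnitude bias of a constant
signal stays below 1% of the signal, so the Gaussian default is a clean
approximation in the regimes simulated here.

Deliberately *not* modelled: anatomy, partial-volume gradients, B1
inhomogeneity and stimulated echoes (no EPG correction — the fit assumes
ideal refocusing), multi-slice effects, and k-space artefacts. Passing
phantom tests therefore demonstrates correctness of the inversion and the
ROI pipeline, not robustness to acquisition imperfections in vivo.

Sphere-on-cuboid geometry keeps volume oracles exact (ROI volume is voxel
count × voxel volume, 1×1×4 mm by default, matching a whole-cerebrum
GRASE protocol).

## The synthetic cohort

`simulate_cohort()` draws per-subject NAWM MWF ~ N(0.0999, 0.012), an MWF
ratio ~ N(0.80, 0.10) clipped to (0, 1.5], sets lesion MWF = ratio × NAWM
MWF, and plants

$$\Delta \mathrm{TUG} = \beta_0 + \beta_1 \cdot \mathrm{ratio} + \varepsilon,
 \qquad \varepsilon \sim N(0, \sigma).$$

Negative change means improvement, so the default slope is negative
(−15 s per unit ratio): less myelin disruption predicts greater response.
The residual SD comes from the population-R² identity
$R^2 = \beta_1^2 \mathrm{var}(x) / (\beta_1^2 \mathrm{var}(x) + \sigma^2)$
via `calibrate_noise_sd()`, with the default planting R² = 0.31 at
n = 14. Day-10 TUG is Day 1 plus the planted change, floored at 1 s to
avoid non-physical times in extreme draws. Lesion volumes are log-normal
around the reference cohort's mean; age, sex and EDSS are drawn to match
its demographics. All seeds are explicit arguments (default 0) with no
hidden global state; `with_seed()` restores the caller's RNG.

Because fitted R² at n = 14 is biased upward (roughly by
$(1 - \rho^2) \cdot k/n$), the median fitted R² over replicates sits near
0.33–0.35 for a planted 0.31 — inside the ±0.05 band the acceptance
checks use, but worth remembering when reading single-study R² values.

## Cohort statistics

The statistical stage mirrors a standard small-cohort analysis plan:
Shapiro–Wilk on each dependent measure (p ≤ 0.05 would route to
non-parametric branches), a paired t on TUG Day 1 vs Day 10 with Cohen's
d = mean difference / SD of differences, an exploratory Pearson screen of
the four candidate predictors (lesion volume, lesion MWF, NAWM MWF, MWF
ratio) against TUG change, and a follow-up simple regression on the
screen winner. Design choices worth stating:

* Missing Day-10 values are excluded pairwise, never imputed; degrees of
  freedom are reported as complete pairs minus one.
* The screen's selection rule is explicit — smallest screen p advances —
  and all four screen rows are always reported, not only the winner.
* No multiple-testing correction is applied, matching the exploratory
  framing of a 16-participant feasibility cohort; p-values from the
  screen should be read accordingly.
* Shapiro–Wilk, the t-test, Pearson and OLS delegate to R's vetted
  `stats` routines; the identities $R^2 = r^2$ and
  $F = (n-2)R^2/(1-R^2)$ are asserted to numerical precision in tests.
* ICC for inter-rater reliability is the single-measures
  absolute-agreement form from the two-way random-effects ANOVA
  decomposition, ICC(2,1): with a handful of targets rated by the same
  raters, absolute agreement (which penalises systematic rater offsets)
  is the appropriate reliability for manually delineated lesion masks.
  The 0.75 threshold conventionally marks excellent reliability.

## Numerical choices and degenerate inputs

* NNLS tolerance is scale-aware (relative to `max|A|`, `max|b|` and
  machine epsilon); rank-deficient passive sets fall back to zero
  coefficients rather than failing.
* A zero spectrum yields an undefined MWF (`NA`), never 0/0; voxels whose
  total amplitude is below 1e−12 × the volume's median first-echo signal
  are marked undefined and excluded from ROI means.
* The χ² bisection brackets the weight geometrically, runs at most 100
  iterations to a relative misfit tolerance of 1e−6, and raises a
  numerical error with diagnostics if it cannot converge.
* Masks with values other than 0/1 (some tools emit 0/255) are coerced
  with a warning; shape mismatches between any map and mask abort with a
  registration error. Co-registration itself is out of scope: masks must
  arrive in register, and the shape check is the guard.
* Published-table comparisons round half away from zero
  (`round_half_up()`) at each statistic's printed precision, since IEEE
  round-half-even can disagree with printed tables at exact midpoints.

## Problem sizes

The default phantom is 32×32×16 voxels × 32 echoes (a full voxelwise fit
takes ~15 s on one CPU); the reproducibility checks run a 16×16×8 phantom
end-to-end twice; cohort calibration uses 1000 simulated cohorts of
n = 14 and the screen-consistency check 200 cohorts of n = 80 (at n = 14
the induced correlation between lesion MWF and the ratio makes screen
selection genuinely ambiguous, so consistency is asserted at a sample
size where the planted signal is resolvable).

## Known limitations

* No stimulated-echo (flip-angle) correction: real GRASE decays deviate
  from pure exponentials; MWF from this package on uncorrected in vivo
  data will inherit that bias.
* Voxelwise MWF maps at SNR ≲ 100 carry the downward noise bias discussed
  above; use the region-averaged estimator for quantitative ROI values.
* The reliability module assumes a complete targets × raters table; no
  missing-cell ICC variants are implemented.
* Lesion segmentation is out of scope — masks are inputs.
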