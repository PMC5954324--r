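# mwfr — myelin water fraction mapping by multi-echo T2 relaxometry

Multiple sclerosis degrades the myelin sheath, and the degree of myelin
disruption may govern how well a patient responds to rehabilitation.
Conventional MRI shows *where* lesions are but not *how demyelinated* they
are. Multi-component T2 relaxation imaging separates the water pools of
brain tissue by their transverse relaxation times: water trapped in myelin
bilayers relaxes fast (T2 ≈ 15–40 ms), intra/extracellular water slower
(40–200 ms), and free water/CSF slower still (> 1500 ms). The **myelin
water fraction (MWF)** — the short-T2 share of the total T2 signal — is a
histopathologically validated proxy for myelin content.

`mwfr` is an R package for the full analysis chain:

* **Spectrum inversion.** For each voxel of a 32-echo decay
  (TE = 10, 20, …, 320 ms) the T2 spectrum is recovered by non-negative
  least squares (NNLS) over a grid of T2 values
  (default 40 log-spaced points on 15–2000 ms):

  `min over s ≥ 0 of || A s − y ||²,  A[i, j] = exp(−TE_i / T2_j)`

  and `MWF = Σ s_j (15 ≤ T2_j < 40 ms) / Σ s_j (15 ≤ T2_j ≤ 2000 ms)`.
  An optional χ²-constrained mode returns the minimum-energy non-negative
  spectrum whose misfit is inflated by a set factor (default 1.02), the
  classical regularisation for noisy voxelwise fits.
* **Simulation.** Multi-compartment phantoms (three-pool NAWM plus
  spherical lesions with lower myelin content, Gaussian or Rician noise)
  with known ground-truth MWF, and synthetic cohorts in which the
  lesion/NAWM MWF ratio linearly predicts the change in Timed Up and Go
  (TUG) time with a chosen population R².
* **ROI analysis.** Lesion-mask subtraction from the NAWM mask, ROI
  mean/SE/volume, the lesion/NAWM **MWF ratio** (values near 1 = less
  myelin disruption), and inter-rater reliability via the two-way
  random-effects ICC(2,1) (absolute agreement).
* **Cohort statistics.** TUG change (Day 10 − Day 1), Shapiro–Wilk
  normality gate, paired t with Cohen's d, a Pearson screen over the
  candidate predictors, and the follow-up simple regression of TUG change
  on the selected predictor.

## Worked example

Simulate a phantom at SNR 100 with planted NAWM MWF 0.0999 and lesion MWF
0.080, and recover the ROI estimates:

```r
library(mwfr)
spec <- phantom_spec(noise_sigma = 0.01)   # 32x32x16, three lesions
ph   <- make_phantom(spec, seed = 1)
cfg  <- fit_config()
nawm_only <- subtract_mask(ph$nawm_mask, ph$lesion_mask)
est_n <- compute_mwf(roi_spectrum_mwf(ph$volume, nawm_only,  ph$protocol, cfg), cfg)
est_l <- compute_mwf(roi_spectrum_mwf(ph$volume, ph$lesion_mask, ph$protocol, cfg), cfg)
cat(sprintf("NAWM MWF %.4f, lesion MWF %.4f, ratio %.4f\n",
            est_n, est_l, mwf_ratio(est_l, est_n)))
#> NAWM MWF 0.0964, lesion MWF 0.0780, ratio 0.8090
```

The planted values are recovered to within 0.004 and the lesion sits
clearly below NAWM, the qualitative hallmark of demyelination. The
packaged 16-participant reference cohort reproduces its published
summaries exactly:

```r
print(reproduce_table1())
#>            quantity    computed rounded reference status
#>            mean_age   47.062500   47.10     47.10   pass
#>       mean_tug_day1   12.750000   12.80     12.80   pass
#>      mean_tug_day10   11.933300   11.90     11.90   pass
#>  mean_lesion_volume 7276.880000 7276.90   7276.90   pass
#>         median_edss    4.000000    4.00      4.00   pass
#>  mean_tug_reduction    1.100000    1.10      1.10   pass
#>       sd_tug_change    3.054270    3.05      3.05   pass
#>         t_statistic    1.394860    1.40      1.40   pass
#>            cohens_d    0.360151    0.36      0.36   pass
#>        n_responders    9.000000    9.00      9.00   pass
#> 10/10 reproduced at printed precision
```

A mean TUG reduction of 1.1 s (SD 3.05) is not significant at the group
level (t(14) ≈ 1.4, d ≈ 0.36), yet 9 of 15 participants improved — the
heterogeneity that motivates the MWF ratio as a responder biomarker.

The end-to-end pipeline (simulate → fit map → ROI stats → cohort stats)
runs from one YAML config via `run_pipeline()`, or from the shell via the
thin CLI in `inst/cli/mwfr` (`simulate-phantom`, `fit-mwf`, `roi-stats`,
`cohort-analysis`, `reproduce-table1`, `run`).

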