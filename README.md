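# vitalcam

Non-contact heart rate (HR) and respiration rate (RR) estimation from
single-channel video, with a liveness filter that rejects inanimate
subjects (photographs, drawings, screens). The package targets
telemedicine-style monitoring — infants asleep under an IR camera, elderly
patients at night, laboratory animals — where only a monochrome image
stream is available and a false "healthy pulse" from a lifeless scene is
the worst possible failure mode.

## Method

The spatial mean brightness of a region of interest (a face patch for the
cardiac pulse, a chest band for breathing) gives one observed series
`x(t)` per vital sign. Each 30 s analysis window is processed as:

1. smoothness-priors detrending: subtract the trend
   `t = (I + λ² D₂ᵀD₂)⁻¹ x` (second-difference operator `D₂`; λ = 20 for
   the cardiac, λ = 300 for the respiratory series), then normalize to
   zero mean and unit variance;
2. delay-coordinate embedding `X[i, j] = x(j + i·d)` with dimension
   `m = 3` and delay `d = 1`, reconstructing the state space of the
   cardiorespiratory system from the single observable;
3. FastICA (kurtosis contrast, symmetric decorrelation) unmixes `X = A Y`
   into independent sources; the component with the highest peak
   power-density ratio `R = max_k P_k / Σ_k P_k` (over 0–8 Hz) is the
   physiological one;
4. moving-average smoothing (5 points cardiac / 13 respiratory),
   three-layer autocorrelation, and a zero-padded FFT; the rate is the
   band-restricted spectral peak times 60.

Liveness uses the ratio-variation statistic
`ν = |R_pre − R_post| / R_post`, the relative change of the peak
power-density ratio under smoothing: tiny when a real physiological peak
dominates, about 0.5 for the wideband signal of an inanimate scene. The
verdict compares two reference densities, live `ν ~ Gamma(a = 1.5335,
b = 0.0599)` and inanimate `ν ~ N(0.4905, 0.1434)`, choosing "live" iff
`f_T(ν) > f_F(ν)`; `classify_accumulated()` sums both densities over
three successive windows, and `fit_pds()` refits the densities for a new
acquisition chain. `bland_altman()` supplies the standard agreement
statistics against a contact reference.

## Worked example

```r
library(vitalcam)

# simulate a 30 s monochrome recording of a subject at 15 fps
p <- scene_params(hr_freq = 1.2, rr_freq = 0.25, seed = 42)   # 72 bpm, 15 br/min
frames <- generate_frame_sequence(p)

res <- run_pipeline(frames,
                    bvp_roi = p$skin_roi, resp_roi = p$chest_roi,
                    window_s = 30, stride_s = 30, seed = 1)
res[, c("kind", "rate_per_min", "peak_freq_hz", "nu", "liveness_flag")]
#> # A tibble: 2 × 5
#>   kind  rate_per_min peak_freq_hz      nu liveness_flag
#>   <chr>        <dbl>        <dbl>   <dbl> <chr>
#> 1 bvp           72.1        1.20  0.00943 live
#> 2 resp          14.9        0.249 0.297   <NA>
```

The cardiac chain recovers 72.1 bpm against a ground truth of 72 and the
respiratory chain 14.9 breaths/min against 15; the cardiac ν of 0.009 is
far inside the live region (the classifier's decision boundary sits near
ν ≈ 0.25). The same scene with the physiological amplitudes set to zero —
drift, flicker and sensor noise only — still yields numerical "rates", but
the liveness filter rejects them:

```r
dead <- generate_inanimate_sequence(p)
res_dead <- run_pipeline(dead, bvp_roi = p$skin_roi, resp_roi = p$chest_roi,
                         window_s = 30, stride_s = 30, seed = 1)
res_dead[, c("kind", "rate_per_min", "nu", "liveness_flag")]
#> # A tibble: 2 × 4
#>   kind  rate_per_min    nu liveness_flag
#>   <chr>        <dbl> <dbl> <chr>
#> 1 bvp           44.6 0.603 inanimate
#> 2 resp          19.1 0.521 <NA>
```

Agreement with a reference method:

```r
ref <- c(70, 76, 70, 78, 77)
glance(bland_altman(ref + c(2, -1, -1, 3, 1), ref))
#> # A tibble: 1 × 7
#>   n_pairs mean_diff sd_diff upper_limit lower_limit  rmse     r
#>     <int>     <dbl>   <dbl>       <dbl>       <dbl> <dbl> <dbl>
#> 1       5       0.8    1.79        4.31       -2.71  1.79 0.933
```

A thin command-line interface lives in `inst/cli/vitalcam`
(`measure`, `simulate`, `agree` subcommands) for shell use on frame
directories.

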