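# photosync

Analysis of **dual-region, spectrometer-based fiber photometry** recordings
of neuronal calcium dynamics — the kind of experiment in which two brain
regions (say, a hypothalamic nucleus and the dentate gyrus) are recorded
simultaneously through two optic fibers while an animal performs a spatial
memory task, and the question is *how strongly, and in which frequency band,
the two regions' calcium activities are coupled* across behavioral states.

The package is aimed at systems-neuroscience labs using spectral (full
emission spectrum per frame) photometry with a GCaMP6f + tdTomato dual
labeling strategy. It covers the whole chain from raw spectra to group
statistics, plus a seeded synthetic-session generator that provides ground
truth for every stage, so the entire pipeline is testable without any
recording hardware.

## What it computes

Each 10 Hz frame is a spectrum modeled as
`I(t,λ) = m(t)·b(t)·[c_g(t)·R_g(λ) + c_r(t)·R_r(λ)] + ε`, with `R_g, R_r`
the fluorophores' reference emission curves, `m` a motion factor, `b`
photobleaching. The stages:

| Stage | Function | Method |
|---|---|---|
| Spectral unmixing | `unmix_session()` | per-frame least squares on the reference curves (optional NNLS) |
| Motion correction | `motion_correct()` | green/red ratio × median(red); artifacts are common-mode |
| Bleach correction | `highpass_bleach_correct()` | zero-phase Butterworth high-pass, 0.1 Hz |
| Normalization | `compute_dff()` | ΔF/F = (F − F₀)/F₀, F₀ = session median |
| Band decomposition | `morlet_decompose()` | Morlet CWT (ω₀ = 6, 12 voices/octave), 0.05–2 Hz, band reconstruction with cone-of-influence masking |
| Coupling | `band_correlation_matrix()` | Pearson r per band (band of interest 0.1–0.5 Hz) |
| Group comparison | `fisher_compare_groups()` | z = atanh(r) per animal, unpaired t |
| Peri-event | `align_trials()`, `cumulative_activity()` | ±3 s windows at bout onsets; ∫ΔF/F dt over pre/exploring/post 2 s sub-windows |
| Epoch peaks | `top_k_peak_mean()` | mean of the top 20 ΔF/F local maxima |
| Behavior | `discrimination_ratio()` | (novel − old)/(novel + old) exploration time, with exclusion rules |

`simulate_session()` generates the forward model with known ground truth:
exactly band-limited two-region latents with a controllable shared
component (population band correlation = `rho_band_target`),
exploration-locked transients, bleach, motion pulses and spectral noise.
`run_pipeline()` chains everything with a provenance log; see the methods
vignette (`vignettes/photosync-methods.Rmd`) for the model, parameter and
design details.

## Worked example

Simulate a retrieval-phase session with strong (ρ = 0.9) 0.1–0.5 Hz
coupling and run the full pipeline:

```r
library(photosync)
cfg <- pipeline_config(sim = sim_config(duration_s = 300, rho_band_target = 0.9,
                                        phase = "retrieval", seed = 11))
res <- run_pipeline(cfg)
print(res)
#> <photosync_run>
#>   band 0.1-0.5 Hz inter-regional correlation: R = 0.8863
#>   broadband dF/F correlation: R = 0.8847 (p = 0)
#>   region1 cumulative activity (dF/F*s): pre -0.066, exploring 0.112, post -0.074
#>   region2 cumulative activity (dF/F*s): pre -0.052, exploring 0.095, post -0.056
#>   behavior (retrieval): discrimination ratio -0.579 (novel 3.3 s, old 12.5 s)
#>   seed 11, config 6cb79212a9b6201ec7c490e22878e9ef
```

The headline number is the 0.1–0.5 Hz band correlation (R = 0.886 here,
recovering the ρ = 0.9 ground truth up to sampling error). The per-band
table separates genuine band-limited coupling from the decoupled 1–2 Hz
control band:

```r
res$band_cor[, 1:5]
#>   band_lo_hz band_hi_hz         r    n            p
#> 1       0.05        0.1 0.9104661 2478 0.000000e+00
#> 2       0.10        0.5 0.8863314 2738 0.000000e+00
#> 3       0.50        1.0 0.9113891 2944 0.000000e+00
#> 4       1.00        2.0 0.2716274 2972 1.991897e-51
```

(The 0.5–1 Hz band also reads high here because the exploration-locked
transients — shared event timing across regions — are broadband; in a
no-bout session it drops to noise level.) The cumulative-activity rows show
ΔF/F integrating highest in the exploring (−1 to 1 s) sub-window, where the
bout-locked transients live. The discrimination ratio is negative because
this synthetic schedule happened to favor the old object — the scorer
reports what the bout table contains.

Group-level comparison of per-animal session correlations:

```r
fisher_compare_groups(c(0.91, 0.88, 0.94, 0.90), c(0.55, 0.61, 0.48, 0.57))
#> <group_comparison> mean R: 0.9101 vs 0.5542; t(6) = 10.5314, p = 4.308e-05 (unpaired t on Fisher z)
```

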