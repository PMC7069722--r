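---
title: "Methods: dual-region spectral fiber-photometry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-region spectral fiber-photometry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photosync)
```

# The measurement and the model

A spectrometer-based fiber photometry system records, at 10 Hz per fiber, a
full emission spectrum rather than a single photodetector value. Each frame
is modeled as a nonnegative linear mixture of two fluorophores' emission
curves — GCaMP6f (activity-dependent, green) and tdTomato
(activity-independent, red) — scaled by a common multiplicative gain that
carries slow photobleaching and fast motion artifacts:

$$
I(t, \lambda) \;=\; m(t)\, b(t)\,\bigl[c_g(t)\,R_g(\lambda) + c_r(t)\,R_r(\lambda)\bigr] + \varepsilon(t,\lambda),
$$

where $R_g, R_r$ are max-normalized reference emission curves, $c_g$ is
affine in the neuronal calcium activity, $c_r$ is constant up to noise,
$m(t) > 0$ is the motion factor, $b(t) = e^{-t/\tau}$ the bleach factor, and
$\varepsilon$ is additive acquisition noise.

The analysis chain inverts this model stage by stage:

1. **Spectral unmixing** (`unmix_session`). Per frame, ordinary least
   squares of the measured spectrum on the two reference curves. Because
   both fluorophores share the gain $m\,b$, the fitted coefficients are
   $\hat c_g \approx m\,b\,c_g$ and $\hat c_r \approx m\,b\,c_r$. A
   nonnegative (Lawson–Hanson) variant is available for low-SNR data;
   the unconstrained fit is the default because it is linear, which makes
   the estimator exactly testable against the closed-form normal equations.
2. **Ratiometric motion correction** (`motion_correct`). The green/red
   ratio cancels the common-mode gain; multiplying by the red median
   restores the green order of magnitude. Frames where the red channel
   falls below `epsilon = 0.05` of its median are interpolated (and
   counted) rather than divided through.
3. **Bleach correction** (`highpass_bleach_correct`). A zero-phase
   (forward–backward) second-order Butterworth high-pass at 0.1 Hz.
   Zero-phase filtering preserves event timing, which matters for the
   peri-event analyses below. The effective response attenuates 0.04–0.05 Hz
   power by more than 20 dB while passing 0.3 Hz with < 3% amplitude loss.
   The pre-filter median is re-added so the next stage is well defined.
4. **dF/F** (`compute_dff`). $(F - F_0)/F_0$ with $F_0$ the median of the
   whole session trace (sessions are short, ~5 min, so a single global
   baseline is appropriate; no sliding window). The output median is
   exactly zero and the result is invariant to positive rescaling.

The stage order — unmix, then ratio, then detrend, then normalize — is
fixed by the structure of the forward model: the artifacts are
multiplicative, so they must be cancelled by the ratio *before* any additive
detrending, otherwise the filter distorts the ratio. The order is recorded
in each run's provenance log.

# Band-wise inter-regional correlation

Two simultaneously recorded regions are compared in frequency bands.
`morlet_decompose` computes an FFT-based continuous wavelet transform with
an analytic Morlet mother, $\omega_0 = 6$, on log-spaced scales (12 voices
per octave) covering 0.05–2 Hz, and reconstructs each band's real component
as the inverse-CWT partial sum over the scales whose center frequencies fall
in the band (Torrence–Compo normalization, reconstruction factor
$C_\delta = 0.776$, $\psi_0(0) = \pi^{-1/4}$ for $\omega_0=6$). The default
band segmentation is 0.05–0.1, **0.1–0.5** (the band of interest for slow
calcium coupling), 0.5–1, and 1–2 Hz (a control band).

Numerical choices worth knowing:

* **Cone of influence.** Edge-contaminated frames — within the e-folding
  radius $\sqrt{2}\,s$ of either end, evaluated at the band's largest
  scale — are flagged and excluded from correlation.
* **Energy bookkeeping.** The band components sum exactly to the full
  0.05–2 Hz reconstruction (the bands partition the scale set), but their
  *variances* add only approximately: adjacent bands share spectral mass
  through the Morlet bandwidth ($\sigma_f \approx f/6$), which produces a
  positive cross-band covariance of roughly 17% of the total on broadband
  input. This is intrinsic to non-orthogonal wavelet frames, not an error.
* **Backends.** Band extraction can be cross-checked against a zero-phase
  Butterworth band-pass (`butter_band_component`); the two agree (r > 0.95)
  on tone mixtures. A power-envelope mode (`mode = "envelope"`) is provided
  because reconstructed-signal versus envelope correlation is a genuinely
  open choice for slow calcium signals; reconstruction is the default and
  every output records which mode produced it.
* **High-pass versus the 0.05–0.1 Hz band.** The bleach filter at 0.1 Hz
  attenuates part of the lowest analysis band. The default pipeline
  filters first and decomposes second, so the 0.05–0.1 Hz component of a
  default run is attenuated; callers who need that band unattenuated can
  decompose the motion-corrected trace directly. This ordering ambiguity is
  surfaced here rather than silently resolved.

Per band, `band_correlation_matrix` reports Pearson's r over the jointly
valid frames with a t-based two-sided p on $n-2$ df. Session-level r values
are compared *across animals* with `fisher_compare_groups`: $z =
\operatorname{atanh}(r)$ per subject, then an unpaired two-sample t-test
($df = n_1 + n_2 - 2$). The subject is the experimental unit; per-frame
samples are never fed to the group test.

# Peri-event analysis and behavior

`align_trials` snaps bout onsets to the nearest photometry frame (the
behavioral clock is assumed pre-synchronized; the snap error is at most half
a frame, 50 ms, and is logged), extracts frames with relative time in
$[-3, 3)$ s, and drops (counting them) bouts whose window crosses a
recording edge. `cumulative_activity` integrates dF/F over three half-open
2 s sub-windows — pre (−3 to −1 s), exploring (−1 to 1 s), post (1 to 3 s) —
as a left-Riemann sum times the 0.1 s frame interval, so a constant dF/F of
1 yields exactly 2.0 dF/F·s per sub-window and the three values sum exactly
to the whole-window integral. `top_k_peak_mean` averages the k = 20 largest
local maxima in an epoch, with a 0.5 s minimum inter-peak separation
(larger peaks win ties for space); fewer than k peaks triggers a warning
and the mean of what exists.

`discrimination_ratio` scores novel-place preference as
$(t_{novel} - t_{old}) / (t_{old} + t_{novel})$ per phase. The exclusion
rule is conjunctive by default — excluded if *both* objects drew fewer than
three bouts, or if either drew none — with a strict disjunctive mode
available; the rule that fired is reported, first match wins.
`group_ratio_tests` runs the one-sample (versus zero, i.e. chance) and
unpaired two-sample t-tests on group ratio vectors.

# What the synthetic generator emulates — and what it does not

`simulate_session` provides ground truth for every stage: exactly
band-limited latent dynamics with a controllable shared component, bout
schedules, exploration-locked transients, bleach, motion, and spectral
rendering with noise.

* **Correlated band-limited latents.** Each region is
  $w\,s + \sqrt{1-w^2}\,e_i$ with $s, e_1, e_2$ independent unit-variance
  signals band-limited to 0.1–0.5 Hz and $w = \sqrt{|\rho|}$, giving the
  pair a population band correlation of exactly $\rho$. The components are
  synthesized by a zero-phase FFT brick-wall band-pass of white noise:
  unlike an IIR band-pass, the stopband is exactly empty, so a control band
  (1–2 Hz) sees none of the shared component — only the independent
  broadband noise floor (`ca_noise_sd = 0.05`). An IIR synthesis would leak
  enough of the shared signal into the control band to fake coupling there.
* **Transients.** Difference-of-exponentials kernel, 0.2 s rise / 1.5 s
  decay (GCaMP6f-order kinetics), unit peak, triggered at bout onsets with
  ±20% amplitude jitter per region.
* **Spectra.** Reference curves are log-normal-shaped unimodal densities
  peaking at 512 nm (GCaMP6f) and 581 nm (tdTomato), max-normalized on a
  500–650 nm grid at 2 nm — the collection band above a 488 nm excitation
  longpass. The grid and shapes are conventions (real instruments vary);
  the unmixing only assumes the frames and references share a grid.
* **Defaults as study conditions.** 10 Hz frames; 300 s sessions (the
  5-minute epoch length of the task and home-cage recordings; recovery
  studies that need tighter sampling error use 600 s); bleach $\tau$ = 300 s;
  10% motion pulses; default $\rho$ = 0.4 (a typical resting coupling);
  transient amplitude 1 (dF/F-scale via a gain of 0.25 on a baseline of 1).
* **Negative intensities** after noise are clipped at zero (photon counts
  are nonnegative) and counted; a clip fraction above 1% warns.

Not emulated: video or tracking (bout tables are consumed, never computed),
hardware (lasers, commutators, spectrometer calibration), spike-to-calcium
transfer beyond the kernel convolution, wavelength registration between
mismatched grids, and isosbestic-style correction alternatives. Passing
tests on this generator therefore demonstrate correctness of the *analysis*
given the stated forward model — not robustness to instrument drift,
hemodynamic contamination, or indicator nonlinearity, none of which the
generator produces.

# Validation design and problem sizes

The test suite checks each stage against an independent oracle computed a
different way: unmixing against the closed-form normal equations and (for
the nonnegative mode, two fluorophores) an exhaustive active-set
enumeration; band correlation against direct Pearson correlation of the
stored ground-truth components; motion correction against the stored
artifact-free coefficients; cumulative activity against analytic integrals
of constant and ramp inputs; peak statistics against the sorted injected
amplitudes; group tests against their nominal type-I error under simulated
nulls (1000 replicates, α = 0.05).

Problem sizes were chosen as the smallest at which sampling error is
negligible relative to the tolerances: 3000-frame (300 s) sessions for
unmixing and preprocessing fidelity; 600 s sessions × 20 seeds per coupling
target for correlation recovery (the sampling sd of band r at 600 s is
≈ 0.02–0.05, so 20-seed means resolve 0.07 tolerances comfortably); and 40
cohort pairs of 6 simulated animals × 8 bouts per phase (~48 pooled trials,
the order of magnitude at which the phase contrasts operate) for the
retrieval-versus-encoding direction checks. The qualitative contrast uses
retrieval-like coupling 0.92 with transient amplitude 2 against
encoding-like 0.54 with amplitude 1.

# Known limitations

* The Morlet band reconstruction is a non-orthogonal partial sum; band
  variances cross-talk by ~17% between adjacent bands (see above). Band
  *correlations* are unaffected in practice because both regions are
  decomposed identically.
* A single global median $F_0$ assumes stationary baseline within a
  session; very long recordings with residual drift would need a windowed
  baseline, which this package deliberately does not implement.
* The unmixing fits no background/autofluorescence term by default; data
  with substantial spectral background need a third basis column, which the
  reference-spectra container supports but the simulator does not generate.
* The exclusion rule's conjunctive reading ("both objects fewer than three
  times") is one of two defensible parses; the strict mode exists for the
  other, and results report which rule fired.
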