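---
title: "Phase-coupling decomposition: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-coupling decomposition: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdenoise)
```

## The forward model and what PCD assumes

The recorded multichannel signal is treated as an instantaneous linear mix
of statistical sources, `X = A S`, with `X` a channels × samples voltage
matrix. At least one source is assumed to be an acoustic-induced vibration
artifact: the participant's voice couples mechanically into the acquisition
chain, so that one source is (approximately) the produced audio waveform
`z` itself. Phase-coupling decomposition (PCD) estimates an unmixing matrix
whose leading components are maximally phase coupled to `z`, and
reconstructs the data with those components removed.

Three assumptions carry the method:

1. **Narrow-band artifact.** The artifact concentrates in a band
   `Fc ± ΔFc` around the voice fundamental F0 (the speech-artifact
   frequency band, SAFB). Broadband artifacts violate this and degrade the
   spatiospectral step.
2. **Common artifact across modalities.** Because the coupling happens in
   the cabling/amplifier chain, all simultaneously recorded modalities are
   stacked into one sensor space before fitting
   (`run_pcd_trial()` treats the trial's channel dimension as one space).
3. **The audio is a faithful artifact proxy.** No spectral distortion or
   delay between `z` and the artifact source is modeled. `fit_pco()`
   optimizes instantaneous phase coupling; a systematic audio-artifact lag
   would show up as reduced mean vector length.

Because the artifact's phase relation to the audio changes from trial to
trial, the model is fitted per trial on an epoch around the produced-speech
onset and then applied to a wider epoch, so downstream analyses see no
discontinuities at epoch borders.

## The four stages and their tunable parameters

### 1. Band estimation (`estimate_f0()`, `estimate_safband()`)

The audio's Welch power spectrum is searched for its largest prominent peak
in the voice range (default 50–250 Hz); a Gaussian plus a constant floor is
then fitted to the spectrum in a ±25 Hz window around that peak
(`minpack.lm` Levenberg–Marquardt). The band center `Fc` is the fitted
mean; the half-extent `ΔFc` is the fitted full width at half maximum
(2.355 σ), floored at two frequency bins. Whether "band width" means the
FWHM or half of it is a genuine ambiguity; we take `ΔFc = FWHM`, which for
voiced speech (spectral peaks a few Hz wide) yields total SAFB widths of
roughly 10–20 Hz — wide enough to cover pitch jitter within a trial,
narrow enough to leave the rest of the gamma band untouched.

Two Welch resolutions are used deliberately. The *width fit* uses 1 s Hann
segments (1 Hz bins), because ΔFc is resolution-limited from below. *Peak
finding* uses 0.5 s segments: the prominence rule ("peak ≥ 6 dB above the
in-band median") needs enough segment averages to be selective, and a
2.5–3 s fitting epoch provides only 3–4 one-second segments, at which point
a flat spectrum produces spurious 6 dB excursions; with ~10 averages the
rule rejects white noise reliably while any voiced F0 peak clears it by an
order of magnitude. A failed Gaussian fit falls back to
`(Fc = F0, ΔFc = 5 Hz)` with a warning.

### 2. Spatiospectral decomposition (`fit_ssd()`)

The data are split into `X_signal` (zero-phase Butterworth band-pass over
the SAFB, order 4 per pass) and `X_noise` (band-stop complement over the
same edges — "everything except the SAFB", rather than flanking bands).
SSD solves the generalized eigenvalue problem

\[
\Sigma_{signal}\, w \;=\; \lambda\, \Sigma_{noise}\, w ,
\]

with channel-space covariances `Σ = X_band X_bandᵀ / Ns`. We solve it by
symmetric whitening of `Σ_noise` followed by a symmetric
eigendecomposition, which yields filters normalized to
`wᵀ Σ_noise w = 1` and eigenvalues equal to the in-band/out-of-band power
ratio of each component. `Σ_noise` receives a Tikhonov ridge of
`1e-6 · trace/Nc` before inversion; if it is still numerically singular the
fit aborts with a rank diagnostic rather than returning garbage filters.
Filter signs are fixed by making each column's largest-magnitude entry
positive (eigenvectors are otherwise sign-ambiguous). Where eigenvalues are
degenerate the corresponding filters are only defined up to rotation — a
caveat for anyone comparing filter matrices across runs, not a defect.

The retained dimension is the participation ratio
`k = ⌊(Σλ)² / Σλ²⌋`, an effective dimensionality of the eigenvalue
spectrum: a single dominant in-band direction gives `k = 1`, a flat
spectrum gives `k = Nc`.

### 3. Phase-coupling optimization (`fit_pco()`)

In the retained SSD space the analytic signal `Y = X̃ + i·H(X̃)` is formed
(FFT Hilbert transform) and the real part is PCA-whitened
(rank-truncated at condition 10⁸). A real filter `w` is then sought that
maximizes the mean vector length

\[
\mathrm{MVL}(w) \;=\; \Bigl|\tfrac{1}{N_s}\sum_t z_t\,
\frac{w^\mathsf{T} y_t}{|w^\mathsf{T} y_t|}\Bigr| ,
\]

with `z` the z-scored audio. The objective is smooth but nonconvex and
scale-invariant in `w`; each component is the best of `n_restarts`
(default 10) BFGS ascents with the analytic gradient, from random unit
starts drawn once from the model seed, converged at relative tolerance
1e-10 or 500 iterations. A guard of 1e-12 on the projection amplitude
prevents division by zero at isolated samples. Components are extracted
sequentially, each search confined to the orthogonal complement of the
filters already found, and finally sorted by achieved MVL. Filters are
*not* sign-normalized: a solution and its negation are equivalent (the
extracted source may be in phase or in antiphase with the audio), and the
reconstruction below is invariant to that sign.

The number of artifactual components `m` is selected at the elbow of the
descending MVL trace — the index just before the largest discrete second
difference, clamped to `[1, k−1]`, with `m = 1` whenever `k ≤ 2`. A fixed
`m` can be forced through the configuration for sensitivity analyses.

### 4. Composition and low-rank reconstruction

The two filter stages compose into a single channel-space unmixing

\[
W_{pcd} \;=\; W_{ssd}
\begin{bmatrix} M & 0 \\ 0 & I \end{bmatrix}^{\mathsf T}
\begin{bmatrix} W_{pco} & 0 \\ 0 & I \end{bmatrix},
\qquad A_{pcd} \;=\; \mathrm{pinv}(W_{pcd}^{\mathsf T}),
\]

with `M` the k-dimensional whitening matrix embedded block-diagonally
(identity on the non-retained SSD directions). This makes
`W_pcdᵀ X` exactly path-equivalent to applying SSD, whitening, and PCO in
sequence, and `A_pcd` the Moore–Penrose companion under which the
forward/backward pair `X = A S`, `S = Wᵀ X` is consistent. Denoising zeroes
the `m` leading columns of both matrices:
`X_denoised = A[,-(1:m)] (W[,-(1:m)])ᵀ X`. With `m = 0` and a
well-conditioned square `W` this is the identity; removing all components
is rejected.

### Trial orchestration (`run_pcd_trial()`)

Defaults: high-pass above 2 Hz and zero-phase notches at 60/120/180/240 Hz
(notches at or above Nyquist are skipped); fit epoch −0.5 s to +2.0 s
around the produced-speech onset (the bounds are not dictated by the
method and are exposed in `pcd_config()`); application epoch ±6 s, clipped
at the recording edges; the audio is z-scored with the fit epoch's
statistics. All Butterworth filters run forward–backward with
odd-reflection padding sized from the slowest pole's decay (eight time
constants), so that zero-phase behavior holds in the epoch interior and
low-frequency filters do not leak start-up transients into the data.

## What the synthetic data emulates — and what it does not

The generator stands in for a spiking-network simulation of physiological
gamma. It reproduces the statistical features that matter for evaluating
artifact removal, not the biophysics:

* **Neural sources** are 60–200 Hz band-limited Gaussian noise with a
  deterministic amplitude envelope: a Gaussian burst
  (`A·exp(−(t−μ)²/(2(FWHM/2.355)²))`, FWHM 0.5 s, centered after the
  speech onset) for the realistic speech-locked scenario, or a sustained
  envelope with slow periodic modulation (`As + Ap sin(2π f_p t + φ_p)`)
  for the parameter-sweep toys. Optional phase–amplitude coupling
  multiplies the envelope by `1 + d·cos(2π f t)`.
* **Artifact source**: a noisy sinusoid at F0 (SAS), colored noise with an
  order-25 Butterworth band-pass spectrum over `F0 ± dF` (CAS), or that
  colored noise gated by three 0.5 s syllable windows (MCAS). The
  colored-noise spectrum is imposed by FFT-domain shaping with the analytic
  Butterworth magnitude response — at order 25 a recursive `(b, a)`
  realization is numerically unstable, while spectral shaping is exact and
  zero-phase.
* **Mixing**: a standard-normal random matrix; the artifact is rescaled so
  that the artifact-to-gamma ratio
  `AGR = 10·log₁₀(P_artifact / P̄_gamma)`, measured as mean Welch power in
  the 60–200 Hz band, hits its target exactly. The AGR definition is not
  pinned down by the source material beyond "inverse of SNR"; in-band gamma
  power is the natural denominator because that is the band the artifact
  competes with. Per-trial parameters (sources, noise, mixing) all derive
  from a single named seed; `mix_seed` can be held fixed across trials to
  emulate a stable acquisition chain — which is what gives the artifact a
  consistent cross-trial phase and makes intertrial phase consistency
  (ITPC) able to detect it. Degenerate (rank-deficient) mixing draws are
  redrawn from a documented substream with a warning.

Not emulated: spiking dynamics and their input entrainment, 1/f background,
line noise, electrode drift, audio-to-artifact transfer distortion, room
acoustics. Consequently, passing benchmarks here demonstrate correct
behavior of the *decomposition machinery* under its own assumptions; they
do not certify performance on recordings where those assumptions fail
(notably broadband or distorted artifacts).

Desk-scale problem sizes are used throughout: 16 (sweeps: 8–32) channels,
3 s trials at 1 kHz, 20-trial sessions, 3 gamma-burst sources in the
realistic scenario. The toy sweep instead uses sustained-periodic sources
with `min(Nc−1, 8)` sources: chance-level coherence floors average across
effective source dimensions, and with only three sources the artifact-free
floor itself fluctuates enough to blur the comparison the sweep is making.

## Evaluation metrics and their conventions

* `msce()` — Welch magnitude-squared coherence; on 3 s epochs we evaluate
  it with 0.5 s segments (11 averages), keeping the chance floor
  (≈ 1/#segments) near 0.09; with 1 s segments the floor of a 3 s epoch is
  ≈ 0.2 and swamps the quantity of interest.
* `plv()` — phase-locking value from analytic phases; phase differences
  are *not* folded. Where the in/antiphase equivalence matters (comparing
  a recovered artifact source to the truth), the folding
  `min(|Δφ|, π − |Δφ|)` is applied explicitly at the point of comparison.
* `itpc()` — per trial, the normalized inner product between the 70–240 Hz
  band-passed analytic channel and audio; across trials,
  `|mean(φ)| / std(φ)` with `std` the RMS deviation of the complex values
  about their complex mean (the complex-dispersion convention under which
  the published significance threshold 3.08 is used as given). Identical
  phases across trials give `Inf` with a degeneracy flag implicit in the
  value.
* `artifact_summary()` — homogeneity `1 − Nc·var(ϑ/‖ϑ‖)`. The `Nc`
  multiplier is the only scaling that maps the variance range of a unit
  vector, `[0, 1/Nc]`, onto `[1, 0]`; the closed forms (1 for a uniform
  artifact, `1/Nc` for a one-channel artifact) are pinned in the tests.
* `normalized_mse()` — MSE after dividing each signal by its own maximum
  absolute value. When comparing a recovered source to ground truth the
  estimate's sign is first aligned by the sign of the correlation, since
  the decomposition determines the source only up to sign.
* `loading_cosine_similarity()` — absolute cosine similarity of the first
  three PCA loadings, fitted independently to each dataset; absolute value
  because PCA loading signs are arbitrary.

## Baselines

`car()` implements the common average reference as the explicit projector
`I − J/Nc` (applied per modality on request) — useful precisely because it
fails in a characteristic way: it removes a perfectly channel-homogeneous
artifact exactly and *subtracts the artifact into* clean channels when the
artifact is channel-specific. `ica_denoise()` implements the conventional
pipeline: 2 Hz high-pass, channel z-scoring, PCA at 99% explained
variance, a deterministic maximum-likelihood ICA (symmetric fixed-point
iteration with the logcosh nonlinearity on whitened scores, tolerance
1e-7, 500 iterations; non-convergence returns the best iterate with a
warning flag), components ranked by phase-locking value with the audio
inside the SAFB, and the same elbow rule as PCD for the removal count —
mirrored deliberately so the two pipelines differ only in how they find
components, not in how many they remove.

## Known limitations

* Performance degrades for broadband artifact spectra (an SSD limitation);
  the colored-noise scenarios probe this at `dF = 8 Hz` but nothing wider.
* No modeling of audio-to-artifact distortion or delay.
* Strictly offline and trial-wise; the nonconvex PCO stage with restarts
  is the computational bottleneck and is not suited to streaming use.
* The EDF reader is minimal (16-bit EDF, single common sampling rate,
  annotations dropped); mixed-rate files are rejected rather than
  resampled. The trial container is R-native serialization with a fixed
  list layout, readable only from R.
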