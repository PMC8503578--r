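---
title: "Extracting seizure-onset activity from scalp EEG and validating it against intracerebral recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In presurgical evaluation of focal epilepsy, stereo-EEG (SEEG) depth
electrodes record the seizure-onset zone (SOZ) directly but sparsely, while
scalp EEG sees everything but buried under mixing, noise and muscle.
`seizcoh` implements a fully quantitative pipeline for asking: *can the
seizure-onset activity be pulled out of the scalp recording as an
independent component (IC), and does that component really reflect the
generator the depth electrodes see?* The validation instrument is wavelet
coherence between scalp ICs and simultaneously recorded SEEG signals, with
surrogate-calibrated significance, plus equivalent-current-dipole (ECD)
localization of the IC topography against the SOZ position.

Because real simultaneous scalp/SEEG sessions cannot be shipped with a
package, `seizcoh` includes a synthetic session generator with full ground
truth; every stage of the pipeline is exercised and tested against it.

## The synthetic sessions

A session is built from a spherical head (radius 92.5 mm, homogeneous
conductivity 0.33 S/m) with an idealized 21-electrode 10-20 scalp cap and a
clinical-style implantation of 7 depth shafts (62 contacts, 3.5 mm pitch);
one shaft runs along the source axis so that a nearby contact pair exists at
every probed depth, the other six explore distant regions, as real
implantations mostly do.

**The ictal generator is a patch, not a point.** Scalp-visible ictal
patterns require of the order of 10 cm² of synchronously active cortex, and
a fitted ECD is best read as the center of a broad dipole sheet. The default
generator is therefore a 30 mm geodesic-radius cap (~28 cm²) of
surface-normal dipoles sharing one waveform and splitting a total moment of
65 nA·m. This has two consequences that matter: the scalp topography has a
realistic spatial extent (a point dipole 14 mm under the scalp of a
homogeneous sphere — which has no skull to blur it — is so focal that the
pipeline's own artifact screen would reject it), and the fitted ECD lands
slightly *deeper* than the patch, the classic extended-source depth bias.

Waveform patterns follow the seizure-onset morphologies seen in SEEG:
low-voltage fast activity (LVFA; noise-like, bandwidth 8% of the center
frequency, default 60 Hz, with an envelope that builds up linearly over the
discharge — it starts genuinely low-voltage), bursts of polyspikes followed
by ~10 Hz repetitive discharges, a plain repetitive spike train, and
sporadic preictal spikes. All are silent before the onset marker except the
preictal pattern, and all are unit-RMS so the amplitude parameter is
interpretable. The default total moment (65 nA·m; the literature gives no
calibrated value for an ictal patch) was set so that the scalp-visibility
transition falls inside the probed depth range: at 0.85 R the component is
recovered essentially perfectly, at 0.45 R it hovers at the edge of
detectability — the regime the clinical observations describe, where
superficial onsets are scalp-visible and deep (insular, mesial) ones are
not.

The background is 120 independent dipole sources (10.6 nA·m RMS each)
spread through the sphere, with 1/f spectra flattened by a broadband floor
(real EEG spectra flatten in the gamma band) and slowly modulated
amplitudes (background rhythms wax and wane — the resulting mild
super-Gaussianity is also what lets ICA resolve the strong background
generators into dipolar components, as it does on real EEG). On top: 5 µV
white amplifier noise per stream, and 20–100 Hz band-limited EMG (5 µV) on
the temporal/frontal scalp channels only — the SEEG, referenced
intracranially, is EMG-free. The background dimensionality is deliberately
high: with only a handful of background sources, the residual mixture left
in an IC after unmixing is dominated by a few sources that individual SEEG
pairs also see, and far pairs show above-chance coherence that no real
recording shows.

For the depth sweep, the axial SEEG shaft is placed so the generator always
projects midway between two adjacent contacts: the eccentricity step
(9.25 mm) is 2.64 contact pitches, and without this the source's phase on
the 3.5 mm contact grid — and with it the SOZ pair's bipolar amplitude —
would oscillate pseudo-randomly across the swept depths, confounding the
variable of interest.

**Two clocks.** The two streams emulate galvanically isolated amplifiers:
the SEEG stream's content is delayed by `imposed_lag` samples (fractional
allowed) and its clock runs at `fs (1 + drift_ppm 1e-6)`. Both carry a
digital trigger channel (pulses every 10 s) and a 50 Hz reference sine.
Sessions default to 64 s at a desk-scale rate (512 Hz for the generator,
256 Hz in the analyses below): the 4 s tail beyond the last trigger keeps
all `floor(duration/interval)+1` pulses inside both streams under realistic
lags, which an exact multiple of the trigger interval cannot do.

## Alignment

The 50 Hz sine alone determines the lag only modulo its period (fs/50
samples); the triggers resolve the integer ambiguity. Per trigger, a 2 s
window of the reference sine is compared across streams: the trigger
pairing bounds the residual shift to under one sample, so the sine *phase
difference* (Hann-windowed single-bin DFT), wrapped to half a period,
resolves it with ~0.001-sample precision — more accurate than parabolic
interpolation of the cosine-shaped correlation peak, which is kept only as
a fallback for degenerate sines. A linear fit of per-trigger lags over time
gives the drift (slope) and the lag at stream start (intercept); merging
resamples the second stream onto the first clock by cubic splines along the
piecewise-linear lag function. On the synthetic sessions an imposed lag of
1234.25 samples with 100 ppm drift is recovered to well under 0.05 samples
and trigger coincidence after merging is within one sample.

## Preprocessing

Scalp and SEEG channels are band-passed 5–100 Hz with a Hamming
windowed-sinc FIR (transition 2 Hz; taps from the Hamming rule
≈ 3.3·fs/Δf, forced odd), applied zero-phase by exact group-delay
compensation. SEEG is re-referenced to a bipolar montage of consecutive
same-shaft contacts; each pair's geometric midpoint is the spatial referent
for distance profiles. Whether the SEEG should also be band-passed before
coherence is a genuinely open choice; the default applies the same band to
both streams for comparability, with a flag to disable. The ictal epoch is
30 s: 20 s before the onset marker, 10 s after.

## ICA and screening

Extended infomax (natural-gradient, sub/super-Gaussian switching by the
stability criterion, learning-rate annealing on the update angle) after PCA
whitening; rank deficiency reduces the dimension with a warning. The
decomposition is deterministic under a seed, activations are unit-variance
(scale lives in the topographies), and recovery is always evaluated by
best-matched absolute correlation, never raw ordering.

Screening removes artifact-like components with an outlier electrode.
The Z-score is computed leave-one-out — each electrode's absolute deviation
from the mean of the *others*, over their SD — because the naive all-in
Z-score is bounded by (n−1)/√n, below 6 for any cap of ≤ 37 electrodes, and
a threshold of 10 could never fire. Components are retained when unflagged
and their ECD goodness of fit exceeds 90% (a dipolar topography);
candidates are ranked by GOF. Choosing the ictal component among the
candidates is an expert step in clinical practice; analyses here select by
maximal SNA against the SOZ pair (ground truth in simulations), and an
explicit override exists.

## Dipole fitting

A single ECD in the head sphere. The surface potential of an interior
dipole has a closed form (the generating-function sum of the classical
Legendre series), so the forward model is exact and cheap; the test suite
checks it against an independently coded truncated series. Fitting
minimizes residual variance over position with the moment solved linearly
at each candidate position; the search combines a deterministic
Fibonacci-sphere coarse grid (3 shells × 40 directions) with seeded random
restarts and BFGS refinement on a smooth unconstrained parameterization of
the ball of eccentricity 0.95 (the surface is a gain singularity).
GOF = 100·(1 − residual/total variance). Noiseless forward topographies are
recovered to sub-mm accuracy; 5% sensor noise keeps errors under 10 mm.

## Wavelet coherence and significance

Morlet transform with oscillation parameter ξ = 7 (temporal SD
σ(f) = ξ/2πf, width 2σ = ξ/πf), frequencies log-spaced at 10 voices per
octave from 5 to 100 Hz (44 rows). The implementation is cross-correlation
with the sampled analytic wavelet truncated at ±4σ, computed via FFT — it
equals a direct time-domain convolution to rounding, which the oracle test
exploits. A display-only Z-scored map (baseline = the lowest-amplitude 20%
of each row) makes weak high-frequency activity visible but never feeds the
analysis.

Coherence smooths the cross- and auto-spectra with a rectangular kernel
spanning 20σ(f) seconds in time per row and 10 voice rows in frequency
(both truncated at the array boundary). A point is an *edge point* when its
time-smoothing window overruns the record, so the excluded band widens
toward low frequencies; all counts use non-edge points only.

Significance thresholds are calibrated per frequency as the 0.95 quantile
(linear interpolation of order statistics) of coherence pooled over 200
independent two-channel white-noise realizations of the same length, rate
and parameters. Pooling subsamples the non-edge time axis at stride 4 —
after 20σ smoothing, neighboring points are strongly autocorrelated, so the
stride only bounds memory. The package verifies the calibration the only
way that matters: on fresh noise the per-frequency exceedance is
0.05 ± 0.01. 1/f surrogates are available behind a flag and shift the
thresholds only modestly (reported by `analysis/03_surrogate_calibration.R`:
median 1.4%, max 7.3% relative); `phase_scramble()` builds data-driven
surrogates for a specific signal pair when the extra sensitivity is worth
the cost.

The per-plane statistics are Ns (significant non-edge points) and
SNA = Ns/total. Outlier planes across pairs are those with
Ns > m + 5·(Q₀.₇₅ − Q₀.₂₅) on the Ns distribution (median and quartiles,
same quantile convention; strict inequality, so an all-equal distribution
selects nothing).

## Spatial statistics

Distances are Euclidean in the common mm frame (coordinates are assumed
co-registered; no registration is performed). The SOZ geometric center is
the unweighted mean of its contact coordinates; the localization error
d_SOZ is the dipole-to-center distance. Coherence–distance association is
reported as Pearson r and Spearman ρ with two-sided p-values; LOWESS
(tricube local linear, `stats::lowess`) is display-only.

## What the synthetic study does and does not show

The depth sweep (eccentricities 0.45–0.85 R, 5 seeds each, analyzed fully
end to end) reproduces the study's central qualitative findings: the SNA
between the selected IC and the true SOZ pair roughly doubles from the
deepest to the shallowest condition — deep generators are barely visible on
scalp — and the maximum-coherence SNA falls with the distance between that
pair and the fitted dipole (negative Spearman ρ). These are *sign and
shape* properties. Two statistical caveats are worth stating plainly.
First, in a homogeneous sphere the scalp attenuation of a fixed patch
changes only by a factor ~2.4 across the probed depths, so adjacent-depth
differences in median SNA (a few hundredths) are the same order as the
sampling noise of a 5-session median under decomposition-level variability:
the end-to-end rise is robust, strict monotonicity of all five medians is
not guaranteed on every seed set. Second, the per-frequency surrogate
thresholds inherit the Monte-Carlo error of the 200-realization quantile;
at the lowest frequencies, where the 20σ smoothing window leaves only a
handful of independent time points per epoch, that error alone moves the
empirical exceedance by ±0.005–0.007 around the nominal 0.05. The
generator also omits skull and CSF layering, real cortical geometry,
spreading seizure dynamics, electrode artifacts and non-stationary EMG, and
the group-level numbers of any real cohort (mean localization errors, mean
SNA) depend on patient anatomy and template head models — passing tests
demonstrate that the statistical machinery is correct and calibrated, not
that a particular clinical error in millimeters would be achieved.

## Numerical choices and degenerate inputs

Problem sizes used throughout the analyses: 30 s epochs at 256 Hz, 200
calibration and 100 validation surrogates, 25 sweep sessions; these keep a
full run on one desktop core in the tens of minutes while leaving every
Monte-Carlo check comfortably inside its tolerance. Other specifics:
quantiles are always type-7; coherence denominators are floored at the
smallest positive double (zero-power windows give coherence 0); the
Z-display floors a zero-variance baseline SD at machine epsilon with a
warning; the EDF writer quantizes to the 16-bit range read back from its
own ASCII-rounded physical scaling, so a round trip is exact to the
quantization step; all simulation and fitting randomness is seeded, and a
fixed seed reproduces sessions bit for bit.
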