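# seizcoh

Can the electrical signature of a seizure onset be pulled out of ordinary
scalp EEG, and how would you know you got the right one? In presurgical
evaluation of focal epilepsy, stereo-EEG (SEEG) depth electrodes record the
seizure-onset zone (SOZ) directly, which makes simultaneous scalp + SEEG
recordings a rare chance to validate non-invasive analysis against ground
truth. `seizcoh` implements that validation pipeline for R, together with a
fully synthetic simultaneous-session generator so every stage can be tested
against known ground truth on a desk.

The pipeline: align two independently clocked amplifiers (digital triggers
for the integer lag, a 50 Hz reference sine for the sub-sample residual and
clock drift), band-pass 5–100 Hz (Hamming windowed-sinc FIR, zero phase),
re-reference the SEEG to a bipolar montage, decompose the 30 s ictal scalp
epoch (20 s before / 10 s after the onset marker) with extended-infomax
ICA, screen components (leave-one-out outlier-electrode Z > 10; equivalent
current dipole goodness of fit GOF > 90 % in a spherical head model), and
quantify each component–SEEG-pair coupling by Morlet wavelet coherence
(ξ = 7, 5–100 Hz, 10 voices/octave, 20σ × 10-voice smoothing):

    C = |S(X Y*)|² / ( S(|X|²) · S(|Y|²) )

Per-frequency significance thresholds are the p = 0.05 quantile of
coherence over 200 two-channel white-noise surrogates; the **significant
normalized area** SNA = Ns / N is the fraction of non-edge time–frequency
points above threshold, and pairs with Ns > m + 5·(Q₀.₇₅ − Q₀.₂₅) across
all pairs are flagged as outliers. Spatial statistics relate the selected
component's fitted dipole to SEEG pair midpoints and the SOZ geometric
center (localization error d_SOZ, Pearson/Spearman coherence–distance
correlations, LOWESS display smoothing).

## Worked example

Simulate a shallow (0.85 R) ictal generator — a 30 mm cortical patch
emitting 60 Hz low-voltage fast activity over a 1/f background, recorded by
a 21-electrode scalp cap and 62 SEEG contacts on 7 shafts by two
independently clocked amplifiers — then analyze it end to end:

```r
library(seizcoh)
demo <- make_demo_session(eccentricity = 0.85, seed = 11, amplitude = 100,
                          imposed_lag = 1234.25, clock_drift_ppm = 100)
al <- align_streams(demo$session$scalp, demo$session$seeg)
al
#> <alignment> coarse 1234, fine 1234.250 samples, drift 100.00 ppm, residual 0.000

res <- analyze_session(demo$session$scalp, demo$session$seeg,
                       demo$sensors, demo$head,
                       so = demo$session$truth$onset_time,
                       soz_labels = demo$session$truth$soz_labels,
                       ica_seed = 7)
demo$session$truth$soz_pair     # ground truth
#> [1] "V12-V13"
res$outliers$selected_pairs     # pairs flagged by the Ns outlier rule
#> [1] "V12-V13" "V13-V14"
round(res$screens$gof[res$selected], 1)   # dipolarity of the selected IC, %
#> [1] 99.8
round(res$spatial$d_soz, 1)     # dipole-to-SOZ-center error, mm
#> [1] 11.1
round(res$spatial$correlations$spearman_rho, 2)
#> [1] -0.4
```

The alignment recovers the imposed inter-amplifier lag (1234.25 samples)
and clock drift (100 ppm) essentially exactly; the outlier rule on the Ns
distribution singles out the bipolar pairs at the true SOZ; the selected
component is dipolar (GOF 99.8%) and its dipole lands ~11 mm from the SOZ
center; and coherence falls with distance from the dipole (negative
Spearman rho), the study's central spatial signature.

The numbered scripts under `analysis/` run the full study on synthetic
ground truth and write their tables under `results/`: session generation
and EDF/TSV/JSON export (01), alignment recovery (02), surrogate-threshold
calibration with a type-I-rate check and a white-vs-1/f robustness report
(03), the single-session analysis above (04), and the depth-visibility
sweep — eccentricities 0.45–0.85 R × 5 seeds, showing that scalp
visibility of the onset rises with eccentricity while coherence falls with
dipole distance (05).

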