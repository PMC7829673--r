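---
title: "Models and methods in fnirsuite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fnirsuite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsuite)
```

This vignette documents the models implemented in fnirsuite, the
assumptions behind them, the tunable parameters and the reasoning behind
every numerically consequential choice. It is the package's reference for
*why* the code does what it does; the function reference documents *what*
each call computes.

## The data model

fNIRS measures cortical hemodynamics through scalp optodes: each
source–detector pair ("channel") yields a time series of raw optical
intensity at (typically two) wavelengths, or, after conversion, relative
concentration changes of oxy- (HbO) and deoxyhemoglobin (HbR), with total
hemoglobin HbT = HbO + HbR. The central container, `NirsRecording`, stores
a time-by-column matrix with uniform sampling: time is carried implicitly
as a sampling rate, and SNIRF files with nonuniform time vectors (relative
jitter above 1e-6) are rejected rather than silently resampled, because
resampling at import time would alter spectral content without the user's
knowledge. Columns are chromophore (or wavelength) blocks — all channels
of HbO, then all channels of HbR — matching the package's CSV dialect,
which fixes the block order (HbO first, HbT never stored, always derived)
to remove the main ambiguity of free-form text input. Channel identifiers
are 1-based everywhere user-facing, the convention of the field.

Every mutating operation appends exactly one record (name, parameters,
timestamp) to the recording's history. The history is the audit trail that
makes a processing protocol reportable and a serialized pipeline
re-runnable; timestamps are excluded from batch outputs so that identical
configurations reproduce output files bitwise.

## Beer–Lambert conversion

Raw intensity is converted to optical density against a baseline
$I_0(\lambda)$, by default the temporal mean per wavelength — the common
convention when no designated baseline period exists; a configured window
can replace it. The modified Beer–Lambert law is inverted as a 2×2 linear
system per sample. Units: extinction coefficients in mm⁻¹·mM⁻¹ (decadic),
source–detector distance in mm, so concentrations come out in mM. The
packaged extinction table is a compiled literature spectrum sampled at
10 nm steps from 650–900 nm with nearest-nm lookup; the differential
pathlength factor defaults to 6.0 at both wavelengths, the conventional
adult-head value. Both are configurable because systematic errors in
either scale the recovered concentrations; since all downstream statistics
are scale-invariant within channel, this mainly matters when comparing
absolute amplitudes across studies. Only the two-chromophore,
two-wavelength inversion is implemented; an overdetermined multi-wavelength
least-squares fit is a documented extension point.

## Preprocessing

Steps are composable in any order through `PipelineSpec`; the package's
reference resting-state order is detrend → motion correction → band-pass
filter (trimming and resampling where needed). Reasons for the defaults:

* **Detrending** (default order 1) fits an orthogonal polynomial basis on
  a time axis normalised to [−1, 1]. The orthogonal basis keeps the
  normal equations well-conditioned at higher orders; the intercept is
  always included, so output channels are exactly mean-zero.
* **CBSI** assumes the neural components of HbO and HbR are strongly
  anticorrelated while motion moves both with the same sign. The
  correction is the closed form $HbO' = (HbO - \alpha HbR)/2$ with
  $\alpha = \sigma_{HbO}/\sigma_{HbR}$ and $HbR' = -HbO'/\alpha$; the
  output correlation is −1 *by construction*, so that property is a
  structural test, not an empirical one. Channels with zero HbR variance
  have no defined $\alpha$ and are skipped with a warning.
* **TDDR** targets spikes and baseline shifts without tunable thresholds:
  the signal is split at 0.5 Hz (skipped when the sampling rate is at or
  below 1 Hz, where the split is undefined), the temporal derivative of
  the low-frequency part is iteratively reweighted with the Tukey
  biweight (tuning constant 4.685, robust scale 1.4826·MAD, at most 50
  iterations, stopping when the weights move by less than 1e-10), the
  weighted derivative is re-integrated, and the mean and high-frequency
  part are restored. These constants follow the original published
  algorithm. Note that TDDR preserves the (possibly contaminated) signal
  mean; performance comparisons against a reference signal are therefore
  made on demeaned series, which is also the natural scale for relative
  concentration changes.
* **Filtering** offers three designs. The Butterworth IIR (default order
  3) is applied zero-phase (forward–backward) because phase distortion
  would bias connectivity and spectral-amplitude analyses; the effective
  magnitude response is then $|H(f)|^2$, which is documented rather than
  hidden. Zero-phase application uses odd-reflection padding *and*
  steady-state initial conditions for both passes, so that constant
  signals pass through exactly and start-up transients do not leak into
  the analysis window. The FIR design is a Hamming-window filter (default
  order 34), applied single-pass with its integer group delay (order/2
  samples) removed — hence the order must be even. The FFT-ideal filter
  zeroes every bin strictly outside the passband; DC is removed for band-
  and high-pass (re-addable via `keepDC`) and kept for low-pass. Its
  passband is exact on-bin, which makes it the reference filter in tests.
* **Nuisance regression** is per-channel OLS on an intercept plus the
  short-separation reference channels (or external series), keeping
  residual + intercept. Collinear regressors are dropped with a warning
  instead of failing, and per-channel R² goes into the history record so
  the amount of removed variance is reportable.
* **Resampling** is rational polyphase: zero-stuffing by p, a
  linear-phase anti-alias/anti-image FIR (Hamming, half-order 10·max(p,q)
  at the upsampled rate), integer group-delay compensation, and
  decimation by q, with odd-reflection padding at the edges. The output
  length is exactly `round(T * new_fs / fs)` and task onsets, stored in
  seconds, are untouched. Upsampling factors above 100 are refused as
  almost certainly a configuration error.
* **Custom steps** receive the raw (matrix, fs, params) contract and must
  preserve shape — checked at apply time, because a silent shape change
  would corrupt the channel bookkeeping. Plugins are logged in the
  history exactly like built-ins, so a pipeline containing user code
  remains reproducible from its log.
* **Missing samples**: processing steps assume NaN-free input. Missing
  cells accepted at CSV import are surfaced by the QC report; the user
  chooses interpolation or exclusion explicitly before preprocessing,
  and that choice is logged. Silent imputation inside filter code would
  be invisible in the audit trail.

## Resting-state indices

The amplitude spectrum follows the one-sided cosine decomposition
$x(t) = a_0 + \sum_k A_k \cos(2\pi f_k t - \phi_k)$ with
$A_k = 2|X_k|/N$ for $1 \le k < N/2$ and $|X_k|/N$ at the Nyquist bin;
$a_0$ is the mean. The implementation satisfies Parseval's identity
(checked to 1e-6 relative in tests, the scale of accumulated FFT
round-off on white noise).

ALFF is the mean amplitude over the band, fALFF the ratio of the in-band
amplitude sum to the total over $k \ge 1$ (DC excluded from both). Choices
that needed fixing:

* **Band inclusivity**: bins with $f_{lo} \le f_k \le f_{hi}$, inclusive
  on both ends, matching the closed-interval band notation standard in
  the ALFF literature.
* **z-standardisation** uses the *population* (divide-by-C) standard
  deviation across channels. With sample SD the two-channel case gives
  z = ±0.707; with population SD it gives exactly ±1, and the "mean 0,
  SD 1" invariant holds exactly at every C. All-identical channels make
  the z-score undefined and raise an error rather than returning NaNs.
* **fALFF on filtered data is ill-defined**: after a 0.01–0.08 Hz
  band-pass the denominator nearly equals the numerator and fALFF → 1.
  The package computes what is asked, but the documentation (and this
  vignette) state that fALFF belongs on unfiltered or wide-band
  (≈0–0.25 Hz) data. This mirrors the worked example, where fALFF values
  near 0.8 on band-passed data reflect the remaining out-of-band noise
  floor, not physiology.

Functional connectivity is Pearson correlation; ROI series are unweighted
means of member channels, averaged *before* correlating (the alternative —
averaging pairwise correlations — is not equivalent; series-averaging was
chosen as the more common convention and is flagged here as a choice).
Fisher z = arctanh(r) is available and recommended before group tests,
where r's bounded support breaks normality assumptions. Zero-variance
channels produce NA correlations with a warning instead of an error, so a
single flat channel does not abort a batch.

Thresholding: *absolute* keeps entries strictly greater than τ;
*sparsity* keeps the ⌊s·C(C−1)/2⌋ largest upper-triangle values. Ties at
the cutoff are all kept — dropping an arbitrary subset of tied edges would
make the network depend on channel ordering — and the attained edge
fraction is reported alongside the requested one. Graph metrics themselves
are out of scope; thresholded matrices are exported as plain text for the
established graph-theory toolkits.

## Task GLM

The canonical HRF is the double-gamma $g(t;6,1) - g(t;16,1)/6$ (shape
parameters in seconds, peak ≈ 5 s, undershoot ≈ 15 s, ratio 1/6),
peak-normalised, over a 32 s kernel. Condition regressors are unit boxcars
over [onset, onset+duration) — a one-sample impulse at duration 0 —
convolved at acquisition resolution with onsets rounded to the nearest
sample; no microtime upsampling is performed, which at typical fNIRS
sampling rates (≥ 1 Hz) misplaces onsets by at most half a sample.
Covariates are z-scored (so their scale does not leak into effect sizes)
and the constant column is last. Estimation is plain OLS per channel with
no prewhitening: fNIRS noise is autocorrelated, so individual-level
t-statistics are optimistic, which is one reason the package reserves
inference for the group level (the other: the per-subject effects feed a
between-subject variance estimate, which is robust to within-subject
autocorrelation). Rank-deficient designs fall back to a pseudoinverse with
rank-adjusted degrees of freedom and a warning. Contrasts return
$c'\hat\beta$, its variance and t; they are the per-subject inputs to the
group stage.

## Group statistics

All models are channelwise general linear models: one/two-sample and
paired t, (partial) correlation, independent one-way ANOVA (F for the
group factor after covariates), repeated-measures one-way ANOVA (subject
effects removed; no sphericity correction — Greenhouse–Geisser is a listed
extension), and plain averaging. Tests are two-sided by default. Missing
values are handled pairwise-complete per channel with per-channel degrees
of freedom. FC matrices should enter group tests Fisher-z transformed,
and when edges of a matrix are tested the family for correction is the set
of unique upper-triangle edges.

Correction is computed within an optional mask, with the family size m
equal to the mask size: Bonferroni flags $p \le q/m$; Benjamini–Hochberg
flags all $p \le p_{(k^*)}$, $k^* = \max\{k: p_{(k)} \le kq/m\}$. HbO and
HbR maps are corrected separately (per chromophore), which is stated
rather than assumed because the joint alternative halves the threshold.

## Quality control

The QC report gives per-column variance, spike count, flatline fraction
and missing fraction. A spike is defined on the differenced series: a
sample whose derivative exceeds 5 robust SDs (1.4826·MAD of the
derivative) in both directions with a sign reversal. The derivative
formulation makes the count robust to baseline steps and slow drifts,
which would inflate a median-distance rule's scale estimate and mask true
spikes; the reversal requirement distinguishes a spike (up-then-down) from
a step (single large derivative). The constant 5 is a conservative
convention, not a fitted value. Periodograms are $A_k^2/2$ from the same
spectrum code path used by ALFF, so QC and analysis can never disagree
about spectral content.

## The synthetic generator

`ScenarioSpec`/`generateScenario` build recordings as
trend + deterministic oscillators (Mayer ~0.1 Hz, respiration ~0.3 Hz,
cardiac ~1 Hz, slow neural bands) + random smooth neural series with a
specified inter-channel covariance + a shared superficial (scalp)
component + HRF-convolved task responses + spike/step artifacts + white
noise. HbR is the neural signal scaled by −1/3 (anticorrelated) plus its
own noise, while artifacts and the superficial component enter both
chromophores with the same sign — exactly the premise CBSI relies on, so
motion-correction tests are meaningful. Short channels carry the
superficial component but no neural signal.

The named scenarios fix the study conditions: `rest44` (44 channels from
two standard 3×5 probes, 7 min at 10 Hz, block-structured covariance),
`task_finger` (nine subjects, 20 s tapping blocks alternating with 20 s
rest, true amplitude 0.8), `motion_heavy` (spikes of ±4–5 and a baseline
step of 7 ≈ 10× the clean signal SD), and `short_channel` (two
short-separation references among ten channels). Oscillator amplitudes
(0.1–0.5), noise SDs (0.05–0.15) and the activation amplitude were chosen
once as plausible relative magnitudes for band-limited hemoglobin
fluctuations and are not revisited.

What the generator does **not** emulate: 1/f-distributed instrumental
noise, serially correlated measurement error, optode-coupling drifts,
heterogeneous per-channel HRFs, or photon-transport physics. Passing tests
therefore demonstrate algorithmic correctness under the stated model, not
end-to-end validity on any particular device's data.

## Numerical conventions and degenerate inputs

* Exactness tiers in the test suite: algebraic identities to 1e-9–1e-12;
  FFT-based identities to 1e-9; Monte-Carlo quantities within binomial or
  3·SE bounds at fixed seeds.
* Validation problem sizes: spectra on 1000–2000 samples, GLM null
  calibration on 2500 simulated channels, group-level error control on
  500 replicates of 10 subjects × 8 channels, batch determinism on three
  44-channel subjects. These sizes make all checks exact enough to be
  decisive while keeping the default suite fast.
* Degenerate inputs fail loudly and specifically: nonpositive intensity
  (MBLL), singular extinction matrices, cutoffs at or beyond Nyquist,
  zero-variance channels (CBSI skip, FC NA), empty correction masks,
  designs with T ≤ P, trims that consume the whole recording.
* Sampling-rate changes use a rational approximation of the rate ratio
  with tolerance 1e-9 and denominator cap 1000.
* Seeds: every stochastic path (generator, acceptance script) takes an
  explicit seed; identical seed and spec give bitwise-identical output.

## Known limitations

Individual-level inference is intentionally absent (no prewhitening, see
above). Vendor binary formats are out of scope — SNIRF or the CSV dialect
are the entry points. Registration of optodes to MNI space is accepted as
a precomputed coordinate table, not computed. Graph metrics, interpolated
topographic rendering and 3D visualisation are delegated to the dedicated
tools the field already uses; this package produces their input files.
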