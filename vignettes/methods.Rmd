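---
title: "Models and methods behind optovis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optovis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(optovis)
```

`optovis` analyses extracellular recordings from the mouse visual
thalamocortical system under optogenetic perturbation of inhibitory
thalamic reticular (nRT) neurons. This vignette explains the models the
package implements, the design decisions taken where conventions in the
field differ, and what the synthetic-data generator does and does not
emulate.

## The scientific question

Driving inhibitory nRT neurons suppresses the thalamic relay to visual
cortex. Three signatures are analysed together: (1) firing-rate suppression
in narrow-spiking (NS) and broad-spiking (BS) cortical cells, (2) loss of
gamma-band (30–80 Hz) LFP power, and (3) degraded encoding of the visual
stimulus, quantified by single-unit mutual information and by population
decoding. Because a rate drop alone would reduce decodable information, the
package implements a spike-count-matched decoding comparison that asks
whether accuracy differs between laser conditions *at equal population
spike counts* — if it does, the perturbation changes the response pattern,
not just its gain.

## Trial model and locomotion

Trials are drifting gratings (default 8 directions × 20 repetitions per
laser condition, 2 s each, 2 s gray gaps, laser pulses coupled to stimulus
onset on randomly interleaved trials). Spike counts are taken in the
1000 ms window beginning 500 ms after onset. The window is half-open,
`[start, end)`, so adjacent windows partition time; the convention only
matters for spikes landing exactly on a boundary.

Running speed is integrated over 100 ms bins; a trial is `running` when its
mean speed is strictly above a threshold (default 2 cm/s, the midpoint of
the 1–3 cm/s range that per-experiment tracker noise dictates; a mean
exactly at threshold is `still`). Trials whose state changes mid-trial are
classified by their mean speed — the simplest rule consistent with
trial-level labelling. For LFP condition averages
(`condition_band_power()`), windows are labelled only when at least 90% of
speed bins agree on the state, because a half-running window would dilute
the locomotion contrast in a way trial-mean labelling cannot detect.

A laser trial is one whose stimulus span overlaps any laser pulse. In the
generated schedules the pulse starts exactly at stimulus onset, so overlap
and onset-coincidence agree; overlap is the more robust rule for real event
streams with clock jitter.

## Spectral estimation

The LFP is band-pass filtered 1–300 Hz with a 4th-order Butterworth applied
forward and backward (zero phase, so event alignment survives filtering).
Spectra come from a complex Morlet wavelet filterbank on a 60-point
log-spaced 2–100 Hz grid with 7 cycles (the classical compromise between
time and frequency resolution; the value is recorded in the output). The
power estimate is normalised as a one-sided PSD,

P(f) = 2 · mean |z_f(t)|² / (f_s · Σ|ψ|²),

which makes the estimate independent of wavelet scaling, gives
unit-variance white noise a flat reading of 2/f_s, and is verified in the
tests against a direct periodogram oracle (band-integrated agreement within
20%). Spectra are flattened by multiplying by `f^α` with α = 2.5 — the
direction that turns a `1/f^2.5` background into a flat line; dividing
would steepen it. Applying the adjustment twice is refused via a flag on the
spectrum object. Band powers average the grid points inside θ = [4, 8],
β = [15, 30], γ = [30, 80] Hz, inclusive at both edges; 30 Hz counts as
the gamma lower edge (β is effectively [15, 30)).

Current source density is the negative second spatial difference of the
depth-averaged LFP, `CSD_i = −(V_{i−1} − 2V_i + V_{i+1})/h²`, with no
spatial smoothing and boundary channels omitted. Channels sharing a depth
must be averaged within a shank beforehand; non-uniform spacing is an
error rather than silently interpolated.

Absolute power values depend on the wavelet normalisation and frequency
grid, neither of which is canonical; all analyses in the package therefore
use ratios or within-grid contrasts, which are normalisation-free.

## Waveform classification

Three features are computed from each unit's mean waveform, normalised so
the trough is −1: the positive peak height relative to the trough (stored
as the positive ratio peak/|trough|; published tables sometimes print this
with a negative sign convention, which is a labelling choice, not a
different quantity), the trough-to-peak time in ms, and the waveform slope
0.5 ms after the trough (central difference, per ms; a one-sided
difference is available as an option since the convention is not
standardised). Units are split into NS/BS by 2-means on the z-scored
features with deterministic farthest-point initialisation, so the result
is independent of RNG state and unit order; the cluster with the larger
mean trough-to-peak is BS. This reproduces the classical bimodal split
without extra hyper-parameters.

## Information and decoding

Mutual information uses the plug-in estimator on the joint table of raw
spike counts × stimulus classes. No bias correction is applied by default
(the plug-in convention); the tests document the consequence — on
independent data the estimate sits near `(|R|−1)(|S|−1)/(2N ln 2)` bits
rather than exactly zero — and a Miller–Madow correction is available
behind a flag. Classes default to the 8 movement directions; orientation
classes (directions mod 180°) are available through the decoder's class
map. Raw counts are kept as symbols because counts in a fixed 1 s window
are the natural response alphabet; an optional cap pools the sparse tail.

The population decoder is a Gaussian classifier with a diagonal, class-
shared covariance: class means, pooled within-class variances (n − K
denominator) floored at `1e-6 ×` their mean (degenerate, silent units
otherwise produce infinite likelihood ratios), and empirical priors.
Prediction maximises `log prior − ½ Σ (x − μ)²/σ²`; ties resolve to the
lowest class index so results are deterministic. Leave-one-out
cross-validation refits per held-out trial via sufficient-statistic
downdates (exactly equivalent to refitting, verified against a literal
refit in the tests). Chance level is 1/K; with six equiprobable classes
that is 0.167, and the package's acceptance checks recover it on
label-independent data.

Two sampling conventions exist in the field for the count-matched
analysis — neuron subsets drawn with or without replacement, 70 or 100
times. The default here is *without* replacement (a physical neuron cannot
be recorded twice) with 100 subsets; both are exposed as options. The
number of decoded classes follows the stimulus set (8 directions → 4
orientations) but is configurable, since published chance levels sometimes
imply other class counts (e.g. 0.16 ⇒ 6 classes). Population-count bins
default to integer width, merged left-to-right until each holds at least
20 pooled samples; no canonical binning rule exists, so the rule is
explicit and overridable.

One subtlety the rate-only control makes visible: at equal population
counts, the laser-on decoder uses *more neurons at lower rates* than the
laser-off decoder. More neurons carry more independent tuning information
per spike, so under pure rate scaling the laser-on side is, if anything,
marginally *more* accurate at matched counts. The dissociation criterion
is therefore directional — pattern degradation must produce a laser-on
*deficit* at matched (especially high) counts, which rate scaling alone
cannot.

## Hierarchical inference

Channels and cells are nested within mice, so pooling them as independent
observations overstates evidence. The package's nested comparison is a
subject-stratified permutation test: the statistic is the difference of
the averages of per-subject means (each subject weighted equally,
neutralising pseudo-replication), and the null is built by permuting
condition labels within subject (paired designs) or subject assignments
(unpaired), with `p = (1 + #{|perm| ≥ |obs|})/(1 + n_perm)`. This targets
the same inferential question as a nested/multilevel model-based test but
with fewer distributional assumptions; a Welch t-test on subject means is
reported alongside as a cross-check. All tests are two-sided. Full
mixed-model variance-component estimation is deliberately out of scope.

## The synthetic generator

`generate_session()` produces sessions with exactly the statistical
structure the analyses consume, plus the generating truth:

- **Schedule** — deterministic trial count and spacing; only the
  interleaving order is random.
- **Tuning** — von Mises in direction with a half-amplitude 180°-periodic
  lobe, normalised so the across-direction mean equals the configured base
  rate (defaults 10 Hz BS, 16 Hz NS, ≈30% NS). Spike counts are Poisson.
- **Laser** — rates scale by the opto factors (defaults: BS 0.79 still /
  0.67 running; NS 0.65 / 0.59) and tuning curves flatten toward their mean
  by `pattern_degradation` at fixed mean rate. Flattening is the simplest
  mechanism that lowers stimulus information at matched spike counts,
  which is precisely the effect the matched-count analysis must detect;
  `pattern_degradation = 1` produces flat tuning and MI at the plug-in
  bias floor.
- **Locomotion** — a two-state Markov chain at 100 ms resolution
  (mean bouts ≈ 20 s still / 10 s running), running speeds uniform
  5–15 cm/s, still 0–0.5 cm/s; rates gain ×1.5 while running.
- **LFP** — white noise spectrally shaped to `f^(−2.5/2)` amplitude
  (30 µV RMS) plus narrow-band gamma (Gaussian spectral window, 55 ± 10 Hz,
  20 µV RMS at still/laser-off) whose *power* follows condition gains:
  ×1.5 running, ×0.5 laser-on, ×1.5 during visual stimulation. Gamma is
  filtered noise, not a sinusoid, to emulate a broad 30–80 Hz elevation.
  The background is small inside the gamma band by construction, so
  measured band-power ratios recover the configured gains to within the
  estimator noise of a few-hundred-second block.
- **Waveforms** — Gaussian-bump templates whose extracted features centre
  on the empirical class centroids (BS: height 0.20, trough-to-peak
  0.73 ms; NS: 0.34, 0.32 ms) with jitter (SD 0.08 ms on trough-to-peak,
  0.04 on height); the slope feature is positive for BS (still rising at
  +0.5 ms) and negative for NS (already falling), reproducing the sign
  structure without targeting a numeric slope value, whose published unit
  is ambiguous.
- **Noise movies** — spatially low-pass white-noise frames drive
  linear–nonlinear units through a shared difference-of-Gaussians
  centre-surround kernel, so spike-triggered averages converge to the
  kernel.

What the generator does **not** emulate: correlated variability between
neurons (units are conditionally independent given the condition, matching
the decoder's independence assumption — real data violate both together),
onset transients and temporal dynamics within a trial, laminar structure in
the LFP, eye movements, and adaptation. Passing tests on generated data
therefore validate the *estimators* — that each quantity is computed
correctly and recovers known effect sizes — not that real cortical data
satisfy the generative assumptions.

## Numerical and scale choices

- Sessions are stored in a single JSON container with full 17-digit float
  precision; round trips are bit-exact. A text container keeps every
  artifact inspectable with standard tools.
- Seeds: one master seed fans out to fixed per-stage child seeds
  (`seed × 7919 + stage × 104729 mod 2^31`), so stages rerun in isolation
  reproduce their outputs; all generator and decoder sampling is seeded.
- Default problem sizes were chosen as the smallest at which the targeted
  effects are comfortably resolved: 160 trials per laser condition for
  rate-factor recovery (Poisson SE ≈ 3%), 300 s gray blocks for gamma
  ratios (≈ 70 four-second windows), 20 seeds for the sign-check of the
  matched-count deficit, and 1000 simulations × 200 permutations for the
  permutation test's type-I calibration (the discrete add-one p-value
  makes the attainable rejection rate 10/201 ≈ 0.0498 at α = 0.05).
- Ties: the decoder prefers the lowest class index; the optimal-direction
  rule prefers the lowest direction; k-means uses deterministic
  farthest-point initialisation with Lloyd iterations.

## Known limitations

Absolute spectral power is defined only up to the stated normalisation;
cross-study comparisons should use ratios. The plug-in MI is biased upward
at small trial counts — comparisons between conditions with equal trial
counts are unaffected, but absolute bit values at 160 trials carry bias of
order 0.1 bits for typical count alphabets. The permutation test assumes
exchangeability of condition labels within subject under the null; strong
within-subject time trends would violate it. The generator's waveform
model spans the two empirical classes but not rarer morphologies
(triphasic spikes, axonal waveforms).
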