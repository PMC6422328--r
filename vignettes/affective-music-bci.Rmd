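---
title: "Methods: a closed-loop music-based affective BCI in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a closed-loop music-based affective BCI in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical decisions
behind `affectbci`, in the spirit of a methods section: what the package
computes, which knobs matter, what the synthetic data do and do not emulate,
and where the design was genuinely open.

## 1. The affective music engine

Music is generated rule-by-rule from two continuous inputs, valence and
arousal, both clamped to $[0,1]$. The five structural mappings are

| parameter | mapping | units / range |
|---|---|---|
| eighth-note duration | $0.3 - 0.15\,a$ | s, $[0.15, 0.3]$ |
| slot probability | $p(\text{note}) = a$ | per eighth-note slot |
| velocity range | $\{50, \dots, \operatorname{round}(40a+60)\}$ | MIDI velocity |
| register probabilities | monotone piecewise-linear in $v$ over (C3, C4, C5) | probability triple |
| mode index | $\operatorname{round}(7-6v)$, clamped to $1..7$ | valence-ordered church modes |

Two mappings needed interpretation:

* **Register rule.** The textbook piecewise form ($p(C3)=2v$ for $v<0.5$,
  $p(C5)=2(v-0.5)$ for $v\ge 0.5$, remainder on C4) is not monotone in
  valence: it sends *both* extremes of the lower branch back to C4, which
  contradicts the intended "higher valence, higher register" relationship.
  The default replaces the lower branch with $p(C3)=1-2v$, which is monotone
  and reaches all-C3 at $v=0$ and all-C5 at $v=1$. The literal form remains
  available via `pitch_rule = "as-printed"`.
* **Mode discretization.** $7-6v$ is real-valued; modes are discrete, so the
  index is rounded half-up and clamped. Endpoints: $v=0 \mapsto 7$ (Locrian),
  $v=0.5 \mapsto 4$ (Dorian), $v=1 \mapsto 1$ (Lydian).

**Harmony.** All seven modes are rotations of the C-major pitch material; the
mode's tonic is the corresponding degree of C major. The four-bar progression
is tonic, dominant-function, subdominant-function, tonic — scale degrees
(1, 5, 4, 1) of the mode. We adopted this order because the canonical Lydian
realization is `F_maj | C_maj | B_dim | F_maj` (C is the triad on the 5th
degree of F Lydian, B° on the 4th); building the middle chords in (4, 5) order
instead would contradict that realization, and no diatonic rule produces
degree order (1, 4, 5) for Ionian *and* the Lydian chords above. The first and
fourth chords are always identical and every chord tone is diatonic to the
mode — both properties are enforced by tests across all seven modes.

**Texture and timing.** The piano voice carries the stochastic eighth-note
stream (chord tones placed in the octave starting at the sampled register's C;
C3 = MIDI 48). The cello holds the chord root at the C3 octave for the whole
bar and the bass doubles it an octave lower — a minimal chamber texture with a
single stochastic voice. Affect updates are quantized: mode (hence chord
progression) is re-read at bar boundaries, all other parameters at eighth-note
slot boundaries, so a parameter change never cuts a sounding note. Trajectories
are zero-order-hold between breakpoints; ramps are modelled by dense
breakpoints. Given a seed, the event stream is fully deterministic.

**MIDI.** Files are Standard MIDI format 1, one tempo track plus one track per
voice, PPQ 480, with set-tempo meta events at $2 \times 10^6 \cdot
\text{note\_dur}$ µs per quarter (one quarter = two eighths). There is no R
MIDI library in the supported stack, so the writer and reader are implemented
against the SMF byte layout directly; a hand-computed byte fixture in the test
suite pins the writer to the format itself rather than to the reader.

## 2. The affect decoder

The decoder maps a 14-channel, 128 Hz recording (10-20 montage:
AF3 F7 F3 FC5 T7 P7 O1 O2 P8 T8 FC6 F4 F8 AF4) to a score $s \in (0,1)$.

1. **Segmentation.** 4-s windows every 0.5 s. Windows start at every step
   inside a labeled period and are labeled by their start, so each period of
   duration $D$ yields $\lfloor D/0.5 \rfloor$ observations — the convention
   that reproduces the protocol's printed counts (80 per class from
   2 × 20 s, 120 idle from 6 × 10 s) and mirrors online labeling. The naive
   "fully contained windows" arithmetic $(D-4)/0.5+1$ does not. Generators
   append a 4-s background tail so that the trailing windows are full length.
2. **Filtering.** Each segment is filtered independently (no continuous
   filtering, hence no streaming filter delay) with a 2nd-order Chebyshev
   Type-I band-pass, 0.5 dB passband ripple, applied forward and backward
   (zero net phase). Type and ripple are configurable; the defaults are the
   conventional choice where only "2nd-order Chebyshev" is fixed. Bands:
   theta 4–7, alpha 8–13, low beta 14–21, high beta 22–29, gamma 30–47 Hz.
   Delta is excluded (ocular artifacts and drift).
3. **Features.** Natural log of the per-channel band variance: 14 × 5 = 70
   features, channel-major order.
4. **Baseline.** The mean feature vector over idle observations, subtracted
   from every observation; removes per-session offsets.
5. **Standardization.** Per-feature mean/SD estimated over the two *fitted*
   classes only (happy, sad). Neutral excerpts are mediators in the stimulus
   sequence and are never fitted; including idle in the standardization would
   mix a different regime into the scale estimate.
6. **LDA.** $w = (\Sigma_1+\Sigma_2+\lambda I)^{-1}(\mu_2-\mu_1)$ with
   class-wise sample covariances. With 70 features from ~80 observations per
   class the pooled covariance is ill-conditioned, so a ridge
   $\lambda = 10^{-3}\,\mathrm{tr}(\Sigma_1+\Sigma_2)/70$ is added by default
   (configurable); a still-singular matrix is an error, not a silent
   pseudo-inverse. The bias centres the discriminant at the class-mean
   midpoint, $b = -w^\top(\mu_1+\mu_2)/2$, the only choice for which the
   sigmoid yields a balanced control signal ($s = 0.5$ exactly between the
   classes, for any steepness). An `"as-printed"` bias without the ½ is
   available behind a flag for comparison.
7. **Scoring.** $s = 1/(1+e^{-\alpha d})$ with $\alpha = 2$; one score per
   0.5 s from the latest 4-s window. $\alpha$ trades responsiveness against
   stability of the feedback and is exposed as a calibration argument. Scores
   are clamped to the nearest representable doubles inside $(0,1)$: the exact
   sigmoid never reaches the endpoints, but floating point rounds it there
   once $|\alpha d| \gtrsim 745$, which strongly separable synthetic data do
   reach.

Models serialize to a single JSON document (vectors at full precision) and
round-trip losslessly to text precision. Non-128 Hz inputs are resampled by
Fourier-domain resampling (band-limited, zero delay) before processing.

## 3. Closed-loop protocol

Calibration: six 20-s excerpts (sad, neutral, happy × 2; sad at affect (0,0),
neutral (0.5,0.5), happy (1,1)) in pseudo-random order with no immediate
class repeats, each followed by 10 s of silence — 180 s total. The idle period
also follows the final excerpt; that sixth idle is required for the 120 idle
observations.

A trial is 15 s rest (no music) → task assignment → 2 s cue → 30 s action.
The cue gap is *appended* to the 15-s rest (the alternative, carving it out of
the rest, would shorten the scored rest window; the protocol's period
durations are given as 15 and 30 s, so we keep both intact). The task rule is:
mean rest score < 0.5 ⇒ *modulate towards happy*, ≥ 0.5 ⇒ *towards sad*.
Rest scores are the scores *emitted during* the rest period, so the earliest
ones use data reaching back into the previous action period — exactly what a
streaming implementation sees. During action, every 0.5-s score update sets
the engine input to $val = aro = s$ (60 updates per trial); no music events
exist during rest. Sessions run in simulated time against a responder model.

## 4. Synthetic data and the simulated responder

`gen_background` produces independent $1/f^{\gamma}$ Gaussian noise per
channel ($\gamma = 1$ by default; 10 µV SD nominal — arbitrary but fixed so
fixtures are comparable). The spectrum is shaped in the Fourier domain and
normalized by the *analytic* spectral constant so that the expected variance
is 1 regardless of chunk length. (Normalizing by the realization SD instead
couples relative band power to the chunk length; an early version did this
per protocol chunk and the band-power null test caught it as a systematic
theta difference between 17-s rest and 30-s action chunks.)

Class effects are amplitude-scaled, band-limited noise (band-filtered white
noise) added to a subset of channels — amplitude-modulated narrowband noise
rather than pure sinusoids, so log-variance features keep realistic
dispersion. Calibration effects default to alpha (8–13 Hz) on posterior
channels; the responder couples gamma (30–47 Hz) on right-frontal channels,
echoing the emotion-related band modulations this construction emulates.

The responder's internal affect state $s^{*} \in [0,1]$ follows first-order
dynamics with time constant `tau_action` (default 5 s) towards the task target
during action and `tau_rest` (default 10 s) towards a personal bias during
rest; `tau = Inf` freezes the state (the decoupled null responder). Emitted
EEG is background plus a coupled-band carrier whose amplitude is a monotone
(by default linear, 5–30 µV) function of the state. Background and carrier
are generated continuously for the whole session up front and only the
carrier's amplitude is stepped every 0.5 s — chunkwise generation would leave
spectral seams at period boundaries that bias rest/action contrasts.
Calibrating on `gen_calibration_recording(responder_effect(cfg))` guarantees
the decoder's discriminant aligns with the responder's coupled features, which
is what closing the loop requires.

What the generator does **not** emulate: volume conduction and channel
correlations, eye-blink/EMG artifacts, non-stationary drifts, electrode
impedance changes, and any genuine neural dynamics of emotion. Passing tests
therefore demonstrate that the *pipeline* recovers what it assumes — planted
band-power structure under 1/f noise — not that the method works on human
EEG.

## 5. Evaluation statistics

* **Cross-validation** re-windows the two-class calibration data into
  non-overlapping 1-s segments (80 observations), then runs repeated
  stratified 10-fold CV. Baseline comes from the idle data (outside the
  folds); standardization and the LDA are re-estimated on training folds
  only — the leakage-free placement. The original protocol may have
  standardized before splitting; we deliberately do not, and note that
  leakage would bias accuracies upward. Accuracy threshold: the score
  midpoint. AUC is the rank statistic of the continuous discriminant
  (equivalent to the trapezoidal rule over all thresholds).
* **Chance threshold**: $100\,k/n$ with $k$ the smallest count whose
  exceedance probability under $\mathrm{Bin}(n, 1/2)$ is ≤ $p$
  ($k = q_{\mathrm{Bin}}(1-p)$). This reproduces 58.75 % at $n = 80$,
  $p = 0.05$ (and 100 % at $n = 2$). The threshold is *not* monotone in $n$
  at unit spacing — parity of $n$ produces wiggles — though the
  law-of-large-numbers trend holds at coarser spacing; the test suite asserts
  the anchors and the spacing-20 trend.
* **Modulation statistics**: per task, trial-wise rest/action means
  aggregated into RM, AM, TD ($TD_{happy} = AM - RM$, $TD_{sad} = RM - AM$)
  and $\bar{s}_{diff}$; one-tailed paired t-tests (right-tailed for
  *to happy*, left for *to sad*), marginal significance at $p < 0.1$. The t
  statistic is computed in closed form so the degenerate all-zero-difference
  case yields $t = 0$, $p = 0.5$ rather than an error; tasks with fewer than
  two trials are marked unavailable, mirroring the imbalanced-task problem.
  No normality pre-test is performed.
* **Band-power contrast**: one observation per trial (mean action minus mean
  rest feature vector), within-participant scaling by the participant's own
  per-feature SD (the mean is retained — it carries the effect under test),
  pooled two-sided t-tests per feature, Bonferroni threshold $0.05/70$.
  Zero-variance features get an undefined statistic and are never flagged.
  Note that a planted narrow-band effect also appears, attenuated, in the
  neighbouring band of the same channels through the order-2 filter skirts —
  expected physics, not a defect.
* **Granger causality**: for each (score, feature) pair and both directions,
  an OLS F-test of whether `nlags = 10` lags of the predictor (5 s at the
  0.5-s observation rate) improve prediction of the target beyond its own 10
  lags. Fixed lag order, no order selection; bivariate only (conditional /
  multivariate Granger is out of scope). Bonferroni correction over the tests
  actually performed (constant series are flagged and skipped), threshold
  $p < 0.01$.

Individual LDA weights are *not* used to localize effects in the tests:
weights on correlated features form noise-cancelling contrasts whose single
coefficients are unstable. Localization checks use the standardized class-mean
difference per feature.

## 6. Problem sizes and numerical choices

Test and acceptance runs use deliberately moderate sizes chosen to exercise
the statistics at the protocol's own scale: 20-trial sessions (the
familiarization-session size; a 50-trial session is configuration, not new
code), 20 seeds × 5 CV repeats for null calibration, 3 families of 2 × 8-trial
null sessions for the false-positive check, and 600-sample VAR pairs for
causality. The zero-phase filter kernel is compiled (direct-form II
transposed, column-wise over segments) and numerically identical to
`signal::filtfilt` (asserted to ~1e-14 in the tests); segments are batched
per band so a full session scores in seconds. All randomness flows through
explicit integer seeds; fixture generators, the engine and the session runner
are bit-reproducible for a fixed seed.

## 7. Known limitations

* Human-subject results (listening-study ratings, per-participant decoding
  tables, topographic maps) are not reproducible from synthetic data and are
  out of scope; the package demonstrates the machinery, not the neuroscience.
* EEG I/O is CSV; there is no EDF reader in the supported dependency set.
* The responder tracks the task target, not the actual musical feedback; it
  models a compliant participant, so closed-loop "success" in simulation
  validates the loop's plumbing and statistics, not human controllability.
* Bivariate Granger tests inherit the usual caveats (no conditioning on other
  features, fixed lag order, stationarity assumed within the concatenated
  action data).
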