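---
title: "The looming-detector circuit model and its analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The looming-detector circuit model and its analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scloom)
```

`scloom` studies how three response properties emerge along the depth of
the mouse superior colliculus (SC): selectivity for expanding dark disks
("looming" stimuli), invariance to where in the visual field the loom
appears, and near-complete, location-specific habituation after a single
presentation. This vignette documents the model, every tunable parameter
with its default and the reason for it, the design choices that were
genuinely open, and the limitations a user should know before trusting a
result.

## The circuit model

Each model input neuron is a linear–nonlinear (LN) element. The stimulus
`s(x, y, t)` is a Weber-contrast field on `[-1, 1]` (0 = gray background),
sampled at 1°/pixel and 60 frames/s by default (the monitor refresh of the
emulated experiments). The linear drive is the space–time convolution of
the stimulus with a separable kernel `k = F(x, y) T(t)`: an isotropic
Gaussian `F` and a biphasic difference-of-gamma-like `T`, followed by a
half-wave rectifier `N(g) = max(0, m g − θ)`.

A **local looming detector** subtracts a concentric slow surround unit
from a fast centre unit and rectifies the difference:
`r_LD = max(0, r_c − r_s)`. Detectors sit on a retinotopic grid with 15°
spacing. A **widefield unit** pools all detectors through synapses with
short-term depression,

$$\frac{dw}{dt} = \frac{1-w}{\tau} - a\,(w - w_{min})\,r(t),$$

computing `r_WF(t) = Σ_i w_i r_LD,i(t)` with the *current* weights before
each weight update. Depression of one synapse is invisible to all others,
which is what makes the habituation location-specific.

### Parameters and defaults

| parameter | default | meaning / rationale |
|---|---|---|
| centre kernel | σ = 4°, τ₁ = 104 ms, n₁ = 2.77, τ₂ = 91.2 ms, n₂ = 3.94, b = 1.34 | fit of a fast transient Off alpha-RGC receptive field |
| surround kernel | σ = 10°, τ₁ = 84.6 ms, n₁ = 1.24, τ₂ = 79.7 ms, n₂ = 1.87, b = 1.33 | fit of a slower, more sustained Off cell |
| rectifier | m = 1, θ = 0 | plain half-wave rectification |
| depression | a = 1, w_min = 0 | near-total use-dependent depression |
| recovery τ | 180 s | not constrained by a measured value; chosen so that simulated recovery of the pooled response stays below ~60% two minutes after habituation, on the scale of the slow recovery seen in deep-SC recordings; configurable and worth revisiting for any quantitative recovery claim |
| detector grid | 7 × 7, 15° spacing | covers the standard 5 × 5 stimulus grid with a full ring of neighbours, so every stimulus location sees an identical detector neighbourhood (this is what makes the position-invariance exact) |
| `loom_dose` | 8 rate-unit·s | see next section |
| kernel truncation | spatial 3σ, temporal 500 ms | both lobes of both kernels have decayed to <2% of their extrema |

### Rate units and the `loom_dose` normalization

The equations leave the physical scale of `r(t)` open, yet the depression
dynamics depend on it directly: with `a = 1`, a presynaptic input that
delivers `D = ∫ r dt` depresses its synapse by the factor `e^{-D}`
(ignoring the slow recovery). We therefore define the rate unit by the
stimulus: detector rates are rescaled so that the time-integrated response
of a detector to the standard centred loom (30° at 60°/s plus a 250 ms
hold) equals `loom_dose = 8`. One standard loom then leaves its synapse at
`e^{-8} ≈ 3×10⁻⁴` of full strength — the near-complete single-trial
habituation that deep-SC recordings show — and the pooled response to a
repeated loom decays to ~9% of the first trial by the tenth repeat. An
alternative convention (peak rate = 1) was considered and rejected: it
delivers a dose of only ~0.25 per loom, i.e. ~25% depression per trial,
which contradicts the single-trial character of the phenomenon and breaks
the slow-recovery behaviour that motivates τ = 180 s.

### Sign conventions (and why they are a genuine choice)

For Off units the package negates the stimulus before convolution, so
darkening produces positive drive. Because the default temporal kernels
are themselves biphasic with a negative primary lobe (they are fits to
measured receptive fields, i.e. they already encode response phase), the
convention chosen here fixes which stimulus phase excites the cascade. We
explored the alternative — no negation, with volume-normalized spatial
kernels — at length. It produces centre responses during the expansion
phase, but the fast centre's rebound at bright-stimulus offset then
escapes the slower surround, and contracting/expanding *white* disks drive
the detector more strongly than the loom, destroying the selectivity
ordering. Under the shipped convention the detector-level ordering is
clean (standard loom dose 8 versus ~3.3 for a moving dark disk, ~0.16 for
dimming, and exactly 0 for contracting/expanding white disks, whose
responses are fully cancelled by the surround), at the cost of part of the
loom response arriving late in the stimulus period. Neither convention
reproduces every observed behaviour; the choice and its consequences are
stated here rather than hidden.

### Numerical choices

* **Integration.** The depression ODE is advanced with an explicit Heun
  (second-order) step at the stimulus frame rate, sub-stepping whenever
  `a·r·dt > 0.05` and clamping to `[w_min, 1]`. Heun is needed for the
  integrator to track the closed-form solutions to better than 10⁻⁶ at
  steps of τ/10⁴; first-order Euler plateaus around 10⁻⁵.
* **Gaps.** Between stimulus events the weights relax toward 1 in closed
  form (exactly), so protocols minutes long cost nothing.
* **Rasterization.** A pixel belongs to a disk iff its centre lies within
  the radius — no anti-aliasing, so pixel counts are exactly checkable.
  Frame `k` shows the scene at time `(k−1)/frame_rate`; at `t = 0` a loom
  has zero area.
* **Memoization.** Event movies are rendered in event-local coordinates
  and unit responses cached by (event kind, offset), which is exact
  because the grid spacing is an integer multiple of the pixel pitch.

## The synthetic population

The generator emulates the two response classes the analyses contrast,
driving spikes through the circuit model itself:

* **sSC neurons** are single Off LN units with small receptive fields
  (σ ~ 2–5°) tiling the stimulated span, per-stimulus-kind tuning spread
  (0.6–1.4×), maintained baselines (log-uniform 0.1–15 Hz, spanning the
  sub-spike to >10 spikes/s regimes), and no habituation. Their `gain` is
  calibrated as the expected *stimulus-period* spike count for a loom
  centred on the receptive field (default 50–80 spikes, a vigorous but
  realistic burst); latency naturally varies with the distance between
  the loom edge and the receptive field.
* **dSC neurons** read out the widefield unit (gain in spikes per
  rate-unit·s, default 30–50, giving ~40–90 spikes on a first trial),
  inheriting looming selectivity, position invariance with a fixed
  ~150 ms model latency plus a small per-trial jitter (0.5–3 ms), and the
  synaptic habituation. All dSC neurons sharing a circuit configuration
  share its deterministic rate trace — their synapse trajectories would be
  identical anyway — while spiking independently.

Spikes are drawn from an inhomogeneous Poisson process, exactly for the
piecewise-constant rate at frame resolution (frame-wise Poisson counts
placed uniformly within frames — equivalent to thinning), plus a
homogeneous baseline over the whole recording; times are kept at 1 µs
resolution. There is no refractory period, no adaptation other than the
modelled synaptic depression, no correlated noise across neurons, and no
behavioural covariates (locomotion, pupil). Consequently, a passing test
suite demonstrates that the *analysis chain* is correct under its own
statistical assumptions (Poisson counts), not that real SC data satisfy
those assumptions.

## Conventions in the single-neuron statistics

* **Background windows** use the 5 s just before each stimulus (the
  experimentally typical 5–10 s), clipped to stimulus-free time: the
  window never reaches into a preceding stimulus period (clipped windows
  are flagged). μ is the window rate times the stimulus duration.
* **Poisson test**: upper tail `P(X ≥ r′)` (the ≥ convention), with the
  mean floored at one whenever μ < 1 so that 1–2 chance spikes are never
  declared a response; α = 0.005, divided by the number of presentations
  when a series is scanned (Bonferroni).
* **Corrected counts** `r = r′ − μ` are clamped at 0 before any index is
  formed, keeping selectivity and habituation indices in `[-1, 1]`.
* **Receptive-field size**: per-location response is the *maximum* over
  repeats (so a habituating neuron is scored by its novel-location
  bursts), non-significant locations are zeroed, and the size is
  `2Δ + spacing` — the spacing term encodes the 15° resolution limit of
  the measurement.
* **Latency variability** uses the sample (n−1) standard deviation of
  first-spike times ≥ 30 ms after onset, only for neurons with μ < 1 and
  at least five individually significant trials (each trial must pass the
  corrected test; neuron-level inclusion alone is not enough).

## STA and its separation

The spike-triggered average assigns lag 0 to the frame containing the
spike and averages per spike (a frame holding two spikes enters twice);
30 lags (500 ms) by default. The checkerboard is zero-mean by
construction, so no whitening is applied. The SVD operates on the
(space × lag) unfolding; the sign indeterminacy is resolved by making each
temporal course's largest-magnitude extremum negative — the natural
orientation for the Off-dominated populations this targets — with the
spatial map compensating.

## Decoding choices

* The location task is fit as a single multinomial (softmax) model rather
  than one-vs-rest; novelty is binomial.
* `LogisticRegression(penalty = 'l2', C = 1)` maps onto
  `glmnet(alpha = 0, lambda = 1/(C·n_train))` — identical penalized
  likelihood up to glmnet's 1/n scaling. No feature standardization; the
  intercept is unpenalized. Coordinate descent is warmed along a path from
  the data-driven λ_max down to the target λ.
* Location classes with fewer than two training trials in a fold are
  dropped from that training fold (the fitter cannot estimate them); their
  test trials remain and score as errors.
* Folds are stratified by label where possible and seeded.
* Virtual-neuron augmentation shifts a neuron's response profile to the
  eight neighbours of a 3 × 3 grid neighbourhood; a copy is kept only if
  its shifted profile centre stays inside the presentation area. A
  virtual neuron's response to a trial at location ℓ is the source's
  recorded response at ℓ − shift, matched by per-location repeat index
  (capped at availability) — counts are relabelled, never resampled. When
  ℓ − shift falls off the grid the copy takes the source's response at
  the in-grid location farthest from its receptive field, i.e. a
  background-level response drawn from real trials.
* A consequence of trial-wise relabelling worth knowing: for a
  *habituating* neuron the per-location response sequence (big first
  occurrence, then silence) is location-specific even when the maximal
  response is position invariant, so shifted copies of deep-layer neurons
  carry some location information that the physical neuron alone does
  not. Deep-layer location accuracy in augmented populations is therefore
  above raw chance, though it remains far below the superficial layer's.

## Problem sizes used by the test suite

The shipped tests run the full chain at sizes chosen to make the
statistics decisive yet quick: 100-trial random-loom protocols; 50 + 50
neuron populations augmented to ~350–450 virtual neurons per layer;
decoding subsample curves at size 300 with 20 repeats; 300 s checkerboards
for the receptive-field recovery; 1000 simulated protocols for the
chance-level estimates; 10⁴ trials for the significance-test calibration.

## Known limitations

* **Moving disks beat the loom at the widefield stage.** The local
  detector prefers the loom over a moving dark disk (dose 8 vs ~3.3), but
  the widefield unit pools the moving disk's sweep across ~4 detector
  columns plus its onset transient, and the *pooled* moving response
  (~13 rate-unit·s) exceeds a single local loom. Looming selectivity in
  this architecture is a property of the local stage, not of the pooled
  sum.
* **Habituation transfer to adjacent locations.** Each loom deposits ~4%
  of its central dose on the four adjacent detectors (the 30° disk's
  final edge reaches their receptive-field centres, and the surround's
  rebound cancellation is imperfect for ~3 frames after offset). With
  near-complete per-trial depression this accumulates: after ten looms at
  one location, a first loom 15° away recovers only ~35–40% of a naive
  response in the model, whereas recordings show essentially full
  specificity at 15°. No parameter consistent with the standard stimulus
  geometry removes this; treat fine-grained spatial-specificity
  predictions with caution.
* **Recovery floor.** For the same reason the pooled response never falls
  below ~23% during a recovery-interval ladder and sits at ~59% two
  minutes after habituation at the default τ = 180 s, somewhat above the
  <50% seen in deep-SC recordings; the fraction-vs-interval curve also
  dips before rising (early short-interval trials face less accumulated
  depression).
* **Chance-level arithmetic.** For truly uniform 100-trial protocols over
  25 locations, the expected maximum location share is 8.4%, slightly
  below the ~10% quoted for empirical protocols (real location sequences
  are not perfectly uniform); the novelty chance matches its closed form
  (75.4%) exactly.
* The Poisson spiking assumptions (above) bound what the synthetic
  pipeline can certify about recorded data.
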