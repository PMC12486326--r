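---
title: "De-mixing mechanical state from proprioceptive afferent populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-mixing mechanical state from proprioceptive afferent populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlemix)
```

## The model

Muscle proprioceptors are analysed here as a population whose firing rates
are linear functions of the mechanical state of the contractile tissue.
Three afferent classes are modelled: group Ia and group II muscle-spindle
afferents, driven by the contractile force `F_C` (N) and its positive rate
of change, the yank `Y = dF_C/dt` (N/s), and the group Ib Golgi tendon
organ afferent, driven by contractile force alone:

```
R_Ia = k11 F_C + k12 max(Y, 0)
R_II = k21 F_C + k22 max(Y, 0)
R_Ib = kF_Ib F_C
```

Stacking the two spindle equations gives `R = K [F_C; Y]` with a 2 × 2 gain
matrix `K`, and inverting it per sample de-mixes measured rates into force
and yank estimates. Combining the group II and Ib channels through their
force gains decomposes contractile force into an externally imposed part
(`F_EI = R_II / kF_II`, what the spindle feels during stretch) and the total
(`F_C = R_Ib / kF_Ib`); their difference is the self-generated force
`F_SG`. During a purely passive stretch the two estimates cancel; an
eccentric contraction — emulated as a small constant offset added to the Ib
rate — appears as a non-zero `F_SG` of exactly `offset / kF_Ib`.

The package's reference gains are `K = [337.8 33.6; 182.8 4.9]`,
`kF_II = 182.8` and `kF_Ib = 128.8` spikes/(N·s). They serve two roles: as
the default encoder parameters of the synthetic-data generator, and as the
ground truth that the fitting stages must recover in the round-trip tests.

Assumptions worth keeping in view: encoding is linear and memoryless (no
spindle thixotropy or history dependence, no fusimotor drive), yank drive is
half-wave rectified (all reference gains are positive and firing rates
cannot be negative), and the Ib afferent carries no yank term by default.

## The passive muscle model

Total muscle–tendon unit (MTU) force splits into contractile and
non-contractile tissue components, `F_MTU = F_C + F_NC`, and the simulator
builds each from the imposed length trajectory `L(t)` (mm of length change
from rest):

* **Non-contractile (extracellular matrix / extramysial tissue):** an
  exponential force–length curve, `F_NC = a (exp(b (L − L0)) − 1)` for
  `L > L0` and zero below — zero force at the rest length, exponential
  stiffening above it. This is the simplest curve with those two
  properties; only "exponential" is prescribed by the analysis it supports.
* **Contractile:** a linear spring-dashpot `F_C = k L + c v`, floored at
  zero (passive tissue cannot push). Linear viscoelasticity is a modelling
  choice; it produces the force/yank velocity scaling the de-mixing
  analysis needs while keeping every fit identifiable.

Yank is computed from `F_C` by Savitzky–Golay differentiation (below), so
the simulated mechanics pass through exactly the derivative operator the
analysis chain uses.

### Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| amplitude | 3 | mm | stretch protocol |
| hold | 1 | s | stretch protocol |
| velocities | 15, 17.1, 20, 24, 30 | mm/s | stretch protocol |
| reps per velocity | 3 | — | 15 trials per cell |
| baselines | 0.25 / 0.25 | s | room for onset/offset transients |
| sample rate | 1780 | Hz | processed recording rate (17.8 kHz / 10) |
| `a`, `b`, `L0` | 0.05, 1, 0.5 | N, 1/mm, mm | sub-newton ECM force over a 3 mm stretch |
| `k`, `c` | 0.15, 0.01 | N/mm, N·s/mm | rat triceps-surae-scale passive forces |
| fascicle fraction | 0.7 | — | fascicle shortening < MTU length change |

With these values a 15 mm/s trial peaks near 0.6 N of contractile force,
giving hold-phase rates of roughly 150 (Ia), 80 (II) and 60 (Ib) spikes/s —
the tens-to-hundreds of spikes/s range typical of rat hindlimb afferent
recordings. The generator emulates the *structure* the analysis assumes
(trapezoidal kinematics, additive force components, linear rate encoding,
regular spiking); it does not emulate initial-burst dynamics beyond an
optional extra yank gain near onset (default off, since no magnitude or
shape is established for it), spindle history dependence, fusimotor
modulation, or irregular firing. Tests passing on these data therefore
validate the *computations*, not the physiological completeness of the
encoder.

## Signal processing

The processing chain mirrors a standard electrophysiology workflow:
recordings at 17.8 kHz are decimated by 10 (anti-alias low-pass at 80% of
the post-decimation Nyquist, then subsampling), low-pass filtered with a
4th-order Butterworth at 100 Hz, and differentiated with a 2nd-order
Savitzky–Golay filter spanning 51 samples (≈ 28.7 ms at 1.78 kHz).

Numerical choices:

* **Zero-phase filtering.** The Butterworth is applied forward and
  backward so mechanics and firing rates stay time-aligned (the effective
  magnitude response is the square of a single pass). The
  forward–backward pass is implemented in-package with odd-reflection end
  padding because `signal::filtfilt` pads with zeros and leaves large end
  transients. The pad length is derived from the filter's slowest pole
  (`r^padlen < 1e-12`), so DC is preserved to ~1e-9 even for low cut-offs.
* **Savitzky–Golay edges.** Derivatives are exact for polynomials up to
  the fit order in window interiors; the first and last half-windows come
  from the fitted end polynomials and are only approximate there.
* **Instantaneous firing rate (IFR).** Each interspike interval
  contributes one sample, `1/ISI`, timestamped at the *later* spike — the
  instant the value becomes known. IFR samples are linearly interpolated
  onto a 1 kHz grid whose origin is the first recorded event; the trace is
  anchored at zero at the origin (or at the last pre-stretch rate when the
  afferent has background firing) and held constant after the final
  sample. Holding avoids spurious decays during the hold phase.
* **Spike emission.** The generator's inverse of the IFR computation is
  deterministic integrate-to-threshold: a spike is emitted each time the
  integral of the rate crosses the next whole count, with crossing times
  found by linear interpolation. This makes round-trip tests exact up to
  discretisation; a seeded Poisson mode (time rescaling) exists for
  stochastic trains.
* **Onset for grid origin.** When analysing arbitrary data the stretch
  onset is not auto-detected; the origin is an explicit argument
  (`origin`), defaulting to the first IFR event of each trace.

The backward-ISI timestamp makes the reconstructed rate lag the true rate
by about half an ISI, so round-trip error concentrates in the ramp
transients and vanishes during the hold. The round-trip property tests
therefore bound the RMS reconstruction error (over samples with true rate
≥ 10 spikes/s) by 5% of the trace's *peak* rate — the same peak
normalisation used for the cancellation bounds — rather than by the
trace's RMS, which the transient lag alone would dominate.

## Fitting

* **Spindle gains** are fitted by non-negative least squares of the rate
  on `[F_C, max(Y, 0)]`, without intercept: the encoding model has no
  offset term and the reference gains are all positive. An intercept is
  available behind a flag for recordings with background firing, and an
  onset mask (default first 20 ms when enabled) can exclude initial-burst
  samples. Near-collinear regressors trigger a warning rather than an
  error.
* **The K matrix** is the per-coefficient arithmetic mean of the fitted
  Ia and II gain pairs over the trials at one reference velocity
  (15 mm/s by default). Assembly fails loudly if `|det K| < 1e-6` and
  always reports the condition number.
* **The non-contractile model** is fitted jointly with the Ib gain:
  `(a, b, L0, kF_Ib)` minimise the squared error between
  `kF_Ib (F_MTU − F_NC(L))` (floored at zero) and the Ib rate, under
  bounds `a ≥ 0`, `b > 0`, `kF_Ib > 0`. The optimiser is L-BFGS-B with
  three seeded multiplicative starts — the exponential has a classic
  scale/offset ridge (`a e^{−bL0}` trades against `L0` at fixed `b`) and
  single far-off starts can stall in poor local minima — followed by two
  Nelder–Mead polish restarts, which converge the ridge to machine
  precision on noiseless data. A fit whose implied contractile force is
  identically ~0 is flagged degenerate. For spindle afferents the
  analysis convention is to share `a` and `b` from the Ib fit and allow
  only a per-afferent rest-length override.

On spike-derived IFR traces the joint fit behaves differently from the
noiseless case: the discretisation lag and end-hold artifacts let the
optimiser trade the exponential's parameters against the gain (the
`run_full(fit_on = "ifr")` test documents this: the fit still explains the
rate well, while the scalar force-gain projection of the same traces pins
`kF_Ib` tightly). This is an identifiability property of the joint model,
not an optimiser failure, and is why the scalar projection is the
preferred gain estimate for processed spike data.

## De-mixing

Inversion uses the explicit linear solve per sample and reports
conditioning (`det K`, condition number) on every result; matrices with
`|det| < 1e-6` are rejected. The reference matrix has determinant ≈ −4487 —
comfortably invertible (condition number ≈ 33) despite the negative
determinant. Negative force/yank estimates are *reported, not clipped*; a
`rectify` flag exists for display only. The eccentric offset has no default
magnitude — it is a scenario parameter (`eccentric_offset`, spikes/s)
because only its smallness, not its value, is part of the scenario
definition. The hypothetical interneuron weights (`w_Ia = 1, w_II = 0,
w_Ib = −1`, rectified) are illustrative defaults, chosen so that yank
excitation and force inhibition yield a startle-like response; they are
exposed, not asserted as physiological.

## Pipeline and problem sizes

`run_full()` composes the stages and returns a report with gain-recovery
relative errors, cancellation metrics, conditioning and per-stage counts;
every artifact is regenerable bit-identically from the resolved
configuration and seed (the YAML written beside the outputs). The test
suite runs the full default session (15 trials of ~3,400 samples each, 45
rate traces) plus reduced one- and two-velocity sessions for the slower
spike-path and property tests; the acceptance script uses a single 15 mm/s
trial (~3,400 samples). These sizes keep every fit deterministic and
well-conditioned while exercising all five protocol velocities.

## Known limitations

* Encoding is linear in force and yank; real spindle firing shows
  history dependence, initial bursts and fusimotor modulation that this
  package deliberately does not model.
* The contractile spring-dashpot is linear; saturation or nonlinearity of
  passive contractile force would change the velocity scaling
  quantitatively (not the de-mixing algebra).
* The eccentric contraction is a constant Ib offset — a scenario, not a
  contraction model; real eccentric firing would differ.
* The decomposition into self-generated vs. externally imposed force is
  defined per muscle and does not separate exafference from reafference
  across muscles.
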