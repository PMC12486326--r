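# spindlemix

De-mixing muscle mechanical state variables from proprioceptive afferent
firing.

## The problem

Muscles report their mechanical state to the spinal cord through three
proprioceptive afferent classes: group Ia and group II afferents from muscle
spindles, and group Ib afferents from Golgi tendon organs (GTOs). No single
afferent cleanly encodes a single mechanical variable — spindle firing mixes
the static and dynamic components of a stretch, and spindle feedback alone
cannot tell a passive stretch from an eccentric contraction. Treating the
afferents as a *population*, however, makes the mechanical variables
recoverable by simple linear algebra:

- **Spindle de-mixing.** If group Ia and II rates follow a linear
  force/yank encoding of the contractile force `F_C` and its time derivative
  (the yank, `Ẏ = dF_C/dt`),

  ```
  [R_Ia]       [F_C]           [k11 k12]
  [R_II] = K · [Y  ],    K  =  [k21 k22]
  ```

  then inverting the gain matrix per sample de-mixes the rates back into
  force and yank estimates: `[F̂; Ŷ] = K⁻¹ [R_Ia; R_II]`.

- **Self-generated vs. externally imposed force.** With the total MTU force
  split as `F_MTU = F_C + F_NC` (contractile vs. non-contractile tissue) and
  the contractile force as `F_C = F_SG + F_EI` (self-generated vs.
  externally imposed), the spindle signals the imposed force
  (`R_II ≈ kF_II · F_EI`) while the GTO signals the whole contractile force
  (`R_Ib = kF_Ib · F_C`). Their gain-scaled difference

  ```
  F_SG = R_Ib / kF_Ib − R_II / kF_II
  ```

  cancels during passive stretch and reads out the contraction force during
  an eccentric contraction (modelled here as a small constant offset on the
  Ib rate).

The package implements this analysis end to end as a tested, simulation-backed
pipeline: a ramp–hold–release stretch generator, a passive MTU force model
(exponential non-contractile force–length curve plus a linear spring-dashpot
contractile element), linear force/yank afferent encoders, spike-train
emission and instantaneous-firing-rate (IFR) processing, non-negative
least-squares and bounded nonlinear gain fitting, and the two de-mixing
computations, with ggplot2 display functions. The reference gains are

```
K = [337.8 33.6; 182.8 4.9],  kF_II = 182.8,  kF_Ib = 128.8  spikes/(N·s)
```

## Worked example

```r
library(spindlemix)

run <- run_full(demix_config())   # simulate, fit, de-mix, decompose
print(run)
#> <demix_run>
#>   15 trials, 45 rate traces
#>   fitted K (averaged at 15 mm/s):
#>    force yank
#> Ia 337.8 33.6
#> II 182.8  4.9
#>   kF_II = 182.800, kF_Ib = 128.800 spikes/(N.s)
#>   passive cancellation: max|F_SG| = 0.485 N, RMS = 0.0397 N (peak F_C 0.747 N)
#>   conditioning: det K = -4487, condition number = 33.11
```

The default configuration simulates the full stretch session (3 mm
ramp–hold–release, 1 s hold, velocities 15, 17.1, 20, 24 and 30 mm/s, three
repetitions each → 15 trials), encodes the three afferent classes, and
refits every gain from the synthetic traces: the fitted `K` matrix and the
scalar force gains land exactly on the generating values. The cancellation
residual (RMS 0.04 N against a 0.75 N peak contractile force) is the group
II yank sensitivity that the force-only approximation `R_II ≈ kF_II F_EI`
ignores; re-running with force-only group II encoding drives it to numerical
zero.

Individual stages compose with the pipe, and fitted objects support
`tidy()`/`glance()`:

```r
library(dplyr)
forces <- stretch_protocol() |> generate_trials() |> simulate_forces()
rates  <- encode_afferent(forces, afferent_params("Ia"))
fit    <- rates |>
  filter(trial_id == "v15_r1") |>
  left_join(select(forces, trial_id, t, F_C, Y), by = c("trial_id", "t")) |>
  fit_force_yank_gains()
tidy(fit)
#> # A tibble: 2 × 2
#>   term       estimate
#>   <chr>         <dbl>
#> 1 force_gain    338.
#> 2 yank_gain      33.6
```

`autoplot(run$demix)` draws the de-mixed force/yank traces per velocity;
`autoplot(run$decomposition)` draws the `F_EI` / `F_C` / `F_SG` traces.

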