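# Shared fixtures: one full simulated session under the default protocol
# (3 mm, 1 s hold, velocities 15/17.1/20/24/30 mm/s, 3 reps), built once per
# test run.
fix_protocol <- stretch_protocol()
fix_forces <- simulate_forces(generate_trials(fix_protocol))
fix_rates <- encode_afferents(fix_forces)

# rates with co-registered mechanics, for fitting
fix_fitdata <- dplyr::left_join(
  fix_rates,
  dplyr::select(fix_forces, trial_id, t, L_MTU, F_MTU, F_NC, F_C, Y),
  by = c("trial_id", "t")
)

one_trial <- function(data, id = "v15_r1", class = NULL) {
  out <- dplyr::filter(data, trial_id == id)
  if (!is.null(class)) out <- dplyr::filter(out, afferent_class == class)
  out
}

# reference gain values used throughout
K_REF <- c(k11 = 337.8, k12 = 33.6, k21 = 182.8, k22 = 4.9)
KF_II <- 182.8
KF_IB <- 128.8
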