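#' Ramp-hold-release stretch protocol
#'
#' Describes a servo-motor stretch protocol applied to a muscle-tendon unit
#' (MTU): a trapezoidal length change of fixed amplitude, ramped up at each of
#' several velocities, held, and ramped back down at the same velocity, with a
#' quiet baseline before and after. The defaults are the protocol used for the
#' in situ rat triceps surae recordings this package emulates: a 3 mm stretch
#' with a 1 s hold at ramp velocities of 15, 17.1, 20, 24 and 30 mm/s, three
#' repetitions per velocity (15 trials per afferent).
#'
#' @param amplitude Stretch amplitude in mm. Must be > 0.
#' @param hold_duration Hold-phase duration in seconds.
#' @param velocities Ramp velocities in mm/s (applied to both ramp-up and
#'   release). All must be > 0.
#' @param reps_per_velocity Number of repetitions per velocity (>= 1).
#' @param baseline_pre,baseline_post Quiet time in seconds before the ramp and
#'   after the release.
#' @param sample_rate Sampling rate of the generated trials in Hz. The default
#'   1780 Hz matches the rate the recordings are processed at (17.8 kHz
#'   recordings decimated by 10).
#' @param fascicle_fraction Fraction of the MTU length change attributed to
#'   the muscle fascicle (emulating sonomicrometry); the remainder is tendon.
#'
#' @return An object of class `stretch_protocol`.
#' @seealso [generate_trials()]
#' @export
#' @examples
#' stretch_protocol()
stretch_protocol <- function(amplitude = 3,
                             hold_duration = 1,
                             velocities = c(15, 17.1, 20, 24, 30),
                             reps_per_velocity = 3,
                             baseline_pre = 0.25,
                             baseline_post = 0.25,
                             sample_rate = 1780,
                             fascicle_fraction = 0.7) {
  check_number(amplitude, "amplitude", 0, strict = TRUE)
  check_number(hold_duration, "hold_duration", 0)
  if (!is.numeric(velocities) || length(velocities) < 1L || any(!is.finite(velocities)) ||
      any(velocities <= 0)) {
    stop_("`velocities` must be positive finite ramp speeds (mm/s)")
  }
  check_number(reps_per_velocity, "reps_per_velocity", 1)
  check_number(baseline_pre, "baseline_pre", 0)
  check_number(baseline_post, "baseline_post", 0)
  check_number(sample_rate, "sample_rate", 0, strict = TRUE)
  check_number(fascicle_fraction, "fascicle_fraction", 0)
  structure(
    list(
      amplitude = amplitude,
      hold_duration = hold_duration,
      velocities = as.numeric(velocities),
      reps_per_velocity = as.integer(reps_per_velocity),
      baseline_pre = baseline_pre,
      baseline_post = baseline_post,
      sample_rate = sample_rate,
      fascicle_fraction = fascicle_fraction
    ),
    class = "stretch_protocol"
  )
}

#' @export
print.stretch_protocol <- function(x, ...) {
  cat("<stretch_protocol>\n")
  cat(sprintf("  %g mm ramp-hold-release, %g s hold\n", x$amplitude, x$hold_duration))
  cat(sprintf("  velocities: %s mm/s x %d reps (%d trials)\n",
              paste(x$velocities, collapse = ", "), x$reps_per_velocity,
              length(x$velocities) * x$reps_per_velocity))
  cat(sprintf("  baseline %g/%g s, sampled at %g Hz\n",
              x$baseline_pre, x$baseline_post, x$sample_rate))
  invisible(x)
}

#' Generate stretch trials from a protocol
#'
#' Expands a [stretch_protocol()] into one trapezoidal length trajectory per
#' (velocity, repetition) pair: baseline at rest length, ramp up at the nominal
#' velocity, hold at full amplitude, ramp back down at the same velocity, and a
#' final baseline. The length-change rate `v` is the analytic derivative of
#' the trapezoid (piecewise constant).
#'
#' @param protocol A [stretch_protocol()].
#' @return A tibble with one row per sample and columns `trial_id`,
#'   `velocity_label` (nominal ramp speed, mm/s), `rep`, `t` (s), `L_MTU`
#'   (MTU length change, mm), `L_fasc` (fascicle length change, mm) and `v`
#'   (mm/s).
#' @export
#' @examples
#' trials <- generate_trials(stretch_protocol())
#' dplyr::n_distinct(trials$trial_id) # 15
generate_trials <- function(protocol = stretch_protocol()) {
  if (!inherits(protocol, "stretch_protocol")) {
    stop_("`protocol` must be a `stretch_protocol` object")
  }
  p <- protocol
  grid <- expand.grid(rep = seq_len(p$reps_per_velocity),
                      velocity = p$velocities)
  purrr::pmap_dfr(grid, function(rep, velocity) {
    ramp <- p$amplitude / velocity
    t_on <- p$baseline_pre
    t_hold <- t_on + ramp
    t_rel <- t_hold + p$hold_duration
    t_end0 <- t_rel + ramp
    total <- t_end0 + p$baseline_post
    t <- seq(0, total, by = 1 / p$sample_rate)
    L <- pmin(pmax((t - t_on) * velocity, 0), p$amplitude) -
      pmin(pmax((t - t_rel) * velocity, 0), p$amplitude)
    v <- numeric(length(t))
    v[t >= t_on & t < t_hold] <- velocity
    v[t >= t_rel & t < t_end0] <- -velocity
    tibble(
      trial_id = sprintf("v%s_r%d", format(velocity), rep),
      velocity_label = velocity,
      rep = as.integer(rep),
      t = t,
      L_MTU = L,
      L_fasc = p$fascicle_fraction * L,
      v = v
    )
  })
}
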