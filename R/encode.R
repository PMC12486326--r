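#' Afferent encoding parameters
#'
#' Gains of the linear force/yank encoding model for one proprioceptive
#' afferent. The firing rate is modelled as
#' `rate = force_gain * F_C + yank_gain * max(Y, 0) + rate_offset +
#' background_rate`, half-wave rectified at zero. Group Ia and II muscle
#' spindle afferents carry both force and yank terms; the group Ib Golgi
#' tendon organ afferent is force-only by default.
#'
#' Defaults per class are the fitted gains this package treats as its
#' reference encoder: Ia (337.8, 33.6), II (182.8, 4.9) and Ib (128.8, 0),
#' all in spikes/(N.s) for force and spikes/s per N/s for yank.
#'
#' @param afferent_class One of `"Ia"`, `"II"`, `"Ib"`.
#' @param force_gain Force gain in spikes/(N.s) (>= 0). Default depends on
#'   class (see above).
#' @param yank_gain Yank gain in spikes/s per N/s (>= 0).
#' @param rate_offset Constant rate offset in spikes/s (>= 0).
#' @param background_rate Background firing in spikes/s (>= 0).
#' @param rectify_output Half-wave rectify the output rate at zero?
#' @param initial_burst_gain Optional extra yank gain applied only within
#'   `burst_window` of stretch onset, emulating the group Ia initial burst;
#'   default 0 (off).
#' @param burst_window Duration (s) after stretch onset over which the
#'   initial-burst gain applies.
#'
#' @return An object of class `afferent_params`.
#' @export
#' @examples
#' afferent_params("Ia")
#' afferent_params("Ib")$force_gain # 128.8
afferent_params <- function(afferent_class = c("Ia", "II", "Ib"),
                            force_gain = NULL,
                            yank_gain = NULL,
                            rate_offset = 0,
                            background_rate = 0,
                            rectify_output = TRUE,
                            initial_burst_gain = 0,
                            burst_window = 0.02) {
  afferent_class <- match.arg(afferent_class)
  defaults <- list(Ia = c(337.8, 33.6), II = c(182.8, 4.9), Ib = c(128.8, 0))[[afferent_class]]
  force_gain <- force_gain %||% defaults[1]
  yank_gain <- yank_gain %||% defaults[2]
  check_number(force_gain, "force_gain", 0)
  check_number(yank_gain, "yank_gain", 0)
  check_number(rate_offset, "rate_offset", 0)
  check_number(background_rate, "background_rate", 0)
  check_number(initial_burst_gain, "initial_burst_gain", 0)
  check_number(burst_window, "burst_window", 0)
  structure(
    list(afferent_class = afferent_class, force_gain = force_gain,
         yank_gain = yank_gain, rate_offset = rate_offset,
         background_rate = background_rate, rectify_output = isTRUE(rectify_output),
         initial_burst_gain = initial_burst_gain, burst_window = burst_window),
    class = "afferent_params"
  )
}

#' Default afferent set (Ia, II, Ib)
#'
#' @return A named list of [afferent_params()] for the three classes.
#' @export
default_afferents <- function() {
  list(Ia = afferent_params("Ia"), II = afferent_params("II"),
       Ib = afferent_params("Ib"))
}

#' Encode afferent firing rates from a force trace
#'
#' Applies the linear force/yank encoding model of [afferent_params()] to
#' simulated forces: the rate follows contractile force and (for spindle
#' afferents) the rectified yank. The optional initial-burst term adds extra
#' yank drive within a short window after stretch onset (the first sample
#' where the length-change rate becomes positive).
#'
#' @param forces Forces tibble from [simulate_forces()] (columns `t`, `F_C`,
#'   `Y`, plus trial keys; `v` needed only when the initial burst is on).
#' @param params An [afferent_params()] object.
#' @return A tibble with trial keys, `afferent_class`, `t` and `rate`
#'   (spikes/s).
#' @export
#' @examples
#' forces <- simulate_forces(generate_trials(stretch_protocol()))
#' rates <- encode_afferent(forces, afferent_params("Ia"))
encode_afferent <- function(forces, params) {
  check_cols(forces, c("t", "F_C", "Y"))
  if (!inherits(params, "afferent_params")) stop_("`params` must be an `afferent_params` object")
  keys <- intersect(TRACE_KEYS, names(forces))
  forces %>%
    group_by(across(all_of(setdiff(keys, "afferent_class")))) %>%
    group_modify(function(df, key) {
      rate <- params$force_gain * df$F_C + params$yank_gain * pmax(df$Y, 0) +
        params$rate_offset + params$background_rate
      if (params$initial_burst_gain > 0 && "v" %in% names(df)) {
        onset <- which(df$v > 0)[1]
        if (!is.na(onset)) {
          in_burst <- df$t >= df$t[onset] & df$t < df$t[onset] + params$burst_window
          rate[in_burst] <- rate[in_burst] +
            params$initial_burst_gain * pmax(df$Y[in_burst], 0)
        }
      }
      if (params$rectify_output) rate <- pmax(rate, 0)
      tibble(afferent_class = params$afferent_class, t = df$t, rate = rate)
    }) %>%
    ungroup()
}

#' Encode all afferents in a set
#'
#' @param forces Forces tibble from [simulate_forces()].
#' @param afferents A list of [afferent_params()], e.g. [default_afferents()].
#' @return Long tibble of rates for every afferent class.
#' @export
encode_afferents <- function(forces, afferents = default_afferents()) {
  purrr::map_dfr(afferents, ~ encode_afferent(forces, .x))
}

#' Convert a rate trace to spike times
#'
#' Deterministic integrate-to-threshold spike emission: the rate (spikes/s)
#' is integrated over time (trapezoid rule) and a spike is emitted each time
#' the integral crosses the next whole count, with the crossing time found by
#' linear interpolation. The reciprocal interspike interval of the emitted
#' train reconstructs the driving rate up to discretisation error, making the
#' spike pathway an exact inverse of [spikes_to_ifr()] for slowly varying
#' rates. A seeded Poisson mode is available for stochastic trains.
#'
#' @param rates Rate tibble (columns `t`, `rate`, plus trace keys).
#' @param mode `"integrate"` (deterministic, default) or `"poisson"`.
#' @param seed Integer seed; only consumed in Poisson mode.
#' @return A tibble with trace keys and `spike_time` (s), sorted within trace.
#' @export
#' @examples
#' r <- tibble::tibble(t = seq(0, 1, by = 1e-3), rate = 10)
#' nrow(rate_to_spikes(r)) # ~10 spikes
rate_to_spikes <- function(rates, mode = c("integrate", "poisson"), seed = 1L) {
  mode <- match.arg(mode)
  check_cols(rates, c("t", "rate"))
  if (any(rates$rate < 0)) stop_("`rate` must be non-negative")
  keys <- intersect(TRACE_KEYS, names(rates))
  emit <- function(df, key) {
    t <- df$t
    dt <- diff(t)
    cum <- c(0, cumsum((df$rate[-1] + df$rate[-nrow(df)]) / 2 * dt))
    total <- cum[length(cum)]
    if (mode == "integrate") {
      thresholds <- seq_len(floor(total))
    } else {
      # unit-rate Poisson arrivals in integrated-rate time (time rescaling);
      # per-trace seed offset so traces are not duplicates of each other
      seed <- seed + sum(utf8ToInt(paste(unlist(key), collapse = "_"))) %% 100000L
      thresholds <- withr::with_seed(seed, {
        arr <- cumsum(stats::rexp(max(10, ceiling(total * 2 + 20))))
        arr[arr <= total]
      })
    }
    if (length(thresholds) == 0L) return(tibble(spike_time = numeric(0)))
    idx <- pmin(findInterval(thresholds, cum), length(cum) - 1L)
    frac <- (thresholds - cum[idx]) / (cum[idx + 1L] - cum[idx])
    tibble(spike_time = t[idx] + frac * (t[idx + 1L] - t[idx]))
  }
  rates %>%
    group_by(across(all_of(keys))) %>%
    group_modify(emit) %>%
    ungroup()
}

#' Add multiplicative rate noise
#'
#' Perturbs each rate sample by a multiplicative Gaussian factor
#' `1 + cv * eps`, `eps ~ N(0, 1)`, then rectifies at zero. Reproducible for
#' a fixed seed; `cv = 0` returns the input unchanged.
#'
#' @param rates Rate tibble (column `rate`).
#' @param cv Coefficient of variation of the perturbation (>= 0).
#' @param seed Integer seed.
#' @return The input tibble with perturbed `rate`.
#' @export
add_rate_noise <- function(rates, cv, seed = 1L) {
  check_number(cv, "cv", 0)
  check_cols(rates, "rate")
  if (cv == 0) return(rates)
  noise <- withr::with_seed(seed, stats::rnorm(nrow(rates)))
  rates$rate <- pmax(rates$rate * (1 + cv * noise), 0)
  rates
}
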