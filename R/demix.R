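#' De-mix force and yank from spindle firing rates
#'
#' Inverts the spindle gain matrix per sample to turn the combined group Ia
#' and II firing rates into estimates of the driving mechanical state:
#' `[F_est; Y_est](t) = K^-1 [R_Ia; R_II](t)`. Negative estimates are
#' reported as-is (the estimator is linear; clipping would hide
#' miscalibration) unless `rectify = TRUE` is requested for display.
#'
#' @param data Tibble with aligned rate columns on one time grid.
#' @param K A [gain_matrix()] (or plain invertible 2 x 2 matrix).
#' @param ia,ii Names of the group Ia and II rate columns.
#' @param rectify Floor the estimates at zero (display only).
#' @param det_floor Minimum acceptable `|det K|`.
#' @return A `demix_result` tibble: the input keys and `t` plus `F_est` (N)
#'   and `Y_est` (N/s), with `det` and `condition_number` attributes.
#' @export
#' @examples
#' K <- gain_matrix()
#' d <- tibble::tibble(t = 0:9 / 10, rate_Ia = 337.8, rate_II = 182.8)
#' demix_spindle(d, K) # F_est = 1 N, Y_est = 0
demix_spindle <- function(data, K, ia = "rate_Ia", ii = "rate_II",
                          rectify = FALSE, det_floor = 1e-6) {
  check_cols(data, c("t", ia, ii))
  K <- as.matrix(K)
  if (!all(dim(K) == c(2, 2)) || any(!is.finite(K))) {
    stop_("`K` must be a finite 2 x 2 matrix")
  }
  d <- det(K)
  if (abs(d) < det_floor) {
    stop_("`K` is singular to tolerance: |det| = %.3g < %.3g", abs(d), det_floor)
  }
  est <- solve(K, rbind(data[[ia]], data[[ii]]))
  out <- data %>%
    select(any_of(c(TRACE_KEYS, "t", "complete"))) %>%
    mutate(F_est = est[1, ], Y_est = est[2, ])
  if (rectify) out <- mutate(out, F_est = pmax(.data$F_est, 0),
                             Y_est = pmax(.data$Y_est, 0))
  structure(out, det = d, condition_number = kappa(K, exact = TRUE),
            class = c("demix_result", class(out)))
}

#' Decompose contractile force into self-generated and external parts
#'
#' Combines group II (muscle spindle) and group Ib (Golgi tendon organ)
#' firing through their force gains: the spindle signals the externally
#' imposed force (`F_EI = R_II / kF_II`), the tendon organ the total
#' contractile force (`F_C = R_Ib / kF_Ib`), and their difference is the
#' self-generated force (`F_SG = F_C - F_EI`). During purely passive stretch
#' the two estimates cancel; during (modelled) eccentric contraction the
#' residual is the contraction force.
#'
#' @param data Tibble with aligned group II and Ib rate columns.
#' @param gains A [force_gains()] object.
#' @param ii,ib Names of the group II and Ib rate columns.
#' @return A `force_decomposition` tibble: keys, `t`, `F_EI_est`, `F_C_est`
#'   and `F_SG_est` (N).
#' @export
#' @examples
#' d <- tibble::tibble(t = 0:9 / 10, rate_II = 182.8, rate_Ib = 128.8)
#' estimate_forces(d, force_gains()) # all forces 1 N, F_SG = 0
estimate_forces <- function(data, gains = force_gains(),
                            ii = "rate_II", ib = "rate_Ib") {
  check_cols(data, c("t", ii, ib))
  if (!inherits(gains, "force_gains")) stop_("`gains` must be a `force_gains` object")
  out <- data %>%
    select(any_of(c(TRACE_KEYS, "t", "complete"))) %>%
    mutate(F_EI_est = data[[ii]] / gains$kF_II,
           F_C_est = data[[ib]] / gains$kF_Ib,
           F_SG_est = .data$F_C_est - .data$F_EI_est)
  structure(out, class = c("force_decomposition", class(out)))
}

#' Model an eccentric contraction as an Ib rate offset
#'
#' Adds a small constant offset to the group Ib firing rate over an epoch,
#' emulating the extra tendon-organ drive of an eccentric (actively
#' lengthening) contraction while spindle firing is unchanged. Feeding the
#' result to [estimate_forces()] shifts `F_SG_est` by exactly
#' `offset / kF_Ib` within the epoch.
#'
#' @param data Tibble with a `t` column and the Ib rate column.
#' @param offset Constant rate offset in spikes/s (>= 0).
#' @param epoch Length-2 numeric `c(start, end)` in seconds, or `NULL` for
#'   the whole trace. Must lie within the trace span.
#' @param ib Name of the Ib rate column.
#' @return `data` with the offset applied.
#' @export
apply_eccentric <- function(data, offset, epoch = NULL, ib = "rate_Ib") {
  check_cols(data, c("t", ib))
  check_number(offset, "offset", 0)
  if (is.null(epoch)) {
    sel <- rep(TRUE, nrow(data))
  } else {
    if (!is.numeric(epoch) || length(epoch) != 2L || epoch[1] > epoch[2]) {
      stop_("`epoch` must be c(start, end) in seconds")
    }
    if (epoch[1] < min(data$t) - 1e-12 || epoch[2] > max(data$t) + 1e-12) {
      stop_("`epoch` [%g, %g] lies outside the trace span [%g, %g]",
            epoch[1], epoch[2], min(data$t), max(data$t))
    }
    sel <- data$t >= epoch[1] & data$t <= epoch[2]
  }
  data[[ib]] <- data[[ib]] + offset * sel
  data
}

#' Interneuron input weights
#'
#' Signed weights for a hypothetical spinal interneuron combining the three
#' proprioceptive afferent classes. The default weighting — excitation by the
#' group Ia (which carries the stretch yank) and inhibition by the group Ib
#' (which carries contractile force) — produces a "startle"-like response:
#' strong at sudden stretch onset, suppressed during the hold and during
#' self-generated force.
#'
#' @param w_Ia,w_II,w_Ib Dimensionless signed weights.
#' @param rectify Half-wave rectify the summed response at zero (a firing
#'   rate cannot be negative).
#' @return An object of class `interneuron_weights`.
#' @export
interneuron_weights <- function(w_Ia = 1, w_II = 0, w_Ib = -1, rectify = TRUE) {
  for (nm in c("w_Ia", "w_II", "w_Ib")) check_number(get(nm), nm)
  structure(list(w_Ia = w_Ia, w_II = w_II, w_Ib = w_Ib,
                 rectify = isTRUE(rectify)),
            class = "interneuron_weights")
}

#' Hypothetical interneuron response to combined afferent input
#'
#' Weighted linear combination of aligned group Ia, II and Ib firing rates,
#' optionally half-wave rectified: `r(t) = w_Ia R_Ia + w_II R_II + w_Ib
#' R_Ib`.
#'
#' @param data Tibble with aligned rate columns `rate_Ia`, `rate_II`,
#'   `rate_Ib` on one grid.
#' @param weights An [interneuron_weights()] object.
#' @return Tibble with keys, `t` and the summed `rate`.
#' @export
interneuron_response <- function(data, weights = interneuron_weights()) {
  check_cols(data, c("t", "rate_Ia", "rate_II", "rate_Ib"))
  if (!inherits(weights, "interneuron_weights")) {
    stop_("`weights` must be an `interneuron_weights` object")
  }
  r <- weights$w_Ia * data$rate_Ia + weights$w_II * data$rate_II +
    weights$w_Ib * data$rate_Ib
  if (weights$rectify) r <- pmax(r, 0)
  data %>%
    select(any_of(c(TRACE_KEYS, "t"))) %>%
    mutate(rate = r)
}
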