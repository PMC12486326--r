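#' Scalar force gains for group II and Ib afferents
#'
#' Holds the proportional force-encoding gains used for the
#' spindle/tendon-organ force decomposition: `R_II ~ kF_II * F_EI` and
#' `R_Ib = kF_Ib * F_C`. Defaults are the package's reference gains,
#' 182.8 and 128.8 spikes/(N.s).
#'
#' @param kF_II Group II force gain in spikes/(N.s) (> 0).
#' @param kF_Ib Group Ib force gain in spikes/(N.s) (> 0).
#' @return An object of class `force_gains`.
#' @export
force_gains <- function(kF_II = 182.8, kF_Ib = 128.8) {
  check_number(kF_II, "kF_II", 0, strict = TRUE)
  check_number(kF_Ib, "kF_Ib", 0, strict = TRUE)
  structure(list(kF_II = kF_II, kF_Ib = kF_Ib), class = "force_gains")
}

#' Spindle gain matrix
#'
#' The 2 x 2 matrix `K` mapping mechanical drive (contractile force, yank)
#' to group Ia and II firing rates: row 1 the Ia force/yank gains, row 2 the
#' II force/yank gains. The inverse of `K` de-mixes measured rates back into
#' force and yank estimates, so `K` must be comfortably invertible: matrices
#' with `|det| < floor` are rejected and the condition number is attached.
#'
#' @param k11,k12 Group Ia force and yank gains.
#' @param k21,k22 Group II force and yank gains.
#' @param det_floor Minimum acceptable `|det K|` (in gain units).
#' @return A `gain_matrix`: a 2 x 2 matrix with rows `Ia`, `II` and columns
#'   `force`, `yank`, with `det` and `condition_number` attributes.
#' @export
#' @examples
#' K <- gain_matrix() # reference gains
#' attr(K, "det")
gain_matrix <- function(k11 = 337.8, k12 = 33.6, k21 = 182.8, k22 = 4.9,
                        det_floor = 1e-6) {
  for (nm in c("k11", "k12", "k21", "k22")) check_number(get(nm), nm, 0)
  K <- matrix(c(k11, k12, k21, k22), nrow = 2, byrow = TRUE,
              dimnames = list(c("Ia", "II"), c("force", "yank")))
  d <- det(K)
  if (abs(d) < det_floor) {
    stop_("gain matrix is singular to tolerance: |det| = %.3g < %.3g", abs(d), det_floor)
  }
  structure(K, det = d, condition_number = kappa(K, exact = TRUE),
            class = c("gain_matrix", "matrix", "array"))
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat("<gain_matrix> (spikes/s per N, spikes/s per N/s)\n")
  print(unclass(structure(x, det = NULL, condition_number = NULL)))
  cat(sprintf("det = %.4g, condition number = %.4g\n",
              attr(x, "det"), attr(x, "condition_number")))
  invisible(x)
}

new_afferent_fit <- function(gains, fitted, observed, method, extra = list()) {
  resid <- observed - fitted
  ss_tot <- sum(observed^2) # intercept-free model: variance about zero
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  structure(
    c(list(gains = gains,
           residual_rms = sqrt(mean(resid^2)),
           r_squared = r2,
           n = length(observed),
           method = method,
           fitted = fitted),
      extra),
    class = "afferent_fit"
  )
}

#' @export
print.afferent_fit <- function(x, ...) {
  cat("<afferent_fit> (", x$method, ")\n", sep = "")
  print(round(x$gains, 4))
  cat(sprintf("residual RMS %.4g spikes/s, R^2 %.4f, n = %d\n",
              x$residual_rms, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.afferent_fit <- function(x, ...) {
  tibble(term = names(x$gains), estimate = unname(x$gains))
}

#' @export
glance.afferent_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$residual_rms, nobs = x$n,
         method = x$method)
}

#' Fit force and yank gains to a firing rate
#'
#' Non-negative least squares of an afferent firing rate on contractile force
#' and half-wave-rectified yank, without intercept (the encoding model has no
#' offset term and physiological gains are non-negative): `rate ~ force_gain *
#' F_C + yank_gain * max(Y, 0)`. An optional onset mask excludes an initial
#' window (e.g. the group Ia initial burst) from the fit, and an intercept
#' can be enabled for recordings with background firing.
#'
#' @param data Tibble with the rate and mechanical columns co-registered on
#'   one grid.
#' @param rate,force,yank Column names.
#' @param nonneg Constrain gains to be >= 0 (default) or fall back to
#'   ordinary least squares.
#' @param intercept Include a background-rate intercept.
#' @param mask_onset If non-`NULL`, seconds after the start of the trace to
#'   exclude from the fit.
#' @return An `afferent_fit` with `gains` (`force_gain`, `yank_gain`, and
#'   `intercept` if requested); supports [tidy()] and [glance()].
#' @export
#' @examples
#' d <- tibble::tibble(t = 1:100 / 100, F_C = sin(1:100 / 20)^2, Y = cos(1:100 / 20))
#' d$rate <- 337.8 * d$F_C + 33.6 * pmax(d$Y, 0)
#' tidy(fit_force_yank_gains(d))
fit_force_yank_gains <- function(data, rate = "rate", force = "F_C", yank = "Y",
                                 nonneg = TRUE, intercept = FALSE,
                                 mask_onset = NULL) {
  check_cols(data, c(rate, force, yank))
  keep <- rep(TRUE, nrow(data))
  if (!is.null(mask_onset) && "t" %in% names(data)) {
    keep <- data$t >= data$t[1] + mask_onset
  }
  y <- data[[rate]][keep]
  X <- cbind(force_gain = data[[force]][keep],
             yank_gain = pmax(data[[yank]][keep], 0))
  if (intercept) X <- cbind(X, intercept = 1)
  # collinearity guard: rectified yank proportional to force defeats the fit
  if (all(abs(X[, 2]) < 1e-12) ||
      kappa(crossprod(X), exact = TRUE) > 1e12) {
    warn_("force and rectified-yank regressors are (near-)collinear; gains are ill-determined")
  }
  if (all(abs(y) < 1e-300)) {
    coef <- stats::setNames(numeric(ncol(X)), colnames(X))
  } else if (nonneg) {
    coef <- stats::setNames(pracma::lsqnonneg(X, y)$x, colnames(X))
  } else {
    coef <- stats::setNames(stats::lm.fit(X, y)$coefficients, colnames(X))
  }
  new_afferent_fit(coef, as.numeric(X %*% coef), y,
                   method = if (nonneg) "nnls" else "ols")
}

#' Fit a single proportional force gain
#'
#' Least-squares fit of the one-parameter force-encoding model
#' `rate = k * F_C` used for group II and Ib afferents, constrained
#' non-negative.
#'
#' @inheritParams fit_force_yank_gains
#' @return An `afferent_fit` with a single `force_gain`.
#' @export
fit_force_gain <- function(data, rate = "rate", force = "F_C") {
  check_cols(data, c(rate, force))
  y <- data[[rate]]
  f <- data[[force]]
  ss <- sum(f^2)
  if (ss == 0) stop_("force regressor is identically zero")
  k <- max(sum(f * y) / ss, 0)
  new_afferent_fit(c(force_gain = k), k * f, y, method = "proportional-ls")
}

#' Joint non-contractile-model and Ib-gain fit
#'
#' Fits the exponential non-contractile force-length model together with the
#' Golgi tendon organ force gain. The contractile force implied by parameters
#' `(a, b, L0)` is `F_C = F_MTU - F_NC(L)` (floored at zero), and the
#' objective is the squared error between `k * F_C` and the recorded Ib
#' firing rate. Optimisation is bounded (`a >= 0`, `b > 0`, `k > 0`) by
#' L-BFGS-B with seeded multiplicative multi-start to reduce the risk of
#' local minima on the exponential's scale/offset ridge.
#'
#' @param data Tibble with length, total force and Ib rate columns on one
#'   grid.
#' @param length,force,rate Column names for MTU length change (mm), total
#'   MTU force (N) and Ib firing rate (spikes/s).
#' @param init A [muscle_params()] used as the starting point for
#'   `(a, b, L0)`.
#' @param init_gain Starting value for the Ib force gain (spikes/(N.s)).
#' @param n_starts Number of optimisation starts (first start is `init`
#'   itself, the rest are seeded perturbations).
#' @param seed Seed for the start perturbations.
#' @return An object of class `nc_fit`: fitted `params` (a `muscle_params`;
#'   CE terms carried over from `init`), `kF_Ib`, residual RMS, variance
#'   explained, the per-start objective table, a `degenerate` flag (fitted
#'   contractile force identically ~0), and the fitted `F_C` trace. Supports
#'   [tidy()] and [glance()].
#' @export
fit_noncontractile <- function(data, length = "L_MTU", force = "F_MTU",
                               rate = "rate", init = muscle_params(),
                               init_gain = 100, n_starts = 3, seed = 1L) {
  check_cols(data, c(length, force, rate))
  if (!inherits(init, "muscle_params")) stop_("`init` must be a `muscle_params` object")
  L <- data[[length]]
  Fm <- data[[force]]
  R <- data[[rate]]
  fc_of <- function(th) pmax(Fm - noncontractile_force(L, th[1], th[2], th[3]), 0)
  obj <- function(th) {
    r <- th[4] * fc_of(th) - R
    sum(r * r)
  }
  lower <- c(0, 1e-6, min(L) - diff(range(L)), 1e-6)
  upper <- c(Inf, Inf, max(L), Inf)
  th0 <- c(init$nc_scale, init$nc_rate, init$nc_rest_length, init_gain)
  starts <- list(th0)
  if (n_starts > 1) {
    pert <- withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        s <- th0 * exp(stats::rnorm(4, sd = 0.5))
        s[3] <- th0[3] + stats::rnorm(1, sd = 0.3 * max(diff(range(L)), 1))
        pmin(pmax(s, lower + 1e-8), pmin(upper, 1e6))
      })
    })
    starts <- c(starts, pert)
  }
  fits <- lapply(starts, function(s) {
    stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 1000, factr = 10, pgtol = 1e-12))
  })
  values <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(values)]]
  # simplex polish: L-BFGS-B stalls short of the optimum on the exponential's
  # scale/offset ridge; two Nelder-Mead restarts converge it out
  for (i in 1:2) {
    polish <- stats::optim(best$par, obj, method = "Nelder-Mead",
                           control = list(maxit = 20000, reltol = 1e-16))
    if (polish$value <= best$value &&
        all(polish$par >= lower) && all(polish$par <= upper)) best <- polish
  }
  th <- best$par
  fc_hat <- th[4] * fc_of(th)
  resid <- fc_hat - R
  ss_tot <- sum(R^2)
  params <- muscle_params(nc_scale = th[1], nc_rate = th[2], nc_rest_length = th[3],
                          ce_stiffness = init$ce_stiffness,
                          ce_viscosity = init$ce_viscosity)
  structure(
    list(params = params,
         kF_Ib = th[4],
         residual_rms = sqrt(mean(resid^2)),
         r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_,
         n = base::length(R),
         starts = tibble(start = seq_along(values), objective = values),
         initial_objective = obj(th0),
         objective = best$value,
         convergence = best$convergence,
         degenerate = max(fc_of(th)) < 1e-9,
         F_C = fc_of(th),
         fitted = fc_hat),
    class = "nc_fit"
  )
}

#' @export
print.nc_fit <- function(x, ...) {
  cat("<nc_fit> exponential non-contractile model + Ib gain\n")
  cat(sprintf("  a = %.4g N, b = %.4g /mm, L0 = %.4g mm, kF_Ib = %.4g spikes/(N.s)\n",
              x$params$nc_scale, x$params$nc_rate, x$params$nc_rest_length, x$kF_Ib))
  cat(sprintf("  residual RMS %.4g spikes/s, R^2 %.4f, n = %d%s\n",
              x$residual_rms, x$r_squared, x$n,
              if (x$degenerate) " [degenerate: F_C ~ 0]" else ""))
  invisible(x)
}

#' @export
tidy.nc_fit <- function(x, ...) {
  tibble(
    term = c("nc_scale", "nc_rate", "nc_rest_length", "kF_Ib"),
    estimate = c(x$params$nc_scale, x$params$nc_rate, x$params$nc_rest_length,
                 x$kF_Ib)
  )
}

#' @export
glance.nc_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$residual_rms, nobs = x$n,
         convergence = x$convergence, degenerate = x$degenerate)
}

#' Fit force/yank gains for every trial and afferent
#'
#' Convenience wrapper running [fit_force_yank_gains()] per
#' (trial, afferent class) on a rates tibble that already carries the
#' co-registered mechanical columns.
#'
#' @param data Tibble with trace keys and columns `rate`, `F_C`, `Y`.
#' @param ... Passed to [fit_force_yank_gains()].
#' @return Tibble with one row per trace: keys, `force_gain`, `yank_gain`,
#'   `r_squared`, `residual_rms`.
#' @export
fit_gains_by_trial <- function(data, ...) {
  keys <- intersect(TRACE_KEYS, names(data))
  data %>%
    group_by(across(all_of(keys))) %>%
    group_modify(function(df, key) {
      f <- fit_force_yank_gains(df, ...)
      tibble(force_gain = f$gains[["force_gain"]],
             yank_gain = f$gains[["yank_gain"]],
             r_squared = f$r_squared, residual_rms = f$residual_rms)
    }) %>%
    ungroup()
}

#' Assemble the spindle gain matrix from per-trial gains
#'
#' Averages the fitted group Ia and II force/yank gain pairs over the trials
#' at one reference velocity (15 mm/s by default) and assembles them into the
#' 2 x 2 [gain_matrix()] used for de-mixing.
#'
#' @param gains Per-trial gain tibble from [fit_gains_by_trial()] (columns
#'   `afferent_class`, `velocity_label`, `force_gain`, `yank_gain`).
#' @param velocity Reference ramp velocity (mm/s) whose trials are averaged.
#' @param tol Velocity matching tolerance (mm/s).
#' @return A [gain_matrix()] with a `provenance` attribute recording the
#'   velocity and per-class trial counts.
#' @export
assemble_K <- function(gains, velocity = 15, tol = 1e-6) {
  check_cols(gains, c("afferent_class", "velocity_label", "force_gain", "yank_gain"))
  sel <- gains %>%
    filter(abs(.data$velocity_label - velocity) <= tol,
           .data$afferent_class %in% c("Ia", "II"))
  counts <- table(sel$afferent_class)
  for (cl in c("Ia", "II")) {
    if (!cl %in% names(counts) || counts[[cl]] < 1) {
      stop_("no %s trials at velocity %g mm/s to average", cl, velocity)
    }
  }
  avg <- sel %>%
    group_by(.data$afferent_class) %>%
    summarise(force_gain = mean(.data$force_gain),
              yank_gain = mean(.data$yank_gain), .groups = "drop")
  ia <- filter(avg, .data$afferent_class == "Ia")
  ii <- filter(avg, .data$afferent_class == "II")
  K <- gain_matrix(ia$force_gain, ia$yank_gain, ii$force_gain, ii$yank_gain)
  attr(K, "provenance") <- list(velocity = velocity,
                                n_trials = as.list(counts))
  K
}
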