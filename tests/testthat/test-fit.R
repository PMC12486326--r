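test_that("force/yank gains are recovered exactly from noiseless traces", {
  # every afferent class, several trials: generating gains recovered to 1e-6
  cases <- expand.grid(cl = c("Ia", "II"), id = c("v15_r1", "v24_3" = "v24_r3"),
                       stringsAsFactors = FALSE)
  truth <- list(Ia = c(337.8, 33.6), II = c(182.8, 4.9))
  for (i in seq_len(nrow(cases))) {
    f <- fit_force_yank_gains(one_trial(fix_fitdata, cases$id[i], cases$cl[i]))
    expect_equal(unname(f$gains), truth[[cases$cl[i]]], tolerance = 1e-6)
    expect_gt(f$r_squared, 1 - 1e-10)
  }
})

test_that("gain fitting degrades gracefully and stays non-negative", {
  d <- one_trial(fix_fitdata, class = "II")
  # zero rate -> zero gains
  d0 <- dplyr::mutate(d, rate = 0)
  expect_equal(unname(fit_force_yank_gains(d0)$gains), c(0, 0))
  # anti-correlated rate clamps to zero rather than going negative
  dneg <- dplyr::mutate(d, rate = -F_C)
  expect_equal(unname(fit_force_yank_gains(dneg)$gains), c(0, 0))
  # residual RMS never exceeds the RMS of the rate itself
  for (dd in list(d, d0, dneg)) {
    f <- fit_force_yank_gains(dd)
    expect_lte(f$residual_rms, sqrt(mean(dd$rate^2)) + 1e-12)
  }
  # collinear regressors warn
  dcol <- dplyr::mutate(d, Y = 2 * F_C)
  expect_warning(fit_force_yank_gains(dcol), "collinear")
})

test_that("noisy rates still recover the generating gains within 5%", {
  d <- one_trial(fix_fitdata, class = "II")
  noisy <- add_rate_noise(d, cv = 0.05, seed = 42)
  expect_gt(nrow(noisy), 1000)
  f <- fit_force_yank_gains(noisy)
  expect_equal(f$gains[["force_gain"]], 182.8, tolerance = 0.05)
  expect_equal(f$gains[["yank_gain"]], 4.9, tolerance = 0.05)
})

test_that("the scalar force gain fit matches the analytic projection", {
  d <- one_trial(fix_fitdata, class = "Ib")
  f <- fit_force_gain(d)
  expect_equal(f$gains[["force_gain"]], 128.8, tolerance = 1e-9)
  expect_equal(f$gains[["force_gain"]],
               sum(d$F_C * d$rate) / sum(d$F_C^2)) # closed-form projection
  expect_error(fit_force_gain(dplyr::mutate(d, F_C = 0)), "zero")
})

test_that("the joint non-contractile fit recovers parameters and the Ib gain", {
  d <- dplyr::filter(fix_fitdata, afferent_class == "Ib", velocity_label == 15)
  init_away <- muscle_params(nc_scale = 0.2, nc_rate = 2.5, nc_rest_length = 1.2)
  fit <- fit_noncontractile(d, init = init_away, init_gain = 40)
  est <- tidy(fit)$estimate
  expect_equal(est, c(0.05, 1, 0.5, 128.8), tolerance = 0.01)
  expect_equal(fit$kF_Ib, 128.8, tolerance = 1e-4)
  expect_false(fit$degenerate)
  # accepted objective never above the starting objective
  expect_lte(fit$objective, fit$initial_objective)
  expect_gt(fit$r_squared, 0.999)
})

test_that("a zero-contractile-force dataset is flagged degenerate", {
  # all MTU force is non-contractile; the Ib rate is zero
  trials <- generate_trials(stretch_protocol(velocities = 15, reps_per_velocity = 1))
  stiff0 <- muscle_params(ce_stiffness = 0, ce_viscosity = 0)
  forces <- simulate_forces(trials, stiff0)
  d <- dplyr::mutate(forces, rate = 128.8 * F_C) # identically zero
  fit <- fit_noncontractile(d, init = stiff0)
  expect_true(fit$degenerate)
  expect_lt(max(abs(fit$fitted)), 1e-6)
})

test_that("K assembly averages the reference-velocity trials", {
  # hand-built per-trial gains whose means are the reference matrix
  gains <- tibble::tibble(
    afferent_class = rep(c("Ia", "II"), each = 3),
    velocity_label = 15,
    force_gain = c(300, 370, 343.4, 170, 190, 188.4),
    yank_gain = c(30, 37, 33.8, 4, 5, 5.7)
  )
  K <- assemble_K(gains)
  expect_equal(unname(unclass(K)[1, ]), c(337.8, 33.6))
  expect_equal(unname(unclass(K)[2, ]), c(182.8, 4.9))
  # identical gain sets average to themselves
  same <- tibble::tibble(afferent_class = rep(c("Ia", "II"), 3),
                         velocity_label = 15,
                         force_gain = rep(c(337.8, 182.8), 3),
                         yank_gain = rep(c(33.6, 4.9), 3))
  expect_equal(unclass(assemble_K(same))[, ], unclass(K)[, ])
  # trials at other velocities are excluded by the filter
  with20 <- dplyr::bind_rows(gains, tibble::tibble(
    afferent_class = "Ia", velocity_label = 20, force_gain = 1e6, yank_gain = 1e6))
  expect_equal(unclass(assemble_K(with20))[, ], unclass(K)[, ])
  # missing class at the filter velocity errors
  expect_error(assemble_K(dplyr::filter(gains, afferent_class == "Ia")), "II")
  # singular mean matrix errors with the conditioning metric named
  sing <- tibble::tibble(afferent_class = c("Ia", "II"), velocity_label = 15,
                         force_gain = c(100, 100), yank_gain = c(10, 10))
  expect_error(assemble_K(sing), "singular")
})

test_that("fit objects expose tidy() and glance() summaries", {
  f <- fit_force_yank_gains(one_trial(fix_fitdata, class = "Ia"))
  td <- tidy(f)
  expect_equal(td$term, c("force_gain", "yank_gain"))
  gl <- glance(f)
  expect_true(all(c("r.squared", "sigma", "nobs") %in% names(gl)))
  d <- dplyr::filter(fix_fitdata, afferent_class == "Ib", velocity_label == 15)
  nc <- fit_noncontractile(d)
  expect_equal(tidy(nc)$term, c("nc_scale", "nc_rate", "nc_rest_length", "kF_Ib"))
  expect_equal(glance(nc)$nobs, nrow(d))
})

test_that("per-trial gain fitting covers every trace", {
  sub <- dplyr::filter(fix_fitdata, velocity_label %in% c(15, 30))
  g <- fit_gains_by_trial(sub)
  expect_equal(nrow(g), 2 * 3 * 3) # 2 velocities x 3 reps x 3 classes
  expect_true(all(g$force_gain >= 0 & g$yank_gain >= 0))
})
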