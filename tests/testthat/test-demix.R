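# independent 2x2 inversion oracle: explicit adjugate formula
solve2_oracle <- function(K, r) {
  d <- K[1, 1] * K[2, 2] - K[1, 2] * K[2, 1]
  c((K[2, 2] * r[1] - K[1, 2] * r[2]) / d,
    (-K[2, 1] * r[1] + K[1, 1] * r[2]) / d)
}

test_that("spindle de-mixing inverts the gain matrix per sample", {
  K <- gain_matrix()
  d <- tibble::tibble(t = 0:9 / 10, rate_Ia = 337.8, rate_II = 182.8)
  out <- demix_spindle(d, K)
  expect_equal(out$F_est, rep(1, 10))
  expect_equal(out$Y_est, rep(0, 10))
  z <- demix_spindle(dplyr::mutate(d, rate_Ia = 0, rate_II = 0), K)
  expect_equal(z$F_est, rep(0, 10))
  expect_equal(z$Y_est, rep(0, 10))
  # independent oracle on an arbitrary rate pair
  o <- solve2_oracle(unclass(K), c(100, 50))
  out2 <- demix_spindle(dplyr::mutate(d, rate_Ia = 100, rate_II = 50), K)
  expect_equal(out2$F_est[1], o[1], tolerance = 1e-12)
  expect_equal(out2$Y_est[1], o[2], tolerance = 1e-12)
  expect_equal(o, c(0.2652, 0.3098), tolerance = 1e-4)
  expect_equal(attr(out, "det"), 337.8 * 4.9 - 33.6 * 182.8)
})

test_that("de-mix/re-mix identity holds on random traces", {
  set.seed(101)
  max_rel <- 0
  for (i in 1:1000) {
    K <- matrix(runif(4, 0.5, 400), 2)
    if (abs(det(K)) < 1) next # stay clear of the conditioning floor
    FY <- rbind(runif(20, 0, 2), runif(20, -5, 5))
    R <- K %*% FY
    d <- tibble::tibble(t = seq_len(20) / 100, rate_Ia = R[1, ], rate_II = R[2, ])
    out <- demix_spindle(d, K)
    rel <- max(abs(rbind(out$F_est, out$Y_est) - FY)) / max(abs(FY))
    max_rel <- max(max_rel, rel)
  }
  expect_lt(max_rel, 1e-9)
})

test_that("singular or mismatched inputs fail loudly", {
  d <- tibble::tibble(t = 0:9 / 10, rate_Ia = 1, rate_II = 1)
  expect_error(demix_spindle(d, matrix(c(1, 2, 2, 4), 2)), "singular")
  expect_error(gain_matrix(100, 10, 100, 10), "singular")
  expect_error(demix_spindle(d, matrix(1:6, 2)), "2 x 2")
  expect_error(demix_spindle(dplyr::select(d, -rate_II), gain_matrix()), "rate_II")
})

test_that("force decomposition divides by the force gains and subtracts", {
  g <- force_gains()
  d <- tibble::tibble(t = 0:9 / 10, rate_II = 182.8, rate_Ib = 128.8)
  out <- estimate_forces(d, g)
  expect_equal(out$F_EI_est, rep(1, 10))
  expect_equal(out$F_C_est, rep(1, 10))
  expect_equal(out$F_SG_est, rep(0, 10))
  z <- estimate_forces(dplyr::mutate(d, rate_II = 0, rate_Ib = 0), g)
  expect_true(all(z$F_EI_est == 0 & z$F_C_est == 0 & z$F_SG_est == 0))
  expect_error(force_gains(kF_II = 0), "kF_II")
})

test_that("passive stretch cancels; an Ib offset appears as self-generated force", {
  # rates generated from one contractile force trace with matched gains
  tr <- one_trial(fix_forces)
  d <- tibble::tibble(t = tr$t, rate_II = 182.8 * tr$F_C, rate_Ib = 128.8 * tr$F_C)
  out <- estimate_forces(d)
  expect_lt(max(abs(out$F_SG_est)), 1e-9)
  # decomposition difference identity holds pointwise
  expect_equal(out$F_SG_est, out$F_C_est - out$F_EI_est)
  # constant Ib offset of 12.88 spikes/s -> F_SG of exactly 0.1 N
  out2 <- estimate_forces(apply_eccentric(d, 12.88))
  expect_equal(out2$F_SG_est, rep(0.1, nrow(d)), tolerance = 1e-12)
  # with 5% rate noise the residual stays under 5% of peak contractile force
  dn <- d
  dn$rate_II <- add_rate_noise(tibble::tibble(rate = d$rate_II), 0.05, seed = 11)$rate
  dn$rate_Ib <- add_rate_noise(tibble::tibble(rate = d$rate_Ib), 0.05, seed = 12)$rate
  outn <- estimate_forces(dn)
  expect_lt(sqrt(mean(outn$F_SG_est^2)), 0.05 * max(tr$F_C))
})

test_that("force estimation is linear in each rate input", {
  tr <- one_trial(fix_forces)
  d1 <- tibble::tibble(t = tr$t, rate_II = 182.8 * tr$F_C, rate_Ib = 128.8 * tr$F_C)
  d2 <- tibble::tibble(t = tr$t, rate_II = 40 + 10 * tr$t, rate_Ib = 80 * tr$F_C)
  a <- 0.3
  dsum <- tibble::tibble(t = tr$t,
                         rate_II = d1$rate_II + a * d2$rate_II,
                         rate_Ib = d1$rate_Ib + a * d2$rate_Ib)
  lhs <- estimate_forces(dsum)
  rhs1 <- estimate_forces(d1)
  rhs2 <- estimate_forces(d2)
  expect_equal(lhs$F_SG_est, rhs1$F_SG_est + a * rhs2$F_SG_est, tolerance = 1e-12)
  expect_equal(lhs$F_EI_est, rhs1$F_EI_est + a * rhs2$F_EI_est, tolerance = 1e-12)
})

test_that("the eccentric offset is local to its epoch and scales as delta/kF_Ib", {
  tr <- one_trial(fix_forces)
  d <- tibble::tibble(t = tr$t, rate_II = 182.8 * tr$F_C, rate_Ib = 128.8 * tr$F_C)
  expect_identical(apply_eccentric(d, 0), d)
  half <- c(min(d$t), stats::median(d$t))
  out <- estimate_forces(apply_eccentric(d, 6.44, epoch = half))
  inside <- d$t >= half[1] & d$t <= half[2]
  expect_equal(out$F_SG_est[inside], rep(6.44 / 128.8, sum(inside)), tolerance = 1e-9)
  expect_lt(max(abs(out$F_SG_est[!inside])), 1e-9)
  expect_error(apply_eccentric(d, 1, epoch = c(-5, 1)), "outside")
  expect_error(apply_eccentric(d, -1), "offset")
})

test_that("interneuron responses combine and rectify afferent input", {
  d <- tibble::tibble(t = 0:4 / 10, rate_Ia = 100, rate_II = 20, rate_Ib = 30)
  w <- interneuron_weights(1, 0, -1)
  expect_equal(unique(interneuron_response(d, w)$rate), 70)
  low <- dplyr::mutate(d, rate_Ia = 10, rate_Ib = 50)
  expect_equal(unique(interneuron_response(low, w)$rate), 0) # rectified
  expect_equal(unique(interneuron_response(low, interneuron_weights(1, 0, -1,
                                                                    rectify = FALSE))$rate),
               -40)
})

test_that("force-gain weighted interneuron input reproduces -F_SG", {
  tr <- one_trial(fix_forces)
  d <- tibble::tibble(t = tr$t, rate_Ia = 337.8 * tr$F_C,
                      rate_II = 182.8 * tr$F_C,
                      rate_Ib = 128.8 * tr$F_C + 12.88)
  w <- interneuron_weights(0, 1 / 182.8, -1 / 128.8, rectify = FALSE)
  r <- interneuron_response(d, w)
  fsg <- estimate_forces(d)$F_SG_est
  expect_equal(r$rate, -fsg, tolerance = 1e-12)
})

test_that("yank-driven interneurons respond to stretch onset, not the hold", {
  # Ia excitation / Ib inhibition: a startle-like response that leads the
  # ramp and is suppressed during the hold, at every protocol velocity
  w <- interneuron_weights(1, 0, -1)
  wide <- fix_rates |>
    tidyr::pivot_wider(names_from = afferent_class, values_from = rate,
                       names_prefix = "rate_")
  for (df in dplyr::group_split(wide, trial_id)) {
    r <- interneuron_response(df, w)
    forces <- dplyr::filter(fix_forces, trial_id == df$trial_id[1])
    ramp <- forces$v > 0
    hold <- forces$v == 0 & forces$L_MTU > 2.99
    hold_core <- hold & forces$t > min(forces$t[hold]) + 0.1
    expect_gt(max(r$rate[ramp]), max(r$rate[hold_core]))
    expect_lt(which.max(r$rate), min(which(hold_core)))
  }
})
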