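# amplitude of a sinusoid estimated away from the ends
mid_amp <- function(x, frac = 0.25) {
  n <- length(x)
  max(abs(x[round(n * frac):round(n * (1 - frac))]))
}

test_that("downsampling decimates rate and length with anti-aliasing", {
  fs <- 17800
  t <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  y <- downsample_signal(x, factor = 10, fs = fs)
  expect_equal(length(y), ceiling(length(x) / 10))
  expect_equal(mid_amp(y), 1, tolerance = 1e-3) # 20 Hz survives 1.78 kHz
  expect_identical(downsample_signal(x, 1, fs), x)
  expect_lt(max(abs(downsample_signal(rep(2.5, 5000), 10, fs) - 2.5)), 1e-6)
  expect_error(downsample_signal(x, 0, fs), "factor")
})

test_that("zero-phase Butterworth preserves DC and the passband, kills the stopband", {
  fs <- 1780
  t <- seq(0, 2, by = 1 / fs)
  expect_lt(max(abs(lowpass_filter(rep(3, 1000), fs) - 3)), 1e-9)
  s10 <- lowpass_filter(sin(2 * pi * 10 * t), fs)
  expect_gt(mid_amp(s10), 0.99) # < 1% attenuation at 10 Hz
  s400 <- lowpass_filter(sin(2 * pi * 400 * t), fs)
  expect_lt(mid_amp(s400), 0.01) # > 99% attenuation at 400 Hz
  expect_error(lowpass_filter(t, fs, cutoff = 1000), "Nyquist")
})

test_that("lowpass leaves already-band-limited signals essentially unchanged", {
  fs <- 1780
  t <- seq(0, 2, by = 1 / fs)
  x <- 1 + 0.5 * sin(2 * pi * 5 * t) + 0.2 * cos(2 * pi * 12 * t)
  y <- lowpass_filter(x, fs)
  expect_lt(sqrt(mean((y - x)^2)) / sqrt(mean(x^2)), 0.01)
})

test_that("Savitzky-Golay derivative is exact on low-order polynomials", {
  fs <- 1780
  t <- seq(0, 1, by = 1 / fs)
  interior <- 51:(length(t) - 51)
  d_ramp <- sg_derivative(15 * t, fs)
  expect_lt(max(abs(d_ramp[interior] - 15)), 1e-9)
  expect_lt(max(abs(sg_derivative(rep(4, 500), fs))), 1e-9)
  d_quad <- sg_derivative(t^2, fs)
  expect_lt(max(abs(d_quad[interior] - 2 * t[interior])), 1e-9)
  expect_error(sg_derivative(t[1:20], fs, window = 51), "longer")
  expect_error(sg_derivative(t, fs, window = 50), "odd")
})

test_that("the 51-sample derivative window spans ~29 ms at 1.78 kHz", {
  spec <- filter_spec()
  expect_equal(spec$sg_window / 1780 * 1000, 29, tolerance = 0.02)
})

test_that("instantaneous firing rate follows the 1/ISI convention", {
  ifr <- spikes_to_ifr(tibble::tibble(spike_time = c(0.1, 0.2, 0.3)))
  expect_equal(ifr$t, c(0.2, 0.3))
  expect_equal(ifr$rate, c(10, 10))
  expect_warning(out <- spikes_to_ifr(tibble::tibble(spike_time = 0.5)), "fewer than 2")
  expect_equal(nrow(out), 0L)
  # geometric ISI halving doubles the rate sample by sample
  st <- cumsum(c(0, 0.4, 0.2, 0.1, 0.05))
  ifr <- spikes_to_ifr(tibble::tibble(spike_time = st))
  expect_equal(ifr$rate, 2.5 * 2^(0:3))
})

test_that("IFR interpolation is linear, anchored and end-held", {
  s <- tibble::tibble(t = c(0, 0.1), rate = c(0, 10))
  tr <- interpolate_ifr(s, t_end = 0.2)
  expect_equal(tr$rate[tr$t == 0.05], 5)      # linear midpoint
  expect_equal(tr$rate[tr$t == 0.1], 10)      # on-grid sample preserved
  expect_equal(tr$rate[tr$t > 0.1], rep(10, sum(tr$t > 0.1))) # held after last
  expect_equal(diff(tr$t), rep(1e-3, nrow(tr) - 1))
  # background firing initialises the trace at the pre-stretch rate
  s2 <- tibble::tibble(t = c(0.3, 0.4), rate = c(20, 30))
  bg <- interpolate_ifr(s2, t_end = 0.5, background_rate = 12, origin = 0.25)
  expect_equal(bg$rate[1], 12)
  expect_equal(bg$t[1], 0.25)
  # non-negative inputs give non-negative output (convexity of linear interp)
  s3 <- tibble::tibble(t = sort(runif(20)), rate = runif(20, 0, 50))
  expect_true(all(interpolate_ifr(s3, t_end = 1.2)$rate >= 0))
  expect_warning(z <- interpolate_ifr(tibble::tibble(t = numeric(0), rate = numeric(0)),
                                      t_end = 0.1), "empty")
  expect_true(all(z$rate == 0))
})

test_that("velocity alignment groups classes on one truncated grid", {
  grid1 <- tibble::tibble(t = seq(0.2, 1.2, by = 1e-3))
  mk <- function(cl, v, n_extra = 0) {
    tibble::tibble(afferent_class = cl, velocity_label = v,
                   t = seq(0.2, 1.2 + n_extra * 1e-3, by = 1e-3)) |>
      dplyr::mutate(rate = 100 + t)
  }
  traces <- dplyr::bind_rows(lapply(c(15, 17.1, 20, 24, 30), function(v) {
    dplyr::bind_rows(mk("Ia", v, 5), mk("II", v), mk("Ib", v, 2))
  }))
  al <- align_by_velocity(traces)
  expect_equal(dplyr::n_distinct(al$velocity_label), 5L)
  expect_true(all(al$complete))
  # truncated to the shortest member, time re-referenced to the group origin
  cnt <- dplyr::count(al, velocity_label)
  expect_equal(unique(cnt$n), nrow(grid1))
  expect_equal(min(al$t), 0)
  # a missing class flags the group incomplete
  traces2 <- dplyr::filter(traces, !(velocity_label == 20 & afferent_class == "Ib"))
  al2 <- align_by_velocity(traces2)
  expect_equal(sum(!dplyr::distinct(al2, velocity_label, complete)$complete), 1L)
  expect_true(all(is.na(al2$rate_Ib[al2$velocity_label == 20])))
})

test_that("trace resampling holds end values and passes through nodes", {
  d <- tibble::tibble(t = c(0, 1, 2), F_C = c(0, 1, 0))
  out <- resample_to_grid(d, c(-1, 0.5, 1, 3), "F_C")
  expect_equal(out$F_C, c(0, 0.5, 1, 0))
})
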