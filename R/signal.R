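#' Signal-processing specification
#'
#' Bundles the processing constants applied to mechanical traces and firing
#' rates: decimation of the raw 17.8 kHz recordings to 1.78 kHz, zero-phase
#' low-pass Butterworth filtering (4th order, 100 Hz cut-off), and
#' Savitzky-Golay differentiation (2nd order polynomial, 51-sample window,
#' about 29 ms at 1.78 kHz).
#'
#' @param butterworth_order Butterworth filter order (per pass; the filter is
#'   applied forward and backward, so the effective magnitude response is
#'   squared).
#' @param cutoff Low-pass cut-off frequency in Hz.
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param sg_window Savitzky-Golay window width in samples; must be odd and
#'   greater than `sg_polyorder`.
#' @param decimation_factor Integer decimation factor from the raw recording
#'   rate.
#' @return An object of class `filter_spec`.
#' @export
#' @examples
#' filter_spec()
filter_spec <- function(butterworth_order = 4,
                        cutoff = 100,
                        sg_polyorder = 2,
                        sg_window = 51,
                        decimation_factor = 10) {
  check_number(butterworth_order, "butterworth_order", 1)
  check_number(cutoff, "cutoff", 0, strict = TRUE)
  check_number(sg_polyorder, "sg_polyorder", 0)
  check_number(sg_window, "sg_window", 1)
  check_number(decimation_factor, "decimation_factor", 1)
  if (sg_window %% 2 == 0) stop_("`sg_window` must be odd")
  if (sg_window <= sg_polyorder) stop_("`sg_window` must exceed `sg_polyorder`")
  structure(
    list(butterworth_order = butterworth_order, cutoff = cutoff,
         sg_polyorder = sg_polyorder, sg_window = sg_window,
         decimation_factor = as.integer(decimation_factor)),
    class = "filter_spec"
  )
}

# zero-phase IIR filtering with odd-reflection end padding. signal::filtfilt
# leaves large end transients (it pads with zeros), so the forward-backward
# pass is done here with the signal continued by point reflection at both
# ends. The pad must outlast the filter transient, so its length is set from
# the slowest pole: r^padlen < 1e-12.
zero_phase <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) {
    r <- max(abs(polyroot(rev(a))))
    padlen <- if (r < 1) ceiling(log(1e-12) / log(r)) else 10L * n
    padlen <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), padlen))
  }
  if (padlen < 1L) stop_("signal too short to filter")
  xp <- c(2 * x[1] - rev(x[2:(padlen + 1L)]),
          x,
          2 * x[n] - rev(x[(n - padlen):(n - 1L)]))
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies a Butterworth low-pass filter forward and backward (zero phase, DC
#' gain exactly 1), so filtered mechanics stay time-aligned with firing
#' rates. End effects are controlled by odd-reflection padding.
#'
#' @param x Numeric signal on a uniform grid.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cut-off frequency in Hz; must be below the Nyquist frequency
#'   `fs/2`.
#' @param order Filter order per pass.
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 1, by = 1 / 1780))
#' y <- lowpass_filter(x, fs = 1780)
lowpass_filter <- function(x, fs, cutoff = 100, order = 4) {
  check_number(fs, "fs", 0, strict = TRUE)
  check_number(cutoff, "cutoff", 0, strict = TRUE)
  if (cutoff >= fs / 2) stop_("`cutoff` (%g Hz) must be below Nyquist (%g Hz)", cutoff, fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  zero_phase(bf$b, bf$a, x)
}

#' Savitzky-Golay derivative
#'
#' First time-derivative of a uniformly sampled signal by local polynomial
#' (Savitzky-Golay) fitting, in signal units per second. Exact (to numerical
#' precision) for polynomials up to the fit order in window interiors; window
#' edges are handled by the fitted end polynomials.
#'
#' @param x Numeric signal on a uniform grid.
#' @param fs Sampling rate in Hz.
#' @param window Window width in samples (odd, > `polyorder`, <= length of
#'   `x`).
#' @param polyorder Polynomial order of the local fit.
#' @return `dx/dt`, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 1780)
#' d <- sg_derivative(15 * t, fs = 1780) # ~15 everywhere
sg_derivative <- function(x, fs, window = 51, polyorder = 2) {
  check_number(fs, "fs", 0, strict = TRUE)
  if (window %% 2 == 0) stop_("`window` must be odd")
  if (window <= polyorder) stop_("`window` must exceed `polyorder`")
  if (window > length(x)) stop_("`window` (%d) longer than signal (%d)", window, length(x))
  signal::sgolayfilt(x, p = polyorder, n = window, m = 1, ts = 1 / fs)
}

#' Downsample a signal with anti-alias filtering
#'
#' Low-pass filters at 80% of the post-decimation Nyquist frequency
#' (zero-phase Butterworth) and keeps every `factor`-th sample starting from
#' the first, so a 17.8 kHz recording decimated by 10 lands on a 1.78 kHz
#' grid of length `ceiling(n / factor)`. `factor = 1` returns the input
#' unchanged.
#'
#' @param x Numeric signal on a uniform grid.
#' @param factor Integer decimation factor (>= 1).
#' @param fs Input sampling rate in Hz.
#' @param order Anti-alias filter order.
#' @return Decimated signal of length `ceiling(length(x) / factor)`.
#' @export
downsample_signal <- function(x, factor, fs, order = 8) {
  check_number(factor, "factor", 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  cutoff <- 0.8 * (fs / factor) / 2
  y <- lowpass_filter(x, fs = fs, cutoff = cutoff, order = order)
  y[seq(1L, length(y), by = factor)]
}

#' Instantaneous firing rate from spike times
#'
#' Converts spike trains to event-indexed instantaneous firing rate (IFR)
#' samples: at each spike after the first, the rate is the reciprocal of the
#' preceding interspike interval, timestamped at the later spike (the instant
#' the value becomes known).
#'
#' @param spikes Tibble with `spike_time` (s) plus optional trace keys;
#'   processed per trace.
#' @return A tibble with trace keys, `t` and `rate` (spikes/s). Traces with
#'   fewer than two spikes yield no samples, with a warning.
#' @export
#' @examples
#' spikes_to_ifr(tibble::tibble(spike_time = c(0.1, 0.2, 0.3)))
spikes_to_ifr <- function(spikes) {
  check_cols(spikes, "spike_time")
  keys <- intersect(TRACE_KEYS, names(spikes))
  short <- FALSE
  out <- spikes %>%
    group_by(across(all_of(keys))) %>%
    group_modify(function(df, key) {
      st <- sort(df$spike_time)
      if (length(st) < 2L) {
        short <<- TRUE
        return(tibble(t = numeric(0), rate = numeric(0)))
      }
      isi <- diff(st)
      tibble(t = st[-1], rate = 1 / isi)
    }) %>%
    ungroup()
  if (short) warn_("trace(s) with fewer than 2 spikes yield no IFR samples")
  out
}

#' Interpolate IFR samples onto a uniform grid
#'
#' Linearly interpolates event-indexed IFR samples onto a uniform grid
#' (1 kHz by default) for linear combination across afferents. Per trace, the
#' grid starts at the first IFR event (typically tied to the first spike
#' after stretch onset) unless an explicit `origin` is given; the trace is
#' anchored at the origin at zero, or at `background_rate` when the afferent
#' fires at rest; values after the final sample are held constant.
#'
#' @param samples IFR tibble from [spikes_to_ifr()] (columns `t`, `rate`,
#'   plus trace keys).
#' @param t_end End of the analysis window in seconds (required).
#' @param grid_rate Output grid rate in Hz.
#' @param background_rate Pre-stretch firing rate in spikes/s, or `NULL` for
#'   a silent-at-rest afferent (trace starts at zero).
#' @param origin Grid origin in seconds, or `NULL` to use each trace's first
#'   sample time.
#' @return Rate tibble with trace keys, uniform `t` and `rate >= 0`. Empty
#'   traces give an all-zero trace over `[origin, t_end]`, with a warning
#'   (origin falls back to 0 when unknown).
#' @export
interpolate_ifr <- function(samples, t_end, grid_rate = 1000,
                            background_rate = NULL, origin = NULL) {
  check_cols(samples, c("t", "rate"))
  check_number(t_end, "t_end")
  check_number(grid_rate, "grid_rate", 0, strict = TRUE)
  if (!is.null(background_rate)) check_number(background_rate, "background_rate", 0)
  init <- background_rate %||% 0
  keys <- intersect(TRACE_KEYS, names(samples))
  interp_one <- function(df, key) {
    if (nrow(df) == 0L) {
      warn_("empty IFR sample set; returning all-zero trace")
      t0 <- origin %||% 0
      grid <- seq(t0, t_end, by = 1 / grid_rate)
      return(tibble(t = grid, rate = 0))
    }
    df <- arrange(df, t)
    t0 <- origin %||% df$t[1]
    grid <- seq(t0, t_end, by = 1 / grid_rate)
    # anchor the trace at the origin (zero, or the pre-stretch background
    # rate) when the origin precedes the first recorded sample
    keep <- df$t > t0
    if (t0 < df$t[1]) {
      tt <- c(t0, df$t[keep])
      rr <- c(init, df$rate[keep])
    } else {
      tt <- df$t
      rr <- df$rate
    }
    if (length(tt) == 1L) return(tibble(t = grid, rate = rep(rr, length(grid))))
    tibble(t = grid, rate = approx(tt, rr, xout = grid, rule = 2)$y)
  }
  if (length(keys) == 0L) return(interp_one(samples, NULL))
  samples %>%
    group_by(across(all_of(keys))) %>%
    group_modify(interp_one) %>%
    ungroup()
}

#' Align rate traces by stretch velocity
#'
#' Groups rate traces by nominal ramp velocity (and repetition, when
#' present), re-references each trace's time to its own first sample, and
#' truncates every member of a group to the shortest trace so all afferent
#' classes in a group share one uniform grid. Groups missing an afferent
#' class are flagged incomplete.
#'
#' @param traces Long rate tibble with columns `t`, `rate`,
#'   `afferent_class`, `velocity_label` (and optionally `rep`).
#' @param classes Afferent classes expected in every group.
#' @return A wide tibble with columns `velocity_label` (and `rep`), `t`
#'   (group-relative, uniform), one `rate_<class>` column per class, and a
#'   logical `complete` column. Incomplete groups keep `NA` rate columns.
#' @export
align_by_velocity <- function(traces, classes = c("Ia", "II", "Ib")) {
  check_cols(traces, c("t", "rate", "afferent_class", "velocity_label"))
  keys <- intersect(c("velocity_label", "rep"), names(traces))
  rel <- traces %>%
    group_by(across(all_of(c(keys, "afferent_class")))) %>%
    mutate(.i = dplyr::row_number(), t = t - t[1]) %>%
    ungroup()
  rel %>%
    group_by(across(all_of(keys))) %>%
    group_modify(function(df, key) {
      present <- unique(df$afferent_class)
      n_min <- min(tapply(df$.i, df$afferent_class, max))
      wide <- df %>%
        filter(.data$.i <= n_min) %>%
        select(all_of(c("afferent_class", ".i", "rate"))) %>%
        tidyr::pivot_wider(names_from = "afferent_class", values_from = "rate",
                           names_prefix = "rate_")
      grid <- df %>% filter(.data$afferent_class == present[1], .data$.i <= n_min)
      wide$t <- grid$t
      for (cl in setdiff(classes, present)) wide[[paste0("rate_", cl)]] <- NA_real_
      wide$complete <- all(classes %in% present)
      select(wide, all_of("t"), all_of(paste0("rate_", classes)),
             all_of("complete"))
    }) %>%
    ungroup()
}

#' Resample trace columns onto a new time grid
#'
#' Linear interpolation of mechanical columns onto (e.g.) an IFR grid so
#' rates and mechanics are co-registered before fitting; values outside the
#' source span are held at the end values.
#'
#' @param data Tibble with a `t` column and the columns in `cols`.
#' @param t_out Target time grid (s).
#' @param cols Character vector of columns to resample.
#' @return Tibble with `t = t_out` and resampled columns.
#' @export
resample_to_grid <- function(data, t_out, cols) {
  check_cols(data, c("t", cols))
  out <- tibble(t = t_out)
  for (cl in cols) {
    out[[cl]] <- approx(data$t, data[[cl]], xout = t_out, rule = 2)$y
  }
  out
}
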