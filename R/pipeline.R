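#' Pipeline run configuration
#'
#' Bundles every parameter of a simulate-process-fit-demix run: the stretch
#' protocol, passive muscle mechanics, the afferent encoder set, the signal
#' processing constants, the reference velocity whose trials are averaged
#' into the gain matrix, optional multiplicative rate noise, an optional
#' eccentric Ib offset, and the seed.
#'
#' @param protocol A [stretch_protocol()].
#' @param muscle A [muscle_params()].
#' @param afferents Named list of [afferent_params()] (default
#'   [default_afferents()]).
#' @param filter A [filter_spec()].
#' @param velocity_filter Ramp velocity (mm/s) whose trials are averaged when
#'   assembling the gain matrix.
#' @param noise_cv Multiplicative rate-noise coefficient of variation (0 =
#'   noiseless).
#' @param eccentric_offset Constant Ib rate offset (spikes/s) for the
#'   eccentric-contraction scenario; 0 disables it.
#' @param seed Integer seed for every stochastic element of the run.
#' @return An object of class `demix_config`.
#' @export
demix_config <- function(protocol = stretch_protocol(),
                         muscle = muscle_params(),
                         afferents = default_afferents(),
                         filter = filter_spec(),
                         velocity_filter = 15,
                         noise_cv = 0,
                         eccentric_offset = 0,
                         seed = 1L) {
  stopifnot(inherits(protocol, "stretch_protocol"),
            inherits(muscle, "muscle_params"),
            inherits(filter, "filter_spec"))
  if (!all(vapply(afferents, inherits, logical(1), "afferent_params"))) {
    stop_("`afferents` must be a list of `afferent_params` objects")
  }
  check_number(velocity_filter, "velocity_filter", 0, strict = TRUE)
  check_number(noise_cv, "noise_cv", 0)
  check_number(eccentric_offset, "eccentric_offset", 0)
  structure(
    list(protocol = protocol, muscle = muscle, afferents = afferents,
         filter = filter, velocity_filter = velocity_filter,
         noise_cv = noise_cv, eccentric_offset = eccentric_offset,
         seed = as.integer(seed)),
    class = "demix_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' @param config A [demix_config()].
#' @param path File path.
#' @return `read_demix_config()` returns a [demix_config()];
#'   `write_demix_config()` returns `path` invisibly.
#' @export
write_demix_config <- function(config, path) {
  stopifnot(inherits(config, "demix_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' @rdname write_demix_config
#' @export
read_demix_config <- function(path) {
  raw <- yaml::read_yaml(path)
  demix_config(
    protocol = do.call(stretch_protocol, raw$protocol),
    muscle = do.call(muscle_params, raw$muscle),
    afferents = lapply(raw$afferents, function(a) do.call(afferent_params, a)),
    filter = do.call(filter_spec, raw$filter),
    velocity_filter = raw$velocity_filter,
    noise_cv = raw$noise_cv,
    eccentric_offset = raw$eccentric_offset,
    seed = raw$seed
  )
}

trial_file_stem <- function(velocity_label, rep) {
  sprintf("trial_v%s_r%d", gsub("[^0-9p.]", "", format(velocity_label)), rep)
}

#' Write / read simulated trials as CSV
#'
#' One CSV per trial with the schema `t, L_MTU, L_fasc, v, F_MTU, F_NC, F_C,
#' Y`; filenames encode velocity and repetition.
#'
#' @param forces Forces tibble from [simulate_forces()].
#' @param dir Output directory (created if missing).
#' @return `write_trials()` returns the written paths invisibly;
#'   `read_trials()` returns the combined tibble.
#' @export
write_trials <- function(forces, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cols <- c("t", "L_MTU", "L_fasc", "v", "F_MTU", "F_NC", "F_C", "Y")
  check_cols(forces, c("trial_id", "velocity_label", "rep", cols))
  paths <- forces %>%
    group_by(.data$trial_id, .data$velocity_label, .data$rep) %>%
    group_map(function(df, key) {
      p <- file.path(dir, paste0(trial_file_stem(key$velocity_label, key$rep), ".csv"))
      readr::write_csv(df[cols], p)
      p
    })
  invisible(unlist(paths))
}

#' @rdname write_trials
#' @export
read_trials <- function(dir) {
  files <- list.files(dir, pattern = "^trial_v.*\\.csv$", full.names = TRUE)
  if (length(files) == 0L) stop_("no trial CSVs found in %s", dir)
  purrr::map_dfr(files, function(f) {
    m <- regmatches(basename(f), regexec("^trial_v([0-9.]+)_r([0-9]+)\\.csv$", basename(f)))[[1]]
    readr::read_csv(f, show_col_types = FALSE) %>%
      mutate(trial_id = sprintf("v%s_r%s", m[2], m[3]),
             velocity_label = as.numeric(m[2]), rep = as.integer(m[3]),
             .before = 1)
  })
}

#' Write / read spike trains as one-column text files
#'
#' One plain-text file of spike times (s) per trace; filenames encode
#' afferent class, velocity and repetition.
#'
#' @param spikes Spike tibble from [rate_to_spikes()].
#' @param dir Output directory.
#' @return Written paths (invisibly) / combined spike tibble.
#' @export
write_spike_times <- function(spikes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  check_cols(spikes, c("afferent_class", "velocity_label", "rep", "spike_time"))
  paths <- spikes %>%
    group_by(.data$afferent_class, .data$velocity_label, .data$rep) %>%
    group_map(function(df, key) {
      p <- file.path(dir, sprintf("spikes_%s_%s.txt", key$afferent_class,
                                  sub("^trial_", "", trial_file_stem(key$velocity_label, key$rep))))
      writeLines(format(df$spike_time, digits = 12, trim = TRUE, scientific = FALSE), p)
      p
    })
  invisible(unlist(paths))
}

#' @rdname write_spike_times
#' @export
read_spike_times <- function(dir) {
  files <- list.files(dir, pattern = "^spikes_.*\\.txt$", full.names = TRUE)
  if (length(files) == 0L) stop_("no spike-time files found in %s", dir)
  purrr::map_dfr(files, function(f) {
    m <- regmatches(basename(f),
                    regexec("^spikes_(Ia|II|Ib)_v([0-9.]+)_r([0-9]+)\\.txt$", basename(f)))[[1]]
    tibble(afferent_class = m[2],
           trial_id = sprintf("v%s_r%s", m[3], m[4]),
           velocity_label = as.numeric(m[3]), rep = as.integer(m[4]),
           spike_time = as.numeric(readLines(f)))
  })
}

#' Simulate a full stretch session and write its artifacts
#'
#' Runs the synthetic-data stage of the pipeline: generates the stretch
#' trials, simulates forces, encodes the configured afferents (with optional
#' seeded rate noise), emits spike trains, and writes trial CSVs, spike-time
#' files and the resolved configuration to `dir`.
#'
#' @param config A [demix_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the `trials` (forces) tibble, `rates`,
#'   `spikes` and the written file paths.
#' @export
run_simulate <- function(config = demix_config(), dir) {
  stopifnot(inherits(config, "demix_config"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  forces <- simulate_forces(generate_trials(config$protocol), config$muscle,
                            config$filter)
  rates <- encode_afferents(forces, config$afferents)
  if (config$noise_cv > 0) rates <- add_rate_noise(rates, config$noise_cv, config$seed)
  spikes <- rate_to_spikes(rates, seed = config$seed)
  paths <- c(write_trials(forces, dir), write_spike_times(spikes, dir))
  write_demix_config(config, file.path(dir, "config.yaml"))
  message(sprintf("wrote %d trial files and %d spike files to %s",
                  n_distinct(forces$trial_id), n_distinct(spikes$trial_id) * 3, dir))
  invisible(list(trials = forces, rates = rates, spikes = spikes,
                 files = c(paths, file.path(dir, "config.yaml"))))
}

# wide (per-trial) rate table on the simulation grid
rates_wide <- function(rates) {
  rates %>%
    select(all_of(c("trial_id", "velocity_label", "rep", "afferent_class", "t", "rate"))) %>%
    tidyr::pivot_wider(names_from = "afferent_class", values_from = "rate",
                       names_prefix = "rate_")
}

#' Run the full simulate-fit-demix pipeline
#'
#' End-to-end run: simulate trials and afferent firing, fit the encoding
#' models (force/yank gain pairs per trial for Ia and II, joint
#' non-contractile + Ib gain fit at the reference velocity), assemble the
#' gain matrix, de-mix force and yank from the spindle rates, decompose
#' contractile force into externally imposed and self-generated components
#' (optionally under the eccentric Ib-offset scenario), and summarise
#' recovery of the generating gains.
#'
#' With `fit_on = "rates"` the encoder rate traces are fitted directly (the
#' noiseless validation path: recovery is exact to numerical precision).
#' With `fit_on = "ifr"` the rates are first converted to spike trains and
#' back through the instantaneous-firing-rate processing chain
#' ([rate_to_spikes()], [spikes_to_ifr()], [interpolate_ifr()]), which adds
#' spike-discretisation error.
#'
#' @param config A [demix_config()].
#' @param dir Optional output directory for CSV artifacts and the resolved
#'   config.
#' @param fit_on Fit gains on encoder `"rates"` (default) or spike-derived
#'   `"ifr"` traces.
#' @return A `demix_run` list: `config`, `forces`, `rates`, per-trial
#'   `gains`, `K_fit`, `nc_fit`, `force_gains_fit`, `demix`,
#'   `decomposition`, optional `decomposition_eccentric`, and a `report`
#'   list (gain-recovery table, cancellation metrics, conditioning, stage
#'   counts).
#' @export
run_full <- function(config = demix_config(), dir = NULL,
                     fit_on = c("rates", "ifr")) {
  stopifnot(inherits(config, "demix_config"))
  fit_on <- match.arg(fit_on)

  forces <- simulate_forces(generate_trials(config$protocol), config$muscle,
                            config$filter)
  rates <- encode_afferents(forces, config$afferents)
  if (config$noise_cv > 0) rates <- add_rate_noise(rates, config$noise_cv, config$seed)

  mech_cols <- c("L_MTU", "F_MTU", "F_NC", "F_C", "Y")
  if (fit_on == "rates") {
    fitdata <- rates %>%
      left_join(select(forces, all_of(c("trial_id", "t", mech_cols))),
                by = c("trial_id", "t"))
  } else {
    spikes <- rate_to_spikes(rates, seed = config$seed)
    ifr <- spikes_to_ifr(spikes)
    fitdata <- ifr %>%
      group_by(across(any_of(TRACE_KEYS))) %>%
      group_modify(function(df, key) {
        tr <- filter(forces, .data$trial_id == key$trial_id)
        out <- interpolate_ifr(df, t_end = max(tr$t))
        mech <- resample_to_grid(tr, out$t, mech_cols)
        dplyr::bind_cols(out, mech[mech_cols])
      }) %>%
      ungroup()
  }

  gains <- fit_gains_by_trial(fitdata)
  K_fit <- assemble_K(gains, velocity = config$velocity_filter)

  nc_data <- fitdata %>%
    filter(.data$afferent_class == "Ib",
           abs(.data$velocity_label - config$velocity_filter) <= 1e-6)
  nc_fit <- fit_noncontractile(nc_data, init = config$muscle,
                               seed = config$seed)
  force_gains_fit <- force_gains(kF_II = K_fit["II", "force"],
                                 kF_Ib = nc_fit$kF_Ib)

  wide <- rates_wide(rates)
  demix <- demix_spindle(wide, K_fit)
  decomposition <- estimate_forces(wide, force_gains_fit)
  decomposition_ecc <- NULL
  if (config$eccentric_offset > 0) {
    decomposition_ecc <- estimate_forces(
      apply_eccentric(wide, config$eccentric_offset), force_gains_fit)
  }

  true_gains <- purrr::map_dfr(config$afferents, function(a) {
    tibble(afferent_class = a$afferent_class,
           force_gain_true = a$force_gain, yank_gain_true = a$yank_gain)
  })
  recovery <- gains %>%
    filter(abs(.data$velocity_label - config$velocity_filter) <= 1e-6) %>%
    group_by(.data$afferent_class) %>%
    summarise(force_gain = mean(.data$force_gain),
              yank_gain = mean(.data$yank_gain), .groups = "drop") %>%
    left_join(true_gains, by = "afferent_class") %>%
    mutate(force_rel_err = abs(.data$force_gain - .data$force_gain_true) /
             pmax(.data$force_gain_true, 1e-12),
           yank_rel_err = ifelse(.data$yank_gain_true > 0,
                                 abs(.data$yank_gain - .data$yank_gain_true) /
                                   .data$yank_gain_true, NA_real_))

  report <- list(
    recovery = recovery,
    kF_Ib_fit = nc_fit$kF_Ib,
    cancellation = list(
      max_abs_F_SG = max(abs(decomposition$F_SG_est)),
      rms_F_SG = sqrt(mean(decomposition$F_SG_est^2)),
      peak_F_C = max(forces$F_C)
    ),
    conditioning = list(det = attr(K_fit, "det"),
                        condition_number = attr(K_fit, "condition_number")),
    counts = list(trials = n_distinct(forces$trial_id),
                  samples_per_trial = nrow(forces) / n_distinct(forces$trial_id),
                  rate_traces = nrow(dplyr::distinct(
                    rates, .data$trial_id, .data$afferent_class)))
  )

  out <- structure(
    list(config = config, forces = forces, rates = rates, gains = gains,
         K_fit = K_fit, nc_fit = nc_fit, force_gains_fit = force_gains_fit,
         demix = demix, decomposition = decomposition,
         decomposition_eccentric = decomposition_ecc, report = report),
    class = "demix_run"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_trials(forces, dir)
    readr::write_csv(gains, file.path(dir, "gains_by_trial.csv"))
    readr::write_csv(as.data.frame(unclass(K_fit)), file.path(dir, "K_matrix.csv"))
    readr::write_csv(as_tibble(demix), file.path(dir, "demix.csv"))
    readr::write_csv(as_tibble(decomposition), file.path(dir, "force_decomposition.csv"))
    if (!is.null(decomposition_ecc)) {
      readr::write_csv(as_tibble(decomposition_ecc),
                       file.path(dir, "force_decomposition_eccentric.csv"))
    }
    write_demix_config(config, file.path(dir, "config.yaml"))
  }
  out
}

#' @export
print.demix_run <- function(x, ...) {
  cat("<demix_run>\n")
  cat(sprintf("  %d trials, %d rate traces\n", x$report$counts$trials,
              x$report$counts$rate_traces))
  cat("  fitted K (averaged at", x$config$velocity_filter, "mm/s):\n")
  print(round(unclass(structure(x$K_fit, det = NULL, condition_number = NULL,
                                provenance = NULL)), 3))
  cat(sprintf("  kF_II = %.3f, kF_Ib = %.3f spikes/(N.s)\n",
              x$force_gains_fit$kF_II, x$force_gains_fit$kF_Ib))
  cat(sprintf("  passive cancellation: max|F_SG| = %.3g N, RMS = %.3g N (peak F_C %.3g N)\n",
              x$report$cancellation$max_abs_F_SG, x$report$cancellation$rms_F_SG,
              x$report$cancellation$peak_F_C))
  cat(sprintf("  conditioning: det K = %.4g, condition number = %.4g\n",
              x$report$conditioning$det, x$report$conditioning$condition_number))
  invisible(x)
}
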