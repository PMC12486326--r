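stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_("`%s` must be a single finite number", name)
  }
  if (strict && x <= lower) stop_("`%s` must be > %g", name, lower)
  if (!strict && x < lower) stop_("`%s` must be >= %g", name, lower)
  invisible(x)
}

check_cols <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop_("column(s) %s not found in `data`", paste0("`", missing, "`", collapse = ", "))
  }
  invisible(data)
}

# uniform-grid check; returns the sampling interval
grid_dt <- function(t, tol = 1e-8) {
  if (length(t) < 2L) stop_("time grid needs at least 2 samples")
  dt <- diff(t)
  if (any(dt <= 0) || max(dt) - min(dt) > tol * stats::median(dt)) {
    stop_("time grid must be uniform and strictly increasing")
  }
  stats::median(dt)
}

# grouping columns carried through per-trace operations when present
TRACE_KEYS <- c("trial_id", "velocity_label", "rep", "afferent_class")
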