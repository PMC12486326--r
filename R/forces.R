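#' Passive muscle-tendon mechanical parameters
#'
#' Parameters of the passive MTU force model used by [simulate_forces()].
#' Total MTU force is decomposed into a contractile-tissue component `F_C`
#' and a non-contractile (extramysial / extracellular-matrix) component
#' `F_NC`:
#'
#' * non-contractile: an exponential force-length curve,
#'   `F_NC(L) = a * (exp(b * (L - L0)) - 1)` for `L > L0`, zero below the
#'   rest length `L0`;
#' * contractile: a linear spring-dashpot, `F_C = k * L + c * v`, floored at
#'   zero (passive tissue does not push).
#'
#' @param nc_scale Exponential scale `a` in N (>= 0).
#' @param nc_rate Exponential rate `b` in 1/mm (> 0).
#' @param nc_rest_length Rest length offset `L0` in mm (length change below
#'   which the non-contractile tissue is slack).
#' @param ce_stiffness Contractile-element stiffness `k` in N/mm (>= 0).
#' @param ce_viscosity Contractile-element viscosity `c` in N.s/mm (>= 0).
#'
#' @return An object of class `muscle_params`.
#' @export
#' @examples
#' muscle_params()
muscle_params <- function(nc_scale = 0.05,
                          nc_rate = 1,
                          nc_rest_length = 0.5,
                          ce_stiffness = 0.15,
                          ce_viscosity = 0.01) {
  check_number(nc_scale, "nc_scale", 0)
  check_number(nc_rate, "nc_rate", 0, strict = TRUE)
  check_number(nc_rest_length, "nc_rest_length")
  check_number(ce_stiffness, "ce_stiffness", 0)
  check_number(ce_viscosity, "ce_viscosity", 0)
  structure(
    list(nc_scale = nc_scale, nc_rate = nc_rate, nc_rest_length = nc_rest_length,
         ce_stiffness = ce_stiffness, ce_viscosity = ce_viscosity),
    class = "muscle_params"
  )
}

#' @export
print.muscle_params <- function(x, ...) {
  cat("<muscle_params>\n")
  cat(sprintf("  non-contractile: a = %g N, b = %g /mm, L0 = %g mm\n",
              x$nc_scale, x$nc_rate, x$nc_rest_length))
  cat(sprintf("  contractile: k = %g N/mm, c = %g N.s/mm\n",
              x$ce_stiffness, x$ce_viscosity))
  invisible(x)
}

# non-contractile exponential force-length curve, slack below L0
noncontractile_force <- function(L, a, b, L0) {
  ifelse(L > L0, a * (exp(b * (L - L0)) - 1), 0)
}

#' Simulate passive MTU forces for stretch trials
#'
#' Computes, per trial, the non-contractile force `F_NC` from the exponential
#' force-length curve, the contractile force `F_C` from the linear
#' spring-dashpot (floored at zero), the total `F_MTU = F_C + F_NC`, and the
#' yank `Y = dF_C/dt` by Savitzky-Golay differentiation of the contractile
#' force.
#'
#' @param trials Trials tibble from [generate_trials()] (columns `t`, `L_MTU`,
#'   `v`, plus trial keys).
#' @param params A [muscle_params()] object.
#' @param spec A [filter_spec()]; its `sg_window`/`sg_polyorder` control the
#'   yank derivative.
#' @return The input tibble with columns `F_NC`, `F_C`, `F_MTU` (N) and `Y`
#'   (N/s) appended.
#' @export
#' @examples
#' forces <- simulate_forces(generate_trials(stretch_protocol()))
simulate_forces <- function(trials, params = muscle_params(), spec = filter_spec()) {
  check_cols(trials, c("t", "L_MTU", "v"))
  if (!inherits(params, "muscle_params")) stop_("`params` must be a `muscle_params` object")
  trials %>%
    group_by(across(any_of(TRACE_KEYS))) %>%
    group_modify(function(df, key) {
      dt <- grid_dt(df$t)
      F_NC <- noncontractile_force(df$L_MTU, params$nc_scale, params$nc_rate,
                                   params$nc_rest_length)
      F_C <- pmax(params$ce_stiffness * df$L_MTU + params$ce_viscosity * df$v, 0)
      df$F_NC <- F_NC
      df$F_C <- F_C
      df$F_MTU <- F_C + F_NC
      df$Y <- sg_derivative(F_C, fs = 1 / dt, window = spec$sg_window,
                            polyorder = spec$sg_polyorder)
      df
    }) %>%
    ungroup() %>%
    select(any_of(TRACE_KEYS), dplyr::everything())
}
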