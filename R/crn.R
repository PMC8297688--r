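#' CRN model parameter table
#'
#' Returns the full parameter set of the Courtemanche-Ramirez-Nattel (CRN)
#' human atrial cell model used by the simulator, one row per parameter, with
#' units and a source tag (`"CRN"` for published cell-model constants,
#' `"cv-param"` for the conduction-velocity-driven remodeling constants added
#' on top of it).
#'
#' @return A tibble with columns `name`, `value`, `unit`, `source`.
#' @export
#' @examples
#' crn_parameters()
crn_parameters <- function() {
  tibble::tribble(
    ~name, ~value, ~unit, ~source,
    "g_Na", 7.8, "nS/pF", "CRN",
    "g_K1", 0.09, "nS/pF", "CRN",
    "g_to", 0.1652, "nS/pF", "CRN",
    "g_Kr", 0.029411765, "nS/pF", "CRN",
    "g_Ks", 0.12941176, "nS/pF", "CRN",
    "g_CaL", 0.12375, "nS/pF", "CRN",
    "g_bCa", 0.001131, "nS/pF", "CRN",
    "g_bNa", 0.0006744375, "nS/pF", "CRN",
    "I_NaK_max", 0.59933874, "pA/pF", "CRN",
    "I_NaCa_max", 1600, "pA/pF", "CRN",
    "I_pCa_max", 0.275, "pA/pF", "CRN",
    "K_o", 5.4, "mM", "CRN",
    "Na_o", 140, "mM", "CRN",
    "Ca_o", 1.8, "mM", "CRN",
    "C_m", 100, "pF", "CRN",
    "V_cell_i", 13668, "um^3", "CRN",
    "V_up", 1109.52, "um^3", "CRN",
    "V_rel", 96.48, "um^3", "CRN",
    "k_rel", 30, "1/ms", "CRN",
    "I_up_max", 0.005, "mM/ms", "CRN",
    "K_up", 0.00092, "mM", "CRN",
    "Ca_up_max", 15, "mM", "CRN",
    "tau_tr", 180, "ms", "CRN",
    "tau_u", 8, "ms", "CRN",
    "tau_fCa", 2, "ms", "CRN",
    "cv_lo_baseline", 0.25, "m/s", "cv-param",
    "cv_lo_progressed", 0.5, "m/s", "cv-param",
    "cv_hi", 1.25, "m/s", "cv-param",
    "floor_to", 0.5, "", "cv-param",
    "floor_CaL", 0.3, "", "cv-param",
    "floor_Kur", 0.5, "", "cv-param"
  )
}

#' CV-dependent ionic remodeling law
#'
#' Electrical remodeling in slow-conducting (fibrotic) atrial tissue is
#' encoded as a reduction of the transient outward (I_to), L-type calcium
#' (I_CaL) and ultrarapid delayed rectifier (I_Kur) maximal conductances.
#' The degree of remodeling is driven by the local conduction velocity
#' through the fraction I_CV: 0 in tissue at or below `cv_lo` (fully
#' remodeled / fibrotic), 1 at or above `cv_hi` (healthy), linear in between.
#'
#' The `"baseline"` variant ramps from 0.25 to 1.25 m/s; the `"progressed"`
#' variant models more advanced disease, ramping from 0.5 to 1.25 m/s so that
#' a wider band of tissue is fully remodeled.
#'
#' @param variant `"baseline"` or `"progressed"`.
#' @return An object of class `remodeling_law`: list with `variant`,
#'   `cv_lo`, `cv_hi` (m/s), and the floor factors `floor_to`, `floor_CaL`,
#'   `floor_Kur` applied at I_CV = 0.
#' @export
#' @examples
#' law <- remodeling_law("baseline")
#' icv(c(0.2, 0.75, 1.3), law)
remodeling_law <- function(variant = c("baseline", "progressed")) {
  variant <- match.arg(variant)
  structure(
    list(
      variant = variant,
      cv_lo = if (variant == "baseline") 0.25 else 0.5,
      cv_hi = 1.25,
      floor_to = 0.5, floor_CaL = 0.3, floor_Kur = 0.5
    ),
    class = "remodeling_law"
  )
}

#' @export
print.remodeling_law <- function(x, ...) {
  cat("<remodeling_law> variant:", x$variant,
      sprintf("| I_CV ramp %.2f-%.2f m/s | floors to/CaL/Kur %.1f/%.1f/%.1f\n",
              x$cv_lo, x$cv_hi, x$floor_to, x$floor_CaL, x$floor_Kur))
  invisible(x)
}

#' Remodeling fraction I_CV from conduction velocity
#'
#' Piecewise-linear ramp: 0 for `cv <= cv_lo`, 1 for `cv >= cv_hi`,
#' `(cv - cv_lo) / (cv_hi - cv_lo)` in between.
#'
#' @param cv Conduction-velocity magnitude(s), m/s; must be nonnegative.
#' @param law A [remodeling_law()].
#' @return Numeric vector in `[0, 1]`, same length as `cv`.
#' @export
icv <- function(cv, law = remodeling_law()) {
  stopifnot(inherits(law, "remodeling_law"))
  if (any(!is.finite(cv)) || any(cv < 0)) {
    stop("`cv` must be finite and nonnegative (m/s)")
  }
  pmin(1, pmax(0, (cv - law$cv_lo) / (law$cv_hi - law$cv_lo)))
}

#' Remodeled maximal conductances
#'
#' Applies the affine remodeling laws
#' `g_X = (floor_X + I_CV * (1 - floor_X)) * g_X_bar` for X in
#' {to, CaL, Kur}, with the CRN published values as reference conductances.
#'
#' @inheritParams icv
#' @return A tibble with columns `cv`, `icv`, `g_to`, `g_CaL`, `g_Kur`
#'   (nS/pF) and the scale factors `s_to`, `s_CaL`, `s_Kur`.
#' @export
#' @examples
#' remodeled_conductances(c(0.2, 0.75, 1.3))
remodeled_conductances <- function(cv, law = remodeling_law()) {
  f <- icv(cv, law)
  pars <- crn_parameters()
  g_bar <- function(nm) pars$value[pars$name == nm]
  s_to <- law$floor_to + f * (1 - law$floor_to)
  s_CaL <- law$floor_CaL + f * (1 - law$floor_CaL)
  s_Kur <- law$floor_Kur + f * (1 - law$floor_Kur)
  tibble::tibble(
    cv = cv, icv = f,
    s_to = s_to, s_CaL = s_CaL, s_Kur = s_Kur,
    g_to = s_to * g_bar("g_to"),
    g_CaL = s_CaL * g_bar("g_CaL"),
    # g_Kur is voltage dependent in CRN; the scale multiplies the whole
    # expression, reported here against its 0.05 nS/pF amplitude
    g_Kur = s_Kur * 0.05
  )
}

#' CRN resting state
#'
#' Published CRN initial condition: transmembrane potential, 15 gating
#' variables and 5 intracellular concentrations.
#'
#' @return A list with `v` (mV), `gates` (named numeric, length 15) and
#'   `conc` (named numeric, length 5, mM).
#' @export
crn_initial_state <- function() {
  s <- crn_initial_state_cpp()
  names(s$gates) <- crn_gate_names()
  names(s$conc) <- crn_conc_names()
  s
}

crn_gate_names <- function() {
  c("m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
    "d", "f", "f_Ca", "u", "v", "w")
}

crn_conc_names <- function() {
  c("Na_i", "K_i", "Ca_i", "Ca_up", "Ca_rel")
}

#' CRN right-hand side
#'
#' Evaluates the total ionic current and the state derivatives of the CRN
#' model at a given transmembrane potential and state, optionally with
#' remodeled conductance scales.
#'
#' @param v Transmembrane potential, mV.
#' @param gates Numeric vector of the 15 gating variables, in `[0, 1]`.
#' @param conc Numeric vector of the 5 concentrations, mM, positive.
#' @param scales Length-3 numeric: multiplicative scales on
#'   (g_to, g_CaL, g_Kur); defaults to no remodeling.
#' @return A list with `iion` (pA/pF), `dgates` (1/ms), `dconc` (mM/ms) and
#'   a tibble `currents` with the per-current breakdown (pA/pF; SR fluxes in
#'   mM/ms).
#' @export
crn_rhs <- function(v, gates, conc, scales = c(1, 1, 1)) {
  stopifnot(length(gates) == 15, length(conc) == 5, length(scales) == 3)
  if (any(gates < 0) || any(gates > 1)) stop("gates must lie in [0, 1]")
  if (any(conc <= 0)) stop("concentrations must be positive")
  r <- crn_rhs_cpp(v, as.numeric(gates), as.numeric(conc), as.numeric(scales))
  names(r$dgates) <- crn_gate_names()
  names(r$dconc) <- crn_conc_names()
  r$currents <- tibble::tibble(current = names(r$currents),
                               value = as.numeric(r$currents))
  r
}

#' Pace a single CRN cell
#'
#' Integrates the CRN model under periodic rectangular stimulation with the
#' same segregated BDF scheme as the tissue solver, and reports the trace
#' together with last-beat action-potential metrics.
#'
#' @param cycle_length_ms Pacing cycle length, ms (must exceed
#'   `stim_dur_ms`).
#' @param n_beats Number of pacing cycles.
#' @param stim_amp Stimulus amplitude, pA/pF (equivalently mV/ms); default 20
#'   corresponds to the tissue amplitude of 200 1/s on the normalized
#'   potential scaled by the 100 mV span.
#' @param stim_dur_ms Stimulus duration, ms.
#' @param dt_ms Time step, ms; 0.005 is used for reference-quality runs.
#' @param scales Length-3 remodeling scales on (g_to, g_CaL, g_Kur), e.g.
#'   from [remodeled_conductances()].
#' @param bdf_order BDF order 1-3.
#' @param init Optional initial state as returned by [crn_initial_state()].
#' @param record_currents Record the per-current breakdown along the trace.
#' @return An object of class `crn_pacing`: list with `trace` (tibble
#'   `t_ms`, `v_mv`), `apd90_ms` (last beat; `NA` if no AP was elicited),
#'   `v_rest_mv`, `v_max_mv`, `captured` (logical), the final `state`, and
#'   the call parameters.
#' @export
#' @examples
#' \donttest{
#' p <- cell_pace(1000, 2, dt_ms = 0.02)
#' p$apd90_ms
#' }
cell_pace <- function(cycle_length_ms, n_beats = 1, stim_amp = 20,
                      stim_dur_ms = 2, dt_ms = 0.02, scales = c(1, 1, 1),
                      bdf_order = 3, init = NULL, record_currents = FALSE) {
  stopifnot(cycle_length_ms > stim_dur_ms, n_beats >= 1, dt_ms > 0,
            bdf_order %in% 1:3)
  iv <- numeric(0); ig <- numeric(0); ic <- numeric(0)
  if (!is.null(init)) {
    iv <- init$v; ig <- as.numeric(init$gates); ic <- as.numeric(init$conc)
  }
  raw <- cell_pace_cpp(cycle_length_ms, as.integer(n_beats), stim_amp,
                       stim_dur_ms, dt_ms, as.numeric(scales),
                       as.integer(bdf_order), iv, ig, ic, record_currents)
  trace <- tibble::tibble(t_ms = raw$t_ms, v_mv = raw$v_mv)
  if (record_currents) {
    cur <- raw$currents
    colnames(cur) <- c("I_Na", "I_K1", "I_to", "I_Kur", "I_Kr", "I_Ks",
                       "I_CaL", "I_pCa", "I_NaK", "I_NaCa", "I_bNa", "I_bCa")
    trace <- dplyr::bind_cols(trace, tibble::as_tibble(cur))
  }
  m <- ap_metrics(raw$t_ms, raw$v_mv,
                  t0 = (n_beats - 1) * cycle_length_ms,
                  t1 = n_beats * cycle_length_ms)
  state <- list(v = raw$v_mv[length(raw$v_mv)], gates = raw$gates,
                conc = raw$conc)
  names(state$gates) <- crn_gate_names()
  names(state$conc) <- crn_conc_names()
  structure(
    list(trace = trace, apd90_ms = m$apd90, v_rest_mv = m$v_rest,
         v_max_mv = m$v_max, captured = m$captured, state = state,
         cycle_length_ms = cycle_length_ms, n_beats = n_beats,
         dt_ms = dt_ms, scales = scales),
    class = "crn_pacing"
  )
}

# last-beat AP metrics; APD90 measured from max dV/dt to 90% repolarization
ap_metrics <- function(t, v, t0, t1) {
  i <- t >= t0 & t <= t1
  tb <- t[i]; vb <- v[i]
  v_rest <- vb[1]
  v_max <- max(vb)
  captured <- (v_max - v_rest) > 50 && v_max > -20
  if (!captured) {
    return(list(apd90 = NA_real_, v_rest = v_rest, v_max = v_max,
                captured = FALSE))
  }
  dv <- diff(vb) / diff(tb)
  i_up <- which.max(dv)
  t_up <- tb[i_up]
  v90 <- v_max - 0.9 * (v_max - v_rest)
  post <- which(tb > t_up & vb <= v90)
  apd <- if (length(post) == 0) NA_real_ else tb[post[1]] - t_up
  list(apd90 = apd, v_rest = v_rest, v_max = v_max, captured = TRUE)
}

#' @export
print.crn_pacing <- function(x, ...) {
  cat(sprintf(
    "<crn_pacing> CL %g ms x %d beats (dt %g ms)\n", x$cycle_length_ms,
    x$n_beats, x$dt_ms))
  if (x$captured) {
    cat(sprintf("  APD90 %.1f ms | rest %.1f mV | peak %.1f mV\n",
                x$apd90_ms, x$v_rest_mv, x$v_max_mv))
  } else {
    cat("  no action potential elicited (subthreshold stimulus)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy crn_pacing
#' @export
tidy.crn_pacing <- function(x, ...) x$trace

#' @method glance crn_pacing
#' @export
glance.crn_pacing <- function(x, ...) {
  tibble::tibble(apd90_ms = x$apd90_ms, v_rest_mv = x$v_rest_mv,
                 v_max_mv = x$v_max_mv, captured = x$captured,
                 cycle_length_ms = x$cycle_length_ms, n_beats = x$n_beats,
                 dt_ms = x$dt_ms)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot crn_pacing
#' @export
autoplot.crn_pacing <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$t_ms, y = .data$v_mv)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "V (mV)",
                  title = sprintf("CRN cell, CL %g ms", object$cycle_length_ms))
}

#' Normalize / denormalize the transmembrane potential
#'
#' The tissue model is driven in physical CRN units (mV); the normalized
#' potential `u = (V - V_min) / (V_max - V_min)` with V_min = -84 mV and
#' V_max = +16 mV (100 mV span) is offered for I/O and analysis.
#'
#' @param v_mv Potential in mV.
#' @param u Normalized potential.
#' @return The converted values.
#' @export
normalize_potential <- function(v_mv) (v_mv - (-84)) / 100

#' @rdname normalize_potential
#' @export
denormalize_potential <- function(u) u * 100 - 84
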