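# shared helpers: independent reference integrations and small constructors

# deSolve reference integration of the CRN equations (adaptive LSODA,
# tight tolerances) driven by the package's right-hand side; used as the
# independent integration route against the package's BDF integrator.
crn_reference_trace <- function(t_end_ms, stim_fn = function(t) 0,
                                scales = c(1, 1, 1), init = NULL,
                                dt_out = 0.5) {
  skip_if_not_installed("deSolve")
  s0 <- init %||% crn_initial_state()
  y0 <- c(v = s0$v, s0$gates, s0$conc)
  rhs <- function(t, y, parms) {
    r <- crn_rhs_bare(y[1], y[2:16], y[17:21], scales)
    list(c(-r$iion + stim_fn(t), r$dgates, r$dconc))
  }
  out <- deSolve::lsoda(y0, seq(0, t_end_ms, by = dt_out), rhs, NULL,
                        rtol = 1e-8, atol = 1e-10)
  tibble::tibble(t_ms = out[, 1], v_mv = out[, 2])
}

# unvalidated RHS access (deSolve may step slightly outside [0,1])
crn_rhs_bare <- function(v, gates, conc, scales = c(1, 1, 1)) {
  gates <- pmin(1, pmax(0, as.numeric(gates)))
  conc <- pmax(1e-10, as.numeric(conc))
  r <- atrialcv:::crn_rhs_cpp(v, gates, conc, as.numeric(scales))
  r
}

apd90_of <- function(t, v, t0, t1) {
  atrialcv:::ap_metrics(t, v, t0, t1)$apd90
}

# uniform-substrate strip for planar-wave tests
strip_substrate <- function(cv = 0.7, h = 0.33, lx = 30, ly = 6,
                            preset = "baseline",
                            law = remodeling_law("baseline")) {
  m <- gen_sheet_mesh(round(lx / h) * h, round(ly / h) * h, h)
  build_substrate(m, rep(cv, nrow(m$nodes)),
                  coefficients = conductivity_presets(preset), law = law)
}

planar_protocol <- function(width_mm = 2) {
  protocol(impulse("slab", size_mm = width_mm, amplitude_per_s = 200,
                   duration_ms = 5), label = "planar")
}

# minimal simulation_result carrying constructed frames (for analysis tests)
fake_result <- function(mesh, frames, frame_t_ms) {
  structure(list(
    activation = tibble::tibble(node = mesh$nodes$node,
                                x_mm = mesh$nodes$x_mm,
                                y_mm = mesh$nodes$y_mm,
                                at_ms = NA_real_, max_slope = 0),
    frames = frames, frame_t_ms = frame_t_ms, mesh = mesh,
    diverged = FALSE, config = solver_config(t_end_ms = max(frame_t_ms)),
    config_hash = "fake"), class = "simulation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
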