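#' Space-time convergence study of the sinus-rhythm activation map
#'
#' Runs the sinus-rhythm protocol (three 6 mm spherical impulses, amplitude
#' 200 1/s, 5 ms, onset delays 0/10/20 ms) on a synthetic CV substrate at a
#' ladder of space/time resolutions, computes the max-slope activation map
#' of each run over the activation window, and reports the L1 relative
#' error of every level against the finest one.
#'
#' The CV field is generated once on a fixture mesh (h = 0.5 mm) and
#' transferred to each ladder mesh by bilinear interpolation, so all levels
#' discretize the same continuous substrate. The default domain is the
#' 5 x 5 cm paroxysmal-like sheet.
#'
#' @param spec A [cv_field_spec()] for the substrate (default paroxysmal).
#' @param lx_mm Sheet side, mm (default 50).
#' @param seed Seed for the CV field.
#' @param levels A data frame with columns `h_mm`, `dt_ms`; the last row is
#'   the reference. Defaults to the
#'   (0.65, 0.1), (0.65, 0.05), (0.33, 0.1), (0.33, 0.05), (0.17, 0.025)
#'   ladder.
#' @param t_end_ms Activation window length (default 200 ms).
#' @param law,coefficients Remodeling law and conductivity preset.
#' @return A tibble `h_mm`, `dt_ms`, `err` (`NA` for the reference row),
#'   `n_nodes`, `runtime_s`.
#' @export
sinus_rhythm_convergence <- function(spec = cv_field_spec("paroxysmal"),
                                     lx_mm = 50, seed = 1,
                                     levels = NULL, t_end_ms = 200,
                                     law = remodeling_law("baseline"),
                                     coefficients =
                                       conductivity_presets("baseline")) {
  levels <- levels %||% data.frame(
    h_mm = c(0.65, 0.65, 0.33, 0.33, 0.17),
    dt_ms = c(0.1, 0.05, 0.1, 0.05, 0.025))
  lx <- lx_mm
  fx_mesh <- gen_sheet_mesh(lx, lx, 0.5)
  fx_cv <- gen_cv_field(fx_mesh, spec, seed = seed)

  runs <- purrr::pmap(levels, function(h_mm, dt_ms) {
    n_el <- round(lx / h_mm)
    mesh <- gen_sheet_mesh(lx, lx, lx / n_el)
    cv <- interp_nodal(fx_mesh, fx_cv$cv, mesh$nodes$x_mm, mesh$nodes$y_mm)
    sub <- build_substrate(mesh, cv, coefficients = coefficients, law = law)
    pr <- baseline_preset(mesh, variant = "persistent")  # r_p = 6 mm
    cfg <- solver_config(dt_ms = dt_ms, t_end_ms = t_end_ms,
                         at_window_ms = c(0, t_end_ms))
    t0 <- Sys.time()
    res <- run_monodomain(sub, pr, cfg)
    list(map = activation_map(res), mesh = mesh,
         runtime = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  })
  ref <- runs[[length(runs)]]
  errs <- purrr::map_dbl(runs[-length(runs)], function(r) {
    as.numeric(relative_error(r$map, ref$map, r$mesh, ref$mesh))
  })
  tibble::tibble(
    h_mm = levels$h_mm, dt_ms = levels$dt_ms,
    err = c(errs, NA_real_),
    n_nodes = purrr::map_int(runs, ~ nrow(.x$mesh$nodes)),
    runtime_s = purrr::map_dbl(runs, "runtime")
  )
}

#' Planar-wave speed calibration
#'
#' Measures the propagation speed of a planar wavefront on a uniform strip
#' for each prescribed conduction velocity, with the CV-squared
#' conductivity law. With the printed longitudinal coefficient the measured
#' speed tracks the prescribed CV (speed proportional to CV since
#' conductivity scales with CV squared).
#'
#' @param cv_star Prescribed CVs, m/s.
#' @param h_mm,dt_ms Discretization.
#' @param C_l Longitudinal coefficient, s.
#' @param t_end_ms Simulation length per run.
#' @return A tibble `cv_star`, `speed` (m/s), `ratio` (= speed / cv_star).
#' @export
speed_calibration <- function(cv_star = c(0.4, 0.7, 1.0), h_mm = 0.33,
                              dt_ms = 0.05, C_l = 3.0e-4,
                              t_end_ms = 100) {
  speeds <- purrr::map_dbl(cv_star, function(cv) {
    lx <- round(30 / h_mm) * h_mm
    ly <- round(6 / h_mm) * h_mm
    mesh <- gen_sheet_mesh(lx, ly, h_mm)
    sub <- build_substrate(mesh, rep(cv, nrow(mesh$nodes)),
                           coefficients = list(preset = "custom", C_l = C_l,
                                               C_tn = 0.16 * C_l))
    cfg <- solver_config(dt_ms = dt_ms, t_end_ms = t_end_ms)
    res <- run_monodomain(sub, protocol(
      impulse("slab", size_mm = 2, amplitude_per_s = 200,
              duration_ms = 5)), cfg)
    measure_planar_speed(res)
  })
  tibble::tibble(cv_star = cv_star, speed = speeds,
                 ratio = speeds / cv_star)
}

#' Baseline-plus-trigger pacing experiment
#'
#' Applies the physiological baseline preset (1.82 Hz, three spheres at one
#' edge) together with the high-frequency pulmonary-vein-like trigger
#' (8.26 Hz, cubic, far corner) on a uniform sheet and records the
#' potential at a probe remote from the trigger; reports the probe's
#' dominant frequency.
#'
#' @param cv Uniform prescribed CV, m/s (default 0.7).
#' @param lx_mm Sheet side (default 50 mm).
#' @param h_mm,dt_ms Discretization.
#' @param t_end_ms Simulated time (default 2500 ms).
#' @param probe_mm Probe position, mm (default (10, 10): >= 3 cm from the
#'   trigger corner).
#' @param law Remodeling law.
#' @return List with `df` (the [dominant_frequency()] tibble), `result`
#'   (the simulation), `trigger_hz`, `probe_node`.
#' @export
trigger_dominance <- function(cv = 0.7, lx_mm = 50, h_mm = 50 / 77,
                              dt_ms = 0.1, t_end_ms = 2500,
                              probe_mm = c(10, 10),
                              law = remodeling_law("baseline")) {
  n_el <- round(lx_mm / h_mm)
  mesh <- gen_sheet_mesh(lx_mm, lx_mm, lx_mm / n_el)
  sub <- build_substrate(mesh, rep(cv, nrow(mesh$nodes)), law = law)
  pr <- protocol(baseline_preset(mesh), trigger_preset(mesh),
                 label = "baseline+trigger")
  probe <- nearest_node(mesh, probe_mm[1], probe_mm[2])
  cfg <- solver_config(dt_ms = dt_ms, t_end_ms = t_end_ms, probes = probe)
  res <- run_monodomain(sub, pr, cfg)
  df <- dominant_frequency(res, t_min_ms = 400)
  list(df = df, result = res, trigger_hz = 8.26, probe_node = probe)
}

#' Vulnerable-window experiment on a small sheet
#'
#' Cross-field S1-S2 protocol on a 3 x 3 cm slow, fully remodeled sheet:
#' S1 is a planar wave from the left edge, S2 a 15 mm square covering the
#' lower-left quadrant, delivered at each coupling interval. Outcomes are
#' classified early / reentry / late by [vulnerable_window_scan()].
#'
#' @param preset Conductivity preset (`"baseline"` or `"progressed"`); the
#'   cell settings (remodeling) are identical across presets so only
#'   conduction speed differs.
#' @param cis_ms Coupling intervals to scan.
#' @param cv Uniform prescribed CV, m/s (default 0.3: severe slow
#'   conduction).
#' @param h_mm,dt_ms Discretization.
#' @param t_post_ms Observation window after S2.
#' @return The [vulnerable_window_scan()] tibble (window bounds in
#'   `attr(, "window_ms")`).
#' @export
vulnerable_window_experiment <- function(preset = "baseline",
                                         cis_ms = seq(160, 320, by = 20),
                                         cv = 0.3, h_mm = 0.6, dt_ms = 0.1,
                                         t_post_ms = 600) {
  lx <- round(30 / h_mm) * h_mm
  mesh <- gen_sheet_mesh(lx, lx, h_mm)
  sub <- build_substrate(mesh, rep(cv, nrow(mesh$nodes)),
                         coefficients = conductivity_presets(preset),
                         law = remodeling_law("progressed"))
  s1 <- impulse("slab", size_mm = 2, amplitude_per_s = 200, duration_ms = 5)
  s2 <- impulse("cube", c(7.5, 7.5), 15, 200, 5)
  prs <- s1s2_preset(s1, s2, cis_ms)
  run_fn <- function(pr) {
    ci <- max(pr$delay_ms)
    run_monodomain(sub, pr,
                   solver_config(dt_ms = dt_ms, t_end_ms = ci + t_post_ms,
                                 record_stride_ms = 5))
  }
  vulnerable_window_scan(prs, run_fn)
}
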