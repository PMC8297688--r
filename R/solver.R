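#' Solver configuration
#'
#' @param dt_ms Time step, ms.
#' @param t_end_ms Final time, ms.
#' @param bdf_order BDF order, 1-3 (startup ramps 1 -> 2 -> 3).
#' @param lin_tol Relative residual tolerance of the conjugate-gradient
#'   solve.
#' @param stim_scale_mv Voltage span converting normalized-potential
#'   stimulus amplitudes (1/s) to mV/ms; default 100 mV (200 1/s -> 20
#'   mV/ms).
#' @param rush_larsen Use the exponential (Rush-Larsen) gate update instead
#'   of the BDF one.
#' @param ionic `TRUE` for the CRN model; `FALSE` runs pure diffusion
#'   (testing).
#' @param at_window_ms Length-2 window for the online activation-time
#'   argmax; defaults to the whole run.
#' @param record_stride_ms Frame recording stride, ms; 0 disables frames.
#' @param probes Integer node indices whose potential trace is recorded at
#'   every step.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(dt_ms = 0.05, t_end_ms = 200, bdf_order = 3,
                          lin_tol = 1e-8, stim_scale_mv = 100,
                          rush_larsen = FALSE, ionic = TRUE,
                          at_window_ms = NULL, record_stride_ms = 0,
                          probes = integer(0)) {
  stopifnot(dt_ms > 0, t_end_ms >= dt_ms, bdf_order %in% 1:3)
  structure(
    list(dt_ms = dt_ms, t_end_ms = t_end_ms, bdf_order = bdf_order,
         lin_tol = lin_tol, stim_scale_mv = stim_scale_mv,
         rush_larsen = rush_larsen, ionic = ionic,
         at_window_ms = at_window_ms %||% c(0, t_end_ms),
         record_stride_ms = record_stride_ms, probes = as.integer(probes)),
    class = "solver_config"
  )
}

#' BDF coefficients and extrapolation weights
#'
#' Standard backward-differentiation coefficients: the scheme advances
#' `alpha u^{n+1} - sum(history_weights * u^{n,n-1,...}) = dt f^{n+1}` with
#' matching-order extrapolation `u_ext = sum(extrapolation_weights * u^...)`.
#'
#' @param order 1, 2 or 3.
#' @return List with `alpha`, `history_weights`, `extrapolation_weights`.
#' @export
#' @examples
#' bdf_coefficients(2)
bdf_coefficients <- function(order) {
  stopifnot(order %in% 1:3)
  switch(order,
    list(alpha = 1, history_weights = 1, extrapolation_weights = 1),
    list(alpha = 3 / 2, history_weights = c(2, -1 / 2),
         extrapolation_weights = c(2, -1)),
    list(alpha = 11 / 6, history_weights = c(3, -3 / 2, 1 / 3),
         extrapolation_weights = c(3, -3, 1))
  )
}

#' Assemble the finite-element matrices
#'
#' Bilinear-quad Galerkin mass and stiffness matrices (2x2 Gauss
#' quadrature) for a substrate's element-wise diffusion tensors. Pure
#' Neumann boundary: the stiffness has the constants in its kernel; the mass
#' entries sum to the domain area.
#'
#' @param substrate A [build_substrate()] object (or a `tissue_mesh` plus
#'   explicit `Dxx`, `Dxy`, `Dyy` per element, mm^2/ms).
#' @param mesh,Dxx,Dxy,Dyy Explicit alternative to `substrate`.
#' @return List with sparse `mass` and `stiffness` (`Matrix::dgCMatrix`).
#' @export
assemble_system <- function(substrate = NULL, mesh = NULL, Dxx = NULL,
                            Dxy = NULL, Dyy = NULL) {
  if (!is.null(substrate)) {
    mesh <- substrate$mesh
    Dxx <- substrate$elem$Dxx; Dxy <- substrate$elem$Dxy
    Dyy <- substrate$elem$Dyy
  }
  coords <- as.matrix(mesh$nodes[c("x_mm", "y_mm")])
  tr <- assemble_fem_cpp(coords, mesh$elems, Dxx, Dxy, Dyy)
  n <- nrow(coords)
  list(
    mass = Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$mass,
                                dims = c(n, n)),
    stiffness = Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$stiff,
                                     dims = c(n, n))
  )
}

# protocol -> C++ inputs: per-impulse FE load vectors and timing matrix
protocol_to_cpp <- function(protocol, mesh, stim_scale_mv) {
  coords <- as.matrix(mesh$nodes[c("x_mm", "y_mm")])
  n_imp <- nrow(protocol)
  vecs <- matrix(0, nrow(coords), max(1L, n_imp))
  timing <- matrix(0, max(1L, n_imp), 5)
  for (k in seq_len(n_imp)) {
    p <- protocol[k, ]
    type <- switch(p$shape, sphere = 0L, cube = 1L, slab = 2L)
    size <- if (p$shape == "cube") p$size_mm / 2 else p$size_mm
    vecs[, k] <- stim_load_vector_cpp(coords, mesh$elems, type,
                                      p$cx_mm, p$cy_mm, size)
    amp_mv_ms <- p$amplitude_per_s * stim_scale_mv / 1000
    period <- if (p$frequency_hz > 0) 1000 / p$frequency_hz else 0
    npul <- if (is.finite(p$n_pulses)) p$n_pulses else 0  # 0 = unlimited
    timing[k, ] <- c(amp_mv_ms, p$delay_ms, p$duration_ms, period, npul)
  }
  list(vecs = vecs, timing = timing, n_imp = n_imp)
}

#' Run a monodomain simulation
#'
#' Advances the monodomain/CRN system on a tissue sheet: linear finite
#' elements in space, BDF time integration with a segregated ionic step at
#' every node (extrapolated coupling), SVI evaluation of the ionic current
#' at quadrature points, homogeneous Neumann boundary. Deterministic for
#' identical inputs.
#'
#' @param substrate A [build_substrate()] object.
#' @param protocol A [protocol()] (or `NULL` for an unstimulated run).
#' @param config A [solver_config()].
#' @param init Optional initial condition: list with per-node `v`, `gates`
#'   (n x 15), `conc` (n x 5); defaults to the CRN rest state everywhere.
#' @return An object of class `simulation_result`: list with
#'   `activation` (tibble `node`, `x_mm`, `y_mm`, `at_ms`, `max_slope`),
#'   `u_final`, `gates_final`, `conc_final`, optional `frames` (matrix
#'   nodes x frames) with `frame_t_ms`, optional `probe_traces` (tibble),
#'   `stim_log`, `diverged`, `config`, `mesh`, and a deterministic
#'   `config_hash`.
#' @export
run_monodomain <- function(substrate, protocol = NULL,
                           config = solver_config(), init = NULL) {
  stopifnot(inherits(substrate, "substrate_fields"),
            inherits(config, "solver_config"))
  mesh <- substrate$mesh
  coords <- as.matrix(mesh$nodes[c("x_mm", "y_mm")])
  n <- nrow(coords)

  scales <- as.matrix(substrate$nodal[c("s_to", "s_CaL", "s_Kur")])
  if (is.null(protocol)) {
    pc <- list(vecs = matrix(0, n, 1), timing = matrix(0, 1, 5), n_imp = 0L)
    timing <- matrix(numeric(0), 0, 5)
    vecs <- matrix(0, n, 0)
  } else {
    pc <- protocol_to_cpp(protocol, mesh, config$stim_scale_mv)
    vecs <- pc$vecs
    timing <- pc$timing
  }
  if (pc$n_imp == 0L) {
    vecs <- matrix(0, n, 1)
    timing <- matrix(c(0, 0, -1, 0, 1), 1, 5)  # never-active placeholder
  }

  n_steps <- as.integer(round(config$t_end_ms / config$dt_ms))
  stride_steps <- if (config$record_stride_ms > 0) {
    max(1L, as.integer(round(config$record_stride_ms / config$dt_ms)))
  } else 0L

  iv <- numeric(0); ig <- matrix(0, 0, 15); ic <- matrix(0, 0, 5)
  if (!is.null(init)) {
    iv <- init$v; ig <- init$gates; ic <- init$conc
    stopifnot(length(iv) == n, nrow(ig) == n, nrow(ic) == n)
  }

  raw <- run_monodomain_cpp(
    coords, mesh$elems, substrate$elem$Dxx, substrate$elem$Dxy,
    substrate$elem$Dyy, scales, config$dt_ms, n_steps,
    as.integer(config$bdf_order), vecs, timing, config$lin_tol,
    config$ionic, config$rush_larsen, config$at_window_ms, stride_steps,
    config$probes, iv, ig, ic)

  activation <- tibble::tibble(
    node = mesh$nodes$node, x_mm = mesh$nodes$x_mm, y_mm = mesh$nodes$y_mm,
    at_ms = raw$at_ms, max_slope = raw$max_slope
  )
  stim_log <- if (!is.null(protocol) && pc$n_imp > 0) {
    purrr::map_dfr(seq_len(pc$n_imp), function(k) {
      p <- protocol[k, ]
      period <- if (p$frequency_hz > 0) 1000 / p$frequency_hz else Inf
      onsets <- if (p$delay_ms > config$t_end_ms) {
        numeric(0)
      } else if (is.finite(period)) {
        seq(p$delay_ms, config$t_end_ms, by = period)
      } else p$delay_ms
      onsets <- onsets[seq_len(min(length(onsets), p$n_pulses))]
      tibble::tibble(impulse = k, shape = p$shape, onset_ms = onsets)
    })
  } else tibble::tibble(impulse = integer(0), shape = character(0),
                        onset_ms = numeric(0))

  res <- list(
    activation = activation, u_final = raw$u_final,
    gates_final = raw$gates_final, conc_final = raw$conc_final,
    diverged = raw$diverged, diverge_t_ms = raw$diverge_t_ms,
    cg_iterations = raw$cg_iterations, stim_log = stim_log,
    config = config, mesh = mesh,
    protocol = protocol, substrate_summary = list(
      coefficients = substrate$coefficients, law_variant = substrate$law$variant)
  )
  if (!is.null(raw$probe_traces)) {
    pt <- raw$probe_traces
    colnames(pt) <- paste0("node_", config$probes)
    res$probe_traces <- dplyr::bind_cols(
      tibble::tibble(t_ms = seq(0, by = config$dt_ms,
                                length.out = nrow(pt))),
      tibble::as_tibble(pt))
  }
  if (!is.null(raw$frames)) {
    res$frames <- raw$frames
    res$frame_t_ms <- raw$frame_t_ms
  }
  res$config_hash <- rlang::hash(list(
    coords = coords, elems = mesh$elems, D = substrate$elem[c("Dxx", "Dxy", "Dyy")],
    scales = scales, config = unclass(config),
    protocol = if (is.null(protocol)) NULL else as.data.frame(protocol)))
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d nodes, T = %g ms (dt %g ms, BDF%d)%s\n",
    nrow(x$activation), x$config$t_end_ms, x$config$dt_ms,
    x$config$bdf_order, if (x$diverged) " [DIVERGED]" else ""))
  act <- sum(is.finite(x$activation$at_ms))
  cat(sprintf("  activated nodes in window: %d / %d | config %s\n", act,
              nrow(x$activation), substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' @method glance simulation_result
#' @export
glance.simulation_result <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$activation), t_end_ms = x$config$t_end_ms,
    dt_ms = x$config$dt_ms, bdf_order = x$config$bdf_order,
    diverged = x$diverged, cg_iterations = x$cg_iterations,
    config_hash = x$config_hash
  )
}

#' @method tidy simulation_result
#' @export
tidy.simulation_result <- function(x, ...) x$activation

#' @method autoplot simulation_result
#' @export
autoplot.simulation_result <- function(object, ...) {
  ggplot2::ggplot(object$activation,
                  ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                               fill = .data$at_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "AT (ms)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

# measure planar wave speed along x by regressing activation time on x
# over the central band of the sheet
measure_planar_speed <- function(result, x_range = NULL) {
  act <- result$activation
  mesh <- result$mesh
  if (is.null(x_range)) x_range <- c(0.25, 0.75) * mesh$lx_mm
  mid <- act$x_mm >= x_range[1] & act$x_mm <= x_range[2] &
    is.finite(act$at_ms)
  if (sum(mid) < 10) return(NA_real_)
  fit <- stats::lm(at_ms ~ x_mm, data = act[mid, ])
  1 / stats::coef(fit)[["x_mm"]]  # mm/ms = m/s
}
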