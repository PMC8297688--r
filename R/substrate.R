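#' Conductivity coefficient presets
#'
#' Two printed coefficient pairs for the CV-squared conductivity law:
#' `"baseline"` (C_l = 3.0e-4 s, C_tn = 0.48e-4 s), tuned to make simulated
#' wavefronts reproduce the mapped conduction velocities, and
#' `"progressed"` (C_l = 2.0e-4 s, C_tn = 0.32e-4 s), representing increased
#' slow conduction with disease progression. Both satisfy
#' `C_tn = 0.16 * C_l`, which makes the transversal law continuous at its
#' 0.4 m/s threshold.
#'
#' @param preset `"baseline"` or `"progressed"`.
#' @return A list with `C_l`, `C_tn` (seconds; diffusivity interpretation
#'   C_l * CV^2 in m^2/s) and `preset`.
#' @export
#' @examples
#' conductivity_presets("baseline")
conductivity_presets <- function(preset = c("baseline", "progressed")) {
  preset <- match.arg(preset)
  if (preset == "baseline") {
    list(preset = preset, C_l = 3.0e-4, C_tn = 0.48e-4)
  } else {
    list(preset = preset, C_l = 2.0e-4, C_tn = 0.32e-4)
  }
}

#' Longitudinal conductivity from conduction velocity
#'
#' `sigma_l = C_l * CV^2` (m^2/s when C_l is in seconds and CV in m/s).
#'
#' @param cv CV magnitude, m/s (nonnegative).
#' @param C_l Longitudinal coefficient, s.
#' @return Conductivity, m^2/s.
#' @export
sigma_longitudinal <- function(cv, C_l = conductivity_presets()$C_l) {
  stopifnot(all(cv >= 0), C_l > 0)
  C_l * cv^2
}

#' Transversal/normal conductivity from conduction velocity
#'
#' Thresholded law: below 0.4 m/s the tissue is effectively isotropic
#' (`C_l * CV^2`, same as longitudinal); at or above 0.4 m/s the constant
#' `C_tn` applies, maintaining the physiological anisotropy ratio. The law
#' is continuous at the threshold whenever `C_tn = 0.16 * C_l`, as both
#' printed presets satisfy.
#'
#' @inheritParams sigma_longitudinal
#' @param C_tn Transversal coefficient, s.
#' @param threshold Transversal CV threshold, m/s.
#' @return Conductivity, m^2/s.
#' @export
sigma_transversal <- function(cv, C_l = conductivity_presets()$C_l,
                              C_tn = conductivity_presets()$C_tn,
                              threshold = 0.4) {
  stopifnot(all(cv >= 0))
  ifelse(cv < threshold, C_l * cv^2, C_tn)
}

#' Anisotropic diffusion tensor from a fiber frame
#'
#' `D = sigma_l f0 (x) f0 + sigma_t s0 (x) s0 (+ sigma_n n0 (x) n0 in 3D)`.
#' On 2D sheets only the in-plane pair (f0, s0) is used.
#'
#' @param sigma_l,sigma_t,sigma_n Conductivities (any consistent unit).
#' @param f0,s0,n0 Orthonormal frame vectors (length 2 for sheets, 3
#'   otherwise); `n0` optional in 2D.
#' @param tol Orthonormality tolerance.
#' @return The symmetric positive semidefinite tensor (2x2 or 3x3 matrix).
#' @export
#' @examples
#' build_diffusion_tensor(3e-4, 0.48e-4, f0 = c(1, 0), s0 = c(0, 1))
build_diffusion_tensor <- function(sigma_l, sigma_t, sigma_n = sigma_t,
                                   f0, s0, n0 = NULL, tol = 1e-8) {
  stopifnot(length(f0) == length(s0))
  chk <- c(abs(sum(f0^2) - 1), abs(sum(s0^2) - 1), abs(sum(f0 * s0)))
  if (!is.null(n0)) {
    chk <- c(chk, abs(sum(n0^2) - 1), abs(sum(f0 * n0)), abs(sum(s0 * n0)))
  }
  if (max(chk) > tol) stop("fiber frame is not orthonormal within tolerance")
  D <- sigma_l * tcrossprod(f0) + sigma_t * tcrossprod(s0)
  if (!is.null(n0)) D <- D + sigma_n * tcrossprod(n0)
  D
}

#' Build the heterogeneous substrate from a nodal CV field
#'
#' Turns a nodal conduction-velocity field plus the mesh fiber frame into
#' (i) per-element conductivity tensors via the CV-squared longitudinal law
#' and the thresholded transversal law (element CV = mean of its nodes) and
#' (ii) nodal ionic remodeling (I_CV fraction and scaled maximal
#' conductances). Conductivities are converted to mm^2/ms internally
#' (1 m^2/s = 1000 mm^2/ms) for the millimeter/millisecond solver.
#'
#' @param mesh A [gen_sheet_mesh()] mesh.
#' @param cv_nodal Numeric vector of CV per node (m/s) or a tibble with
#'   columns `node`, `cv` (e.g. from [gen_cv_field()] or
#'   [project_to_mesh()]).
#' @param coefficients A [conductivity_presets()] list.
#' @param law A [remodeling_law()].
#' @return An object of class `substrate_fields`: list with `nodal`
#'   (tibble `node`, `cv`, `icv`, `s_to`, `s_CaL`, `s_Kur`, `g_to`,
#'   `g_CaL`, `g_Kur`), `elem` (tibble `elem`, `cv`, `sigma_l`, `sigma_t`
#'   in m^2/s, and the tensor entries `Dxx`, `Dxy`, `Dyy` in mm^2/ms), plus
#'   the inputs.
#' @export
build_substrate <- function(mesh, cv_nodal,
                            coefficients = conductivity_presets("baseline"),
                            law = remodeling_law("baseline")) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  if (is.data.frame(cv_nodal)) cv_nodal <- cv_nodal$cv[order(cv_nodal$node)]
  if (length(cv_nodal) != nrow(mesh$nodes)) {
    stop("CV must be defined on every node (fill invalid nodes first)")
  }
  if (any(!is.finite(cv_nodal)) || any(cv_nodal < 0)) {
    stop("CV must be finite and nonnegative")
  }
  if (is.null(mesh$fibers)) stop("mesh has no fiber frame")

  g <- remodeled_conductances(cv_nodal, law)
  nodal <- dplyr::bind_cols(tibble::tibble(node = mesh$nodes$node), g)

  cv_elem <- (cv_nodal[mesh$elems[, 1]] + cv_nodal[mesh$elems[, 2]] +
                cv_nodal[mesh$elems[, 3]] + cv_nodal[mesh$elems[, 4]]) / 4
  s_l <- sigma_longitudinal(cv_elem, coefficients$C_l)
  s_t <- sigma_transversal(cv_elem, coefficients$C_l, coefficients$C_tn)
  # m^2/s -> mm^2/ms
  sl_mm <- s_l * 1e3
  st_mm <- s_t * 1e3
  fx <- mesh$fibers$fx; fy <- mesh$fibers$fy
  sx <- mesh$fibers$sx; sy <- mesh$fibers$sy
  elem <- tibble::tibble(
    elem = seq_along(cv_elem), cv = cv_elem,
    sigma_l = s_l, sigma_t = s_t,
    Dxx = sl_mm * fx^2 + st_mm * sx^2,
    Dxy = sl_mm * fx * fy + st_mm * sx * sy,
    Dyy = sl_mm * fy^2 + st_mm * sy^2
  )
  structure(
    list(nodal = nodal, elem = elem, mesh = mesh,
         coefficients = coefficients, law = law),
    class = "substrate_fields"
  )
}

#' @export
print.substrate_fields <- function(x, ...) {
  cat(sprintf(
    "<substrate_fields> %d nodes, %d elements | %s coefficients, %s remodeling\n",
    nrow(x$nodal), nrow(x$elem), x$coefficients$preset, x$law$variant))
  cat(sprintf("  CV %.2f-%.2f m/s (mean %.2f) | I_CV mean %.2f\n",
              min(x$nodal$cv), max(x$nodal$cv), mean(x$nodal$cv),
              mean(x$nodal$icv)))
  invisible(x)
}

#' @method tidy substrate_fields
#' @export
tidy.substrate_fields <- function(x, ...) {
  dplyr::left_join(x$mesh$nodes, x$nodal, by = "node")
}

#' @method autoplot substrate_fields
#' @export
autoplot.substrate_fields <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                   fill = .data$cv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "CV (m/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}
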