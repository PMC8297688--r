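#' Read an activation point cloud from CSV
#'
#' Expects a header `x_mm,y_mm,z_mm,at_ms`. Rows with non-finite entries are
#' dropped with a warning reporting the count.
#'
#' @param path CSV file path.
#' @return A tibble `x_mm`, `y_mm`, `z_mm`, `at_ms`.
#' @export
read_activation_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm", "at_ms")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("activation CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df[need])
  ok <- stats::complete.cases(df) &
    apply(as.matrix(df), 1, function(r) all(is.finite(r)))
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with non-finite entries dropped")
    df <- df[ok, ]
  }
  df
}

#' Read an activation point cloud from a VTU/VTK XML file
#'
#' Expects a point-data array with the activation times (named `AT` or
#' `at_ms`).
#'
#' @param path VTU path.
#' @param array Name of the activation-time point array.
#' @return A tibble `x_mm`, `y_mm`, `z_mm`, `at_ms`.
#' @export
read_activation_vtu <- function(path, array = c("AT", "at_ms")) {
  v <- read_vtu(path)
  nm <- intersect(array, names(v$point_data))
  if (length(nm) == 0) {
    stop("no activation-time point array (looked for: ",
         paste(array, collapse = ", "), ")")
  }
  tibble::tibble(x_mm = v$points[, 1], y_mm = v$points[, 2],
                 z_mm = v$points[, 3], at_ms = v$point_data[[nm[1]]])
}

#' Write an activation point cloud to CSV
#'
#' @param cloud Tibble with columns `x_mm`, `y_mm`, `z_mm`, `at_ms`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activation_csv <- function(cloud, path) {
  utils::write.csv(cloud[c("x_mm", "y_mm", "z_mm", "at_ms")], path,
                   row.names = FALSE)
  invisible(path)
}

# total-least-squares plane through points: smallest principal direction of
# the centered scatter is the normal; returns NULL for degenerate geometry
fit_tangent_plane <- function(pts) {
  if (nrow(pts) < 3) return(NULL)
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  s <- crossprod(x) / nrow(pts)
  e <- eigen(s, symmetric = TRUE)
  # collinear: second-smallest eigenvalue ~ 0 relative to largest
  if (e$values[2] < 1e-10 * max(e$values[1], 1e-300)) return(NULL)
  list(origin = ctr, e1 = e$vectors[, 1], e2 = e$vectors[, 2],
       normal = e$vectors[, 3], rms_residual = sqrt(max(e$values[3], 0)))
}

# degree-2 polynomial least squares T(x,y) = a0 + a1 x + a2 y + a3 x^2 +
# a4 xy + a5 y^2 on centered/scaled tangent coordinates; returns NULL if
# the design is rank deficient
fit_poly2 <- function(xy, at, cond_limit = 1e8) {
  if (nrow(xy) < 6) return(NULL)
  sc <- max(stats::sd(xy[, 1]), stats::sd(xy[, 2]), 1e-9)
  xs <- xy[, 1] / sc
  ys <- xy[, 2] / sc
  X <- cbind(1, xs, ys, xs^2, xs * ys, ys^2)
  qrX <- qr(X)
  if (qrX$rank < 6) return(NULL)
  d <- abs(diag(qr.R(qrX)))
  if (max(d) / min(d) > cond_limit) return(NULL)
  b <- qr.coef(qrX, at)
  # un-scale back to mm coordinates
  coef <- c(b[1], b[2] / sc, b[3] / sc, b[4] / sc^2, b[5] / sc^2, b[6] / sc^2)
  names(coef) <- c("a0", "a1", "a2", "a3", "a4", "a5")
  list(coef = coef,
       residual = sqrt(sum(qr.resid(qrX, at)^2)))
}

# inverse-gradient rule: v = grad(T) / |grad(T)|^2; grad in ms/mm at the
# patch center (local origin), speed in mm/ms = m/s
velocity_from_fit <- function(coef, grad_min = 1e-6) {
  g <- c(coef[["a1"]], coef[["a2"]])
  g2 <- sum(g^2)
  if (sqrt(g2) < grad_min) return(NULL)
  g / g2
}

#' Estimate a conduction-velocity field from an activation map
#'
#' For each point of the cloud: neighboring points within a 7.1 mm ball are
#' projected onto a local total-least-squares tangent plane; points whose
#' tangent coordinates fall within the 1 cm x 1 cm square centered at the
#' query point form the patch; a degree-2 polynomial is fit to the
#' activation times by least squares; the velocity is the inverse-gradient
#' transform of the fitted gradient at the center, lifted back to 3D along
#' the tangent axes. Speeds outside `[0, 2] m/s` (the physiological 0-200
#' cm/s range) or degenerate fits mark the point invalid.
#'
#' @param cloud Activation point cloud: tibble with `x_mm`, `y_mm`, `z_mm`,
#'   `at_ms` (e.g. from [read_activation_csv()] or [eikonal_activation()]).
#' @param patch_size_mm Side of the square patch (default 10 mm).
#' @param min_points Minimum patch size for a fit (default 6).
#' @param cv_max Upper validity bound, m/s (default 2).
#' @return An object of class `cv_field`, a tibble with the cloud columns
#'   plus `vx`, `vy`, `vz` (m/s), `cv` (speed, m/s) and `valid`; summary
#'   statistics in `attr(., "qc")`.
#' @export
estimate_cv_field <- function(cloud, patch_size_mm = 10, min_points = 6,
                              cv_max = 2.0) {
  need <- c("x_mm", "y_mm", "z_mm", "at_ms")
  stopifnot(all(need %in% names(cloud)))
  pts <- as.matrix(cloud[c("x_mm", "y_mm", "z_mm")])
  at <- cloud$at_ms
  n <- nrow(pts)
  half <- patch_size_mm / 2
  r_ball <- sqrt(2) * half + 0.05  # circumscribing ball pre-filter

  vx <- vy <- vz <- speed <- rep(NA_real_, n)
  valid <- rep(FALSE, n)

  for (i in seq_len(n)) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2 +
      (pts[, 3] - pts[i, 3])^2
    nb <- which(d2 <= r_ball^2)
    if (length(nb) < min_points) next
    pl <- fit_tangent_plane(pts[nb, , drop = FALSE])
    if (is.null(pl)) next
    rel <- sweep(pts[nb, , drop = FALSE], 2, pts[i, ])
    u <- rel %*% pl$e1
    v <- rel %*% pl$e2
    inside <- abs(u) <= half & abs(v) <= half
    if (sum(inside) < min_points) next
    fit <- fit_poly2(cbind(u[inside], v[inside]), at[nb][inside])
    if (is.null(fit)) next
    v2d <- velocity_from_fit(fit$coef)
    if (is.null(v2d)) next
    v3d <- v2d[1] * pl$e1 + v2d[2] * pl$e2
    s <- sqrt(sum(v3d^2))
    if (s > cv_max) next  # out-of-range speeds invalidated, not clamped
    vx[i] <- v3d[1]; vy[i] <- v3d[2]; vz[i] <- v3d[3]
    speed[i] <- s
    valid[i] <- TRUE
  }

  out <- tibble::as_tibble(cloud)
  out$vx <- vx; out$vy <- vy; out$vz <- vz
  out$cv <- speed
  out$valid <- valid
  qc <- list(
    n_points = n,
    n_valid = sum(valid),
    frac_invalid = mean(!valid),
    mean_cv = mean(speed[valid]),
    sd_cv = stats::sd(speed[valid])
  )
  attr(out, "qc") <- qc
  class(out) <- c("cv_field", class(out))
  out
}

#' @method glance cv_field
#' @export
glance.cv_field <- function(x, ...) {
  tibble::as_tibble(attr(x, "qc"))
}

#' @method autoplot cv_field
#' @export
autoplot.cv_field <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$valid),
                  ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                               color = .data$cv)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_viridis_c(name = "CV (m/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Project a CV field onto mesh nodes
#'
#' Nearest-neighbor projection: each mesh node takes the CV magnitude of its
#' nearest valid cloud point (lowest index wins ties). The donor distance is
#' recorded for quality control.
#'
#' @param cv A `cv_field` from [estimate_cv_field()], or any tibble with
#'   `x_mm`, `y_mm`, `z_mm` (optional), `cv` and optionally `valid`.
#' @param mesh A [gen_sheet_mesh()] mesh.
#' @return A tibble `node`, `x_mm`, `y_mm`, `cv`, `donor`,
#'   `donor_dist_mm`.
#' @export
project_to_mesh <- function(cv, mesh) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  ok <- if ("valid" %in% names(cv)) cv$valid else rep(TRUE, nrow(cv))
  src <- cv[ok, ]
  if (nrow(src) == 0) stop("no valid cloud points to project")
  sz <- if ("z_mm" %in% names(src)) src$z_mm else 0
  nn <- vapply(seq_len(nrow(mesh$nodes)), function(i) {
    d2 <- (src$x_mm - mesh$nodes$x_mm[i])^2 +
      (src$y_mm - mesh$nodes$y_mm[i])^2 + sz^2
    which.min(d2)  # which.min returns the first (lowest-index) minimum
  }, integer(1))
  d <- sqrt((src$x_mm[nn] - mesh$nodes$x_mm)^2 +
              (src$y_mm[nn] - mesh$nodes$y_mm)^2)
  tibble::tibble(
    node = mesh$nodes$node, x_mm = mesh$nodes$x_mm, y_mm = mesh$nodes$y_mm,
    cv = src$cv[nn], donor = which(ok)[nn], donor_dist_mm = d
  )
}
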