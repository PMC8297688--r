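#' Structured quadrilateral tissue sheet
#'
#' Builds a structured 2D quadrilateral mesh of a rectangular tissue sheet
#' with a per-element fiber frame. Coordinates are in mm. The fiber pattern
#' is either a uniform direction at a fixed angle or a circular field around
#' the sheet center.
#'
#' @param lx_mm,ly_mm Sheet dimensions, mm; must be positive multiples of
#'   `h_mm`.
#' @param h_mm Element size, mm.
#' @param fiber_pattern `"uniform"` or `"circular"`.
#' @param fiber_angle_deg Fiber angle for the uniform pattern, degrees from
#'   the x axis.
#' @return An object of class `tissue_mesh`: list with `nodes` (tibble
#'   `node`, `x_mm`, `y_mm`), `elems` (integer matrix, one row per element,
#'   4 node indices, counterclockwise), `fibers` (tibble `elem`, `fx`, `fy`
#'   unit fiber vector, `sx`, `sy` in-sheet transverse unit vector), `h_mm`,
#'   `nx`, `ny` (node counts per direction).
#' @export
#' @examples
#' m <- gen_sheet_mesh(20, 20, 0.5)
#' nrow(m$nodes)  # 41 x 41
gen_sheet_mesh <- function(lx_mm, ly_mm, h_mm,
                           fiber_pattern = c("uniform", "circular"),
                           fiber_angle_deg = 0) {
  fiber_pattern <- match.arg(fiber_pattern)
  if (lx_mm <= 0 || ly_mm <= 0 || h_mm <= 0) {
    stop("sheet dimensions and element size must be positive")
  }
  nex <- round(lx_mm / h_mm)
  ney <- round(ly_mm / h_mm)
  if (abs(nex * h_mm - lx_mm) > 1e-9 || abs(ney * h_mm - ly_mm) > 1e-9) {
    stop("`lx_mm` and `ly_mm` must be multiples of `h_mm`")
  }
  nx <- nex + 1L
  ny <- ney + 1L
  xs <- seq(0, lx_mm, length.out = nx)
  ys <- seq(0, ly_mm, length.out = ny)
  nodes <- tibble::tibble(
    node = seq_len(nx * ny),
    x_mm = rep(xs, times = ny),
    y_mm = rep(ys, each = nx)
  )
  # element connectivity, counterclockwise
  e0 <- rep(seq_len(nex), times = ney) +
    rep((seq_len(ney) - 1L) * nx, each = nex)
  elems <- cbind(e0, e0 + 1L, e0 + 1L + nx, e0 + nx)
  storage.mode(elems) <- "integer"
  colnames(elems) <- NULL

  cx <- (nodes$x_mm[elems[, 1]] + nodes$x_mm[elems[, 2]] +
           nodes$x_mm[elems[, 3]] + nodes$x_mm[elems[, 4]]) / 4
  cy <- (nodes$y_mm[elems[, 1]] + nodes$y_mm[elems[, 2]] +
           nodes$y_mm[elems[, 3]] + nodes$y_mm[elems[, 4]]) / 4
  if (fiber_pattern == "uniform") {
    a <- fiber_angle_deg * pi / 180
    fx <- rep(cos(a), nrow(elems))
    fy <- rep(sin(a), nrow(elems))
  } else {
    # circular field around the sheet center (tangential)
    dx <- cx - lx_mm / 2
    dy <- cy - ly_mm / 2
    r <- sqrt(dx^2 + dy^2)
    r[r < 1e-9] <- 1
    fx <- -dy / r
    fy <- dx / r
  }
  fibers <- tibble::tibble(elem = seq_len(nrow(elems)),
                           fx = fx, fy = fy, sx = -fy, sy = fx)
  structure(
    list(nodes = nodes, elems = elems, fibers = fibers,
         h_mm = h_mm, nx = nx, ny = ny, lx_mm = lx_mm, ly_mm = ly_mm),
    class = "tissue_mesh"
  )
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf("<tissue_mesh> %g x %g mm sheet, h = %g mm: %d nodes, %d quads\n",
              x$lx_mm, x$ly_mm, x$h_mm, nrow(x$nodes), nrow(x$elems)))
  invisible(x)
}

#' @method tidy tissue_mesh
#' @export
tidy.tissue_mesh <- function(x, ...) x$nodes

# nearest mesh node to a point (mm)
nearest_node <- function(mesh, x_mm, y_mm) {
  which.min((mesh$nodes$x_mm - x_mm)^2 + (mesh$nodes$y_mm - y_mm)^2)
}

# bilinear interpolation of nodal values at arbitrary points on a
# structured sheet mesh; returns NA outside the sheet
interp_nodal <- function(mesh, values, x_mm, y_mm) {
  hx <- mesh$lx_mm / (mesh$nx - 1L)
  hy <- mesh$ly_mm / (mesh$ny - 1L)
  ex <- pmin(pmax(floor(x_mm / hx), 0), mesh$nx - 2L)
  ey <- pmin(pmax(floor(y_mm / hy), 0), mesh$ny - 2L)
  xi <- x_mm / hx - ex
  eta <- y_mm / hy - ey
  n00 <- ey * mesh$nx + ex + 1L
  v <- (1 - xi) * (1 - eta) * values[n00] +
    xi * (1 - eta) * values[n00 + 1L] +
    xi * eta * values[n00 + 1L + mesh$nx] +
    (1 - xi) * eta * values[n00 + mesh$nx]
  out <- x_mm < -1e-9 | x_mm > mesh$lx_mm + 1e-9 |
    y_mm < -1e-9 | y_mm > mesh$ly_mm + 1e-9
  v[out] <- NA_real_
  v
}
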