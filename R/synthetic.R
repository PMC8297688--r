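#' Specification of a synthetic conduction-velocity field
#'
#' Describes the statistics of a synthetic nodal CV field. The two named
#' presets emulate the published contrast between atrial-fibrillation
#' substrates: the persistent-like preset has a lower mean and contains
#' patches of severe slow conduction (below 0.25 m/s), while the
#' paroxysmal-like preset has a mean 0.40 m/s higher, a comparable standard
#' deviation and no severe slow zones (minimum 0.3 m/s).
#'
#' @param preset `"paroxysmal"`, `"persistent"`, `"uniform"` or `"custom"`.
#' @param mean_cv Background mean, m/s.
#' @param sd_cv Background standard deviation (after smoothing), m/s.
#' @param n_patches Number of slow-conduction patches (persistent-like).
#' @param patch_radius_mm Patch radius, mm.
#' @param patch_floor CV floor inside a patch, m/s.
#' @param smooth_mm Gaussian smoothing length, mm.
#' @param cv_min,cv_max Clipping range, m/s.
#' @return An object of class `cv_field_spec`.
#' @export
#' @examples
#' cv_field_spec("persistent")
cv_field_spec <- function(preset = c("paroxysmal", "persistent", "uniform",
                                     "custom"),
                          mean_cv = NULL, sd_cv = NULL, n_patches = NULL,
                          patch_radius_mm = 6, patch_floor = 0.15,
                          smooth_mm = 8, cv_min = 0.05, cv_max = 2.0) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    paroxysmal = list(mean_cv = 1.0, sd_cv = 0.25, n_patches = 0L,
                      cv_min = 0.3),
    persistent = list(mean_cv = 0.6, sd_cv = 0.25, n_patches = 3L,
                      cv_min = 0.05),
    uniform    = list(mean_cv = 0.7, sd_cv = 0, n_patches = 0L,
                      cv_min = 0.05),
    custom     = list(mean_cv = 0.7, sd_cv = 0.2, n_patches = 0L,
                      cv_min = 0.05)
  )
  spec <- list(
    preset = preset,
    mean_cv = mean_cv %||% defaults$mean_cv,
    sd_cv = sd_cv %||% defaults$sd_cv,
    n_patches = as.integer(n_patches %||% defaults$n_patches),
    patch_radius_mm = patch_radius_mm,
    patch_floor = patch_floor,
    smooth_mm = smooth_mm,
    cv_min = if (preset == "paroxysmal") max(cv_min, 0.3) else cv_min,
    cv_max = cv_max
  )
  structure(spec, class = "cv_field_spec")
}

#' @export
print.cv_field_spec <- function(x, ...) {
  cat(sprintf(
    "<cv_field_spec> %s: mean %.2f m/s, sd %.2f, %d slow patches (r %.0f mm, floor %.2f)\n",
    x$preset, x$mean_cv, x$sd_cv, x$n_patches, x$patch_radius_mm,
    x$patch_floor))
  invisible(x)
}

#' Generate a synthetic nodal conduction-velocity field
#'
#' Draws a Gaussian random background on the mesh nodes, smooths it with a
#' Gaussian kernel of length `smooth_mm` (rescaled to restore the requested
#' marginal standard deviation), multiplies in radial smoothstep
#' slow-conduction patches down to the floor value, clips to
#' `[cv_min, cv_max]` and finally recenters so the realized spatial mean
#' matches the preset mean. The result is a pure function of
#' `(mesh, spec, seed)`.
#'
#' @param mesh A [gen_sheet_mesh()] mesh.
#' @param spec A [cv_field_spec()].
#' @param seed Integer seed.
#' @return A tibble `node`, `x_mm`, `y_mm`, `cv` (m/s) with the spec stored
#'   in attribute `"spec"`.
#' @export
#' @examples
#' m <- gen_sheet_mesh(20, 20, 1)
#' f <- gen_cv_field(m, cv_field_spec("persistent"), seed = 1)
#' mean(f$cv)
gen_cv_field <- function(mesh, spec = cv_field_spec("uniform"), seed = 1) {
  stopifnot(inherits(mesh, "tissue_mesh"), inherits(spec, "cv_field_spec"))
  nx <- mesh$nx; ny <- mesh$ny
  h <- mesh$lx_mm / (nx - 1L)

  if (spec$sd_cv <= 0) {
    cv <- rep(spec$mean_cv, nx * ny)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    z <- matrix(stats::rnorm(nx * ny), nrow = nx, ncol = ny)
    z <- gauss_smooth2d(z, sigma_cells = spec$smooth_mm / h)
    z <- z / stats::sd(as.numeric(z))
    cv <- spec$mean_cv + spec$sd_cv * as.numeric(z)

    if (spec$n_patches > 0) {
      # patch centers away from the boundary
      px <- stats::runif(spec$n_patches, 0.15, 0.85) * mesh$lx_mm
      py <- stats::runif(spec$n_patches, 0.15, 0.85) * mesh$ly_mm
      for (k in seq_len(spec$n_patches)) {
        r <- sqrt((mesh$nodes$x_mm - px[k])^2 + (mesh$nodes$y_mm - py[k])^2)
        s <- smoothstep(r / spec$patch_radius_mm)  # 0 at center, 1 outside
        cv <- pmin(cv, spec$patch_floor + s * (cv - spec$patch_floor))
      }
    }
  }
  cv <- pmin(spec$cv_max, pmax(spec$cv_min, cv))
  # recenter the spatial mean onto the preset mean (patches and clipping
  # shift it); two passes are enough at these amplitudes
  for (i in 1:2) {
    cv <- cv + (spec$mean_cv - mean(cv))
    cv <- pmin(spec$cv_max, pmax(spec$cv_min, cv))
  }
  out <- tibble::tibble(node = mesh$nodes$node, x_mm = mesh$nodes$x_mm,
                        y_mm = mesh$nodes$y_mm, cv = cv)
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  out
}

# C^1 smoothstep clamped to [0,1]
smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# separable Gaussian smoothing with reflected boundaries
gauss_smooth2d <- function(z, sigma_cells) {
  if (sigma_cells <= 0) return(z)
  half <- max(1L, ceiling(3 * sigma_cells))
  k <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  k <- k / sum(k)
  pad_filter <- function(v) {
    n <- length(v)
    hh <- min(half, n - 1L)
    kk <- if (hh < half) {
      k2 <- stats::dnorm(seq(-hh, hh), sd = sigma_cells)
      k2 / sum(k2)
    } else k
    vp <- c(v[(hh + 1):2], v, v[(n - 1):(n - hh)])
    stats::filter(vp, kk, sides = 2)[(hh + 1):(hh + n)]
  }
  z <- apply(z, 2, pad_filter)
  t(apply(t(z), 2, pad_filter))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Eikonal activation map from a CV field
#'
#' Shortest-travel-time activation from one or more source nodes, computed
#' with Dijkstra's algorithm on the mesh edge graph (edges and element
#' diagonals; edge weight = length / harmonic mean of the endpoint CVs).
#' The result is subsampled to an approximately regular point cloud with the
#' requested spacing, mimicking a mapping catheter's interelectrode
#' distance.
#'
#' @param mesh A [gen_sheet_mesh()] mesh.
#' @param cv_nodal Numeric CV per node (m/s), or a tibble from
#'   [gen_cv_field()].
#' @param source_nodes Integer node indices of the activation source(s).
#' @param spacing_mm Point-cloud subsampling spacing; `NULL` returns all
#'   nodes. Default 2.5 mm.
#' @return An activation point cloud: tibble `x_mm`, `y_mm`, `z_mm`,
#'   `at_ms`, `node`, with the full nodal map in attribute `"at_nodal"`.
#' @export
eikonal_activation <- function(mesh, cv_nodal, source_nodes,
                               spacing_mm = 2.5) {
  stopifnot(inherits(mesh, "tissue_mesh"), length(source_nodes) >= 1)
  if (is.data.frame(cv_nodal)) cv_nodal <- cv_nodal$cv
  if (length(cv_nodal) != nrow(mesh$nodes)) {
    stop("`cv_nodal` must have one value per mesh node")
  }
  if (any(cv_nodal <= 0)) stop("CV must be positive everywhere")

  nx <- mesh$nx; ny <- mesh$ny
  idx <- function(i, j) (j - 1L) * nx + i  # i in 1..nx, j in 1..ny
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  from <- c(
    idx(i[i < nx], j[i < nx]),                      # horizontal
    idx(i[j < ny], j[j < ny]),                      # vertical
    idx(i[i < nx & j < ny], j[i < nx & j < ny]),    # diagonal /
    idx(i[i < nx & j < ny] + 1L, j[i < nx & j < ny])  # diagonal \
  )
  to <- c(
    idx(i[i < nx] + 1L, j[i < nx]),
    idx(i[j < ny], j[j < ny] + 1L),
    idx(i[i < nx & j < ny] + 1L, j[i < nx & j < ny] + 1L),
    idx(i[i < nx & j < ny], j[i < nx & j < ny] + 1L)
  )
  len <- sqrt((mesh$nodes$x_mm[from] - mesh$nodes$x_mm[to])^2 +
                (mesh$nodes$y_mm[from] - mesh$nodes$y_mm[to])^2)
  hmean <- 2 * cv_nodal[from] * cv_nodal[to] / (cv_nodal[from] + cv_nodal[to])
  w <- len / hmean  # mm / (mm/ms) = ms

  g <- igraph::make_graph(rbind(from, to), n = nx * ny, directed = FALSE)
  d <- igraph::distances(g, v = source_nodes, weights = w)
  at <- apply(d, 2, min)  # multiple sources: earliest arrival

  keep <- seq_len(nx * ny)
  if (!is.null(spacing_mm)) {
    h <- mesh$lx_mm / (nx - 1L)
    stride <- max(1L, round(spacing_mm / h))
    keep <- which((i - 1L) %% stride == 0L & (j - 1L) %% stride == 0L)
  }
  out <- tibble::tibble(
    x_mm = mesh$nodes$x_mm[keep], y_mm = mesh$nodes$y_mm[keep],
    z_mm = 0, at_ms = at[keep], node = keep
  )
  attr(out, "at_nodal") <- at
  out
}

#' Bundled reproducible fixtures
#'
#' Named, seeded synthetic cases used throughout the tests and examples.
#' Each fixture is rebuilt deterministically on request; the registry is:
#' `"cable-1d"` (40 x 2 mm strip), `"sheet-2x2cm-uniform"`,
#' `"sheet-5x5cm-paroxysmal"`, `"sheet-5x5cm-persistent"` and
#' `"spiral-phase-field"` (an Archimedean-spiral phase snapshot for rotor
#' detection tests).
#'
#' @param name Fixture name.
#' @param h_mm Mesh size override, mm.
#' @param seed Seed override.
#' @return A list with `mesh`, and per fixture: `cv` (CV-field tibble),
#'   `spec`, or `phase`/`u` fields for the spiral; plus `name` and a
#'   `checksum` of the numeric content.
#' @export
make_fixture <- function(name, h_mm = NULL, seed = 1) {
  registry <- c("cable-1d", "sheet-2x2cm-uniform", "sheet-5x5cm-paroxysmal",
                "sheet-5x5cm-persistent", "spiral-phase-field")
  if (!name %in% registry) {
    stop("unknown fixture `", name, "`; registry: ",
         paste(registry, collapse = ", "))
  }
  fx <- switch(name,
    "cable-1d" = {
      h <- h_mm %||% 0.5
      mesh <- gen_sheet_mesh(40, 2, h)
      cvf <- gen_cv_field(mesh, cv_field_spec("uniform"), seed = seed)
      list(mesh = mesh, cv = cvf, spec = attr(cvf, "spec"))
    },
    "sheet-2x2cm-uniform" = {
      h <- h_mm %||% 0.33
      mesh <- gen_sheet_mesh(round(20 / h) * h, round(20 / h) * h, h)
      cvf <- gen_cv_field(mesh, cv_field_spec("uniform"), seed = seed)
      list(mesh = mesh, cv = cvf, spec = attr(cvf, "spec"))
    },
    "sheet-5x5cm-paroxysmal" = {
      h <- h_mm %||% 0.5
      mesh <- gen_sheet_mesh(round(50 / h) * h, round(50 / h) * h, h)
      cvf <- gen_cv_field(mesh, cv_field_spec("paroxysmal"), seed = seed)
      list(mesh = mesh, cv = cvf, spec = attr(cvf, "spec"))
    },
    "sheet-5x5cm-persistent" = {
      h <- h_mm %||% 0.5
      mesh <- gen_sheet_mesh(round(50 / h) * h, round(50 / h) * h, h)
      cvf <- gen_cv_field(mesh, cv_field_spec("persistent"), seed = seed)
      list(mesh = mesh, cv = cvf, spec = attr(cvf, "spec"))
    },
    "spiral-phase-field" = {
      h <- h_mm %||% 0.5
      mesh <- gen_sheet_mesh(30, 30, h)
      cx <- 15; cy <- 15; lambda <- 10
      r <- sqrt((mesh$nodes$x_mm - cx)^2 + (mesh$nodes$y_mm - cy)^2)
      th <- atan2(mesh$nodes$y_mm - cy, mesh$nodes$x_mm - cx)
      phase <- (th + 2 * pi * r / lambda) %% (2 * pi) - pi
      list(mesh = mesh, phase = phase, core = c(cx, cy))
    }
  )
  fx$name <- name
  nums <- unlist(lapply(fx, function(x) {
    if (is.data.frame(x)) unlist(x[vapply(x, is.numeric, TRUE)]) else
      if (is.numeric(x)) x else NULL
  }), use.names = FALSE)
  fx$checksum <- rlang::hash(signif(nums, 12))
  fx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
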