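#' Activation map from a simulation
#'
#' Per node, the activation time is the instant of maximum absolute
#' discrete time derivative of the transmembrane potential (in the BDF
#' form) within the window; it is tracked online during the run. Nodes
#' whose maximum slope is below 10% of the global median upstroke slope are
#' marked invalid (never depolarized).
#'
#' @param result A [run_monodomain()] result whose `at_window_ms` covered
#'   the requested window, or one with recorded frames at stride <= 1 ms
#'   (the derivative is then recomputed from frames by finite differences).
#' @param window_ms Optional length-2 window; must be within the run's
#'   online window unless frames are available.
#' @param slope_frac Validity threshold as a fraction of the median
#'   upstroke slope (default 0.1).
#' @return An `activation_map`: tibble `node`, `x_mm`, `y_mm`, `at_ms`,
#'   `max_slope`, `valid`, with provenance attributes.
#' @export
activation_map <- function(result, window_ms = NULL, slope_frac = 0.1) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(window_ms)) window_ms <- result$config$at_window_ms
  if (window_ms[2] <= window_ms[1]) stop("empty activation window")

  same_window <- isTRUE(all.equal(window_ms, result$config$at_window_ms)) &&
    any(is.finite(result$activation$at_ms))
  if (same_window) {
    at <- result$activation$at_ms
    slope <- result$activation$max_slope
  } else {
    if (is.null(result$frames)) {
      stop("window differs from the run's online window and no frames ",
           "were recorded")
    }
    ft <- result$frame_t_ms
    if (min(diff(ft)) > 1 + 1e-9) {
      stop("frame stride exceeds 1 ms; activation times would be too coarse")
    }
    sel <- which(ft >= window_ms[1] & ft <= window_ms[2])
    if (length(sel) < 3) stop("empty activation window")
    fr <- result$frames[, sel, drop = FALSE]
    dv <- abs(fr[, -1, drop = FALSE] - fr[, -ncol(fr), drop = FALSE]) /
      rep(diff(ft[sel]), each = nrow(fr))
    k <- max.col(dv, ties.method = "first")
    at <- ft[sel][k + 1L]
    slope <- dv[cbind(seq_len(nrow(dv)), k)]
  }

  med_up <- stats::median(slope[slope > 0], na.rm = TRUE)
  valid <- is.finite(at) & slope >= slope_frac * med_up
  out <- tibble::tibble(
    node = result$activation$node, x_mm = result$activation$x_mm,
    y_mm = result$activation$y_mm,
    at_ms = ifelse(valid, at, NA_real_), max_slope = slope, valid = valid
  )
  attr(out, "window_ms") <- window_ms
  attr(out, "config_hash") <- result$config_hash
  attr(out, "mesh_dims") <- c(result$mesh$nx, result$mesh$ny,
                              result$mesh$lx_mm, result$mesh$ly_mm)
  class(out) <- c("activation_map", class(out))
  out
}

#' Relative L1 activation-map error
#'
#' `err = sum |AT_i - AT_ref_i| / sum |AT_ref_i|` over the valid nodes of
#' the reference map, with the coarse map interpolated to the reference
#' nodes through the bilinear element basis (nested structured meshes).
#'
#' @param map A coarse `activation_map` (with its `mesh`).
#' @param map_ref The reference `activation_map`.
#' @param mesh,mesh_ref The meshes the maps live on.
#' @return The scalar error, with the excluded-node fraction in
#'   `attr(, "excluded_frac")`.
#' @export
relative_error <- function(map, map_ref, mesh, mesh_ref) {
  stopifnot(inherits(map, "activation_map"),
            inherits(map_ref, "activation_map"))
  at_c <- map$at_ms
  # interpolated coarse AT at reference nodes; corners must all be valid
  vals <- ifelse(map$valid, at_c, NA_real_)
  at_i <- interp_nodal(mesh, vals, mesh_ref$nodes$x_mm, mesh_ref$nodes$y_mm)
  ok <- map_ref$valid & is.finite(at_i)
  if (!any(ok)) stop("validity sets of the two maps are disjoint")
  err <- sum(abs(at_i[ok] - map_ref$at_ms[ok])) / sum(abs(map_ref$at_ms[ok]))
  attr(err, "excluded_frac") <- 1 - mean(ok[map_ref$valid])
  err
}

#' Dominant frequency at probe nodes
#'
#' Peak of the magnitude spectrum of the detrended (mean-removed,
#' Hann-windowed, zero-padded) potential trace; spectral resolution is at
#' most `resolution_hz`.
#'
#' @param result A [run_monodomain()] result with `probe_traces` covering
#'   at least 2 s, or a tibble with `t_ms` plus one column per probe.
#' @param t_min_ms Discard the trace before this time (transients).
#' @param resolution_hz Maximum spectral resolution (default 0.25 Hz).
#' @param f_max_hz Upper frequency bound for the peak search.
#' @return A tibble `probe`, `dominant_hz`, `power`, `silent`.
#' @export
dominant_frequency <- function(result, t_min_ms = 0, resolution_hz = 0.25,
                               f_max_hz = 30) {
  traces <- if (inherits(result, "simulation_result")) {
    if (is.null(result$probe_traces)) {
      stop("no probe traces recorded; set `probes` in solver_config()")
    }
    result$probe_traces
  } else result
  t <- traces$t_ms
  keep <- t >= t_min_ms
  t <- t[keep]
  span_s <- (max(t) - min(t)) / 1000
  if (span_s < 2) stop("need at least 2 s of trace after `t_min_ms`")
  dt_s <- (t[2] - t[1]) / 1000
  nfft <- 2^ceiling(log2(max(length(t), 1 / (resolution_hz * dt_s))))
  cols <- setdiff(names(traces), "t_ms")
  purrr::map_dfr(cols, function(cn) {
    v <- traces[[cn]][keep]
    if (max(v) - min(v) < 1) {
      return(tibble::tibble(probe = cn, dominant_hz = NA_real_,
                            power = 0, silent = TRUE))
    }
    v <- v - mean(v)
    w <- 0.5 * (1 - cos(2 * pi * seq_along(v) / (length(v) + 1)))  # Hann
    sp <- abs(stats::fft(c(v * w, rep(0, nfft - length(v)))))^2
    freqs <- (seq_len(nfft) - 1) / (nfft * dt_s)
    band <- freqs > 0.5 & freqs <= f_max_hz
    i <- which(band)[which.max(sp[band])]
    tibble::tibble(probe = cn, dominant_hz = freqs[i], power = sp[i],
                   silent = FALSE)
  })
}

#' Phase singularities in a potential frame
#'
#' The activation phase is `phi = atan2(u(t - tau) - u_mean, u(t) -
#' u_mean)` per node, with `tau` = 8 ms and `u_mean` the node's temporal
#' mean over the recorded window. A phase singularity sits in any element
#' whose discrete phase winding around its corners is +-2 pi.
#'
#' @param result A [run_monodomain()] result with recorded frames.
#' @param t_ms Frame time to analyze (nearest recorded frame is used).
#' @param tau_ms Phase delay (default 8 ms).
#' @return A tibble `x_mm`, `y_mm`, `chirality` (+-1), `elem`, `t_ms`.
#' @export
phase_singularities <- function(result, t_ms, tau_ms = 8) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(result$frames)) stop("no frames recorded")
  ft <- result$frame_t_ms
  i_now <- which.min(abs(ft - t_ms))
  stride <- ft[2] - ft[1]
  lag <- round(tau_ms / stride)
  if (i_now - lag < 1) stop("insufficient history for the phase delay")
  ubar <- rowMeans(result$frames)
  phi <- atan2(result$frames[, i_now - lag] - ubar,
               result$frames[, i_now] - ubar)
  find_phase_singularities(phi, result$mesh, t_frame = ft[i_now])
}

# winding-number scan of a nodal phase field over all elements
find_phase_singularities <- function(phi, mesh, t_frame = NA_real_) {
  el <- mesh$elems
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  d1 <- wrap(phi[el[, 2]] - phi[el[, 1]])
  d2 <- wrap(phi[el[, 3]] - phi[el[, 2]])
  d3 <- wrap(phi[el[, 4]] - phi[el[, 3]])
  d4 <- wrap(phi[el[, 1]] - phi[el[, 4]])
  wind <- (d1 + d2 + d3 + d4) / (2 * pi)
  hit <- which(abs(wind) > 0.5)
  cx <- (mesh$nodes$x_mm[el[hit, 1]] + mesh$nodes$x_mm[el[hit, 2]] +
           mesh$nodes$x_mm[el[hit, 3]] + mesh$nodes$x_mm[el[hit, 4]]) / 4
  cy <- (mesh$nodes$y_mm[el[hit, 1]] + mesh$nodes$y_mm[el[hit, 2]] +
           mesh$nodes$y_mm[el[hit, 3]] + mesh$nodes$y_mm[el[hit, 4]]) / 4
  tibble::tibble(x_mm = cx, y_mm = cy, chirality = sign(wind[hit]),
                 elem = hit, t_ms = t_frame)
}

#' Track rotor tips across frames
#'
#' Detects phase singularities in every recorded frame (after an initial
#' settling margin for the phase delay) and links them over time by
#' nearest-neighbor association within `link_radius_mm`.
#'
#' @param result A [run_monodomain()] result with frames.
#' @param t_start_ms First frame time to analyze.
#' @param tau_ms Phase delay.
#' @param link_radius_mm Maximum tip displacement between consecutive
#'   frames for track linking (default 10 mm).
#' @return A `rotor_tracks` tibble: `track`, `t_ms`, `x_mm`, `y_mm`,
#'   `chirality`.
#' @export
track_rotors <- function(result, t_start_ms = NULL, tau_ms = 8,
                         link_radius_mm = 10) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(result$frames)) stop("no frames recorded")
  ft <- result$frame_t_ms
  stride <- ft[2] - ft[1]
  first <- max(round(tau_ms / stride) + 1, 2)
  if (!is.null(t_start_ms)) first <- max(first, which(ft >= t_start_ms)[1])
  ubar <- rowMeans(result$frames)
  lag <- round(tau_ms / stride)

  active <- list()  # open tracks: list(id, x, y, chir)
  rows <- list()
  next_id <- 1L
  for (i in seq(first, length(ft))) {
    phi <- atan2(result$frames[, i - lag] - ubar,
                 result$frames[, i] - ubar)
    ps <- find_phase_singularities(phi, result$mesh, ft[i])
    assigned <- rep(FALSE, nrow(ps))
    new_active <- list()
    for (tr in active) {
      if (nrow(ps) > 0) {
        d <- sqrt((ps$x_mm - tr$x)^2 + (ps$y_mm - tr$y)^2)
        d[assigned | ps$chirality != tr$chir] <- Inf
        j <- which.min(d)
        if (length(j) == 1 && is.finite(d[j]) && d[j] <= link_radius_mm) {
          assigned[j] <- TRUE
          tr$x <- ps$x_mm[j]; tr$y <- ps$y_mm[j]
          rows[[length(rows) + 1]] <- tibble::tibble(
            track = tr$id, t_ms = ft[i], x_mm = tr$x, y_mm = tr$y,
            chirality = tr$chir)
          new_active[[length(new_active) + 1]] <- tr
        }
      }
    }
    if (nrow(ps) > 0) {
      for (j in which(!assigned)) {
        tr <- list(id = next_id, x = ps$x_mm[j], y = ps$y_mm[j],
                   chir = ps$chirality[j])
        next_id <- next_id + 1L
        rows[[length(rows) + 1]] <- tibble::tibble(
          track = tr$id, t_ms = ft[i], x_mm = tr$x, y_mm = tr$y,
          chirality = tr$chir)
        new_active[[length(new_active) + 1]] <- tr
      }
    }
    active <- new_active
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(track = integer(0), t_ms = numeric(0), x_mm = numeric(0),
                   y_mm = numeric(0), chirality = numeric(0))
  }
  class(out) <- c("rotor_tracks", class(out))
  out
}

#' Classify a rotor track
#'
#' `anchored`: bounding radius < `anchor_radius_mm` and lifetime >
#' `sustained_ms`; `wandering`: larger excursion but sustained;
#' `terminated`: anything shorter. A track elongated along a line
#' (aspect ratio > 3) is additionally flagged as a functional line of
#' block. If a CV field is supplied, the mean CV within the track's
#' bounding region is reported.
#'
#' @param track Tibble `t_ms`, `x_mm`, `y_mm` for one rotor track.
#' @param cv_field Optional tibble `x_mm`, `y_mm`, `cv`.
#' @param anchor_radius_mm Anchoring radius threshold (default 5 mm).
#' @param sustained_ms Sustained-lifetime threshold (default 1000 ms).
#' @return One-row tibble: `label`, `lifetime_ms`, `bounding_radius_mm`,
#'   `aspect_ratio`, `line_of_block`, `mean_cv`.
#' @export
classify_rotor <- function(track, cv_field = NULL, anchor_radius_mm = 5,
                           sustained_ms = 1000) {
  lifetime <- max(track$t_ms) - min(track$t_ms)
  cx <- mean(track$x_mm); cy <- mean(track$y_mm)
  r <- sqrt((track$x_mm - cx)^2 + (track$y_mm - cy)^2)
  br <- max(r)
  # principal-axis aspect ratio of the tip cloud
  ar <- if (nrow(track) >= 3 && br > 1e-9) {
    ev <- eigen(stats::cov(cbind(track$x_mm, track$y_mm)),
                symmetric = TRUE, only.values = TRUE)$values
    sqrt(max(ev[1], 1e-300) / max(ev[2], 1e-12))
  } else 1
  label <- if (lifetime > sustained_ms) {
    if (br < anchor_radius_mm) "anchored" else "wandering"
  } else "terminated"
  mean_cv <- NA_real_
  if (!is.null(cv_field)) {
    inside <- cv_field$x_mm >= min(track$x_mm) - 1 &
      cv_field$x_mm <= max(track$x_mm) + 1 &
      cv_field$y_mm >= min(track$y_mm) - 1 &
      cv_field$y_mm <= max(track$y_mm) + 1
    if (any(inside)) mean_cv <- mean(cv_field$cv[inside])
  }
  tibble::tibble(label = label, lifetime_ms = lifetime,
                 bounding_radius_mm = br, aspect_ratio = ar,
                 line_of_block = label != "terminated" & ar > 3,
                 mean_cv = mean_cv)
}

#' Vulnerable-window scan
#'
#' Runs one simulation per S1-S2 coupling interval and classifies each
#' outcome: `"early"` (S2 blocked, no propagated wave), `"reentry"` (a
#' phase singularity persists longer than `reentry_persist_ms` after S2),
#' `"late"` (a single propagated extra beat that extinguishes). The
#' vulnerable window is the contiguous range of intervals labeled reentry;
#' a non-contiguous structure is reported as-is with a warning.
#'
#' @param protocols Named list of S1-S2 protocols from [s1s2_preset()].
#' @param run_fn Function taking a protocol and returning a
#'   [run_monodomain()] result with frames recorded (stride <= 5 ms).
#' @param s2_time_ms The S2 delivery time per protocol (vector or single
#'   value); inferred from the protocols when `NULL`.
#' @param reentry_persist_ms Persistence threshold for the reentry label
#'   (default 250 ms, about two rotation periods).
#' @return A `vw_scan` tibble: `ci_ms`, `outcome`, `n_ps_frames`,
#'   `ps_span_ms`, `late_activity`; window bounds in `attr(, "window_ms")`.
#' @export
vulnerable_window_scan <- function(protocols, run_fn, s2_time_ms = NULL,
                                   reentry_persist_ms = 250) {
  cis <- as.numeric(sub("^ci_", "", names(protocols)))
  if (is.null(s2_time_ms)) {
    s2_time_ms <- vapply(protocols, function(p) max(p$delay_ms), numeric(1))
  }
  s2_time_ms <- rep_len(s2_time_ms, length(protocols))

  rows <- purrr::map2_dfr(protocols, s2_time_ms, function(pr, t2) {
    res <- run_fn(pr)
    ft <- res$frame_t_ms
    post <- which(ft > t2 + 10)
    ubar <- rowMeans(res$frames)
    stride <- ft[2] - ft[1]
    lag <- max(1, round(8 / stride))
    ps_t <- numeric(0)
    for (i in post) {
      if (i - lag < 1) next
      phi <- atan2(res$frames[, i - lag] - ubar, res$frames[, i] - ubar)
      ps <- find_phase_singularities(phi, res$mesh)
      if (nrow(ps) > 0) ps_t <- c(ps_t, ft[i])
    }
    # longest contiguous run of PS-bearing frames
    span <- 0
    if (length(ps_t) > 1) {
      gaps <- diff(ps_t) > 2.5 * stride
      runs <- split(ps_t, cumsum(c(0, gaps)))
      span <- max(vapply(runs, function(r) max(r) - min(r), numeric(1)))
    }
    # did S2 propagate? look for activation after S2 away from the S2 site
    s2row <- pr[nrow(pr), ]
    far <- sqrt((res$activation$x_mm - s2row$cx_mm)^2 +
                  (res$activation$y_mm - s2row$cy_mm)^2) >
      (s2row$size_mm + 5)
    at <- res$activation$at_ms
    propagated <- any(is.finite(at[far]) & at[far] > t2 + 2, na.rm = TRUE)
    # residual activity at the end of the run (last two frames differ)
    nf <- length(ft)
    late_act <- max(abs(res$frames[, nf] - res$frames[, nf - 1])) > 1
    outcome <- if (span >= reentry_persist_ms) "reentry"
      else if (!propagated) "early" else "late"
    tibble::tibble(outcome = outcome, n_ps_frames = length(ps_t),
                   ps_span_ms = span, late_activity = late_act)
  })
  out <- dplyr::bind_cols(tibble::tibble(ci_ms = cis), rows)
  re <- which(out$outcome == "reentry")
  if (length(re) > 0 && any(diff(re) > 1)) {
    warning("non-contiguous reentry window; reporting outcomes as-is")
  }
  attr(out, "window_ms") <- if (length(re) > 0) {
    c(min(out$ci_ms[re]), max(out$ci_ms[re]))
  } else c(NA_real_, NA_real_)
  class(out) <- c("vw_scan", class(out))
  out
}

#' @method autoplot vw_scan
#' @export
autoplot.vw_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ci_ms, y = 1,
                                       fill = .data$outcome)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "S1-S2 coupling interval (ms)", y = NULL,
                  fill = "outcome")
}
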