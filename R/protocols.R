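#' Define a stimulation impulse
#'
#' An impulse delivers a rectangular current pulse on a spatial support —
#' a sphere (disc on 2D sheets) of radius `size_mm`, a cube (square) of
#' side `size_mm`, or a planar slab `x <= size_mm` — with a given amplitude
#' (in 1/s on the normalized potential; 200 1/s corresponds to 20 mV/ms on
#' the 100 mV span), duration, repetition frequency and onset delay.
#'
#' @param shape `"sphere"`, `"cube"` or `"slab"`.
#' @param center_mm Length-2 center (ignored for `"slab"`).
#' @param size_mm Radius (sphere), side (cube), or right boundary (slab), mm.
#' @param amplitude_per_s Amplitude, 1/s on the normalized potential.
#' @param duration_ms Pulse duration, ms.
#' @param frequency_hz Repetition frequency, Hz; 0 for a single pulse.
#' @param delay_ms Onset delay, ms.
#' @param n_pulses Number of pulses; `Inf` for unlimited.
#' @return A tibble row describing the impulse.
#' @export
impulse <- function(shape = c("sphere", "cube", "slab"), center_mm = c(0, 0),
                    size_mm = 6, amplitude_per_s = 200, duration_ms = 5,
                    frequency_hz = 0, delay_ms = 0, n_pulses = Inf) {
  shape <- match.arg(shape)
  stopifnot(size_mm > 0, amplitude_per_s > 0, duration_ms > 0)
  if (frequency_hz > 0 && duration_ms >= 1000 / frequency_hz) {
    stop("pulse duration must be shorter than the pacing period")
  }
  tibble::tibble(
    shape = shape, cx_mm = center_mm[1],
    cy_mm = if (length(center_mm) > 1) center_mm[2] else 0,
    size_mm = size_mm, amplitude_per_s = amplitude_per_s,
    duration_ms = duration_ms, frequency_hz = frequency_hz,
    delay_ms = delay_ms, n_pulses = n_pulses
  )
}

#' Assemble a stimulation protocol
#'
#' @param ... Impulse rows from [impulse()] (or tibbles of them).
#' @param label Protocol tag.
#' @return An object of class `stim_protocol` (a tibble of impulses).
#' @export
protocol <- function(..., label = "custom") {
  p <- dplyr::bind_rows(...)
  stopifnot(nrow(p) >= 1)
  attr(p, "label") <- label
  class(p) <- c("stim_protocol", class(p))
  p
}

#' Applied current at a point and time
#'
#' Sum over the protocol's impulses of `amplitude * [x inside support] *
#' [t inside an active window]`; active windows recur at the impulse period
#' starting at the onset delay. Overlapping impulses superpose.
#'
#' @param x_mm,y_mm Query position, mm.
#' @param t_ms Query time, ms.
#' @param protocol A [protocol()].
#' @return Applied current in 1/s (normalized-potential units).
#' @export
applied_current <- function(x_mm, y_mm, t_ms, protocol) {
  total <- 0
  for (k in seq_len(nrow(protocol))) {
    p <- protocol[k, ]
    inside <- switch(p$shape,
      sphere = (x_mm - p$cx_mm)^2 + (y_mm - p$cy_mm)^2 <= p$size_mm^2,
      cube = abs(x_mm - p$cx_mm) <= p$size_mm / 2 &
        abs(y_mm - p$cy_mm) <= p$size_mm / 2,
      slab = x_mm <= p$size_mm
    )
    if (!inside) next
    tloc <- t_ms - p$delay_ms
    if (tloc < 0) next
    period <- if (p$frequency_hz > 0) 1000 / p$frequency_hz else Inf
    kp <- if (is.finite(period)) floor(tloc / period) else 0
    if (kp >= p$n_pulses) next
    phase <- tloc - kp * ifelse(is.finite(period), period, 0)
    if (phase <= p$duration_ms) total <- total + p$amplitude_per_s
  }
  total
}

#' Physiological baseline pacing preset
#'
#' Three spherical impulses standing in for the main inter-atrial
#' connections (Bachmann's bundle, fossa ovalis, coronary sinus
#' musculature): radius 6 mm (7 mm for the paroxysmal variant), amplitude
#' 200 1/s, duration 5 ms, repeating at 1.82 Hz with per-cycle onset delays
#' of 0, 10 and 20 ms. On synthetic sheets the default landmarks sit along
#' the x = 0 edge, spaced 15 mm apart.
#'
#' @param mesh A [gen_sheet_mesh()] mesh (for default landmarks).
#' @param landmarks Optional 3x2 matrix of landmark coordinates, mm.
#' @param variant `"persistent"` (r = 6 mm) or `"paroxysmal"` (r = 7 mm).
#' @param frequency_hz Baseline frequency (default 1.82 Hz).
#' @return A `stim_protocol` with three impulses.
#' @export
baseline_preset <- function(mesh, landmarks = NULL,
                            variant = c("persistent", "paroxysmal"),
                            frequency_hz = 1.82) {
  variant <- match.arg(variant)
  r <- if (variant == "paroxysmal") 7 else 6
  if (is.null(landmarks)) {
    y0 <- mesh$ly_mm / 2
    landmarks <- rbind(c(0, min(y0 + 15, mesh$ly_mm)),
                       c(0, y0),
                       c(0, max(y0 - 15, 0)))
  }
  stopifnot(nrow(landmarks) == 3)
  inb <- landmarks[, 1] >= 0 & landmarks[, 1] <= mesh$lx_mm &
    landmarks[, 2] >= 0 & landmarks[, 2] <= mesh$ly_mm
  if (!all(inb)) stop("landmarks fall outside the mesh")
  protocol(
    impulse("sphere", landmarks[1, ], r, 200, 5, frequency_hz, delay_ms = 0),
    impulse("sphere", landmarks[2, ], r, 200, 5, frequency_hz, delay_ms = 10),
    impulse("sphere", landmarks[3, ], r, 200, 5, frequency_hz, delay_ms = 20),
    label = paste0("baseline-", variant)
  )
}

#' Ectopic trigger preset
#'
#' A cubic impulse of side 6 mm at 8.26 Hz (clinically derived
#' pulmonary-vein trigger frequency), amplitude 200 1/s, duration 5 ms. On
#' synthetic sheets the trigger is placed in the corner opposite the
#' baseline landmarks, mimicking pulmonary-vein remoteness.
#'
#' @param mesh A [gen_sheet_mesh()] mesh.
#' @param center_mm Trigger center; default is 6 mm inside the far corner.
#' @param frequency_hz Trigger frequency (default 8.26 Hz).
#' @param delay_ms Trigger onset (default 0: superimposed on the baseline).
#' @return A `stim_protocol` with one cubic impulse.
#' @export
trigger_preset <- function(mesh, center_mm = NULL, frequency_hz = 8.26,
                           delay_ms = 0) {
  if (is.null(center_mm)) {
    center_mm <- c(mesh$lx_mm - 6, mesh$ly_mm - 6)
  }
  if (center_mm[1] < 0 || center_mm[1] > mesh$lx_mm ||
      center_mm[2] < 0 || center_mm[2] > mesh$ly_mm) {
    stop("trigger center falls outside the mesh")
  }
  protocol(
    impulse("cube", center_mm, 6, 200, 5, frequency_hz, delay_ms = delay_ms),
    label = "trigger"
  )
}

#' S1-S2 pinwheel protocols
#'
#' One S1 stimulus followed by one S2 premature stimulus at each listed
#' coupling interval; returns one protocol per interval for scanning the
#' vulnerable window.
#'
#' @param s1 An [impulse()] row for S1 (single pulse).
#' @param s2 An [impulse()] row template for S2 (its delay is overwritten).
#' @param coupling_intervals_ms Positive, sorted S1-to-S2 intervals, ms.
#' @return A named list of `stim_protocol`s, one per coupling interval.
#' @export
s1s2_preset <- function(s1, s2, coupling_intervals_ms) {
  stopifnot(all(coupling_intervals_ms > 0),
            !is.unsorted(coupling_intervals_ms))
  s1$frequency_hz <- 0; s1$n_pulses <- 1
  lapply(stats::setNames(coupling_intervals_ms,
                         paste0("ci_", coupling_intervals_ms)), function(ci) {
    s2i <- s2
    s2i$delay_ms <- s1$delay_ms + ci
    s2i$frequency_hz <- 0
    s2i$n_pulses <- 1
    protocol(s1, s2i, label = sprintf("s1s2-ci%g", ci))
  })
}
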