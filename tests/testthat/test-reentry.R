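test_that("activation map finds the max-slope instant of a tanh upstroke", {
  mesh <- gen_sheet_mesh(10, 10, 1)
  n <- nrow(mesh$nodes)
  ft <- seq(0, 100, by = 1)
  t0 <- 30 + 0.4 * mesh$nodes$x_mm  # per-node inflection time
  frames <- -80 + 100 / (1 + exp(-outer(-t0, ft, `+`) / 2))
  res <- fake_result(mesh, frames, ft)
  am <- activation_map(res, window_ms = c(0, 100))
  expect_true(all(am$valid))
  expect_lt(max(abs(am$at_ms - t0)), 1.01)  # within one sample
  expect_error(activation_map(res, window_ms = c(50, 50)), "empty")
})

test_that("planar-wave AT slope equals the inverse speed", {
  sub <- strip_substrate(cv = 0.7, h = 0.5, lx = 25, ly = 4)
  res <- run_monodomain(sub, planar_protocol(),
                        solver_config(dt_ms = 0.1, t_end_ms = 80))
  am <- activation_map(res)
  mid <- am$x_mm > 6 & am$x_mm < 19 & am$valid
  fit <- stats::lm(at_ms ~ x_mm, data = am[mid, ])
  speed_meas <- atrialcv:::measure_planar_speed(res)
  expect_equal(stats::coef(fit)[["x_mm"]], 1 / speed_meas, tolerance = 0.02)
  # nodes that never depolarize are invalid
  expect_true(all(!is.na(am$at_ms[am$valid])))
})

test_that("never-depolarized nodes fall below the slope threshold", {
  mesh <- gen_sheet_mesh(10, 10, 1)
  n <- nrow(mesh$nodes)
  ft <- seq(0, 50, by = 1)
  frames <- matrix(-81, n, length(ft))
  active <- mesh$nodes$x_mm < 5
  frames[active, ] <- -80 + 100 / (1 + exp(-(rep(1, sum(active)) %o% ft - 20) / 2))
  am <- activation_map(fake_result(mesh, frames, ft), window_ms = c(0, 50))
  expect_true(all(am$valid[active]))
  expect_true(all(!am$valid[!active]))
})

test_that("relative L1 error: identity, homogeneity, closed form", {
  mesh <- gen_sheet_mesh(10, 10, 1)
  mk <- function(at) {
    out <- tibble::tibble(node = mesh$nodes$node, x_mm = mesh$nodes$x_mm,
                          y_mm = mesh$nodes$y_mm, at_ms = at,
                          max_slope = 1, valid = TRUE)
    class(out) <- c("activation_map", class(out))
    out
  }
  at0 <- 10 + mesh$nodes$x_mm
  expect_equal(relative_error(mk(at0), mk(at0), mesh, mesh), 0,
               ignore_attr = TRUE)
  # both maps scaled by alpha: error unchanged (homogeneity of the ratio)
  e1 <- relative_error(mk(at0 + 1), mk(at0), mesh, mesh)
  e2 <- relative_error(mk(3 * (at0 + 1)), mk(3 * at0), mesh, mesh)
  expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-12)
  # uniform +1 ms shift against a mean-50 reference: err = 1/50
  at50 <- rep(50, nrow(mesh$nodes))
  e3 <- relative_error(mk(at50 + 1), mk(at50), mesh, mesh)
  expect_equal(as.numeric(e3), 1 / 50, tolerance = 1e-12)
  # disjoint validity errors out
  bad <- mk(at0); bad$valid <- FALSE; bad$at_ms <- NA_real_
  expect_error(relative_error(bad, mk(at0), mesh, mesh), "disjoint")
})

test_that("relative error interpolates across nested meshes", {
  coarse <- gen_sheet_mesh(10, 10, 1)
  fine <- gen_sheet_mesh(10, 10, 0.5)
  mk <- function(mesh, at) {
    out <- tibble::tibble(node = mesh$nodes$node, x_mm = mesh$nodes$x_mm,
                          y_mm = mesh$nodes$y_mm, at_ms = at, max_slope = 1,
                          valid = TRUE)
    class(out) <- c("activation_map", class(out))
    out
  }
  # linear field is reproduced exactly by bilinear interpolation
  mc <- mk(coarse, 5 + 2 * coarse$nodes$x_mm + coarse$nodes$y_mm)
  mf <- mk(fine, 5 + 2 * fine$nodes$x_mm + fine$nodes$y_mm)
  expect_lt(as.numeric(relative_error(mc, mf, coarse, fine)), 1e-12)
})

test_that("dominant frequency: pure tones and tone mixtures", {
  t_ms <- seq(0, 4000, by = 2)
  tr <- tibble::tibble(
    t_ms = t_ms,
    five = 40 * sin(2 * pi * 5 * t_ms / 1000),
    mix = 40 * sin(2 * pi * 3 * t_ms / 1000) +
      80 * sin(2 * pi * 8 * t_ms / 1000),
    flat = rep(0, length(t_ms))
  )
  df <- dominant_frequency(tr)
  expect_equal(df$dominant_hz[df$probe == "five"], 5, tolerance = 0.25)
  expect_equal(df$dominant_hz[df$probe == "mix"], 8, tolerance = 0.25)
  expect_true(df$silent[df$probe == "flat"])
  expect_error(dominant_frequency(tr[tr$t_ms < 1000, ]), "2 s")
})

test_that("phase singularity detection on constructed fields", {
  # planar phase field: no winding anywhere
  mesh <- gen_sheet_mesh(30, 30, 1)
  phi_planar <- ((mesh$nodes$x_mm / 5) %% (2 * pi)) - pi
  ps0 <- atrialcv:::find_phase_singularities(phi_planar, mesh)
  expect_equal(nrow(ps0), 0)
  # Archimedean spiral: exactly one singularity at the core
  sp <- make_fixture("spiral-phase-field")
  ps1 <- atrialcv:::find_phase_singularities(sp$phase, sp$mesh)
  expect_equal(nrow(ps1), 1)
  expect_lt(sqrt((ps1$x_mm - sp$core[1])^2 + (ps1$y_mm - sp$core[2])^2),
            sp$mesh$h_mm * 1.5)
  # mirrored spiral pair: two singularities with opposite chirality
  m <- gen_sheet_mesh(60, 30, 0.5)
  th1 <- atan2(m$nodes$y_mm - 15, m$nodes$x_mm - 15)
  th2 <- atan2(m$nodes$y_mm - 15, m$nodes$x_mm - 45)
  r1 <- sqrt((m$nodes$x_mm - 15)^2 + (m$nodes$y_mm - 15)^2)
  r2 <- sqrt((m$nodes$x_mm - 45)^2 + (m$nodes$y_mm - 15)^2)
  left <- m$nodes$x_mm < 30
  phi <- ifelse(left, th1 + 2 * pi * r1 / 10, -th2 + 2 * pi * r2 / 10)
  phi <- (phi + pi) %% (2 * pi) - pi
  ps2 <- atrialcv:::find_phase_singularities(phi, m)
  # keep the two dominant cores (the seam between half-fields may cut
  # through elements; restrict to the core neighborhoods)
  near1 <- ps2[sqrt((ps2$x_mm - 15)^2 + (ps2$y_mm - 15)^2) < 3, ]
  near2 <- ps2[sqrt((ps2$x_mm - 45)^2 + (ps2$y_mm - 15)^2) < 3, ]
  expect_equal(nrow(near1), 1)
  expect_equal(nrow(near2), 1)
  expect_equal(near1$chirality * near2$chirality, -1)
})

test_that("phase from delayed potential finds a rotating source", {
  # synthetic rotating wave u(x, t) = cos(theta - omega t) on a ring
  mesh <- gen_sheet_mesh(20, 20, 0.5)
  th <- atan2(mesh$nodes$y_mm - 10, mesh$nodes$x_mm - 10)
  ft <- seq(0, 200, by = 2)
  omega <- 2 * pi / 100  # 10 Hz rotation
  frames <- -70 + 30 * cos(outer(th, omega * ft, `-`))
  res <- fake_result(mesh, frames, ft)
  ps <- phase_singularities(res, t_ms = 150)
  expect_gte(nrow(ps), 1)
  d <- sqrt((ps$x_mm - 10)^2 + (ps$y_mm - 10)^2)
  expect_lt(min(d), 2)
})

test_that("rotor classification thresholds and order invariance", {
  set.seed(5)
  jitter_track <- tibble::tibble(
    t_ms = seq(0, 2000, by = 10),
    x_mm = 15 + rnorm(201, sd = 0.5), y_mm = 15 + rnorm(201, sd = 0.5))
  expect_equal(classify_rotor(jitter_track)$label, "anchored")
  drift <- tibble::tibble(t_ms = seq(0, 1500, by = 10),
                          x_mm = seq(5, 25, length.out = 151), y_mm = 10)
  cls <- classify_rotor(drift)
  expect_equal(cls$label, "wandering")
  expect_true(cls$line_of_block)  # elongated trajectory
  short <- tibble::tibble(t_ms = seq(0, 300, by = 10), x_mm = 10, y_mm = 10)
  expect_equal(classify_rotor(short)$label, "terminated")
  # permuting the samples does not change the label
  perm <- drift[sample(nrow(drift)), ]
  expect_equal(classify_rotor(perm)$label, "wandering")
  # mean CV restricted to the track's neighborhood
  cvf <- tibble::tibble(x_mm = rep(seq(0, 30, 1), 31),
                        y_mm = rep(seq(0, 30, 1), each = 31), cv = 0.4)
  expect_equal(classify_rotor(drift, cvf)$mean_cv, 0.4)
})

test_that("rotor tracking links a moving synthetic tip", {
  mesh <- gen_sheet_mesh(20, 20, 0.5)
  ft <- seq(0, 300, by = 2)
  omega <- 2 * pi / 100
  # core drifts slowly to the right
  frames <- sapply(seq_along(ft), function(i) {
    cx <- 8 + 0.01 * ft[i]
    th <- atan2(mesh$nodes$y_mm - 10, mesh$nodes$x_mm - cx)
    -70 + 30 * cos(th - omega * ft[i])
  })
  res <- fake_result(mesh, frames, ft)
  tr <- track_rotors(res)
  expect_gt(nrow(tr), 10)
  main <- dplyr::count(tr, track, sort = TRUE)$track[1]
  tt <- tr[tr$track == main, ]
  expect_gt(max(tt$t_ms) - min(tt$t_ms), 200)
})
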