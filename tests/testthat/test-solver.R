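test_that("assembly: Neumann kernel, total mass, single-element oracle", {
  mesh <- gen_sheet_mesh(10, 8, 1)
  sub <- build_substrate(mesh, rep(0.7, nrow(mesh$nodes)))
  sys <- assemble_system(sub)
  ones <- rep(1, nrow(mesh$nodes))
  # constants in the stiffness kernel (pure Neumann)
  expect_lt(max(abs(sys$stiffness %*% ones)),
            1e-10 * max(abs(sys$stiffness)))
  # partition of unity: total mass = sheet area
  expect_equal(sum(sys$mass), 80, tolerance = 1e-10)
  expect_true(Matrix::isSymmetric(sys$mass))
  expect_true(Matrix::isSymmetric(sys$stiffness))

  # unit square, one bilinear element, D = sigma I: textbook 4x4 stiffness
  # (textbook uses counterclockwise corner order; global node 3 is (0,1),
  # node 4 is (1,1), so permute with (1, 2, 4, 3))
  m1 <- gen_sheet_mesh(1, 1, 1)
  sys1 <- assemble_system(mesh = m1, Dxx = 2, Dxy = 0, Dyy = 2)
  perm <- c(1, 2, 4, 3)
  K_exact <- 2 * matrix(c(4, -1, -2, -1,
                          -1, 4, -1, -2,
                          -2, -1, 4, -1,
                          -1, -2, -1, 4), 4, 4)[perm, perm] / 6
  expect_equal(as.matrix(sys1$stiffness), K_exact, tolerance = 1e-12,
               ignore_attr = TRUE)
  M_exact <- matrix(c(4, 2, 1, 2,
                      2, 4, 2, 1,
                      1, 2, 4, 2,
                      2, 1, 2, 4), 4, 4)[perm, perm] / 36
  expect_equal(as.matrix(sys1$mass), M_exact, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("BDF coefficients match their Taylor-expansion construction", {
  # oracle: solve the Vandermonde conditions for each order
  for (ord in 1:3) {
    co <- bdf_coefficients(ord)
    # consistency: alpha = sum of history weights (constants preserved)
    expect_equal(co$alpha, sum(co$history_weights))
    # order conditions: alpha*(n+1)^p - sum_k w_k (n-k)^p = p*(n+1)^(p-1)*dt
    # in units dt=1, n=0: alpha*1^p - sum w_k (-k)^p = p for p = 1..ord
    for (p in 1:ord) {
      lhs <- co$alpha - sum(co$history_weights * (-(seq_len(ord) - 1))^p)
      expect_equal(lhs, p * 1^(p - 1), tolerance = 1e-12)
    }
    # extrapolation weights reproduce polynomials up to degree ord-1 at n+1
    for (p in 0:(ord - 1)) {
      expect_equal(sum(co$extrapolation_weights * (-(seq_len(ord) - 1))^p),
                   1^p, tolerance = 1e-12)
    }
  }
  expect_equal(bdf_coefficients(1)$alpha, 1)
  expect_equal(bdf_coefficients(2)$alpha, 3 / 2)
  expect_equal(bdf_coefficients(2)$history_weights, c(2, -1 / 2))
  expect_equal(bdf_coefficients(2)$extrapolation_weights, c(2, -1))
})

test_that("BDF order is observed on a scalar linear ODE", {
  # integrate du/dt = lambda u with the package coefficients and measure
  # the convergence rate on a Richardson triplet
  lam <- -1
  integrate_bdf <- function(ord, dt, t_end = 1) {
    n <- round(t_end / dt)
    co <- bdf_coefficients(ord)
    u <- exp(lam * dt * (0:-2))  # exact history (avoids startup-ramp order loss)
    for (k in seq_len(n)) {
      ubdf <- sum(co$history_weights * u[seq_len(ord)])
      # implicit: alpha u1 - ubdf = dt lam u1
      u1 <- ubdf / (co$alpha - dt * lam)
      u <- c(u1, u[1:2])
    }
    u[1]
  }
  for (ord in 1:3) {
    errs <- vapply(c(0.05, 0.025, 0.0125), function(dt) {
      abs(integrate_bdf(ord, dt) - exp(lam))
    }, numeric(1))
    rate <- mean(log2(errs[-3] / errs[-1]))
    expect_lt(abs(rate - ord) / ord, 0.1)
  }
})

test_that("segregated ionic step: equilibrium, determinism, divergence", {
  s <- crn_initial_state()
  n <- 4
  gates <- matrix(rep(s$gates, each = n), n)
  conc <- matrix(rep(s$conc, each = n), n)
  scales <- matrix(1, n, 3)
  up <- atrialcv:::ionic_step_cpp(rep(s$v, n), gates, conc, scales, 0.05,
                                  FALSE)
  # rest is preserved up to the (tiny) residual of the published rest state
  expect_lt(max(abs(up$gates - gates)), 1e-5)
  expect_lt(max(abs(up$conc - conc) / conc), 1e-6)
  # identical nodes update bitwise identically
  expect_identical(up$gates[1, ], up$gates[2, ])
  expect_identical(up$conc[1, ], up$conc[3, ])
  # gates stay in [0,1] even when driven hard
  up2 <- atrialcv:::ionic_step_cpp(rep(40, n), gates, conc, scales, 0.5,
                                   FALSE)
  expect_true(all(up2$gates >= 0 & up2$gates <= 1))
  expect_error(atrialcv:::ionic_step_cpp(rep(NaN, n), gates, conc, scales,
                                         0.05, FALSE), "non-finite")
  # Rush-Larsen option also preserves rest
  rl <- atrialcv:::ionic_step_cpp(rep(s$v, n), gates, conc, scales, 0.05,
                                  TRUE)
  expect_lt(max(abs(rl$gates - gates)), 1e-6)
})

test_that("unstimulated tissue stays at rest (SVI equilibrium)", {
  sub <- strip_substrate(cv = 0.7, h = 1, lx = 10, ly = 4)
  res <- run_monodomain(sub, NULL, solver_config(dt_ms = 0.1, t_end_ms = 20))
  s <- crn_initial_state()
  expect_false(res$diverged)
  expect_lt(max(abs(res$u_final - s$v)), 0.05)
  # no node registered an upstroke
  expect_lt(max(res$activation$max_slope), 0.5)
})

test_that("pure diffusion conserves the spatial mean under Neumann", {
  mesh <- gen_sheet_mesh(20, 20, 1)
  sub <- build_substrate(mesh, rep(0.7, nrow(mesh$nodes)))
  # nonuniform initial potential, ionic model off
  x <- mesh$nodes$x_mm
  init <- list(v = -80 + 20 * exp(-((x - 10)^2) / 8),
               gates = matrix(rep(crn_initial_state()$gates,
                                  each = nrow(mesh$nodes)), nrow(mesh$nodes)),
               conc = matrix(rep(crn_initial_state()$conc,
                                 each = nrow(mesh$nodes)), nrow(mesh$nodes)))
  cfg <- solver_config(dt_ms = 0.1, t_end_ms = 10, ionic = FALSE)
  res <- run_monodomain(sub, NULL, cfg, init = init)
  sys <- assemble_system(sub)
  m0 <- sum(sys$mass %*% init$v)
  m1 <- sum(sys$mass %*% res$u_final)
  expect_lt(abs(m1 - m0) / abs(m0), 1e-8)
  # diffusion flattened the bump
  expect_lt(max(res$u_final) - min(res$u_final),
            max(init$v) - min(init$v))
})

test_that("planar wave speed scales as sqrt(sigma)", {
  sub1 <- strip_substrate(cv = 0.7, h = 0.5, lx = 25, ly = 4)
  sub2 <- strip_substrate(cv = 0.7, h = 0.5, lx = 25, ly = 4)
  sub2$elem$Dxx <- 2 * sub2$elem$Dxx
  sub2$elem$Dxy <- 2 * sub2$elem$Dxy
  sub2$elem$Dyy <- 2 * sub2$elem$Dyy
  cfg <- solver_config(dt_ms = 0.1, t_end_ms = 80)
  s1 <- atrialcv:::measure_planar_speed(
    run_monodomain(sub1, planar_protocol(), cfg))
  s2 <- atrialcv:::measure_planar_speed(
    run_monodomain(sub2, planar_protocol(), cfg))
  expect_lt(abs(s2 / s1 - sqrt(2)), 0.05 * sqrt(2))
  # speed is uniform along the cable away from the ends
  res <- run_monodomain(sub1, planar_protocol(), cfg)
  act <- res$activation
  mid <- act$x_mm > 6 & act$x_mm < 19 & abs(act$y_mm - 2) < 0.6
  fit <- stats::lm(at_ms ~ x_mm, data = act[mid, ])
  rel_sd <- sd(stats::residuals(fit)) / mean(act$at_ms[mid])
  expect_lt(rel_sd, 0.02)
})

test_that("identical configurations reproduce bitwise identical maps", {
  sub <- strip_substrate(cv = 0.7, h = 0.5, lx = 15, ly = 4)
  cfg <- solver_config(dt_ms = 0.1, t_end_ms = 40)
  r1 <- run_monodomain(sub, planar_protocol(), cfg)
  r2 <- run_monodomain(sub, planar_protocol(), cfg)
  expect_identical(r1$activation$at_ms, r2$activation$at_ms)
  expect_identical(r1$u_final, r2$u_final)
  expect_identical(r1$config_hash, r2$config_hash)
})

test_that("central stimulus activates concentrically, 90-degree symmetric", {
  # below the 0.4 m/s transversal threshold the tensor is isotropic, so the
  # activation pattern must be rotation symmetric
  mesh <- gen_sheet_mesh(20, 20, 0.5)
  sub <- build_substrate(mesh, rep(0.35, nrow(mesh$nodes)))
  pr <- protocol(impulse("sphere", c(10, 10), 3, 200, 5))
  res <- run_monodomain(sub, pr, solver_config(dt_ms = 0.1, t_end_ms = 80))
  at <- matrix(res$activation$at_ms, mesh$nx, mesh$ny)
  # rotate the grid by 90 degrees: activation pattern preserved
  at90 <- t(at[, rev(seq_len(mesh$ny))])
  ok <- is.finite(at) & is.finite(at90) & at > 2
  expect_gt(mean(ok), 0.8)
  expect_lt(max(abs(at[ok] - at90[ok]) / at[ok]), 0.02)
})

test_that("BDF1 and BDF3 agree at fine time step", {
  sub <- strip_substrate(cv = 0.7, h = 0.5, lx = 15, ly = 4)
  cfg1 <- solver_config(dt_ms = 0.0125, t_end_ms = 30, bdf_order = 1)
  cfg3 <- solver_config(dt_ms = 0.0125, t_end_ms = 30, bdf_order = 3)
  r1 <- run_monodomain(sub, planar_protocol(), cfg1)
  r3 <- run_monodomain(sub, planar_protocol(), cfg3)
  ok <- is.finite(r1$activation$at_ms) & is.finite(r3$activation$at_ms)
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(r1$activation$at_ms[ok] - r3$activation$at_ms[ok])), 0.5)
})

test_that("degenerate elements are reported by index", {
  mesh <- gen_sheet_mesh(5, 5, 1)
  mesh$nodes$x_mm[8] <- mesh$nodes$x_mm[8] + 10  # fold an element
  sub <- try(build_substrate(mesh, rep(0.7, nrow(mesh$nodes))), silent = TRUE)
  expect_error(assemble_system(sub), "element")
})
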