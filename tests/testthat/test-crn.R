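test_that("I_CV ramp matches the printed breakpoints for both variants", {
  base <- remodeling_law("baseline")
  prog <- remodeling_law("progressed")
  # clamping and breakpoints
  expect_equal(icv(1.30, base), 1.0)
  expect_equal(icv(0.20, base), 0.0)
  expect_equal(icv(0.75, base), 0.5)
  expect_equal(icv(1.25, base), 1.0)
  expect_equal(icv(0.25, base), 0.0)
  expect_equal(icv(0.75, prog), (0.75 - 0.5) / 0.75)
  expect_equal(icv(0.49, prog), 0.0)
  # monotone nondecreasing, always within [0, 1]
  cvs <- seq(0, 2, by = 0.01)
  for (law in list(base, prog)) {
    v <- icv(cvs, law)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) >= 0))
  }
  expect_error(icv(-0.1, base), "nonnegative")
})

test_that("remodeled conductances follow the affine floor laws", {
  g <- remodeled_conductances(c(0.2, 0.75, 1.3))
  # fully remodeled: floors 0.5 / 0.3 / 0.5
  expect_equal(g$s_to[1], 0.5)
  expect_equal(g$s_CaL[1], 0.3)
  expect_equal(g$s_Kur[1], 0.5)
  # midpoint of the ramp
  expect_equal(g$s_to[2], 0.75)
  expect_equal(g$s_CaL[2], 0.65)
  expect_equal(g$s_Kur[2], 0.75)
  # healthy tissue: CRN values unchanged
  expect_equal(g$s_to[3], 1)
  expect_equal(g$g_to[3], 0.1652)
  expect_equal(g$g_CaL[3], 0.12375)
})

test_that("published rest state is an equilibrium of the right-hand side", {
  s <- crn_initial_state()
  r <- crn_rhs(s$v, s$gates, s$conc)
  # derivative scale: gates O(1), concentrations O(mM), voltage O(100 mV)
  expect_lt(abs(r$iion), 5e-3)
  expect_lt(max(abs(r$dgates)), 5e-4)
  expect_lt(max(abs(r$dconc)), 1e-5)
  # after a long unstimulated deSolve relaxation the state stays put
  ref <- crn_reference_trace(2000)
  expect_lt(abs(ref$v_mv[nrow(ref)] - s$v), 0.5)
})

test_that("gate relaxation pulls a zeroed m gate upward", {
  s <- crn_initial_state()
  s$gates[["m"]] <- 0
  r <- crn_rhs(0, s$gates, s$conc)  # m_inf(0 mV) is large
  expect_gt(r$dgates[["m"]], 0)
})

test_that("remodeling scales enter their currents exactly linearly", {
  s <- crn_initial_state()
  v <- -20  # plateau-ish voltage with open gates
  g <- s$gates
  g[c("oa", "oi", "ua", "ui", "d", "f", "f_Ca")] <- 0.5
  r1 <- crn_rhs(v, g, s$conc, scales = c(1, 1, 1))
  r0 <- crn_rhs(v, g, s$conc, scales = c(0.5, 0.3, 0.5))
  cur <- function(r, nm) r$currents$value[r$currents$current == nm]
  expect_equal(cur(r0, "I_to"), 0.5 * cur(r1, "I_to"), tolerance = 1e-14)
  expect_equal(cur(r0, "I_CaL"), 0.3 * cur(r1, "I_CaL"), tolerance = 1e-14)
  expect_equal(cur(r0, "I_Kur"), 0.5 * cur(r1, "I_Kur"), tolerance = 1e-14)
  # halving g_CaL halves I_CaL to floating associativity
  rh <- crn_rhs(v, g, s$conc, scales = c(1, 0.5, 1))
  expect_equal(cur(rh, "I_CaL"), 0.5 * cur(r1, "I_CaL"), tolerance = 1e-14)
  # other currents untouched
  expect_identical(cur(r0, "I_Na"), cur(r1, "I_Na"))
  expect_identical(cur(r0, "I_K1"), cur(r1, "I_K1"))
})

test_that("non-finite inputs are rejected as numerical divergence", {
  s <- crn_initial_state()
  expect_error(crn_rhs(NaN, s$gates, s$conc), "non-finite")
  expect_error(crn_rhs(Inf, s$gates, s$conc), "non-finite")
})

test_that("paced AP matches an independent adaptive-step reference", {
  stim <- function(t) ifelse(t %% 1000 <= 2 & t <= 2000, 20, 0)
  ref <- crn_reference_trace(2000, stim_fn = stim, dt_out = 0.2)
  apd_ref <- apd90_of(ref$t_ms, ref$v_mv, 1000, 2000)
  p <- cell_pace(1000, 2, dt_ms = 0.02)
  expect_false(is.na(p$apd90_ms))
  expect_lt(abs(p$apd90_ms - apd_ref) / apd_ref, 0.10)
  expect_lt(abs(p$v_rest_mv - ref$v_mv[ref$t_ms == 1000]), 2)
})

test_that("zero stimulus keeps the cell at rest, no AP reported", {
  p <- cell_pace(500, 1, stim_amp = 0, dt_ms = 0.05)
  expect_false(p$captured)
  expect_true(is.na(p$apd90_ms))
  expect_lt(max(abs(p$trace$v_mv - p$trace$v_mv[1])), 1)
})

test_that("remodeled cell has shorter APD than the unremodeled one", {
  p_healthy <- cell_pace(1000, 2, dt_ms = 0.05)
  p_remod <- cell_pace(1000, 2, dt_ms = 0.05, scales = c(0.5, 0.3, 0.5))
  expect_lt(p_remod$apd90_ms, p_healthy$apd90_ms)
})

test_that("APD90 is nondecreasing in I_CV at fixed cycle length", {
  law <- remodeling_law("baseline")
  apds <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    s <- c(law$floor_to + f * 0.5, law$floor_CaL + f * 0.7,
           law$floor_Kur + f * 0.5)
    cell_pace(1000, 2, dt_ms = 0.05, scales = s)$apd90_ms
  }, numeric(1))
  expect_true(all(diff(apds) >= 0))
})

test_that("rate adaptation: faster pacing shortens APD", {
  slow <- cell_pace(1000, 3, dt_ms = 0.05)
  fast <- cell_pace(300, 10, dt_ms = 0.05)
  expect_lt(fast$apd90_ms, slow$apd90_ms)
})

test_that("gates stay in [0,1] and concentrations positive over 10 s at 1 Hz", {
  p <- cell_pace(1000, 10, dt_ms = 0.05)
  expect_true(all(p$state$gates >= 0 & p$state$gates <= 1))
  expect_true(all(p$state$conc > 0))
  expect_false(any(is.na(p$trace$v_mv)))
  # trace stayed physiological throughout
  expect_true(all(p$trace$v_mv > -120 & p$trace$v_mv < 60))
})

test_that("parameter table carries units and sources for every entry", {
  pars <- crn_parameters()
  expect_true(all(c("g_to", "g_CaL", "g_Na") %in% pars$name))
  expect_true(all(pars$source %in% c("CRN", "cv-param")))
  expect_equal(pars$value[pars$name == "g_to"], 0.1652)
  # serializes cleanly to JSON and back
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(pars, path, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$value, pars$value)
})

test_that("normalized potential map is a consistent affine bijection", {
  v <- c(-84, 16, -81.18)
  expect_equal(normalize_potential(v), c(0, 1, (84 - 81.18) / 100))
  expect_equal(denormalize_potential(normalize_potential(v)), v)
})
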