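test_that("valve mobility switches with the gradient sign", {
  expect_equal(valve_permeability(c(-10, -1e-12, 0, 1e-12, 10), 1, 100),
               c(1, 1, 100, 100, 100))
  expect_equal(valve_permeability(c(-1, 1), 5, 5), c(5, 5))  # valve off
  expect_error(valve_permeability(0, K0 = 2, K1 = 1), "K1 >= K0")
  expect_error(valve_permeability(0, K0 = 0, K1 = 1), "K1 >= K0")
})

test_that("zero pressure gradient leaves the thickness at rest", {
  kin <- synthetic_kinematics()
  st <- bm_evolve(kin, ipad_config(), ratio = 1)
  expect_equal(max(abs(st$h - 2e-5)), 0)
  expect_equal(max(abs(st$q1)), 0)
  expect_equal(max(abs(st$Q_bm)), 0)
})

test_that("wall motion redistributes thickness while conserving line density", {
  # zero gradient but pulsating radius: the conserved density gamma*R*h is
  # frozen, so h(z, t) = h0 * R(z, 0) / R(z, t) exactly
  kin <- synthetic_kinematics(
    R_fun = function(z, t) 0.14 * (1 + 0.02 * sin(2 * pi * t / 0.5))
  )
  st <- bm_evolve(kin, ipad_config())
  expect_equal(st$h, 2e-5 * kin$R_i[, rep(1, length(kin$t))] / kin$R_i,
               tolerance = 1e-14)
})

test_that("no-flux run conserves the discrete fluid volume to machine precision", {
  kin <- synthetic_kinematics(
    p_fun = function(z, t) 1e6 * (z - 1)^2 * cos(2 * pi * t / 0.5),
    R_fun = function(z, t) 0.14 * (1 + 0.01 * sin(2 * pi * t / 0.5))
  )
  st <- bm_evolve(kin, ipad_config(), bc = "noflux")
  vol <- bm_fluid_volume(st, kin)
  expect_lt(max(abs(vol - vol[1])) / vol[1], 1e-13)
  expect_true(all(st$flux_in == 0) && all(st$flux_out == 0))
})

test_that("open boundaries balance volume change against boundary fluxes", {
  kin <- synthetic_kinematics(
    p_fun = function(z, t) 1e6 * (z - 1)^2 * cos(2 * pi * t / 0.5)
  )
  st <- bm_evolve(kin, ipad_config(), bc = "open")
  vol <- bm_fluid_volume(st, kin)
  dts <- diff(st$t)
  expected <- dts * (st$flux_out[-1] - st$flux_in[-1])
  expect_lt(max(abs(diff(vol) - expected)), 1e-12 * vol[1])
  expect_gt(max(abs(expected)), 0)  # the balance is non-trivial
})

test_that("periodic boundaries conserve volume exactly", {
  kin <- synthetic_kinematics(
    p_fun = function(z, t) 1e6 * cos(pi * z) * cos(2 * pi * t / 0.5)
  )
  st <- bm_evolve(kin, ipad_config(), bc = "periodic")
  vol <- bm_fluid_volume(st, kin)
  expect_lt(max(abs(vol - vol[1])) / vol[1], 1e-13)
})

test_that("the solver refuses a time step above its stability bound", {
  kin <- synthetic_kinematics(nt = 6, p_fun = function(z, t) 1e12 * (z - 1)^2)
  expect_error(bm_evolve(kin, ipad_config()), "stability bound")
})

test_that("flux metrics report cycle means in micrometre units", {
  # engineered run: q1 = -K1 * p_z = 1 cm/s exactly, R = 0.14, and the mid
  # station keeps h = h_bm0 (the boundary depletion never reaches it)
  cfg <- ipad_config()
  K1 <- mobility_k1(cfg)
  kin <- synthetic_kinematics(nz = 81, nt = 81, L = 8, period = 0.2,
                              p_fun = function(z, t) -z / K1)
  st <- bm_evolve(kin, cfg, ratio = 1)
  m <- flux_metrics(st, station = "mid")
  # [DERIVED: 2*pi*0.14*2e-5*1 cm^3/s in um^3/s]
  expect_equal(m$mean_flux_um3_s, 17592918.86, tolerance = 1e-9)
  expect_equal(m$mean_velocity_um_s, 1e4, tolerance = 1e-12)
  expect_equal(m$direction, 1)
  expect_equal(m$station_z, 4)
  expect_error(flux_metrics(st, cycle_window = 1:3), "invalid window")
})

test_that("flux metrics accept an explicit station index", {
  kin <- synthetic_kinematics()
  st <- bm_evolve(kin, ipad_config())
  m <- flux_metrics(st, station = 5L)
  expect_equal(m$station_z, kin$z[5])
})

test_that("bisection locates a synthetic reverse-flow threshold", {
  res <- reverse_flow_threshold(flux_fn = function(r) r - 0.0274,
                                lo = 0.005, hi = 1, tol = 1e-4)
  expect_lt(abs(res$ratio_critical - 0.0274), 1e-4)
  expect_lt(res$flux_lo, 0)
  expect_gt(res$flux_hi, 0)
  expect_error(
    reverse_flow_threshold(flux_fn = function(r) r + 1, lo = 0.005, hi = 1),
    "no reverse-flow threshold"
  )
})

test_that("bm_state tidies to a long tibble", {
  kin <- synthetic_kinematics()
  st <- bm_evolve(kin, ipad_config())
  td <- tidy(st)
  expect_equal(nrow(td), length(st$z) * length(st$t))
  expect_named(td, c("z", "t", "h", "q1", "Q_bm"))
})
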