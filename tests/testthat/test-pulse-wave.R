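test_that("wall stiffness evaluates the compliance law", {
  # Table values at the MCA radius  [DERIVED: direct evaluation]
  expect_equal(2e7 * exp(-22.53 * 0.14) + 8.65e5, 1718450.507, tolerance = 1e-8)
  expect_equal(wall_stiffness(0.14, 2e7, -22.53, 8.65e5), 2291267.343,
               tolerance = 1e-8)
  # degenerate exponential
  expect_equal(wall_stiffness(c(0.1, 1), 0, -22.53, 8.65e5),
               rep(4 * 8.65e5 / 3, 2))
  # monotone decreasing for k1 > 0, k2 < 0 (strict where the exponential is
  # resolvable, non-increasing beyond), with the k3 asymptote
  r <- seq(0.05, 1, by = 0.05)
  f <- wall_stiffness(r, 2e7, -22.53, 8.65e5)
  expect_true(all(diff(f) < 0))
  f2 <- wall_stiffness(seq(1, 2, by = 0.05), 2e7, -22.53, 8.65e5)
  expect_true(all(diff(f2) <= 0))
  expect_equal(wall_stiffness(50, 2e7, -22.53, 8.65e5), 4 * 8.65e5 / 3)
  expect_error(wall_stiffness(-0.1, 2e7, -22.53, 8.65e5), "positive")
})

test_that("state equation: values, limits, and exact round trip", {
  f <- wall_stiffness(0.14, 2e7, -22.53, 8.65e5)
  A0 <- pi * 0.14^2
  expect_equal(state_pressure(A0, A0, f), 0)
  # 10% area increase  [DERIVED: direct evaluation, ~80 mmHg]
  expect_equal(state_pressure(1.1 * A0, A0, f), 106629.6495, tolerance = 1e-8)
  # asymptote p -> p0 + f
  expect_equal(state_pressure(1e8 * A0, A0, f), f, tolerance = 1e-3)
  expect_error(state_pressure(-1, A0, f), "positive")
  # round trip exact to machine precision over a wide area range
  A <- A0 * exp(seq(log(0.5), log(3), length.out = 41))
  p <- state_pressure(A, A0, f, p0 = 123)
  expect_equal(area_from_pressure(p, A0, f, p0 = 123), A, tolerance = 1e-14)
  expect_error(area_from_pressure(f + 1, A0, f), "invalid state")
})

test_that("boundary-layer thickness: value and scaling", {
  expect_equal(boundary_layer_thickness(0.046, 0.85), 0.07888572922,
               tolerance = 1e-9)
  expect_equal(boundary_layer_thickness(0.046, 4 * 0.85),
               2 * boundary_layer_thickness(0.046, 0.85))
  expect_error(boundary_layer_thickness(0, 0.85), "positive")
})

test_that("Lax-Wendroff stepper: constant state and exact CFL-1 transport", {
  z <- seq(0, 1, length.out = 33)
  U <- matrix(2.5, 33, 2)
  expect_equal(lax_wendroff_step(U, z, 1e-3, function(U, z) U), U)
  # linear advection, CFL = 1: profile moves exactly one cell per step
  dz <- z[2] - z[1]
  u <- matrix(sin(2 * pi * z), ncol = 1)
  unew <- lax_wendroff_step(u, z, dz, function(U, z) U)
  i <- 2:32
  expect_equal(unew[i, 1], u[i - 1, 1], tolerance = 1e-12)
})

test_that("Lax-Wendroff observed order is at least 1.9", {
  # linear advection with exact boundary values; error at a fixed final time
  err <- function(n) {
    z <- seq(0, 1, length.out = n + 1)
    dz <- 1 / n
    dt <- 0.4 * dz
    steps <- 100 * n / 64          # fixed final time across resolutions
    u <- matrix(sin(2 * pi * z), ncol = 1)
    tcur <- 0
    for (s in seq_len(steps)) {
      u <- lax_wendroff_step(u, z, dt, function(U, z) U)
      tcur <- tcur + dt
      u[1, 1] <- sin(2 * pi * (0 - tcur))
      u[n + 1, 1] <- sin(2 * pi * (1 - tcur))
    }
    max(abs(u[, 1] - sin(2 * pi * (z - tcur))))
  }
  e1 <- err(64); e2 <- err(128)
  order <- log2(e1 / e2)
  expect_gte(order, 1.9)
})

test_that("Windkessel: steady limit, degenerate capacitor, RC relaxation", {
  wk <- list(R1 = 14.13, R2 = 7.2, CT = 2.4752e-3)
  st <- list(pc = 0)
  for (i in 1:20000) st <- windkessel_update(st$pc, 2, wk, 1e-4)
  expect_equal(st$p, 2 * (14.13 + 7.2), tolerance = 1e-9)
  # CT -> 0: purely resistive at the first step already
  st0 <- windkessel_update(0, 2, list(R1 = 14.13, R2 = 7.2, CT = 1e-15), 1e-4)
  expect_equal(st0$p, 2 * (14.13 + 7.2), tolerance = 1e-6)
  # step response relaxes with time constant R2*CT
  tau <- wk$R2 * wk$CT
  dt <- tau / 200
  pc <- 0
  n <- round(tau / dt)
  for (i in seq_len(n)) pc <- windkessel_update(pc, 1, wk, dt)$pc
  target <- wk$R2 * (1 - exp(-1))
  expect_equal(pc, target, tolerance = 5e-3)
})

test_that("junction solve: symmetry, conservation, continuity", {
  rho <- 1.06
  fp <- wall_stiffness(0.14, 2e7, -22.53, 8.65e5)
  fd <- wall_stiffness(0.13, 2e7, -22.53, 8.65e5)
  A0p <- pi * 0.14^2; A0d <- pi * 0.13^2
  cp <- sqrt(0.5 * fp / rho); cd <- sqrt(0.5 * fd / rho)
  j <- ipadflow:::.junction_solve(45 - 4 * cp, 20 + 4 * cd, 20 + 4 * cd,
                                  fp, fd, fd, A0p, A0d, A0d, rho,
                                  c(A0p, 45, A0d, 20, A0d, 20))
  expect_equal(j$Q[2], j$Q[3], tolerance = 1e-12)           # symmetry
  expect_lt(abs(j$Q[1] - j$Q[2] - j$Q[3]), 1e-10 * abs(j$Q[1]))
  p <- function(f, A0, A) f * (1 - sqrt(A0 / A))
  expect_lt(abs(p(fp, A0p, j$A[1]) - p(fd, A0d, j$A[2])), 1e-8)
  expect_lt(abs(p(fp, A0p, j$A[1]) - p(fd, A0d, j$A[3])), 1e-8)
})

test_that("steady inlet converges to a spatially uniform-flux steady state", {
  cfg <- ipad_config(cycles = 4L)
  hemo <- simulate_network(2.76, cfg)
  n <- length(hemo$t)
  for (seg in c("mca", "d1", "d2")) {
    Q <- hemo[[seg]]$Q[, n]
    expect_lt(diff(range(Q)) / mean(Q), 0.01)
    expect_true(all(hemo[[seg]]$A[, n] > 0))
  }
  expect_equal(mean(hemo$mca$Q[, n]), 2.76, tolerance = 0.01)
  # daughters split the parent flux equally (same geometry up to 0.1 cm)
  expect_equal(mean(hemo$d1$Q[, n]), 1.38, tolerance = 0.02)
  # outlet pressure approaches the resistive value Q (R1 + R2)
  expect_equal(hemo$d1$p[nrow(hemo$d1$p), n], 1.38 * (14.13 + 7.2),
               tolerance = 0.05)
})

test_that("zero inflow stays near rest: tapered well-balancing", {
  # regression for the characteristic source-term correction: without it the
  # strongly tapered daughters pumped a spurious steady circulation
  cfg <- ipad_config(cycles = 4L)
  hemo <- simulate_network(1e-6, cfg)
  n <- length(hemo$t)
  expect_lt(max(abs(hemo$mca$p[, n])), 100)          # dyn/cm^2, ~0.1% of pulse
  expect_lt(max(abs(hemo$d1$p[, n])), 100)
  expect_lt(max(abs(hemo$d1$Q[, n])), 0.01)
  # no spurious axial gradient inside the (untapered) MCA
  expect_lt(diff(range(hemo$mca$p[, n])), 1)
})

test_that("pulsatile run: positivity, periodic settling, diagnostics, lag", {
  hemo <- fast_hemo()
  for (seg in c("mca", "d1", "d2")) expect_true(all(hemo[[seg]]$A > 0))
  expect_lt(hemo$diagnostics$cfl_max, 1)
  expect_lt(hemo$diagnostics$junction_residual_flux, 1e-10)
  # after the full settling run the final two cycles agree within 1% of the
  # pulse amplitude (the 2-cycle run above still carries start-up transients)
  hemo8 <- default_hemo()
  cfg <- default_cfg()
  it <- final_cycle_index(hemo8$t, hemo8$period)
  i2 <- it - round(cfg$T / cfg$store_dt)
  p_last <- hemo8$mca$p[36, it]; p_prev <- hemo8$mca$p[36, i2]
  expect_lt(max(abs(p_last - p_prev)) / diff(range(p_last)), 0.01)
  # peak outlet pressure lags peak inlet flux (wave travel + Windkessel)
  t_in <- hemo8$t[it][which.max(hemo8$mca$Q[1, it])]
  t_out <- hemo8$t[it][which.max(hemo8$d1$p[nrow(hemo8$d1$p), it])]
  lag <- (t_out - t_in) %% cfg$T
  expect_gt(lag, 0)
  expect_lt(lag, cfg$T / 2)
})

test_that("simulate_network validates its inlet", {
  expect_error(simulate_network(list(1, 2), fast_cfg()), "inlet")
})

test_that("hemodynamic fields tidy into a long tibble and export to CSV", {
  hemo <- fast_hemo()
  td <- tidy(hemo, segments = "mca", final_cycle = TRUE)
  it <- final_cycle_index(hemo$t, hemo$period)
  expect_equal(nrow(td), 71 * length(it))
  expect_named(td, c("segment", "z", "t", "A", "Q", "p"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_hemo_csv(hemo, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(tidy(hemo, final_cycle = TRUE)))
})
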