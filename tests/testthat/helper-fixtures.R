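# Shared, lazily computed fixtures. The default (study-conditions) run is
# expensive (~10 s) and reused by several files; it is computed at most once
# per test session. Hemodynamics are independent of the valve ratio and the
# BM position, so one field is reused across all drainage variants.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_cfg <- function() ipad_config()

default_hemo <- function() {
  fixture("hemo_default", function() {
    cfg <- default_cfg()
    simulate_network(inlet_flux_waveform(cfg), cfg)
  })
}

default_kin <- function(eta = NULL) {
  cfg <- default_cfg()
  if (is.null(eta)) eta <- cfg$wall$eta
  fixture(paste0("kin_eta_", eta), function() {
    wall_kinematics(default_hemo(), cfg, eta = eta)
  })
}

fast_cfg <- function() ipad_config(cycles = 2L)

fast_hemo <- function() {
  fixture("hemo_fast", function() {
    cfg <- fast_cfg()
    simulate_network(inlet_flux_waveform(cfg), cfg)
  })
}

# Synthetic wall kinematics for BM-solver unit tests: prescribed analytic
# R_i(z, t) and p_isf(z, t) on a small grid, no hemodynamic run needed.
synthetic_kinematics <- function(nz = 21, nt = 101, L = 2, period = 0.5,
                                 p_fun = function(z, t) 0 * z,
                                 R_fun = function(z, t) 0.14 + 0 * z) {
  z <- seq(0, L, length.out = nz)
  tt <- seq(0, period, length.out = nt)
  p <- outer(z, tt, p_fun)
  R <- outer(z, tt, R_fun)
  structure(
    list(z = z, t = tt, R_i = R, p_isf = p,
         p_z = axial_pressure_gradient(p, z[2] - z[1]),
         geom = wall_geometry(0.14, 0.014, 0.5),
         eta = 0.5, segment = "synthetic", period = period),
    class = "wall_kinematics"
  )
}
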