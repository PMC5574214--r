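#' Build a run configuration
#'
#' Collects every parameter of the coupled pulse-wave / BM-drainage model into
#' one validated list. Defaults are the study conditions: MCA bifurcation
#' geometry, compliance constants, Windkessel elements, cardiac period and
#' solver steps as printed for the reference MCA simulation, plus documented
#' choices for the quantities the printed tables leave open (blood density,
#' wall thickness, BM position, fluid fraction, initial BM thickness).
#'
#' All values are CGS (cm, g, s, dyn) unless noted. Notable fields:
#'
#' * `vessels`: tibble with one row per segment (`mca`, `d1`, `d2`) holding
#'   upstream radius `Ru`, downstream radius `Rd` and length `L` in cm.
#' * `k1`, `k2`, `k3`: wall compliance constants of the stiffness law
#'   `Eh/r0 = k1*exp(k2*r0) + k3` (g cm^-1 s^-2, cm^-1, g cm^-1 s^-2).
#' * `nu`: kinematic viscosity of blood, cm^2 s^-1; `rho`: blood density,
#'   g cm^-3 (needed to dimensionalise the momentum equation; not printed in
#'   the parameter tables, standard value 1.06).
#' * `R1`, `R2`, `CT`: Windkessel resistances (g cm^-4 s^-1) and compliance
#'   (cm^4 s^2 g^-1), applied identically at both daughter outlets.
#' * `T` cardiac period (s); `cycles` settling cycles (default 8, i.e. 6.8 s);
#'   `dt`, `dz` solver steps; `store_dt` output sampling interval.
#' * `p0`: reference (diastolic) pressure; default 0 so all pressures are
#'   relative to diastole. A constant offset has zero axial gradient and does
#'   not affect drainage.
#' * `inlet`: synthetic Doppler generator parameters, see
#'   [synth_doppler_series()].
#' * `wall`: `h_w_ratio` (wall thickness as a fraction of rest radius,
#'   default 0.1) and `eta` (radial BM position in the wall, 0 = lumen,
#'   1 = outer wall; default 0.5).
#' * `bm`: `h_bm0` initial BM thickness (cm, default 200 nm), `gamma` fluid
#'   volume fraction (default 0.5), `k` intrinsic permeability (cm^2),
#'   `mu` ISF viscosity (g cm^-1 s^-1; 1.5e-3 Pa s = 1.5e-2 CGS), `ratio`
#'   the valve ratio K0/K1 (default 0.01). The open-gradient mobility is
#'   `K1 = k/mu`.
#'
#' @param ... named overrides for any top-level field, or for nested fields as
#'   named lists merged into the defaults (e.g. `bm = list(gamma = 1)`).
#' @param seed integer seed for the synthetic inlet generator.
#' @return A named list of class `ipad_config`.
#' @examples
#' cfg <- ipad_config(seed = 1, bm = list(ratio = 1))
#' cfg$bm$ratio
#' @export
ipad_config <- function(..., seed = 1L) {
  cfg <- list(
    vessels = tibble::tibble(
      segment = c("mca", "d1", "d2"),
      Ru = c(0.14, 0.13, 0.13),
      Rd = c(0.14, 0.08, 0.08),
      L  = c(7.0, 6.5, 6.4)
    ),
    k1 = 2.0e7, k2 = -22.53, k3 = 8.65e5,
    nu = 0.046, rho = 1.06,
    R1 = 14.130, R2 = 7.200, CT = 2.4752e-3,
    T = 0.85, cycles = 8L,
    dt = 1e-5, dz = 0.1, store_dt = 1e-3,
    p0 = 0,
    taper = "exponential",
    inlet = list(
      v_peak = 90, v_min = 33, fs = 200, n_beats = 12L, n_peaks = 10L,
      jitter = 0.03, noise_sd = 1, n_grid = 1024L, profile_factor = 1
    ),
    wall = list(h_w_ratio = 0.1, eta = 0.5),
    bm = list(h_bm0 = 2e-5, gamma = 0.5, k = 1e-10, mu = 1.5e-2,
              ratio = 0.01),
    seed = as.integer(seed)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) {
      rlang::abort(sprintf("unknown configuration field '%s'", nm))
    }
    if (is.list(cfg[[nm]]) && !is.data.frame(cfg[[nm]]) && is.list(dots[[nm]])) {
      bad <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
      if (length(bad)) {
        rlang::abort(sprintf("unknown field '%s' in '%s'", bad[1], nm))
      }
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  validate_ipad_config(cfg)
  structure(cfg, class = "ipad_config")
}

#' Validate a run configuration
#'
#' Checks unit-consistent positivity and the module preconditions (geometry,
#' CFL-relevant steps, valve ordering, BM position) before any computation.
#'
#' @param cfg list as built by [ipad_config()].
#' @return `cfg`, invisibly. Errors on the first violated precondition.
#' @export
validate_ipad_config <- function(cfg) {
  v <- cfg$vessels
  stopifnot(is.data.frame(v), nrow(v) == 3)
  if (any(v$Rd > v$Ru) || any(v$Rd <= 0)) {
    rlang::abort("vessel radii must satisfy Ru >= Rd > 0 (slight taper)")
  }
  if (any(v$L <= 0)) rlang::abort("vessel lengths must be positive")
  for (f in c("nu", "rho", "R1", "R2", "CT", "T", "dt", "dz", "store_dt")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      rlang::abort(sprintf("'%s' must be a positive number", f))
    }
  }
  if (cfg$cycles < 1) rlang::abort("'cycles' must be >= 1")
  if (cfg$store_dt < cfg$dt) rlang::abort("'store_dt' must be >= 'dt'")
  if (!cfg$taper %in% c("exponential", "linear")) {
    rlang::abort("'taper' must be 'exponential' or 'linear'")
  }
  w <- cfg$wall
  if (w$h_w_ratio < 0) rlang::abort("wall thickness ratio must be >= 0")
  if (w$eta < 0 || w$eta > 1) rlang::abort("'eta' must lie in [0, 1]")
  b <- cfg$bm
  if (b$h_bm0 <= 0) rlang::abort("'h_bm0' must be positive")
  if (b$gamma <= 0 || b$gamma > 1) rlang::abort("'gamma' must lie in (0, 1]")
  if (b$k <= 0 || b$mu <= 0) rlang::abort("'k' and 'mu' must be positive")
  if (b$ratio <= 0 || b$ratio > 1) {
    rlang::abort("valve ratio K0/K1 must lie in (0, 1] with K1 > K0 > 0")
  }
  invisible(cfg)
}

#' Mobility of the open-gradient branch, K1 = k / mu
#' @param cfg an `ipad_config`.
#' @return K1 in cm^3 s g^-1.
#' @export
mobility_k1 <- function(cfg) cfg$bm$k / cfg$bm$mu

#' Write / read a run configuration
#'
#' Round-trippable serialisation of an [ipad_config()] to YAML (default) or
#' JSON so that every run is reproducible from its echoed configuration.
#'
#' @param cfg an `ipad_config`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `path` (write) or an `ipad_config` (read).
#' @export
write_ipad_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$vessels <- as.list(as.data.frame(x$vessels))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_ipad_config
#' @param path file path to read.
#' @export
read_ipad_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  x$vessels <- tibble::as_tibble(x$vessels)
  x$cycles <- as.integer(x$cycles)
  x$seed <- as.integer(x$seed)
  cfg <- structure(x, class = "ipad_config")
  validate_ipad_config(cfg)
  cfg
}

#' @exportS3Method base::print
print.ipad_config <- function(x, ...) {
  cat("<ipad_config>\n")
  cat(sprintf("  vessels: MCA bifurcation (L = %s cm)\n",
              paste(x$vessels$L, collapse = ", ")))
  cat(sprintf("  period T = %g s, %d cycles, dt = %g s, dz = %g cm\n",
              x$T, x$cycles, x$dt, x$dz))
  cat(sprintf("  BM: h_bm0 = %g cm, gamma = %g, K1 = %g cm^3 s/g, K0/K1 = %g, eta = %g\n",
              x$bm$h_bm0, x$bm$gamma, mobility_k1(x), x$bm$ratio, x$wall$eta))
  invisible(x)
}
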