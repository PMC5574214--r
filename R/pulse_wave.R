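#' Wall stiffness from the compliance law
#'
#' `f(r0) = (4/3) * (k1 * exp(k2 * r0) + k3)`, the elastic coefficient of the
#' pressure-area state equation, derived from `Eh/r0 = k1 exp(k2 r0) + k3`
#' and `f = 4Eh/(3 r0)`.
#'
#' @param r0 rest radius, cm (> 0). Vectorised.
#' @param k1,k3 compliance constants, g cm^-1 s^-2.
#' @param k2 compliance constant, cm^-1.
#' @return stiffness f in g cm^-1 s^-2.
#' @examples
#' wall_stiffness(0.14, 2e7, -22.53, 8.65e5)  # ~2.291e6
#' @export
wall_stiffness <- function(r0, k1, k2, k3) {
  if (any(r0 <= 0)) rlang::abort("'r0' must be positive")
  (4 / 3) * (k1 * exp(k2 * r0) + k3)
}

wall_stiffness_deriv <- function(r0, k1, k2, k3) {
  (4 / 3) * k1 * k2 * exp(k2 * r0)
}

#' Pressure-area state equation and its inverse
#'
#' `p = p0 + f * (1 - sqrt(A0 / A))`; `area_from_pressure()` inverts the map,
#' and the round trip is exact to machine precision.
#'
#' @param A lumen area, cm^2 (> 0). Vectorised.
#' @param A0 rest area, cm^2 (> 0).
#' @param f wall stiffness, g cm^-1 s^-2.
#' @param p0 reference (diastolic) pressure, dyn cm^-2.
#' @return pressure in dyn cm^-2 (or area in cm^2 for the inverse).
#' @examples
#' f <- wall_stiffness(0.14, 2e7, -22.53, 8.65e5)
#' state_pressure(1.1 * pi * 0.14^2, pi * 0.14^2, f)  # ~1.066e5 dyn/cm^2
#' @export
state_pressure <- function(A, A0, f, p0 = 0) {
  if (any(A <= 0) || any(A0 <= 0)) {
    rlang::abort("invalid state: areas must be positive")
  }
  p0 + f * (1 - sqrt(A0 / A))
}

#' @rdname state_pressure
#' @param p pressure, dyn cm^-2 (must satisfy p - p0 < f).
#' @export
area_from_pressure <- function(p, A0, f, p0 = 0) {
  s <- 1 - (p - p0) / f
  if (any(s <= 0)) rlang::abort("invalid state: pressure at or above p0 + f")
  A0 / s^2
}

#' Oscillatory boundary-layer thickness
#'
#' `delta_b = sqrt(nu * T / (2 * pi))`, the Stokes-layer scale used in the
#' flat-profile friction term of the momentum equation.
#'
#' @param nu kinematic viscosity, cm^2 s^-1 (> 0).
#' @param T cardiac period, s (> 0).
#' @return thickness in cm.
#' @examples
#' boundary_layer_thickness(0.046, 0.85)  # ~0.0789 cm
#' @export
boundary_layer_thickness <- function(nu, T) {
  if (nu <= 0 || T <= 0) rlang::abort("'nu' and 'T' must be positive")
  sqrt(nu * T / (2 * pi))
}

#' Rest radius profile of a tapered segment
#'
#' Exponential taper (default) `r0(z) = Ru * (Rd/Ru)^(z/L)` or linear taper.
#'
#' @param z axial positions, cm, measured from the segment inlet.
#' @param Ru,Rd upstream and downstream radii, cm.
#' @param L segment length, cm.
#' @param taper `"exponential"` or `"linear"`.
#' @return rest radii, cm.
#' @export
rest_radius <- function(z, Ru, Rd, L, taper = "exponential") {
  switch(taper,
    exponential = Ru * (Rd / Ru)^(z / L),
    linear = Ru + (Rd - Ru) * z / L,
    rlang::abort("unknown taper")
  )
}

rest_radius_deriv <- function(z, Ru, Rd, L, taper = "exponential") {
  switch(taper,
    exponential = Ru * (Rd / Ru)^(z / L) * log(Rd / Ru) / L,
    linear = rep((Rd - Ru) / L, length(z)),
    rlang::abort("unknown taper")
  )
}

segment_geometry <- function(Ru, Rd, L, dz, cfg) {
  n <- round(L / dz) + 1L
  z <- seq(0, L, length.out = n)
  zh <- (z[-n] + z[-1]) / 2
  g <- function(zz) {
    r0 <- rest_radius(zz, Ru, Rd, L, cfg$taper)
    list(r0 = r0, A0 = pi * r0^2,
         f = wall_stiffness(r0, cfg$k1, cfg$k2, cfg$k3),
         df = wall_stiffness_deriv(r0, cfg$k1, cfg$k2, cfg$k3),
         dr0dz = rest_radius_deriv(zz, Ru, Rd, L, cfg$taper))
  }
  gn <- g(z); gh <- g(zh)
  list(z = z, dz = z[2] - z[1],
       r0 = gn$r0, A0 = gn$A0, f = gn$f, df = gn$df, dr0dz = gn$dr0dz,
       r0h = gh$r0, A0h = gh$A0, fh = gh$f, dfh = gh$df, dr0dzh = gh$dr0dz)
}

#' One Richtmyer two-step Lax-Wendroff update (reference stepper)
#'
#' Advances the interior nodes of a hyperbolic system
#' `dU/dt + dF/dz = S` by one time step: a half-step predictor at cell
#' midpoints followed by a full-step corrector, second-order accurate in space
#' and time on smooth solutions. Boundary nodes are returned unchanged; the
#' caller supplies boundary closures. This R stepper is the scheme reference
#' used for order-of-accuracy tests and for cross-checking the compiled
#' network solver.
#'
#' @param U state matrix, `n` nodes by `m` components.
#' @param z node positions (uniform spacing).
#' @param dt time step, s.
#' @param flux_fn `function(U, z)` returning the flux matrix.
#' @param source_fn optional `function(U, z)` returning the source matrix.
#' @return updated state matrix.
#' @examples
#' # linear advection at CFL = 1 transports the profile one cell per step
#' z <- seq(0, 1, length.out = 65)
#' u <- matrix(sin(2 * pi * z), ncol = 1)
#' unew <- lax_wendroff_step(u, z, dt = diff(z)[1], function(U, z) U)
#' @export
lax_wendroff_step <- function(U, z, dt, flux_fn, source_fn = NULL) {
  U <- as.matrix(U)
  n <- nrow(U)
  if (n < 3) rlang::abort("need at least 3 nodes")
  dz <- z[2] - z[1]
  if ((dz <= 0) || any(abs(diff(z) - dz) > 1e-12 * dz)) {
    rlang::abort("'z' must be uniformly spaced and increasing")
  }
  zh <- (z[-n] + z[-1]) / 2
  S <- if (is.null(source_fn)) matrix(0, n, ncol(U)) else source_fn(U, z)
  Fv <- flux_fn(U, z)
  Uh <- (U[-n, , drop = FALSE] + U[-1, , drop = FALSE]) / 2 -
    dt / (2 * dz) * (Fv[-1, , drop = FALSE] - Fv[-n, , drop = FALSE]) +
    dt / 4 * (S[-n, , drop = FALSE] + S[-1, , drop = FALSE])
  Sh <- if (is.null(source_fn)) matrix(0, n - 1, ncol(U)) else source_fn(Uh, zh)
  Fh <- flux_fn(Uh, zh)
  i <- 2:(n - 1)
  Unew <- U
  Unew[i, ] <- U[i, , drop = FALSE] -
    dt / dz * (Fh[i, , drop = FALSE] - Fh[i - 1, , drop = FALSE]) +
    dt / 2 * (Sh[i, , drop = FALSE] + Sh[i - 1, , drop = FALSE])
  if (any(!is.finite(Unew))) rlang::abort("solver divergence: non-finite state")
  Unew
}

#' Three-element Windkessel outlet update
#'
#' Backward-Euler discretisation of the 3WK outlet: proximal resistance `R1`
#' in series with the parallel pair (`R2`, `CT`). The capacitor pressure `pc`
#' is the state; given the outlet flux over one step the relation returns the
#' outlet pressure `p = R1 * Q + pc_new`. At steady flux the relation relaxes
#' to `p = Q * (R1 + R2)` with time constant `R2 * CT`.
#'
#' @param pc capacitor pressure at the previous step, dyn cm^-2.
#' @param Q outlet flux at the new step, cm^3 s^-1.
#' @param wk list with `R1`, `R2`, `CT`.
#' @param dt time step, s.
#' @return list with `p` (outlet pressure) and `pc` (new capacitor state).
#' @examples
#' wk <- list(R1 = 14.13, R2 = 7.2, CT = 2.4752e-3)
#' st <- list(pc = 0)
#' for (i in 1:5000) st <- windkessel_update(st$pc, 2, wk, 1e-4)
#' st$p  # ~ 2 * (R1 + R2)
#' @export
windkessel_update <- function(pc, Q, wk, dt) {
  beta <- 1 / (1 + dt / (wk$R2 * wk$CT))
  pc_new <- beta * (pc + dt / wk$CT * Q)
  list(p = wk$R1 * Q + pc_new, pc = pc_new)
}

#' Simulate the MCA bifurcation network
#'
#' Solves the 1D compliant-vessel equations on the parent MCA and its two
#' daughter branches with a prescribed periodic inlet flux and identical
#' three-element Windkessel models at both outlets, for `cfg$cycles` cardiac
#' cycles. The junction enforces flux conservation and pressure continuity
#' (Newton iteration, residual tolerance 1e-12); inlet and outlets use
#' characteristic-compatibility closures. Fields are sampled every
#' `cfg$store_dt` seconds.
#'
#' @param inlet an `ipad_waveform` flux waveform (one period), or a single
#'   number for a steady inlet.
#' @param cfg an [ipad_config()].
#' @param cycles number of cardiac cycles (default `cfg$cycles`).
#' @return An object of class `hemo_fields`: list with `t` (stored times),
#'   per-segment lists (`mca`, `d1`, `d2`) each holding `z`, `A`, `Q`, `p`
#'   (node-by-time matrices, CGS) and rest geometry, plus solver
#'   `diagnostics` (max CFL number, junction residuals).
#' @examples
#' \donttest{
#' cfg <- ipad_config(cycles = 2)
#' hemo <- simulate_network(inlet_flux_waveform(cfg), cfg)
#' }
#' @export
simulate_network <- function(inlet, cfg, cycles = cfg$cycles) {
  validate_ipad_config(cfg)
  v <- cfg$vessels
  geoms <- lapply(1:3, function(i) {
    segment_geometry(v$Ru[i], v$Rd[i], v$L[i], cfg$dz, cfg)
  })
  if (is.numeric(inlet) && length(inlet) == 1) {
    q_samples <- rep(inlet, 16)
  } else {
    if (!inherits(inlet, "ipad_waveform") || !"q" %in% names(inlet)) {
      rlang::abort("'inlet' must be a flux waveform (see velocity_to_flux) or a number")
    }
    q_samples <- inlet$q
  }
  db <- boundary_layer_thickness(cfg$nu, cfg$T)
  n_steps <- as.integer(round(cycles * cfg$T / cfg$dt))
  store_every <- max(1L, as.integer(round(cfg$store_dt / cfg$dt)))
  res <- .solve_bifurcation(
    geoms[[1]], geoms[[2]], geoms[[3]],
    q_samples, cfg$T,
    cfg$rho, cfg$nu, db,
    cfg$R1, cfg$R2, cfg$CT,
    cfg$dt, n_steps, store_every,
    q_samples[1]
  )
  segs <- list()
  for (i in 1:3) {
    nm <- c("mca", "d1", "d2")[i]
    g <- geoms[[i]]
    A <- res[[nm]]$A
    p <- cfg$p0 + g$f * (1 - sqrt(g$A0 / A))  # column-wise recycling over t
    segs[[nm]] <- list(z = g$z, r0 = g$r0, A0 = g$A0, f = g$f,
                       A = A, Q = res[[nm]]$Q, p = p)
  }
  structure(
    list(t = res$t, mca = segs$mca, d1 = segs$d1, d2 = segs$d2,
         period = cfg$T, cycles = cycles, diagnostics = res$diagnostics,
         inlet = if (is.numeric(inlet)) NULL else inlet, cfg = cfg),
    class = "hemo_fields"
  )
}

#' @exportS3Method base::print
print.hemo_fields <- function(x, ...) {
  cat("<hemo_fields>\n")
  cat(sprintf("  %d cycles of T = %g s, %d stored samples\n",
              x$cycles, x$period, length(x$t)))
  cat(sprintf("  max CFL %.3f, junction residuals: flux %.2e, pressure %.2e\n",
              x$diagnostics$cfl_max,
              x$diagnostics$junction_residual_flux,
              x$diagnostics$junction_residual_pressure))
  invisible(x)
}

#' Indices of the final cardiac cycle in a stored time vector
#' @param t stored times, s.
#' @param period cardiac period, s.
#' @return integer indices spanning the final complete cycle.
#' @export
final_cycle_index <- function(t, period) {
  t_end <- t[length(t)]
  which(t > t_end - period - 1e-9)
}

#' Tidy a hemodynamic field object
#'
#' @param x a `hemo_fields` object.
#' @param segments which segments to include.
#' @param final_cycle keep only the final cardiac cycle?
#' @param ... unused.
#' @return long tibble with columns `segment`, `z`, `t`, `A`, `Q`, `p`.
#' @export
tidy.hemo_fields <- function(x, segments = c("mca", "d1", "d2"),
                             final_cycle = FALSE, ...) {
  it <- if (final_cycle) final_cycle_index(x$t, x$period) else seq_along(x$t)
  purrr::map_dfr(segments, function(nm) {
    s <- x[[nm]]
    tibble::tibble(
      segment = nm,
      z = rep(s$z, times = length(it)),
      t = rep(x$t[it], each = length(s$z)),
      A = as.vector(s$A[, it]),
      Q = as.vector(s$Q[, it]),
      p = as.vector(s$p[, it])
    )
  })
}

#' Export the final cycle of a hemodynamic run as CSV
#'
#' @param x a `hemo_fields` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hemo_csv <- function(x, path) {
  utils::write.csv(tidy.hemo_fields(x, final_cycle = TRUE), path,
                   row.names = FALSE)
  invisible(path)
}
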