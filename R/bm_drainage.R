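#' Valve-like pressure-gradient-dependent mobility
#'
#' The BM extracellular matrix is modelled as a porous medium whose mobility
#' `K = k / mu` switches with the sign of the axial ISF pressure gradient:
#' `K(p_z) = K0` for `p_z < 0` and `K(p_z) = K1` for `p_z >= 0`, with
#' `K1 >= K0 > 0`. Because the Darcy flux is `q1 = -K(p_z) * p_z`, a small
#' `K0` obstructs flow in the direction of the blood (+z) while `K1` admits
#' reverse (IPAD) flow; `K0 = K1` switches the valve off.
#'
#' @param p_z axial pressure gradient, dyn cm^-3 (vectorised).
#' @param K0,K1 mobilities, cm^3 s g^-1, with `K1 >= K0 > 0`.
#' @return mobility values, same shape as `p_z`.
#' @examples
#' valve_permeability(c(-10, 0, 10), K0 = 1, K1 = 100)
#' @export
valve_permeability <- function(p_z, K0, K1) {
  if (!(K1 >= K0 && K0 > 0)) {
    rlang::abort("valve mobilities must satisfy K1 >= K0 > 0")
  }
  ifelse(p_z < 0, K0, K1)
}

#' Evolve the BM thickness under the lubrication Darcy model
#'
#' Advances `d(gamma * R_i * h_bm)/dt = d(R_i * h_bm * K(p_z) * p_z)/dz`
#' conservatively in flux form on the vessel's z grid, with the valve
#' mobility evaluated at cell faces from the face-centred pressure gradient
#' and first-order upwinding of `R_i * h_bm` in the face flux. The conserved
#' line density `gamma * R_i * h_bm` responds to both wall motion (through
#' `R_i(z, t)`) and the Darcy flux; thickness is recovered as
#' `h_bm = m / (gamma * R_i)`. Default boundary conditions are zero flux at
#' both ends; `"periodic"` is available for method tests.
#'
#' @param kin a [wall_kinematics()] object (supplies `R_i`, `p_isf`, `p_z`
#'   and the space-time grid).
#' @param cfg an [ipad_config()] (supplies `gamma`, `h_bm0`, `k`, `mu`).
#' @param ratio valve ratio `K0 / K1` in (0, 1]; default `cfg$bm$ratio`.
#' @param bc `"noflux"` (default), `"open"` (one-sided end-face fluxes fed by
#'   the boundary node) or `"periodic"` (for method tests). The discrete
#'   change of total fluid volume equals the net boundary flux each step.
#' @return object of class `bm_state`: list with `z`, `t`, matrices `h`
#'   (thickness, cm), `q1` (node axial Darcy flux, cm/s, positive = blood
#'   flow direction), `Q_bm` (`2 pi R_i h q1`, cm^3/s), the boundary flux
#'   history `flux_in`/`flux_out` (cm^2/s line-flux at the two end faces),
#'   and the parameters used.
#' @export
bm_evolve <- function(kin, cfg, ratio = cfg$bm$ratio, bc = "noflux") {
  if (ratio <= 0 || ratio > 1) rlang::abort("'ratio' must lie in (0, 1]")
  K1 <- mobility_k1(cfg)
  K0 <- ratio * K1
  gamma <- cfg$bm$gamma
  h0 <- cfg$bm$h_bm0
  z <- kin$z; tt <- kin$t
  nz <- length(z); nt <- length(tt)
  dz <- z[2] - z[1]
  R <- kin$R_i
  # face-centred pressure gradients from the ISF pressure field
  pzf <- (kin$p_isf[-1, , drop = FALSE] - kin$p_isf[-nz, , drop = FALSE]) / dz
  Kf <- matrix(valve_permeability(pzf, K0, K1), nrow = nz - 1)
  # stability bound for the explicit update (advective character)
  vmax <- max(abs(Kf * pzf)) / gamma
  dtmax <- 0.5 * dz / max(vmax, .Machine$double.eps)
  dts <- diff(tt)
  if (any(dts > dtmax)) {
    rlang::abort(sprintf(
      "BM time step %.3g s exceeds the stability bound %.3g s; reduce store_dt",
      max(dts), dtmax))
  }
  h <- matrix(0, nz, nt)
  m <- gamma * R[, 1] * h0            # conserved line density
  h[, 1] <- h0
  flux_in <- flux_out <- numeric(nt)  # end-face fluxes (R h K pz)
  Kn <- matrix(valve_permeability(kin$p_z, K0, K1), nrow = nz)
  K1v <- K1; K0v <- K0
  for (k in seq_len(nt - 1)) {
    dt <- tt[k + 1] - tt[k]
    Rh <- m / gamma                    # = R * h at time k
    Fface <- Kf[, k] * pzf[, k]        # mobility * gradient at faces
    # upwind R*h: flux in +z direction is -K pz * Rh
    up <- ifelse(Fface <= 0, Rh[-nz], Rh[-1])
    G <- up * Fface                    # face flux R h K pz
    if (bc == "periodic") {
      # wrap face between the last and first node
      pzw <- (kin$p_isf[1, k] - kin$p_isf[nz, k]) / dz
      Fw <- valve_permeability(pzw, K0v, K1v) * pzw
      Gw <- (if (Fw <= 0) Rh[nz] else Rh[1]) * Fw
      Gl <- Gw; Gr <- Gw
    } else if (bc == "open") {
      # one-sided gradients at the domain ends, material drawn from the
      # boundary node (reservoir with the same R*h)
      pzl <- kin$p_z[1, k]; pzr <- kin$p_z[nz, k]
      Gl <- Rh[1] * valve_permeability(pzl, K0v, K1v) * pzl
      Gr <- Rh[nz] * valve_permeability(pzr, K0v, K1v) * pzr
    } else {
      Gl <- 0; Gr <- 0
    }
    Gext <- c(Gl, G, Gr)
    m <- m + dt / dz * (Gext[-1] - Gext[-(nz + 1)])
    flux_in[k + 1] <- Gl; flux_out[k + 1] <- Gr
    h[, k + 1] <- m / (gamma * R[, k + 1])
    if (any(h[, k + 1] <= 0)) {
      rlang::abort(sprintf("solver divergence: non-positive BM thickness at t = %g",
                           tt[k + 1]))
    }
  }
  q1 <- -Kn * kin$p_z
  Q_bm <- 2 * pi * R * h * q1
  structure(
    list(z = z, t = tt, h = h, q1 = q1, Q_bm = Q_bm,
         flux_in = flux_in, flux_out = flux_out,
         ratio = ratio, K0 = K0, K1 = K1, gamma = gamma, h_bm0 = h0,
         eta = kin$eta, period = kin$period, bc = bc),
    class = "bm_state"
  )
}

#' @exportS3Method base::print
print.bm_state <- function(x, ...) {
  cat("<bm_state>\n")
  cat(sprintf("  K0/K1 = %g, eta = %g, %d nodes x %d times\n",
              x$ratio, x$eta, nrow(x$h), ncol(x$h)))
  invisible(x)
}

#' Tidy a BM state to a long tibble
#' @param x a `bm_state`.
#' @param ... unused.
#' @return tibble with `z`, `t`, `h`, `q1`, `Q_bm`.
#' @export
tidy.bm_state <- function(x, ...) {
  tibble::tibble(
    z = rep(x$z, times = length(x$t)),
    t = rep(x$t, each = length(x$z)),
    h = as.vector(x$h),
    q1 = as.vector(x$q1),
    Q_bm = as.vector(x$Q_bm)
  )
}

#' Cycle-averaged drainage metrics
#'
#' Averages the BM volumetric flux and axial Darcy flux over the final
#' cardiac cycle at a reporting station (default mid-vessel) and reports them
#' in micrometre-based units, together with the maximum BM width excursion
#' from its initial value. Sign convention: positive = direction of blood
#' flow (+z); negative = reverse (IPAD) direction.
#'
#' @param state a [bm_evolve()] result.
#' @param station node index for the reporting station, or `"mid"`.
#' @param cycle_window indices of stored times to average over; default the
#'   final complete cycle.
#' @return one-row tibble: `mean_flux_um3_s` (cycle-mean `Q_bm`, um^3/s),
#'   `mean_velocity_um_s` (cycle-mean `q1`, um/s),
#'   `max_width_variation_A` (max over z and the window of
#'   `|h_bm - h_bm0|`, Angstrom), `direction` (+1/-1/0), `ratio`, `eta`,
#'   `station_z` (cm).
#' @examples
#' # unit arithmetic: q1 = 1 cm/s, R_i = 0.14 cm, h = 2e-5 cm gives
#' # Q_bm = 2*pi*0.14*2e-5 ~ 1.76e-5 cm^3/s = 1.76e7 um^3/s
#' @export
flux_metrics <- function(state, station = "mid", cycle_window = NULL) {
  tt <- state$t
  if (is.null(cycle_window)) {
    cycle_window <- final_cycle_index(tt, state$period)
  }
  span <- diff(range(tt[cycle_window]))
  if (span < state$period * (1 - 1e-6)) {
    rlang::abort("invalid window: shorter than one cardiac period")
  }
  j <- if (identical(station, "mid")) {
    as.integer(round((nrow(state$h) + 1) / 2))
  } else {
    as.integer(station)
  }
  mean_flux <- mean(state$Q_bm[j, cycle_window]) * 1e12   # cm^3/s -> um^3/s
  mean_vel <- mean(state$q1[j, cycle_window]) * 1e4       # cm/s  -> um/s
  max_dev <- max(abs(state$h[, cycle_window] - state$h_bm0)) * 1e8  # cm -> A
  tibble::tibble(
    mean_flux_um3_s = mean_flux,
    mean_velocity_um_s = mean_vel,
    max_width_variation_A = max_dev,
    direction = sign(mean_flux),
    ratio = state$ratio,
    eta = state$eta,
    station_z = state$z[j]
  )
}

#' Critical valve ratio for net reverse drainage
#'
#' Bisection on the valve ratio `K0/K1` for the root of the cycle-averaged BM
#' flux: below the critical ratio the net flux is reverse (negative), above
#' it antegrade. By default the flux function re-runs [bm_evolve()] +
#' [flux_metrics()] on fixed wall kinematics; a custom `flux_fn(ratio)` can
#' be supplied (e.g. for method tests).
#'
#' @param kin a [wall_kinematics()] object (ignored when `flux_fn` given).
#' @param cfg an [ipad_config()] (ignored when `flux_fn` given).
#' @param lo,hi ratio bracket, `0 < lo < hi <= 1`.
#' @param tol absolute tolerance on the ratio (default 1e-4).
#' @param flux_fn optional `function(ratio)` returning the mean flux.
#' @param station reporting station passed to [flux_metrics()].
#' @return one-row tibble: `ratio_critical`, bracketing fluxes `flux_lo`,
#'   `flux_hi` (um^3/s), `n_iter`.
#' @export
reverse_flow_threshold <- function(kin = NULL, cfg = NULL, lo = 0.005,
                                   hi = 1, tol = 1e-4, flux_fn = NULL,
                                   station = "mid") {
  if (is.null(flux_fn)) {
    flux_fn <- function(r) {
      flux_metrics(bm_evolve(kin, cfg, ratio = r),
                   station = station)$mean_flux_um3_s
    }
  }
  f_lo <- flux_fn(lo); f_hi <- flux_fn(hi)
  if (!(f_lo < 0 && f_hi > 0)) {
    rlang::abort(sprintf(
      "no reverse-flow threshold in [%g, %g]: flux is %.3g at lo and %.3g at hi",
      lo, hi, f_lo, f_hi))
  }
  n <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- flux_fn(mid)
    if (f_mid < 0) { lo <- mid; f_lo <- f_mid } else { hi <- mid; f_hi <- f_mid }
    n <- n + 1L
  }
  tibble::tibble(ratio_critical = (lo + hi) / 2,
                 flux_lo = f_lo, flux_hi = f_hi, n_iter = n)
}

#' Total BM fluid volume (discrete line integral)
#'
#' `gamma * sum_j R_i(z_j) * h_bm(z_j) * dz`, the solver's conserved discrete
#' fluid volume (per radian of annulus, cm^3). Its change over one step
#' equals `dt * (flux_out - flux_in)` to machine precision.
#'
#' @param state a `bm_state`.
#' @param kin the matching `wall_kinematics`.
#' @return numeric vector over stored times.
#' @export
bm_fluid_volume <- function(state, kin) {
  dz <- state$z[2] - state$z[1]
  state$gamma * colSums(kin$R_i * state$h) * dz
}
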