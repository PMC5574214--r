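#' Two-dimensional annular Darcy reference solver
#'
#' Brute-force quasi-static solver for incompressible Darcy flow in the
#' annular strip `Ri(z) <= r <= Ro(z)` of an axisymmetric vessel:
#' `dq1/dz + (1/r) d(r q2)/dr = 0` with `q = -K grad p`. It verifies the 1D
#' lubrication reduction used by [bm_evolve()]. The strip is mapped to the
#' unit square with `s = (r - Ri)/(Ro - Ri)` and the full metric terms of the
#' mapping retained, so the only approximation is the finite-difference grid
#' (small instances intended: up to ~1e4 cells).
#'
#' Boundary conditions: Dirichlet pressures at the two z ends (reservoirs),
#' or `"noflux"`; kinematic conditions at the moving walls, imposed as the
#' material-surface normal-flux relation `q2 - R'(z) q1 = dR/dt` on each
#' wall. If every boundary is a flux condition the pressure is only defined
#' up to a constant; the gauge is then fixed by pinning one node (reported
#' via a message).
#'
#' @param z axial node positions, cm (uniform).
#' @param Ri,Ro inner/outer wall radii at `z`, cm (`Ro > Ri > 0`).
#' @param K Darcy mobility `k/mu`, cm^3 s g^-1: a scalar or an `nz x nr`
#'   matrix field.
#' @param nr number of radial nodes (default 9).
#' @param p_left,p_right end pressures (dyn cm^-2) or `"noflux"`.
#' @param v_inner,v_outer wall normal speeds `dRi/dt`, `dRo/dt` (cm/s),
#'   scalar or length-`nz`.
#' @return list with `z`, `s`, `r` (radius matrix), `p`, `q1`, `q2`
#'   (`nz x nr` matrices), `Q_axial` (axial volume flux per radian,
#'   `integral q1 r dr`, length `nz`), and `gauge_fixed`.
#' @examples
#' z <- seq(0, 1, length.out = 21)
#' sol <- darcy2d_oracle(z, Ri = rep(1, 21), Ro = rep(1.02, 21), K = 2,
#'                       p_left = 1, p_right = 0)
#' range(sol$q1)  # ~ -K * (-1) = 2 everywhere
#' @export
darcy2d_oracle <- function(z, Ri, Ro, K, nr = 9,
                           p_left = 0, p_right = 0,
                           v_inner = 0, v_outer = 0) {
  nz <- length(z)
  if (nz < 5 || nr < 5) rlang::abort("need at least a 5 x 5 grid")
  if (any(Ro <= Ri) || any(Ri <= 0)) {
    rlang::abort("invalid annulus: need Ro > Ri > 0")
  }
  if (nz * nr > 2e4) rlang::abort("oracle is for small instances (<= ~1e4 cells)")
  dzeta <- z[2] - z[1]
  ds <- 1 / (nr - 1)
  s <- seq(0, 1, length.out = nr)
  W <- Ro - Ri
  d1 <- function(y) { # central, one-sided 2nd order at ends
    n <- length(y); g <- y
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dzeta)
    g[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * dzeta)
    g[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * dzeta)
    g
  }
  Rip <- d1(Ri); Wp <- d1(W)
  Ripp <- d1(Rip); Wpp <- d1(Wp)
  if (length(v_inner) == 1) v_inner <- rep(v_inner, nz)
  if (length(v_outer) == 1) v_outer <- rep(v_outer, nz)
  Kmat <- if (is.matrix(K)) K else matrix(K, nz, nr)
  # metric fields on the grid
  rmat <- outer(Ri, rep(1, nr)) + outer(W, s)
  a <- (outer(Rip, rep(1, nr)) + outer(Wp, s)) / W      # recycles W by row
  a_s <- matrix(Wp / W, nz, nr)
  a_z <- (outer(Ripp, rep(1, nr)) + outer(Wpp, s)) / W - a * (Wp / W)
  Ks <- t(apply(Kmat, 1, function(y) {
    g <- y; n <- nr
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * ds)
    g[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * ds)
    g[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * ds)
    g
  }))
  Kz <- apply(Kmat, 2, d1)

  idx <- function(i, j) (j - 1L) * nz + i
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  rhs <- numeric(nz * nr)
  add <- function(row, col, val) {
    trip_i[[length(trip_i) + 1L]] <<- row
    trip_j[[length(trip_j) + 1L]] <<- col
    trip_x[[length(trip_x) + 1L]] <<- val
  }
  dir_left <- !identical(p_left, "noflux")
  dir_right <- !identical(p_right, "noflux")

  for (i in seq_len(nz)) {
    for (j in seq_len(nr)) {
      row <- idx(i, j)
      if (i == 1 && dir_left) { add(row, row, 1); rhs[row] <- p_left; next }
      if (i == nz && dir_right) { add(row, row, 1); rhs[row] <- p_right; next }
      if (j == 1 || j == nr) {
        # wall kinematic condition: -K p_s / W + R' K (p_zeta - a p_s) = v
        Rp <- if (j == 1) Rip[i] else Rip[i] + Wp[i]
        v <- if (j == 1) v_inner[i] else v_outer[i]
        Kij <- Kmat[i, j]
        cs <- -Kij / W[i] - Rp * Kij * a[i, j]
        # one-sided second-order p_s
        sgn <- if (j == 1) 1 else -1
        j2 <- j + sgn; j3 <- j + 2 * sgn
        add(row, idx(i, j), cs * sgn * (-3) / (2 * ds))
        add(row, idx(i, j2), cs * sgn * 4 / (2 * ds))
        add(row, idx(i, j3), cs * sgn * (-1) / (2 * ds))
        # p_zeta term (central; one-sided at flux ends)
        cz <- Rp * Kij
        if (i > 1 && i < nz) {
          add(row, idx(i + 1, j), cz / (2 * dzeta))
          add(row, idx(i - 1, j), -cz / (2 * dzeta))
        } else if (i == 1) {
          add(row, idx(1, j), -3 * cz / (2 * dzeta))
          add(row, idx(2, j), 4 * cz / (2 * dzeta))
          add(row, idx(3, j), -cz / (2 * dzeta))
        } else {
          add(row, idx(nz, j), 3 * cz / (2 * dzeta))
          add(row, idx(nz - 1, j), -4 * cz / (2 * dzeta))
          add(row, idx(nz - 2, j), cz / (2 * dzeta))
        }
        rhs[row] <- v
        next
      }
      if ((i == 1 || i == nz) && !(if (i == 1) dir_left else dir_right)) {
        # no-flux end: q1 = -K (p_zeta - a p_s) = 0, one-sided p_zeta
        sgn <- if (i == 1) 1 else -1
        i2 <- i + sgn; i3 <- i + 2 * sgn
        add(row, idx(i, j), sgn * (-3) / (2 * dzeta))
        add(row, idx(i2, j), sgn * 4 / (2 * dzeta))
        add(row, idx(i3, j), sgn * (-1) / (2 * dzeta))
        aa <- -a[i, j]
        add(row, idx(i, j + 1), aa / (2 * ds))
        add(row, idx(i, j - 1), -aa / (2 * ds))
        rhs[row] <- 0
        next
      }
      # interior: c_zz p_zz + c_ss p_ss + c_zs p_zs + c_z p_z + c_s p_s = 0
      Kij <- Kmat[i, j]; aij <- a[i, j]
      c_zz <- Kij
      c_ss <- Kij * aij^2 + Kij / W[i]^2
      c_zs <- -2 * Kij * aij
      c_z <- Kz[i, j] - aij * Ks[i, j]
      c_s <- -Kij * a_z[i, j] - Kz[i, j] * aij + Kij * aij * a_s[i, j] +
        aij^2 * Ks[i, j] + Ks[i, j] / W[i]^2 + Kij / (rmat[i, j] * W[i])
      add(row, idx(i + 1, j), c_zz / dzeta^2 + c_z / (2 * dzeta))
      add(row, idx(i - 1, j), c_zz / dzeta^2 - c_z / (2 * dzeta))
      add(row, idx(i, j + 1), c_ss / ds^2 + c_s / (2 * ds))
      add(row, idx(i, j - 1), c_ss / ds^2 - c_s / (2 * ds))
      add(row, idx(i, j), -2 * c_zz / dzeta^2 - 2 * c_ss / ds^2)
      add(row, idx(i + 1, j + 1), c_zs / (4 * dzeta * ds))
      add(row, idx(i - 1, j - 1), c_zs / (4 * dzeta * ds))
      add(row, idx(i + 1, j - 1), -c_zs / (4 * dzeta * ds))
      add(row, idx(i - 1, j + 1), -c_zs / (4 * dzeta * ds))
    }
  }
  gauge_fixed <- FALSE
  if (!dir_left && !dir_right) {
    # all-flux problem: pressure defined up to a constant. Pin an interior
    # node: for straight walls the metric couplings (a, c_zs) vanish, so a
    # corner node is referenced by no other equation and pinning it would
    # leave the constant mode on the rest of the grid.
    row <- idx(2L, 2L)
    keep <- trip_i != row
    trip_i <- trip_i[keep]; trip_j <- trip_j[keep]; trip_x <- trip_x[keep]
    trip_i <- c(trip_i, row); trip_j <- c(trip_j, row); trip_x <- c(trip_x, 1)
    rhs[row] <- 0
    gauge_fixed <- TRUE
    message("darcy2d_oracle: all-Neumann system, gauge fixed at node (2,2)")
  }
  M <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(nz * nr, nz * nr))
  pvec <- as.numeric(Matrix::solve(M, rhs))
  p <- matrix(pvec, nz, nr)

  dmat_z <- function(Y) apply(Y, 2, d1)
  dmat_s <- function(Y) t(apply(Y, 1, function(y) {
    g <- y; n <- nr
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * ds)
    g[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * ds)
    g[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * ds)
    g
  }))
  p_zeta <- dmat_z(p); p_s <- dmat_s(p)
  q1 <- -Kmat * (p_zeta - a * p_s)
  q2 <- -Kmat * p_s / matrix(W, nz, nr)
  # axial volume flux per radian: integral q1 r dr = W * integral q1 r ds
  integrand <- q1 * rmat
  Q_axial <- W * (rowSums(integrand) - (integrand[, 1] + integrand[, nr]) / 2) * ds
  list(z = z, s = s, r = rmat, p = p, q1 = q1, q2 = q2,
       Q_axial = Q_axial, gauge_fixed = gauge_fixed)
}

#' One quasi-static slice of the 1D lubrication model
#'
#' Given the instantaneous gap geometry (`R`, `h`) and its rate of change,
#' incompressibility integrates to `R h K p_z = C + G(z)` with
#' `G(z) = integral_0^z d(R h)/dt dz'`; the constant `C` follows from the
#' end pressures (both zero: reservoir conditions). Returns the slice
#' pressure, Darcy flux and axial volume flux per radian, for comparison
#' with [darcy2d_oracle()].
#'
#' @param z axial nodes, cm (uniform).
#' @param R interface radius at `z`, cm.
#' @param h gap width at `z`, cm.
#' @param dRh_dt time derivative of `R * h` at `z`, cm^2/s.
#' @param K Darcy mobility (scalar), cm^3 s g^-1.
#' @return list with `p`, `q1` (`-K p_z`), and `Q_axial = R h q1` (per
#'   radian, cm^3/s).
#' @export
lubrication_pressure_slice <- function(z, R, h, dRh_dt, K) {
  nz <- length(z)
  dz <- z[2] - z[1]
  cum_trap <- function(y) c(0, cumsum((y[-nz] + y[-1]) / 2 * dz))
  G <- cum_trap(dRh_dt)
  inv <- 1 / (R * h * K)
  # p(L) - p(0) = 0  =>  C = -int G inv dz / int inv dz
  int_Ginv <- sum(((G * inv)[-nz] + (G * inv)[-1]) / 2 * dz)
  int_inv <- sum((inv[-nz] + inv[-1]) / 2 * dz)
  C <- -int_Ginv / int_inv
  p_z <- (C + G) * inv
  p <- cum_trap(p_z)
  q1 <- -K * p_z
  list(p = p, q1 = q1, Q_axial = R * h * q1)
}
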