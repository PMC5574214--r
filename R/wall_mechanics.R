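#' Wall geometry of one arterial cross-section
#'
#' @param a lumen rest radius, cm.
#' @param h_w wall thickness, cm (default physiological ratio 0.1 * a).
#' @param eta dimensionless BM position in the wall: 0 at the lumen, 1 at the
#'   outer wall; the BM rest radius is `a + eta * h_w`.
#' @return list of class `wall_geometry` with `a`, `h_w`, `b = a + h_w`,
#'   `eta`. Vectorised over `a`/`h_w` (e.g. along a tapered vessel).
#' @export
wall_geometry <- function(a, h_w = 0.1 * a, eta = 0.5) {
  if (any(a <= 0) || any(h_w < 0)) {
    rlang::abort("invalid geometry: need a > 0 and h_w >= 0")
  }
  if (eta < 0 || eta > 1) rlang::abort("'eta' must lie in [0, 1]")
  structure(list(a = a, h_w = h_w, b = a + h_w, eta = eta),
            class = "wall_geometry")
}

#' Lumen-wall radial displacement from the area field
#'
#' `xi = sqrt(A / pi) - r0`: the radial displacement of the lumen wall
#' implied by the cross-sectional area.
#'
#' @param A lumen area, cm^2 (matrix nodes x times or vector).
#' @param r0 rest radius, cm (vector over nodes, recycled over columns).
#' @return displacement xi in cm, same shape as `A`.
#' @examples
#' lumen_displacement(1.02 * pi * 0.14^2, 0.14)  # ~1.39e-3 cm
#' @export
lumen_displacement <- function(A, r0) {
  if (any(A <= 0)) rlang::abort("'A' must be positive")
  sqrt(A / pi) - r0
}

#' Radial-stress transfer weight across the wall (Lame solution)
#'
#' Fraction of the transmural (pulse) pressure carried as compressive radial
#' stress at radius `r = a + eta * h_w` inside a thick-walled cylinder:
#' `w(eta) = a^2 (b^2 - r^2) / (r^2 (b^2 - a^2))`, with `w(0) = 1` at the
#' lumen and `w(1) = 0` at the stress-free outer wall; `w` is monotone
#' decreasing in `eta`. For a vanishing wall thickness the limit `1 - eta`
#' is returned.
#'
#' @param eta BM position in [0, 1].
#' @param geom a [wall_geometry()] (its own `eta` is ignored in favour of the
#'   argument).
#' @return dimensionless weight(s).
#' @examples
#' lame_stress_weight(0.5, wall_geometry(0.14, 0.014))  # ~0.464
#' @export
lame_stress_weight <- function(eta, geom) {
  a <- geom$a; b <- geom$b
  r <- a + eta * geom$h_w
  ifelse(geom$h_w == 0, 1 - eta,
         a^2 * (b^2 - r^2) / (r^2 * (b^2 - a^2)))
}

#' Displacement attenuation from lumen to BM position
#'
#' Incompressible thick-cylinder kinematics give a radial displacement field
#' `u(r) = xi * a / r`, so the lumen displacement reaching the BM at rest
#' radius `a + eta * h_w` is attenuated by `a / (a + eta * h_w)`, a factor
#' in (0, 1].
#'
#' @inheritParams lame_stress_weight
#' @return attenuation factor(s).
#' @export
displacement_attenuation <- function(eta, geom) {
  geom$a / (geom$a + eta * geom$h_w)
}

#' BM inner-interface radius
#'
#' `R_i(z, t) = (a + eta * h_w) + xi(z, t) * a / (a + eta * h_w)`: the rest
#' radius of the BM position plus the lumen displacement attenuated by the
#' incompressible thick-cylinder kinematics.
#'
#' @param xi lumen displacement, cm (matrix nodes x times or vector).
#' @param geom a [wall_geometry()] whose `eta` locates the BM.
#' @return R_i in cm, same shape as `xi`.
#' @examples
#' g <- wall_geometry(0.14, 0.014, eta = 1)
#' bm_interface_radius(1e-3, g)  # ~0.15491 cm
#' @export
bm_interface_radius <- function(xi, geom) {
  r_rest <- geom$a + geom$eta * geom$h_w
  r_rest + xi * displacement_attenuation(geom$eta, geom)
}

#' ISF pressure at the BM position
#'
#' The pulse (transmural) component of blood pressure transferred to the BM
#' depth by the Lame radial-stress weight:
#' `p_isf = (p_blood - p0) * w(eta)`. The weight is 1 at the lumen and 0 at
#' the stress-free outer wall.
#'
#' @param p_blood blood pressure, dyn cm^-2 (matrix nodes x times or vector).
#' @param p0 reference (diastolic) pressure, dyn cm^-2.
#' @param geom a [wall_geometry()].
#' @return ISF pressure, dyn cm^-2.
#' @export
isf_pressure <- function(p_blood, p0, geom) {
  (p_blood - p0) * lame_stress_weight(geom$eta, geom)
}

#' Axial pressure gradient on a uniform grid
#'
#' Second-order central differences at interior nodes and one-sided
#' second-order stencils at the two ends (exact for quadratics).
#'
#' @param p pressure field, matrix nodes x times (or vector).
#' @param dz node spacing, cm.
#' @return gradient field, dyn cm^-3, same shape.
#' @export
axial_pressure_gradient <- function(p, dz) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (n < 3) rlang::abort("invalid grid: need at least 3 nodes")
  g <- p
  g[2:(n - 1), ] <- (p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]) /
    (2 * dz)
  g[1, ] <- (-3 * p[1, ] + 4 * p[2, ] - p[3, ]) / (2 * dz)
  g[n, ] <- (3 * p[n, ] - 4 * p[n - 1, ] + p[n - 2, ]) / (2 * dz)
  g
}

#' Wall kinematics: BM interface radius, ISF pressure and its gradient
#'
#' Maps a hemodynamic field to the inputs of the BM drainage model on the
#' chosen segment: the BM inner-interface radius `R_i(z, t)` (rest radius at
#' the BM position plus attenuated lumen displacement), the ISF pressure at
#' the BM depth, and its axial gradient `p_z`.
#'
#' @param hemo a [simulate_network()] result.
#' @param cfg the [ipad_config()] of the run.
#' @param eta BM position in the wall (default `cfg$wall$eta`).
#' @param segment which vessel segment carries the BM (default `"mca"`).
#' @return object of class `wall_kinematics`: list with `z`, `t`, `R_i`,
#'   `p_isf`, `p_z` (node-by-time matrices, CGS), the `wall_geometry`, and
#'   `period`.
#' @export
wall_kinematics <- function(hemo, cfg, eta = cfg$wall$eta, segment = "mca") {
  s <- hemo[[segment]]
  geom <- wall_geometry(a = s$r0, h_w = cfg$wall$h_w_ratio * s$r0, eta = eta)
  xi <- lumen_displacement(s$A, s$r0)
  R_i <- bm_interface_radius(xi, geom)
  p_isf <- isf_pressure(s$p, cfg$p0, geom)
  p_z <- axial_pressure_gradient(p_isf, s$z[2] - s$z[1])
  structure(
    list(z = s$z, t = hemo$t, R_i = R_i, p_isf = p_isf, p_z = p_z,
         geom = geom, eta = eta, segment = segment, period = hemo$period),
    class = "wall_kinematics"
  )
}

#' @exportS3Method base::print
print.wall_kinematics <- function(x, ...) {
  cat("<wall_kinematics>\n")
  cat(sprintf("  segment %s, eta = %g, %d nodes x %d times\n",
              x$segment, x$eta, nrow(x$R_i), ncol(x$R_i)))
  invisible(x)
}

#' Tidy wall kinematics to a long tibble
#' @param x a `wall_kinematics` object.
#' @param ... unused.
#' @return tibble with `z`, `t`, `R_i`, `p_isf`, `p_z`.
#' @export
tidy.wall_kinematics <- function(x, ...) {
  tibble::tibble(
    z = rep(x$z, times = length(x$t)),
    t = rep(x$t, each = length(x$z)),
    R_i = as.vector(x$R_i),
    p_isf = as.vector(x$p_isf),
    p_z = as.vector(x$p_z)
  )
}
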