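#' Run the full IPAD pipeline
#'
#' End-to-end driver: synthesise the Doppler inlet waveform, run the
#' bifurcation pulse-wave simulation, map the fields to BM wall kinematics,
#' evolve the BM drainage model and summarise the cycle-averaged drainage.
#' Because the hemodynamics do not depend on the valve ratio or the BM
#' position, a previously computed `hemo` field can be reused across
#' `ratio`/`eta` values (see [eta_ratio_sweep()]).
#'
#' @param cfg an [ipad_config()]; the defaults are the study conditions.
#' @param hemo optional [simulate_network()] result to reuse.
#' @param ratio valve ratio `K0 / K1` (default `cfg$bm$ratio`).
#' @param eta BM position in the wall (default `cfg$wall$eta`).
#' @param station reporting station for [flux_metrics()].
#' @return object of class `ipad_run`: list with the echoed `cfg`, the inlet
#'   `waveform`, `hemo` fields, wall `kin`ematics, the `bm` state and the
#'   one-row `metrics` tibble.
#' @examples
#' \dontrun{
#' run <- run_ipad_pipeline(ipad_config(cycles = 2L))
#' glance(run)
#' }
#' @export
run_ipad_pipeline <- function(cfg = ipad_config(), hemo = NULL,
                              ratio = cfg$bm$ratio, eta = cfg$wall$eta,
                              station = "mid") {
  waveform <- if (is.null(hemo)) inlet_flux_waveform(cfg) else hemo$inlet
  if (is.null(hemo)) hemo <- simulate_network(waveform, cfg)
  kin <- wall_kinematics(hemo, cfg, eta = eta)
  bm <- bm_evolve(kin, cfg, ratio = ratio)
  metrics <- flux_metrics(bm, station = station)
  structure(
    list(cfg = cfg, waveform = waveform, hemo = hemo, kin = kin, bm = bm,
         metrics = metrics),
    class = "ipad_run"
  )
}

#' @exportS3Method base::print
print.ipad_run <- function(x, ...) {
  cat("<ipad_run>\n")
  cat(sprintf("  valve ratio K0/K1 = %g, eta = %g\n",
              x$bm$ratio, x$bm$eta))
  cat(sprintf("  cycle-mean BM flux %.3e um^3/s (%s), mean q1 %.3e um/s\n",
              x$metrics$mean_flux_um3_s,
              if (x$metrics$direction < 0) "reverse / IPAD" else "forward",
              x$metrics$mean_velocity_um_s))
  cat(sprintf("  max BM width variation %.3g Angstrom\n",
              x$metrics$max_width_variation_A))
  invisible(x)
}

#' Tidy an `ipad_run` to a long tibble of BM fields
#' @param x an `ipad_run`.
#' @param ... unused.
#' @return tibble with `z`, `t`, `h`, `q1`, `Q_bm` (see [tidy.bm_state()]).
#' @export
tidy.ipad_run <- function(x, ...) tidy(x$bm)

#' One-row summary of an `ipad_run`
#' @param x an `ipad_run`.
#' @param ... unused.
#' @return one-row tibble: the [flux_metrics()] columns plus the solver
#'   diagnostics `cfl_max`, `junction_residual_flux`,
#'   `junction_residual_pressure` and the `seed`.
#' @export
glance.ipad_run <- function(x, ...) {
  d <- x$hemo$diagnostics
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(
      cfl_max = d$cfl_max,
      junction_residual_flux = d$junction_residual_flux,
      junction_residual_pressure = d$junction_residual_pressure,
      seed = x$cfg$seed
    )
  )
}

#' Sweep drainage metrics over BM position and valve ratio
#'
#' Runs the hemodynamics once and re-evolves the (cheap) BM model for every
#' combination of `eta` and `ratio`, returning one metrics row per
#' combination.
#'
#' @param cfg an [ipad_config()].
#' @param etas BM positions in `[0, 1]`.
#' @param ratios valve ratios in `(0, 1]`.
#' @param hemo optional precomputed [simulate_network()] result.
#' @param station reporting station for [flux_metrics()].
#' @return tibble with the [flux_metrics()] columns for every
#'   `eta` x `ratio` combination.
#' @export
eta_ratio_sweep <- function(cfg, etas = cfg$wall$eta, ratios = cfg$bm$ratio,
                            hemo = NULL, station = "mid") {
  if (is.null(hemo)) hemo <- simulate_network(inlet_flux_waveform(cfg), cfg)
  purrr::map_dfr(etas, function(eta) {
    kin <- wall_kinematics(hemo, cfg, eta = eta)
    purrr::map_dfr(ratios, function(r) {
      flux_metrics(bm_evolve(kin, cfg, ratio = r), station = station)
    })
  })
}

#' Clearance turnover time implied by a per-artery drainage rate
#'
#' Converts a cycle-averaged BM volumetric flux into the time required to
#' turn over a given interstitial-fluid volume, assuming `n_arteries`
#' identical drainage routes: `volume / (|flux| * n_arteries)`.
#'
#' @param per_artery_flux_um3_s cycle-mean BM flux per artery, um^3/s
#'   (sign ignored).
#' @param total_isf_volume_ml interstitial fluid volume to clear, ml
#'   (default 280, a human-brain-scale value).
#' @param n_arteries number of parallel drainage routes (default 1).
#' @return turnover time in days.
#' @examples
#' turnover_time(6.33e-2, total_isf_volume_ml = 280)  # ~5.1e13 days
#' @export
turnover_time <- function(per_artery_flux_um3_s, total_isf_volume_ml = 280,
                          n_arteries = 1) {
  if (any(per_artery_flux_um3_s == 0)) {
    rlang::abort("flux must be non-zero to define a turnover time")
  }
  volume_um3 <- total_isf_volume_ml * 1e12   # 1 ml = 1 cm^3 = 1e12 um^3
  volume_um3 / (abs(per_artery_flux_um3_s) * n_arteries) / 86400
}
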