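#' Plot a velocity or flux waveform
#'
#' @param object an `ipad_waveform` (one period) or `ipad_series`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ipad_waveform <- function(object, ...) {
  ycol <- if ("q" %in% names(object)) "q" else "v"
  ylab <- if (ycol == "q") "inlet flux (cm³/s)" else "velocity (cm/s)"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data[[ycol]])) +
    ggplot2::geom_line(colour = "#8d2f23") +
    ggplot2::labs(x = "time in cycle (s)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ipad_waveform
#' @export
autoplot.ipad_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line(colour = "grey35", linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "velocity (cm/s)") +
    ggplot2::theme_minimal()
}

#' Plot hemodynamic fields over the final cycle
#'
#' Time series of flux and pressure at a station of each segment over the
#' final cardiac cycle.
#'
#' @param object a `hemo_fields` object.
#' @param station fractional position along each segment in `[0, 1]`
#'   (default mid-vessel).
#' @param ... unused.
#' @return a ggplot, faceted by variable.
#' @export
autoplot.hemo_fields <- function(object, station = 0.5, ...) {
  it <- final_cycle_index(object$t, object$period)
  df <- purrr::map_dfr(c("mca", "d1", "d2"), function(nm) {
    s <- object[[nm]]
    j <- 1L + as.integer(round(station * (length(s$z) - 1)))
    tibble::tibble(
      segment = nm, t = object$t[it] - object$t[it[1]],
      `flux (cm³/s)` = s$Q[j, it],
      `pressure (dyn/cm²)` = s$p[j, it]
    )
  })
  long <- tidyr::pivot_longer(df, cols = -c("segment", "t"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time in final cycle (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the BM drainage state
#'
#' Cycle-mean axial Darcy flux profile along the vessel (final cycle) and the
#' BM width history at the reporting station.
#'
#' @param object a `bm_state`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bm_state <- function(object, ...) {
  it <- final_cycle_index(object$t, object$period)
  df <- tibble::tibble(
    z = object$z,
    q1_mean = rowMeans(object$q1[, it, drop = FALSE]) * 1e4
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$q1_mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "#1f5673") +
    ggplot2::labs(
      x = "axial position z (cm)",
      y = "cycle-mean Darcy flux q₁ (µm/s)",
      title = sprintf("K₀/K₁ = %g, η = %g",
                      object$ratio, object$eta)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a valve-ratio sweep
#'
#' Cycle-mean BM flux against the valve ratio, one line per BM position,
#' with the reverse/forward transition marked.
#'
#' @param sweep a tibble from [eta_ratio_sweep()].
#' @return a ggplot.
#' @export
plot_ratio_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$ratio,
                                      y = .data$mean_flux_um3_s,
                                      colour = factor(.data$eta))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(K[0] / K[1]),
                  y = "cycle-mean BM flux (µm³/s)",
                  colour = expression(eta)) +
    ggplot2::theme_minimal()
}
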