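#' Synthetic Doppler-like MCA velocity series
#'
#' Generates a pulsatile centreline-velocity time series emulating a
#' transcranial Doppler recording of the middle cerebral artery. Each beat is
#' a smooth periodic template (fast systolic upstroke, sharp systolic peak,
#' dicrotic notch and wave, exponential-like diastolic decay) built once from
#' clinical MCA envelope landmarks; beats receive multiplicative amplitude
#' jitter on the pulsatile component, mild period jitter, and additive white
#' noise. The trace is a stand-in for a patient recording: its defaults are
#' frozen so that the converted volumetric flux lies in the literature MCA
#' range (roughly 1.5-4.5 cm^3/s for a 0.14 cm radius).
#'
#' @param period cardiac period in seconds (> 0).
#' @param n_beats number of complete beats to generate (>= 1).
#' @param fs sampling frequency, Hz.
#' @param v_peak,v_min peak systolic and end-diastolic (beat-foot) velocity,
#'   cm/s. `v_min` is hit exactly at each beat foot; the smooth interpolation
#'   of the sharp systolic upstroke may undershoot it slightly in between, as
#'   real Doppler envelopes do.
#' @param jitter relative s.d. of the per-beat multiplicative amplitude
#'   jitter (>= 0); the per-beat period jitter uses `jitter / 3`.
#' @param noise_sd s.d. of additive white noise, cm/s.
#' @param seed integer seed; the generator is fully reproducible for a fixed
#'   seed and parameter set.
#' @return A tibble of class `ipad_series` with columns `t` (s, uniform) and
#'   `v` (cm/s), and a `meta` attribute echoing the generator parameters.
#' @examples
#' ser <- synth_doppler_series(seed = 1)
#' range(ser$v)
#' @export
synth_doppler_series <- function(period = 0.85, n_beats = 12L, fs = 200,
                                 v_peak = 90, v_min = 33,
                                 jitter = 0.03, noise_sd = 1, seed = 1L) {
  if (period <= 0) rlang::abort("'period' must be positive")
  if (n_beats < 1) rlang::abort("'n_beats' must be >= 1")
  if (jitter < 0 || noise_sd < 0) {
    rlang::abort("'jitter' and 'noise_sd' must be >= 0")
  }
  if (v_peak <= v_min) rlang::abort("'v_peak' must exceed 'v_min'")
  shape <- beat_shape_fun()
  set.seed(as.integer(seed))
  amp <- (v_peak - v_min) * (1 + jitter * stats::rnorm(n_beats))
  per <- period * (1 + (jitter / 3) * stats::rnorm(n_beats))
  feet <- c(0, cumsum(per))
  total <- feet[n_beats + 1]
  t <- seq(0, total, by = 1 / fs)
  t <- t[t < total]
  beat <- findInterval(t, feet, rightmost.closed = TRUE)
  tau <- (t - feet[beat]) / per[beat]
  v <- v_min + amp[beat] * shape(tau)
  if (noise_sd > 0) v <- v + noise_sd * stats::rnorm(length(v))
  out <- tibble::tibble(t = t, v = v)
  attr(out, "meta") <- list(
    period = period, n_beats = as.integer(n_beats), fs = fs,
    v_peak = v_peak, v_min = v_min, jitter = jitter,
    noise_sd = noise_sd, seed = as.integer(seed), feet = feet
  )
  class(out) <- c("ipad_series", class(out))
  out
}

# Periodic beat template, normalised to [0, 1] between end-diastolic foot and
# peak systole. Landmarks follow healthy adult MCA Doppler envelopes.
beat_shape_fun <- function() {
  tau <- c(0.000, 0.030, 0.060, 0.085, 0.110, 0.140, 0.180, 0.240,
           0.300, 0.360, 0.430, 0.550, 0.700, 0.850, 0.940, 1.000)
  v <- c(33, 62, 82, 90, 82, 68, 57, 50, 46, 52, 49, 44, 40, 36.5, 34, 33)
  s <- (v - min(v)) / (max(v) - min(v))
  # periodic cubic spline (first == last) evaluated on the unit circle
  fit <- stats::splinefun(tau, s, method = "periodic")
  function(x) fit(x %% 1)
}

#' Average the final beats of a velocity series in Fourier space
#'
#' Segments the last `n_peaks` complete beats of a pulsatile series (beat
#' boundaries by foot detection: the local minimum preceding each maximal
#' systolic upslope), resamples each beat onto a common `n_grid`-point grid of
#' one period with a cubic spline, averages the complex Fourier coefficients
#' across beats, and inverse-transforms. Because the transform is linear this
#' equals the time-domain mean of the resampled beats; it is carried out in
#' Fourier space so that the smoothing procedure is explicit.
#'
#' @param series an `ipad_series` (or any data frame with `t`, `v`).
#' @param n_peaks number of final beats to average (default 10).
#' @param period target cardiac period in seconds for the output grid.
#' @param n_grid number of output samples (a power of two; default 1024).
#' @return A tibble of class `ipad_waveform` with columns `t` in `[0, period)`
#'   and `v` (cm/s), attributes `period`, `kind = "velocity"`.
#' @examples
#' wf <- fourier_average_peaks(synth_doppler_series(seed = 1))
#' nrow(wf)
#' @export
fourier_average_peaks <- function(series, n_peaks = 10L, period = 0.85,
                                  n_grid = 1024L) {
  if (period <= 0) rlang::abort("'period' must be positive")
  feet <- detect_feet(series$t, series$v)
  if (length(feet) < n_peaks + 1) {
    rlang::abort(sprintf(
      "insufficient data: %d complete beats detected, %d requested",
      max(length(feet) - 1, 0), n_peaks))
  }
  feet <- utils::tail(feet, n_peaks + 1)
  tau_out <- seq(0, 1 - 1 / n_grid, length.out = n_grid)
  coef <- matrix(0 + 0i, nrow = n_grid, ncol = n_peaks)
  for (b in seq_len(n_peaks)) {
    t0 <- feet[b]; t1 <- feet[b + 1]
    sel <- series$t >= t0 - 0.15 * (t1 - t0) &
      series$t <= t1 + 0.15 * (t1 - t0)
    tau <- (series$t[sel] - t0) / (t1 - t0)
    vb <- stats::spline(tau, series$v[sel], xout = tau_out,
                        method = "fmm")$y
    coef[, b] <- stats::fft(vb)
  }
  v <- Re(stats::fft(rowMeans(coef), inverse = TRUE)) / n_grid
  out <- tibble::tibble(t = tau_out * period, v = v)
  attr(out, "period") <- period
  attr(out, "kind") <- "velocity"
  attr(out, "n_peaks") <- as.integer(n_peaks)
  class(out) <- c("ipad_waveform", class(out))
  out
}

# Beat feet: local minimum preceding each maximal systolic upslope. The
# slope detector runs on a lightly smoothed trace (5-sample moving average)
# so that sample-to-sample noise cannot fire it, and events closer together
# than half the median beat interval are merged (keeping the stronger
# upslope): a refractory period, as in standard beat detectors.
detect_feet <- function(t, v) {
  k <- 5L
  vs <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  vs[is.na(vs)] <- v[is.na(vs)]
  dv <- diff(vs) / diff(t)
  thr <- 0.5 * max(dv)
  up <- which(dv > thr)
  if (!length(up)) return(numeric(0))
  # group consecutive upslope samples into one event per beat
  grp <- cumsum(c(1, diff(up) > 3))
  events <- vapply(split(up, grp), function(ix) ix[which.max(dv[ix])], 1L)
  if (length(events) > 1) {
    min_gap <- 0.5 * stats::median(diff(t[events]))
    repeat {
      close <- which(diff(t[events]) <= min_gap)
      if (!length(close)) break
      i <- close[1] + 1L
      drop <- if (dv[events[i]] > dv[events[i - 1L]]) i - 1L else i
      events <- events[-drop]
    }
  }
  feet <- numeric(0)
  for (e in events) {
    j <- e
    while (j > 1 && vs[j - 1] <= vs[j]) j <- j - 1
    feet <- c(feet, t[j])
  }
  unique(feet)
}

#' Convert a velocity waveform to volumetric flux
#'
#' `Q(t) = profile_factor * v(t) * pi * lumen_radius^2`. The default
#' `profile_factor = 1` corresponds to a flat velocity profile with a thin
#' boundary layer; values below 1 account for a blunted profile. Negative
#' velocities are carried through unchanged.
#'
#' @param waveform an `ipad_waveform` with velocity samples (`v`, cm/s).
#' @param lumen_radius lumen radius, cm (> 0).
#' @param profile_factor dimensionless factor in (0, 1].
#' @return An `ipad_waveform` tibble with columns `t` and `q` (cm^3/s),
#'   attribute `kind = "flux"`.
#' @examples
#' wf <- fourier_average_peaks(synth_doppler_series(seed = 1))
#' qf <- velocity_to_flux(wf, lumen_radius = 0.14)
#' mean(qf$q)
#' @export
velocity_to_flux <- function(waveform, lumen_radius, profile_factor = 1) {
  if (lumen_radius <= 0) rlang::abort("'lumen_radius' must be positive")
  if (profile_factor <= 0 || profile_factor > 1) {
    rlang::abort("'profile_factor' must lie in (0, 1]")
  }
  out <- tibble::tibble(
    t = waveform$t,
    q = profile_factor * waveform$v * pi * lumen_radius^2
  )
  attr(out, "period") <- attr(waveform, "period")
  attr(out, "kind") <- "flux"
  class(out) <- c("ipad_waveform", class(out))
  out
}

#' Evaluate a single-period waveform at arbitrary times (periodic)
#'
#' Linear interpolation on the waveform's sample grid, wrapped periodically.
#'
#' @param waveform an `ipad_waveform`.
#' @param t times in seconds (any real values).
#' @return numeric vector of samples.
#' @export
evaluate_waveform <- function(waveform, t) {
  period <- attr(waveform, "period")
  ycol <- if ("q" %in% names(waveform)) waveform$q else waveform$v
  n <- length(ycol)
  tt <- c(waveform$t, period)
  yy <- c(ycol, ycol[1])
  stats::approx(tt, yy, xout = t %% period)$y
}

#' Build the default inlet flux waveform from a configuration
#'
#' Runs the generator -> Fourier averaging -> flux conversion chain with the
#' parameters in `cfg$inlet` and the MCA upstream radius.
#'
#' @param cfg an [ipad_config()].
#' @return An `ipad_waveform` flux tibble (one period).
#' @export
inlet_flux_waveform <- function(cfg) {
  p <- cfg$inlet
  ser <- synth_doppler_series(
    period = cfg$T, n_beats = p$n_beats, fs = p$fs,
    v_peak = p$v_peak, v_min = p$v_min,
    jitter = p$jitter, noise_sd = p$noise_sd, seed = cfg$seed
  )
  wf <- fourier_average_peaks(ser, n_peaks = p$n_peaks, period = cfg$T,
                              n_grid = p$n_grid)
  velocity_to_flux(wf, lumen_radius = cfg$vessels$Ru[1],
                   profile_factor = p$profile_factor)
}

#' Write / read a waveform fixture
#'
#' Two-column CSV (`t_seconds`, `value`) with a JSON sidecar (`<path>.json`)
#' carrying the period, units and generator metadata.
#'
#' @param waveform an `ipad_waveform`.
#' @param path CSV file path.
#' @return `path` (write) or an `ipad_waveform` (read).
#' @export
write_waveform <- function(waveform, path) {
  ycol <- if ("q" %in% names(waveform)) "q" else "v"
  utils::write.csv(
    data.frame(t_seconds = waveform$t, value = waveform[[ycol]]),
    path, row.names = FALSE)
  meta <- list(
    period = attr(waveform, "period"),
    kind = attr(waveform, "kind"),
    units = if (ycol == "q") "cm^3 s^-1" else "cm s^-1"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nm <- if (identical(meta$kind, "flux")) "q" else "v"
  out <- tibble::tibble(t = d$t_seconds)
  out[[nm]] <- d$value
  attr(out, "period") <- meta$period
  attr(out, "kind") <- meta$kind
  class(out) <- c("ipad_waveform", class(out))
  out
}
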