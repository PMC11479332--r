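#' Low-pass filter specification for respiration isolation
#'
#' Chebyshev Type II design: monotone passband, equiripple stopband at
#' `stopband_attenuation` dB below unity, stopband edge at `cutoff` Hz.
#' Applied forward-backward ([isolate_respiration()]) for zero net phase, so
#' breath extrema keep their timing.
#'
#' @param cutoff Stopband edge, Hz; must lie below the Nyquist frequency.
#' @param order Filter order (>= 2).
#' @param stopband_attenuation Minimum stopband attenuation, dB.
#' @param zero_phase Apply forward-backward (TRUE, default).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(cutoff = 0.5, order = 5, stopband_attenuation = 40,
                        zero_phase = TRUE) {
  if (order < 2) stop("filter order must be >= 2", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  structure(list(filter_family = "Chebyshev Type II", cutoff = cutoff,
                 order = order,
                 stopband_attenuation = stopband_attenuation,
                 zero_phase = zero_phase),
            class = "filter_spec")
}

#' Personalized respiration filter
#'
#' Estimates the recording's dominant respiration frequency from the power
#' spectrum of the detrended CoM signals restricted to 0.1-0.5 Hz, and
#' places the Chebyshev II stopband edge at `multiple` times that frequency.
#' With the default order-5, 40 dB design the respiration line is passed at
#' gain > 0.999 while the cardiac band (around 1 Hz) is attenuated below
#' 1%.
#'
#' @param com CoM data.frame from [compute_com()].
#' @param rate Sampling rate, Hz.
#' @param multiple Stopband edge as a multiple of the estimated respiration
#'   frequency.
#' @param ... Passed to [filter_spec()].
#' @return A `filter_spec` with the personalized cutoff; the estimated
#'   frequency is attached as attribute `resp_freq`.
#' @export
personalize_filter <- function(com, rate = 50, multiple = 3, ...) {
  f <- dominant_frequency(com$CoM_x, rate, c(0.1, 0.5))
  fy <- dominant_frequency(com$CoM_y, rate, c(0.1, 0.5))
  # use whichever axis carries more band power
  px <- attr(f, "power"); py <- attr(fy, "power")
  fr <- as.numeric(if (is.na(f) || (!is.na(fy) && py > px)) fy else f)
  if (is.na(fr)) fr <- 0.25  # fallback: typical adult resting rate
  spec <- filter_spec(cutoff = multiple * fr, ...)
  attr(spec, "resp_freq") <- as.numeric(fr)
  spec
}

# Frequency of the largest FFT power line within `band` (Hz); NA if the
# signal is too short or flat. Power attached as an attribute.
dominant_frequency <- function(x, rate, band) {
  n <- length(x)
  if (n < 4 * rate) return(structure(NA_real_, power = 0))
  x <- x - mean(x)
  if (all(abs(x) < .Machine$double.eps)) {
    return(structure(NA_real_, power = 0))
  }
  sp <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * rate / n
  keep <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(keep)) return(structure(NA_real_, power = 0))
  i <- keep[which.max(sp[keep])]
  structure(freqs[i], power = sp[i])
}

# Shared zero-phase IIR application. The signal is demeaned first (the
# start-up transient of the forward-backward pass scales with the signal
# level around zero) and reflect-padded so edge transients decay inside the
# padding; the mean is restored afterwards (unity DC gain). `dc = FALSE`
# skips restoring the mean (band-pass use).
apply_zero_phase <- function(flt, x, dc = TRUE) {
  mu <- mean(x)
  x0 <- x - mu
  pad <- min(length(x0) - 1L, 100L * (max(length(flt$b), length(flt$a)) - 1L))
  y <- if (pad > 0) {
    head_pad <- 2 * x0[1] - x0[seq(pad + 1, 2)]
    tail_pad <- 2 * x0[length(x0)] - x0[seq(length(x0) - 1, length(x0) - pad)]
    signal::filtfilt(flt, c(head_pad, x0, tail_pad))[(pad + 1):(pad + length(x0))]
  } else {
    signal::filtfilt(flt, x0)
  }
  if (dc) y + mu else y
}

#' Isolate the respiration component of the CoM trace
#'
#' Low-pass filters `CoM_x` and `CoM_y` with the given Chebyshev Type II
#' specification, applied forward and backward so the output has zero net
#' phase shift and the same length as the input.
#'
#' @param com CoM data.frame from [compute_com()].
#' @param spec A [filter_spec()]; default: fixed 0.5 Hz stopband edge.
#' @param rate Sampling rate, Hz.
#' @return A data.frame with columns `CoM_resp_x`, `CoM_resp_y`.
#' @export
isolate_respiration <- function(com, spec = filter_spec(), rate = 50) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- rate / 2
  if (spec$cutoff >= nyq) {
    stop("filter cutoff must lie below the Nyquist frequency", call. = FALSE)
  }
  flt <- signal::cheby2(spec$order, spec$stopband_attenuation,
                        spec$cutoff / nyq, type = "low")
  data.frame(CoM_resp_x = apply_zero_phase(flt, com$CoM_x),
             CoM_resp_y = apply_zero_phase(flt, com$CoM_y))
}

#' Band-pass filter the corner forces for the cardiac component
#'
#' Isolates the ballistocardiographic band of each load-cell channel with a
#' zero-phase Chebyshev Type II band-pass. Feeds the `rmsPulse` feature.
#'
#' @param force Force data.frame with columns `LH`, `RH`, `LF`, `RF`.
#' @param band Length-2 numeric, pass band in Hz (default 0.8-2.5).
#' @param rate Sampling rate, Hz.
#' @param order Per-edge filter order.
#' @param stopband_attenuation Stopband attenuation, dB.
#' @return A data.frame of filtered channels, same columns and length.
#' @export
pulse_band_filter <- function(force, band = c(0.8, 2.5), rate = 50,
                              order = 4, stopband_attenuation = 30) {
  nyq <- rate / 2
  if (length(band) != 2 || band[1] <= 0 || band[2] >= nyq ||
      band[1] >= band[2]) {
    stop("band must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  flt <- signal::cheby2(order, stopband_attenuation, band / nyq,
                        type = "pass")
  out <- lapply(force[c("LH", "RH", "LF", "RF")],
                function(x) apply_zero_phase(flt, x, dc = FALSE))
  as.data.frame(out)
}
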