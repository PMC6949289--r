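# Pre-processing chain: powerline-harmonic notch bank applied zero-phase,
# sync-pulse edge detection by differentiation, dual-stream alignment with a
# pulse-count check, and force up-sampling to the iEMG rate.

#' Design a powerline-harmonic notch filter bank
#'
#' Builds one narrow IIR stop-band per harmonic of `base` up to `fmax`
#' (100 centers for 50 Hz harmonics up to 5 kHz), each with a -3 dB
#' bandwidth of `width` Hz, intended for zero-phase (forward-backward)
#' application.  Each notch is an order-2 Butterworth band-stop (fourth
#' order overall), whose steeper skirts remove less out-of-band energy than
#' a single biquad when a signal is re-filtered; still higher orders sit
#' too close to the unit circle to filter reliably in double precision at
#' this narrowness.
#'
#' @param fs sampling rate in Hz; must exceed `2 * fmax`.
#' @param base fundamental interference frequency in Hz.
#' @param fmax highest harmonic to include, Hz.
#' @param width -3 dB notch width in Hz.
#' @return object of class `notch_bank` with the centers, an `active` subset
#'   (initially all centers) and per-center biquad coefficients.
#' @examples
#' bank <- design_notch_bank(10240)
#' length(bank$centers)   # 100
#' @export
design_notch_bank <- function(fs, base = 50, fmax = 5000, width = 2) {
  if (fmax >= fs / 2)
    iemg_error("iemg_design_error",
               sprintf("fmax (%g Hz) must lie below the Nyquist rate (%g Hz)",
                       fmax, fs / 2))
  stopifnot(width > 0, base > 0)
  centers <- seq(base, fmax, by = base)
  filters <- lapply(centers, function(f0) {
    bt <- signal::butter(2, c(f0 - width / 2, f0 + width / 2) / (fs / 2),
                         type = "stop")
    list(b = bt$b, a = bt$a)
  })
  structure(list(fs = fs, base = base, width = width, centers = centers,
                 active = centers, filters = filters),
            class = "notch_bank")
}

#' @export
print.notch_bank <- function(x, ...) {
  cat(sprintf("Notch bank: %d centers (%g..%g Hz, width %g Hz) at fs %g Hz; %d active\n",
              length(x$centers), min(x$centers), max(x$centers), x$width,
              x$fs, length(x$active)))
  invisible(x)
}

#' Frequency response of the active notch cascade
#'
#' Evaluates the single-pass complex response of the cascade of active
#' notches at the requested frequencies.
#'
#' @param bank a [design_notch_bank()] object.
#' @param f frequencies in Hz.
#' @return complex response, same length as `f`.
#' @export
notch_response <- function(bank, f) {
  z1 <- exp(-1i * 2 * pi * f / bank$fs)
  poly_eval <- function(coef) Reduce(`+`, lapply(seq_along(coef), function(k)
    coef[k] * z1^(k - 1)))
  h <- rep(1 + 0i, length(f))
  for (k in which(bank$centers %in% bank$active)) {
    fl <- bank$filters[[k]]
    h <- h * poly_eval(fl$b) / poly_eval(fl$a)
  }
  h
}

#' Apply the notch bank with zero phase
#'
#' Runs every active notch of the bank over the signal forward and backward
#' (filtfilt-style), so the net phase shift is zero and channel timing is
#' preserved.  Odd-symmetric mirror padding suppresses edge transients; the
#' output has the length of the input.
#'
#' @param bank a [design_notch_bank()] object (possibly subset by
#'   [select_active_notches()]).
#' @param x numeric signal sampled at `bank$fs`.
#' @return filtered signal, same length as `x`.
#' @export
apply_zero_phase <- function(bank, x) {
  n <- length(x)
  if (n < 24L)
    iemg_error("iemg_length_error",
               "signal shorter than the filter transient; cannot filter")
  pad <- min(n - 1L, ceiling(3 * bank$fs / bank$width))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  for (k in which(bank$centers %in% bank$active)) {
    fl <- bank$filters[[k]]
    xp <- signal::filter(fl$b, fl$a, xp)
    xp <- rev(signal::filter(fl$b, fl$a, rev(xp)))
  }
  xp[(pad + 1L):(pad + n)]
}

#' Keep only the notches a recording needs
#'
#' The deposited recordings were filtered with a per-recording subset of the
#' harmonic bank to minimize spectral distortion.  This selector estimates
#' the periodogram of `x` and retains a center only when the power inside
#' its +/- 1 Hz band exceeds `factor` times the local baseline (median
#' periodogram power over the surrounding +/- 10 Hz, the band itself
#' excluded).
#'
#' @param bank a [design_notch_bank()] object.
#' @param x signal to inspect.
#' @param factor activation threshold relative to the local baseline.
#' @param band half-width of the harmonic band, Hz.
#' @param surround half-width of the baseline neighbourhood, Hz.
#' @return the bank with its `active` set reduced.
#' @export
select_active_notches <- function(bank, x, factor = 3, band = 1,
                                  surround = 10) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x))[seq_len(n %/% 2L)])^2
  freq <- (seq_len(n %/% 2L) - 1L) * bank$fs / n
  active <- vapply(bank$centers, function(f0) {
    inband <- freq >= f0 - band & freq <= f0 + band
    near <- freq >= f0 - surround & freq <= f0 + surround & !inband
    if (!any(inband) || !any(near)) return(FALSE)
    mean(spec[inband]) > factor * stats::median(spec[near])
  }, logical(1))
  bank$active <- bank$centers[active]
  bank
}

#' Detect synchronization pulses
#'
#' Locates the 5 V / 200 ms / 0.5 Hz square synchronization pulses by
#' numerically differentiating the sync channel and thresholding the
#' derivative at half the pulse amplitude, so detection is insensitive to
#' how the auxiliary input scaled the pulses.  Edges closer than the
#' debounce window are merged (first crossing kept); a final pulse whose
#' trailing edge is missing is excluded from the count.
#'
#' @param sync numeric sync-channel signal.
#' @param fs its sampling rate in Hz.
#' @param debounce merge window in seconds (default 100 ms, half the pulse
#'   width).
#' @return object of class `sync_events`: leading/trailing edge sample
#'   indices (1-based, first sample of the new level), complete-pulse
#'   `count`, and `fs`.
#' @export
detect_sync_pulses <- function(sync, fs, debounce = 0.1) {
  amp <- diff(range(sync))
  empty <- structure(list(lead = integer(0), trail = integer(0), count = 0L,
                          fs = fs), class = "sync_events")
  if (length(sync) < 2L || amp <= 0) return(empty)
  d <- diff(sync)
  thr <- amp / 2
  merge_edges <- function(idx) {
    if (!length(idx)) return(integer(0))
    keep <- c(TRUE, diff(idx) > debounce * fs)
    idx[keep]
  }
  lead <- merge_edges(which(d > thr) + 1L)
  trail <- merge_edges(which(d < -thr) + 1L)
  trail <- trail[if (length(lead)) trail > lead[1] else FALSE]  # starts high
  count <- sum(vapply(lead, function(l) any(trail > l), logical(1)))
  structure(list(lead = lead, trail = trail, count = as.integer(count),
                 fs = fs), class = "sync_events")
}

#' @export
print.sync_events <- function(x, ...) {
  cat(sprintf("Sync events: %d complete pulse(s) at fs %g Hz", x$count, x$fs))
  if (length(x$lead))
    cat(sprintf("; first leading edge at %.3f s", (x$lead[1] - 1) / x$fs))
  cat("\n")
  invisible(x)
}

#' Align the amplifier and force acquisition streams
#'
#' Both devices record the same synchronization pulse train; the relative
#' start offset of the two streams is the difference between the times of
#' their first detected leading edges, and the total pulse counts must agree
#' for the two files to hold the same data.  A positive offset means the
#' force stream started later.
#'
#' @param emg_sync [detect_sync_pulses()] result for the amplifier's
#'   auxiliary sync channel.
#' @param force_sync the same for the force stream's recorded sync channel.
#' @return list with `offset` (seconds), `verified` (`TRUE`) and `count`.
#'   A pulse-count mismatch raises an `iemg_alignment_error` carrying both
#'   counts.
#' @export
align_streams <- function(emg_sync, force_sync) {
  stopifnot(inherits(emg_sync, "sync_events"),
            inherits(force_sync, "sync_events"))
  if (!length(emg_sync$lead) || !length(force_sync$lead))
    iemg_error("iemg_alignment_error",
               "cannot align: a stream has no detected sync pulses",
               emg_count = emg_sync$count, force_count = force_sync$count)
  if (emg_sync$count != force_sync$count)
    iemg_error("iemg_alignment_error",
               sprintf("sync pulse counts differ: %d (EMG) vs %d (force)",
                       emg_sync$count, force_sync$count),
               emg_count = emg_sync$count, force_count = force_sync$count)
  offset <- (emg_sync$lead[1] - 1) / emg_sync$fs -
            (force_sync$lead[1] - 1) / force_sync$fs
  list(offset = offset, verified = TRUE, count = emg_sync$count)
}

#' Up-sample a force series to the iEMG rate
#'
#' Linearly interpolates a 200 Hz force series onto the amplifier's sample
#' grid over the same time span (endpoints held), so force and iEMG share a
#' common time axis in the merged record.  Linear interpolation introduces
#' no overshoot, so the output stays within the input's range.
#'
#' @param force numeric series sampled at `fs_in`.
#' @param fs_in input sampling rate, Hz.
#' @param fs_target output sampling rate, Hz.
#' @return interpolated series on the grid `seq(0, (n-1)/fs_in, 1/fs_target)`.
#' @export
upsample_force <- function(force, fs_in = 200, fs_target = 10240) {
  n <- length(force)
  if (n < 2L)
    iemg_error("iemg_length_error",
               "need at least 2 samples to interpolate a force series")
  t_in <- (seq_len(n) - 1L) / fs_in
  t_out <- seq(0, t_in[n], by = 1 / fs_target)
  stats::approx(t_in, force, xout = t_out, method = "linear", rule = 2)$y
}
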