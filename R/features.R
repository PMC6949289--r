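# Signal features and quantitative QC: RMS envelopes, pairwise channel
# cross-correlation, spectral percentile summaries and the computational
# channel/force pairing table.

#' Sliding RMS envelope
#'
#' Root-mean-square of the signal over a 250 ms window shifted in steps of
#' one sample.  In the zero-phase variant the window is centred on the
#' current sample, so envelope and signal stay aligned; windows shrink to
#' the available samples at the boundaries (no padding, so no amplitude
#' bias).  The causal variant is the centred envelope delayed by half the
#' window (1280 samples at 10240 Hz), the form a real-time feature extractor
#' could produce; its first half-window repeats the initial value.  Values
#' are not normalized.
#'
#' @param x numeric signal, mV.
#' @param fs sampling rate, Hz.
#' @param window_ms window width, ms.
#' @param causal return the delayed (causal) variant.
#' @return object of class `envelope_series`: `values` (same length as
#'   `x`), `window` (samples), `shift` (samples, 0 for zero-phase), `fs`,
#'   `mode`.
#' @export
rms_envelope <- function(x, fs, window_ms = 250, causal = FALSE) {
  n <- length(x)
  w <- as.integer(round(window_ms * fs / 1000))
  if (w >= n)
    iemg_error("iemg_length_error",
               sprintf("window (%d samples) must be shorter than the signal (%d)",
                       w, n))
  half <- w %/% 2L
  cs <- cumsum(c(0, x^2))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + (w - half - 1L))
  env <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  shift <- 0L
  if (causal) {
    shift <- half
    env <- c(rep(env[1], half), env[seq_len(n - half)])
  }
  structure(list(values = env, window = w, shift = shift, fs = fs,
                 mode = if (causal) "causal" else "zero-phase"),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("RMS envelope (%s): %d samples, window %d samples (%.0f ms) at %g Hz",
              x$mode, length(x$values), x$window, x$window / x$fs * 1000,
              x$fs))
  if (x$shift > 0) cat(sprintf(", shift %d samples", x$shift))
  cat("\n")
  invisible(x)
}

# max |normalized cross-correlation| over lags within +/- max_lag samples
max_xcorr <- function(x, y, max_lag) {
  x <- x - mean(x); y <- y - mean(y)
  ex <- sum(x^2); ey <- sum(y^2)
  if (ex == 0 || ey == 0) return(NA_real_)
  L <- length(x)
  N <- stats::nextn(2L * L)
  cc <- Re(stats::fft(stats::fft(c(x, numeric(N - L))) *
                      Conj(stats::fft(c(y, numeric(N - L)))),
                      inverse = TRUE)) / N
  lags <- -max_lag:max_lag
  max(abs(cc[(lags %% N) + 1L])) / sqrt(ex * ey)
}

#' Pairwise channel cross-correlation matrix
#'
#' Crosstalk screen over the iEMG channels of a (notch-filtered) record: per
#' channel pair the maximum absolute normalized cross-correlation over lags
#' within ±`max_lag_ms`, computed inside each movement segment (maximal runs
#' of a constant non-zero movement code) and aggregated as the median with
#' 5th/95th percentiles across segments.  Selective fine-wire channels show
#' near-zero off-diagonal values; common noise or wire migration raises
#' them.
#'
#' @param rec a [session_record()] (iEMG channels should be notch-filtered
#'   first, e.g. with [apply_zero_phase()]).
#' @param per_segment aggregate across movement segments; when `FALSE` the
#'   whole recording forms one segment.
#' @param max_lag_ms cross-correlation lag cap, ms.
#' @param min_segment_s segments shorter than this are skipped.
#' @return object of class `crosscorr_matrix`: symmetric matrices `median`,
#'   `p5`, `p95` with unit diagonal, plus `segments` used.  Zero-variance
#'   channel segments are excluded from aggregation.
#' @export
channel_crosscorr <- function(rec, per_segment = TRUE, max_lag_ms = 100,
                              min_segment_s = 0.5) {
  stopifnot(inherits(rec, "session_record"))
  idx <- iemg_channels(rec)
  if (length(idx) < 2L)
    iemg_error("iemg_validation_error",
               "need at least two iEMG channels for a cross-correlation matrix")
  segs <- if (per_segment) {
    mv <- movement_stream(rec)
    codes <- setdiff(unique(code100(mv)), 0L)
    do.call(rbind, lapply(codes / 100, function(cd) segment_by_code(rec, cd)))
  } else {
    data.frame(start = 1L, end = nrow(rec$data))
  }
  segs <- segs[segs$end - segs$start + 1L >= min_segment_s * rec$fs, ,
               drop = FALSE]
  if (!nrow(segs))
    iemg_error("iemg_validation_error", "no usable movement segments")
  max_lag <- round(max_lag_ms / 1000 * rec$fs)
  k <- length(idx)
  vals <- array(NA_real_, c(k, k, nrow(segs)))
  for (si in seq_len(nrow(segs))) {
    rows <- segs$start[si]:segs$end[si]
    for (a in seq_len(k - 1L))
      for (b in (a + 1L):k)
        vals[a, b, si] <- max_xcorr(rec$data[rows, idx[a]],
                                    rec$data[rows, idx[b]], max_lag)
  }
  agg <- function(f) {
    m <- diag(1, k)
    for (a in seq_len(k - 1L))
      for (b in (a + 1L):k) {
        v <- vals[a, b, ]
        v <- v[!is.na(v)]
        m[a, b] <- m[b, a] <- if (length(v)) f(v) else NA_real_
      }
    dimnames(m) <- list(rec$channels[idx], rec$channels[idx])
    m
  }
  structure(list(median = agg(stats::median),
                 p5 = agg(function(v) stats::quantile(v, 0.05, names = FALSE)),
                 p95 = agg(function(v) stats::quantile(v, 0.95, names = FALSE)),
                 segments = nrow(segs)),
            class = "crosscorr_matrix")
}

#' @export
print.crosscorr_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Channel cross-correlation (median over %d segment(s)):\n",
              x$segments))
  print(round(x$median, digits))
  invisible(x)
}

#' Welch amplitude spectrum
#'
#' Averaged-periodogram amplitude spectrum with Hann windows (1 s segments,
#' 50% overlap by default); the returned amplitude is the square root of the
#' averaged power per frequency bin.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param segment_s segment length, s.
#' @param overlap fractional segment overlap.
#' @return list with `freq` (Hz) and `amplitude`.
#' @export
welch_spectrum <- function(x, fs, segment_s = 1, overlap = 0.5) {
  L <- round(segment_s * fs)
  L <- min(L, length(x))
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  norm <- sum(win^2)
  nf <- L %/% 2L
  p <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- p + Mod(stats::fft(seg)[seq_len(nf)])^2 / norm
  }
  list(freq = (seq_len(nf) - 1L) * fs / L,
       amplitude = sqrt(p / length(starts)))
}

#' Spectral percentile summary of a signal collection
#'
#' Welch amplitude spectrum of every signal in the collection, summarized
#' pointwise across signals as the median with the 25--75 and 9--91
#' percentile bands -- the cumulative spectral view used to screen a whole
#' database of channels at once.
#'
#' @param signals list of numeric signals (or a matrix, one per column),
#'   all sampled at `fs`.
#' @param fs sampling rate, Hz.
#' @param segment_s,overlap passed to [welch_spectrum()].
#' @return object of class `spectrum_summary` with `freq` and the matrices
#'   of pointwise percentiles `p9`, `p25`, `median`, `p75`, `p91`.
#' @export
spectrum_summary <- function(signals, fs, segment_s = 1, overlap = 0.5) {
  if (is.matrix(signals))
    signals <- lapply(seq_len(ncol(signals)), function(j) signals[, j])
  if (!length(signals))
    iemg_error("iemg_validation_error", "empty signal collection")
  specs <- lapply(signals, welch_spectrum, fs = fs, segment_s = segment_s,
                  overlap = overlap)
  nf <- unique(vapply(specs, function(s) length(s$freq), 0L))
  if (length(nf) != 1L)
    iemg_error("iemg_validation_error",
               "signals produce inconsistent frequency grids")
  amp <- do.call(cbind, lapply(specs, `[[`, "amplitude"))
  q <- function(p) apply(amp, 1L, stats::quantile, probs = p, names = FALSE)
  structure(list(freq = specs[[1]]$freq, p9 = q(0.09), p25 = q(0.25),
                 median = q(0.5), p75 = q(0.75), p91 = q(0.91),
                 n = length(signals)),
            class = "spectrum_summary")
}

#' @export
plot.spectrum_summary <- function(x, log = "y", ...) {
  ok <- x$median > 0 | log != "y"
  graphics::plot(x$freq[ok], x$median[ok], type = "n", log = log,
                 xlab = "frequency (Hz)", ylab = "amplitude (mV)", ...)
  graphics::polygon(c(x$freq[ok], rev(x$freq[ok])),
                    c(pmax(x$p9[ok], .Machine$double.xmin),
                      rev(x$p91[ok])), border = NA,
                    col = grDevices::adjustcolor("lightblue", 0.7))
  graphics::polygon(c(x$freq[ok], rev(x$freq[ok])),
                    c(pmax(x$p25[ok], .Machine$double.xmin),
                      rev(x$p75[ok])), border = NA,
                    col = grDevices::adjustcolor("steelblue", 0.6))
  graphics::lines(x$freq[ok], x$median[ok], col = "red")
  invisible(x)
}

#' Pair iEMG channels with force channels
#'
#' Computational surrogate of the deposited channel/force pairing table
#' (which was produced by expert review): for every iEMG channel, finds the
#' force channel and base movement code maximizing the absolute correlation
#' between the channel's RMS envelope and the calibrated force inside that
#' movement's segments.  The pairing `sign` is the sign of that correlation
#' (flexion reads negative on the bidirectional transducers); channels whose
#' best association stays below `floor` are marked unpaired.
#'
#' @param rec a [session_record()].
#' @param envelopes optional list of [rms_envelope()] results (or numeric
#'   vectors), one per iEMG channel; computed from the record when omitted.
#' @param floor minimum `|r|` for a pairing to count.
#' @return data frame of class `pairing_table` with columns `emg_channel`,
#'   `force_channel`, `movement_code`, `sign`, `score`, `paired`; attribute
#'   `method = "computational"` marks it as a surrogate of the expert table.
#' @export
pair_channels_with_forces <- function(rec, envelopes = NULL, floor = 0.3) {
  stopifnot(inherits(rec, "session_record"))
  ei <- iemg_channels(rec)
  fi <- force_channel_index(rec)
  if (!length(fi))
    iemg_error("iemg_validation_error", "record has no force channels")
  if (is.null(envelopes))
    envelopes <- lapply(ei, function(j) rms_envelope(rec$data[, j], rec$fs))
  env_values <- lapply(envelopes, function(e)
    if (inherits(e, "envelope_series")) e$values else as.numeric(e))
  mv <- movement_stream(rec)
  bases <- sort(unique(code100(mv) %/% 100L))
  bases <- bases[bases > 0L]
  forces_n <- apply(rec$data[, fi, drop = FALSE], 2L,
                    function(v) suppressWarnings(volts_to_newtons(v)))
  rows <- lapply(seq_along(ei), function(a) {
    best <- list(score = 0, force = NA_character_, code = NA_real_, sign = NA_real_)
    for (b in bases) {
      # all samples of base stage b, any sub-code
      sel <- code100(mv) %/% 100L == b
      if (sum(sel) < 2L) next
      for (j in seq_along(fi)) {
        f <- forces_n[sel, j]
        if (stats::sd(f) == 0 || stats::sd(env_values[[a]][sel]) == 0) next
        r <- stats::cor(env_values[[a]][sel], f)
        if (!is.na(r) && abs(r) > abs(best$score))
          best <- list(score = r, force = rec$channels[fi[j]],
                       code = b, sign = sign(r))
      }
    }
    data.frame(emg_channel = rec$channels[ei[a]],
               force_channel = if (abs(best$score) >= floor) best$force else
                 NA_character_,
               movement_code = if (abs(best$score) >= floor) best$code else
                 NA_real_,
               sign = if (abs(best$score) >= floor) best$sign else NA_real_,
               score = abs(best$score),
               paired = abs(best$score) >= floor)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pairing_table", class(out))
  attr(out, "method") <- "computational"
  out
}

#' Export the pairing table as delimited text
#'
#' Writes the channel/force pairing table with columns `emg_channel`,
#' `force_channel`, `movement_code`, `sign` and `quality` (the association
#' score) as tab-separated text.
#'
#' @param pairing a [pair_channels_with_forces()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pairing_table <- function(pairing, path) {
  out <- data.frame(emg_channel = pairing$emg_channel,
                    force_channel = pairing$force_channel,
                    movement_code = pairing$movement_code,
                    sign = pairing$sign,
                    quality = pairing$score)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
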