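# Three-pass template-matching motor-unit spike sorter.
#
# Candidate MUAPs are detected by an amplitude threshold, then processed in
# chronological order three times: pass 1 assigns each event to a similar
# template (updating it) or creates a new one; pass 2 reprocesses every event
# updating templates but never creating; templates carrying less than 5% of
# all events are then discarded; pass 3 labels each event with its best
# accepted surviving template or "unknown".  Similarity uses the lag that
# maximizes the cross-correlation, then requires correlation coefficient
# r > 0.9 and mean square difference below half the template power.

#' Detect candidate MUAP events
#'
#' Thresholds the (filtered) signal at `threshold_mult` times the robust
#' noise SD (`median(|x|) / 0.6745`), keeps one event per local maximum of
#' `|x|` within the snippet window -- smaller peaks closer than
#' `merge_frac` of a window to a larger one are merged into it (default half
#' a window, so the secondary phases of one MUAP -- which can sit several
#' ms from its main peak -- can never split into separate events) -- and
#' extracts fixed odd-length snippets centred on each absolute peak,
#' zero-padded at the signal boundaries.
#'
#' @param x filtered iEMG signal, mV.
#' @param fs sampling rate, Hz.
#' @param threshold_mult detection threshold in robust-SD units.
#' @param window_ms snippet window length, ms (10 ms covers physiological
#'   MUAP durations; rounded to an odd sample count).
#' @param merge_frac merge radius as a fraction of the window.
#' @return object of class `candidate_events`: `peaks` (sample indices, in
#'   chronological order), `snippets` (events x window matrix), `threshold`,
#'   `window`, `fs`.
#' @export
detect_candidates <- function(x, fs, threshold_mult = 5, window_ms = 10,
                              merge_frac = 0.5) {
  wl <- round(window_ms * fs / 1000)
  if (wl %% 2L == 0L) wl <- wl + 1L
  half <- (wl - 1L) %/% 2L
  sigma <- stats::median(abs(x)) / 0.6745
  thr <- threshold_mult * sigma
  ax <- abs(x)
  n <- length(x)
  cand <- which(ax > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[ax[cand] >= ax[cand - 1L] & ax[cand] > ax[cand + 1L]]
  # merge: keep the larger peak when two candidates fall inside the radius
  merge_r <- max(1L, round(merge_frac * wl))
  if (length(cand) > 1L) {
    ord <- cand[order(ax[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord)
      if (!length(kept) || min(abs(kept - p)) > merge_r) kept <- c(kept, p)
    cand <- sort(kept)
  }
  snippets <- matrix(0, length(cand), wl)
  for (i in seq_along(cand)) {
    lo <- cand[i] - half; hi <- cand[i] + half
    src <- max(1L, lo):min(n, hi)
    snippets[i, src - lo + 1L] <- x[src]
  }
  structure(list(peaks = cand, snippets = snippets, threshold = thr,
                 window = wl, fs = fs), class = "candidate_events")
}

#' @export
print.candidate_events <- function(x, ...) {
  cat(sprintf("Candidate events: %d peak(s), window %d samples, threshold %.3g mV\n",
              length(x$peaks), x$window, x$threshold))
  invisible(x)
}

# full cross-correlation of demeaned snippet/template via FFT;
# cc(l) = sum_i s0[i] * t0[i - l]
xcorr_lags <- function(s0, t0, max_lag) {
  L <- length(s0)
  N <- 2L * L
  cc <- Re(stats::fft(stats::fft(c(s0, numeric(L))) *
                      Conj(stats::fft(c(t0, numeric(L)))),
                      inverse = TRUE)) / N
  lags <- -max_lag:max_lag
  vals <- cc[(lags %% N) + 1L]
  list(lags = lags, vals = vals)
}

aligned_overlap <- function(s, t, lag) {
  L <- length(s)
  if (lag >= 0) {
    list(s = s[(1L + lag):L], t = t[1L:(L - lag)])
  } else {
    list(s = s[1L:(L + lag)], t = t[(1L - lag):L])
  }
}

#' Score a snippet against a template
#'
#' Aligns the snippet to the template at the lag (within `± max_lag`) that
#' maximizes their cross-correlation, then evaluates the two acceptance
#' criteria on the aligned overlap: (a) correlation coefficient `r > r_thresh`
#' and (b) mean square difference below `mse_frac` times the template power
#' (mean of its squared samples).  A zero-variance snippet has no defined
#' correlation and is rejected with `degenerate = TRUE`.
#'
#' @param snippet,template equal-length waveforms, mV.
#' @param max_lag alignment search half-range in samples (default: half the
#'   window).
#' @param r_thresh correlation acceptance threshold.
#' @param mse_frac mean-square-difference acceptance threshold, as a
#'   fraction of template power.
#' @return object of class `match_score`: `r`, `mse`, `lag`, `power`,
#'   `accepted`, `degenerate`.
#' @export
match_template <- function(snippet, template, max_lag = NULL,
                           r_thresh = 0.9, mse_frac = 0.5) {
  stopifnot(length(snippet) == length(template))
  L <- length(snippet)
  if (is.null(max_lag)) max_lag <- (L - 1L) %/% 2L
  power <- mean(template^2)
  s0 <- snippet - mean(snippet)
  t0 <- template - mean(template)
  if (stats::sd(snippet) == 0 || stats::sd(template) == 0)
    return(structure(list(r = NA_real_, mse = NA_real_, lag = 0L,
                          power = power, accepted = FALSE,
                          degenerate = TRUE), class = "match_score"))
  xc <- xcorr_lags(s0, t0, max_lag)
  lag <- xc$lags[which.max(xc$vals)]
  ov <- aligned_overlap(snippet, template, lag)
  r <- suppressWarnings(stats::cor(ov$s, ov$t))
  if (is.na(r))
    return(structure(list(r = NA_real_, mse = NA_real_, lag = lag,
                          power = power, accepted = FALSE,
                          degenerate = TRUE), class = "match_score"))
  mse <- mean((ov$s - ov$t)^2)
  structure(list(r = r, mse = mse, lag = as.integer(lag), power = power,
                 accepted = (r > r_thresh) && (mse < mse_frac * power),
                 degenerate = FALSE), class = "match_score")
}

#' @export
print.match_score <- function(x, ...) {
  cat(sprintf("Match: r = %.4f, mse = %.4g (power %.4g), lag %d -> %s\n",
              x$r, x$mse, x$power, x$lag,
              if (isTRUE(x$accepted)) "accepted" else "rejected"))
  invisible(x)
}

# snippet shifted onto the template's frame (zero-padded)
shift_snippet <- function(s, lag) {
  L <- length(s)
  out <- numeric(L)
  ov <- if (lag >= 0) {
    out[1L:(L - lag)] <- s[(1L + lag):L]
    out
  } else {
    out[(1L - lag):L] <- s[1L:(L + lag)]
    out
  }
  ov
}

#' Update a template with an accepted MUAP
#'
#' Running mean weighted by the member count: the new waveform is
#' `(n * template + snippet) / (n + 1)`; the count increments and the power
#' is recomputed.
#'
#' @param tpl template (list with `waveform`, `n`, `power`).
#' @param snippet aligned snippet, same length as the waveform.
#' @return updated template.
#' @export
update_template <- function(tpl, snippet) {
  w <- (tpl$n * tpl$waveform + snippet) / (tpl$n + 1)
  list(waveform = w, n = tpl$n + 1L, power = mean(w^2))
}

# roll a template so its absolute peak sits at the window centre; keeps the
# template frame canonical so alignment lags (and reported spike times)
# measure true offsets rather than the anchoring of the first member event
recenter_template <- function(tpl) {
  w <- tpl$waveform
  shift <- ((length(w) + 1L) %/% 2L) - which.max(abs(w))
  if (shift != 0L) {
    tpl$waveform <- shift_snippet(w, -shift)
    tpl$power <- mean(tpl$waveform^2)
  }
  tpl
}

best_accepted <- function(scores) {
  ok <- which(vapply(scores, function(s) isTRUE(s$accepted), logical(1)))
  if (!length(ok)) return(0L)
  rs <- vapply(scores[ok], `[[`, 0, "r")
  ms <- vapply(scores[ok], `[[`, 0, "mse")
  # highest r; ties by lower mse, then lower template index
  ok[order(-rs, ms, ok)][1]
}

#' Sort detected MUAPs into motor units
#'
#' Runs the three-pass chronological template-matching sorter.  Given a raw
#' numeric signal it first detects candidates ([detect_candidates()]); given
#' a `candidate_events` object it sorts those events.  Pass 1 assigns each
#' event to the best accepted template or creates a new one; pass 2
#' reprocesses all events, updating but never creating; templates whose
#' pass-2 share of all events is below `prune_frac` are then discarded;
#' pass 3 labels every event with its best accepted surviving template
#' (highest r, ties by lower mse, then lower template index) or leaves it
#' unknown.  The procedure is deterministic for a given event sequence.
#'
#' @param x numeric signal (mV) or a [detect_candidates()] result.
#' @param fs sampling rate, Hz (when `x` is a signal).
#' @param threshold_mult,window_ms,merge_frac passed to
#'   [detect_candidates()].
#' @param r_thresh,mse_frac acceptance criteria ([match_template()]).
#' @param prune_frac minimum share of events a template must hold after
#'   pass 2 to survive.
#' @param ... passed to methods.
#' @return a [spikesort_result()] whose `unit` templates carry the sorter's
#'   running-mean waveforms; diagnostic fields `assignment` (per-event unit
#'   index, 0 = unknown) and `shares` (pass-2 template shares) are attached.
#' @export
spikesort <- function(x, ...) UseMethod("spikesort")

#' @rdname spikesort
#' @export
spikesort.default <- function(x, fs, threshold_mult = 5, window_ms = 10,
                              merge_frac = 0.5, r_thresh = 0.9,
                              mse_frac = 0.5, prune_frac = 0.05, ...) {
  events <- detect_candidates(x, fs, threshold_mult, window_ms, merge_frac)
  spikesort(events, r_thresh = r_thresh, mse_frac = mse_frac,
            prune_frac = prune_frac)
}

#' @rdname spikesort
#' @export
spikesort.candidate_events <- function(x, r_thresh = 0.9, mse_frac = 0.5,
                                       prune_frac = 0.05, ...) {
  events <- x
  ne <- length(events$peaks)
  fs <- events$fs
  if (ne == 0L)
    return(spikesort_result(list(), list(), fs))
  if (is.unsorted(events$peaks))
    iemg_error("iemg_validation_error",
               "events must be in chronological order")
  templates <- list()
  score_all <- function(snippet)
    lapply(templates, function(tp)
      match_template(snippet, tp$waveform, r_thresh = r_thresh,
                     mse_frac = mse_frac))
  # pass 1: assign-or-create
  for (i in seq_len(ne)) {
    s <- events$snippets[i, ]
    scores <- score_all(s)
    b <- best_accepted(scores)
    if (b > 0L) {
      templates[[b]] <- update_template(templates[[b]],
                                        shift_snippet(s, scores[[b]]$lag))
    } else {
      templates[[length(templates) + 1L]] <-
        list(waveform = s, n = 1L, power = mean(s^2))
    }
  }
  templates <- lapply(templates, recenter_template)
  # pass 2: update only
  count2 <- integer(length(templates))
  for (i in seq_len(ne)) {
    s <- events$snippets[i, ]
    scores <- score_all(s)
    b <- best_accepted(scores)
    if (b > 0L) {
      templates[[b]] <- update_template(templates[[b]],
                                        shift_snippet(s, scores[[b]]$lag))
      count2[b] <- count2[b] + 1L
    }
  }
  templates <- lapply(templates, recenter_template)
  # prune templates below the share floor
  shares <- count2 / ne
  keep <- shares >= prune_frac
  templates <- templates[keep]
  # pass 3: final labelling against surviving templates; an assigned
  # event's spike time is referenced to the template frame (peak + lag),
  # which undoes detection-peak wander between waveform lobes
  assignment <- integer(ne)
  lag3 <- integer(ne)
  for (i in seq_len(ne)) {
    s <- events$snippets[i, ]
    scores <- score_all(s)
    assignment[i] <- best_accepted(scores)
    if (assignment[i] > 0L) lag3[i] <- scores[[assignment[i]]]$lag
  }
  units <- seq_along(templates)
  res <- spikesort_result(
    samples = lapply(units, function(u)
      sort(unique(events$peaks[assignment == u] + lag3[assignment == u]))),
    templates = lapply(templates, `[[`, "waveform"),
    fs = fs,
    unknown = events$peaks[assignment == 0L])
  res$assignment <- assignment
  res$shares <- shares[keep]
  res$member_counts <- vapply(units, function(u) sum(assignment == u), 0L)
  res
}

#' @export
summary.spikesort_result <- function(object, ...) {
  cat(sprintf("Spike sorting summary (%g Hz):\n", object$fs))
  for (i in seq_along(object$samples)) {
    s <- object$samples[[i]]
    rate <- if (length(s) > 1L)
      (length(s) - 1L) / diff(range(s)) * object$fs else NA_real_
    cat(sprintf("  unit %d: %d spikes, mean rate %.1f Hz, template peak %.3g mV\n",
                i, length(s), rate, max(abs(object$templates[[i]]))))
  }
  cat(sprintf("  unknown: %d event(s)\n", length(object$unknown)))
  invisible(object)
}

#' @export
plot.spikesort_result <- function(x, ...) {
  nu <- length(x$templates)
  if (nu == 0L) {
    graphics::plot.new()
    graphics::title("No units")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, nu), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(nu)) {
    w <- x$templates[[i]]
    tt <- (seq_along(w) - 1) / x$fs * 1000
    graphics::plot(tt, w, type = "l", xlab = "time (ms)",
                   ylab = "amplitude (mV)",
                   main = sprintf("unit %d (n = %d)", i,
                                  length(x$samples[[i]])), ...)
  }
  invisible(x)
}
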