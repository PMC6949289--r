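# Shared fixtures: synthetic sessions are expensive, so they are generated
# once per run and cached; snippet families for the matcher's decision
# boundary are built from library shapes.

.fixture_cache <- new.env(parent = emptyenv())

cached_session <- function(seed = 1L) {
  key <- paste0("syn", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- synthesize_session(default_session_config(),
                                                seed = seed)
  .fixture_cache[[key]]
}

cached_notch_filtered <- function(seed, channel) {
  key <- paste0("flt", seed, "_", channel)
  if (is.null(.fixture_cache[[key]])) {
    syn <- cached_session(seed)
    bank <- design_notch_bank(syn$session$fs)
    x <- syn$session$data[, channel]
    .fixture_cache[[key]] <- apply_zero_phase(select_active_notches(bank, x),
                                              x)
  }
  .fixture_cache[[key]]
}

cached_sorted <- function(seed, channel) {
  key <- paste0("srt", seed, "_", channel)
  if (is.null(.fixture_cache[[key]])) {
    syn <- cached_session(seed)
    .fixture_cache[[key]] <- spikesort(cached_notch_filtered(seed, channel),
                                       syn$session$fs)
  }
  .fixture_cache[[key]]
}

# fraction of true spikes matched (within +/- tol samples) to the recovered
# unit that best captures each true unit, plus recovered-vs-generator
# template correlations
recovery_stats <- function(syn, seed, tol_ms = 1) {
  rec <- syn$session
  tol <- round(tol_ms / 1000 * rec$fs)
  matched <- total <- 0
  template_r <- numeric(0)
  for (ci in seq_along(syn$config$channels)) {
    res <- cached_sorted(seed, ci)
    truth <- syn$truth$spikes[syn$truth$unit_channel == ci]
    gens <- syn$truth$units[syn$truth$unit_channel == ci]
    for (ti in seq_along(truth)) {
      hits <- vapply(seq_along(res$samples), function(ui)
        sum(vapply(truth[[ti]], function(s)
          any(abs(res$samples[[ui]] - s) <= tol), logical(1))), 0)
      best <- if (length(hits)) which.max(hits) else integer(0)
      matched <- matched + if (length(best)) hits[best] else 0
      total <- total + length(truth[[ti]])
      if (length(best) && hits[best] > 0) {
        tw <- gens[[ti]]$template
        rw <- res$templates[[best]]
        L <- max(length(tw), length(rw))
        cc <- stats::ccf(c(tw, numeric(L - length(tw))),
                         c(rw, numeric(L - length(rw))),
                         lag.max = 60, plot = FALSE)$acf
        template_r <- c(template_r, max(cc))
      }
    }
  }
  list(fraction = matched / total, template_r = template_r)
}

# zero-mean vector orthogonal to `w` with the same mean-square power
orthogonal_same_power <- function(w, seed = 42) {
  set.seed(seed)
  repeat {
    u <- stats::rnorm(length(w))
    u <- u - mean(u)
    u <- u - sum(u * w) / sum(w * w) * w
    if (stats::sd(u) > 0) break
  }
  u * sqrt(mean(w^2) / mean(u^2))
}

# snippet with exact correlation `r` to the (zero-mean) template and the
# smallest mean-square difference that correlation admits
snippet_with_correlation <- function(template, r, u = NULL) {
  stopifnot(abs(mean(template)) < 1e-9)
  if (is.null(u)) u <- orthogonal_same_power(template)
  r * template + sqrt(1 - r^2) * u
}

# noiseless candidate-event stream holding two alternating units
two_unit_stream <- function(n_events, minority_share, fs = 10240,
                            window = 103) {
  lib <- iemgkit:::muap_shape_library()
  make <- function(p, amp) {
    w <- do.call(muap_template, c(list(fs = fs, amplitude = amp), p))
    out <- numeric(window)
    lo <- (window - length(w)) %/% 2L
    out[lo + seq_along(w)] <- w
    out
  }
  a <- make(lib[[1]], 1.0)
  b <- make(lib[[6]], 0.8)
  n_min <- round(minority_share * n_events)
  labels <- rep(1L, n_events)
  if (n_min > 0)
    labels[round(seq(1, n_events, length.out = n_min))] <- 2L
  snippets <- rbind(a, b)[labels, , drop = FALSE]
  structure(list(peaks = seq_len(n_events) * 500L, snippets = snippets,
                 threshold = 0.1, window = window, fs = fs,
                 labels = labels),
            class = "candidate_events")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
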