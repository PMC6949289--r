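#' Spike-sort result container
#'
#' Holds the output of motor-unit spike sorting in the published metadata
#' layout: per-unit spike sample indices (`samples`, 1-based as deposited),
#' the same events as times in seconds (`times`, each value is the sample
#' index divided by the sampling rate), one waveform template per unit
#' (`templates`, mV) and the sampling rate `fs`.  Events the sorter could not
#' assign are kept in `unknown`.
#'
#' @param samples list of numeric vectors, one strictly increasing spike
#'   sample train per unit.
#' @param templates list of numeric template waveforms (or a matrix with one
#'   template per column), one per unit.
#' @param fs sampling rate in Hz.
#' @param unknown sample indices of unassigned events.
#' @param times per-unit spike times in s; recomputed from `samples` when
#'   omitted, validated against them when given.
#' @return object of class `spikesort_result`.
#' @export
spikesort_result <- function(samples, templates, fs, unknown = numeric(0),
                             times = NULL) {
  samples <- lapply(samples, as.numeric)
  if (is.matrix(templates))
    templates <- lapply(seq_len(ncol(templates)), function(j) templates[, j])
  templates <- lapply(templates, as.numeric)
  if (length(templates) != length(samples))
    iemg_error("iemg_integrity_error",
               sprintf("%d templates for %d units", length(templates),
                       length(samples)))
  if (!is.numeric(fs) || fs <= 0)
    iemg_error("iemg_integrity_error", "fs must be a positive scalar")
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (length(s) > 1L && any(diff(s) <= 0))
      iemg_error("iemg_integrity_error",
                 sprintf("unit %d spike train is not strictly increasing", i))
  }
  computed <- lapply(samples, function(s) s / fs)
  if (!is.null(times)) {
    times <- lapply(times, as.numeric)
    ok <- length(times) == length(samples) &&
      all(mapply(function(a, b) length(a) == length(b) &&
                   (length(a) == 0L || max(abs(a - b)) <= 1e-9), times,
                 computed))
    if (!ok)
      iemg_error("iemg_integrity_error",
                 "times element disagrees with samples / fs")
  }
  structure(list(samples = samples, times = computed, templates = templates,
                 fs = fs, unknown = as.numeric(unknown)),
            class = "spikesort_result")
}

#' @export
print.spikesort_result <- function(x, ...) {
  cat(sprintf("Spike-sort result: %d unit(s) at %g Hz\n", length(x$samples),
              x$fs))
  for (i in seq_along(x$samples))
    cat(sprintf("  unit %d: %d spikes, template peak %.3g mV\n", i,
                length(x$samples[[i]]),
                if (length(x$templates[[i]]))
                  max(abs(x$templates[[i]])) else NA_real_))
  cat(sprintf("  unknown events: %d\n", length(x$unknown)))
  invisible(x)
}

#' Read or write spike-sort metadata files
#'
#' `save_spikesort()` stores a [spikesort_result()] in the published layout
#' with elements `samples` (cell of spike trains), `times` (cell of the same
#' trains divided by the sampling rate), `template` (cell of waveforms) and
#' `fs`.  Invariants (strictly increasing trains, one template per unit) are
#' enforced on save.  `load_spikesort()` reads such a file back.
#'
#' @param res a `spikesort_result`.
#' @param path file path.
#' @return `load_spikesort()` returns a `spikesort_result`.
#' @export
save_spikesort <- function(res, path) {
  stopifnot(inherits(res, "spikesort_result"))
  write_mat(list(samples = res$samples, times = res$times,
                 template = res$templates, fs = res$fs),
            path)
  invisible(path)
}

#' @rdname save_spikesort
#' @export
load_spikesort <- function(path) {
  vars <- read_mat(path)
  for (el in c("samples", "times", "template", "fs"))
    if (is.null(vars[[el]]))
      iemg_error("iemg_format_error",
                 paste0("spike-sort file is missing element '", el, "'"),
                 element = el)
  as_trains <- function(x) if (is.list(x)) x else list(x)
  spikesort_result(samples = as_trains(vars$samples),
                   templates = as_trains(vars$template),
                   fs = as.numeric(vars$fs)[1],
                   times = as_trains(vars$times))
}
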