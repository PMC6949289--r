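# Ground-truth-annotated synthetic sessions.
#
# The generator emulates the structure of the real recordings: motor-unit
# action-potential (MUAP) trains whose recruitment and firing rate follow the
# cued force, templates convolved onto the iEMG channels, broadband noise
# plus 50 Hz-harmonic interference, a 0.1 Hz sinusoidal tracking cue, 5 s MVC
# epochs, 4-repetition synergy epochs, the movement-code stream, and the
# 5 V / 200 ms / 0.5 Hz synchronization pulse train carried by both
# acquisition streams.

#' Parametric MUAP template
#'
#' Builds a motor-unit action potential shape as a sequence of signed
#' Gaussian lobes (the waveform's phases): `lobes = c(1, -0.7)` gives a
#' biphasic shape, `c(-0.5, 1, -0.5)` a triphasic one, and so on.  Phase
#' polarity, count, width and spacing are what distinguish MUAPs of
#' different units in a real channel, so varying them yields waveform
#' families with low mutual correlation.  The result has zero mean, peak
#' absolute amplitude `amplitude` (mV) and its absolute peak centred in an
#' odd-length window.
#'
#' @param fs sampling rate, Hz.
#' @param duration_ms waveform support in ms (physiological MUAPs span
#'   roughly 5--15 ms).
#' @param amplitude peak absolute amplitude in mV.
#' @param lobes signed relative amplitudes of the phases.
#' @param lobe_ms Gaussian width of each phase, ms.
#' @param spacing_ms spacing between consecutive phase centres, ms.
#' @return numeric waveform (odd length).
#' @export
muap_template <- function(fs, duration_ms = 8, amplitude = 1,
                          lobes = c(1, -0.7), lobe_ms = 0.7,
                          spacing_ms = 1.5) {
  len <- round(duration_ms * fs / 1000)
  if (len %% 2L == 0L) len <- len + 1L
  t <- (seq_len(len) - (len + 1L) / 2L) / fs * 1000     # ms
  k <- length(lobes)
  cen <- (k + 1) / 2
  w <- numeric(len)
  for (i in seq_len(k))
    w <- w + lobes[i] * exp(-(t - (i - cen) * spacing_ms)^2 / (2 * lobe_ms^2))
  w <- w - mean(w)
  w <- w / max(abs(w)) * amplitude
  # centre the absolute peak so a spike's sample index is its peak index
  shift <- which.max(abs(w)) - (len + 1L) %/% 2L
  if (shift != 0L) {
    idx <- seq_len(len) + shift
    w <- ifelse(idx >= 1L & idx <= len, w[pmin(pmax(idx, 1L), len)], 0)
    w <- w - mean(w)
  }
  w
}

#' Motor-unit model
#'
#' One simulated motor unit: its MUAP template, the fraction of MVC at which
#' it is recruited, the firing-rate range it spans as drive grows, and the
#' inter-spike-interval variability.
#'
#' @param template MUAP waveform in mV ([muap_template()]).
#' @param recruitment_threshold drive (fraction of MVC) below which the unit
#'   is silent; in `[0, 1)`.
#' @param rate_min,rate_max firing rate (Hz) at recruitment and at maximal
#'   drive.
#' @param jitter inter-spike-interval coefficient of variation.
#' @return object of class `unit_model`.
#' @export
unit_model <- function(template, recruitment_threshold = 0.05, rate_min = 8,
                       rate_max = 14, jitter = 0.1) {
  stopifnot(rate_min < rate_max, recruitment_threshold >= 0,
            recruitment_threshold < 1, jitter >= 0)
  template <- template - mean(template)
  structure(list(template = template,
                 recruitment_threshold = recruitment_threshold,
                 rate_min = rate_min, rate_max = rate_max, jitter = jitter),
            class = "unit_model")
}

#' Simulate one motor-unit spike train
#'
#' Inhomogeneous gamma-renewal process driven by the force profile: the unit
#' is silent while drive is below its recruitment threshold, and its
#' instantaneous rate interpolates linearly from `rate_min` at recruitment to
#' `rate_max` at full drive.  Spikes are generated by time rescaling, so rate
#' modulation and silent periods are exact; the gamma shape is
#' `1 / jitter^2`, giving ISIs with the requested coefficient of variation.
#'
#' @param force_profile drive as a fraction of MVC, in `[0, 1]`, one value
#'   per sample.
#' @param unit a [unit_model()].
#' @param fs sampling rate of `force_profile`, Hz.
#' @param seed optional integer seed for a reproducible train.
#' @return integer vector of spike sample indices (1-based).
#' @export
simulate_unit_train <- function(force_profile, unit, fs, seed = NULL) {
  stopifnot(inherits(unit, "unit_model"))
  if (any(force_profile < -1e-9 | force_profile > 1 + 1e-9))
    iemg_error("iemg_validation_error",
               "force profile must lie in [0, 1] (fraction of MVC)")
  if (!is.null(seed)) set.seed(seed)
  thr <- unit$recruitment_threshold
  excess <- pmax(0, force_profile - thr) / (1 - thr)
  rate <- ifelse(force_profile > thr,
                 unit$rate_min + (unit$rate_max - unit$rate_min) *
                   pmin(excess, 1),
                 0)
  lambda <- cumsum(rate) / fs
  total <- lambda[length(lambda)]
  if (total <= 0) return(integer(0))
  shape <- if (unit$jitter < 1e-3) 1e6 else 1 / unit$jitter^2
  ndraw <- ceiling(total + 6 * sqrt(total) + 20)
  thresholds <- cumsum(stats::rgamma(ndraw, shape = shape, rate = shape))
  thresholds <- thresholds[thresholds <= total]
  if (!length(thresholds)) return(integer(0))
  findInterval(thresholds, lambda) + 1L
}

# ---- protocol -------------------------------------------------------------

#' Protocol stage and schedule constructors
#'
#' `protocol_stage()` describes one sub-stage of the automated protocol;
#' `protocol_schedule()` assembles stages into an ordered schedule and
#' validates the protocol structure: MVC cue duration is 5 s, tracking sine
#' frequency 0.1 Hz, synergies run 4 repetitions, stage codes must exist in
#' the movement table with the matching task kind, and stage order must
#' follow the table order.
#'
#' @param base,substage stage and sub-stage number (e.g. `4` and `1` for the
#'   little-finger MVC flexion sub-stage, code 4.1).
#' @param joints force channel(s) (joint names) the stage drives.
#' @param direction `+1`/`-1` per joint; flexion is negative on the
#'   bidirectional transducers.
#' @param amplitude cue amplitude as a fraction of MVC.
#' @param duration tracking-stage duration in s.
#' @param amplitude2 second single-DoF amplitude for circle stages; the
#'   circle radius is the lesser of `amplitude` and `amplitude2`.
#' @param bidirectional for sine stages on a two-direction DoF (stages
#'   1--8), swing the target through both directions of the joint
#'   (`direction` sets the starting half-cycle); one-sided stages (the
#'   trumpet tasks) raise the target from rest only.
#' @param rest_pre,rest_post preparation/relaxation padding, s.
#' @param cue_s contraction-cue duration, s (5 for MVC stages).
#' @param reps synergy repetitions (4).
#' @param rest_s rest between synergy repetitions, s.
#' @param sine_freq tracking sine frequency, Hz (0.1).
#' @return `protocol_stage()`: a stage list; `protocol_schedule()`: object of
#'   class `protocol_schedule`.
#' @export
protocol_stage <- function(base, substage, joints, direction = -1,
                           amplitude = 0.5, duration = 30, amplitude2 = NA,
                           bidirectional = NULL, rest_pre = 3, rest_post = 2,
                           cue_s = NULL, reps = 4, rest_s = 2,
                           sine_freq = 0.1) {
  tab <- movement_table()
  hit <- tab[code100(tab$code) == base * 100L + substage * 10L, ]
  if (nrow(hit) != 1L)
    iemg_error("iemg_validation_error",
               sprintf("no protocol sub-stage %d.%d in the movement table",
                       base, substage))
  kind <- hit$kind
  if (is.null(cue_s)) cue_s <- switch(kind, mvc = 5, synergy = 3, NA_real_)
  if (is.null(bidirectional)) bidirectional <- kind == "sine" && base <= 8
  direction <- rep_len(direction, length(joints))
  total <- switch(kind,
    mvc = rest_pre + cue_s + rest_post,
    synergy = rest_pre + reps * (cue_s + rest_s),
    sine = ,
    circle = duration)
  list(base = base, substage = substage, kind = kind, joints = joints,
       direction = direction, amplitude = amplitude, amplitude2 = amplitude2,
       duration = total, bidirectional = bidirectional, rest_pre = rest_pre,
       rest_post = rest_post, cue_s = cue_s, reps = reps, rest_s = rest_s,
       sine_freq = sine_freq)
}

#' @rdname protocol_stage
#' @param stages list of [protocol_stage()] objects, in protocol order.
#' @export
protocol_schedule <- function(stages) {
  codes <- vapply(stages, function(s) s$base * 10 + s$substage, 0)
  if (is.unsorted(codes))
    iemg_error("iemg_validation_error",
               "stages must follow the protocol (movement table) order")
  for (s in stages) {
    if (s$kind == "mvc" && s$cue_s != 5)
      iemg_error("iemg_validation_error", "MVC cue duration must be 5 s")
    if (s$kind %in% c("sine", "circle") && s$sine_freq != 0.1)
      iemg_error("iemg_validation_error",
                 "tracking cue frequency must be 0.1 Hz")
    if (s$kind == "synergy" && s$reps != 4)
      iemg_error("iemg_validation_error",
                 "synergy stages run 4 repetitions")
    if (s$kind == "circle" && is.na(s$amplitude2))
      iemg_error("iemg_validation_error",
                 "circle stages need both single-DoF amplitudes")
  }
  structure(list(stages = stages,
                 duration = sum(vapply(stages, `[[`, 0, "duration"))),
            class = "protocol_schedule")
}

# trapezoidal 0->1->0 pulse with linear ramps
trapezoid <- function(t, t_on, t_off, ramp = 0.4) {
  pmax(0, pmin(1, (t - t_on) / ramp, (t_off + ramp - t) / ramp))
}

# evaluate code / cue / per-joint signed targets at absolute times t (s)
protocol_eval <- function(schedule, t, joints = NULL) {
  stages <- schedule$stages
  if (is.null(joints))
    joints <- unique(unlist(lapply(stages, `[[`, "joints")))
  code <- numeric(length(t))
  cue <- numeric(length(t))
  targets <- stats::setNames(rep(list(numeric(length(t))), length(joints)),
                             joints)
  t0 <- 0
  for (s in stages) {
    inside <- t >= t0 & t < t0 + s$duration
    if (any(inside)) {
      tr <- t[inside] - t0
      if (s$kind == "mvc") {
        cue_on <- tr >= s$rest_pre & tr < s$rest_pre + s$cue_s
        code[inside] <- encode_code(s$base, s$substage,
                                    "rest") * !cue_on +
                        encode_code(s$base, s$substage, "cue") * cue_on
        level <- s$amplitude * trapezoid(tr, s$rest_pre,
                                         s$rest_pre + s$cue_s)
        cue[inside] <- s$amplitude * cue_on
        for (j in seq_along(s$joints))
          targets[[s$joints[j]]][inside] <-
            targets[[s$joints[j]]][inside] + s$direction[j] * level
      } else if (s$kind == "sine") {
        code[inside] <- encode_code(s$base, s$substage)
        level <- if (isTRUE(s$bidirectional))
          s$amplitude * sin(2 * pi * s$sine_freq * tr)
        else
          s$amplitude * (1 - cos(2 * pi * s$sine_freq * tr)) / 2
        cue[inside] <- abs(level)
        for (j in seq_along(s$joints))
          targets[[s$joints[j]]][inside] <-
            targets[[s$joints[j]]][inside] + s$direction[j] * level
      } else if (s$kind == "circle") {
        code[inside] <- encode_code(s$base, s$substage)
        r <- min(s$amplitude, s$amplitude2)
        theta <- 2 * pi * s$sine_freq * tr
        # circle of radius r through the rest point, so the cue starts at 0
        j1 <- r * sin(theta)
        j2 <- r * (1 - cos(theta))
        cue[inside] <- sqrt(j1^2 + j2^2)
        targets[[s$joints[1]]][inside] <-
          targets[[s$joints[1]]][inside] + s$direction[1] * j1
        targets[[s$joints[2]]][inside] <-
          targets[[s$joints[2]]][inside] + s$direction[2] * j2
      } else {                                    # synergy, 4 repetitions
        period <- s$cue_s + s$rest_s
        rep_t <- tr - s$rest_pre
        k <- floor(rep_t / period)
        in_cue <- rep_t >= 0 & k < s$reps & (rep_t - k * period) < s$cue_s
        code[inside] <- encode_code(s$base, s$substage, "rest") * !in_cue +
                        encode_code(s$base, s$substage, "cue") * in_cue
        level <- numeric(length(tr))
        for (r_i in seq_len(s$reps) - 1L) {
          on <- s$rest_pre + r_i * period
          level <- pmax(level, trapezoid(tr, on, on + s$cue_s))
        }
        level <- s$amplitude * level
        cue[inside] <- s$amplitude * in_cue
        for (j in seq_along(s$joints))
          targets[[s$joints[j]]][inside] <-
            targets[[s$joints[j]]][inside] + s$direction[j] * level
      }
    }
    t0 <- t0 + s$duration
  }
  list(code = code, cue = cue, targets = targets)
}

#' Generate the protocol streams
#'
#' Samples the movement-code stream, the presented cue level (fraction of
#' MVC) and the per-joint signed force-target streams on a uniform grid.
#' Cue-pulsed stages emit the `x.y0`/`x.y1` rest/cue sub-codes; sine stages
#' emit a 0.1 Hz sinusoidal target; circle stages emit two orthogonal
#' sinusoidal targets whose radius is the lesser of the two referenced
#' single-DoF amplitudes.
#'
#' @param schedule a [protocol_schedule()].
#' @param fs sampling rate of the generated streams, Hz.
#' @return list with `code`, `cue`, `targets` (named list per joint), `fs`.
#' @export
generate_protocol <- function(schedule, fs) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  t <- seq(0, schedule$duration - 1 / fs, by = 1 / fs)
  out <- protocol_eval(schedule, t)
  out$fs <- fs
  out
}

#' Generate a synchronization pulse train
#'
#' Square pulses as emitted by the force-acquisition card at the start of a
#' recording: 5 V amplitude, 200 ms width, 0.5 Hz repetition rate, first
#' onset after a clean 1 s baseline.
#'
#' @param duration signal duration, s.
#' @param fs sampling rate, Hz.
#' @param rate pulse repetition rate, Hz.
#' @param width pulse width, s.
#' @param amplitude pulse amplitude, V.
#' @param onset time of the first leading edge, s.
#' @return numeric pulse train of `round(duration * fs)` samples.
#' @export
generate_sync_pulses <- function(duration, fs, rate = 0.5, width = 0.2,
                                 amplitude = 5, onset = 1.0) {
  n <- round(duration * fs)
  x <- numeric(n)
  if (onset >= duration) return(x)
  for (t0 in seq(onset, duration - 1e-9, by = 1 / rate)) {
    i0 <- round(t0 * fs) + 1L
    i1 <- min(round((t0 + width) * fs), n)
    if (i0 <= n) x[i0:i1] <- amplitude
  }
  x
}

# ---- session synthesis ----------------------------------------------------

# library of well-separated physiological MUAP shapes (biphasic and
# triphasic, both polarities); mutual signed correlation after optimal-lag
# alignment stays well below the sorter's 0.9 acceptance threshold
muap_shape_library <- function() {
  list(
    list(duration_ms = 7,  lobes = c(1, -0.7),       lobe_ms = 0.55, spacing_ms = 1.3),
    list(duration_ms = 9,  lobes = c(-0.5, 1, -0.5), lobe_ms = 0.85, spacing_ms = 1.9),
    list(duration_ms = 6,  lobes = c(-1, 0.8),       lobe_ms = 0.45, spacing_ms = 1.1),
    list(duration_ms = 10, lobes = c(0.6, -1, 0.7),  lobe_ms = 1.05, spacing_ms = 2.1),
    list(duration_ms = 8,  lobes = c(1, -0.4, 0.5),  lobe_ms = 0.65, spacing_ms = 1.5),
    list(duration_ms = 9,  lobes = c(-0.7, 1, 0.6),  lobe_ms = 0.95, spacing_ms = 1.9))
}

# one motor unit from the shape library; defaults follow the size principle
# (later-recruited units are larger) and the onion-skin rate profile
# (later-recruited units fire slower at equal drive)
library_unit <- function(fs, shape, amplitude, threshold, rates) {
  p <- muap_shape_library()[[shape]]
  unit_model(do.call(muap_template,
                     c(list(fs = fs, amplitude = amplitude), p)),
             recruitment_threshold = threshold, rate_min = rates[1],
             rate_max = rates[2])
}

# a physiological two-unit pool for one channel: a small low-threshold unit
# and a larger unit recruited near half of MVC
default_units <- function(fs, shapes, amps, thrs = c(0.05, 0.45),
                          rates = list(c(8, 12), c(6, 9))) {
  lapply(seq_along(amps), function(i)
    library_unit(fs, shapes[i], amps[i], thrs[i], rates[[i]]))
}

#' Default synthetic-session configuration
#'
#' A compact session emulating a slice of the short-residual-limb protocol:
#' three iEMG channels (FDP and EDC on the little finger, APL on thumb
#' abduction-adduction), two motor units per channel.  The unit pools follow
#' recruitment physiology: a small low-threshold unit plus a larger unit
#' recruited near half of MVC (size principle), the later-recruited unit
#' firing at lower rates (onion-skin profile), with distinct biphasic or
#' triphasic waveform shapes per unit.  Stages are the little-finger MVC
#' flexion/extension and sine-tracking sub-stages followed by the thumb
#' abduction MVC and sine stages; single-DoF sine cues swing through both
#' directions of the joint, alternating the antagonists.  Interference
#' holds the first three 50 Hz harmonics; broadband noise (0.03 mV) leaves
#' MUAP peaks 10--30 times above the robust noise SD, as selective
#' fine-wire recordings show.
#'
#' @param seed integer seed (mandatory for generation).
#' @param fs_emg,fs_force amplifier and force-card sampling rates, Hz.
#' @param force_delay start delay of the force stream relative to the
#'   amplifier stream, s.
#' @return configuration list for [synthesize_session()].
#' @export
default_session_config <- function(seed = 1L, fs_emg = 10240,
                                   fs_force = 200, force_delay = 0) {
  schedule <- protocol_schedule(list(
    protocol_stage(4, 1, joints = "little", direction = -1, amplitude = 1,
                   duration = NA),
    protocol_stage(4, 2, joints = "little", direction = +1, amplitude = 1,
                   duration = NA),
    protocol_stage(4, 3, joints = "little", direction = -1, amplitude = 0.5,
                   duration = 30),
    protocol_stage(6, 2, joints = "thumb_aa", direction = +1, amplitude = 1,
                   duration = NA),
    protocol_stage(6, 3, joints = "thumb_aa", direction = +1,
                   amplitude = 0.5, duration = 30)))
  channels <- list(
    list(name = "FDP", joint = "little", sign = -1,
         units = default_units(fs_emg, shapes = c(1, 6),
                               amps = c(0.45, 0.9))),
    list(name = "EDC", joint = "little", sign = +1,
         units = default_units(fs_emg, shapes = c(4, 5),
                               amps = c(0.5, 0.8))),
    list(name = "APL", joint = "thumb_aa", sign = +1,
         units = default_units(fs_emg, shapes = c(3, 6),
                               amps = c(0.55, 1.0))))
  list(seed = as.integer(seed), fs_emg = fs_emg, fs_force = fs_force,
       schedule = schedule, channels = channels,
       mvc_newtons = 60,
       noise_sd = 0.03,                    # mV, broadband
       harmonics = c("50" = 0.02, "100" = 0.01, "150" = 0.01),  # mV
       force_noise_sd = 0.002,             # V on the force sensors
       sync = list(rate = 0.5, width = 0.2, amplitude = 5, onset = 1.0),
       force_delay = force_delay)
}

#' Synthesize a ground-truth-annotated session
#'
#' Generates a full dual-stream recording: iEMG channels are the sum of each
#' unit's template placed at its simulated spike times plus broadband noise
#' and powerline-harmonic interference at the amplifier rate; force channels
#' are the signed per-joint targets scaled to newtons and mapped through the
#' inverse sensor calibration to volts at the force-card rate; both streams
#' carry the synchronization pulse train.  The merged session record (forces
#' on the amplifier time axis, as published) and the complete ground truth
#' are returned alongside the raw streams.
#'
#' @param config configuration list ([default_session_config()]); `seed` is
#'   mandatory.
#' @param seed overrides `config$seed` when given.
#' @return object of class `synthetic_session`: list with `session` (a
#'   [session_record()]), `raw` (`emg` and `force` stream lists), `truth`
#'   (per-unit true spike samples, unit-to-channel map, true channel/force
#'   pairing with sign, cue trace) and `config`.
#' @export
synthesize_session <- function(config = default_session_config(),
                               seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed))
    iemg_error("iemg_validation_error", "config must carry an integer seed")
  for (el in c("fs_emg", "fs_force", "schedule", "channels"))
    if (is.null(config[[el]]))
      iemg_error("iemg_validation_error",
                 paste0("config is missing element '", el, "'"))
  set.seed(config$seed)
  fs <- config$fs_emg
  fsf <- config$fs_force
  dur <- config$schedule$duration
  joints <- unique(vapply(config$channels, `[[`, "", "joint"))

  emg_prot <- generate_protocol(config$schedule, fs)
  n <- length(emg_prot$code)
  t_emg <- (seq_len(n) - 1L) / fs

  spikes <- list()
  unit_channel <- integer(0)
  iemg <- matrix(0, n, length(config$channels))
  for (ci in seq_along(config$channels)) {
    ch <- config$channels[[ci]]
    drive <- pmax(0, ch$sign * emg_prot$targets[[ch$joint]])
    drive <- pmin(drive, 1)
    for (u in ch$units) {
      train <- simulate_unit_train(drive, u, fs)
      spikes[[length(spikes) + 1L]] <- train
      unit_channel <- c(unit_channel, ci)
      half <- (length(u$template) - 1L) %/% 2L
      for (s in train) {
        lo <- max(1L, s - half); hi <- min(n, s + half)
        seg <- (lo:hi) - s + half + 1L
        iemg[lo:hi, ci] <- iemg[lo:hi, ci] + u$template[seg]
      }
    }
    iemg[, ci] <- iemg[, ci] + stats::rnorm(n, sd = config$noise_sd)
    if (length(config$harmonics))
      for (hi in seq_along(config$harmonics)) {
        f0 <- as.numeric(names(config$harmonics)[hi])
        iemg[, ci] <- iemg[, ci] + config$harmonics[[hi]] *
          sin(2 * pi * f0 * t_emg + stats::runif(1, 0, 2 * pi))
      }
  }

  sync_emg <- do.call(generate_sync_pulses,
                      c(list(duration = dur, fs = fs), config$sync))

  # force stream: its local time axis starts config$force_delay after the
  # amplifier's, so absolute-time events appear earlier in this stream
  delay <- config$force_delay
  nf <- round((dur - delay) * fsf)
  t_force <- delay + (seq_len(nf) - 1L) / fsf
  force_prot <- protocol_eval(config$schedule, t_force, joints = joints)
  forces <- vapply(joints, function(j)
    newtons_to_volts(force_prot$targets[[j]] * config$mvc_newtons) +
      stats::rnorm(nf, sd = config$force_noise_sd), numeric(nf))
  dim(forces) <- c(nf, length(joints))
  colnames(forces) <- paste0("force_", joints)
  sync_force <- do.call(generate_sync_pulses,
                        c(list(duration = dur, fs = fsf),
                          config$sync))[round(delay * fsf) + seq_len(nf)]

  # merged record on the amplifier time axis, as in the published containers
  force_cols <- vapply(joints, function(j)
    newtons_to_volts(emg_prot$targets[[j]] * config$mvc_newtons), numeric(n))
  dim(force_cols) <- c(n, length(joints))
  colnames(force_cols) <- paste0("force_", joints)
  data <- cbind(iemg, force_cols, movement_code = emg_prot$code,
                cue = emg_prot$cue)
  labels <- c(vapply(config$channels, `[[`, "", "name"),
              colnames(force_cols), "movement_code", "cue")
  session <- session_record(data, labels, movement_table(), fs)

  pairing <- do.call(rbind, lapply(seq_along(config$channels), function(ci) {
    ch <- config$channels[[ci]]
    stage_bases <- vapply(config$schedule$stages, `[[`, 0, "base")
    on_joint <- vapply(config$schedule$stages, function(s)
      ch$joint %in% s$joints, logical(1))
    data.frame(emg_channel = ch$name,
               force_channel = paste0("force_", ch$joint),
               movement_code = if (any(on_joint))
                 stage_bases[which(on_joint)[1]] else NA_real_,
               sign = ch$sign)
  }))

  structure(list(
    session = session,
    raw = list(
      emg = list(iemg = iemg, sync = sync_emg, fs = fs),
      force = list(forces = forces, sync = sync_force,
                   code = force_prot$code, cue = force_prot$cue, fs = fsf,
                   delay = delay)),
    truth = list(spikes = spikes, unit_channel = unit_channel,
                 pairing = pairing, cue = emg_prot$cue,
                 units = unlist(lapply(config$channels, `[[`, "units"),
                                recursive = FALSE)),
    config = config), class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("Synthetic session (seed %d): %.1f s, %d iEMG channel(s), %d unit(s)\n",
              x$config$seed, nrow(x$session$data) / x$session$fs,
              length(x$config$channels), length(x$truth$spikes)))
  print(x$session)
  invisible(x)
}
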