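# Synthetic session generator: protocol streams, unit trains, interference,
# sync pulses, and integration with the container layer.

test_that("protocol streams use only movement-table codes with cue variants", {
  syn <- cached_session(1)
  mv <- movement_stream(syn$session)
  seen <- setdiff(unique(round(mv * 100)), 0)
  tab100 <- round(movement_table()$code * 100)
  expect_true(all(seen %in% c(tab100, tab100 + 1)))
  # every emitted code decodes
  for (c100 in seen) expect_s3_class(decode_code(c100 / 100), "movement_code")
})

test_that("sine stages emit a 0.1 Hz dominant cue frequency", {
  sched <- protocol_schedule(list(
    protocol_stage(4, 3, joints = "little", amplitude = 0.5, duration = 40)))
  prot <- generate_protocol(sched, fs = 200)
  cue <- prot$targets$little
  n <- length(cue)
  spec <- Mod(stats::fft(cue - mean(cue))[2:(n %/% 2)])
  dominant <- (which.max(spec)) * 200 / n
  expect_equal(dominant, 0.1, tolerance = 1e-6)
})

test_that("circle stages use the lesser single-DoF amplitude as radius", {
  sched <- protocol_schedule(list(
    protocol_stage(9, 1, joints = c("thumb_fe", "thumb_aa"),
                   direction = c(1, 1), amplitude = 2, amplitude2 = 1,
                   duration = 20)))
  prot <- generate_protocol(sched, fs = 100)
  j1 <- prot$targets$thumb_fe
  j2 <- prot$targets$thumb_aa
  # circle through the rest point: radius of (j1, j2 - r) is r = min(2, 1)
  expect_equal(max(abs(sqrt(j1^2 + (j2 - 1)^2) - 1)), 0, tolerance = 1e-9)
})

test_that("schedules violating the protocol structure are rejected", {
  expect_error(protocol_stage(4, 9, joints = "little"), "no protocol")
  expect_error(protocol_schedule(list(
    protocol_stage(4, 1, joints = "little", cue_s = 3))),
    class = "iemg_validation_error")
  expect_error(protocol_schedule(list(
    protocol_stage(4, 3, joints = "little", sine_freq = 0.2))),
    class = "iemg_validation_error")
  expect_error(protocol_schedule(list(
    protocol_stage(15, 1, joints = "little", reps = 3))),
    class = "iemg_validation_error")
  # stage order must follow the table
  expect_error(protocol_schedule(list(
    protocol_stage(4, 3, joints = "little"),
    protocol_stage(4, 1, joints = "little"))),
    class = "iemg_validation_error")
})

test_that("unit trains follow the drive: silence, rate scaling, determinism", {
  fs <- 10240
  u <- unit_model(muap_template(fs), recruitment_threshold = 0.1,
                  rate_min = 8, rate_max = 20, jitter = 1e-6)
  expect_length(simulate_unit_train(rep(0, fs), u, fs, seed = 1), 0)
  # constant full drive for 10 s at rate_max 20 Hz, vanishing jitter
  train <- simulate_unit_train(rep(1, 10 * fs), u, fs, seed = 2)
  expect_true(abs(length(train) - 200) <= 2)
  # reproducibility
  t1 <- simulate_unit_train(rep(0.6, fs), u, fs, seed = 3)
  t2 <- simulate_unit_train(rep(0.6, fs), u, fs, seed = 3)
  expect_identical(t1, t2)
  expect_error(simulate_unit_train(c(0.5, 1.7), u, fs),
               class = "iemg_validation_error")
})

test_that("interference-only channels peak exactly at configured harmonics", {
  cfg <- default_session_config(seed = 5)
  cfg$channels <- list(list(name = "quiet", joint = "little", sign = -1,
                            units = list()))
  cfg$harmonics <- c("50" = 0.05, "150" = 0.03, "350" = 0.02)
  cfg$noise_sd <- 1e-4
  syn <- synthesize_session(cfg)
  x <- syn$session$data[, 1]
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x))[seq_len(n %/% 2)])
  freq <- (seq_len(n %/% 2) - 1) * syn$session$fs / n
  for (f0 in c(50, 150, 350)) {
    band <- which(freq >= f0 - 1 & freq <= f0 + 1)
    expect_equal(freq[band[which.max(spec[band])]], f0, tolerance = 0.02)
    # band power dominates its neighbourhood
    near <- which(freq >= f0 - 10 & freq <= f0 + 10)
    expect_gt(max(spec[band]), 10 * stats::median(spec[near]))
  }
})

test_that("a noiseless single-unit channel is an exact template train", {
  cfg <- default_session_config(seed = 9)
  u <- iemgkit:::library_unit(cfg$fs_emg, 1, 1.0, 0.05, c(8, 12))
  cfg$channels <- list(list(name = "solo", joint = "little", sign = -1,
                            units = list(u)))
  cfg$noise_sd <- 0
  cfg$harmonics <- numeric(0)
  syn <- synthesize_session(cfg)
  x <- syn$session$data[, 1]
  rebuilt <- numeric(length(x))
  half <- (length(u$template) - 1) %/% 2
  for (s in syn$truth$spikes[[1]]) {
    lo <- max(1, s - half); hi <- min(length(x), s + half)
    rebuilt[lo:hi] <- rebuilt[lo:hi] + u$template[(lo:hi) - s + half + 1]
  }
  expect_equal(x, rebuilt, tolerance = 1e-12)
})

test_that("generated sync pulses measure 0.5 Hz and 200 ms at half amplitude", {
  sync <- generate_sync_pulses(60, 200)
  ev <- detect_sync_pulses(sync, 200)
  expect_identical(ev$count, 30L)
  expect_equal((ev$lead[1] - 1) / 200, 1.0, tolerance = 1 / 200)
  onsets <- (ev$lead - 1) / 200
  expect_equal(1 / mean(diff(onsets)), 0.5, tolerance = 1e-9)
  widths <- (ev$trail - ev$lead) / 200
  expect_equal(mean(widths), 0.2, tolerance = 1e-9)
})

test_that("generated sessions pass container validation and round-trip", {
  syn <- cached_session(1)
  expect_s3_class(syn$session, "session_record")
  path <- withr::local_tempfile(fileext = ".mat")
  save_session(syn$session, path)
  got <- load_session(path)
  expect_identical(got$data, syn$session$data)
  expect_identical(got$channels, syn$session$channels)
  # ground truth is aligned with the record extent
  n <- nrow(syn$session$data)
  for (train in syn$truth$spikes)
    expect_true(all(train >= 1 & train <= n))
  # raw force stream carries the sync pulses at the force rate
  fe <- detect_sync_pulses(syn$raw$force$sync, syn$raw$force$fs)
  ee <- detect_sync_pulses(syn$raw$emg$sync, syn$raw$emg$fs)
  expect_identical(fe$count, ee$count)
})

test_that("the generator is reproducible under a fixed seed", {
  a <- synthesize_session(default_session_config(), seed = 123)
  b <- synthesize_session(default_session_config(), seed = 123)
  expect_identical(a$session$data, b$session$data)
  expect_identical(a$truth$spikes, b$truth$spikes)
  expect_error(synthesize_session(list(fs_emg = 1, fs_force = 1,
                                       schedule = 1, channels = 1)),
               class = "iemg_validation_error")
})
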