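# Notch bank, zero-phase application, sync detection, stream alignment,
# force up-sampling.

test_that("the harmonic bank covers 100 centers with the designed response", {
  bank <- design_notch_bank(10240, base = 50, fmax = 5000, width = 2)
  expect_length(bank$centers, 100)
  expect_identical(bank$centers, seq(50, 5000, by = 50))
  # >= 40 dB attenuation at the fundamental, unity passband 10 Hz away
  expect_lt(20 * log10(Mod(notch_response(bank, 50))), -40)
  g60 <- Mod(notch_response(bank, 60))
  expect_true(g60 >= 0.95 && g60 <= 1.05)
  expect_error(design_notch_bank(8000, fmax = 5000),
               class = "iemg_design_error")
})

test_that("zero-phase filtering removes 50 Hz, keeps 60 Hz, shifts nothing", {
  fs <- 10240
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  bank <- design_notch_bank(fs)
  hum <- sin(2 * pi * 50 * t)
  expect_lt(sqrt(mean(apply_zero_phase(bank, hum)^2)) / sqrt(mean(hum^2)),
            0.01)
  tone <- sin(2 * pi * 60 * t)
  out60 <- apply_zero_phase(bank, tone)
  expect_equal(sqrt(mean(out60^2)) / sqrt(mean(tone^2)), 1, tolerance = 0.05)
  # broadband: cross-correlation between input and output peaks at lag 0
  set.seed(1)
  x <- rnorm(fs)
  y <- apply_zero_phase(bank, x)
  cc <- stats::ccf(x, y, lag.max = 50, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
  expect_error(apply_zero_phase(bank, rnorm(10)),
               class = "iemg_length_error")
})

test_that("refiltering an already-filtered signal changes it only marginally", {
  fs <- 10240
  set.seed(2)
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  x <- rnorm(length(t), sd = 0.05) + 0.3 * sin(2 * pi * 50 * t) +
    0.1 * sin(2 * pi * 150 * t)
  bank <- design_notch_bank(fs)
  once <- apply_zero_phase(bank, x)
  twice <- apply_zero_phase(bank, once)
  # the residual change is transition-skirt noise removal, bounded by the
  # second-order skirts of a 2 Hz notch (about 1% RMS on broadband input)
  expect_lt(abs(sqrt(mean(twice^2)) - sqrt(mean(once^2))) /
              sqrt(mean(once^2)), 0.01)
})

test_that("per-recording notch selection keeps only present harmonics", {
  fs <- 10240
  set.seed(3)
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  noise <- rnorm(length(t), sd = 0.05)
  bank <- design_notch_bank(fs)
  sel <- select_active_notches(bank, noise + 0.2 * sin(2 * pi * 50 * t) +
                                 0.2 * sin(2 * pi * 150 * t))
  expect_true(all(c(50, 150) %in% sel$active))
  # spurious activations from the noise stay under 5% of centers
  expect_lt(length(setdiff(sel$active, c(50, 150))), 5)
  # pure noise: expected false-activation rate below 5% of centers
  sel0 <- select_active_notches(bank, noise)
  expect_lt(length(sel0$active), 5)
  # every harmonic present: full set
  all_h <- noise + rowSums(vapply(bank$centers, function(f0)
    0.2 * sin(2 * pi * f0 * t), numeric(length(t))))
  expect_identical(select_active_notches(bank, all_h)$active, bank$centers)
})

test_that("sync detection counts pulses and excludes truncated ones", {
  sync <- generate_sync_pulses(60, 200)
  ev <- detect_sync_pulses(sync, 200)
  expect_identical(ev$count, 30L)
  expect_equal(ev$lead[1], 201L)          # first onset at t = 1.0 s
  expect_identical(detect_sync_pulses(rep(0, 1000), 200)$count, 0L)
  # cut the final pulse mid-width: its trailing edge is gone
  cut <- sync[1:(59.1 * 200)]
  expect_identical(detect_sync_pulses(cut, 200)$count, 29L)
})

test_that("alignment recovers constructed offsets and checks pulse counts", {
  fs <- 200
  base <- generate_sync_pulses(60, fs)
  ev0 <- detect_sync_pulses(base, fs)
  # identical streams: zero offset
  al0 <- align_streams(ev0, ev0)
  expect_identical(al0$offset, 0)
  expect_true(al0$verified)
  # force stream started 0.35 s later: its pulses appear 0.35 s earlier
  delayed <- generate_sync_pulses(60, fs, onset = 1.0 - 0.35)[1:(59 * fs)]
  ald <- align_streams(detect_sync_pulses(generate_sync_pulses(59, fs), fs),
                       detect_sync_pulses(delayed[1:(59 * fs - 100)], fs))
  expect_equal(ald$offset, 0.35, tolerance = 1 / fs)
  # count mismatch is an error carrying both counts
  short <- detect_sync_pulses(generate_sync_pulses(58, fs), fs)
  err <- expect_error(align_streams(ev0, short),
                      class = "iemg_alignment_error")
  expect_identical(err$emg_count, 30L)
  expect_identical(err$force_count, 29L)
})

test_that("alignment recovers random sub-second offsets to one force sample", {
  fs <- 200
  set.seed(11)
  for (k in 1:100) {
    delay <- round(runif(1, 0, 0.9) * fs) / fs
    emg <- detect_sync_pulses(generate_sync_pulses(30, fs), fs)
    frc <- detect_sync_pulses(
      generate_sync_pulses(30, fs, onset = 1.0 - delay), fs)
    if (emg$count != frc$count) next    # truncation can drop the last pulse
    expect_lte(abs(align_streams(emg, frc)$offset - delay), 1 / fs)
  }
})

test_that("force up-sampling is linear, exact and span-preserving", {
  const <- upsample_force(rep(2.5, 200), 200, 10240)
  expect_length(const, length(seq(0, 199 / 200, by = 1 / 10240)))
  expect_equal(range(const), c(2.5, 2.5), tolerance = 1e-12)
  ramp <- seq(0, 1, length.out = 201)
  up <- upsample_force(ramp, 200, 10240)
  t_out <- seq(0, 1, by = 1 / 10240)
  expect_equal(up, t_out, tolerance = 1e-12)
  # one second of 200 Hz input covers the same interval on the 10240 grid
  x <- rnorm(201)
  up2 <- upsample_force(x, 200, 10240)
  expect_length(up2, 10241)
  expect_gte(min(up2), min(x))
  expect_lte(max(up2), max(x))
  expect_error(upsample_force(1.5), class = "iemg_length_error")
})
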