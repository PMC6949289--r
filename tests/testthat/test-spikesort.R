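# Detection, matching, template updates and the three-pass sorter.

test_that("candidates are detected at injected MUAP positions", {
  fs <- 10240
  set.seed(21)
  noise_sd <- 0.05
  x <- rnorm(fs, sd = noise_sd)
  # sharp spike with a dominant main phase so the peak sample is unambiguous
  w <- muap_template(fs, duration_ms = 5, amplitude = 8 * noise_sd,
                     lobes = c(1, -0.5), lobe_ms = 0.12,
                     spacing_ms = 0.6)   # 8x the noise SD
  half <- (length(w) - 1) %/% 2
  truth <- c(2000, 5000, 8000)
  for (s in truth) x[(s - half):(s + half)] <- x[(s - half):(s + half)] + w
  ev <- detect_candidates(x, fs)
  expect_length(ev$peaks, 3)
  expect_true(all(abs(ev$peaks - truth) <= 1))
  expect_identical(ncol(ev$snippets), 103L)
})

test_that("pure noise yields almost no events at five robust SDs", {
  set.seed(22)
  counts <- vapply(1:10, function(i)
    length(detect_candidates(rnorm(10240, sd = 0.05), 10240)$peaks), 0L)
  expect_lt(mean(counts), 1)
})

test_that("two peaks two milliseconds apart merge into the larger one", {
  fs <- 10240
  x <- numeric(fs)
  x[3000] <- 1.0
  x[3000 + round(0.002 * fs)] <- 0.6
  ev <- detect_candidates(x, fs, threshold_mult = 5)
  expect_identical(ev$peaks, 3000L)
})

test_that("the match rule implements both similarity criteria", {
  w <- muap_template(10240, amplitude = 0.8)
  pad <- numeric(103)
  pad[seq_along(w) + (103 - length(w)) %/% 2] <- w
  # identity: perfect score
  m1 <- match_template(pad, pad)
  expect_equal(m1$r, 1)
  expect_equal(m1$mse, 0)
  expect_true(m1$accepted)
  # scaled copy: r = 1 but mse = 4x template power fails criterion (b)
  m3 <- match_template(3 * pad, pad)
  expect_equal(m3$r, 1, tolerance = 1e-9)
  expect_equal(m3$mse, 4 * mean(pad^2), tolerance = 1e-9)
  expect_false(m3$accepted)
  # anti-correlated: criterion (a) fails; at zero lag the correlation is
  # exactly -1, and free-lag alignment cannot rescue it either
  mneg0 <- match_template(-pad, pad, max_lag = 0)
  expect_equal(mneg0$r, -1, tolerance = 1e-9)
  expect_false(mneg0$accepted)
  mneg <- match_template(-pad, pad)
  expect_lt(mneg$r, 0.9)
  expect_false(mneg$accepted)
  # zero-variance snippet: undefined correlation, flagged rejection
  mz <- match_template(numeric(103), pad)
  expect_true(mz$degenerate)
  expect_false(mz$accepted)
})

test_that("alignment finds the true lag within half a window", {
  w <- muap_template(10240, amplitude = 0.8)
  pad <- numeric(103)
  pad[seq_along(w) + (103 - length(w)) %/% 2] <- w
  for (lag in c(-20, -5, 7, 30)) {
    # shift_snippet moves content left by `lag`, so the matcher must report
    # the opposite alignment shift
    shifted <- iemgkit:::shift_snippet(pad, lag)
    m <- match_template(shifted, pad)
    expect_identical(m$lag, as.integer(-lag))
    expect_true(m$accepted)
  }
})

test_that("template updates are running means", {
  tpl <- list(waveform = c(1, 2, 3), n = 1L, power = mean(c(1, 2, 3)^2))
  same <- update_template(tpl, c(1, 2, 3))
  expect_equal(same$waveform, c(1, 2, 3))
  expect_identical(same$n, 2L)
  half <- update_template(tpl, c(3, 4, 5))
  expect_equal(half$waveform, c(2, 3, 4))
  # averaging noisy copies converges toward the true waveform ~ 1/sqrt(n)
  set.seed(23)
  w <- muap_template(10240)
  err_at <- function(n_upd) {
    tp <- list(waveform = w + rnorm(length(w), sd = 0.2), n = 1L, power = 1)
    for (i in seq_len(n_upd))
      tp <- update_template(tp, w + rnorm(length(w), sd = 0.2))
    sqrt(mean((tp$waveform - w)^2))
  }
  e10 <- mean(replicate(5, err_at(10)))
  e90 <- mean(replicate(5, err_at(90)))
  expect_equal(e10 / e90, sqrt(91 / 11), tolerance = 0.5)
})

test_that("two clean units sort perfectly and deterministically", {
  ev <- two_unit_stream(200, minority_share = 0.4)
  res <- spikesort(ev)
  expect_length(res$samples, 2)
  expect_length(res$unknown, 0)
  # labels agree with construction up to unit numbering
  got <- res$assignment
  expect_true(all(got > 0))
  expect_identical(length(unique(got[ev$labels == 1])), 1L)
  expect_identical(length(unique(got[ev$labels == 2])), 1L)
  # determinism: bit-identical rerun
  res2 <- spikesort(two_unit_stream(200, minority_share = 0.4))
  expect_identical(res[names(res) != "call"], res2[names(res2) != "call"])
})

test_that("a 3% minority unit is pruned and its events become unknown", {
  ev <- two_unit_stream(1000, minority_share = 0.03)
  res <- spikesort(ev)
  expect_length(res$samples, 1)
  expect_identical(length(res$unknown), sum(ev$labels == 2))
  # every surviving template holds at least the 5% share
  expect_true(all(res$shares >= 0.05))
})

test_that("the sorter partitions all events across units and unknown", {
  for (share in c(0.03, 0.2, 0.5)) {
    ev <- two_unit_stream(400, minority_share = share)
    res <- spikesort(ev)
    n_assigned <- sum(lengths(res$samples)) + length(res$unknown)
    expect_identical(n_assigned, length(ev$peaks))
  }
  # empty input: empty result
  empty <- spikesort(detect_candidates(numeric(2048), 10240))
  expect_length(empty$samples, 0)
  expect_length(empty$unknown, 0)
})

test_that("acceptance boundaries sit at the published thresholds", {
  # correlation criterion: bisect the accept/reject outcome over snippets
  # whose correlation with the template varies continuously
  w <- muap_template(10240, amplitude = 0.8)
  pad <- numeric(103)
  pad[seq_along(w) + (103 - length(w)) %/% 2] <- w
  pad <- pad - mean(pad)
  u <- orthogonal_same_power(pad)
  accept_at <- function(r)
    match_template(snippet_with_correlation(pad, r, u), pad)$accepted
  expect_false(accept_at(0.88))
  expect_true(accept_at(0.92))
  lo <- 0.85; hi <- 0.95
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (accept_at(mid)) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, 0.9, tolerance = 0.005)

  # mse criterion: scale the snippet until mean-square difference crosses
  # half the template power
  accept_scale <- function(k) match_template(pad * (1 + k), pad)$accepted
  lo <- 0; hi <- 1.5
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (accept_scale(mid)) lo <- mid else hi <- mid
  }
  # mse = k^2 * power crosses 0.5 * power at k = sqrt(0.5)
  expect_equal((lo + hi) / 2, sqrt(0.5), tolerance = 0.01)

  # pruning boundary: minority share swept around 5% of 1000 events
  discarded <- vapply(c(0.040, 0.045, 0.050, 0.055), function(s)
    length(spikesort(two_unit_stream(1000, s))$samples) == 1L, logical(1))
  expect_identical(discarded, c(TRUE, TRUE, FALSE, FALSE))
})
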