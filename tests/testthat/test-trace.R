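# deterministic toy trace: 100 Hz frames, 0.5 s baseline, stimulus at 0.5 s
make_toy_trace <- function(events = list(), n_frames = 120, noise = 0.01,
                           seed = 5, f0 = 1000) {
  set.seed(seed)
  times <- (seq_len(n_frames) - 1) * 0.01
  dff <- matrix(0, n_frames, 1)
  for (ev in events) {
    i <- which.min(abs(times - ev$t))
    on <- seq(i, n_frames)
    dff[on, 1] <- dff[on, 1] + ev$a * exp(-(times[on] - times[i]) / 0.1)
  }
  raw <- f0 * (1 + dff + rnorm(n_frames, 0, noise))
  fluorescence_trace(raw, time = times)
}

test_that("dF/F0 and baseline noise come from the pre-stimulus window", {
  tr <- make_toy_trace(noise = 0.02)
  expect_equal(nrow(tr$dff), 120)
  expect_equal(tr$f0[1], mean(tr$raw[tr$time < 0.5, 1]))
  expect_equal(mean(tr$dff[tr$time < 0.5, 1]), 0, tolerance = 1e-12)
  expect_equal(tr$noise_sd[1], 0.02, tolerance = 0.3)
  expect_error(fluorescence_trace(matrix(1, 10, 1), time = 1:10,
                                  baseline_window = 0.5), "baseline")
})

test_that("event detection thresholds, classifies and separates dual peaks", {
  # flat noise-only trace: nothing detected
  expect_equal(nrow(detect_events(make_toy_trace(), 0.5)), 0)
  # one clean step at the first frame after the stimulus: synchronous
  tr <- make_toy_trace(list(list(t = 0.51, a = 1)), noise = 0.01)
  ev <- detect_events(tr, 0.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$class, "synchronous")
  expect_equal(ev$bin, 1L)
  # dual peak: synchronous at +10 ms and asynchronous at +40 ms
  tr2 <- make_toy_trace(list(list(t = 0.51, a = 1), list(t = 0.54, a = 0.8)),
                        noise = 0.01)
  ev2 <- detect_events(tr2, 0.5)
  expect_equal(nrow(ev2), 2)
  expect_setequal(ev2$class, c("synchronous", "asynchronous"))
  expect_equal(sort(ev2$rel_ms), c(10, 40))
  # sub-threshold events are ignored
  tr3 <- make_toy_trace(list(list(t = 0.51, a = 0.02)), noise = 0.01)
  expect_equal(nrow(detect_events(tr3, 0.5)), 0)
})

test_that("percent asynchronous is the event-count fraction and is scale-invariant", {
  ev <- data.frame(class = c(rep("synchronous", 640), rep("asynchronous", 360)))
  class(ev) <- c("vesikin_events", "data.frame")
  expect_equal(percent_asynchronous(ev), 36)
  ev2 <- data.frame(class = rep("synchronous", 5))
  class(ev2) <- c("vesikin_events", "data.frame")
  expect_equal(percent_asynchronous(ev2), 0)
  expect_error(percent_asynchronous(ev2[0, , drop = FALSE]), "undefined")
  # uniform amplitude scaling rescales signal and noise SD alike
  tr <- make_toy_trace(list(list(t = 0.51, a = 1), list(t = 0.54, a = 0.8)),
                       noise = 0.01)
  tr_scaled <- fluorescence_trace(2 * tr$raw - 1000, time = tr$time)
  expect_equal(percent_asynchronous(detect_events(tr_scaled, 0.5)),
               percent_asynchronous(detect_events(tr, 0.5)))
})

test_that("train AR fractions follow the per-stimulus event split", {
  ev <- data.frame(stimulus = c(1, 1, 2, 3),
                   class = c("synchronous", "asynchronous",
                             "synchronous", "synchronous"))
  class(ev) <- c("vesikin_events", "data.frame")
  expect_equal(train_ar_fraction(ev, 4), c(0.5, 0, 0, 0))
  ev$class <- rep("synchronous", 4)
  expect_equal(train_ar_fraction(ev, 4), rep(0, 4))
})

test_that("paired-pulse ratio divides the second response by the first", {
  expect_equal(paired_pulse_ratio(c(1, 1)), 1)
  expect_equal(paired_pulse_ratio(c(1.0, 0.57)), 0.57)
  expect_equal(paired_pulse_ratio(c(1.0, 1.3, 0.9)), 1.3)
  expect_error(paired_pulse_ratio(c(0, 1)), "zero")
  expect_error(paired_pulse_ratio(1), "two stimuli")
})

test_that("biexponential decomposition recovers known components", {
  syn <- synth_biexp_current(q_fast = 30, q_slow = 20, tau_fast = 0.006,
                             tau_slow = 0.09, noise_sd = 0)
  d <- cumulative_charge_decomposition(syn$trace)
  expect_equal(d$q_fast, 30, tolerance = 0.01)
  expect_equal(d$q_slow, 20, tolerance = 0.01)
  expect_equal(d$tau_fast, 0.006, tolerance = 0.01)
  expect_equal(d$tau_slow, 0.09, tolerance = 0.01)
  expect_false(d$degenerate)
  expect_true(d$tau_fast < d$tau_slow)
})

test_that("a single-exponential input is flagged as degenerate or slow-free", {
  syn <- synth_biexp_current(q_fast = 40, q_slow = 0, tau_fast = 0.008,
                             tau_slow = 0.1, noise_sd = 0)
  d <- cumulative_charge_decomposition(syn$trace)
  slow_frac <- d$q_slow / (d$q_fast + d$q_slow)
  expect_true(d$degenerate || slow_frac < 0.05)
  expect_equal(d$total_charge, 40, tolerance = 0.01)
})

test_that("a generator with the slow charge reduced 61% yields that ratio on analysis", {
  ctrl <- cumulative_charge_decomposition(
    synth_biexp_current(q_fast = 30, q_slow = 20, noise_sd = 0)$trace)
  ko <- cumulative_charge_decomposition(
    synth_biexp_current(q_fast = 30, q_slow = 20 * 0.39, noise_sd = 0)$trace)
  expect_equal(ko$q_slow / ctrl$q_slow, 0.39, tolerance = 0.02)
})

test_that("tonic charge integrates the baseline-to-tail envelope", {
  fs <- 10e3
  onsets <- 0.2 + (0:49) / 20
  times <- seq(0, 3, by = 1 / fs)
  # current returns exactly to baseline before every stimulus: zero charge
  cur <- rep(-20, length(times))
  tc0 <- tonic_charge(current_trace(times, cur, onsets))
  expect_equal(tc0$charge, 0, tolerance = 1e-9)
  # sustained -100 pA offset from the first onset: the anchored piecewise-
  # linear envelope gives the rectangle minus the onset triangle (the
  # envelope is pinned to baseline at the first stimulus)
  cur2 <- cur - 100 * (times >= 0.2)
  tc2 <- tonic_charge(current_trace(times, cur2, onsets))
  span <- 50 * 0.05 - 0.001          # first onset to the terminal tail
  expect_equal(tc2$charge, 100 * span - 0.5 * 100 * 0.049, tolerance = 1e-6)
  # the same analytic form holds on a shorter disjoint segment
  timesA <- seq(0, 1.6, by = 1 / fs)
  curA <- -20 - 100 * (timesA >= 0.2)
  onsetsA <- 0.2 + (0:24) / 20
  chA <- tonic_charge(current_trace(timesA, curA, onsetsA))$charge
  spanA <- 25 * 0.05 - 0.001
  expect_equal(chA, 100 * spanA - 0.5 * 100 * 0.049, tolerance = 1e-6)
  expect_error(tonic_charge(current_trace(times, cur, 0.2)), "train")
})
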