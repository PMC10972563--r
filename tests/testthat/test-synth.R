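test_that("generators are deterministic under a fixed seed", {
  a <- synth_iglu(synth_spec(seed = 3, n_boutons = 10))
  b <- synth_iglu(synth_spec(seed = 3, n_boutons = 10))
  c <- synth_iglu(synth_spec(seed = 4, n_boutons = 10))
  expect_identical(a$trace$raw, b$trace$raw)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$trace$raw, c$trace$raw))
  e1 <- synth_epsc(seed = 3, n_stimuli = 10)
  e2 <- synth_epsc(seed = 3, n_stimuli = 10)
  expect_identical(e1$trace$current, e2$trace$current)
})

test_that("ground truth and noiseless traces are mutually consistent", {
  sim <- synth_iglu(synth_spec(seed = 2, n_boutons = 15, noise_sd = 0))
  # re-render the truth with the kernel: must equal the clean traces
  expect_lt(max(abs(sim$trace$dff - sim$clean_dff)), 1e-12)
  # event times respect the class windows
  sync <- sim$truth[sim$truth$class == "synchronous", ]
  async <- sim$truth[sim$truth$class == "asynchronous", ]
  expect_true(all(abs(sync$rel_ms - 10) < 1e-6))
  expect_true(all(async$rel_ms > 10 & async$rel_ms <= 100 + 1e-6))
})

test_that("detection achieves perfect recall and precision at high SNR", {
  # SNR = amplitude/noise = 1.2/0.05 = 24 for synchronous events
  # latency_min 25 ms guarantees an intervening frame between the
  # synchronous peak and any asynchronous peak of the same bouton; adjacent
  # peaks would merge under the peak-counting definition
  sim <- synth_iglu(synth_spec(seed = 6, n_boutons = 40, amp_cv = 0,
                               p_sync = 1, p_async = 0.36,
                               latency_min = 0.025))
  ev <- detect_events(sim$trace, sim$stimulus_onsets)
  truth_key <- paste(sim$truth$bouton, round(sim$truth$time_s, 6))
  det_key <- paste(ev$bouton, round(ev$time_s, 6))
  expect_setequal(det_key, truth_key)          # recall and precision 1
  # bin assignment matches the generator classes exactly
  m <- match(det_key, truth_key)
  expect_identical(ev$class, sim$truth$class[m])
})

test_that("the asynchronous percentage is recovered at the generator truth", {
  sim <- synth_iglu(synth_spec(seed = 9, n_boutons = 400, p_sync = 0.64,
                               p_async = 0.36, amp_cv = 0,
                               latency_min = 0.025))
  ev <- detect_events(sim$trace, sim$stimulus_onsets)
  truth_pct <- 100 * mean(sim$truth$class == "asynchronous")
  expect_equal(percent_asynchronous(ev), truth_pct, tolerance = 0.02)
  # and the truth itself is near the configured 36% split
  se <- 100 * sqrt(0.36 * 0.64 / nrow(sim$truth))
  expect_lt(abs(truth_pct - 36), 4 * se)
})

test_that("train generation recovers rising AR fractions within counting error", {
  sp <- synth_spec(seed = 12, n_boutons = 150, n_stimuli = 8, freq = 10,
                   kernel_tau = 0.03, p_sync = 0.7, p_async = 0.2,
                   amp_cv = 0, latency_min = 0.025)
  sim <- synth_iglu(sp)
  ev <- detect_events(sim$trace, sim$stimulus_onsets)
  got <- train_ar_fraction(ev, sp$n_stimuli)
  want <- vapply(seq_len(sp$n_stimuli), function(k) {
    tt <- sim$truth[sim$truth$stimulus == k, ]
    mean(tt$class == "asynchronous")
  }, 0)
  expect_equal(got, want, tolerance = 0.05)
})

test_that("EPSC generator ground truth matches the tonic-charge analysis", {
  # zero envelope: no tonic charge beyond the noise floor
  e0 <- synth_epsc(seed = 5, tonic_fun = function(t) 0 * t, noise_sd = 0)
  expect_lt(abs(tonic_charge(e0$trace)$charge), 0.5)
  # linear ramp to -R over the train: triangle area, within 0.1%
  ramp <- function(t) -80 * pmax(0, pmin(t / 2.5, 1))
  er <- synth_epsc(seed = 5, tonic_fun = ramp, noise_sd = 0)
  tc <- tonic_charge(er$trace)
  expect_equal(tc$charge, er$truth$tonic_charge, tolerance = 1e-3)
  # and the generator's closed form is the triangle area
  expect_equal(er$truth$tonic_charge, 80 * 2.5 / 2, tolerance = 0.02)
  # default exponential build-up: analysis matches the analytic envelope
  ee <- synth_epsc(seed = 5, noise_sd = 0)
  expect_equal(tonic_charge(ee$trace)$charge, ee$truth$tonic_charge,
               tolerance = 1e-3)
})

test_that("model-driven traces close the loop from kinetics to quantification", {
  p <- default_parameters()
  wt <- model_driven_synth(p, traj = fixture_traj("wt"), n_boutons = 150,
                           seed = 21)
  d2 <- model_driven_synth(p, traj = fixture_traj("doc2_ko"),
                           n_boutons = 150, seed = 22)
  ev_wt <- detect_events(wt$trace, wt$stimulus_onsets)
  ev_d2 <- detect_events(d2$trace, d2$stimulus_onsets)
  fr_wt <- train_ar_fraction(ev_wt, 10)
  fr_d2 <- train_ar_fraction(ev_d2, 10)
  # AR fraction rises across the WT train
  expect_gt(mean(fr_wt[8:10]), mean(fr_wt[1:3]))
  # and is lower without Doc2alpha (averaged; single-stimulus fractions
  # carry counting noise at these event rates)
  expect_lt(mean(fr_d2), mean(fr_wt))
  expect_lt(mean(fr_d2[2:10]), mean(fr_wt[2:10]))
  # zero gain: no events at all
  z <- model_driven_synth(p, traj = fixture_traj("wt"), gain = 0,
                          n_boutons = 5, noise_sd = 0, seed = 23)
  expect_equal(nrow(z$truth), 0)
  expect_true(all(z$trace$dff == 0))
})
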