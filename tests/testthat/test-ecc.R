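# Calcium transient and shortening feature extraction.

test_that("baseline F0 is the pre-stimulus window mean", {
  tr <- trace(0:999, rep(2, 1000),
              events = data.frame(time = 500, label = "stimulus"))
  seg <- segment_beats(tr)
  expect_equal(baseline_f0(seg[1, ], tr, window = 200), 2.0)
  # linear ramp 1 -> 2 over the window averages to ~1.5
  ramp <- trace(0:500, c(seq(1, 2, length.out = 201), rep(2, 300)),
                events = data.frame(time = 200, label = "stimulus"))
  sr <- segment_beats(ramp)
  expect_equal(baseline_f0(sr[1, ], ramp, window = 200), 1.5, tolerance = 0.01)
  flat0 <- trace(0:999, rep(0, 1000),
                 events = data.frame(time = 500, label = "stimulus"))
  expect_error(baseline_f0(segment_beats(flat0)[1, ], flat0), "undefined")
})

test_that("beat segmentation matches stimuli and handles edge cases", {
  sim <- simulate_transient_train(seed = 1, pacing_hz = 1, n_beats = 10,
                                  noise_sd = 0)
  segs <- segment_beats(sim$trace)
  expect_equal(nrow(segs), 10)
  expect_equal(diff(segs$stimulus_time), rep(1000, 9))
  one <- simulate_transient_train(seed = 1, n_beats = 1, noise_sd = 0)
  s1 <- segment_beats(one$trace)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$end[1], nrow(one$trace))
  expect_warning(sg <- segment_beats(trace(0:99, rep(1, 100))), "no stimuli")
  expect_equal(nrow(sg), 0)
})

test_that("pacing-rate reconstruction reproduces event-based boundaries", {
  sim <- simulate_transient_train(seed = 3, pacing_hz = 1, n_beats = 8,
                                  noise_sd = 0.01)
  with_ev <- segment_beats(sim$trace)
  bare <- sim$trace
  attr(bare, "events") <- empty_events()
  recon <- segment_beats(bare, pacing_hz = 1)
  expect_equal(nrow(recon), nrow(with_ev))
  expect_true(all(abs(recon$stimulus_time - with_ev$stimulus_time) <= 5))
})

test_that("noiseless transient features equal the generator truth", {
  sim <- simulate_transient_train(seed = 1, noise_sd = 0, amplitude_dff0 = 1,
                                  ttp_ms = 50, tau_ms = 200)
  f <- all_transient_features(sim$trace)
  expect_equal(f$amplitude[1], 1.0, tolerance = 1e-6)
  expect_equal(f$time_to_peak[1], 50, tolerance = 1)
  expect_equal(f$tau[1], 200, tolerance = 1)
  # closed form: t50 of a pure exponential decay is ln(2) tau
  expect_equal(f$t50_decay[1], log(2) * 200, tolerance = log(2) * 200 * 0.01)
})

test_that("a flat segment is flagged unusable with no kinetics", {
  tr <- trace(0:2000, rep(5, 2001),
              events = data.frame(time = 500, label = "stimulus"))
  f <- transient_features(segment_beats(tr)[1, ], tr)
  expect_false(f$usable)
  expect_true(is.na(f$tau))
})

test_that("amplitude is invariant to fluorescence gain; tau to affine maps", {
  sim <- simulate_transient_train(seed = 7, noise_sd = 0.01, tau_ms = 250)
  f1 <- all_transient_features(sim$trace)
  scaled <- sim$trace
  scaled$value <- 3.7 * scaled$value
  f2 <- all_transient_features(scaled)
  expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-9)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-6)
  shifted <- sim$trace
  shifted$value <- 2 * shifted$value + 5   # F0 recomputed internally
  f3 <- all_transient_features(shifted)
  expect_equal(f3$tau, f1$tau, tolerance = 1e-3)
})

test_that("noiseless shortening features are sample-exact", {
  sim <- simulate_shortening_train(seed = 1, resting_length_um = 100,
                                   max_shortening_pct = 10, ttps_ms = 120,
                                   tthr_ms = 150, noise_sd = 0)
  f <- all_shortening_features(sim$trace)
  dt <- trace_dt(sim$trace)
  expect_equal(f$max_shortening_abs[1], 10, tolerance = 1e-6)
  expect_equal(f$max_shortening_pct[1], 10, tolerance = 1e-6)
  expect_true(all(abs(f$ttps - 120) <= dt))
  expect_true(all(abs(f$tthr - 150) <= dt))
})

test_that("a monotone-decreasing segment flags TTHR as censored", {
  n <- 1000
  v <- c(rep(100, 500), 100 - cumsum(rep(0.01, 500)))
  tr <- trace(seq_len(n) - 1, v,
              events = data.frame(time = 499, label = "stimulus"))
  f <- shortening_features(segment_beats(tr)[1, ], tr)
  expect_true(f$tthr_censored)
  expect_true(is.na(f$tthr))
})

test_that("symmetric triangular dip recovers TTHR = half width", {
  # dip of half-width w: linear down over w, linear up over w; the 50%
  # recovery crossing sits w/2 after the minimum
  w <- 100
  t <- 0:999
  v <- rep(100, 1000)
  dip <- 500 + (-w:w)
  v[dip + 1] <- 100 - 10 * (1 - abs(-w:w) / w)
  tr <- trace(t, v, events = data.frame(time = 500 - w, label = "stimulus"))
  f <- shortening_features(segment_beats(tr)[1, ], tr)
  expect_equal(f$tthr, w / 2, tolerance = 1)
  expect_equal(f$ttps, w, tolerance = 1)
})

test_that("batch features aggregate per cell and frequency by beat median", {
  traces <- list(); meta <- NULL
  for (hz in c(0.5, 1, 2)) {
    sim <- simulate_transient_train(seed = 100 + hz * 10, pacing_hz = hz,
                                    n_beats = 6, noise_sd = 0.01,
                                    tau_ms = 140, amplitude_dff0 = 0.8)
    traces[[length(traces) + 1]] <- sim$trace
    meta <- rbind(meta, data.frame(cell = "c1", group = "CTRL",
                                   pacing_hz = hz))
  }
  tab <- batch_features(traces, meta, kind = "transient")
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$pacing_hz, c(0.5, 1, 2))
  expect_true(all(abs(tab$tau - 140) / 140 < 0.05))
  empty <- batch_features(list(), data.frame(cell = character(0),
                                             group = character(0),
                                             pacing_hz = numeric(0)))
  expect_equal(nrow(empty), 0)
})
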