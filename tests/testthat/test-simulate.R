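# Generators: construction guarantees, determinism, degenerate inputs.

test_that("transient generator hits its configured peak and is deterministic", {
  a <- simulate_transient_train(seed = 11, noise_sd = 0, amplitude_dff0 = 1,
                                f0 = 1)
  expect_equal(max((a$trace$value - 1) / 1), 1.0)
  b <- simulate_transient_train(seed = 11, noise_sd = 0, amplitude_dff0 = 1,
                                f0 = 1)
  expect_identical(a$trace$value, b$trace$value)
  c1 <- simulate_transient_train(seed = 11, noise_sd = 0.05)
  c2 <- simulate_transient_train(seed = 11, noise_sd = 0.05)
  expect_identical(c1$trace$value, c2$trace$value)
  expect_error(simulate_transient_train(amplitude_dff0 = -1), "positive")
  expect_error(simulate_transient_train(tau_ms = 0), "positive")
  expect_warning(simulate_transient_train(pacing_hz = 2, tau_ms = 400),
                 "overlap")
})

test_that("shortening generator dips to the configured minimum", {
  s <- simulate_shortening_train(seed = 1, resting_length_um = 100,
                                 max_shortening_pct = 10, noise_sd = 0)
  expect_equal(min(s$trace$value), 90)
  expect_equal(s$truth$max_shortening_um, 10)
  expect_error(simulate_shortening_train(max_shortening_pct = 0), "0, 100")
  expect_error(simulate_shortening_train(max_shortening_pct = 120), "0, 100")
})

test_that("zero beats requested gives a flat trace with no events", {
  s <- simulate_shortening_train(seed = 1, n_beats = 0, noise_sd = 0,
                                 resting_length_um = 100)
  expect_equal(nrow(trace_events(s$trace)), 0)
  expect_true(all(s$trace$value == 100))
})

test_that("line-scan generator plants the requested sparks deterministically", {
  a <- simulate_linescan(seed = 4, n_sparks = 5)
  b <- simulate_linescan(seed = 4, n_sparks = 5)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$image$img, b$image$img)
  expect_equal(nrow(a$truth$events), 5)
  # 5 sparks on 50 um x 2 s: frequency 5 / (0.5 * 2) = 5 per 100 um s
  expect_equal(a$truth$true_frequency, 5.0)
  z <- simulate_linescan(seed = 4, spark_rate_per_100um_s = 0)
  expect_equal(nrow(z$truth$events), 0)
})

test_that("CRC generator exposes the release index and cumulative load", {
  s <- simulate_crc_trace(seed = 1, release_at_pulse = 7, noise_sd = 0)
  expect_equal(s$truth$pulses_tolerated, 6L)
  expect_equal(s$truth$pulses_tolerated * s$truth$pulse_amount_uM, 60)
  expect_false(s$truth$censored)
  cen <- simulate_crc_trace(seed = 1, release_at_pulse = NA, n_pulses = 10)
  expect_true(cen$truth$censored)
  expect_error(simulate_crc_trace(release_at_pulse = 0), "positive")
})

test_that("influx generator encodes |b| as the true initial rate", {
  s <- simulate_influx_trace(seed = 1, a = 0.5, b = -50, c = 1000)
  expect_equal(s$truth$initial_rate, 50)
  expect_error(simulate_influx_trace(b = 10), "decays")
})

test_that("oxygen trace slopes equal the configured fluxes", {
  s <- simulate_o2_trace(seed = 1, flux_routine = 20, flux_state3 = 100,
                         noise_sd = 0)
  expect_equal(s$truth$respiratory_control, 5.0)
  tr <- s$trace
  ev <- trace_events(tr)
  seg <- tr$time > ev$time[1] + 5 & tr$time < ev$time[2] - 5
  sl <- coef(lm(tr$value[seg] ~ tr$time[seg]))[2]
  expect_equal(unname(sl), -20, tolerance = 1e-9)
})

test_that("PV generator satisfies the hemodynamic identities in its truth", {
  s <- simulate_pv_occlusion(seed = 1, edv_ul = 50, esv_ul = 20, hr_bpm = 600)
  expect_equal(s$truth$sv_ul, 30)
  expect_equal(s$truth$ef_pct, 60)
  expect_equal(s$truth$co_ul_min, 18000)
  expect_error(simulate_pv_occlusion(edv_ul = 20, esv_ul = 30), "exceed")
})

test_that("histology generator produces the exact requested fractions", {
  h <- simulate_histology(seed = 1, width = 200, height = 200,
                          frac_blue = 0.3, frac_red = 0.6)
  expect_equal(h$truth$frac_blue, 0.3)
  expect_equal(h$truth$frac_red, 0.6)
  expect_equal(h$truth$fibrotic_index, 0.5)
  expect_error(simulate_histology(frac_blue = 0.6, frac_red = 0.6), "sum")
})

test_that("qPCR generator reproduces fold changes exactly at zero Ct noise", {
  q <- simulate_qpcr(seed = 1, ct_sd = 0,
                     log2_fold_changes = c(CTRL = 0, HF = 1))
  dd <- ddct(q$table, housekeeping = "Gapdh", control = "CTRL")
  expect_equal(unname(tapply(dd$fold, dd$group, mean)[["HF"]]), 2)
  expect_equal(unname(tapply(dd$fold, dd$group, mean)[["CTRL"]]), 1)
})

test_that("changing only the seed leaves ground-truth parameters unchanged", {
  a <- simulate_linescan(seed = 1, spark_rate_per_100um_s = 2)
  b <- simulate_linescan(seed = 2, spark_rate_per_100um_s = 2)
  expect_equal(a$truth$rate_per_100um_s, b$truth$rate_per_100um_s)
  expect_equal(a$truth$noise_sd, b$truth$noise_sd)
})

test_that("split_seed is deterministic and stream-dependent", {
  expect_identical(split_seed(42, "sparks"), split_seed(42, "sparks"))
  expect_false(split_seed(42, "sparks") == split_seed(42, "transient"))
  expect_true(split_seed(.Machine$integer.max, "x") < 2^31)
})
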