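# Synthetic-data generators.  Each generator returns the simulated dataset
# plus a ground-truth record of the parameters actually used, so every
# downstream analyzer can be validated by parameter recovery.  A fixed seed
# reproduces the output bit-for-bit; seeds for the different assays are
# derived from one master seed via split_seed().

#' Simulate a paced calcium transient train
#'
#' Each beat rises from the baseline `f0` to `f0 * (1 + amplitude_dff0)` as a
#' quarter-sine over `ttp_ms` (smooth and monotone, so the peak is
#' unambiguous), then decays mono-exponentially with time constant `tau_ms`
#' until the next stimulus.  Stimulus times are recorded as events; the trace
#' starts with a quiet baseline so the first beat has an F0 window.
#'
#' @param seed integer seed.
#' @param pacing_hz stimulation frequency (Hz); the protocol uses 0.5, 1, 2.
#' @param n_beats number of stimuli.
#' @param f0 baseline fluorescence (arbitrary units), > 0.
#' @param amplitude_dff0 peak amplitude in dF/F0 units, > 0.
#' @param ttp_ms time from stimulus to peak (ms), > 0.
#' @param tau_ms decay time constant (ms), > 0.
#' @param sampling_interval_ms sampling interval (ms).
#' @param noise_sd additive Gaussian noise SD, fluorescence units.
#' @param baseline_ms quiet lead-in before the first stimulus (ms).
#' @return list with `trace` (a [trace()], ms) and `truth` (parameter list).
#' @export
simulate_transient_train <- function(seed = 1, pacing_hz = 0.5, n_beats = 10,
                                     f0 = 1, amplitude_dff0 = 1,
                                     ttp_ms = 50, tau_ms = 200,
                                     sampling_interval_ms = 1, noise_sd = 0,
                                     baseline_ms = 400) {
  if (amplitude_dff0 <= 0 || tau_ms <= 0) {
    stop("amplitude_dff0 and tau_ms must be positive")
  }
  if (f0 <= 0) stop("f0 must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  period <- 1000 / pacing_hz
  if (n_beats > 0 && period <= ttp_ms + 3 * tau_ms) {
    warning("pacing period <= ttp + 3*tau: beats overlap, kinetics recovery degrades")
  }
  set.seed(seed)
  t <- seq(0, baseline_ms + max(n_beats, 1) * period, by = sampling_interval_ms)
  v <- rep(f0, length(t))
  stim <- if (n_beats > 0) baseline_ms + (seq_len(n_beats) - 1) * period else numeric(0)
  for (s in stim) {
    tl <- t - s
    rise <- tl >= 0 & tl <= ttp_ms
    fall <- tl > ttp_ms & tl < period
    v[rise] <- f0 * (1 + amplitude_dff0 * sin(pi / 2 * tl[rise] / ttp_ms))
    v[fall] <- f0 * (1 + amplitude_dff0 * exp(-(tl[fall] - ttp_ms) / tau_ms))
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  ev <- data.frame(time = stim, label = rep("stimulus", length(stim)),
                   amount = rep(NA_real_, length(stim)))
  list(trace = trace(t, v, events = ev, time_unit = "ms"),
       truth = list(assay = "transient", pacing_hz = pacing_hz, n_beats = n_beats,
                    f0 = f0, amplitude_dff0 = amplitude_dff0, ttp_ms = ttp_ms,
                    tau_ms = tau_ms, noise_sd = noise_sd,
                    t50_ms = log(2) * tau_ms, stimulus_times = stim))
}

#' Simulate a paced cell-shortening train
#'
#' The cell length dips from `resting_length_um` by
#' `max_shortening_pct` percent, reaching the minimum `ttps_ms` after the
#' stimulus (quarter-sine contraction), then relaxes exponentially so that
#' 50% of the shortening is recovered exactly `tthr_ms` after the minimum.
#'
#' @inheritParams simulate_transient_train
#' @param resting_length_um resting cell length (um).
#' @param max_shortening_pct maximal shortening as % of resting length,
#'   in (0, 100).
#' @param ttps_ms time from stimulus to maximal shortening (ms).
#' @param tthr_ms time from maximal shortening to 50% length recovery (ms).
#' @return list with `trace` (cell length, um) and `truth`.
#' @export
simulate_shortening_train <- function(seed = 1, pacing_hz = 0.5, n_beats = 10,
                                      resting_length_um = 120,
                                      max_shortening_pct = 8,
                                      ttps_ms = 120, tthr_ms = 150,
                                      sampling_interval_ms = 1, noise_sd = 0,
                                      baseline_ms = 400) {
  if (max_shortening_pct <= 0 || max_shortening_pct >= 100) {
    stop("max_shortening_pct must be in (0, 100)")
  }
  if (ttps_ms <= 0 || tthr_ms <= 0) stop("ttps_ms and tthr_ms must be positive")
  period <- 1000 / pacing_hz
  set.seed(seed)
  t <- seq(0, baseline_ms + max(n_beats, 1) * period, by = sampling_interval_ms)
  v <- rep(resting_length_um, length(t))
  depth <- resting_length_um * max_shortening_pct / 100
  tau_r <- tthr_ms / log(2)  # 50% recovery crosses at tthr by construction
  stim <- if (n_beats > 0) baseline_ms + (seq_len(n_beats) - 1) * period else numeric(0)
  for (s in stim) {
    tl <- t - s
    con <- tl >= 0 & tl <= ttps_ms
    rel <- tl > ttps_ms & tl < period
    v[con] <- resting_length_um - depth * sin(pi / 2 * tl[con] / ttps_ms)
    v[rel] <- resting_length_um - depth * exp(-(tl[rel] - ttps_ms) / tau_r)
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  ev <- data.frame(time = stim, label = rep("stimulus", length(stim)),
                   amount = rep(NA_real_, length(stim)))
  list(trace = trace(t, v, events = ev, time_unit = "ms"),
       truth = list(assay = "shortening", pacing_hz = pacing_hz, n_beats = n_beats,
                    resting_length_um = resting_length_um,
                    max_shortening_pct = max_shortening_pct,
                    max_shortening_um = depth,
                    ttps_ms = ttps_ms, tthr_ms = tthr_ms, noise_sd = noise_sd,
                    stimulus_times = stim))
}

#' Simulate a confocal line-scan image with planted calcium sparks
#'
#' Sparks are separable: Gaussian in space (given full width at half
#' maximum) with an instantaneous rise and exponential fall in time —
#' canonical spark morphology.  Spark centers are drawn from a uniform
#' Poisson process in space and time unless an exact count is requested.
#'
#' @param seed integer seed.
#' @param length_um scanned cell extent (um).
#' @param pixel_um spatial pixel size (um); the protocol uses 0.1 (100 nm).
#' @param duration_s scan duration (s).
#' @param line_period_ms time per scanned line (ms).
#' @param spark_rate_per_100um_s expected spark rate, sparks per 100 um per s.
#' @param n_sparks exact number of sparks to plant; overrides the Poisson
#'   draw when non-NULL.
#' @param spark_amp_dff0 spark amplitude in dF/F0 units.
#' @param spark_fwhm_um spatial full width at half maximum (um).
#' @param spark_half_time_ms temporal half-decay time (ms).
#' @param f0 baseline intensity (counts).
#' @param noise_sd additive Gaussian noise SD (counts).
#' @return list with `image` (a `linescan`) and `truth` (planted event list).
#' @export
simulate_linescan <- function(seed = 1, length_um = 50, pixel_um = 0.1,
                              duration_s = 2, line_period_ms = 2,
                              spark_rate_per_100um_s = 1, n_sparks = NULL,
                              spark_amp_dff0 = 1, spark_fwhm_um = 2,
                              spark_half_time_ms = 20,
                              f0 = 1000, noise_sd = 100) {
  if (pixel_um <= 0) stop("pixel_um must be positive")
  set.seed(seed)
  nx <- round(length_um / pixel_um)
  nt <- round(duration_s * 1000 / line_period_ms)
  n <- if (is.null(n_sparks)) {
    stats::rpois(1, spark_rate_per_100um_s * (length_um / 100) * duration_s)
  } else {
    as.integer(n_sparks)
  }
  pos <- stats::runif(n, 0, length_um)
  tim <- stats::runif(n, 0, duration_s * 1000)
  ord <- order(tim)
  pos <- pos[ord]; tim <- tim[ord]
  img <- matrix(f0, nrow = nx, ncol = nt)
  x_um <- (seq_len(nx) - 0.5) * pixel_um
  t_ms <- (seq_len(nt) - 0.5) * line_period_ms
  sigma <- spark_fwhm_um / (2 * sqrt(2 * log(2)))
  tau <- spark_half_time_ms / log(2)
  covered <- 0
  for (i in seq_len(n)) {
    sx <- exp(-(x_um - pos[i])^2 / (2 * sigma^2))
    st <- ifelse(t_ms >= tim[i], exp(-(t_ms - tim[i]) / tau), 0)
    add <- spark_amp_dff0 * f0 * outer(sx, st)
    covered <- covered + sum(add > 0.1 * spark_amp_dff0 * f0)
    img <- img + add
  }
  if (n > 0 && covered / (nx * nt) > 0.5) {
    warning("more than 50% of pixels are event-covered; detection validity is doubtful")
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(nx * nt, 0, noise_sd), nx, nt)
  events <- data.frame(position_um = pos, time_ms = tim,
                       amplitude_dff0 = rep(spark_amp_dff0, n),
                       fwhm_um = rep(spark_fwhm_um, n),
                       half_time_ms = rep(spark_half_time_ms, n))
  list(image = linescan(img, pixel_um = pixel_um, line_period_ms = line_period_ms),
       truth = list(assay = "linescan", events = events, f0 = f0,
                    noise_sd = noise_sd, length_um = length_um,
                    duration_s = duration_s,
                    rate_per_100um_s = spark_rate_per_100um_s,
                    true_frequency = nrow(events) / (length_um / 100) / duration_s))
}

#' Simulate a calcium retention capacity (CRC) trace
#'
#' Extramitochondrial Calcium Green-5N fluorescence: each Ca2+ pulse is a
#' step up followed by exponential re-uptake toward baseline; at the pulse
#' indexed `release_at_pulse` the permeability transition pore opens and the
#' trace rises monotonically without recovery (massive release).
#'
#' @param seed integer seed.
#' @param pulse_amount_uM Ca2+ added per pulse (umol/L); protocol value 10.
#' @param pulse_interval_s time between pulses (s); protocol value 180 (3 min).
#' @param n_pulses number of pulses delivered in the trace.
#' @param release_at_pulse 1-based index of the pulse at which massive
#'   release occurs; `NA` for a censored trace where every pulse recovers.
#' @param uptake_tau_s re-uptake time constant (s).
#' @param f_baseline baseline fluorescence (a.u.).
#' @param step_per_uM fluorescence step per umol/L added.
#' @param sampling_interval_s sampling interval (s).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @return list with `trace` (time in s, additions as events) and `truth`.
#' @export
simulate_crc_trace <- function(seed = 1, pulse_amount_uM = 10,
                               pulse_interval_s = 180, n_pulses = 10,
                               release_at_pulse = 7, uptake_tau_s = 30,
                               f_baseline = 100, step_per_uM = 5,
                               sampling_interval_s = 1, noise_sd = 0) {
  if (!is.na(release_at_pulse) && release_at_pulse <= 0) {
    stop("release_at_pulse must be positive (or NA for a censored trace)")
  }
  set.seed(seed)
  lead_s <- 60
  dur <- lead_s + (n_pulses + 1) * pulse_interval_s
  t <- seq(0, dur, by = sampling_interval_s)
  v <- rep(f_baseline, length(t))
  step <- pulse_amount_uM * step_per_uM
  pt <- lead_s + (seq_len(n_pulses) - 1) * pulse_interval_s
  released <- FALSE
  for (i in seq_len(n_pulses)) {
    if (released) break
    tl <- t - pt[i]
    if (!is.na(release_at_pulse) && i == release_at_pulse) {
      # mPTP opening: step plus sustained, saturating monotone rise
      after <- tl >= 0
      v[after] <- v[after] + step +
        3 * step * (1 - exp(-tl[after] / (2 * uptake_tau_s)))
      released <- TRUE
    } else {
      after <- tl >= 0
      v[after] <- v[after] + step * exp(-tl[after] / uptake_tau_s)
    }
  }
  n_delivered <- if (released) release_at_pulse else n_pulses
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  ev <- data.frame(time = pt[seq_len(n_delivered)],
                   label = rep("pulse", n_delivered),
                   amount = rep(pulse_amount_uM, n_delivered))
  list(trace = trace(t, v, events = ev, time_unit = "s"),
       truth = list(assay = "crc", pulse_amount_uM = pulse_amount_uM,
                    pulse_interval_s = pulse_interval_s,
                    n_pulses_delivered = n_delivered,
                    release_at_pulse = release_at_pulse,
                    pulses_tolerated = if (released) release_at_pulse - 1L else NA_integer_,
                    censored = !released, uptake_tau_s = uptake_tau_s,
                    noise_sd = noise_sd))
}

#' Simulate a mitochondrial Ca2+ influx (uptake) trace
#'
#' A 40 umol/L Ca2+ bolus raises extramitochondrial fluorescence; after
#' energization the signal decays as the quadratic
#' F(t) = c + b t + a t^2 (b < 0) within the analysis window — the same
#' polynomial model the rate analyzer fits, so the true initial rate is |b|.
#'
#' @param seed integer seed.
#' @param bolus_uM Ca2+ bolus (umol/L); protocol value 40.
#' @param energize_time_s time of the energizing substrate addition (s).
#' @param a,b,c quadratic coefficients of the post-energization decay
#'   (b < 0; time re-zeroed at energization).
#' @param duration_s total trace duration (s); `NULL` (default) ends the
#'   trace where the quadratic reaches its minimum, so the whole
#'   post-energization record is the analysis window.
#' @param sampling_interval_s sampling interval (s).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @return list with `trace` and `truth` (`initial_rate` = |b|).
#' @export
simulate_influx_trace <- function(seed = 1, bolus_uM = 40, energize_time_s = 60,
                                  a = 0.5, b = -50, c = 1000,
                                  duration_s = NULL, sampling_interval_s = 0.25,
                                  noise_sd = 0) {
  if (is.null(duration_s)) {
    duration_s <- if (a > 0 && b < 0) energize_time_s - b / (2 * a)
      else energize_time_s + 60
  }
  if (b > 0) stop("b must be <= 0 (fluorescence decays during uptake)")
  set.seed(seed)
  t <- seq(0, duration_s, by = sampling_interval_s)
  base <- c / 4
  v <- rep(base, length(t))
  bolus_t <- energize_time_s / 2
  v[t >= bolus_t] <- c
  post <- t >= energize_time_s
  tl <- t[post] - energize_time_s
  q <- c + b * tl + a * tl^2
  if (a > 0) {
    t_vertex <- -b / (2 * a)
    q[tl > t_vertex] <- c + b * t_vertex + a * t_vertex^2  # hold at the minimum
  }
  v[post] <- q
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  ev <- data.frame(time = c(bolus_t, energize_time_s),
                   label = c("bolus", "succinate"),
                   amount = c(bolus_uM, NA_real_))
  list(trace = trace(t, v, events = ev, time_unit = "s"),
       truth = list(assay = "influx", a = a, b = b, c = c,
                    initial_rate = abs(b), energize_time_s = energize_time_s,
                    vertex_s = if (a > 0) -b / (2 * a) else Inf,
                    noise_sd = noise_sd))
}

#' Simulate a high-resolution respirometry oxygen trace
#'
#' Piecewise-linear O2 concentration whose negative slope per protocol
#' segment equals the configured flux: substrate (routine), ADP (state 3),
#' FCCP (uncoupled).  Addition events mark the segment boundaries.
#'
#' @param seed integer seed.
#' @param flux_routine,flux_state3,flux_uncoupled O2 consumption fluxes
#'   (concentration units per s) in the three segments.
#' @param segment_s duration of each segment (s).
#' @param o2_start starting O2 concentration.
#' @param sampling_interval_s sampling interval (s).
#' @param noise_sd additive Gaussian noise SD.
#' @return list with `trace` (time in s) and `truth`.
#' @export
simulate_o2_trace <- function(seed = 1, flux_routine = 20, flux_state3 = 100,
                              flux_uncoupled = 120, segment_s = 120,
                              o2_start = 20000, sampling_interval_s = 1,
                              noise_sd = 0) {
  if (any(c(flux_routine, flux_state3, flux_uncoupled) < 0)) {
    stop("fluxes must be >= 0")
  }
  set.seed(seed)
  lead <- 30
  bounds <- lead + segment_s * (0:2)
  t <- seq(0, lead + 3 * segment_s, by = sampling_interval_s)
  slope <- numeric(length(t))
  slope[t >= bounds[1] & t < bounds[2]] <- flux_routine
  slope[t >= bounds[2] & t < bounds[3]] <- flux_state3
  slope[t >= bounds[3]] <- flux_uncoupled
  v <- o2_start - cumsum(slope) * sampling_interval_s
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  ev <- data.frame(time = bounds, label = c("substrate", "ADP", "FCCP"),
                   amount = c(NA_real_, 200, 0.08))
  list(trace = trace(t, v, events = ev, time_unit = "s"),
       truth = list(assay = "respirometry", flux_routine = flux_routine,
                    flux_state3 = flux_state3, flux_uncoupled = flux_uncoupled,
                    respiratory_control = flux_state3 / flux_routine,
                    noise_sd = noise_sd))
}

#' Simulate a pressure-volume recording with preload occlusion
#'
#' Steady-state loops followed by occlusion beats whose end-diastolic volume
#' falls by `preload_step_ul` per beat.  End-systolic points lie exactly on
#' P = espvr_slope * (V - v0); end-diastolic points on
#' P = edpvr_slope * (V - v0).  During ejection the pressure rises linearly
#' in volume toward the end-systolic corner, which guarantees the corner is
#' the point of maximal P/(V - v0) within each loop.
#'
#' @param seed integer seed.
#' @param n_ss_beats steady-state beats before occlusion.
#' @param n_occl_beats occlusion beats with decreasing preload.
#' @param edv_ul,esv_ul steady-state end-diastolic / end-systolic volume (uL).
#' @param hr_bpm heart rate (beats/min).
#' @param espvr_slope,edpvr_slope true relation slopes (mmHg/uL).
#' @param v0_ul volume-axis intercept shared by both relations (uL).
#' @param preload_step_ul per-beat EDV decrement during occlusion (uL).
#' @param sampling_interval_ms sampling interval (ms).
#' @param noise_sd_p pressure noise SD (mmHg).
#' @param noise_sd_v volume noise SD (uL).
#' @return list with `series` (a `pv_series`) and `truth`.
#' @export
simulate_pv_occlusion <- function(seed = 1, n_ss_beats = 5, n_occl_beats = 8,
                                  edv_ul = 50, esv_ul = 20, hr_bpm = 600,
                                  espvr_slope = 5, edpvr_slope = 0.15,
                                  v0_ul = 2, preload_step_ul = 2.5,
                                  sampling_interval_ms = 0.5,
                                  noise_sd_p = 0, noise_sd_v = 0) {
  if (edv_ul <= esv_ul) stop("edv_ul must exceed esv_ul")
  if (esv_ul <= v0_ul) stop("esv_ul must exceed v0_ul")
  set.seed(seed)
  period <- 60000 / hr_bpm
  nper <- round(period / sampling_interval_ms)
  n_beats <- n_ss_beats + n_occl_beats
  edv_k <- edv_ul - pmax(seq_len(n_beats + 1) - n_ss_beats - 1, 0) * preload_step_ul
  if (min(edv_k) <= esv_ul * 0.6 + v0_ul) {
    stop("occlusion drives EDV too low; reduce n_occl_beats or preload_step_ul")
  }
  # ES point scaled along the ESPVR so it stays on the line as preload falls
  esv_k <- v0_ul + (esv_ul - v0_ul) * (edv_k - v0_ul) / (edv_ul - v0_ul)
  esp_k <- espvr_slope * (esv_k - v0_ul)
  edp_k <- edpvr_slope * (edv_k - v0_ul)
  # phase fractions: isovolumic contraction, ejection, isovol. relaxation, filling
  frac <- c(0.08, 0.30, 0.08, 0.54)
  nph <- round(frac / sum(frac) * nper)
  nph[4] <- nper - sum(nph[1:3])
  p_min <- 2
  vol <- numeric(0); pre <- numeric(0)
  cosramp <- function(n, from, to) {
    s <- (1 - cos(pi * seq_len(n) / n)) / 2
    from + (to - from) * s
  }
  for (k in seq_len(n_beats)) {
    p1 <- 0.75 * esp_k[k]
    # isovolumic contraction at EDV
    v1 <- rep(edv_k[k], nph[1]); pr1 <- cosramp(nph[1], edp_k[k], p1)
    # ejection: V falls EDV -> ESV, P linear in V from p1 -> ESP (corner exact)
    v2 <- cosramp(nph[2], edv_k[k], esv_k[k])
    pr2 <- p1 + (esp_k[k] - p1) * (edv_k[k] - v2) / (edv_k[k] - esv_k[k])
    # isovolumic relaxation at ESV
    v3 <- rep(esv_k[k], nph[3]); pr3 <- cosramp(nph[3], esp_k[k], p_min)
    # filling toward next beat's EDV/EDP
    v4 <- cosramp(nph[4], esv_k[k], edv_k[k + 1])
    pr4 <- cosramp(nph[4], p_min, edp_k[k + 1])
    vol <- c(vol, v1, v2, v3, v4)
    pre <- c(pre, pr1, pr2, pr3, pr4)
  }
  t <- (seq_along(vol) - 1) * sampling_interval_ms
  if (noise_sd_p > 0) pre <- pre + stats::rnorm(length(pre), 0, noise_sd_p)
  if (noise_sd_v > 0) vol <- vol + stats::rnorm(length(vol), 0, noise_sd_v)
  occl_t <- n_ss_beats * nper * sampling_interval_ms
  ev <- data.frame(time = occl_t, label = "occlusion", amount = NA_real_)
  sv <- edv_ul - esv_ul
  list(series = pv_series(t, pre, vol, events = ev),
       truth = list(assay = "pv", edv_ul = edv_ul, esv_ul = esv_ul,
                    sv_ul = sv, ef_pct = 100 * sv / edv_ul,
                    co_ul_min = sv * hr_bpm, hr_bpm = hr_bpm,
                    espvr_slope = espvr_slope, edpvr_slope = edpvr_slope,
                    v0_ul = v0_ul, n_ss_beats = n_ss_beats,
                    n_occl_beats = n_occl_beats, occlusion_time_ms = occl_t))
}

#' Simulate a two-color (Masson-style) histology image
#'
#' Pixels are colored from pure-hue palettes in exactly the requested
#' proportions, arranged as spatially clustered blobs (thresholded smoothed
#' random fields).  With `cell_areas_um2` given, the image instead contains
#' isolated red elliptical "cells" of known area on a white background, for
#' validating the cross-sectional-area pipeline.
#'
#' @param seed integer seed.
#' @param width,height image size (pixels).
#' @param frac_blue,frac_red pixel fractions of the collagen (blue) and
#'   muscle (red) classes; the remainder is background.  Must sum to <= 1.
#' @param scale_um_per_px physical scale (um per pixel).
#' @param cell_areas_um2 optional numeric vector of true ellipse areas (um^2).
#' @param palette named list of RGB triplets (0..1) for blue, red, background.
#' @return list with `image` (an `rgb_image`) and `truth`.
#' @export
simulate_histology <- function(seed = 1, width = 400, height = 400,
                               frac_blue = 0.15, frac_red = 0.75,
                               scale_um_per_px = 1, cell_areas_um2 = NULL,
                               palette = histology_palette()) {
  if (frac_blue < 0 || frac_red < 0 || frac_blue + frac_red > 1) {
    stop("frac_blue and frac_red must be >= 0 and sum to <= 1")
  }
  set.seed(seed)
  if (!is.null(cell_areas_um2)) {
    return(simulate_cell_image(width, height, cell_areas_um2,
                               scale_um_per_px, palette))
  }
  n <- width * height
  n_blue <- round(frac_blue * n)
  n_red <- round(frac_red * n)
  field1 <- clustered_field(height, width)
  field2 <- clustered_field(height, width)
  r1 <- rank(field1, ties.method = "first")
  lab <- matrix("background", height, width)
  lab[r1 <= n_blue] <- "blue"
  rest <- which(lab == "background")
  r2 <- rank(field2[rest], ties.method = "first")
  lab[rest[r2 <= n_red]] <- "red"
  img <- array(0, dim = c(height, width, 3))
  for (cls in c("blue", "red", "background")) {
    m <- lab == cls
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[m] <- palette[[cls]][ch]; img[, , ch] <- plane
    }
  }
  list(image = rgb_image(img, scale_um_per_px = scale_um_per_px),
       truth = list(assay = "histology",
                    frac_blue = n_blue / n, frac_red = n_red / n,
                    frac_background = 1 - (n_blue + n_red) / n,
                    fibrotic_index = if (n_red > 0) n_blue / n_red else NA_real_))
}

# smoothed white-noise field: three passes of a separable box blur
clustered_field <- function(h, w, blur = 15) {
  f <- matrix(stats::rnorm(h * w), h, w)
  for (i in 1:3) {
    f <- t(apply(f, 1, moving_average, k = blur))
    f <- apply(f, 2, moving_average, k = blur)
  }
  f
}

simulate_cell_image <- function(width, height, areas_um2, scale, palette) {
  img <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) img[, , ch] <- palette$background[ch]
  n <- length(areas_um2)
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  cw <- width / ncol_grid; chh <- height / nrow_grid
  truth_areas <- numeric(n)
  for (i in seq_len(n)) {
    gx <- (i - 1) %% ncol_grid; gy <- (i - 1) %/% ncol_grid
    cx <- (gx + 0.5) * cw; cy <- (gy + 0.5) * chh
    area_px <- areas_um2[i] / scale^2
    aspect <- stats::runif(1, 0.6, 1.4)
    ax <- sqrt(area_px / pi * aspect)   # semi-axes in pixels
    ay <- area_px / pi / ax
    if (2 * ax > 0.9 * cw || 2 * ay > 0.9 * chh) {
      stop("cell area too large for the image grid; enlarge the image")
    }
    xs <- seq_len(width); ys <- seq_len(height)
    m <- outer((ys - cy)^2 / ay^2, (xs - cx)^2 / ax^2, "+") <= 1
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[m] <- palette$red[ch]; img[, , ch] <- plane
    }
    truth_areas[i] <- areas_um2[i]
  }
  list(image = rgb_image(img, scale_um_per_px = scale),
       truth = list(assay = "histology_cells", cell_areas_um2 = truth_areas))
}

#' Default pure-hue palette for synthetic histology
#'
#' Values are multiples of 1/255 so 8-bit PNG round-trips are lossless.
#' @return named list of RGB triplets in 0..1
#' @export
histology_palette <- function() {
  list(blue = c(38, 64, 217) / 255,        # hue ~232 deg
       red = c(217, 31, 46) / 255,         # hue ~355 deg
       background = c(245, 245, 245) / 255,
       brown = c(115, 71, 31) / 255)       # hue ~29 deg (DAB)
}

#' Simulate a DAB/TUNEL-style image with a known positive fraction
#'
#' Tissue pixels are red; a fraction `frac_positive` of them are brown
#' (DAB-positive), clustered in blobs; the remainder of the image is white
#' background excluded from the tissue denominator.
#'
#' @inheritParams simulate_histology
#' @param frac_positive fraction of tissue pixels that are positive.
#' @param frac_background fraction of the whole image that is background.
#' @return list with `image` and `truth`.
#' @export
simulate_tunel <- function(seed = 1, width = 300, height = 300,
                           frac_positive = 0.25, frac_background = 0.2,
                           scale_um_per_px = 1, palette = histology_palette()) {
  if (frac_positive < 0 || frac_positive > 1) stop("frac_positive must be in [0,1]")
  set.seed(seed)
  n <- width * height
  n_bg <- round(frac_background * n)
  n_tissue <- n - n_bg
  n_pos <- round(frac_positive * n_tissue)
  f1 <- clustered_field(height, width)
  lab <- matrix("red", height, width)
  lab[rank(f1, ties.method = "first") <= n_bg] <- "background"
  tissue_idx <- which(lab == "red")
  f2 <- clustered_field(height, width)
  r2 <- rank(f2[tissue_idx], ties.method = "first")
  lab[tissue_idx[r2 <= n_pos]] <- "brown"
  img <- array(0, dim = c(height, width, 3))
  for (cls in c("red", "brown", "background")) {
    m <- lab == cls
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[m] <- palette[[cls]][ch]; img[, , ch] <- plane
    }
  }
  list(image = rgb_image(img, scale_um_per_px = scale_um_per_px),
       truth = list(assay = "tunel", frac_positive = n_pos / n_tissue,
                    frac_background = n_bg / n))
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Housekeeping and target Ct values are drawn so that each group's
#' geometric-mean fold change (relative to the control group, 2^-ddCt) equals
#' `2^log2_fold_changes` in expectation, exactly so at `ct_sd = 0`.
#'
#' @param seed integer seed.
#' @param n_per_group samples per group.
#' @param log2_fold_changes named numeric vector of per-group log2 fold
#'   changes; the control group must have value 0 and be first.
#' @param dct_control_mean mean delta-Ct (target - housekeeping) of the
#'   control group (cycles).
#' @param ct_sd per-measurement Ct noise SD (cycles).
#' @param hk_mean housekeeping-gene mean Ct (cycles).
#' @param gene,housekeeping gene labels.
#' @return list with `table` (sample, group, gene, ct) and `truth`.
#' @export
simulate_qpcr <- function(seed = 1, n_per_group = 8,
                          log2_fold_changes = c(CTRL = 0, HF = 1.5, HF_CBD = 0.5),
                          dct_control_mean = 3, ct_sd = 0.25, hk_mean = 18,
                          gene = "Nppb", housekeeping = "Gapdh") {
  if (is.null(names(log2_fold_changes))) stop("log2_fold_changes must be named by group")
  set.seed(seed)
  groups <- names(log2_fold_changes)
  rows <- list()
  for (g in groups) {
    dct_g <- dct_control_mean - log2_fold_changes[[g]]
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s_%02d", g, i)
      ct_hk <- stats::rnorm(1, hk_mean, ct_sd)
      ct_tg <- ct_hk + dct_g + stats::rnorm(1, 0, ct_sd)
      rows[[length(rows) + 1]] <- data.frame(
        sample = id, group = g, gene = c(gene, housekeeping),
        ct = c(ct_tg, ct_hk), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab,
       truth = list(assay = "qpcr", log2_fold_changes = as.list(log2_fold_changes),
                    fold_changes = as.list(2^log2_fold_changes),
                    dct_control_mean = dct_control_mean, ct_sd = ct_sd,
                    gene = gene, housekeeping = housekeeping,
                    control_group = groups[1]))
}

#' Serialize a ground-truth record to JSON
#' @param truth list returned in a generator's `truth` slot
#' @param path output path
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a ground-truth JSON written by [write_ground_truth()]
#' @param path JSON path
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
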