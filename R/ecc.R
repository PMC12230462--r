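# Per-beat calcium transient and cell-shortening kinetics.
#
# Definitions: amplitude is the maximal dF/F0 within the beat, with F0 the
# mean fluorescence over a pre-stimulus window; time to peak runs from beat
# onset to the peak; T50 is the time from the peak to the first interpolated
# crossing of 50% amplitude; tau is the time constant of a least-squares
# mono-exponential fit (with offset) of the decay phase, peak to segment end.
# Shortening mirrors this on the cell-length trace: maximal shortening,
# time to peak shortening (TTPS) and time to half relaxation (TTHR).

#' Split a paced trace into per-beat segments
#'
#' One half-open segment per stimulus, ending at the next stimulus or at the
#' trace end.  Stimuli come from the trace's event table (label "stimulus")
#' or, if absent, are reconstructed from a pacing frequency and the first
#' detectable beat onset.
#'
#' @param x a [trace()]
#' @param pacing_hz optional pacing frequency (Hz) used only when the trace
#'   carries no stimulus events.
#' @return data.frame with one row per beat: `stimulus_time`, `start`, `end`
#'   (indices into the trace, end exclusive).
#' @export
segment_beats <- function(x, pacing_hz = NULL) {
  ev <- trace_events(x)
  stim <- ev$time[ev$label == "stimulus"]
  if (length(stim) == 0 && !is.null(pacing_hz)) {
    stim <- reconstruct_stimuli(x, pacing_hz)
  }
  if (length(stim) == 0) {
    warning("no stimuli found; returning an empty segment list")
    return(data.frame(stimulus_time = numeric(0), start = integer(0),
                      end = integer(0)))
  }
  stim <- sort(stim)
  n <- nrow(x)
  start <- findInterval(stim, x$time)
  end <- c(start[-1], n + 1L)
  keep <- start >= 1 & start <= n & end > start
  data.frame(stimulus_time = stim[keep], start = as.integer(start[keep]),
             end = as.integer(end[keep] - 1L))
}

# locate the first beat onset (steepest sustained deviation from the initial
# baseline) and lay down stimuli every pacing period from there
reconstruct_stimuli <- function(x, pacing_hz) {
  period <- 1000 / pacing_hz
  base_n <- max(5L, round(0.05 * nrow(x)))
  base <- stats::median(x$value[seq_len(base_n)])
  s <- noise_sd_mad(x$value[seq_len(base_n)] - base)
  thr <- 5 * max(s, 1e-12)
  dev <- abs(x$value - base) > thr
  first <- which(dev)[1]
  if (is.na(first)) return(numeric(0))
  t0 <- x$time[max(first - 1L, 1L)]
  seq(t0, x$time[nrow(x)], by = period)
}

#' Baseline fluorescence F0 before a stimulus
#'
#' Arithmetic mean of the samples in `[stimulus - window, stimulus)`.
#'
#' @param segment one row of [segment_beats()] output
#' @param x the [trace()]
#' @param window window length before the stimulus, in trace time units (ms)
#' @return scalar baseline
#' @export
baseline_f0 <- function(segment, x, window = 200) {
  s <- segment$stimulus_time
  sel <- x$time >= s - window & x$time < s
  if (!any(sel)) stop("empty F0 window before stimulus at t = ", s)
  f0 <- mean(x$value[sel])
  if (f0 <= 0) stop("F0 <= 0: dF/F0 is undefined for this trace")
  f0
}

# SD of the F0-window samples, for the usability floor
baseline_noise <- function(segment, x, window = 200) {
  s <- segment$stimulus_time
  sel <- x$time >= s - window & x$time < s
  if (sum(sel) < 3) return(0)
  stats::sd(x$value[sel])
}

#' Per-beat calcium transient features
#'
#' @param segment one row of [segment_beats()] output
#' @param x the fluorescence [trace()]
#' @param f0 baseline from [baseline_f0()]
#' @param onset `"stimulus"` (default) measures time-to-peak from the
#'   stimulus; `"threshold"` from the interpolated 10%-of-amplitude upstroke
#'   crossing, for traces where the stimulus artifact precedes the rise.
#' @param noise_floor_k usability floor: amplitude must exceed
#'   `noise_floor_k` times the baseline noise SD, else the beat is flagged
#'   unusable and no kinetics are reported.
#' @param f0_window window used for the noise estimate (ms).
#' @param smooth_samples boxcar width (samples) applied to the signal before
#'   features are read; `NULL` (default) is adaptive — no smoothing when the
#'   baseline window shows negligible noise (< 0.1% of F0), an 11-sample
#'   boxcar otherwise.  The raw peak of a clean signal is exact, while under
#'   noise the smoothed peak avoids the upward bias of a raw maximum.
#' @return one-row data.frame: `f0`, `amplitude` (dF/F0), `time_to_peak`,
#'   `t50_decay`, `tau` (ms), `fit_rmse`, `usable` (logical).
#' @export
transient_features <- function(segment, x, f0 = baseline_f0(segment, x),
                               onset = c("stimulus", "threshold"),
                               noise_floor_k = 5, f0_window = 200,
                               smooth_samples = NULL) {
  onset <- match.arg(onset)
  idx <- seq(segment$start, segment$end)
  tt <- x$time[idx]; vv <- x$value[idx]
  nsd_raw <- baseline_noise(segment, x, f0_window)
  smooth_samples <- smooth_samples %||%
    (if (nsd_raw > 1e-3 * f0) 11L else 0L)
  if (smooth_samples > 1) vv <- moving_average(vv, smooth_samples)
  dff <- (vv - f0) / f0
  pk <- which.max(dff)
  amplitude <- dff[pk]
  nsd <- nsd_raw / f0
  if (amplitude <= 0 || (nsd > 0 && amplitude < noise_floor_k * nsd)) {
    return(data.frame(f0 = f0, amplitude = max(amplitude, 0),
                      time_to_peak = NA_real_, t50_decay = NA_real_,
                      tau = NA_real_, fit_rmse = NA_real_, usable = FALSE))
  }
  onset_time <- if (onset == "stimulus") {
    segment$stimulus_time
  } else {
    oc <- first_crossing(tt, dff, 0.1 * amplitude, "up", seq_len(pk))
    if (is.na(oc)) segment$stimulus_time else oc
  }
  time_to_peak <- tt[pk] - onset_time
  half_level <- f0 + amplitude * f0 / 2
  t50_abs <- first_crossing(tt, vv, half_level, "down", pk:length(tt))
  t50 <- if (is.na(t50_abs)) NA_real_ else t50_abs - tt[pk]
  fit <- fit_exp_decay(tt[pk:length(tt)], vv[pk:length(vv)])
  data.frame(f0 = f0, amplitude = amplitude, time_to_peak = time_to_peak,
             t50_decay = t50, tau = fit$tau, fit_rmse = fit$rmse / f0,
             usable = TRUE)
}

# least-squares fit of A*exp(-(t-t0)/tau) + C with log-linear initialization;
# returns tau = NA when the decay cannot be fit
fit_exp_decay <- function(t, v) {
  if (length(t) < 5) return(list(tau = NA_real_, rmse = NA_real_))
  tl <- t - t[1]
  c0 <- min(v) - 0.05 * (max(v) - min(v))
  pos <- v - c0
  ok <- pos > 0
  if (sum(ok) < 3) return(list(tau = NA_real_, rmse = NA_real_))
  init <- unname(stats::coef(stats::lm(log(pos[ok]) ~ tl[ok])))
  tau0 <- -1 / init[2]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(tl)) / 3
  a0 <- exp(init[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ A * exp(-tl / tau) + C,
                      start = list(A = a0, tau = tau0, C = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(tau = NA_real_, rmse = NA_real_))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0) {
    return(list(tau = NA_real_, rmse = NA_real_))
  }
  list(tau = unname(cf[["tau"]]),
       rmse = sqrt(mean(stats::residuals(fit)^2)))
}

#' Per-beat cell-shortening features
#'
#' @inheritParams transient_features
#' @param x the cell-length [trace()] (um)
#' @param resting_window window before the stimulus used to estimate the
#'   resting length (ms), same rule as the F0 window.
#' @return one-row data.frame: `resting_length`, `max_shortening_abs` (um),
#'   `max_shortening_pct`, `ttps` (ms), `tthr` (ms, NA with `tthr_censored`
#'   when the cell never recovers to 50% within the segment).
#' @export
shortening_features <- function(segment, x, onset = c("stimulus", "threshold"),
                                resting_window = 200, smooth_samples = NULL) {
  onset <- match.arg(onset)
  s <- segment$stimulus_time
  sel <- x$time >= s - resting_window & x$time < s
  if (!any(sel)) stop("empty resting-length window before stimulus at t = ", s)
  resting <- mean(x$value[sel])
  nsd <- if (sum(sel) >= 3) stats::sd(x$value[sel]) else 0
  idx <- seq(segment$start, segment$end)
  tt <- x$time[idx]; vv <- x$value[idx]
  smooth_samples <- smooth_samples %||%
    (if (nsd > 1e-3 * resting) 11L else 0L)
  if (smooth_samples > 1) vv <- moving_average(vv, smooth_samples)
  mn <- which.min(vv)
  depth <- resting - vv[mn]
  if (depth < 0) depth <- 0
  onset_time <- if (onset == "stimulus") {
    s
  } else {
    oc <- first_crossing(tt, resting - vv, 0.1 * depth, "up", seq_len(mn))
    if (is.na(oc)) s else oc
  }
  ttps <- tt[mn] - onset_time
  half_level <- resting - 0.5 * depth
  tthr_abs <- first_crossing(tt, vv, half_level, "up", mn:length(tt))
  tthr <- if (is.na(tthr_abs)) NA_real_ else tthr_abs - tt[mn]
  data.frame(resting_length = resting, max_shortening_abs = depth,
             max_shortening_pct = 100 * depth / resting,
             ttps = ttps, tthr = tthr, tthr_censored = is.na(tthr))
}

#' Beat-averaged feature table across cells and pacing frequencies
#'
#' Runs per-beat feature extraction on every trace and aggregates per cell
#' and frequency by the median across usable beats (robust to a single
#' arrhythmic beat).
#'
#' @param traces named list of [trace()] objects (fluorescence), one per
#'   cell x frequency recording.
#' @param meta data.frame aligned with `traces`: columns `cell`, `group`,
#'   `pacing_hz`.
#' @param kind `"transient"` or `"shortening"`.
#' @param ... passed to the per-beat feature function.
#' @return tidy data.frame keyed by cell, group, pacing_hz with the
#'   beat-median features and `n_beats` used.
#' @export
batch_features <- function(traces, meta, kind = c("transient", "shortening"),
                           ...) {
  kind <- match.arg(kind)
  stopifnot(length(traces) == nrow(meta))
  out <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    x <- traces[[i]]
    segs <- segment_beats(x, pacing_hz = meta$pacing_hz[i])
    if (nrow(segs) == 0) next
    feats <- do.call(rbind, lapply(seq_len(nrow(segs)), function(j) {
      seg <- segs[j, ]
      if (kind == "transient") transient_features(seg, x, ...)
      else shortening_features(seg, x, ...)
    }))
    if (kind == "transient") feats <- feats[feats$usable, , drop = FALSE]
    if (nrow(feats) == 0) next
    med <- vapply(feats[vapply(feats, is.numeric, logical(1))],
                  stats::median, numeric(1), na.rm = TRUE)
    out[[i]] <- cbind(data.frame(cell = meta$cell[i], group = meta$group[i],
                                 pacing_hz = meta$pacing_hz[i],
                                 n_beats = nrow(feats)),
                      as.data.frame(as.list(med)))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- data.frame()
  rownames(res) <- NULL
  res
}
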