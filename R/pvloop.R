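# Pressure-volume loop hemodynamics: cycle detection, steady-state stroke
# volume / ejection fraction / cardiac output, and occlusion-derived
# ESPVR / EDPVR slopes.

#' Pressure-volume time series
#'
#' @param time ms, uniformly sampled
#' @param pressure mmHg
#' @param volume uL, positive
#' @param events data.frame (time, label, amount); an `occlusion` event
#'   marks the start of the preload occlusion
#' @return object of class `pv_series`: data.frame time, pressure, volume
#'   with an `events` attribute
#' @export
pv_series <- function(time, pressure, volume, events = empty_events()) {
  stopifnot(length(time) == length(pressure), length(time) == length(volume))
  if (any(volume <= 0)) stop("volume must be positive")
  dt <- diff(time)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-9 * max(dt)) {
    stop("pv_series must be uniformly sampled with increasing time")
  }
  if (!"amount" %in% names(events)) events$amount <- rep(NA_real_, nrow(events))
  out <- data.frame(time = time, pressure = pressure, volume = volume)
  attr(out, "events") <- events
  class(out) <- c("pv_series", "data.frame")
  out
}

#' @export
print.pv_series <- function(x, ...) {
  cat(sprintf("<pv_series> %d samples, %.0f ms, P [%.1f, %.1f] mmHg, V [%.1f, %.1f] uL\n",
              nrow(x), x$time[nrow(x)] - x$time[1], min(x$pressure),
              max(x$pressure), min(x$volume), max(x$volume)))
  invisible(x)
}

#' Write / read a PV series as CSV (+ events sidecar)
#' @param x a [pv_series()]
#' @param path CSV path (columns time, pressure_mmHg, volume_uL)
#' @export
write_pv_csv <- function(x, path) {
  df <- data.frame(time = .fmt_num(x$time), pressure_mmHg = .fmt_num(x$pressure),
                   volume_uL = .fmt_num(x$volume))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  ev <- attr(x, "events")
  if (nrow(ev) > 0) {
    utils::write.csv(data.frame(time = .fmt_num(ev$time), label = ev$label,
                                amount = .fmt_num(ev$amount)),
                     default_events_path(path), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_pv_csv
#' @export
read_pv_csv <- function(path) {
  df <- utils::read.csv(path)
  evp <- default_events_path(path)
  ev <- empty_events()
  if (file.exists(evp)) {
    raw <- utils::read.csv(evp, colClasses = c("numeric", "character", "numeric"))
    if (nrow(raw) > 0) ev <- raw
  }
  pv_series(df$time, df$pressure_mmHg, df$volume_uL, events = ev)
}

#' Detect cardiac cycles in a PV series
#'
#' Cycle boundaries are placed at volume maxima (end-diastole) found on a
#' 10-sample moving-average-smoothed volume signal, robust to catheter
#' noise.  Per cycle: EDV = maximal volume, ESV = minimal volume, EDP =
#' pressure at the EDV sample, and the end-systolic point per the chosen
#' convention.
#'
#' @param x a [pv_series()]
#' @param smooth_n moving-average window (samples) for boundary detection
#' @param es_convention `"max_ratio"` (default): end-systole is the point of
#'   maximal P/(V - v0_est), with v0_est from a two-pass fit (pass one uses
#'   v0 = 0, then the ESPVR volume intercept, iterated once);
#'   `"max_pressure"`: the pressure maximum of the cycle.
#' @return data.frame, one row per cycle: `start`, `end` (indices), `edv`,
#'   `esv`, `edp`, `esp`, `esv_at_es`, `period_ms`
#' @export
detect_cycles <- function(x, smooth_n = 10,
                          es_convention = c("max_ratio", "max_pressure")) {
  es_convention <- match.arg(es_convention)
  vs <- moving_average(x$volume, smooth_n)
  n <- length(vs)
  rng <- max(vs) - min(vs)
  if (rng <= 1e-9 * max(abs(vs))) stop("constant volume signal: no cycles")
  # catheter noise level (robust, from second differences — smooth signals
  # have near-zero curvature per sample) decides whether points are read from
  # the raw or the smoothed series: raw reading keeps noise-free corners exact
  nv <- noise_sd_mad(diff(x$volume, differences = 2)) / sqrt(6)
  np <- noise_sd_mad(diff(x$pressure, differences = 2)) / sqrt(6)
  prng <- max(x$pressure) - min(x$pressure)
  noisy <- nv > 1e-3 * rng || np > 1e-3 * prng
  vr <- if (noisy) vs else x$volume
  pr <- if (noisy) moving_average(x$pressure, smooth_n) else x$pressure
  if (!noisy) nv <- 0
  # local maxima of the smoothed volume, high enough to be end-diastole
  is_pk <- c(FALSE, vs[2:(n - 1)] >= vs[1:(n - 2)] & vs[2:(n - 1)] > vs[3:n], FALSE)
  pk <- which(is_pk & vs > min(vs) + 0.5 * rng)
  # merge close peaks: first at the smoothing scale, then at half the median
  # surviving spacing (a beat cannot be shorter than half a typical beat)
  merge_peaks <- function(pk, min_sep) {
    keep <- pk[1]
    for (p in pk[-1]) {
      if (p - keep[length(keep)] < min_sep) {
        if (vs[p] > vs[keep[length(keep)]]) keep[length(keep)] <- p
      } else keep <- c(keep, p)
    }
    keep
  }
  if (length(pk) > 1) pk <- merge_peaks(pk, 2 * smooth_n)
  if (length(pk) > 2) pk <- merge_peaks(pk, 0.5 * stats::median(diff(pk)))
  if (length(pk) < 2) stop("fewer than 2 volume maxima: need at least 2 full cycles")
  # refine each boundary to the first sample of the volume maximum plateau
  # near the smoothed peak (the true end-diastolic sample)
  pk <- vapply(pk, function(p) {
    w <- max(1L, p - smooth_n):min(n, p + smooth_n)
    b <- w[which.max(vr[w])]
    while (b > 1 && vr[b - 1] >= vr[b]) b <- b - 1L
    b
  }, integer(1))
  pk <- sort(unique(pk))
  if (length(pk) < 2) stop("fewer than 2 volume maxima: need at least 2 full cycles")
  cyc <- data.frame(start = pk[-length(pk)], end = pk[-1] - 1L)
  # end-diastole per boundary: the volume-maximum plateau can span several
  # samples (isovolumic contraction) and may extend before the boundary
  # index; EDP is the lowest pressure on that plateau
  ed_tol <- if (noisy) 3 * nv / sqrt(smooth_n) + 0.002 * rng else 1e-9 * rng
  ed_point <- function(b) {
    w <- max(1L, b - 3L * smooth_n):min(n, b + 3L * smooth_n)
    mx <- max(vr[w])
    run <- w[vr[w] >= mx - ed_tol]
    c(edv = mx, edp = min(pr[run]))
  }
  cycles <- do.call(rbind, lapply(seq_len(nrow(cyc)), function(i) {
    idx <- cyc$start[i]:cyc$end[i]
    ed <- ed_point(cyc$start[i])
    data.frame(start = cyc$start[i], end = cyc$end[i],
               edv = ed[["edv"]], esv = min(vr[idx]), edp = ed[["edp"]],
               period_ms = (length(idx)) * (x$time[2] - x$time[1]))
  }))
  # end-systolic point
  es_point <- function(v0) {
    t(vapply(seq_len(nrow(cyc)), function(i) {
      idx <- cyc$start[i]:cyc$end[i]
      v <- vr[idx]; p <- pr[idx]
      if (es_convention == "max_pressure") {
        j <- which.max(p)
      } else {
        r <- ifelse(v > v0 + 1e-6, p / (v - v0), -Inf)
        j <- which.max(r)
      }
      c(esp = p[j], esv_at_es = v[j])
    }, c(esp = 0, esv_at_es = 0)))
  }
  es <- es_point(0)
  if (es_convention == "max_ratio" && nrow(cycles) >= 3) {
    fit <- stats::lm(es[, "esp"] ~ es[, "esv_at_es"])
    v0_est <- -stats::coef(fit)[1] / stats::coef(fit)[2]
    if (is.finite(v0_est) && v0_est < min(x$volume)) es <- es_point(v0_est)
  }
  cycles$esp <- es[, "esp"]
  cycles$esv_at_es <- es[, "esv_at_es"]
  cycles
}

#' Steady-state hemodynamics from pre-occlusion cycles
#'
#' Per-cycle stroke volume SV = EDV - ESV, ejection fraction
#' EF = 100 SV/EDV, heart rate from the cycle period, cardiac output
#' CO = SV x HR; averaged over the steady-state window (all cycles before
#' the occlusion event, or before EDV drops more than 5% below the running
#' median when no event is recorded).
#'
#' @param cycles data.frame from [detect_cycles()]
#' @param x the [pv_series()] (for the occlusion event)
#' @return one-row data.frame: `sv_ul`, `ef_pct`, `co_ul_min`, `hr_bpm`,
#'   `edv_ul`, `esv_ul`, `n_cycles`
#' @export
steady_state_hemodynamics <- function(cycles, x = NULL) {
  ss <- steady_state_window(cycles, x)
  if (nrow(ss) == 0) stop("no steady-state cycles before occlusion")
  sv <- ss$edv - ss$esv
  ef <- 100 * sv / ss$edv
  hr <- 60000 / ss$period_ms
  data.frame(sv_ul = mean(sv), ef_pct = mean(ef),
             co_ul_min = mean(sv * hr), hr_bpm = mean(hr),
             edv_ul = mean(ss$edv), esv_ul = mean(ss$esv), n_cycles = nrow(ss))
}

steady_state_window <- function(cycles, x = NULL) {
  if (!is.null(x)) {
    ev <- attr(x, "events")
    occ <- ev$time[ev$label == "occlusion"]
    if (length(occ) > 0) {
      t_start <- x$time[cycles$start]
      return(cycles[t_start < occ[1], , drop = FALSE])
    }
  }
  run_med <- cummax_median(cycles$edv)
  keep <- cycles$edv > 0.95 * run_med
  first_drop <- which(!keep)[1]
  if (is.na(first_drop)) cycles else cycles[seq_len(first_drop - 1L), , drop = FALSE]
}

cummax_median <- function(x) {
  vapply(seq_along(x), function(i) stats::median(x[seq_len(i)]), numeric(1))
}

#' Fit the end-systolic pressure-volume relationship (ESPVR)
#'
#' Ordinary least squares of the end-systolic (V, P) points of the occlusion
#' cycles: P = slope (V - v0).
#'
#' @param cycles data.frame from [detect_cycles()]; pass occlusion cycles
#'   (e.g. everything after the steady-state window)
#' @return one-row data.frame: `slope` (mmHg/uL), `v0_ul` (volume
#'   intercept), `r_squared`, `n_points`
#' @export
espvr_fit <- function(cycles) {
  pvr_fit(cycles$esv_at_es, cycles$esp, cycles$edv)
}

#' Fit the end-diastolic pressure-volume relationship (EDPVR), linear
#' @rdname espvr_fit
#' @export
edpvr_fit <- function(cycles) {
  pvr_fit(cycles$edv, cycles$edp, cycles$edv)
}

pvr_fit <- function(v, p, edv) {
  if (length(v) < 3) stop("need at least 3 occlusion beats for a relation fit")
  if (!any(diff(edv) < 0)) {
    warning("preload (EDV) is not decreasing across the claimed occlusion beats")
  }
  fit <- stats::lm(p ~ v)
  cf <- stats::coef(fit)
  r2 <- if (stats::var(p) > 0) summary(fit)$r.squared else 1
  data.frame(slope = unname(cf[2]), v0_ul = unname(-cf[1] / cf[2]),
             r_squared = r2, n_points = length(v))
}

#' Cycles belonging to the occlusion phase
#'
#' Complement of the steady-state window: cycles starting at or after the
#' occlusion event (or after the EDV drop when no event is recorded).
#'
#' @inheritParams steady_state_hemodynamics
#' @export
occlusion_cycles <- function(cycles, x = NULL) {
  ss <- steady_state_window(cycles, x)
  cycles[!(rownames(cycles) %in% rownames(ss)), , drop = FALSE]
}
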