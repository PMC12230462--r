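# Mitochondrial fluorometric and respirometric assays: free-Ca2+
# calibration, matrix Ca2+ content per mg protein, Ca2+ retention capacity
# (CRC) with permeability-transition detection, uniporter influx rate, and
# respiratory control from oxygen traces.

#' Fluorophore calibration constants
#'
#' Houses the dissociation constant and the saturating / zero-calcium
#' fluorescence plateaus of a single-wavelength indicator (Fluo-4:
#' Kd = 335 nmol/L).
#'
#' @param kd dissociation constant (nmol/L)
#' @param fmax fluorescence at saturating Ca2+
#' @param fmin fluorescence at zero Ca2+
#' @return object of class `calibration`
#' @export
calibration <- function(kd = 335, fmax, fmin) {
  if (kd <= 0) stop("kd must be positive")
  if (fmax <= fmin) stop("fmax must exceed fmin")
  structure(list(kd = kd, fmax = fmax, fmin = fmin), class = "calibration")
}

#' Free calcium concentration from fluorescence
#'
#' The single-wavelength indicator equation
#' \deqn{[Ca^{2+}] = K_d (F - F_{min}) / (F_{max} - F)}
#' strictly increasing in F; its exact inverse is
#' `F = (fmin*kd + ca*fmax) / (kd + ca)`.
#'
#' @param F fluorescence (scalar or vector), fmin <= F < fmax
#' @param cal a [calibration()]
#' @param below_fmin `"error"` (default) or `"clamp"` (to 0 with a warning)
#'   for readings below fmin
#' @return free Ca2+ in the units of `kd` (nmol/L by default)
#' @export
free_calcium <- function(F, cal, below_fmin = c("error", "clamp")) {
  below_fmin <- match.arg(below_fmin)
  if (any(F >= cal$fmax)) {
    stop("fluorescence at or above fmax: indicator saturated, concentration undefined")
  }
  if (any(F < cal$fmin)) {
    if (below_fmin == "error") stop("fluorescence below fmin")
    warning("fluorescence below fmin clamped to fmin")
    F <- pmax(F, cal$fmin)
  }
  cal$kd * (F - cal$fmin) / (cal$fmax - F)
}

#' Inverse of [free_calcium()]: fluorescence at a given free Ca2+
#' @param ca free Ca2+ (same units as `kd`)
#' @param cal a [calibration()]
#' @export
calcium_to_fluorescence <- function(ca, cal) {
  (cal$fmin * cal$kd + ca * cal$fmax) / (cal$kd + ca)
}

# plateau before the given time: median of the final `window` seconds
# (robust to spikes at the addition instants)
.plateau_before <- function(x, t, window = 10) plateau_median(x, t, window)

addition_time <- function(x, label) {
  ev <- trace_events(x)
  t <- ev$time[ev$label == label]
  if (length(t) == 0) return(NA_real_)
  t[1]
}

#' Mitochondrial Ca2+ content from an FCCP-release trace
#'
#' F0 is the cytosolic-indicator plateau before the FCCP addition and F the
#' plateau after it (released matrix Ca2+); fmax and fmin are read from the
#' post-CaCl2 and post-EGTA calibration plateaus.  Content is the released
#' minus baseline free Ca2+, per mg protein, so a no-release trace reads 0.
#'
#' @param x a fluorometry [trace()] (time in s) with additions labeled
#'   `FCCP`, `CaCl2_max`, `EGTA_min`
#' @param protein_mg protein in the assay (mg), > 0
#' @param kd indicator dissociation constant (nmol/L)
#' @param plateau_s plateau window (s)
#' @return one-row data.frame: `free_ca_baseline`, `free_ca_released`
#'   (nmol/L), `content_per_mg` (nmol/L per mg), `protein_mg`, `fmax`, `fmin`
#' @export
mito_ca_content <- function(x, protein_mg, kd = 335, plateau_s = 10) {
  if (protein_mg <= 0) stop("protein_mg must be positive")
  need <- c("FCCP", "CaCl2_max", "EGTA_min")
  tt <- vapply(need, function(l) addition_time(x, l), numeric(1))
  if (any(is.na(tt))) {
    stop("missing required additions: ", paste(need[is.na(tt)], collapse = ", "))
  }
  t_fccp <- tt[["FCCP"]]; t_camax <- tt[["CaCl2_max"]]; t_egta <- tt[["EGTA_min"]]
  end <- x$time[nrow(x)] + trace_dt(x)
  f0 <- .plateau_before(x, t_fccp, plateau_s)
  f_rel <- .plateau_before(x, t_camax, plateau_s)
  fmax <- .plateau_before(x, if (t_egta > t_camax) t_egta else end, plateau_s)
  fmin <- .plateau_before(x, if (t_egta > t_camax) end else t_camax, plateau_s)
  cal <- calibration(kd = kd, fmax = fmax, fmin = fmin)
  ca0 <- free_calcium(f0, cal, below_fmin = "clamp")
  ca1 <- free_calcium(f_rel, cal, below_fmin = "clamp")
  data.frame(free_ca_baseline = ca0, free_ca_released = ca1,
             content_per_mg = (ca1 - ca0) / protein_mg,
             protein_mg = protein_mg, fmax = fmax, fmin = fmin)
}

#' Calcium retention capacity analysis
#'
#' For each Ca2+ pulse, recovery means the fluorescence returns at least 50%
#' of the way from the post-pulse peak back to the pre-pulse baseline within
#' the inter-pulse interval.  Permeability-transition (mPTP) opening is the
#' first pulse with no recovery followed by a sustained rise; pulses
#' tolerated is the count of pulses before that one.  If every pulse
#' recovers the result is censored.
#'
#' @param x a fluorometry [trace()] (time in s) with `pulse` additions
#' @param pulse_amount_uM Ca2+ per pulse (umol/L); defaults to the `amount`
#'   recorded with the first pulse event
#' @param protein_mg protein in the assay (mg)
#' @param recovery_frac required fractional return toward baseline (0.5)
#' @return one-row data.frame: `pulses_tolerated`, `cumulative_ca_per_mg`
#'   (umol/L per mg), `mptp_time_s` (NA when censored), `censored`
#' @export
crc_analysis <- function(x, pulse_amount_uM = NULL, protein_mg = 1,
                         recovery_frac = 0.5) {
  ev <- trace_events(x)
  pulses <- ev[ev$label == "pulse", , drop = FALSE]
  if (nrow(pulses) == 0) stop("no pulse additions in trace")
  if (is.unsorted(pulses$time, strictly = TRUE)) stop("pulse additions not time-ordered")
  if (is.null(pulse_amount_uM)) {
    pulse_amount_uM <- pulses$amount[1]
    if (is.na(pulse_amount_uM)) stop("pulse amount unknown: pass pulse_amount_uM")
  }
  if (protein_mg <= 0) stop("protein_mg must be positive")
  end_t <- x$time[nrow(x)]
  n <- nrow(pulses)
  release_idx <- NA_integer_
  mptp_time <- NA_real_
  for (i in seq_len(n)) {
    t0 <- pulses$time[i]
    t1 <- if (i < n) pulses$time[i + 1] else min(t0 + median(diff(pulses$time)) %||% (end_t - t0), end_t)
    if (n == 1) t1 <- end_t
    pre_sel <- x$time < t0 & x$time >= t0 - 5
    pre <- stats::median(x$value[pre_sel])
    win <- which(x$time >= t0 & x$time < t1)
    if (length(win) == 0) next
    ipk <- win[which.max(x$value[win])]
    peak <- x$value[ipk]
    floor_lvl <- peak - recovery_frac * (peak - pre)
    after_pk <- win[win > ipk]
    recovered <- length(after_pk) > 0 && any(x$value[after_pk] <= floor_lvl)
    if (!recovered) {
      # sustained rise: the trace never comes back below the recovery level
      # through the end of the recording
      rest <- x$value[x$time >= t1]
      sustained <- length(rest) == 0 || min(rest) > floor_lvl
      if (sustained) { release_idx <- i; mptp_time <- t0; break }
    }
  }
  censored <- is.na(release_idx)
  tolerated <- if (censored) n else release_idx - 1L
  data.frame(pulses_tolerated = tolerated,
             cumulative_ca_per_mg = tolerated * pulse_amount_uM / protein_mg,
             mptp_time_s = mptp_time, censored = censored)
}

#' Mitochondrial Ca2+ influx rate from the post-energization decay
#'
#' Least-squares fit of the quadratic F(t) = a t^2 + b t + c over the
#' analysis window (t re-zeroed at the window start); the influx rate is the
#' magnitude of the derivative at the window start, |b| — the maximal uptake
#' rate immediately after energization.  Evaluation at mid-window is
#' available for slowly developing uptake.
#'
#' @param x a fluorometry [trace()] (time in s)
#' @param window numeric length-2, analysis window (s); defaults to from the
#'   `succinate` addition to the trace end
#' @param at `"start"` (default) or `"midpoint"` derivative evaluation
#' @param cal optional [calibration()] to express the rate in nmol/L/s
#' @return one-row data.frame: `rate` (F units/s, or nmol/L/s with `cal`),
#'   `r_squared`, coefficients `a`, `b`, `c`
#' @export
influx_rate <- function(x, window = NULL, at = c("start", "midpoint"),
                        cal = NULL) {
  at <- match.arg(at)
  if (is.null(window)) {
    t0 <- addition_time(x, "succinate")
    if (is.na(t0)) stop("no succinate addition and no window given")
    window <- c(t0, x$time[nrow(x)])
  }
  sel <- x$time >= window[1] & x$time <= window[2]
  if (sum(sel) < 5) stop("need at least 5 samples in the analysis window")
  tl <- x$time[sel] - window[1]
  v <- x$value[sel]
  if (is.null(cal)) {
    y <- v
  } else {
    y <- free_calcium(pmin(v, cal$fmax - 1e-9), cal, below_fmin = "clamp")
  }
  fit <- stats::lm(y ~ tl + I(tl^2))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) stop("rank-deficient quadratic fit")
  a <- unname(cf[3]); b <- unname(cf[2]); c0 <- unname(cf[1])
  deriv_at <- if (at == "start") b else b + 2 * a * (max(tl) / 2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  data.frame(rate = abs(deriv_at), r_squared = r2, a = a, b = b, c = c0)
}

#' Respirometry fluxes and respiratory control from an oxygen trace
#'
#' Per-segment oxygen flux is the negative slope of the O2 concentration,
#' fitted by least squares over the segment interior after trimming 10% of
#' the samples at each end (addition artifacts contaminate the edges),
#' normalized per mg protein.  Respiratory control is state3 / routine;
#' when an `oligomycin` segment exists the `state3/state4o` convention can
#' be selected.
#'
#' @param x an oxygen [trace()] (time in s) with additions
#'   `substrate`, `ADP`, `FCCP` (optionally `oligomycin`)
#' @param protein_mg protein in the chamber (mg)
#' @param rc_convention `"state3_over_routine"` (default) or
#'   `"state3_over_state4o"`
#' @param trim fraction trimmed at each segment end (default 0.1)
#' @return one-row data.frame: `routine`, `state3`, `uncoupled` (flux per
#'   mg), `respiratory_control`
#' @export
respirometry <- function(x, protein_mg = 1,
                         rc_convention = c("state3_over_routine",
                                           "state3_over_state4o"),
                         trim = 0.1) {
  rc_convention <- match.arg(rc_convention)
  if (protein_mg <= 0) stop("protein_mg must be positive")
  labs <- c("substrate", "ADP", "FCCP")
  tt <- vapply(labs, function(l) addition_time(x, l), numeric(1))
  if (any(is.na(tt))) {
    stop("missing additions: ", paste(labs[is.na(tt)], collapse = ", "))
  }
  t_olig <- addition_time(x, "oligomycin")
  bounds <- c(sort(c(unname(tt), if (!is.na(t_olig)) t_olig)),
              x$time[nrow(x)] + trace_dt(x))
  seg_names <- c("routine", "state3",
                 if (!is.na(t_olig)) "state4o", "uncoupled")
  flux <- setNames(numeric(length(seg_names)), seg_names)
  for (i in seq_along(seg_names)) {
    sel <- which(x$time >= bounds[i] & x$time < bounds[i + 1])
    k <- floor(trim * length(sel))
    sel <- sel[(k + 1):(length(sel) - k)]
    if (length(sel) < 3) stop("segment '", seg_names[i], "' too short")
    sl <- unname(stats::coef(stats::lm(x$value[sel] ~ x$time[sel]))[2])
    if (sl > 0.05 * abs(stats::median(diff(x$value)) / trace_dt(x)) && sl > 1e-9) {
      warning("positive O2 slope in segment '", seg_names[i],
              "': possible re-oxygenation artifact")
    }
    flux[i] <- -sl / protein_mg
  }
  rc <- if (rc_convention == "state3_over_routine") {
    flux[["state3"]] / flux[["routine"]]
  } else {
    if (!"state4o" %in% seg_names) stop("no oligomycin segment for state4o convention")
    flux[["state3"]] / flux[["state4o"]]
  }
  out <- data.frame(routine = flux[["routine"]], state3 = flux[["state3"]],
                    uncoupled = flux[["uncoupled"]], respiratory_control = rc)
  if ("state4o" %in% seg_names) out$state4o <- flux[["state4o"]]
  out
}
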