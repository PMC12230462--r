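# Shared numeric helpers: threshold-crossing interpolation, moving averages,
# robust noise estimates, seed stream splitting.

#' Derive a reproducible sub-seed for a named assay stream
#'
#' One global integer seed drives every generator; each assay derives its own
#' stream so partial re-runs of one assay do not perturb the others.
#'
#' @param seed integer master seed
#' @param stream character stream name (e.g. "transient", "sparks")
#' @return an integer seed below 2^31
#' @export
split_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# first linearly interpolated time at which `value` crosses `level` in the
# stated direction, scanning indices `idx` of (time, value); NA if never
first_crossing <- function(time, value, level, direction = c("down", "up"),
                           idx = seq_along(time)) {
  direction <- match.arg(direction)
  t <- time[idx]; v <- value[idx]
  if (direction == "down") {
    hit <- which(v[-1] <= level & v[-length(v)] > level)
  } else {
    hit <- which(v[-1] >= level & v[-length(v)] < level)
  }
  if (length(hit) == 0) {
    # exact equality at the first sample counts as a crossing
    eq <- which(v == level)
    if (length(eq) > 0) return(t[eq[1]])
    return(NA_real_)
  }
  i <- hit[1]
  frac <- (level - v[i]) / (v[i + 1] - v[i])
  t[i] + frac * (t[i + 1] - t[i])
}

# centered moving average, edges truncated
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# robust noise SD via median absolute deviation
noise_sd_mad <- function(x) stats::mad(x, constant = 1.4826)

# median of the samples within the final `window` time units before `t_end`
plateau_median <- function(trace, t_end, window) {
  sel <- trace$time < t_end & trace$time >= t_end - window
  if (!any(sel)) stop("empty plateau window before t = ", t_end)
  stats::median(trace$value[sel])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
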