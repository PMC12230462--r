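# Calcium spark detection on confocal line-scan images (space x time).
#
# The detector follows the two-pass threshold convention of the classic
# line-scan spark detectors: the image is normalized per spatial row to
# dF/F0, lightly smoothed, candidate pixels must exceed mean + k*SD of the
# baseline noise (k defaults to 3.8), and candidate regions are grown at
# mean + 2*SD.  Minimum-extent and raw-peak filters suppress shot noise.

#' Line-scan image container
#'
#' @param img numeric matrix, space (rows) x time (columns).
#' @param pixel_um spatial pixel size (um); the protocol uses 0.1.
#' @param line_period_ms time per line (ms).
#' @param cell_extent_um scanned cell extent; defaults to the full spatial
#'   axis.
#' @return object of class `linescan`
#' @export
linescan <- function(img, pixel_um, line_period_ms,
                     cell_extent_um = nrow(img) * pixel_um) {
  stopifnot(is.matrix(img), nrow(img) > 0, ncol(img) > 0)
  if (pixel_um <= 0 || line_period_ms <= 0) {
    stop("pixel_um and line_period_ms must be positive")
  }
  if (cell_extent_um > nrow(img) * pixel_um + 1e-9) {
    stop("cell_extent_um exceeds the spatial axis")
  }
  structure(list(img = img, pixel_um = pixel_um,
                 line_period_ms = line_period_ms,
                 cell_extent_um = cell_extent_um),
            class = "linescan")
}

#' @export
print.linescan <- function(x, ...) {
  cat(sprintf("<linescan> %d px x %d lines (%.1f um x %.2f s), pixel %.3g um, line %.3g ms\n",
              nrow(x$img), ncol(x$img), nrow(x$img) * x$pixel_um,
              ncol(x$img) * x$line_period_ms / 1000, x$pixel_um,
              x$line_period_ms))
  invisible(x)
}

#' Normalize a line scan to dF/F0 units
#'
#' Each spatial row is divided by its own temporal baseline F0(x) — the 20th
#' percentile of that row over time, robust to sparse events — and 1 is
#' subtracted, so a quiescent pixel sits at 0 and a spark peak reads directly
#' in dF/F0.
#'
#' @param x a [linescan()]
#' @param baseline_quantile per-row baseline quantile (default 0.2)
#' @return a `linescan` in dF/F0 units with attribute `normalized = TRUE`
#' @export
normalize_linescan <- function(x, baseline_quantile = 0.2) {
  f0 <- apply(x$img, 1, stats::quantile, probs = baseline_quantile, names = FALSE)
  bad <- which(f0 <= 0)
  if (length(bad) > 0) {
    stop("zero or negative baseline in spatial rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  out <- x
  out$img <- sweep(x$img, 1, f0, "/") - 1
  attr(out, "normalized") <- TRUE
  attr(out, "f0_rows") <- f0
  out
}

#' Detect calcium sparks on a normalized line scan
#'
#' Two-pass detection: the normalized image is smoothed with a 3x3 mean
#' filter; connected regions are seeded where the smoothed image exceeds
#' `criterion_k` times the smoothed-noise SD and grown at 2 SD.  Regions
#' must span at least `min_extent_px` pixels in space and `min_extent_lines`
#' lines in time, cover `min_area_px` pixels, and contain an unsmoothed
#' pixel above `criterion_k` times the raw-noise SD.  Overlapping events are
#' split at smoothed local maxima separated by a >= 30% valley (earlier
#' event wins ties).
#'
#' @param x a normalized [linescan()] (see [normalize_linescan()])
#' @param criterion_k detection criterion in SD multiples (default 3.8)
#' @param min_extent_px,min_extent_lines minimum bounding extent
#' @param min_area_px minimum connected suprathreshold area
#' @param min_peak_sep_um,min_peak_sep_ms peaks closer than both of these
#'   are treated as one event (noise ripple on a spark body), not split
#' @return data.frame of events: `center_position_um`, `center_time_ms`,
#'   `amplitude_dff0`, `fwhm_um`, `duration_half_max_ms`
#' @export
detect_sparks <- function(x, criterion_k = 3.8, min_extent_px = 3,
                          min_extent_lines = 2, min_area_px = 30,
                          min_peak_sep_um = 2, min_peak_sep_ms = 100) {
  if (!isTRUE(attr(x, "normalized"))) x <- normalize_linescan(x)
  if (criterion_k <= 0) stop("criterion_k must be positive")
  img <- x$img
  sd_raw <- noise_sd_mad(img)
  if (sd_raw <= 0) stop("degenerate noise estimate (SD = 0); cannot set a threshold")
  sm <- smooth3x3(img)
  sd_sm <- noise_sd_mad(sm)
  mu <- stats::median(sm)
  cand <- sm > mu + criterion_k * sd_sm
  if (!any(cand)) return(empty_spark_events())
  grow <- sm > mu + 2 * sd_sm
  lab <- EBImage::bwlabel(grow * 1)
  keep_ids <- unique(lab[cand])
  keep_ids <- keep_ids[keep_ids > 0]
  events <- list()
  for (id in keep_ids) {
    pix <- which(lab == id, arr.ind = TRUE)
    if (nrow(pix) < min_area_px) next
    if (length(unique(pix[, 1])) < min_extent_px) next
    if (length(unique(pix[, 2])) < min_extent_lines) next
    if (max(img[pix]) < criterion_k * sd_raw) next
    subs <- split_region(pix, sm, peak_floor = mu + criterion_k * sd_sm,
                         sep_px = min_peak_sep_um / x$pixel_um,
                         sep_lines = min_peak_sep_ms / x$line_period_ms)
    for (sub in subs) {
      ev <- summarize_spark(sub, img, sm, x)
      events[[length(events) + 1]] <- ev
    }
  }
  if (length(events) == 0) return(empty_spark_events())
  out <- do.call(rbind, events)
  # duplicate suppression: a weaker event inside the resolution footprint of
  # a stronger one is the same spark (its region was cut by a noise dip)
  ord <- order(-out$amplitude_dff0)
  keep <- rep(TRUE, nrow(out))
  for (i in ord) {
    if (!keep[i]) next
    dup <- keep & seq_len(nrow(out)) != i &
      out$amplitude_dff0 <= out$amplitude_dff0[i] &
      abs(out$center_position_um - out$center_position_um[i]) < min_peak_sep_um &
      abs(out$center_time_ms - out$center_time_ms[i]) < min_peak_sep_ms
    dup[i] <- FALSE
    keep[dup] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$center_time_ms, out$center_position_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_spark_events <- function() {
  data.frame(center_position_um = numeric(0), center_time_ms = numeric(0),
             amplitude_dff0 = numeric(0), fwhm_um = numeric(0),
             duration_half_max_ms = numeric(0))
}

smooth3x3 <- function(img) {
  s <- t(apply(img, 1, moving_average, k = 3))
  apply(s, 2, moving_average, k = 3)
}

# split a connected region at distinct smoothed local maxima separated by a
# >= 30% valley along the line joining them; earlier (in time) maximum keeps
# the shared pixels.  Secondary maxima must themselves clear the candidate
# threshold and lie outside the proximity scale of a stronger peak.
split_region <- function(pix, sm, peak_floor = -Inf, sep_px = 0, sep_lines = 0) {
  vals <- sm[pix]
  peaks <- local_maxima(pix, vals)
  if (nrow(peaks) > 1) {
    top <- which.max(peaks$value)
    peaks <- peaks[peaks$value >= peak_floor | seq_len(nrow(peaks)) == top, ,
                   drop = FALSE]
  }
  if (nrow(peaks) <= 1) return(list(pix))
  # absorb nearby or poorly separated peaks into stronger ones
  keep <- rep(TRUE, nrow(peaks))
  ord <- order(-peaks$value)
  for (i in ord) {
    if (!keep[i]) next
    for (j in ord) {
      if (i == j || !keep[j] || peaks$value[j] > peaks$value[i]) next
      close_by <- abs(peaks$row[j] - peaks$row[i]) < sep_px &&
        abs(peaks$col[j] - peaks$col[i]) < sep_lines
      valley <- path_min(sm, peaks[i, ], peaks[j, ])
      if (close_by || valley > 0.7 * peaks$value[j]) keep[j] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) <= 1) return(list(pix))
  peaks <- peaks[order(peaks$col, peaks$row), , drop = FALSE]  # earlier first
  d2 <- sapply(seq_len(nrow(peaks)), function(k) {
    (pix[, 1] - peaks$row[k])^2 + (pix[, 2] - peaks$col[k])^2
  })
  assign <- max.col(-d2, ties.method = "first")
  lapply(seq_len(nrow(peaks)), function(k) pix[assign == k, , drop = FALSE])
}

local_maxima <- function(pix, vals) {
  lut <- new.env(hash = TRUE)
  for (i in seq_len(nrow(pix))) {
    assign(paste(pix[i, 1], pix[i, 2]), vals[i], envir = lut)
  }
  is_max <- logical(nrow(pix))
  for (i in seq_len(nrow(pix))) {
    v <- vals[i]; mx <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      key <- paste(pix[i, 1] + dr, pix[i, 2] + dc)
      nb <- mget(key, envir = lut, ifnotfound = list(NULL))[[1]]
      if (!is.null(nb) && nb > v) { mx <- FALSE; break }
    }
    is_max[i] <- mx
  }
  data.frame(row = pix[is_max, 1], col = pix[is_max, 2], value = vals[is_max])
}

path_min <- function(sm, p1, p2) {
  n <- max(abs(p1$row - p2$row), abs(p1$col - p2$col)) + 1
  rr <- round(seq(p1$row, p2$row, length.out = n))
  cc <- round(seq(p1$col, p2$col, length.out = n))
  min(sm[cbind(rr, cc)])
}

summarize_spark <- function(pix, img, sm, x) {
  vals <- img[pix]
  w <- pmax(sm[pix], 0)
  if (sum(w) <= 0) w <- rep(1, length(vals))
  pk <- pix[which.max(sm[pix]), , drop = FALSE]
  # position: intensity-weighted centroid (sub-pixel); time: the peak line —
  # sparks rise fast, so the maximum marks the event, not the decay mass
  crow <- sum(pix[, 1] * w) / sum(w)
  ccol <- pk[1, 2]
  amp <- max(vals)
  half <- amp / 2
  # spatial FWHM from the raw profile through the peak line
  prof_x <- img[, pk[1, 2]]
  fwhm_px <- half_max_width(prof_x, pk[1, 1], half)
  # temporal half-max duration from the raw profile along the peak row
  prof_t <- img[pk[1, 1], ]
  dur_ln <- half_max_width(prof_t, pk[1, 2], half)
  data.frame(center_position_um = (crow - 0.5) * x$pixel_um,
             center_time_ms = (ccol - 0.5) * x$line_period_ms,
             amplitude_dff0 = amp,
             fwhm_um = fwhm_px * x$pixel_um,
             duration_half_max_ms = dur_ln * x$line_period_ms)
}

# interpolated width of `prof` around index `center` at level `half`
half_max_width <- function(prof, center, half) {
  n <- length(prof)
  left <- center
  while (left > 1 && prof[left - 1] > half) left <- left - 1
  lo <- if (left > 1) {
    (left - 1) + (half - prof[left - 1]) / (prof[left] - prof[left - 1])
  } else 1
  right <- center
  while (right < n && prof[right + 1] > half) right <- right + 1
  hi <- if (right < n) {
    right + (prof[right] - half) / (prof[right] - prof[right + 1])
  } else n
  hi - lo
}

#' Summarize detected sparks into frequency and amplitude
#'
#' Frequency is expressed in the field's convention,
#' sparks per 100 um of scanned cell per second.
#'
#' @param events data.frame from [detect_sparks()]
#' @param x the [linescan()] the events came from
#' @return one-row data.frame: `n_events`, `frequency_per_100um_s`,
#'   `mean_amplitude_dff0` (NA when there are no events)
#' @export
spark_summary <- function(events, x) {
  total_s <- ncol(x$img) * x$line_period_ms / 1000
  if (total_s <= 0) stop("zero scan time")
  n <- nrow(events)
  data.frame(n_events = n,
             frequency_per_100um_s = n / (x$cell_extent_um / 100) / total_s,
             mean_amplitude_dff0 = if (n > 0) mean(events$amplitude_dff0) else NA_real_)
}

#' Write a line scan as 16-bit grayscale TIFF plus metadata JSON
#'
#' Intensities are stored as counts/65535; integer count images in
#' 0..65535 round-trip losslessly.
#'
#' @param x a [linescan()]
#' @param path TIFF path; metadata goes to `<path>.json`
#' @export
write_linescan_tiff <- function(x, path) {
  img <- x$img / 65535
  if (min(img) < 0 || max(img) > 1) stop("intensities outside 0..65535")
  tiff::writeTIFF(t(img), path, bits.per.sample = 16)
  meta <- list(pixel_um = x$pixel_um, line_period_ms = x$line_period_ms,
               cell_extent_um = x$cell_extent_um)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a line scan written by [write_linescan_tiff()]
#' @param path TIFF path (metadata read from `<path>.json`)
#' @return a [linescan()]
#' @export
read_linescan_tiff <- function(path) {
  img <- t(tiff::readTIFF(path)) * 65535
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  linescan(img, pixel_um = meta$pixel_um, line_period_ms = meta$line_period_ms,
           cell_extent_um = meta$cell_extent_um)
}
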