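# shared helpers for the test suite

# greedy matching of detected spark events to planted ground truth
match_sparks <- function(det, tru, tol_um = 3, tol_ms = 60) {
  used <- rep(FALSE, nrow(det))
  tp <- 0L
  if (nrow(tru) > 0) {
    for (i in seq_len(nrow(tru))) {
      d <- which(!used &
                   abs(det$center_position_um - tru$position_um[i]) < tol_um &
                   abs(det$center_time_ms - tru$time_ms[i]) < tol_ms)
      if (length(d) > 0) {
        used[d[1]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  c(tp = tp, fp = nrow(det) - tp, fn = nrow(tru) - tp)
}

# per-beat transient features for a whole trace
all_transient_features <- function(tr, ...) {
  segs <- segment_beats(tr)
  do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    transient_features(segs[i, ], tr, ...)
  }))
}

all_shortening_features <- function(tr, ...) {
  segs <- segment_beats(tr)
  do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    shortening_features(segs[i, ], tr, ...)
  }))
}

# fluorometry trace for the mitochondrial content assay built from known
# free-calcium plateaus through the inverse calibration equation
make_content_trace <- function(ca_baseline, ca_released, cal,
                               protein_mg = 0.2) {
  t <- seq(0, 400, by = 1)
  f <- numeric(length(t))
  f[t < 100] <- calcium_to_fluorescence(ca_baseline, cal)
  f[t >= 100 & t < 200] <- calcium_to_fluorescence(ca_released, cal)
  f[t >= 200 & t < 300] <- cal$fmax - 1e-7
  f[t >= 300] <- cal$fmin
  ev <- data.frame(time = c(100, 200, 300),
                   label = c("FCCP", "CaCl2_max", "EGTA_min"),
                   amount = c(1, 100, 1))
  trace(t, f, events = ev, time_unit = "s")
}
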