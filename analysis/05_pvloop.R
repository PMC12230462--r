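#!/usr/bin/env Rscript
# Steady-state hemodynamics and occlusion-derived ventricular relations from
# the stored pressure-volume recording.

suppressMessages(library(cardioquant))

x <- read_pv_csv("results/data/pv_CTRL.csv")
truth <- read_ground_truth("results/data/pv_CTRL.csv.truth.json")
cyc <- detect_cycles(x)
h <- steady_state_hemodynamics(cyc, x)
oc <- occlusion_cycles(cyc, x)
es <- suppressWarnings(espvr_fit(oc))
ed <- suppressWarnings(edpvr_fit(oc))
write.csv(cyc, "results/pv_cycles.csv", row.names = FALSE)
jsonlite::write_json(list(hemodynamics = as.list(h),
                          espvr = as.list(es), edpvr = as.list(ed)),
                     "results/pv_summary.json", auto_unbox = TRUE, digits = NA)
message(sprintf("hemodynamics: SV %.1f uL (true %g), EF %.1f%% (true %g), CO %.0f uL/min (true %g), HR %.0f bpm",
                h$sv_ul, truth$sv_ul, h$ef_pct, truth$ef_pct, h$co_ul_min,
                truth$co_ul_min, h$hr_bpm))
message(sprintf("ESPVR slope %.3f mmHg/uL (true %g, r2 %.4f); EDPVR slope %.4f (true %g)",
                es$slope, truth$espvr_slope, es$r_squared, ed$slope,
                truth$edpvr_slope))
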