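#!/usr/bin/env Rscript
# Generate one synthetic dataset per assay, with ground truth, under
# results/data/.  Every downstream analysis script reads only these files,
# so the whole workflow is reproducible from a single seed.

suppressMessages(library(cardioquant))

seed <- 20260926L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- paced transients at 0.5/1/2 Hz, three groups --")
groups <- list(CTRL = list(amp = 1.6, tau = 180),
               HF = list(amp = 0.9, tau = 320),
               HF_CBD = list(amp = 1.4, tau = 220))
meta <- NULL
for (g in names(groups)) {
  for (hz in c(0.5, 1, 2)) {
    for (cell in 1:4) {
      s <- split_seed(seed, paste("tr", g, hz, cell))
      sim <- simulate_transient_train(seed = s, pacing_hz = hz, n_beats = 8,
                                      amplitude_dff0 = groups[[g]]$amp,
                                      tau_ms = min(groups[[g]]$tau,
                                                   if (hz == 2) 140 else groups[[g]]$tau),
                                      noise_sd = 0.02)
      f <- sprintf("%s/transient_%s_%ghz_c%d.csv", out, g, hz, cell)
      write_trace_csv(sim$trace, f)
      write_ground_truth(sim$truth, paste0(f, ".truth.json"))
      meta <- rbind(meta, data.frame(file = basename(f), cell = sprintf("%s_c%d", g, cell),
                                     group = g, pacing_hz = hz))
    }
  }
}
write.csv(meta, file.path(out, "transient_manifest.csv"), row.names = FALSE)

message("-- shortening trains --")
sh <- simulate_shortening_train(seed = split_seed(seed, "short"),
                                n_beats = 8, noise_sd = 0.02 * 9.6)
write_trace_csv(sh$trace, file.path(out, "shortening_CTRL.csv"))
write_ground_truth(sh$truth, file.path(out, "shortening_CTRL.csv.truth.json"))

message("-- spark line scans --")
ls1 <- simulate_linescan(seed = split_seed(seed, "scan"), spark_rate_per_100um_s = 2,
                         spark_amp_dff0 = 0.8, noise_sd = 100)
img <- ls1$image; img$img <- round(pmax(img$img, 0))
write_linescan_tiff(img, file.path(out, "linescan_HF.tif"))
write_ground_truth(ls1$truth, file.path(out, "linescan_HF.truth.json"))

message("-- mitochondrial assays --")
crc <- simulate_crc_trace(seed = split_seed(seed, "crc"), release_at_pulse = 7,
                          noise_sd = 2)
write_trace_csv(crc$trace, file.path(out, "crc_HF.csv"))
write_ground_truth(crc$truth, file.path(out, "crc_HF.csv.truth.json"))
infl <- simulate_influx_trace(seed = split_seed(seed, "influx"), noise_sd = 5)
write_trace_csv(infl$trace, file.path(out, "influx_CTRL.csv"))
write_ground_truth(infl$truth, file.path(out, "influx_CTRL.csv.truth.json"))
o2 <- simulate_o2_trace(seed = split_seed(seed, "o2"), noise_sd = 20)
write_trace_csv(o2$trace, file.path(out, "respirometry_CTRL.csv"))
write_ground_truth(o2$truth, file.path(out, "respirometry_CTRL.csv.truth.json"))

message("-- pressure-volume recording --")
pv <- simulate_pv_occlusion(seed = split_seed(seed, "pv"), noise_sd_p = 1,
                            noise_sd_v = 0.25)
write_pv_csv(pv$series, file.path(out, "pv_CTRL.csv"))
write_ground_truth(pv$truth, file.path(out, "pv_CTRL.csv.truth.json"))

message("-- histology --")
hf <- simulate_histology(seed = split_seed(seed, "masson"), frac_blue = 0.22,
                         frac_red = 0.68)
write_rgb_png(hf$image, file.path(out, "masson_HF.png"))
write_ground_truth(hf$truth, file.path(out, "masson_HF.truth.json"))
cells <- simulate_histology(seed = split_seed(seed, "he"), width = 600,
                            height = 600,
                            cell_areas_um2 = round(rnorm(25, 400, 40)))
write_rgb_png(cells$image, file.path(out, "he_cells_CTRL.png"))
write_ground_truth(cells$truth, file.path(out, "he_cells_CTRL.truth.json"))
tun <- simulate_tunel(seed = split_seed(seed, "tunel"), frac_positive = 0.12)
write_rgb_png(tun$image, file.path(out, "tunel_HF.png"))
write_ground_truth(tun$truth, file.path(out, "tunel_HF.truth.json"))

message("-- qPCR --")
q <- simulate_qpcr(seed = split_seed(seed, "qpcr"), n_per_group = 8,
                   log2_fold_changes = c(CTRL = 0, HF = 1.5, HF_CBD = 0.4),
                   ct_sd = 0.25)
write.csv(q$table, file.path(out, "qpcr_Nppb.csv"), row.names = FALSE)
write_ground_truth(q$truth, file.path(out, "qpcr_Nppb.truth.json"))

message("done: datasets under ", out)
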