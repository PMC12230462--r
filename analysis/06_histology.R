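#!/usr/bin/env Rscript
# Pixel-based histology: fibrotic index on the Masson-style image, myocyte
# areas on the H&E-style image, TUNEL-positive fraction.

suppressMessages(library(cardioquant))

dat <- "results/data"

masson <- read_rgb_png(file.path(dat, "masson_HF.png"))
fi <- fibrotic_index(classify_colors(masson))
fi_true <- read_ground_truth(file.path(dat, "masson_HF.truth.json"))
message(sprintf("fibrotic index: %.4f (true %.4f); %%blue %.1f, %%red %.1f",
                fi$index, fi_true$fibrotic_index, fi$pct_blue, fi$pct_red))

he <- read_rgb_png(file.path(dat, "he_cells_CTRL.png"))
ar <- cell_areas(he)
ar_true <- read_ground_truth(file.path(dat, "he_cells_CTRL.truth.json"))
message(sprintf("myocyte areas: n = %d (planted %d), mean %.0f um^2 (true mean %.0f); inclusion rule met: %s",
                ar$n_cells, length(ar_true$cell_areas_um2), ar$mean_area,
                mean(ar_true$cell_areas_um2), ar$meets_inclusion))

tun <- read_rgb_png(file.path(dat, "tunel_HF.png"))
pf <- positive_pixel_fraction(tun)
pf_true <- read_ground_truth(file.path(dat, "tunel_HF.truth.json"))
message(sprintf("TUNEL-positive fraction: %.4f (true %.4f) over %d tissue pixels",
                pf$fraction_positive, pf_true$frac_positive, pf$n_tissue))

jsonlite::write_json(list(fibrosis = as.list(fi),
                          areas = list(n_cells = ar$n_cells,
                                       mean_area_um2 = ar$mean_area,
                                       median_area_um2 = ar$median_area),
                          tunel = as.list(pf)),
                     "results/histology.json", auto_unbox = TRUE, digits = NA)
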