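#!/usr/bin/env Rscript
# Mitochondrial assays on the stored traces: CRC with permeability-transition
# detection, uniporter influx rate, and respirometry fluxes.

suppressMessages(library(cardioquant))

dat <- "results/data"

crc_tr <- read_trace_csv(file.path(dat, "crc_HF.csv"), time_unit = "s")
crc <- crc_analysis(crc_tr, protein_mg = 0.25)
crc_true <- read_ground_truth(file.path(dat, "crc_HF.csv.truth.json"))
message(sprintf("CRC: %d pulses tolerated (true %d) = %.0f umol/L per mg at 0.25 mg; mPTP at %s s",
                crc$pulses_tolerated, crc_true$pulses_tolerated,
                crc$cumulative_ca_per_mg,
                ifelse(crc$censored, "censored", format(crc$mptp_time_s))))

infl_tr <- read_trace_csv(file.path(dat, "influx_CTRL.csv"), time_unit = "s")
infl <- influx_rate(infl_tr)
infl_true <- read_ground_truth(file.path(dat, "influx_CTRL.csv.truth.json"))
message(sprintf("influx: %.2f F/s (true %.1f), fit R^2 = %.4f",
                infl$rate, infl_true$initial_rate, infl$r_squared))

o2_tr <- read_trace_csv(file.path(dat, "respirometry_CTRL.csv"), time_unit = "s")
resp <- respirometry(o2_tr, protein_mg = 1)
resp_true <- read_ground_truth(file.path(dat, "respirometry_CTRL.csv.truth.json"))
message(sprintf("respirometry: routine %.1f, state3 %.1f, uncoupled %.1f; RC = %.2f (true %.2f)",
                resp$routine, resp$state3, resp$uncoupled,
                resp$respiratory_control, resp_true$respiratory_control))

jsonlite::write_json(list(crc = as.list(crc), influx = as.list(infl),
                          respirometry = as.list(resp)),
                     "results/mito_assays.json", auto_unbox = TRUE, digits = NA)
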