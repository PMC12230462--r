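# cardioquant

Quantification pipeline for the assay panel used to phenotype experimental
heart failure — and, in treatment studies, to measure how far an
intervention preserves cardiac function. It covers the full chain from
organ to organelle:

* **Cardiomyocyte Ca²⁺ transients and contractility** — per-beat amplitude
  (ΔF/F₀), time to peak, T₅₀%, decay τ from a mono-exponential fit
  `A·exp(−t/τ) + C`; maximal shortening, TTPS and TTHR from cell-length
  traces, across 0.5/1/2 Hz pacing.
* **Ca²⁺ sparks** — two-pass threshold detection (criterion k·SD, default
  3.8) on ΔF/F₀-normalized confocal line scans (0.1 µm pixels); frequency
  in sparks·(100 µm)⁻¹·s⁻¹ and amplitude.
* **Mitochondrial assays** — free-Ca²⁺ calibration
  `[Ca²⁺] = K_d(F−F_min)/(F_max−F)` with K_d = 335 nmol/L (Fluo-4); matrix
  Ca²⁺ content per mg protein from FCCP-release traces; Ca²⁺ retention
  capacity with permeability-transition (mPTP) detection on 10 µmol/L
  pulse trains; uniporter influx rate as |b| of a quadratic fit
  `F(t)=at²+bt+c` to the uptake decay; respirometry fluxes and respiratory
  control (state 3 / routine).
* **Pressure-volume hemodynamics** — cycle detection, SV/EF/CO, and
  ESPVR/EDPVR slopes `P = E·(V−V₀)` from vena-cava-occlusion loop families.
* **Histology** — Masson fibrotic index (%blue/%red pixels), myocyte
  cross-sectional areas, DAB/TUNEL positive-pixel fractions, masked mean
  intensity for ΔΨm images.
* **Expression and statistics** — 2^−ΔΔCt relative expression;
  normalization to control; t-test / one- and two-way ANOVA + Tukey HSD /
  Kruskal-Wallis + Dunn with an automatic normality screen.

Every analyzer has a matching synthetic-data generator with known ground
truth and configurable noise, so the whole pipeline is validated by
parameter recovery — no external data needed. The methods, parameter
choices and limitations are documented in
`vignettes/quantification-methods.Rmd`.

## Worked example

```r
library(cardioquant)

# a paced transient train: 0.5 Hz, amplitude 1.6 dF/F0, tau 180 ms, 2% noise
sim  <- simulate_transient_train(seed = 42, pacing_hz = 0.5, n_beats = 8,
                                 amplitude_dff0 = 1.6, tau_ms = 180,
                                 noise_sd = 0.02)
segs <- segment_beats(sim$trace)
f    <- do.call(rbind, lapply(seq_len(nrow(segs)),
                              function(i) transient_features(segs[i, ], sim$trace)))
head(f[, c("f0", "amplitude", "time_to_peak", "t50_decay", "tau")], 3)
#>      f0 amplitude time_to_peak t50_decay     tau
#> 1 1.000     1.583           49   127.411 179.565
#> 2 1.001     1.585           50   129.054 180.456
#> 3 0.999     1.607           50   124.173 179.120
median(f$tau)        # 179.9 ms  — generator truth is 180 ms
median(f$amplitude)  # 1.588     — truth 1.6; T50 ~ ln(2)*tau as expected

# the calibration equation at its midpoint returns Kd exactly
cal <- calibration(kd = 335, fmax = 900, fmin = 100)
free_calcium(500, cal)
#> [1] 335   # nmol/L
```

Each row is one beat: the baseline F₀ is the pre-stimulus window mean, the
amplitude is the peak ΔF/F₀, and τ comes from the exponential fit of the
decay — at 2% noise the per-beat kinetics land within a few percent of the
generated truth, which is the package's acceptance standard.

## Analysis workflow

`analysis/` holds numbered drivers that run the whole panel on generated
datasets and write tables under `results/`:

```sh
Rscript analysis/01_simulate_datasets.R   # all modalities + ground truth
Rscript analysis/02_ecc_features.R        # transient / shortening features
Rscript analysis/03_sparks.R              # spark events and frequency
Rscript analysis/04_mito_assays.R         # CRC, influx, respirometry
Rscript analysis/05_pvloop.R              # SV/EF/CO, ESPVR/EDPVR
Rscript analysis/06_histology.R           # fibrotic index, areas, TUNEL
Rscript analysis/07_expression_stats.R    # 2^-ddCt + group comparisons
```

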