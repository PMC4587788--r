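#!/usr/bin/env Rscript

## Builds the two standing synthetic datasets used by the analysis scripts:
##  - `binary`: monthly 0/1 survival driven by the logistic month-by-month
##    mortality process with direct + indirect genetic effects, the study
##    conditions scaled down to ~1700 hens / ~430 four-bird cages so every
##    later script runs in minutes;
##  - `linear`: the linear-Gaussian twin generated directly from the
##    random-regression-on-time equation (continuous monthly records, exact
##    day-scale sums), used for parameter-recovery and translation checks.
## True parameters are stored alongside the data (truth.json).

suppressPackageStartupMessages(library(cagesurv))

out_root <- "results/data"
dir.create(out_root, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_sires = 36, dams_per_sire = 8, offspring_per_dam = 6,
                  n_generations = 3, n_batches = 1, rows = 2, levels = 2,
                  seed = 2024)
pop <- generate_population(cfg)
cat(sprintf("population: %d pedigree ids, %d caged hens in %d cages, %d classes\n",
            nrow(pop$ped), nrow(pop$cages), length(unique(pop$cages$cage)),
            length(unique(pop$cages$class))))

## binary dataset under the default study-condition parameters
eff_b <- draw_genetic_effects(pop$ped, logit_genetic_defaults(), seed = 2025)
tab_b <- simulate_mortality(pop, eff_b, cfg, seed = 2026)
cat(sprintf("binary: %.1f%% survived to the 416-day cutoff; %d monthly records\n",
            100 * mean(tab_b$days$censored), nrow(tab_b$monthly)))
write_simdata(pop$ped, pop, tab_b, file.path(out_root, "binary"))

## linear-Gaussian twin with day-scale genetic truth mirroring a commercial
## line: direct SD 28 d, indirect SD 10 d, covariance 57 d^2
cS <- cfg$days_per_month * month_score_sum(cfg$months)
C_day <- matrix(c(784, 57, 57, 100), 2)
eff_l <- draw_genetic_effects(pop$ped, C_day / cS^2, seed = 2027)
tab_l <- simulate_linear(pop, eff_l, cfg, seed = 2028)
cat(sprintf("linear: day-scale phenotypic SD %.1f\n", sd(tab_l$days$days)))
write_simdata(pop$ped, pop, tab_l, file.path(out_root, "linear"))

cat("wrote", file.path(out_root, c("binary", "linear")), "\n")
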