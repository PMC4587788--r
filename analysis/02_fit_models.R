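#!/usr/bin/env Rscript

## Fits the four survival models to the binary dataset: the survival-time
## linear mixed model (animal and sire-dam), the two repeated-measures
## random-regression models (regressions on month t_m and on
## x_m = sqrt(p_m(1-p_m))), and the logit GLMM, each with and (for the
## monthly models) without time-dependent indirect-effect incidence.
## Writes the estimated variance components to results/variance_components.csv.

suppressPackageStartupMessages(library(cagesurv))

d <- read_simdata("results/data/binary")
ped <- d$ped; tab <- d$table

fits <- list()
specs <- list(
  STM_animal   = model_spec("STM"),
  STM_sire_dam = model_spec("STM", parameterization = "sire_dam"),
  RMM.t        = model_spec("RMM.t"),
  RMM.t_td     = model_spec("RMM.t", time_dependent_ige = TRUE),
  RMM.p        = model_spec("RMM.p"),
  GLMM         = model_spec("GLMM")
)

rows <- list()
for (nm in names(specs)) {
  sp <- specs[[nm]]
  b <- build_design(tab, ped, sp)
  f <- if (sp$id == "GLMM") glmm_pql_fit(b) else reml_fit(b)
  fits[[nm]] <- f
  C <- f$components$C
  cat(sprintf("%-12s logL %10.2f  conv %-5s  c_dd %.4g  c_di %.4g  c_ii %.4g\n",
              nm, f$logLik, f$converged, C[1, 1], C[1, 2], C[2, 2]))
  rows[[nm]] <- data.frame(
    model = nm, parameterization = sp$parameterization,
    time_dependent = sp$time_dependent_ige,
    var_direct = C[1, 1], cov_di = C[1, 2], var_indirect = C[2, 2],
    se_direct = unname(f$se["c11"]), se_indirect = unname(f$se["c22"]),
    iid = paste(sprintf("%s=%.4g", names(f$components$iid), f$components$iid),
                collapse = ";"),
    resid = paste(sprintf("%.4g", f$components$resid), collapse = ";"),
    logLik = f$logLik, converged = f$converged)
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/variance_components.csv", row.names = FALSE)
dir.create("scratch", showWarnings = FALSE)
saveRDS(fits, "scratch/fits_binary.rds")  # scratch cache for 03 reuse
cat("wrote results/variance_components.csv\n")

## note: the time-dependent incidence typically inflates the indirect
## variance relative to the static fit -- compare RMM.t vs RMM.t_td above.
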