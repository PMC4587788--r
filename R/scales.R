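## Genetic-parameter algebra on the survival-time (days) scale, and the
## translation of monthly random-regression components and EBV to days.

#' Month covariate and its sum
#'
#' Months are coded `t_m = 1..T` (month of entry = 1), giving zero modelled
#' variance at t = 0 when all hens are still alive. The sum `S = sum(t_m)`
#' (91 for T = 13) is the factor that turns a slope effect into a
#' survival-time effect; it is owned here so that fitting and translation
#' cannot drift apart.
#'
#' @param months number of months T.
#' @return `month_scores`: the vector `1:T`; `month_score_sum`: its sum.
#' @export
month_scores <- function(months = 13) seq_len(months)

#' @rdname month_scores
#' @export
month_score_sum <- function(months = 13) sum(month_scores(months))

#' Total breeding-value variance
#'
#' With each individual interacting with n-1 cage mates, the heritable
#' variance available to selection is
#' `sigma2_AD + 2 (n-1) sigma_ADI + (n-1)^2 sigma2_AI`.
#' A negative result is possible when the direct-indirect covariance is
#' strongly negative and the genetic covariance matrix is not PSD; it is
#' returned with a warning.
#'
#' @param sigma2_ad direct genetic variance.
#' @param sigma_adi direct-indirect genetic covariance.
#' @param sigma2_ai indirect genetic variance.
#' @param n cage size.
#' @return total breeding-value variance.
#' @export
tbv_variance <- function(sigma2_ad, sigma_adi, sigma2_ai, n = 4) {
  out <- sigma2_ad + 2 * (n - 1) * sigma_adi + (n - 1)^2 * sigma2_ai
  if (any(out < 0)) {
    warning("negative total breeding-value variance; check that C is PSD")
  }
  out
}

#' Phenotypic variance from its components
#'
#' `sigma2_AD + (n-1) sigma2_AI + sigma2_cage + sigma2_e`.
#'
#' @inheritParams tbv_variance
#' @param sigma2_cage cage variance.
#' @param sigma2_e residual variance.
#' @return phenotypic variance.
#' @export
phenotypic_variance <- function(sigma2_ad, sigma2_ai, sigma2_cage, sigma2_e, n = 4) {
  if (any(c(sigma2_ad, sigma2_ai, sigma2_cage, sigma2_e) < 0)) {
    stop("variance components must be non-negative")
  }
  sigma2_ad + (n - 1) * sigma2_ai + sigma2_cage + sigma2_e
}

#' Total heritable variance relative to phenotypic variance
#'
#' `T2 = sigma2_TBV / sigma2_P`, the group-analogue of heritability.
#'
#' @param sigma2_tbv total breeding-value variance.
#' @param sigma2_p phenotypic variance.
#' @return T-squared.
#' @export
t_squared <- function(sigma2_tbv, sigma2_p) {
  if (sigma2_p <= 0) stop("phenotypic variance must be positive")
  sigma2_tbv / sigma2_p
}

#' Direct-indirect genetic correlation
#'
#' @param sigma_adi direct-indirect genetic covariance.
#' @param sigma_ad direct genetic standard deviation.
#' @param sigma_ai indirect genetic standard deviation.
#' @return the correlation `sigma_ADI / (sigma_AD sigma_AI)`.
#' @export
genetic_correlation <- function(sigma_adi, sigma_ad, sigma_ai) {
  if (sigma_ad <= 0 || sigma_ai <= 0) stop("genetic SDs must be positive")
  sigma_adi / (sigma_ad * sigma_ai)
}

#' Translation context for monthly-to-days mapping
#'
#' @param days_per_month factor c translating months into days (30.4).
#' @param months number of months T.
#' @param sire_dam_factor variance rescaling from the sire-dam to the animal
#'   scale: 4 under separate sire + dam effects (each carrying a quarter of
#'   the additive variance; the package default), 2 under the combined
#'   one-effect-per-pair convention, 1 if components are already on the
#'   animal scale.
#' @param n cage size.
#' @return list of class `translation_ctx`.
#' @export
translation_ctx <- function(days_per_month = 30.4, months = 13,
                            sire_dam_factor = 4, n = 4) {
  stopifnot(days_per_month > 0, months >= 1, sire_dam_factor %in% c(1, 2, 4))
  structure(list(c = days_per_month, months = months,
                 S = month_score_sum(months),
                 sire_dam_factor = sire_dam_factor, n = n),
            class = "translation_ctx")
}

#' Translate monthly random-regression components to the survival-time scale
#'
#' Survival time is `ST = c * sum_m S_m`, so a random slope on `t_m`
#' contributes `c * S` times its slope effect to ST (`S = sum t_m`), a slope
#' variance maps as `(c S)^2 sigma2_slope`, and an iid per-month variance
#' (cage-month, monthly residuals) maps as `c^2 * sum_m sigma2_m`. Sire-dam
#' genetic variances are first rescaled to the animal scale by
#' `sire_dam_factor`.
#'
#' When the input components come from a sire-dam fit, the permanent
#' environment, residual and cage estimates have absorbed the Mendelian
#' (within-family) genetic variance that the parental effects cannot carry;
#' the day-scale cage and residual components are therefore reduced by those
#' Mendelian shares (half the direct variance plus `(n-1)/2` times the
#' indirect variance for the individual terms; `(n-2)/2` times the indirect
#' variance plus the covariance for the cage term) so that the phenotypic
#' variance assembled from the day-scale parts equals the actual phenotypic
#' variance of ST. With animal-scale input (`sire_dam_factor = 1`) no such
#' adjustment applies.
#'
#' @param components `fit_result$components` of a monthly random-regression
#'   fit on time (genetic `C` on the slope scale, iid variances `cage_month`,
#'   `cage_slope`, `pe`, per-month `resid`).
#' @param ctx a [translation_ctx()].
#' @return list of class `day_scale_params`: `sigma2_ad`, `sigma_adi`,
#'   `sigma2_ai`, `sigma2_cage`, `sigma2_e`, `sigma2_tbv`, `sigma2_p` and the
#'   derived `sigma_ad`, `sigma_ai`, `sigma_tbv`, `sigma_p`, `t2`, `r_a`.
#' @export
translate_rmm_to_days <- function(components, ctx = translation_ctx()) {
  stopifnot(inherits(ctx, "translation_ctx"))
  need <- c("cage_month", "cage_slope", "pe")
  if (!all(need %in% names(components$iid))) {
    stop("components lack the monthly random-regression terms (",
         paste(need, collapse = ", "), "); only a fit on time is translatable")
  }
  if (length(components$resid) != ctx$months) {
    stop("per-month residual variances (length T = ", ctx$months,
         ") required; found ", length(components$resid))
  }
  cS <- ctx$c * ctx$S
  f <- ctx$sire_dam_factor
  n <- ctx$n
  C_day <- f * cS^2 * components$C
  sigma2_ad <- C_day[1, 1]; sigma_adi <- C_day[1, 2]; sigma2_ai <- C_day[2, 2]
  cage_raw <- cS^2 * components$iid[["cage_slope"]] +
    ctx$c^2 * ctx$months * components$iid[["cage_month"]]
  indiv_raw <- cS^2 * components$iid[["pe"]] + ctx$c^2 * sum(components$resid)
  if (f > 1) {
    ## Under either sire-dam convention the modelled parental effects carry
    ## half the additive variance; the Mendelian half surfaces partly as
    ## covariance among cage members (shared mates' Mendelian IGE plus the
    ## own-direct x own-indirect Mendelian cross term) -- absorbed by the
    ## cage terms -- and partly as individual environmental variance.
    mend <- 0.5
    c_extra <- mend * ((n - 2) * sigma2_ai + 2 * sigma_adi)
    v_extra <- mend * (sigma2_ad + (n - 1) * sigma2_ai)
    cage <- cage_raw - c_extra
    e <- indiv_raw - (v_extra - c_extra)
  } else {
    cage <- cage_raw
    e <- indiv_raw
  }
  if (cage < 0 || e < 0) {
    warning("Mendelian adjustment drove a day-scale component negative; ",
            "reporting the floored value")
    cage <- max(cage, 0); e <- max(e, 0)
  }
  day_scale_params(sigma2_ad, sigma_adi, sigma2_ai, cage, e, n)
}

## assemble the derived day-scale parameter set, tolerating degenerate zeros
day_scale_params <- function(sigma2_ad, sigma_adi, sigma2_ai, cage, e, n) {
  sigma2_tbv <- tbv_variance(sigma2_ad, sigma_adi, sigma2_ai, n)
  sigma2_p <- phenotypic_variance(sigma2_ad, sigma2_ai, cage, e, n)
  structure(list(
    sigma2_ad = sigma2_ad, sigma_adi = sigma_adi, sigma2_ai = sigma2_ai,
    sigma2_cage = cage, sigma2_e = e,
    sigma2_tbv = sigma2_tbv, sigma2_p = sigma2_p,
    sigma_ad = sqrt(sigma2_ad), sigma_ai = sqrt(sigma2_ai),
    sigma_tbv = sqrt(max(sigma2_tbv, 0)), sigma_p = sqrt(sigma2_p),
    t2 = if (sigma2_p > 0) t_squared(sigma2_tbv, sigma2_p) else 0,
    r_a = if (sigma2_ad > 0 && sigma2_ai > 0) {
      genetic_correlation(sigma_adi, sqrt(sigma2_ad), sqrt(sigma2_ai))
    } else 0),
    class = "day_scale_params")
}

#' @export
print.day_scale_params <- function(x, ...) {
  cat(sprintf("day-scale genetic parameters:\n"))
  cat(sprintf("  sigma_AD  %7.2f   sigma_AI %7.2f   sigma_ADI %9.2f\n",
              x$sigma_ad, x$sigma_ai, x$sigma_adi))
  cat(sprintf("  sigma_TBV %7.2f   sigma_P  %7.2f   T2 %5.3f   r_A %6.3f\n",
              x$sigma_tbv, x$sigma_p, x$t2, x$r_a))
  invisible(x)
}

#' Translate monthly slope EBV to the survival-time scale
#'
#' `EBV_days = c * S * EBV_slope`, separately for the direct and the indirect
#' effect. Only fits with a genetic regression on time are translatable; the
#' corresponding mapping for a regression on `x_m` or for the logit model
#' involves intractable integrals and is deliberately refused.
#'
#' @param fit a `fit_result` for a `RMM.t` bundle.
#' @param ids individuals (default all phenotyped).
#' @param ctx a [translation_ctx()].
#' @return data.frame `id`, `ebv_d`, `ebv_i` in days (ranking is preserved
#'   exactly: the map is a positive scalar).
#' @export
translate_ebv_to_days <- function(fit, ids = NULL, ctx = translation_ctx()) {
  model <- fit$bundle$spec$id
  if (!identical(model, "RMM.t")) {
    stop("day-scale EBV translation is only defined for RMM.t fits, not ",
         model)
  }
  ebv <- extract_ebv(fit, ids = ids)
  ebv$ebv_d <- ctx$c * ctx$S * ebv$ebv_d
  ebv$ebv_i <- ctx$c * ctx$S * ebv$ebv_i
  ebv
}

#' Day-scale parameter summary of a survival-time (STM) fit
#'
#' Assembles the same `day_scale_params` row set directly from an STM fit
#' (rescaling sire-dam genetic components to the animal scale and removing
#' the corresponding Mendelian shares from cage and residual, as in
#' [translate_rmm_to_days()]).
#'
#' @param fit a `fit_result` for an STM bundle.
#' @param ctx a [translation_ctx()] (`c`, `S` unused; `sire_dam_factor`, `n`
#'   apply).
#' @return a `day_scale_params` list.
#' @export
stm_day_params <- function(fit, ctx = translation_ctx(
                             sire_dam_factor = if (fit$bundle$spec$parameterization == "animal") 1 else 4)) {
  stopifnot(identical(fit$bundle$spec$id, "STM"))
  f <- ctx$sire_dam_factor
  n <- ctx$n
  C_day <- f * fit$components$C
  sigma2_ad <- C_day[1, 1]; sigma_adi <- C_day[1, 2]; sigma2_ai <- C_day[2, 2]
  cage_raw <- fit$components$iid[["cage"]]
  e_raw <- fit$components$resid[1]
  if (f > 1) {
    mend <- 0.5  # Mendelian half not carried by the parental effects
    c_extra <- mend * ((n - 2) * sigma2_ai + 2 * sigma_adi)
    v_extra <- mend * (sigma2_ad + (n - 1) * sigma2_ai)
    cage <- cage_raw - c_extra
    e <- e_raw - (v_extra - c_extra)
  } else {
    cage <- cage_raw; e <- e_raw
  }
  cage <- max(cage, 0); e <- max(e, 0)
  day_scale_params(sigma2_ad, sigma_adi, sigma2_ai, cage, e, n)
}

#' Starting values for the monthly time-regression model from a day-scale fit
#'
#' Maps the components of a fitted survival-time model back to the monthly
#' slope scale by inverting the day-scale translation: genetic covariance
#' `C / (cS)^2`, the cage variance split evenly between the cage slope
#' (`/(cS)^2`) and the cage-month term (`/(c^2 T)`), and the residual split
#' 85/15 between the per-month residuals (`/(c^2 T)`) and the
#' permanent-environment slope. Warm-starting the monthly REML this way
#' roughly halves its iteration count.
#'
#' @param stm_fit a `fit_result` for an STM bundle in the same
#'   parameterization the monthly model will use.
#' @param ctx a [translation_ctx()].
#' @return list (`C`, `iid`, `resid`) usable as `start` in [reml_fit()].
#' @export
rmm_start_from_stm <- function(stm_fit, ctx = translation_ctx()) {
  stopifnot(identical(stm_fit$bundle$spec$id, "STM"))
  cS2 <- (ctx$c * ctx$S)^2
  cT2 <- ctx$c^2 * ctx$months
  cage <- max(stm_fit$components$iid[["cage"]], 1e-6)
  res <- max(stm_fit$components$resid[1], 1e-6)
  list(C = stm_fit$components$C / cS2,
       iid = c(cage_month = 0.5 * cage / cT2,
               cage_slope = 0.5 * cage / cS2,
               pe = 0.15 * res / cS2),
       resid = rep(0.85 * res / cT2, ctx$months))
}
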