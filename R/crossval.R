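#' Cage-level cross-validation folds
#'
#' Randomly assigns whole cages to `k` mutually exclusive folds of roughly
#' equal size (all members of a cage share a fold). The plan is redrawn
#' (bounded retries) until every fixed-effect class is represented in every
#' training set, i.e. no class has all of its cages inside one fold.
#'
#' @param cages data.frame with columns `cage` and `class` (one row per cage;
#'   duplicated cage rows are collapsed).
#' @param k number of folds.
#' @param seed integer seed.
#' @param max_tries redraw attempts before giving up.
#' @return data.frame `cage`, `class`, `fold`.
#' @export
make_folds <- function(cages, k = 5, seed = 1, max_tries = 100) {
  cages <- unique(cages[, c("cage", "class")])
  nc <- nrow(cages)
  if (nc < k) stop("need at least ", k, " cages for ", k, " folds")
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    fold <- sample(rep_len(seq_len(k), nc))
    ok <- TRUE
    for (f in seq_len(k)) {
      train_classes <- unique(cages$class[fold != f])
      missing <- setdiff(unique(cages$class), train_classes)
      if (length(missing)) {
        ok <- FALSE
        bad <- missing[1]
        break
      }
    }
    if (ok) {
      return(data.frame(cage = cages$cage, class = cages$class, fold = fold,
                        stringsAsFactors = FALSE))
    }
  }
  stop("could not build folds with class '", bad,
       "' represented in every training set")
}

#' Fixed-effect-adjusted observed phenotypes
#'
#' Ordinary least squares of observed survival days on the fixed-effect
#' classes, fitted on uncensored records only; the residual is the adjusted
#' phenotype. Censored records never receive an adjusted phenotype (they are
#' handled by the tied-rank rule in [rank_with_censoring()]).
#'
#' @param days day-scale view (`survival_table$days`): columns `id`, `class`,
#'   `days`, `censored`.
#' @return data.frame `id`, `adjusted` for the uncensored individuals.
#' @export
adjust_observed <- function(days) {
  unc <- days[!days$censored, , drop = FALSE]
  if (!nrow(unc)) stop("no uncensored records to adjust")
  fit <- stats::lm(days ~ 0 + factor(class), data = unc)
  data.frame(id = unc$id, adjusted = unname(stats::residuals(fit)),
             stringsAsFactors = FALSE)
}

#' Censoring-aware observed ranks
#'
#' Uncensored individuals are ranked ascending by adjusted phenotype (ties
#' get average ranks). All censored individuals are placed above every
#' uncensored one and share the average of the ranks they jointly occupy --
#' the assumption being that they died in random order after surviving to the
#' study cutoff. With 5 censored among 10, each censored individual gets
#' (6+7+8+9+10)/5 = 8.
#'
#' @param ids all individual ids.
#' @param adjusted named or parallel numeric vector of adjusted phenotypes
#'   (`NA` for censored individuals).
#' @param censored logical vector parallel to `ids`.
#' @return numeric vector of ranks parallel to `ids`.
#' @export
rank_with_censoring <- function(ids, adjusted, censored) {
  stopifnot(length(ids) == length(adjusted), length(ids) == length(censored))
  n <- length(ids)
  n_c <- sum(censored)
  out <- numeric(n)
  if (n_c < n) {
    out[!censored] <- rank(adjusted[!censored], ties.method = "average")
  }
  if (n_c > 0) {
    out[censored] <- (n - n_c) + (n_c + 1) / 2  # mean of the top n_c ranks
  }
  out
}

#' Predicted phenotypes from breeding values
#'
#' The predicted phenotype of individual i combines its own estimated direct
#' effect with the estimated indirect effects of the n-1 cage mates present
#' at the start of the experiment: `P_i = EBV_D(i) + sum_j EBV_I(j)`.
#'
#' @param ebv data.frame from [extract_ebv()] covering all ids involved.
#' @param ids focal individuals.
#' @param mates character vector parallel to `ids` of comma-separated
#'   start-of-experiment cage-mate ids.
#' @return numeric vector of predicted phenotypes (model scale).
#' @export
predict_phenotypes <- function(ebv, ids, mates) {
  ed <- stats::setNames(ebv$ebv_d, ebv$id)
  ei <- stats::setNames(ebv$ebv_i, ebv$id)
  ml <- strsplit(mates, ",", fixed = TRUE)
  vapply(seq_along(ids), function(i) {
    m <- ml[[i]]
    unname(ed[[ids[i]]]) + sum(ei[m])
  }, numeric(1))
}

#' Fold-stratified rank correlation
#'
#' Ranks are computed within each validation fold; the pooled correlation is
#' the Pearson correlation of the fold-mean-centred observed and predicted
#' ranks (the fixed-fold-effect analogue of a bivariate analysis of ranks
#' with a subset effect). The standard error comes from a leave-one-fold-out
#' jackknife.
#'
#' @param pairs data.frame with columns `fold`, `obs_rank`, `pred_rank`.
#' @return list: `correlation`, `se`, `per_fold` (named per-fold Spearman
#'   correlations), `n`.
#' @export
rank_correlation <- function(pairs) {
  stopifnot(all(c("fold", "obs_rank", "pred_rank") %in% names(pairs)))
  folds <- unique(pairs$fold)
  if (length(folds) < 2) stop("need at least 2 folds")
  sizes <- table(pairs$fold)
  if (any(sizes < 3)) stop("each fold needs at least 3 pairs")
  centre <- function(d) {
    d$o <- d$obs_rank - stats::ave(d$obs_rank, d$fold)
    d$p <- d$pred_rank - stats::ave(d$pred_rank, d$fold)
    d
  }
  pooled <- function(d) {
    d <- centre(d)
    if (stats::sd(d$o) == 0 || stats::sd(d$p) == 0) {
      stop("zero variance in ranks within every fold")
    }
    stats::cor(d$o, d$p)
  }
  r <- pooled(pairs)
  loo <- vapply(folds, function(f) pooled(pairs[pairs$fold != f, ]), numeric(1))
  g <- length(folds)
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  per_fold <- vapply(folds, function(f) {
    d <- pairs[pairs$fold == f, ]
    stats::cor(d$obs_rank, d$pred_rank)
  }, numeric(1))
  list(correlation = r, se = se,
       per_fold = stats::setNames(per_fold, paste0("fold", folds)),
       n = nrow(pairs))
}

#' Upper bound of the rank correlation
#'
#' The expected rank correlation if breeding values were estimated with
#' accuracy 1: the square root of the genetic share of phenotypic variance,
#' `sqrt((sigma2_AD + (n-1) sigma2_AI) / sigma2_P)`, all on the survival-time
#' (days) scale.
#'
#' @param sigma2_ad direct genetic variance.
#' @param sigma2_ai indirect genetic variance.
#' @param sigma2_p phenotypic variance.
#' @param n cage size.
#' @return the upper bound (scalar).
#' @export
sqrt_r2 <- function(sigma2_ad, sigma2_ai, sigma2_p, n = 4) {
  if (sigma2_p <= 0) stop("phenotypic variance must be positive")
  sqrt((sigma2_ad + (n - 1) * sigma2_ai) / sigma2_p)
}

#' Approximate accuracy of estimated breeding values
#'
#' The observed-vs-predicted rank correlation divided by its upper bound
#' [sqrt_r2()].
#'
#' @param correlation rank correlation between observed and predicted
#'   phenotypes.
#' @param upper_bound value of [sqrt_r2()].
#' @return approximate accuracy.
#' @export
approx_accuracy <- function(correlation, upper_bound) {
  if (!is.finite(upper_bound) || upper_bound <= 0) {
    stop("upper bound must be positive")
  }
  correlation / upper_bound
}

## PQL BLUP at fixed variance components (used for per-fold prediction)
glmm_blup <- function(bundle, components, maxit = 30L, tol = 1e-6) {
  y <- as.numeric(bundle$y)
  eta <- stats::qlogis(pmin(pmax((y + 0.5) / 2, 0.3), 0.7))
  sol <- NULL
  for (it in seq_len(maxit)) {
    p <- pmin(pmax(stats::plogis(eta), 1e-6), 1 - 1e-6)
    wgt <- p * (1 - p)
    wb <- bundle
    wb$y <- eta + (y - p) / wgt
    wb$resid <- list(type = "binomial", weights = wgt)
    sol <- solve_blup(wb, components)
    s <- sol$solutions
    eta_new <- as.numeric(cbind(wb$X, wb$Zd, wb$Zi) %*% c(s$fixed, s$u_d, s$u_i))
    for (k in seq_along(s$iid)) {
      tm <- bundle$terms[[k]]
      eta_new <- eta_new + s$iid[[k]][as.integer(tm$level)] * tm$cov
    }
    delta <- max(abs(eta_new - eta))
    eta <- eta_new
    if (delta < tol) break
  }
  sol$eta <- eta
  sol
}

#' Run the full cross-validation for one model
#'
#' Estimates variance components once on the complete data (unless supplied),
#' then for each of `k` cage-level folds removes the validation cages'
#' phenotypes, re-solves the mixed-model equations on the training records,
#' predicts the validation individuals' phenotypes from their own estimated
#' direct effect plus the estimated indirect effects of their
#' start-of-experiment cage mates, and correlates censoring-aware observed
#' ranks with predicted ranks across folds.
#'
#' @param table the `survival_table` used for fitting.
#' @param ped the [pedigree()].
#' @param spec a [model_spec()].
#' @param k number of folds.
#' @param seed fold seed.
#' @param components optional variance components (skips the full-data REML).
#' @param observed_table table supplying the observed-phenotype side
#'   (defaults to `table`; the mid-period censoring robustness experiment
#'   passes the uncorrupted table here while fitting on the censored one).
#' @param genetic_ctx optional relationship context (see [build_design()]);
#'   built once from the full data when absent and reused for every fold.
#' @param control passed to the fitting routines.
#' @return list: `correlation`, `se`, `per_fold`, `pairs`, `components`,
#'   `folds`.
#' @export
run_crossval <- function(table, ped, spec, k = 5, seed = 1, components = NULL,
                         observed_table = table, genetic_ctx = NULL,
                         control = list()) {
  stopifnot(inherits(table, "survival_table"), inherits(spec, "model_spec"))
  if (is.null(components) || is.null(genetic_ctx)) {
    bundle_full <- build_design(table, ped, spec, genetic_ctx = genetic_ctx)
    genetic_ctx <- bundle_full$genetic
    if (is.null(components)) {
      fit_full <- if (spec$id == "GLMM") {
        glmm_pql_fit(bundle_full, control = control)
      } else {
        reml_fit(bundle_full, control = control)
      }
      components <- fit_full$components
    }
  }
  folds <- make_folds(table$days[, c("cage", "class")], k = k, seed = seed)
  fold_of <- stats::setNames(folds$fold, folds$cage)

  adj <- adjust_observed(observed_table$days)
  adj_of <- stats::setNames(adj$adjusted, adj$id)
  obs_days <- observed_table$days

  ## start-of-experiment cage mates (month-1 sets where available)
  if (!is.null(table$monthly) && any(table$monthly$month == 1L)) {
    m1 <- table$monthly[table$monthly$month == 1L, c("id", "mates")]
    mates_of <- stats::setNames(m1$mates, m1$id)
  } else {
    stop("survival table lacks month-1 mate bookkeeping")
  }

  pair_list <- vector("list", k)
  for (f in seq_len(k)) {
    val_cages <- folds$cage[folds$fold == f]
    val_ids <- table$days$id[table$days$cage %in% val_cages]
    tr <- table
    tr$monthly <- tr$monthly[!(tr$monthly$cage %in% val_cages), , drop = FALSE]
    tr$days <- tr$days[!(tr$days$cage %in% val_cages), , drop = FALSE]
    bundle_tr <- build_design(tr, ped, spec, genetic_ctx = genetic_ctx)
    sol <- if (spec$id == "GLMM") {
      glmm_blup(bundle_tr, components)
    } else {
      solve_blup(bundle_tr, components)
    }
    pseudo <- structure(list(bundle = bundle_tr, solutions = sol$solutions),
                        class = "fit_result")
    all_needed <- unique(c(val_ids, unlist_mates(mates_of[val_ids])))
    ebv <- extract_ebv(pseudo, ids = all_needed, ped = ped)
    pred <- predict_phenotypes(ebv, val_ids, unname(mates_of[val_ids]))
    cens <- obs_days$censored[match(val_ids, obs_days$id)]
    obs_rank <- rank_with_censoring(val_ids, unname(adj_of[val_ids]), cens)
    pair_list[[f]] <- data.frame(
      id = val_ids, fold = f,
      obs_rank = obs_rank,
      pred_rank = rank(pred, ties.method = "average"),
      censored = cens, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_list)
  rc <- rank_correlation(pairs)
  c(rc, list(pairs = pairs, components = components, folds = folds))
}
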