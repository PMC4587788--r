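#' Model specification for the four survival models
#'
#' Declarative description of one of the four direct-indirect genetic effect
#' (DGE-IGE) models:
#' * `STM`    - linear mixed model for survival days; genetic intercepts,
#'              random cage intercept, single residual variance.
#' * `RMM.t`  - repeated-measures model for monthly 0/1 survival with random
#'              genetic / cage / permanent-environment regressions on time
#'              `t_m` (no genetic intercepts), an iid cage-month effect, and a
#'              separate residual variance per month.
#' * `RMM.p`  - as `RMM.t` but the regressions are on
#'              `x_m = sqrt(p_m (1 - p_m))` per fixed-effect class, so fitted
#'              variances track the binomial variance profile.
#' * `GLMM`   - logit model for monthly 0/1 survival; genetic / cage-month /
#'              permanent-environment intercepts only, binomial residual.
#'
#' @param id one of `"STM"`, `"RMM.t"`, `"RMM.p"`, `"GLMM"`.
#' @param parameterization `"animal"` (genetic effect attached to the
#'   phenotyped individual) or `"sire_dam"` (attached to its parents; the
#'   package default for the monthly models, which avoids the extreme-category
#'   problem with binary data). Defaults: animal for STM, sire-dam otherwise.
#' @param time_dependent_ige if `TRUE`, the indirect-effect incidence for each
#'   monthly record only includes cage mates alive at the start of that month
#'   (after the focal's death the composition is frozen at its death-time
#'   set). Only meaningful for the monthly models.
#' @param coding response coding: `"days"` (STM), `"survival"` (0/1 kept for
#'   every month, 0 after death) or `"hazard"` (0/1/missing: records after the
#'   death month removed).
#' @param sire_dam_combined fit one combined effect per sire-dam pair instead
#'   of separate sire and dam effects (changes the sire-dam to animal variance
#'   factor from 4 to 2).
#' @param poly_degree degree of the fixed class-specific polynomial of time
#'   for the monthly models (capped at T-1).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(id = c("STM", "RMM.t", "RMM.p", "GLMM"),
                       parameterization = NULL,
                       time_dependent_ige = FALSE,
                       coding = NULL,
                       sire_dam_combined = FALSE,
                       poly_degree = 6) {
  id <- match.arg(id)
  if (is.null(parameterization)) {
    parameterization <- if (id == "STM") "animal" else "sire_dam"
  }
  parameterization <- match.arg(parameterization, c("animal", "sire_dam"))
  if (is.null(coding)) coding <- if (id == "STM") "days" else "survival"
  coding <- match.arg(coding, c("days", "survival", "hazard"))
  if (id == "STM" && coding != "days") {
    stop("STM analyses survival days")
  }
  if (id != "STM" && coding == "days") {
    stop(id, " analyses monthly 0/1 records")
  }
  if (id == "STM" && time_dependent_ige) {
    stop("STM has no time axis; time-dependent IGE needs a monthly model")
  }
  structure(list(id = id, parameterization = parameterization,
                 time_dependent_ige = time_dependent_ige, coding = coding,
                 sire_dam_combined = sire_dam_combined,
                 poly_degree = poly_degree),
            class = "model_spec")
}

#' Recode monthly survival records to hazard (0/1/missing) coding
#'
#' Records for months strictly after an individual's death month are removed;
#' the death month keeps its 0. Survivor strings are unchanged.
#'
#' @param table a `survival_table` in survival-function coding.
#' @return the table with post-death rows dropped and `coding = "hazard"`.
#' @export
recode_hazard <- function(table) {
  stopifnot(inherits(table, "survival_table"))
  if (identical(table$coding, "hazard")) return(table)
  stopifnot(identical(table$coding, "survival"))
  mo <- table$monthly
  ## death month per id = first month with value 0 (if any)
  dead <- mo$value == 0
  first0 <- stats::aggregate(month ~ id, data = mo[dead, , drop = FALSE], FUN = min)
  dm <- stats::setNames(first0$month, first0$id)
  lim <- dm[mo$id]
  keep <- is.na(lim) | mo$month <= lim
  table$monthly <- mo[keep, , drop = FALSE]
  table$coding <- "hazard"
  table
}

#' Class-by-month mean survival and the x_m covariate
#'
#' `p_m` is the mean of the monthly 0/1 records in each fixed-effect class at
#' month m; `x_m = sqrt(p_m (1 - p_m))`. Degenerate cells (all 0 or all 1) are
#' floored/capped at `1/(2 N)` for a cell of N records so that `x_m` never
#' collapses to zero.
#'
#' @param table a `survival_table` with monthly 0/1 records.
#' @return data.frame with columns `class`, `month`, `n`, `p`, `x`.
#' @export
compute_xm <- function(table) {
  stopifnot(inherits(table, "survival_table"))
  mo <- table$monthly
  if (!all(mo$value %in% c(0, 1))) stop("compute_xm needs 0/1 records")
  agg <- stats::aggregate(value ~ class + month, data = mo,
                          FUN = function(z) c(mean(z), length(z)))
  out <- data.frame(class = agg$class, month = agg$month,
                    p = agg$value[, 1], n = agg$value[, 2],
                    stringsAsFactors = FALSE)
  if (any(out$n == 0)) stop("empty class-month cell")
  lo <- 1 / (2 * out$n)
  out$p <- pmin(pmax(out$p, lo), 1 - lo)
  out$x <- sqrt(out$p * (1 - out$p))
  out[order(out$class, out$month), c("class", "month", "n", "p", "x")]
}

## Ancestor-pruned pedigree: phenotyped ids plus all their ancestors.
prune_pedigree <- function(ped, ids) {
  keep <- logical(nrow(ped))
  keep[match(ids, ped$id)] <- TRUE
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  for (i in rev(seq_len(nrow(ped)))) {  # parents precede offspring
    if (keep[i]) {
      if (si[i] > 0L) keep[si[i]] <- TRUE
      if (di[i] > 0L) keep[di[i]] <- TRUE
    }
  }
  pedigree(ped$id[keep], ped$sire[keep], ped$dam[keep],
           generation = ped$generation[keep], sex = ped$sex[keep])
}

#' Direct genetic effect incidence
#'
#' One row per record. Animal parameterization: a single 1 in the focal
#' individual's column. Sire-dam: a 1 in the focal's sire column and a 1 in
#' its dam column (row sums 2).
#'
#' @param focal_ids character vector, one focal id per record row.
#' @param ped the [pedigree()] covering all focal ids.
#' @param parameterization `"animal"` or `"sire_dam"`.
#' @param levels column (effect-level) ids; defaults to all pedigree ids
#'   (animal) or all ids appearing as a parent of a focal id (sire-dam).
#' @return `Matrix::dgCMatrix` rows x levels, with `levels` as colnames.
#' @export
build_dge_incidence <- function(focal_ids, ped, parameterization = "animal",
                                levels = NULL) {
  miss <- setdiff(unique(focal_ids), ped$id)
  if (length(miss)) stop("focal id(s) missing from pedigree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  n <- length(focal_ids)
  if (parameterization == "animal") {
    if (is.null(levels)) levels <- ped$id
    j <- match(focal_ids, levels)
    if (anyNA(j)) stop("focal id(s) not in effect levels")
    Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1, dims = c(n, length(levels)),
                         dimnames = list(NULL, levels))
  } else {
    pidx <- match(focal_ids, ped$id)
    s <- ped$sire[pidx]; d <- ped$dam[pidx]
    if (anyNA(s) || anyNA(d)) {
      stop("sire-dam parameterization requires both parents known for all focal ids")
    }
    if (is.null(levels)) levels <- sort(unique(c(s, d)))
    js <- match(s, levels); jd <- match(d, levels)
    if (anyNA(js) || anyNA(jd)) stop("parent id(s) not in effect levels")
    Matrix::sparseMatrix(i = rep(seq_len(n), 2L), j = c(js, jd), x = 1,
                         dims = c(n, length(levels)),
                         dimnames = list(NULL, levels))
  }
}

#' Indirect genetic effect incidence
#'
#' Coefficients over the cage mates contributing to each record row: the
#' static version uses the n-1 mates present at the start of the experiment;
#' the time-dependent version uses the alive-at-month-start sets carried by
#' the survival table (already frozen at the focal's death-time composition
#' for post-death rows). In the sire-dam parameterization coefficients
#' accumulate on shared parents (two mates sharing a sire put a 2 in that
#' sire's column).
#'
#' @param mates character vector of comma-separated mate ids, one per row
#'   (from `survival_table$monthly$mates` or built from the cage layout).
#' @inheritParams build_dge_incidence
#' @return `Matrix::dgCMatrix` rows x levels.
#' @export
build_ige_incidence <- function(mates, ped, parameterization = "animal",
                                levels = NULL) {
  ml <- strsplit(mates, ",", fixed = TRUE)
  nm <- lengths(ml)
  if (any(nm == 0 & !nzchar(mates))) nm[!nzchar(mates)] <- 0L
  rows <- rep(seq_along(ml), nm)
  mate_ids <- unlist(ml, use.names = FALSE)
  miss <- setdiff(unique(mate_ids), ped$id)
  if (length(miss)) stop("mate id(s) missing from pedigree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  if (parameterization == "animal") {
    if (is.null(levels)) levels <- ped$id
    j <- match(mate_ids, levels)
    Matrix::sparseMatrix(i = rows, j = j, x = 1,
                         dims = c(length(ml), length(levels)),
                         dimnames = list(NULL, levels))
  } else {
    pidx <- match(mate_ids, ped$id)
    s <- ped$sire[pidx]; d <- ped$dam[pidx]
    if (anyNA(s) || anyNA(d)) {
      stop("sire-dam parameterization requires both parents known for all cage mates")
    }
    if (is.null(levels)) levels <- sort(unique(c(s, d)))
    j <- c(match(s, levels), match(d, levels))
    Matrix::sparseMatrix(i = rep(rows, 2L), j = j, x = 1,
                         dims = c(length(ml), length(levels)),
                         dimnames = list(NULL, levels))
  }
}

#' Fixed-effect design matrix
#'
#' STM: one column per fixed-effect class (cell-means coding, no global
#' intercept). Monthly models: class-specific orthogonal polynomial curves of
#' month up to `poly_degree` (capped at T-1), i.e. `(degree+1)` columns per
#' class including the class intercept. Orthogonal rather than raw powers for
#' conditioning; the fitted curves are identical.
#'
#' @param class character vector of class labels, one per row.
#' @param month integer months (ignored for STM).
#' @param model_id model identifier (see [model_spec()]).
#' @param months total number of months T.
#' @param poly_degree polynomial degree for the monthly models.
#' @return sparse design matrix with named columns.
#' @export
build_fixed_design <- function(class, month = NULL, model_id = "STM",
                               months = 13, poly_degree = 6) {
  clf <- factor(class)
  n <- length(class)
  if (model_id == "STM") {
    X <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(clf), x = 1,
                              dims = c(n, nlevels(clf)),
                              dimnames = list(NULL, paste0("class", levels(clf))))
    return(X)
  }
  deg <- min(poly_degree, months - 1L)
  basis <- cbind(1, if (deg > 0) stats::poly(seq_len(months), degree = deg))
  colnames(basis) <- paste0("t", 0:deg)
  B <- basis[month, , drop = FALSE]
  blocks <- lapply(seq_len(nlevels(clf)), function(k) {
    Bk <- B * (as.integer(clf) == k)
    colnames(Bk) <- paste0("class", levels(clf)[k], ".", colnames(basis))
    Bk
  })
  Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE)
}

#' Assemble the design bundle for a model
#'
#' Turns a `survival_table`, a pedigree and a [model_spec()] into the numeric
#' objects the mixed-model engine consumes: response, fixed design, genetic
#' direct/indirect incidences (with the random-regression covariate baked into
#' the entries), descriptors for the iid random terms, the residual structure,
#' and the relationship-matrix context for the genetic pair.
#'
#' @param table a `survival_table`.
#' @param ped the [pedigree()].
#' @param spec a [model_spec()].
#' @param genetic_ctx optional relationship-matrix context (`$genetic` of a
#'   previously built bundle for the same pedigree and parameterization).
#'   Reusing it skips rebuilding A / A-inverse — worthwhile when the same
#'   data are re-designed repeatedly, e.g. across cross-validation folds.
#'   Effect levels spanning a superset of the current records are valid:
#'   levels without data are simply predicted through the relationship
#'   matrix.
#' @return list of class `design_bundle`.
#' @export
build_design <- function(table, ped, spec, genetic_ctx = NULL) {
  stopifnot(inherits(table, "survival_table"), inherits(spec, "model_spec"))
  if (spec$coding == "hazard") table <- recode_hazard(table)

  if (spec$id == "STM") {
    rows <- table$days
    y <- rows$days
    month <- rep(1L, nrow(rows))
    cov_rand <- rep(1, nrow(rows))
    ## static start-of-experiment mates from the month-1 sets
    m1 <- table$monthly[table$monthly$month == 1L, c("id", "mates")]
    mates <- m1$mates[match(rows$id, m1$id)]
    if (anyNA(mates)) {
      stop("day-scale rows without month-1 mate bookkeeping")
    }
  } else {
    rows <- table$monthly
    y <- rows$value
    month <- rows$month
    if (spec$time_dependent_ige) {
      mates <- rows$mates
    } else {
      m1 <- table$monthly[table$monthly$month == 1L, c("id", "mates")]
      mates <- m1$mates[match(rows$id, m1$id)]
    }
    cov_rand <- switch(spec$id,
      "RMM.t" = as.numeric(month),
      "RMM.p" = {
        xm <- compute_xm(table)
        key <- paste(rows$class, month)
        xm$x[match(key, paste(xm$class, xm$month))]
      },
      "GLMM" = rep(1, nrow(rows)))
  }

  ## genetic levels and relationship context
  if (!is.null(genetic_ctx)) {
    want_type <- if (spec$parameterization == "animal") "animal" else "sire_dam"
    if (!identical(genetic_ctx$type, want_type)) {
      stop("genetic_ctx parameterization does not match the model spec")
    }
    if (isTRUE(spec$sire_dam_combined) != isTRUE(genetic_ctx$combined)) {
      stop("genetic_ctx combined-pair convention does not match the model spec")
    }
    pruned <- genetic_ctx$ped
    glevels <- genetic_ctx$levels
    need <- unique(c(rows$id, unlist_mates(mates)))
    if (!all(need %in% pruned$id)) {
      stop("genetic_ctx pedigree does not cover all record ids")
    }
    Actx <- genetic_ctx
    Zd0 <- build_dge_incidence(rows$id, pruned, spec$parameterization, levels = glevels)
    Zi0 <- build_ige_incidence(mates, pruned, spec$parameterization, levels = glevels)
    Zd <- Zd0 * cov_rand
    Zi <- Zi0 * cov_rand
    return(assemble_bundle(table, spec, rows, y, month, cov_rand,
                           Actx, glevels, Zd, Zi))
  }
  pruned <- prune_pedigree(ped, unique(c(rows$id, unlist_mates(mates))))
  if (spec$parameterization == "animal") {
    glevels <- pruned$id
    Ainv <- build_A_inverse(pruned)
    Actx <- list(type = "animal", Ainv = Ainv, A = NULL, ped = pruned,
                 levels = glevels)
  } else {
    focal_all <- unique(c(rows$id, unlist_mates(mates)))
    pr_idx <- match(focal_all, pruned$id)
    parents <- sort(unique(c(pruned$sire[pr_idx], pruned$dam[pr_idx])))
    parents <- parents[!is.na(parents)]
    ## marginal A among parents, exact from the ancestor-pruned pedigree
    anc <- prune_pedigree(pruned, parents)
    Afull <- build_A(anc)
    Ap <- as.matrix(Afull[parents, parents])
    Actx <- list(type = "sire_dam", A = Ap,
                 Ainv = solve(Ap), ped = pruned,
                 combined = isTRUE(spec$sire_dam_combined),
                 levels = parents)
    glevels <- parents
  }
  Zd0 <- build_dge_incidence(rows$id, pruned, spec$parameterization, levels = glevels)
  Zi0 <- build_ige_incidence(mates, pruned, spec$parameterization, levels = glevels)
  if (spec$parameterization == "sire_dam" && isTRUE(spec$sire_dam_combined)) {
    ## one effect per sire-dam pair: map parent columns to pair columns
    comb <- combine_sire_dam(pruned, rows$id, mates, glevels, Actx$A)
    Zd0 <- comb$map_zd(Zd0); Zi0 <- comb$map_zi(Zi0)
    Actx$A <- comb$A_pair; Actx$Ainv <- solve(comb$A_pair)
    glevels <- comb$levels
    Actx$levels <- glevels
  }
  Zd <- Zd0 * cov_rand
  Zi <- Zi0 * cov_rand
  assemble_bundle(table, spec, rows, y, month, cov_rand, Actx, glevels, Zd, Zi)
}

## common tail of build_design: iid term recipes, residual structure, fixed
## design and packaging
assemble_bundle <- function(table, spec, rows, y, month, cov_rand,
                            Actx, glevels, Zd, Zi) {
  terms <- switch(spec$id,
    "STM" = list(list(name = "cage", level = factor(rows$cage), cov = rep(1, nrow(rows)))),
    "GLMM" = list(
      list(name = "cage_month", level = factor(paste(rows$cage, month, sep = ".")),
           cov = rep(1, nrow(rows))),
      list(name = "pe", level = factor(rows$id), cov = rep(1, nrow(rows)))),
    list(  # RMM.t / RMM.p: both cage terms and the PE regression
      list(name = "cage_month", level = factor(paste(rows$cage, month, sep = ".")),
           cov = rep(1, nrow(rows))),
      list(name = "cage_slope", level = factor(rows$cage), cov = cov_rand),
      list(name = "pe", level = factor(rows$id), cov = cov_rand)))

  resid <- if (spec$id == "STM") {
    list(type = "iid")
  } else if (spec$id == "GLMM") {
    list(type = "binomial")
  } else {
    list(type = "by_month", month = factor(month, levels = seq_len(table$months)))
  }

  X <- build_fixed_design(rows$class, month, spec$id, table$months, spec$poly_degree)
  structure(list(spec = spec, y = y, X = X, Zd = Zd, Zi = Zi,
                 genetic = Actx, glevels = glevels, terms = terms,
                 cov_rand = cov_rand,
                 resid = resid,
                 meta = data.frame(id = rows$id, cage = rows$cage,
                                   class = rows$class, month = month,
                                   stringsAsFactors = FALSE),
                 months = table$months, days_per_month = table$days_per_month),
            class = "design_bundle")
}

unlist_mates <- function(mates) {
  unique(unlist(strsplit(mates[nzchar(mates)], ",", fixed = TRUE),
                use.names = FALSE))
}

## Combined sire-dam-pair variant: one genetic effect per observed pair with
## relationship matrix A_pair = K A K', K averaging the two parents.
combine_sire_dam <- function(ped, focal_ids, mates, parent_levels, A_parents) {
  all_ids <- unique(c(focal_ids, unlist_mates(mates)))
  pidx <- match(all_ids, ped$id)
  pair <- paste(ped$sire[pidx], ped$dam[pidx], sep = "x")
  upair <- sort(unique(pair))
  sp <- sub("x.*$", "", upair); dp <- sub("^.*x", "", upair)
  K <- Matrix::sparseMatrix(
    i = rep(seq_along(upair), 2L),
    j = c(match(sp, parent_levels), match(dp, parent_levels)),
    x = 0.5, dims = c(length(upair), length(parent_levels)))
  A_pair <- as.matrix(K %*% A_parents %*% Matrix::t(K))
  dimnames(A_pair) <- list(upair, upair)
  pair_of <- stats::setNames(pair, all_ids)
  map_zd <- function(Z) {
    ## rebuild from ids: 1 in the focal's pair column
    n <- length(focal_ids)
    j <- match(pair_of[focal_ids], upair)
    Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1,
                         dims = c(n, length(upair)),
                         dimnames = list(NULL, upair))
  }
  map_zi <- function(Z) {
    ml <- strsplit(mates, ",", fixed = TRUE)
    nm <- lengths(ml); nm[!nzchar(mates)] <- 0L
    rows <- rep(seq_along(ml), nm)
    mids <- unlist(ml, use.names = FALSE)
    Matrix::sparseMatrix(i = rows, j = match(pair_of[mids], upair), x = 1,
                         dims = c(length(ml), length(upair)),
                         dimnames = list(NULL, upair))
  }
  list(levels = upair, A_pair = A_pair, map_zd = map_zd, map_zi = map_zi)
}
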