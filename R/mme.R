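## Mixed-model engine for the DGE-IGE survival models.
##
## All four models share the structure
##   y = X b + Z_D u_D + Z_I u_I + sum_k Z_k u_k + e,
##   (u_D', u_I')' ~ N(0, C (x) A),  u_k ~ N(0, sigma2_k I),  e ~ N(0, D)
## with D diagonal (single variance, per-month variances, or fixed binomial
## weights). Every iid term in these models is *cage-local* (cage, cage-month,
## cage slope, permanent environment of a caged hen), so the engine absorbs
## them into a blocked marginal residual R = D + sum_k sigma2_k Z_k Z_k',
## block-diagonal by cage. The mixed-model equations then only carry the
## fixed effects and the genetic pair, which keeps the coefficient matrix
## small for sire-dam models and sparse for animal models.
##
## REML maximization is AI-REML: Newton steps with the average-information
## matrix, analytic scores where the coefficient matrix inverse is affordable
## (dense path), central finite-difference scores otherwise (sparse path),
## with step-halving, projection of variances onto their bounds, bending of
## the genetic covariance to PSD, and EM fallback steps.

## ---- parameter vector layout -------------------------------------------

theta_layout <- function(prep) {
  nm <- c("c11", "c12", "c22", names(prep$Zk))
  if (prep$resid$type == "by_month") {
    nm <- c(nm, paste0("resid_m", seq_len(prep$resid$Tm)))
  } else if (prep$resid$type == "iid") {
    nm <- c(nm, "resid")
  }
  nm
}

theta_from_components <- function(prep, comp) {
  th <- c(comp$C[1, 1], comp$C[1, 2], comp$C[2, 2], comp$iid[names(prep$Zk)])
  if (prep$resid$type == "by_month") th <- c(th, rep_len(comp$resid, prep$resid$Tm))
  if (prep$resid$type == "iid") th <- c(th, comp$resid[1])
  stats::setNames(th, theta_layout(prep))
}

components_from_theta <- function(prep, th) {
  C <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2,
              dimnames = list(c("direct", "indirect"), c("direct", "indirect")))
  iid <- th[3 + seq_along(prep$Zk)]
  names(iid) <- names(prep$Zk)
  resid <- if (prep$resid$type == "by_month") {
    unname(th[3 + length(prep$Zk) + seq_len(prep$resid$Tm)])
  } else if (prep$resid$type == "iid") {
    unname(th[length(th)])
  } else numeric(0)
  list(C = C, iid = iid, resid = resid,
       scale = prep$scale_tag)
}

## eigenvalue flooring of the 2x2 genetic covariance
bend_C <- function(C, floor_frac = 1e-6) {
  e <- eigen(C, symmetric = TRUE)
  fl <- floor_frac * max(sum(abs(diag(C))), 1e-12)
  if (all(e$values >= fl)) return(C)
  v <- pmax(e$values, fl)
  Cb <- e$vectors %*% diag(v, 2) %*% t(e$vectors)
  (Cb + t(Cb)) / 2
}

## ---- preparation --------------------------------------------------------

prep_engine <- function(bundle) {
  stopifnot(inherits(bundle, "design_bundle"))
  y <- as.numeric(bundle$y)
  n <- length(y)
  X <- bundle$X
  q <- length(bundle$glevels)
  W <- cbind(X, bundle$Zd, bundle$Zi)
  p_f <- ncol(X)
  idxD <- p_f + seq_len(q)
  idxI <- p_f + q + seq_len(q)

  ## iid terms as global sparse incidence (covariate baked in)
  Zk <- lapply(bundle$terms, function(tm) {
    Matrix::sparseMatrix(i = seq_len(n), j = as.integer(tm$level), x = tm$cov,
                         dims = c(n, nlevels(tm$level)),
                         dimnames = list(NULL, levels(tm$level)))
  })
  names(Zk) <- vapply(bundle$terms, `[[`, character(1), "name")

  ## check cage-locality of every iid term (levels nested within cages)
  cage <- factor(bundle$meta$cage)
  for (k in seq_along(bundle$terms)) {
    lev <- bundle$terms[[k]]$level
    nl <- tapply(as.integer(cage), lev, function(z) length(unique(z)))
    if (any(nl > 1L)) {
      stop("iid term '", names(Zk)[k], "' is not nested within cages; ",
           "the absorption engine requires cage-local random terms")
    }
  }

  resid <- bundle$resid
  if (resid$type == "by_month") {
    resid$Tm <- nlevels(resid$month)
    resid$month_idx <- as.integer(resid$month)
  } else if (resid$type == "binomial") {
    if (is.null(resid$weights)) stop("binomial residual structure needs weights")
    resid$d0 <- 1 / resid$weights
  }

  ## absorption blocks: one per cage, patterns shared where possible
  rows_by_cage <- split(seq_len(n), cage)
  sig <- vapply(rows_by_cage, function(r) {
    parts <- c(
      if (!is.null(resid$month_idx)) paste(resid$month_idx[r], collapse = ","),
      if (!is.null(resid$d0)) paste(signif(resid$d0[r], 12), collapse = ","),
      vapply(bundle$terms, function(tm) {
        paste(as.integer(factor(as.integer(tm$level[r]))), signif(tm$cov[r], 12),
              collapse = ";")
      }, character(1)))
    paste(parts, collapse = "|")
  }, character(1))
  pat_of <- match(sig, unique(sig))
  patterns <- lapply(which(!duplicated(sig)), function(ci) {
    r <- rows_by_cage[[ci]]
    Pk <- lapply(bundle$terms, function(tm) {
      U <- outer(as.integer(tm$level[r]), unique(as.integer(tm$level[r])), "==") *
        tm$cov[r]
      tcrossprod(U)
    })
    list(nr = length(r),
         month_idx = if (!is.null(resid$month_idx)) resid$month_idx[r],
         d0 = if (!is.null(resid$d0)) resid$d0[r],
         Pk = Pk)
  })

  ## sparse R-inverse template: block fill positions
  ti <- unlist(lapply(rows_by_cage, function(r) rep(r, each = length(r))))
  tj <- unlist(lapply(rows_by_cage, function(r) rep(r, times = length(r))))
  ## per-pattern triplet positions, so each evaluation can fill all cages of
  ## one pattern with a single vectorized assignment
  blk_len <- vapply(rows_by_cage, function(r) length(r)^2, numeric(1))
  blk_off <- cumsum(c(0, blk_len[-length(blk_len)]))
  pat_positions <- lapply(seq_along(unique(pat_of)), function(p) {
    cs <- which(pat_of == p)
    unlist(lapply(cs, function(ci) blk_off[ci] + seq_len(blk_len[ci])))
  })
  pat_count <- tabulate(pat_of, nbins = length(patterns))
  tmpl <- Matrix::sparseMatrix(i = ti, j = tj, x = seq_along(ti),
                               dims = c(n, n))
  ## stored x of the template are the triplet indices themselves, giving the
  ## slot -> triplet map used to refill the block values at each evaluation
  slot_src <- tmpl@x
  Rinv0 <- tmpl
  Rinv0@x <- numeric(length(slot_src))

  dense <- (p_f + 2L * q) <= 2000L

  Ainv <- bundle$genetic$Ainv
  if (dense) Ainv <- as.matrix(Ainv)
  Amat <- bundle$genetic$A
  A_mul <- if (!is.null(Amat)) {
    function(v) as.numeric(Amat %*% v)
  } else {
    function(v) as.numeric(Matrix::solve(bundle$genetic$Ainv, v))
  }
  logdetA <- if (!is.null(Amat)) {
    as.numeric(determinant(Amat, logarithm = TRUE)$modulus)
  } else {
    -as.numeric(Matrix::determinant(Matrix::forceSymmetric(bundle$genetic$Ainv),
                                    logarithm = TRUE)$modulus)
  }

  ## reference scale: residual variance of a plain fixed-effects OLS, so that
  ## starting values and floors are not inflated by large fixed effects
  s_ref <- tryCatch({
    XtX <- as.matrix(Matrix::crossprod(X))
    bt <- solve(XtX + diag(1e-10 * max(diag(XtX)), ncol(X)),
                as.numeric(Matrix::crossprod(X, y)))
    stats::var(y - as.numeric(X %*% bt))
  }, error = function(e) stats::var(y))
  ## mean squared random-regression covariate per term (1 for intercepts)
  c2_k <- vapply(bundle$terms, function(tm) mean(tm$cov^2), numeric(1))
  c2_g <- mean((bundle$cov_rand %||% 1)^2)

  list(y = y, n = n, W = W, p_f = p_f, q = q, idxD = idxD, idxI = idxI,
       Zk = Zk, qk = vapply(Zk, ncol, integer(1)),
       resid = resid, rows_by_cage = rows_by_cage, pat_of = pat_of,
       patterns = patterns, pat_positions = pat_positions,
       pat_count = pat_count, Rinv0 = Rinv0, slot_src = slot_src,
       Ainv = Ainv, A_mul = A_mul, logdetA = logdetA,
       dense = dense, s_ref = s_ref, c2_k = c2_k, c2_g = c2_g,
       scale_tag = list(parameterization = bundle$spec$parameterization,
                        coding = bundle$spec$coding),
       glevels = bundle$glevels, bundle = bundle)
}

## residual diagonal values for a pattern at theta
pattern_block <- function(prep, pat, comp) {
  d <- if (prep$resid$type == "by_month") {
    comp$resid[pat$month_idx]
  } else if (prep$resid$type == "binomial") {
    pat$d0
  } else {
    rep(comp$resid, pat$nr)
  }
  B <- diag(d, pat$nr)
  for (k in seq_along(pat$Pk)) {
    s2 <- comp$iid[[k]]
    if (s2 > 0) B <- B + s2 * pat$Pk[[k]]
  }
  B
}

## ---- likelihood evaluation ---------------------------------------------

engine_eval <- function(prep, th, want_solutions = FALSE, keep = TRUE) {
  comp <- components_from_theta(prep, th)
  Cb <- bend_C(comp$C)
  Cinv <- solve(Cb)
  logdetC <- as.numeric(determinant(Cb, logarithm = TRUE)$modulus)

  ## unique pattern blocks
  pinfo <- lapply(prep$patterns, function(pat) {
    B <- pattern_block(prep, pat, comp)
    ch <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(ch)) {
      B <- B + diag(1e-10 * max(diag(B)), nrow(B))
      ch <- chol(B)
    }
    list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
  })
  vals <- numeric(length(prep$slot_src))
  for (p in seq_along(prep$patterns)) {
    vals[prep$pat_positions[[p]]] <- as.vector(pinfo[[p]]$inv)
  }
  Rinv <- prep$Rinv0
  Rinv@x <- vals[prep$slot_src]
  logR <- sum(prep$pat_count *
                vapply(pinfo, `[[`, numeric(1), "logdet"))

  W <- prep$W
  Riy <- as.numeric(Rinv %*% prep$y)
  Q <- Rinv %*% W
  rhs <- as.numeric(Matrix::crossprod(W, Riy))
  M0 <- Matrix::crossprod(W, Q)
  q <- prep$q
  Gkron <- rbind(cbind(Cinv[1, 1] * prep$Ainv, Cinv[1, 2] * prep$Ainv),
                 cbind(Cinv[2, 1] * prep$Ainv, Cinv[2, 2] * prep$Ainv))
  gidx <- c(prep$idxD, prep$idxI)
  if (prep$dense) {
    M <- as.matrix(M0)
    M[gidx, gidx] <- M[gidx, gidx] + as.matrix(Gkron)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) {
      M <- M + diag(1e-8 * max(diag(M)), nrow(M))
      ch <- chol(M)
    }
    logdetM <- 2 * sum(log(diag(ch)))
    sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
    Minv <- if (keep) chol2inv(ch) else NULL
  } else {
    Gbig <- Matrix::bdiag(Matrix::Diagonal(prep$p_f, 0), Gkron)
    M <- Matrix::forceSymmetric(methods::as(M0, "CsparseMatrix") + Gbig)
    fac <- Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
    logdetM <- 2 * as.numeric(Matrix::determinant(fac, sqrt = TRUE)$modulus)
    sol <- as.numeric(Matrix::solve(fac, rhs))
    Minv <- NULL
    chfac <- fac
  }
  yRy <- sum(prep$y * Riy)
  yPy <- yRy - sum(sol * rhs)
  neg2L <- logR + q * logdetC + 2 * prep$logdetA + logdetM + yPy
  w <- Riy - as.numeric(Q %*% sol)  # P y

  out <- list(neg2L = neg2L, comp = comp, Cb = Cb, Cinv = Cinv, sol = sol,
              w = w, theta = th)
  if (keep) {
    out$Rinv <- Rinv; out$Q <- Q; out$rhs <- rhs
    out$Minv <- Minv
    out$pinfo <- pinfo
    if (!prep$dense) out$fac <- chfac
  }
  if (want_solutions) {
    estar <- prep$y - as.numeric(W %*% sol)
    Rie <- as.numeric(Rinv %*% estar)
    u_iid <- lapply(seq_along(prep$Zk), function(k) {
      comp$iid[[k]] * as.numeric(Matrix::crossprod(prep$Zk[[k]], Rie))
    })
    names(u_iid) <- names(prep$Zk)
    for (k in seq_along(u_iid)) names(u_iid[[k]]) <- colnames(prep$Zk[[k]])
    fit_iid <- Reduce(`+`, lapply(seq_along(prep$Zk), function(k) {
      as.numeric(prep$Zk[[k]] %*% u_iid[[k]])
    }), accumulate = FALSE, right = FALSE) %||% numeric(prep$n)
    out$solutions <- list(
      fixed = stats::setNames(sol[seq_len(prep$p_f)], colnames(prep$W)[seq_len(prep$p_f)]),
      u_d = stats::setNames(sol[prep$idxD], prep$glevels),
      u_i = stats::setNames(sol[prep$idxI], prep$glevels),
      iid = u_iid)
    out$fitted_random <- fit_iid
    out$residuals <- estar - fit_iid
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## apply P to a vector using cached pieces
apply_P <- function(prep, ev, v) {
  Riv <- as.numeric(ev$Rinv %*% v)
  qv <- as.numeric(Matrix::crossprod(ev$Q, v))
  s <- if (prep$dense) as.numeric(ev$Minv %*% qv) else as.numeric(Matrix::solve(ev$fac, qv))
  Riv - as.numeric(ev$Q %*% s)
}

## ---- analytic score (dense path) ---------------------------------------

## trace of Minv %*% S for dense Minv and sparse symmetric S, without
## densifying S
trace_prod <- function(Minv, S) {
  St <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  sum(St@x * Minv[cbind(St@i + 1L, St@j + 1L)])
}

## returns s_i = d(-2logL)/d theta_i plus reusable pieces (trP_k, ypv_k)
engine_score_dense <- function(prep, ev) {
  th <- ev$theta
  comp <- ev$comp
  Minv <- ev$Minv
  w <- ev$w
  nm <- theta_layout(prep)
  s <- stats::setNames(numeric(length(nm)), nm)
  aux <- list()

  ## counts per pattern
  pat_count <- tabulate(prep$pat_of, nbins = length(prep$patterns))

  ## iid terms
  for (k in seq_along(prep$Zk)) {
    tr1 <- sum(vapply(seq_along(prep$patterns), function(pi) {
      pat_count[pi] * sum(ev$pinfo[[pi]]$inv * prep$patterns[[pi]]$Pk[[k]])
    }, numeric(1)))
    Bk <- Matrix::crossprod(ev$Q, prep$Zk[[k]])
    tr2 <- trace_prod(Minv, Matrix::tcrossprod(Bk))
    zw <- as.numeric(Matrix::crossprod(prep$Zk[[k]], w))
    ypv <- sum(zw^2)
    trP <- tr1 - tr2
    s[3 + k] <- trP - ypv
    aux[[names(prep$Zk)[k]]] <- c(trP = trP, ypv = ypv)
  }

  ## residual variances
  if (prep$resid$type %in% c("by_month", "iid")) {
    diagR <- numeric(prep$n)
    for (ci in seq_along(prep$rows_by_cage)) {
      diagR[prep$rows_by_cage[[ci]]] <- diag(ev$pinfo[[prep$pat_of[ci]]]$inv)
    }
    if (prep$resid$type == "iid") {
      trP <- sum(diagR) - trace_prod(Minv, Matrix::crossprod(ev$Q))
      ypv <- sum(w^2)
      s[length(s)] <- trP - ypv
      aux[["resid"]] <- c(trP = trP, ypv = ypv, nm = prep$n)
    } else {
      off <- 3 + length(prep$Zk)
      for (m in seq_len(prep$resid$Tm)) {
        rm_ <- which(prep$resid$month_idx == m)
        Qm <- ev$Q[rm_, , drop = FALSE]
        trP <- sum(diagR[rm_]) - trace_prod(Minv, Matrix::crossprod(Qm))
        ypv <- sum(w[rm_]^2)
        s[off + m] <- trP - ypv
        aux[[paste0("resid_m", m)]] <- c(trP = trP, ypv = ypv, nm = length(rm_))
      }
    }
  }

  ## genetic C via the G-side identity
  gD <- ev$sol[prep$idxD]; gI <- ev$sol[prep$idxI]
  Ai <- prep$Ainv
  AiD <- as.numeric(Ai %*% gD); AiI <- as.numeric(Ai %*% gI)
  S <- matrix(c(sum(gD * AiD), sum(gD * AiI), sum(gI * AiD), sum(gI * AiI)), 2, 2)
  S <- (S + t(S)) / 2
  gidx <- list(prep$idxD, prep$idxI)
  Tm_ <- matrix(0, 2, 2)
  for (j in 1:2) for (l in j:2) {
    Cjl <- ev$Minv[gidx[[j]], gidx[[l]], drop = FALSE]
    Tm_[j, l] <- Tm_[l, j] <- sum(Ai * Cjl)
  }
  Cinv <- ev$Cinv
  dC <- list(c11 = matrix(c(1, 0, 0, 0), 2), c12 = matrix(c(0, 1, 1, 0), 2),
             c22 = matrix(c(0, 0, 0, 1), 2))
  for (j in seq_along(dC)) {
    N <- Cinv %*% dC[[j]] %*% Cinv
    s[j] <- prep$q * sum(diag(Cinv %*% dC[[j]])) - sum(N * Tm_) - sum(N * S)
  }
  aux$genetic <- list(S = S, Tm = Tm_)
  list(s = s, aux = aux)
}

## finite-difference score (sparse path)
engine_score_fd <- function(prep, ev) {
  th <- ev$theta
  s <- stats::setNames(numeric(length(th)), names(th))
  for (i in seq_along(th)) {
    h <- max(1e-5 * abs(th[i]), 1e-6 * prep$s_ref * 1e-2, 1e-9)
    tp <- th; tp[i] <- th[i] + h
    tm <- th; tm[i] <- th[i] - h
    fp <- engine_eval(prep, tp, keep = FALSE)$neg2L
    fm <- engine_eval(prep, tm, keep = FALSE)$neg2L
    s[i] <- (fp - fm) / (2 * h)
  }
  list(s = s, aux = NULL)
}

## ---- average information matrix ----------------------------------------

engine_ai <- function(prep, ev) {
  w <- ev$w
  th <- ev$theta
  nm <- names(th)
  Yh <- matrix(0, prep$n, length(th))
  ## genetic derivatives
  ZdW <- as.numeric(Matrix::crossprod(prep$W[, prep$idxD, drop = FALSE], w))
  ZiW <- as.numeric(Matrix::crossprod(prep$W[, prep$idxI, drop = FALSE], w))
  AZd <- prep$A_mul(ZdW)
  AZi <- prep$A_mul(ZiW)
  Zd <- prep$W[, prep$idxD, drop = FALSE]
  Zi <- prep$W[, prep$idxI, drop = FALSE]
  Yh[, 1] <- as.numeric(Zd %*% AZd)
  Yh[, 2] <- as.numeric(Zd %*% AZi) + as.numeric(Zi %*% AZd)
  Yh[, 3] <- as.numeric(Zi %*% AZi)
  for (k in seq_along(prep$Zk)) {
    zw <- as.numeric(Matrix::crossprod(prep$Zk[[k]], w))
    Yh[, 3 + k] <- as.numeric(prep$Zk[[k]] %*% zw)
  }
  if (prep$resid$type == "iid") {
    Yh[, length(th)] <- w
  } else if (prep$resid$type == "by_month") {
    off <- 3 + length(prep$Zk)
    for (m in seq_len(prep$resid$Tm)) {
      rm_ <- prep$resid$month_idx == m
      Yh[rm_, off + m] <- w[rm_]
    }
  }
  PY <- apply(Yh, 2, function(v) apply_P(prep, ev, v))
  AI <- 0.5 * crossprod(Yh, PY)
  (AI + t(AI)) / 2
}

## ---- REML driver --------------------------------------------------------

default_start <- function(prep) {
  v <- prep$s_ref
  gshare <- if (prep$scale_tag$parameterization == "sire_dam") 0.025 else 0.1
  th <- c(gshare * v / prep$c2_g, 0, 0.3 * gshare * v / prep$c2_g,
          0.05 * v / prep$c2_k)
  if (prep$resid$type == "by_month") {
    th <- c(th, rep(0.6 * v, prep$resid$Tm))
  } else if (prep$resid$type == "iid") {
    th <- c(th, 0.6 * v)
  }
  stats::setNames(th, theta_layout(prep))
}

project_theta <- function(prep, th) {
  fl <- 1e-8 * prep$s_ref
  idxv <- setdiff(seq_along(th), 2L)  # all but the genetic covariance
  th[idxv] <- pmax(th[idxv], fl)
  if (prep$resid$type %in% c("iid", "by_month")) {
    rfl <- 1e-6 * prep$s_ref
    ridx <- (3 + length(prep$Zk) + 1):length(th)
    th[ridx] <- pmax(th[ridx], rfl)
  }
  ## keep C PSD (projection; engine_eval additionally bends)
  det2 <- th[1] * th[3] - th[2]^2
  if (det2 < 0) th[2] <- sign(th[2]) * sqrt(th[1] * th[3]) * 0.999
  th
}

## EM variance-component update from the score auxiliaries (dense path)
em_update <- function(prep, th, aux) {
  thp <- th
  Cn <- (aux$genetic$S + aux$genetic$Tm) / prep$q
  thp[1] <- Cn[1, 1]; thp[2] <- Cn[1, 2]; thp[3] <- Cn[2, 2]
  for (k in seq_along(prep$Zk)) {
    a <- aux[[names(prep$Zk)[k]]]
    v <- th[3 + k]
    thp[3 + k] <- (v^2 * a[["ypv"]] + v * prep$qk[k] - v^2 * a[["trP"]]) / prep$qk[k]
  }
  if (prep$resid$type == "iid") {
    a <- aux[["resid"]]; v <- th[length(th)]
    thp[length(th)] <- (v^2 * a[["ypv"]] + v * a[["nm"]] - v^2 * a[["trP"]]) / a[["nm"]]
  } else if (prep$resid$type == "by_month") {
    off <- 3 + length(prep$Zk)
    for (m in seq_len(prep$resid$Tm)) {
      a <- aux[[paste0("resid_m", m)]]; v <- th[off + m]
      thp[off + m] <- (v^2 * a[["ypv"]] + v * a[["nm"]] - v^2 * a[["trP"]]) / a[["nm"]]
    }
  }
  thp
}

#' REML variance-component estimation (average information)
#'
#' Fits the variance components of a [build_design()] bundle by restricted
#' maximum likelihood. Newton steps use the average-information matrix;
#' scores are analytic when the mixed-model equations are small enough to
#' invert densely (sire-dam models after absorbing the cage-local iid terms)
#' and central finite differences otherwise (animal models, few parameters).
#' Steps that do not improve the restricted likelihood are halved; variances
#' are projected onto their lower bounds; the genetic 2x2 covariance is kept
#' positive semidefinite by eigenvalue flooring ("bending"); if a Newton step
#' fails outright an EM update is taken instead. Convergence requires
#' `|delta logL| < 1e-8` and a relative parameter change `< 1e-6`.
#'
#' @param bundle a `design_bundle` from [build_design()].
#' @param start optional starting `VarianceComponents`-style list
#'   (`C`, `iid`, `resid`).
#' @param control list: `maxit` (default 100), `tol_logl` (1e-8),
#'   `tol_par` (1e-6), `warmup` (number of initial EM iterations on the dense
#'   path, default 3), `verbose`.
#' @return a `fit_result`: variance components at convergence (on the scale
#'   they were fitted: sire-dam components are NOT rescaled to the animal
#'   scale), effect solutions for all levels, restricted log-likelihood,
#'   convergence diagnostics and component standard errors from the inverse
#'   average-information matrix.
#' @export
reml_fit <- function(bundle, start = NULL, control = list()) {
  ctl <- utils::modifyList(list(maxit = 100L, tol_logl = 1e-8, tol_par = 1e-6,
                                warmup = 3L, verbose = FALSE), control)
  prep <- prep_engine(bundle)
  th <- if (is.null(start)) default_start(prep) else theta_from_components(prep, start)
  ## EM warm-up exists to survive crude default starts; a user-supplied start
  ## goes straight to AI steps
  if (!is.null(start)) ctl$warmup <- 0L
  th <- project_theta(prep, th)
  ev <- engine_eval(prep, th)
  ## natural scale per parameter (slope variances live on s_ref / mean cov^2)
  par_scale <- c(rep(prep$s_ref / prep$c2_g, 3), prep$s_ref / prep$c2_k)
  if (prep$resid$type == "by_month") par_scale <- c(par_scale, rep(prep$s_ref, prep$resid$Tm))
  if (prep$resid$type == "iid") par_scale <- c(par_scale, prep$s_ref)
  floor_v <- 1e-8 * prep$s_ref
  grad_norm <- NA_real_
  converged <- FALSE
  iter <- 0L
  n_tiny <- 0L
  for (iter in seq_len(ctl$maxit)) {
    sc <- if (prep$dense) engine_score_dense(prep, ev) else engine_score_fd(prep, ev)
    dL <- -sc$s / 2
    ## active-set: a variance pinned at (or vanishingly close to) its floor
    ## with a score pushing it further down stays fixed; the genetic
    ## covariance is frozen with it whenever either genetic variance is
    ## pinned, since the PSD constraint then forces it to ~0 and the AI
    ## matrix carries no information about it
    at_bound <- seq_along(th) != 2L & th <= 30 * floor_v & dL < 0
    if (at_bound[1] || at_bound[3]) at_bound[2] <- TRUE
    dL_free <- dL
    dL_free[at_bound] <- 0
    grad_norm <- sqrt(sum(dL_free^2))
    AI <- engine_ai(prep, ev)
    accepted <- FALSE
    if (prep$dense && iter <= ctl$warmup && !is.null(sc$aux)) {
      ## EM warm-up: slow but monotone and safe far from the optimum
      thp <- project_theta(prep, em_update(prep, th, sc$aux))
      evp <- tryCatch(engine_eval(prep, thp), error = function(e) NULL)
      accepted <- !is.null(evp) && is.finite(evp$neg2L) &&
        evp$neg2L <= ev$neg2L + 1e-10
    }
    if (!accepted) {
      free <- !at_bound
      step <- numeric(length(th))
      step[free] <- tryCatch({
        Af <- AI[free, free, drop = FALSE]
        solve(Af + diag(1e-8 * max(diag(Af)), nrow(Af)), dL[free])
      }, error = function(e) dL[free] / pmax(diag(AI)[free], 1e-12))
      fac <- 1
      for (half in 0:8) {
        thp <- project_theta(prep, th + fac * step)
        evp <- tryCatch(engine_eval(prep, thp), error = function(e) NULL)
        if (!is.null(evp) && is.finite(evp$neg2L) && evp$neg2L <= ev$neg2L + 1e-10) {
          accepted <- TRUE
          break
        }
        fac <- fac / 2
      }
      if (accepted && fac <= 1 / 8 && prep$dense && !is.null(sc$aux)) {
        ## heavily damped AI step: an EM step is usually the better move
        them <- project_theta(prep, em_update(prep, th, sc$aux))
        evem <- tryCatch(engine_eval(prep, them), error = function(e) NULL)
        if (!is.null(evem) && is.finite(evem$neg2L) && evem$neg2L < evp$neg2L) {
          thp <- them
          evp <- evem
        }
      }
    }
    if (!accepted && prep$dense && !is.null(sc$aux)) {
      ## EM fallback when the AI step fails outright
      thp <- project_theta(prep, em_update(prep, th, sc$aux))
      evp <- tryCatch(engine_eval(prep, thp), error = function(e) NULL)
      accepted <- !is.null(evp) && is.finite(evp$neg2L) && evp$neg2L <= ev$neg2L + 1e-8
    }
    if (!accepted) break
    dlogl <- (ev$neg2L - evp$neg2L) / 2
    dpar <- max(abs(thp - th) / pmax(abs(th), 1e-3 * par_scale))
    th <- thp
    ev <- evp
    if (ctl$verbose) {
      message(sprintf("it %d  -2logL %.6f  |grad| %.3g  dpar %.3g  fac %.3g",
                      iter, ev$neg2L, grad_norm, dpar,
                      if (exists("fac", inherits = FALSE)) fac else NA))
    }
    n_tiny <- if (abs(dlogl) < ctl$tol_logl) n_tiny + 1L else 0L
    if ((abs(dlogl) < ctl$tol_logl && dpar < ctl$tol_par) || n_tiny >= 2L) {
      converged <- TRUE
      break
    }
  }
  ev <- engine_eval(prep, th, want_solutions = TRUE)
  AI <- engine_ai(prep, ev)
  ## SEs from the inverse information over the informative parameters only
  se <- rep(NA_real_, length(th))
  inf <- diag(AI) > 1e-10 * max(diag(AI), 1)
  se[inf] <- tryCatch({
    Ai_inf <- solve(AI[inf, inf, drop = FALSE])
    sqrt(pmax(diag(Ai_inf), 0))
  }, error = function(e) rep(NA_real_, sum(inf)))
  names(se) <- names(th)
  structure(list(components = ev$comp, solutions = ev$solutions,
                 logLik = -ev$neg2L / 2, neg2L = ev$neg2L,
                 iterations = iter, converged = converged,
                 grad_norm = grad_norm, se = se, AI = AI,
                 theta = th, prep_scale = prep$s_ref,
                 bundle = bundle),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: logL = %.4f, %d iterations, converged: %s\n",
              x$logLik, x$iterations, x$converged))
  cat("genetic covariance C:\n")
  print(x$components$C)
  if (length(x$components$iid)) {
    cat("iid variances:\n"); print(x$components$iid)
  }
  if (length(x$components$resid)) {
    cat("residual variance(s):\n"); print(x$components$resid)
  }
  invisible(x)
}

#' BLUP solutions at fixed variance components
#'
#' Solves Henderson's mixed-model equations (with the cage-local iid terms
#' absorbed into the blocked residual) at the supplied components and returns
#' all effect solutions. In the limit where every random variance tends to 0
#' the random solutions shrink to 0 and the fixed solutions tend to GLS.
#'
#' @param bundle a `design_bundle`.
#' @param components list with `C` (2x2 genetic covariance), `iid` (named
#'   variances for the bundle's iid terms) and `resid` (scalar or per-month).
#' @return list with `solutions` (fixed, `u_d`, `u_i`, iid levels),
#'   `logLik`, and `residuals`.
#' @export
solve_blup <- function(bundle, components) {
  prep <- prep_engine(bundle)
  th <- theta_from_components(prep, components)
  ev <- engine_eval(prep, th, want_solutions = TRUE)
  list(solutions = ev$solutions, logLik = -ev$neg2L / 2,
       residuals = ev$residuals, theta = th)
}

#' Penalized quasi-likelihood fit of the logit model
#'
#' Iterates the standard working-response linearization of the logit link
#' (working response `z = eta + (y - p)/(p(1-p))`, weights `p(1-p)`) and
#' refits the variance components of the working linear mixed model with
#' [reml_fit()] at each step until the linear predictor changes by less than
#' `tol` (default 1e-6, capped at `maxit` outer iterations). Near-separated
#' fitted probabilities are clamped to `[1e-6, 1-1e-6]` with a warning.
#'
#' @param bundle a `design_bundle` whose response is 0/1 and whose residual
#'   type is binomial.
#' @param start optional starting components.
#' @param control passed to [reml_fit()]; additionally `pql_tol`, `pql_maxit`.
#' @return a `fit_result` with an extra `pql` element (outer iterations,
#'   final max linear-predictor change).
#' @export
glmm_pql_fit <- function(bundle, start = NULL, control = list()) {
  stopifnot(identical(bundle$resid$type, "binomial"))
  y <- as.numeric(bundle$y)
  if (!all(y %in% c(0, 1))) stop("PQL path requires a 0/1 response")
  ctl <- utils::modifyList(list(pql_tol = 1e-6, pql_maxit = 30L), control)
  ctl_in <- ctl[setdiff(names(ctl), c("pql_tol", "pql_maxit"))]
  eta <- stats::qlogis(pmin(pmax((y + 0.5) / 2, 0.3), 0.7))
  fit <- NULL
  comp <- start
  clamped_any <- FALSE
  it <- 0L
  delta <- Inf
  for (it in seq_len(ctl$pql_maxit)) {
    p <- stats::plogis(eta)
    pc <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    if (any(p != pc)) clamped_any <- TRUE
    wgt <- pc * (1 - pc)
    z <- eta + (y - pc) / wgt
    wb <- bundle
    wb$y <- z
    wb$resid <- list(type = "binomial", weights = wgt)
    fit <- reml_fit(wb, start = comp, control = ctl_in)
    comp <- fit$components
    sol <- fit$solutions
    Wmat <- cbind(wb$X, wb$Zd, wb$Zi)
    eta_new <- as.numeric(Wmat %*% c(sol$fixed, sol$u_d, sol$u_i))
    for (k in seq_along(sol$iid)) {
      tm <- bundle$terms[[k]]
      eta_new <- eta_new + sol$iid[[k]][as.integer(tm$level)] * tm$cov
    }
    delta <- max(abs(eta_new - eta))
    eta <- eta_new
    if (delta < ctl$pql_tol) break
  }
  if (clamped_any) warning("near-separated fitted probabilities were clamped")
  fit$pql <- list(iterations = it, delta_eta = delta,
                  converged = delta < ctl$pql_tol)
  fit$eta <- eta
  fit$components$scale$link <- "logit"
  fit
}

#' Extract estimated breeding values
#'
#' Animal parameterization: the genetic solutions themselves. Sire-dam:
#' the parental prediction, i.e. the sum of the individual's sire and dam
#' effect solutions (separately for the direct and the indirect effect).
#'
#' @param fit a `fit_result`.
#' @param ids individuals to extract; default all phenotyped ids.
#' @param ped pedigree (required for sire-dam fits to look up parents;
#'   defaults to the one carried by the bundle).
#' @return data.frame `id`, `ebv_d`, `ebv_i`.
#' @export
extract_ebv <- function(fit, ids = NULL, ped = NULL) {
  bundle <- fit$bundle
  if (is.null(ids)) ids <- unique(bundle$meta$id)
  ids <- as.character(ids)
  sol <- fit$solutions
  if (bundle$spec$parameterization == "animal") {
    ed <- sol$u_d[ids]; ei <- sol$u_i[ids]
    names(ed) <- names(ei) <- ids
    miss <- which(!(ids %in% names(sol$u_d)))
    if (length(miss)) {
      ## individuals without data or descendants in the fit: BLUP equals the
      ## parental average (exact for a non-phenotyped terminal individual)
      if (is.null(ped)) ped <- bundle$genetic$ped
      pidx <- match(ids[miss], ped$id)
      if (anyNA(pidx)) stop("id(s) not in pedigree: ",
                            paste(utils::head(ids[miss][is.na(pidx)], 5), collapse = ", "))
      s <- ped$sire[pidx]; d <- ped$dam[pidx]
      if (anyNA(s) || anyNA(d) || !all(c(s, d) %in% names(sol$u_d))) {
        stop("id(s) without genetic solutions and without solved parents")
      }
      ed[miss] <- (sol$u_d[s] + sol$u_d[d]) / 2
      ei[miss] <- (sol$u_i[s] + sol$u_i[d]) / 2
    }
    data.frame(id = ids, ebv_d = unname(ed), ebv_i = unname(ei),
               stringsAsFactors = FALSE)
  } else {
    if (is.null(ped)) ped <- bundle$genetic$ped
    pidx <- match(ids, ped$id)
    if (anyNA(pidx)) stop("id(s) not in pedigree")
    s <- ped$sire[pidx]; d <- ped$dam[pidx]
    if (anyNA(s) || anyNA(d)) stop("sire-dam EBV need both parents known")
    if (isTRUE(bundle$genetic$combined)) {
      pair <- paste(s, d, sep = "x")
      data.frame(id = ids, ebv_d = unname(sol$u_d[pair]),
                 ebv_i = unname(sol$u_i[pair]), stringsAsFactors = FALSE)
    } else {
      data.frame(id = ids,
                 ebv_d = unname(sol$u_d[s] + sol$u_d[d]),
                 ebv_i = unname(sol$u_i[s] + sol$u_i[d]),
                 stringsAsFactors = FALSE)
    }
  }
}
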