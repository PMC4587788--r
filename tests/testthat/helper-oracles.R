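## Shared fixtures and independent oracles for the test suite.
## Everything here is built in code at test time; no stored data.

## small nuclear-family pedigree: two founders and a full-sib pair (+ one
## inbred full-sib-mating offspring when extended = TRUE)
toy_pedigree <- function(extended = FALSE) {
  if (!extended) {
    pedigree(c("S", "D", "a", "b"), c("0", "0", "S", "S"), c("0", "0", "D", "D"))
  } else {
    pedigree(c("S", "D", "a", "b", "c"),
             c("0", "0", "S", "S", "a"), c("0", "0", "D", "D", "b"))
  }
}

## random multi-generation pedigree with founders and random matings
random_pedigree <- function(n_founders = 10, n_per_gen = 10, n_gen = 3, seed = 1) {
  set.seed(seed)
  id <- paste0("f", seq_len(n_founders))
  sire <- rep(NA_character_, n_founders)
  dam <- rep(NA_character_, n_founders)
  sex <- rep(c("M", "F"), length.out = n_founders)
  pool_m <- id[sex == "M"]; pool_f <- id[sex == "F"]
  nid <- 0L
  for (g in seq_len(n_gen)) {
    new <- paste0("g", g, "_", seq_len(n_per_gen))
    s <- sample(pool_m, n_per_gen, replace = TRUE)
    d <- sample(pool_f, n_per_gen, replace = TRUE)
    sx <- sample(c("M", "F"), n_per_gen, replace = TRUE)
    id <- c(id, new); sire <- c(sire, s); dam <- c(dam, d); sex <- c(sex, sx)
    pool_m <- c(pool_m, new[sx == "M"]); pool_f <- c(pool_f, new[sx == "F"])
    if (!length(pool_m)) pool_m <- new
    if (!length(pool_f)) pool_f <- new
  }
  pedigree(id, sire, dam, sex = sex)
}

## Gene-dropping Monte-Carlo estimate of additive relationships: founders get
## two unique alleles, descendants inherit one random allele per parent;
## a_ij = 2 * P(random allele of i IBD to random allele of j), estimated over
## `reps` independent drops. Returns estimate and Monte-Carlo SE for the
## requested id pairs.
gene_drop_relationship <- function(ped, pairs, reps = 20000, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  a1 <- matrix(0L, n, reps); a2 <- matrix(0L, n, reps)
  next_allele <- 0L
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (s == 0L) {
      a1[i, ] <- next_allele + 1L; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(reps) < 0.5
      a1[i, ] <- ifelse(pick, a1[s, ], a2[s, ])
    }
    if (d == 0L) {
      a2[i, ] <- next_allele + 1L; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(reps) < 0.5
      a2[i, ] <- ifelse(pick, a1[d, ], a2[d, ])
    }
  }
  idx <- match(pairs[, 1], ped$id); jdx <- match(pairs[, 2], ped$id)
  est <- se <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- idx[k]; j <- jdx[k]
    if (i == j) {
      sh <- 1 + (a1[i, ] == a2[i, ])  # a_ii = 1 + F_i
    } else {
      sh <- 0.5 * ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
                     (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ]))
    }
    est[k] <- mean(sh)
    se[k] <- stats::sd(sh) / sqrt(reps)
  }
  data.frame(i = pairs[, 1], j = pairs[, 2], est = est, se = se)
}

## Dense-covariance oracle for BLUP / REML on a design bundle: forms the full
## phenotypic covariance V and computes GLS fixed effects, conditional-mean
## random effects, and the restricted log-likelihood directly.
dense_v_oracle <- function(bundle, components) {
  y <- as.numeric(bundle$y)
  X <- as.matrix(bundle$X)
  Zd <- as.matrix(bundle$Zd); Zi <- as.matrix(bundle$Zi)
  q <- length(bundle$glevels)
  A <- if (!is.null(bundle$genetic$A)) as.matrix(bundle$genetic$A) else
    solve(as.matrix(bundle$genetic$Ainv))
  C <- components$C
  CoxA <- rbind(cbind(C[1, 1] * A, C[1, 2] * A), cbind(C[2, 1] * A, C[2, 2] * A))
  Zg <- cbind(Zd, Zi)
  V <- Zg %*% CoxA %*% t(Zg)
  Zk_list <- lapply(bundle$terms, function(tm) {
    stats::model.matrix(~ 0 + tm$level)[, , drop = FALSE] * tm$cov
  })
  for (k in seq_along(Zk_list)) {
    V <- V + components$iid[[names(components$iid)[k]]] * tcrossprod(Zk_list[[k]])
  }
  D <- if (bundle$resid$type == "by_month") {
    components$resid[as.integer(bundle$resid$month)]
  } else if (bundle$resid$type == "binomial") {
    1 / bundle$resid$weights
  } else {
    rep(components$resid, length(y))
  }
  V <- V + diag(D, length(y))
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  bhat <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% bhat
  ug <- CoxA %*% t(Zg) %*% Vi %*% r
  uk <- lapply(seq_along(Zk_list), function(k) {
    components$iid[[k]] * t(Zk_list[[k]]) %*% Vi %*% r
  })
  neg2L <- as.numeric(determinant(V, logarithm = TRUE)$modulus +
                        determinant(XtVi %*% X, logarithm = TRUE)$modulus +
                        t(r) %*% Vi %*% r)
  list(fixed = as.numeric(bhat),
       u_d = as.numeric(ug[seq_len(q)]),
       u_i = as.numeric(ug[q + seq_len(q)]),
       iid = lapply(uk, as.numeric),
       neg2L = neg2L)
}

## small logistic-mortality dataset shared across tests
small_binary_sim <- function(seed = 51, n_sires = 12, months = 13,
                             baseline = 0.95) {
  cfg <- sim_config(n_sires = n_sires, dams_per_sire = 3, offspring_per_dam = 5,
                    n_generations = 3, n_batches = 1, rows = 2, levels = 2,
                    months = months, seed = seed)
  pop <- suppressMessages(generate_population(cfg))
  C <- matrix(c(0.1, 0.01, 0.01, 0.03), 2)
  eff <- draw_genetic_effects(pop$ped, C, seed = seed + 1)
  tab <- simulate_mortality(pop, eff, cfg, baseline_survival = baseline,
                            seed = seed + 2)
  list(cfg = cfg, pop = pop, eff = eff, tab = tab, C = C)
}

## small linear-Gaussian dataset (true components known exactly)
small_linear_sim <- function(seed = 71, n_sires = 12) {
  cfg <- sim_config(n_sires = n_sires, dams_per_sire = 3, offspring_per_dam = 5,
                    n_generations = 3, n_batches = 1, rows = 2, levels = 2,
                    seed = seed)
  pop <- suppressMessages(generate_population(cfg))
  cS <- cfg$days_per_month * month_score_sum(cfg$months)
  C_day <- matrix(c(784, 57, 57, 100), 2)
  eff <- draw_genetic_effects(pop$ped, C_day / cS^2, seed = seed + 1)
  tab <- simulate_linear(pop, eff, cfg, seed = seed + 2)
  list(cfg = cfg, pop = pop, eff = eff, tab = tab, C_day = C_day)
}
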