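## manually crafted one-way bundle: y_gj = mu + u_g + e_gj, balanced
make_oneway_bundle <- function(g, r, s2u, s2e, seed = 1, mu = 10) {
  set.seed(seed)
  grp <- factor(rep(seq_len(g), each = r))
  y <- mu + rep(stats::rnorm(g, 0, sqrt(s2u)), each = r) +
    stats::rnorm(g * r, 0, sqrt(s2e))
  n <- length(y)
  spec <- structure(list(id = "STM", parameterization = "animal",
                         time_dependent_ige = FALSE, coding = "days",
                         sire_dam_combined = FALSE, poly_degree = 0),
                    class = "model_spec")
  Z0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(n, 2), dimnames = list(NULL, c("gA", "gB")))
  structure(list(
    spec = spec, y = y,
    X = Matrix::Matrix(matrix(1, n, 1, dimnames = list(NULL, "mu")), sparse = TRUE),
    Zd = Z0, Zi = Z0,
    genetic = list(type = "animal", Ainv = Matrix::Diagonal(2), A = NULL, ped = NULL),
    glevels = c("gA", "gB"),
    terms = list(list(name = "grp", level = grp, cov = rep(1, n))),
    cov_rand = rep(1, n),
    resid = list(type = "iid"),
    meta = data.frame(id = as.character(seq_len(n)), cage = as.character(grp),
                      class = "one", month = 1L, stringsAsFactors = FALSE),
    months = 1L, days_per_month = 30.4), class = "design_bundle")
}

test_that("sparse-MME BLUP equals the dense-covariance oracle across model types", {
  specs <- list(model_spec("STM"),
                model_spec("STM", parameterization = "sire_dam"),
                model_spec("RMM.t"),
                model_spec("RMM.p"),
                model_spec("RMM.t", time_dependent_ige = TRUE))
  for (k in seq_along(specs)) {
    cfg <- sim_config(n_sires = 2, dams_per_sire = 2, offspring_per_dam = 3,
                      n_generations = 2, n_batches = 1, rows = 1, levels = 2,
                      months = 4, seed = 100 + k)
    pop <- suppressMessages(generate_population(cfg))
    C <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
    eff <- draw_genetic_effects(pop$ped, C, seed = k)
    tab <- simulate_mortality(pop, eff, cfg, baseline_survival = 0.85,
                              seed = 200 + k)
    b <- build_design(tab, pop$ped, specs[[k]])
    expect_lte(length(b$y), 50 * 4)
    set.seed(300 + k)
    comp <- list(C = matrix(c(2, 0.4, 0.4, 1), 2) * stats::runif(1, 0.5, 2),
                 iid = stats::setNames(stats::runif(length(b$terms), 0.2, 2),
                                       vapply(b$terms, `[[`, character(1), "name")),
                 resid = if (b$resid$type == "by_month")
                   stats::runif(tab$months, 0.5, 2) else stats::runif(1, 0.5, 2))
    got <- solve_blup(b, comp)
    want <- dense_v_oracle(b, comp)
    expect_lt(max(abs(got$solutions$fixed - want$fixed)), 1e-8)
    expect_lt(max(abs(got$solutions$u_d - want$u_d)), 1e-8)
    expect_lt(max(abs(got$solutions$u_i - want$u_i)), 1e-8)
    for (j in seq_along(want$iid)) {
      expect_lt(max(abs(got$solutions$iid[[j]] - want$iid[[j]])), 1e-8)
    }
    expect_equal(-2 * got$logLik, want$neg2L, tolerance = 1e-8)
  }
})

test_that("random-effect solutions vanish and fixed effects tend to GLS as variances shrink", {
  s <- small_binary_sim(seed = 73, months = 5)
  b <- build_design(s$tab, s$pop$ped, model_spec("STM", parameterization = "sire_dam"))
  eps <- 1e-10
  comp <- list(C = diag(2) * eps, iid = c(cage = eps), resid = 900)
  got <- solve_blup(b, comp)
  expect_lt(max(abs(got$solutions$u_d)), 1e-6)
  expect_lt(max(abs(got$solutions$u_i)), 1e-6)
  expect_lt(max(abs(got$solutions$iid$cage)), 1e-6)
  ## OLS per class (cell means) is the GLS limit
  ols <- tapply(b$y, b$meta$class, mean)
  expect_equal(unname(got$solutions$fixed),
               as.numeric(ols[sub("^class", "", names(got$solutions$fixed))]),
               tolerance = 1e-6)
})

test_that("balanced one-way BLUP shrinks group means by the classical factor", {
  g <- 12; r <- 5; s2u <- 4; s2e <- 9
  b <- make_oneway_bundle(g, r, s2u, s2e, seed = 5)
  comp <- list(C = diag(2) * 1e-10, iid = c(grp = s2u), resid = s2e)
  got <- solve_blup(b, comp)
  ybar <- tapply(b$y, b$meta$cage, mean)[as.character(1:g)]
  f <- s2u / (s2u + s2e / r)
  expect_equal(unname(got$solutions$iid$grp[as.character(1:g)]),
               as.numeric(f * (ybar - mean(b$y))), tolerance = 1e-6)
})

test_that("balanced one-way REML equals the closed-form ANOVA estimators", {
  g <- 40; r <- 6
  b <- make_oneway_bundle(g, r, s2u = 3, s2e = 5, seed = 9)
  f <- reml_fit(b)
  y <- b$y; grp <- b$meta$cage
  msb <- r * stats::var(tapply(y, grp, mean))
  mse <- sum((y - ave(y, grp))^2) / (g * (r - 1))
  expect_equal(f$components$resid, mse, tolerance = 1e-4)
  expect_equal(unname(f$components$iid["grp"]), (msb - mse) / r, tolerance = 1e-4)
  expect_true(f$converged)
})

test_that("a one-variance model is recovered within three analytic SE", {
  g <- 150; r <- 20; s2u <- 1; s2e <- 1
  b <- make_oneway_bundle(g, r, s2u, s2e, seed = 21)
  f <- reml_fit(b)
  var_u_hat <- 2 * ((s2u + s2e / r)^2 / (g - 1) + s2e^2 / (r^2 * g * (r - 1)))
  expect_lt(abs(f$components$iid[["grp"]] - s2u), 3 * sqrt(var_u_hat))
  var_e_hat <- 2 * s2e^2 / (g * (r - 1))
  expect_lt(abs(f$components$resid - s2e), 3 * sqrt(var_e_hat))
  ## the information-matrix SE agrees with the analytic one to first order
  expect_lt(abs(f$se[["grp"]] - sqrt(var_u_hat)) / sqrt(var_u_hat), 0.35)
})

test_that("REML improves on its starting likelihood and satisfies the MME at the optimum", {
  s <- small_linear_sim(seed = 81)
  b <- build_design(s$tab, s$pop$ped, model_spec("STM", parameterization = "sire_dam"))
  prep <- cagesurv:::prep_engine(b)
  th0 <- cagesurv:::default_start(prep)
  l0 <- -cagesurv:::engine_eval(prep, th0, keep = FALSE)$neg2L / 2
  f <- reml_fit(b)
  expect_gte(f$logLik, l0)
  ## solutions returned do satisfy the equations at the returned components
  chk <- solve_blup(b, f$components)
  expect_lt(max(abs(chk$solutions$u_d - f$solutions$u_d)), 1e-8)
})

test_that("the logit model collapses to an intercept GLM when variances vanish", {
  set.seed(31)
  n <- 600
  y <- stats::rbinom(n, 1, 0.72)
  spec <- structure(list(id = "GLMM", parameterization = "animal",
                         time_dependent_ige = FALSE, coding = "survival",
                         sire_dam_combined = FALSE, poly_degree = 0),
                    class = "model_spec")
  Z0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(n, 2), dimnames = list(NULL, c("gA", "gB")))
  grp <- factor(rep(seq_len(n / 4), each = 4))
  b <- structure(list(
    spec = spec, y = y,
    X = Matrix::Matrix(matrix(1, n, 1, dimnames = list(NULL, "mu")), sparse = TRUE),
    Zd = Z0, Zi = Z0,
    genetic = list(type = "animal", Ainv = Matrix::Diagonal(2), A = NULL, ped = NULL),
    glevels = c("gA", "gB"),
    terms = list(list(name = "grp", level = grp, cov = rep(1, n))),
    cov_rand = rep(1, n),
    resid = list(type = "binomial", weights = NULL),
    meta = data.frame(id = as.character(seq_len(n)), cage = as.character(grp),
                      class = "one", month = 1L, stringsAsFactors = FALSE),
    months = 1L, days_per_month = 30.4), class = "design_bundle")
  f <- glmm_pql_fit(b)
  expect_equal(unname(f$solutions$fixed["mu"]), stats::qlogis(mean(y)),
               tolerance = 0.01)
  expect_lt(unname(f$components$iid["grp"]), 0.05)
})

test_that("the PQL path agrees with an independent PQL implementation", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("nlme")
  set.seed(41)
  ns <- 80; off <- 25
  sire <- factor(rep(seq_len(ns), each = off))
  u <- stats::rnorm(ns, 0, sqrt(0.4))
  y <- stats::rbinom(ns * off, 1, stats::plogis(1 + u[as.integer(sire)]))
  n <- length(y)
  spec <- structure(list(id = "GLMM", parameterization = "animal",
                         time_dependent_ige = FALSE, coding = "survival",
                         sire_dam_combined = FALSE, poly_degree = 0),
                    class = "model_spec")
  ## sire effects enter as the "direct" genetic term with A = I
  Zd <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(sire), x = 1,
                             dims = c(n, ns),
                             dimnames = list(NULL, levels(sire)))
  Zi <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(n, ns), dimnames = list(NULL, levels(sire)))
  b <- structure(list(
    spec = spec, y = y,
    X = Matrix::Matrix(matrix(1, n, 1, dimnames = list(NULL, "mu")), sparse = TRUE),
    Zd = Zd, Zi = Zi,
    genetic = list(type = "animal", Ainv = Matrix::Diagonal(ns), A = NULL, ped = NULL),
    glevels = levels(sire),
    terms = list(),
    cov_rand = rep(1, n),
    resid = list(type = "binomial", weights = NULL),
    meta = data.frame(id = as.character(seq_len(n)), cage = as.character(seq_len(n)),
                      class = "one", month = 1L, stringsAsFactors = FALSE),
    months = 1L, days_per_month = 30.4), class = "design_bundle")
  f <- glmm_pql_fit(b)
  ref <- suppressMessages(MASS::glmmPQL(y ~ 1, random = ~ 1 | sire,
                                        family = stats::binomial(),
                                        data = data.frame(y = y, sire = sire),
                                        verbose = FALSE))
  s2_ref <- as.numeric(nlme::VarCorr(ref)[1, 1])
  expect_equal(unname(f$components$C[1, 1]), s2_ref, tolerance = 0.15)
  expect_equal(unname(f$solutions$fixed["mu"]),
               unname(nlme::fixef(ref)), tolerance = 0.05)
})

test_that("breeding values are read out correctly in both parameterizations", {
  s <- small_linear_sim(seed = 91)
  ba <- build_design(s$tab, s$pop$ped, model_spec("STM"))
  fa <- reml_fit(ba)
  ea <- extract_ebv(fa)
  expect_equal(stats::setNames(ea$ebv_d, ea$id), fa$solutions$u_d[ea$id])

  bs <- build_design(s$tab, s$pop$ped, model_spec("STM", parameterization = "sire_dam"))
  fs <- reml_fit(bs)
  es <- extract_ebv(fs)
  ## full sibs share both parents, hence identical sire-dam EBV
  ped <- s$pop$ped
  fam <- paste(ped$sire, ped$dam)[match(es$id, ped$id)]
  dup <- fam[duplicated(fam)][1]
  sibs <- es[fam == dup, ]
  expect_true(nrow(sibs) >= 2)
  expect_lt(max(abs(sibs$ebv_d - sibs$ebv_d[1])), 1e-12)

  ## the two readouts rank animals almost identically on day-scale data
  both <- merge(ea, es, by = "id")
  expect_gt(stats::cor(both$ebv_d.x, both$ebv_d.y), 0.9)
})
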