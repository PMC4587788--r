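test_that("fold plans are balanced, reproducible and class-covering", {
  cages <- data.frame(cage = paste0("c", 1:10),
                      class = rep(c("A", "B"), 5),
                      stringsAsFactors = FALSE)
  f1 <- make_folds(cages, k = 5, seed = 3)
  expect_true(all(table(f1$fold) == 2))
  expect_identical(make_folds(cages, k = 5, seed = 3), f1)
  expect_false(identical(make_folds(cages, k = 5, seed = 4)$fold, f1$fold))

  ## every class present in every training set by construction
  for (f in 1:5) {
    expect_setequal(unique(f1$class[f1$fold != f]), c("A", "B"))
  }
  ## unattainable coverage fails loudly: a class with a single cage and k
  ## folds each needing it in training is fine, but a class whose only cage
  ## is always somewhere means no failure -- force one by k = nrow
  one <- data.frame(cage = c("c1", "c2"), class = c("A", "B"))
  expect_error(make_folds(one, k = 2, seed = 1, max_tries = 5),
               "represented in every training set")

  ## over many seeds each cage visits folds roughly uniformly
  counts <- matrix(0, 10, 5)
  for (s in 1:400) {
    fp <- make_folds(cages, k = 5, seed = s)
    counts[cbind(seq_len(10), fp$fold)] <- counts[cbind(seq_len(10), fp$fold)] + 1
  }
  p <- 1 / 5
  se <- sqrt(p * (1 - p) * 400)
  expect_true(all(abs(counts - 400 * p) < 4 * se))
})

test_that("fixed-effect adjustment returns within-class residuals", {
  days <- data.frame(id = as.character(1:6),
                     class = c("A", "A", "A", "B", "B", "B"),
                     days = c(100, 120, 140, 200, 210, 250),
                     censored = FALSE, stringsAsFactors = FALSE)
  adj <- adjust_observed(days)
  ## hand OLS: class means 120 and 220
  expect_equal(adj$adjusted, c(-20, 0, 20, -20, -10, 30))
  expect_equal(sum(adj$adjusted[1:3]), 0)
  expect_equal(sum(adj$adjusted[4:6]), 0)

  ## censored rows are excluded from the fit and the output
  days$censored[2] <- TRUE
  adj2 <- adjust_observed(days)
  expect_false("2" %in% adj2$id)
  expect_equal(adj2$adjusted[adj2$id == "1"], -20)  # mean(100, 140) = 120
})

test_that("censored ranks follow the average-top-rank rule", {
  ## 5 censored among 10: all censored share (6+7+8+9+10)/5 = 8
  ids <- as.character(1:10)
  adj <- c(sort(stats::runif(5)), rep(NA, 5))
  cens <- c(rep(FALSE, 5), rep(TRUE, 5))
  rk <- rank_with_censoring(ids, adj, cens)
  expect_equal(unique(rk[cens]), 8)
  expect_equal(sort(rk[!cens]), 1:5)

  ## no censoring: plain average ranks
  rk2 <- rank_with_censoring(ids, stats::rnorm(10), rep(FALSE, 10))
  expect_setequal(rk2, 1:10)

  ## everyone censored: everyone at (k + 1)/2
  rk3 <- rank_with_censoring(ids, rep(NA_real_, 10), rep(TRUE, 10))
  expect_equal(unique(rk3), 5.5)

  ## invariant to permuting the censored individuals' inputs
  ord <- c(1:5, sample(6:10))
  rk4 <- rank_with_censoring(ids[ord], adj[ord], cens[ord])
  expect_equal(rk4[match(ids, ids[ord])], rk)
})

test_that("predicted phenotypes combine own direct and mates' indirect EBV", {
  ebv <- data.frame(id = c("f", "m1", "m2", "m3"),
                    ebv_d = c(3, 9, 9, 9),
                    ebv_i = c(99, 1, -2, 0.5), stringsAsFactors = FALSE)
  expect_equal(predict_phenotypes(ebv, "f", "m1,m2,m3"), 2.5)

  ## all-zero EBV: complete ties
  ebv0 <- ebv; ebv0$ebv_d <- 0; ebv0$ebv_i <- 0
  p0 <- predict_phenotypes(ebv0, c("f", "m1"), c("m2,m3", "m2,m3"))
  expect_equal(p0, c(0, 0))

  ## zero indirect EBV: ranking equals the direct-EBV ranking
  ebv1 <- ebv; ebv1$ebv_i <- 0
  ebv1$ebv_d <- c(3, 1, 4, 2)
  ids <- ebv1$id
  mates <- c("m1,m2,m3", "f,m2,m3", "f,m1,m3", "f,m1,m2")
  p1 <- predict_phenotypes(ebv1, ids, mates)
  expect_equal(rank(p1), rank(ebv1$ebv_d))
})

test_that("fold-stratified rank correlation matches hand computation and limits", {
  pairs <- data.frame(fold = rep(1:2, each = 5),
                      obs_rank = c(1:5, 1:5),
                      pred_rank = c(1:5, 1:5))
  expect_equal(rank_correlation(pairs)$correlation, 1)
  pairs$pred_rank <- c(5:1, 5:1)
  expect_equal(rank_correlation(pairs)$correlation, -1)

  ## hand-built example: centre by fold means, pooled Pearson
  pairs2 <- data.frame(fold = rep(1:2, each = 5),
                       obs_rank = c(1, 2, 3, 4, 5, 2, 1, 3, 5, 4),
                       pred_rank = c(2, 1, 3, 5, 4, 1, 2, 4, 3, 5))
  o <- pairs2$obs_rank - ave(pairs2$obs_rank, pairs2$fold)
  p <- pairs2$pred_rank - ave(pairs2$pred_rank, pairs2$fold)
  expect_equal(rank_correlation(pairs2)$correlation, stats::cor(o, p))
  rc <- rank_correlation(pairs2)
  expect_length(rc$per_fold, 2)
  expect_true(is.finite(rc$se))
  expect_error(rank_correlation(pairs2[pairs2$fold == 1, ]), "2 folds")
})

test_that("accuracy bound and approximate accuracy reproduce the worked arithmetic", {
  ## lines with direct SD 28 / indirect SD 10 / phenotypic SD 107 and
  ## 41 / 16 / 135, cage size 4
  expect_equal(round(sqrt_r2(28^2, 10^2, 107^2, 4), 2), 0.31)
  expect_equal(round(sqrt_r2(41^2, 16^2, 135^2, 4), 2), 0.37)
  expect_equal(sqrt_r2(0, 0, 107^2, 4), 0)

  b <- sqrt_r2(28^2, 10^2, 107^2, 4)
  expect_equal(round(approx_accuracy(0.135, b), 2), 0.44)
  expect_equal(round(approx_accuracy(0.162, b), 2), 0.53)
  expect_equal(approx_accuracy(b, b), 1)
  expect_error(approx_accuracy(0.1, 0), "positive")
})

test_that("cross-validation runs end-to-end and behaves sanely on strong signal", {
  ## linear data with a strong genetic share: correlations should be clearly
  ## positive and accuracy in [0, 1 + noise]
  cfg <- sim_config(n_sires = 16, dams_per_sire = 4, offspring_per_dam = 5,
                    n_generations = 3, n_batches = 1, rows = 2, levels = 2,
                    seed = 131)
  pop <- suppressMessages(generate_population(cfg))
  cS <- cfg$days_per_month * month_score_sum(cfg$months)
  C_day <- matrix(c(2500, 100, 100, 300), 2)
  eff <- draw_genetic_effects(pop$ped, C_day / cS^2, seed = 132)
  tab <- simulate_linear(pop, eff, cfg, seed = 133)
  cv <- run_crossval(tab, pop$ped, model_spec("STM", parameterization = "sire_dam"),
                     k = 5, seed = 7)
  expect_gt(cv$correlation, 0.1)
  expect_true(all(table(cv$pairs$fold) >= 3))
  p <- stm_day_params(structure(list(components = cv$components,
                                     bundle = list(spec = model_spec("STM", parameterization = "sire_dam"))),
                                class = "fit_result"))
  acc <- approx_accuracy(cv$correlation, sqrt_r2(p$sigma2_ad, p$sigma2_ai, p$sigma2_p))
  expect_gt(acc, 0)
  expect_lt(acc, 1.15)
})
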