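test_that("population generator honours the family and cage structure", {
  cfg <- sim_config(n_sires = 2, dams_per_sire = 2, offspring_per_dam = 4,
                    n_generations = 2, n_batches = 1, rows = 1, levels = 1,
                    seed = 3)
  pop <- generate_population(cfg)
  cohort <- pop$ped$id[pop$ped$generation == 2]
  expect_length(cohort, 16)                       # 2 sires x 2 dams x 4
  expect_equal(length(unique(pop$cages$cage)), 4) # 16 hens / 4 per cage
  expect_setequal(pop$cages$member, cohort)

  ## the commercial-scale configuration lands near 36 x 8 x 12.3 per batch
  cfgW <- sim_config(seed = 5)
  popW <- suppressMessages(generate_population(cfgW))
  per_batch <- sum(popW$ped$generation == cfgW$n_generations) / cfgW$n_batches
  expect_lt(abs(per_batch - 36 * 8 * 12.3) / (36 * 8 * 12.3), 0.10)
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_sires = 4, dams_per_sire = 2, offspring_per_dam = 5,
                    n_generations = 3, n_batches = 2, rows = 2, levels = 2,
                    seed = 11)
  p1 <- suppressMessages(generate_population(cfg))
  p2 <- suppressMessages(generate_population(cfg))
  expect_identical(as.data.frame(p1$ped), as.data.frame(p2$ped))
  expect_identical(p1$cages, p2$cages)

  s <- small_binary_sim(seed = 31)
  s2 <- small_binary_sim(seed = 31)
  expect_identical(s$tab$monthly, s2$tab$monthly)
  expect_identical(s$tab$days, s2$tab$days)
})

test_that("Mendelian sampling reproduces the C (x) A covariance structure", {
  ## founders only, diagonal C: sample covariance within 3 SE
  n <- 4000
  ped <- pedigree(as.character(seq_len(n)), rep("0", n), rep("0", n))
  C <- matrix(c(2, 0, 0, 0.5), 2)
  eff <- draw_genetic_effects(ped, C, seed = 13)
  S <- stats::cov(eff)
  se_var <- sqrt(2 / n)  # relative SE of a normal variance estimate
  expect_lt(abs(S[1, 1] - 2) / 2, 3 * se_var)
  expect_lt(abs(S[2, 2] - 0.5) / 0.5, 3 * se_var)
  expect_lt(abs(S[1, 2]) / sqrt(2 * 0.5), 3 / sqrt(n) * 3)

  ## zero C gives exactly zero effects
  eff0 <- draw_genetic_effects(ped, matrix(0, 2, 2), seed = 13)
  expect_true(all(eff0 == 0))

  ## parent-offspring regression of the direct effect is ~ 0.5
  np <- 4000
  ped2 <- pedigree(c(paste0("s", 1:np), paste0("d", 1:np), paste0("k", 1:np)),
                   c(rep("0", 2 * np), paste0("s", 1:np)),
                   c(rep("0", 2 * np), paste0("d", 1:np)))
  C2 <- matrix(c(1, 0.2, 0.2, 0.4), 2)
  e2 <- draw_genetic_effects(ped2, C2, seed = 17)
  b <- stats::coef(stats::lm(e2[paste0("k", 1:np), "a_d"] ~ e2[paste0("s", 1:np), "a_d"]))[2]
  expect_lt(abs(b - 0.5), 3 * 1.5 / sqrt(np))

  expect_error(draw_genetic_effects(ped, matrix(c(1, 2, 2, 1), 2), seed = 1),
               "positive semidefinite")
})

test_that("mortality process obeys its closed-form and monotonicity checks", {
  ## all variances zero, baseline survival 1: nobody dies
  cfg <- sim_config(n_sires = 2, dams_per_sire = 2, offspring_per_dam = 8,
                    n_generations = 2, n_batches = 1, rows = 1, levels = 1,
                    months = 6, seed = 19)
  pop <- generate_population(cfg)
  eff0 <- draw_genetic_effects(pop$ped, matrix(0, 2, 2), seed = 1)
  tab1 <- simulate_mortality(pop, eff0, cfg, baseline_survival = 1,
                             class_sd = 0, sigma2_cage = 0, sigma2_pe = 0,
                             seed = 2)
  expect_true(all(tab1$days$censored))
  expect_true(all(tab1$monthly$value == 1))

  ## flat baseline p: survivor fraction ~ p^T within 3 binomial SE
  cfg2 <- sim_config(n_sires = 25, dams_per_sire = 8, offspring_per_dam = 13,
                     n_generations = 2, n_batches = 1, rows = 1, levels = 1,
                     months = 6, seed = 23)
  pop2 <- suppressMessages(generate_population(cfg2))
  eff0 <- draw_genetic_effects(pop2$ped, matrix(0, 2, 2), seed = 1)
  p <- 0.93
  tab2 <- simulate_mortality(pop2, eff0, cfg2, baseline_survival = p,
                             class_sd = 0, sigma2_cage = 0, sigma2_pe = 0,
                             seed = 3)
  nh <- nrow(tab2$days)
  expect_gt(nh, 2000)
  exp_frac <- p^6
  se <- sqrt(exp_frac * (1 - exp_frac) / nh)
  expect_lt(abs(mean(tab2$days$censored) - exp_frac), 3 * se)

  ## harmful cage mates shorten a hen's life on average
  cfgm <- sim_config(n_sires = 2, dams_per_sire = 2, offspring_per_dam = 4,
                     n_generations = 2, n_batches = 1, rows = 1, levels = 1,
                     months = 8, seed = 29)
  popm <- generate_population(cfgm)
  effn <- draw_genetic_effects(popm$ped, matrix(0, 2, 2), seed = 1)
  effbad <- effn
  focal <- popm$cages$member[1]
  mates <- popm$cages$member[2:4]
  effbad[mates, "a_i"] <- -2
  mean_days <- function(effx, seeds) {
    mean(vapply(seeds, function(s) {
      simulate_mortality(popm, effx, cfgm, baseline_survival = 0.93,
                         class_sd = 0, sigma2_cage = 0, sigma2_pe = 0,
                         seed = s)$days$days[1]
    }, numeric(1)))
  }
  seeds <- 1:150
  expect_lt(mean_days(effbad, seeds), mean_days(effn, seeds))
})

test_that("monthly strings are monotone and consistent with the day view", {
  s <- small_binary_sim(seed = 37)
  tab <- s$tab
  mono <- tapply(tab$monthly$value, tab$monthly$id, function(z) all(diff(z) <= 0))
  expect_true(all(mono))
  expect_true(all(table(tab$monthly$id) == tab$months))
  ## censored record is the study cutoff; deaths within c of last month alive
  expect_true(all(tab$days$days[tab$days$censored] == tab$cutoff_days))
  dm <- tab$truth$death_month
  dead <- !is.na(dm)
  last_alive <- dm[dead] - 1
  dd <- tab$days$days[match(names(dm)[dead], tab$days$id)]
  expect_true(all(abs(dd - tab$days_per_month * last_alive) < tab$days_per_month + 0.5))
})

test_that("alive-mate bookkeeping drops dead mates and freezes at focal death", {
  s <- small_binary_sim(seed = 41)
  tab <- s$tab
  dm <- tab$truth$death_month
  mo <- tab$monthly
  ml <- strsplit(mo$mates, ",", fixed = TRUE)
  for (r in sample(nrow(mo), 400)) {
    i <- mo$id[r]; m <- mo$month[r]
    eff_m <- if (!is.na(dm[i])) min(m, dm[i]) else m
    cage_members <- tab$days$id[tab$days$cage == mo$cage[r]]
    expected <- setdiff(cage_members[is.na(dm[cage_members]) |
                                       dm[cage_members] >= eff_m], i)
    expect_setequal(ml[[r]], expected)
  }
})

test_that("censoring scenarios behave as specified", {
  s <- small_binary_sim(seed = 43)
  tab <- s$tab
  expect_identical(apply_censoring_scenario(tab, "all_at_end"), tab)

  tab2 <- apply_censoring_scenario(tab, "half_at_midpoint", seed = 7)
  ns <- sum(tab$days$censored)
  expect_length(tab2$midpoint_censored, floor(ns / 2))
  half <- ceiling(tab$months / 2)
  mid_rows <- tab2$monthly[tab2$monthly$id %in% tab2$midpoint_censored, ]
  expect_true(all(mid_rows$month <= half))
  expect_true(all(table(mid_rows$id) == half))
  expect_equal(unique(tab2$days$days[tab2$days$id %in% tab2$midpoint_censored]),
               round(tab$days_per_month * half))
  ## truncated strings stay monotone
  mono <- tapply(tab2$monthly$value, tab2$monthly$id, function(z) all(diff(z) <= 0))
  expect_true(all(mono))
  expect_error(apply_censoring_scenario(tab, "nonsense"))
})

test_that("with no indirect variance, survival is exchangeable across groupings", {
  ## same genetic direct effects, two different random cage allocations:
  ## the survival-day distributions should be indistinguishable
  base <- function(layout_seed) {
    cfg <- sim_config(n_sires = 20, dams_per_sire = 4, offspring_per_dam = 6,
                      n_generations = 2, n_batches = 1, rows = 1, levels = 1,
                      months = 8, seed = layout_seed)
    pop <- suppressMessages(generate_population(cfg))
    C <- matrix(c(0.3, 0, 0, 0), 2)
    eff <- draw_genetic_effects(pop$ped, C, seed = 99)
    simulate_mortality(pop, eff, cfg, baseline_survival = 0.93,
                       class_sd = 0, sigma2_cage = 0, sigma2_pe = 0,
                       seed = 77)$days$days
  }
  d1 <- base(101); d2 <- base(202)
  ks <- suppressWarnings(stats::ks.test(d1, d2))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated datasets round-trip through the CSV directory format", {
  s <- small_binary_sim(seed = 47)
  d <- file.path(tempdir(), "simdata_test")
  write_simdata(s$pop$ped, s$pop, s$tab, d)
  back <- read_simdata(d)
  expect_equal(as.data.frame(back$ped)[, 1:3], as.data.frame(s$pop$ped)[, 1:3])
  expect_equal(back$table$monthly$value, s$tab$monthly$value)
  expect_equal(back$table$days$days, s$tab$days$days)
  expect_equal(back$table$months, s$tab$months)
  unlink(d, recursive = TRUE)
})
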