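#' Simulation configuration
#'
#' Study conditions for the synthetic layer population. Defaults mirror the
#' commercial setting the package models: per batch, each of 36 sires is mated
#' to 8 dams producing on average 12.3 female offspring; two batches are housed
#' in two laying houses; hens are randomly allocated to 4-bird battery cages
#' nested in fixed-effect classes (house x row x level); the laying period
#' spans 13 months of 30.4 days with all survivors right-censored at 416 days.
#'
#' @param n_sires sires per generation (and per batch mating set).
#' @param dams_per_sire dams mated to each sire.
#' @param offspring_per_dam mean number of female offspring per dam in the
#'   phenotyped generation; the cohort total is `round(n_dams * mean)` and
#'   litter sizes are multinomial over dams (Poisson conditioned on the
#'   total).
#' @param n_generations pedigree depth; generations before the last carry the
#'   selected breeders only.
#' @param n_batches hatches; each batch goes to its own laying house.
#' @param cage_size hens per cage (n).
#' @param rows,levels cage rows and tiers per laying house; the fixed-effect
#'   class is the house x row x level combination.
#' @param months laying period length T in months.
#' @param days_per_month factor c translating months to days.
#' @param cutoff_days censoring day for survivors.
#' @param seed integer seed; everything the generators draw is reproducible
#'   from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 36, dams_per_sire = 8, offspring_per_dam = 12.3,
                       n_generations = 5, n_batches = 2, cage_size = 4,
                       rows = 8, levels = 3, months = 13,
                       days_per_month = 30.4, cutoff_days = 416, seed = 1) {
  stopifnot(n_sires >= 1, dams_per_sire >= 1, offspring_per_dam > 0,
            n_generations >= 1, n_batches >= 1, cage_size >= 2, months >= 1,
            days_per_month > 0)
  structure(list(n_sires = n_sires, dams_per_sire = dams_per_sire,
                 offspring_per_dam = offspring_per_dam,
                 n_generations = n_generations, n_batches = n_batches,
                 cage_size = cage_size, rows = rows, levels = levels,
                 months = months, days_per_month = days_per_month,
                 cutoff_days = cutoff_days, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a pedigree and cage layout
#'
#' Builds `n_generations` of pedigree (breeders only before the last
#' generation, full female cohort in the last), then randomly allocates the
#' final-generation hens of each batch to full cages of `cage_size` within the
#' fixed-effect classes of that batch's laying house. Surplus hens that do not
#' fill a complete cage are dropped (count reported via a message).
#'
#' @param config a [sim_config()].
#' @return list with elements `ped` (a [pedigree()]), `cages` (data.frame:
#'   `cage`, `class`, `member`, `slot`) and `dropped` (ids not caged).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_dams <- config$n_sires * config$dams_per_sire
  nid <- 0L
  new_ids <- function(k) {
    out <- as.character(nid + seq_len(k)); nid <<- nid + k; out
  }
  id <- character(0); sire <- character(0); dam <- character(0)
  gen <- integer(0); sex <- character(0)
  push <- function(ids, s, d, g, sx) {
    id <<- c(id, ids); sire <<- c(sire, s); dam <<- c(dam, d)
    gen <<- c(gen, rep(g, length(ids))); sex <<- c(sex, rep_len(sx, length(ids)))
  }
  ## generation 1: unrelated founders
  sires_g <- new_ids(config$n_sires)
  push(sires_g, rep(NA, config$n_sires), rep(NA, config$n_sires), 1L, "M")
  dams_g <- new_ids(n_dams)
  push(dams_g, rep(NA, n_dams), rep(NA, n_dams), 1L, "F")

  for (g in seq_len(config$n_generations - 1L)) {
    last <- g == config$n_generations - 1L
    ## random mating among current breeders: each dam drawn to a sire
    mate_of <- sample(rep_len(sires_g, length(dams_g)))
    names(mate_of) <- dams_g
    if (!last) {
      ## next generation's breeders, each from a random current mating
      ns <- config$n_sires; ndm <- n_dams
      md <- sample(dams_g, ns + ndm, replace = TRUE)
      ids <- new_ids(ns + ndm)
      push(ids, unname(mate_of[md]), md, g + 1L,
           c(rep("M", ns), rep("F", ndm)))
      sires_g <- ids[seq_len(ns)]
      dams_g <- ids[ns + seq_len(ndm)]
    } else {
      ## final generation: full female cohort, per batch
      offspring <- vector("list", config$n_batches)
      for (b in seq_len(config$n_batches)) {
        mate_b <- sample(rep_len(sires_g, length(dams_g)))
        names(mate_b) <- dams_g
        ## litter sizes: total fixed at round(n_dams * mean), spread
        ## multinomially over dams (Poisson conditioned on its total)
        tot <- round(length(dams_g) * config$offspring_per_dam)
        k <- as.integer(stats::rmultinom(1, tot, rep(1, length(dams_g))))
        d_rep <- rep(dams_g, k)
        ids <- new_ids(length(d_rep))
        push(ids, unname(mate_b[d_rep]), d_rep, g + 1L, "F")
        offspring[[b]] <- ids
      }
    }
  }
  if (config$n_generations == 1L) {
    ## degenerate: founders themselves are the phenotyped cohort
    offspring <- list(dams_g)[rep(1L, config$n_batches)]
  }
  ped <- pedigree(id, sire, dam, generation = gen, sex = sex)

  ## cage allocation: per batch (house), random full cages, random class
  n <- config$cage_size
  cage_rows <- list()
  dropped <- character(0)
  cage_no <- 0L
  for (b in seq_len(config$n_batches)) {
    hens <- sample(offspring[[b]])
    n_cages <- length(hens) %/% n
    surplus <- length(hens) %% n
    if (surplus > 0) dropped <- c(dropped, hens[n * n_cages + seq_len(surplus)])
    if (n_cages == 0L) next
    classes <- sprintf("h%d.r%d.l%d", b,
                       sample.int(config$rows, n_cages, replace = TRUE),
                       sample.int(config$levels, n_cages, replace = TRUE))
    cage_rows[[b]] <- data.frame(
      cage = sprintf("c%d", cage_no + rep(seq_len(n_cages), each = n)),
      class = rep(classes, each = n),
      member = hens[seq_len(n * n_cages)],
      slot = rep(seq_len(n), n_cages),
      stringsAsFactors = FALSE)
    cage_no <- cage_no + n_cages
  }
  if (length(dropped)) {
    message(sprintf("dropped %d surplus hen(s) that did not fill a cage",
                    length(dropped)))
  }
  list(ped = ped, cages = do.call(rbind, cage_rows), dropped = dropped)
}

#' Draw direct and indirect genetic effects down a pedigree
#'
#' Recursive Mendelian sampling: founders are drawn from N(0, C); a
#' non-founder's pair of effects is the mean of its known parents' pairs plus
#' a Mendelian-sampling deviation N(0, d_i C), with d_i the within-family
#' variance from [inbreeding()]. The resulting effects have covariance
#' C (x) A over the pedigree.
#'
#' @param ped a [pedigree()].
#' @param C 2x2 PSD genetic covariance matrix
#'   (direct variance, direct-indirect covariance, indirect variance).
#' @param seed integer seed.
#' @return numeric matrix (pedigree order) with columns `a_d`, `a_i` and ids
#'   as rownames.
#' @export
draw_genetic_effects <- function(ped, C, seed = 1) {
  stopifnot(inherits(ped, "pedigree"))
  C <- as.matrix(C)
  stopifnot(identical(dim(C), c(2L, 2L)))
  if (abs(C[1, 2] - C[2, 1]) > 1e-12) stop("C must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("genetic covariance matrix C must be positive semidefinite")
  }
  set.seed(seed)
  n <- nrow(ped)
  si <- attr(ped, "sire_idx")
  di <- attr(ped, "dam_idx")
  dv <- inbreeding(ped, ids = character(0))$d
  L <- t(chol(C + diag(1e-14 * max(1, sum(diag(C))), 2)))
  Z <- matrix(stats::rnorm(2L * n), n, 2L) %*% t(L)  # N(0, C) deviates
  eff <- matrix(0, n, 2L, dimnames = list(ped$id, c("a_d", "a_i")))
  if (sum(abs(C)) == 0) return(eff)
  for (i in seq_len(n)) {
    pa <- c(si[i], di[i])
    pa <- pa[pa > 0L]
    pmean <- if (length(pa)) colSums(eff[pa, , drop = FALSE]) / 2 else c(0, 0)
    eff[i, ] <- pmean + sqrt(dv[i]) * Z[i, ]
  }
  eff
}

logit_clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

#' Simulate monthly mortality with social genetic effects (binary generator)
#'
#' Month-by-month logistic survival process: in month m a live hen i survives
#' with probability `plogis(mu_m + class + a_D,i + sum of a_I over cage mates
#' alive at the start of the month + cage + pe)`. Deaths are applied
#' simultaneously at month end, so a hen that dies in month m still expresses
#' its indirect effect on its cage mates throughout month m. Survivors at
#' month T are right-censored at `cutoff_days`.
#'
#' @param pop output of [generate_population()].
#' @param effects matrix from [draw_genetic_effects()] (logit scale).
#' @param config the [sim_config()] used to build `pop`.
#' @param baseline_survival scalar or length-T vector of baseline monthly
#'   survival probabilities.
#' @param class_sd SD of fixed class deviations on the logit scale.
#' @param sigma2_cage variance of the random cage intercept (logit scale).
#' @param sigma2_pe variance of the permanent-environment intercept.
#' @param seed integer seed (mortality process only; effects carry their own).
#' @param drop_other_rate fraction of hens removed for unrelated reasons
#'   (their own records are dropped but their ids remain in cage-mate
#'   bookkeeping until their death month); default off.
#' @return a `survival_table`: list with `monthly` (long 0/1 records with the
#'   alive-mate set at each month start), `days` (day-scale view), and the
#'   time constants. Monthly records use survival-function coding (a record
#'   for every month, 0 after death).
#' @export
simulate_mortality <- function(pop, effects, config,
                               baseline_survival = 0.96,
                               class_sd = 0.25,
                               sigma2_cage = 0.22,
                               sigma2_pe = 0.17,
                               seed = 1,
                               drop_other_rate = 0) {
  stopifnot(inherits(config, "sim_config"))
  Tm <- config$months
  p0 <- rep_len(baseline_survival, Tm)
  stopifnot(all(p0 > 0), all(p0 <= 1))
  set.seed(seed + 1L)
  cages <- pop$cages
  cage_ids <- unique(cages$cage)
  cagef <- factor(cages$cage, levels = cage_ids)
  classes_by_cage <- cages$class[match(cage_ids, cages$cage)]
  uclass <- sort(unique(classes_by_cage))
  class_eff <- stats::setNames(stats::rnorm(length(uclass), 0, class_sd), uclass)
  cage_eff <- stats::setNames(
    stats::rnorm(length(cage_ids), 0, sqrt(sigma2_cage)), cage_ids)
  ids <- cages$member
  nh <- length(ids)
  pe <- stats::rnorm(nh, 0, sqrt(sigma2_pe))
  a_d <- unname(effects[ids, "a_d"])
  a_i <- unname(effects[ids, "a_i"])
  base_eta <- class_eff[cages$class] + a_d + cage_eff[cages$cage] + pe

  ## month-by-month process; deaths applied simultaneously at month end
  death <- rep(NA_integer_, nh)
  alive <- rep(TRUE, nh)
  mu_m <- stats::qlogis(p0)
  for (m in seq_len(Tm)) {
    cage_ai <- rowsum(a_i * alive, cagef)[, 1L]  # per-cage sum over live hens
    mate_sum <- cage_ai[as.integer(cagef)] - a_i * alive
    p_surv <- logit_clamp(stats::plogis(mu_m[m] + base_eta + mate_sum))
    die_now <- alive & (stats::runif(nh) > p_surv)
    death[die_now] <- m
    alive[die_now] <- FALSE
  }

  ## drop-for-other-reasons hook: focal records removed, ids stay in mate sets
  dropped_other <- character(0)
  if (drop_other_rate > 0) {
    k <- round(drop_other_rate * nh)
    if (k > 0) dropped_other <- sample(ids, k)
  }

  tab <- build_survival_table(cages, death, config)
  tab$truth <- list(class_eff = as.list(class_eff),
                    sigma2_cage = sigma2_cage, sigma2_pe = sigma2_pe,
                    baseline_survival = p0,
                    death_month = stats::setNames(death, ids))
  if (length(dropped_other)) {
    tab$monthly <- tab$monthly[!(tab$monthly$id %in% dropped_other), ]
    tab$days <- tab$days[!(tab$days$id %in% dropped_other), ]
    tab$dropped_other <- dropped_other
  }
  tab
}

## Assemble the long monthly table and the day-scale view from death months.
## Alive-mate bookkeeping: the mate set of focal i at month m contains cage
## mate j iff j was alive at the start of month min(m, death month of i) --
## i.e. dead mates are dropped from month (their death month + 1) onward, and
## after the focal's own death the composition is frozen at its death-time set.
build_survival_table <- function(cages, death, config) {
  Tm <- config$months
  c_day <- config$days_per_month
  ids <- cages$member
  nh <- length(ids)
  n <- config$cage_size
  ## slot matrices: one row per cage
  ord <- order(match(cages$cage, unique(cages$cage)), cages$slot)
  stopifnot(identical(ord, seq_len(nh)))  # generate_population emits in order
  idm <- matrix(ids, ncol = n, byrow = TRUE)
  dm <- matrix(death[match(as.vector(t(idm)), ids)], ncol = n, byrow = TRUE)
  n_cages <- nrow(idm)

  monthly <- vector("list", n)
  for (s in seq_len(n)) {
    ds <- dm[, s]
    rows <- data.frame(
      id = rep(idm[, s], each = Tm),
      cage = rep(cages$cage[seq(s, nh, by = n) * 0 +
                              (seq_len(n_cages) - 1L) * n + 1L], each = Tm),
      class = rep(cages$class[(seq_len(n_cages) - 1L) * n + 1L], each = Tm),
      month = rep(seq_len(Tm), n_cages),
      stringsAsFactors = FALSE)
    rows$value <- as.integer(is.na(rep(ds, each = Tm)) |
                               rep(ds, each = Tm) > rows$month)
    ## mate sets, vectorized over cages for each month
    mates_m <- matrix("", n_cages, Tm)
    others <- setdiff(seq_len(n), s)
    for (m in seq_len(Tm)) {
      eff_m <- ifelse(is.na(ds), m, pmin(m, ds))
      parts <- matrix("", n_cages, length(others))
      for (k in seq_along(others)) {
        o <- others[k]
        inc <- is.na(dm[, o]) | dm[, o] >= eff_m
        parts[inc, k] <- idm[inc, o]
      }
      str <- do.call(paste, c(split(parts, col(parts)), sep = ","))
      str <- gsub(",{2,}", ",", str)
      str <- gsub("^,+|,+$", "", str)
      mates_m[, m] <- str
    }
    rows$mates <- as.vector(t(mates_m))
    monthly[[s]] <- rows
  }
  monthly <- do.call(rbind, monthly)
  monthly <- monthly[order(match(monthly$id, ids), monthly$month), ]
  rownames(monthly) <- NULL

  days <- data.frame(
    id = ids,
    cage = cages$cage,
    class = cages$class,
    days = ifelse(is.na(death), config$cutoff_days, round(c_day * death)),
    censored = is.na(death),
    stringsAsFactors = FALSE)
  structure(list(monthly = monthly, days = days, months = Tm,
                 days_per_month = c_day, cutoff_days = config$cutoff_days,
                 coding = "survival"),
            class = "survival_table")
}

#' @export
print.survival_table <- function(x, ...) {
  cat(sprintf("survival_table: %d hens, %d monthly records (%s coding), %d censored\n",
              nrow(x$days), nrow(x$monthly), x$coding, sum(x$days$censored)))
  invisible(x)
}

#' Apply a censoring scenario to a survival table
#'
#' `"all_at_end"` leaves the table unchanged (every survivor censored at the
#' study cutoff). `"half_at_midpoint"` additionally censors a random half of
#' the eventual survivors at month `ceiling(T/2)`: their monthly records are
#' truncated there and their day-scale record becomes the censoring day
#' (rounded `c * ceiling(T/2)`), still flagged censored.
#'
#' @param table a `survival_table`.
#' @param scheme `"all_at_end"` or `"half_at_midpoint"`.
#' @param seed integer seed for the random half.
#' @return a `survival_table`.
#' @export
apply_censoring_scenario <- function(table, scheme = c("all_at_end", "half_at_midpoint"),
                                     seed = 1) {
  stopifnot(inherits(table, "survival_table"))
  scheme <- match.arg(scheme)
  if (scheme == "all_at_end") return(table)
  set.seed(seed + 2L)
  half_month <- ceiling(table$months / 2)
  surv_ids <- table$days$id[table$days$censored]
  k <- floor(length(surv_ids) / 2)
  mid <- sample(surv_ids, k)
  table$monthly <- table$monthly[!(table$monthly$id %in% mid &
                                     table$monthly$month > half_month), ]
  sel <- table$days$id %in% mid
  table$days$days[sel] <- round(table$days_per_month * half_month)
  table$censoring_scheme <- scheme
  table$midpoint_censored <- mid
  table
}

#' Simulate continuous monthly records from the random-regression model
#'
#' Linear-Gaussian companion generator used for exact parameter-recovery work:
#' monthly records follow the random-regression-on-time equation directly
#' (class mean curve + (own direct slope + static cage-mate indirect slopes) *
#' t_m + cage-month + cage slope * t_m + permanent-environment slope * t_m +
#' month-specific residual), with no death process, and the day-scale view is
#' exactly `c * sum of monthly records`. Under this generator both the
#' day-scale linear model and the monthly random-regression model are
#' correctly specified and the monthly-to-days variance map is exact.
#'
#' Slope-scale variance defaults are the day-scale parameters
#' `sigma2 / (c S)^2` (genetic, cage-slope, PE) or `sigma2 / (c^2 T)`
#' (cage-month, residual), with `S = sum(t_m)`; the day-scale defaults mirror
#' a commercial White Leghorn line (direct SD 28 d, indirect SD 10 d,
#' covariance 57 d^2, phenotypic SD ~107 d).
#'
#' @param pop output of [generate_population()].
#' @param effects matrix from [draw_genetic_effects()] on the slope scale.
#' @param config the [sim_config()].
#' @param sigma2_cage_month variance of the iid cage-month effect.
#' @param sigma2_cage_slope variance of the random cage regression on time.
#' @param sigma2_pe_slope variance of the permanent-environment regression.
#' @param resid scalar or length-T vector of monthly residual variances.
#' @param class_sd SD of the class-specific mean-curve level (per month).
#' @param seed integer seed.
#' @return a `survival_table` with `coding = "linear"`; `days$days` holds the
#'   continuous day-scale records (`censored` all `FALSE`).
#' @export
simulate_linear <- function(pop, effects, config,
                            sigma2_cage_month = NULL,
                            sigma2_cage_slope = NULL,
                            sigma2_pe_slope = NULL,
                            resid = NULL,
                            class_sd = 0.3,
                            seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  Tm <- config$months
  c_day <- config$days_per_month
  tm <- seq_len(Tm)
  S <- sum(tm)
  cs2 <- (c_day * S)^2
  if (is.null(sigma2_cage_month)) sigma2_cage_month <- 500 / (c_day^2 * Tm)
  if (is.null(sigma2_cage_slope)) sigma2_cage_slope <- 650 / cs2
  if (is.null(sigma2_pe_slope)) sigma2_pe_slope <- 1200 / cs2
  if (is.null(resid)) resid <- 8015 / (c_day^2 * Tm)
  resid <- rep_len(resid, Tm)
  set.seed(seed + 3L)
  cages <- pop$cages
  cagef <- factor(cages$cage, levels = unique(cages$cage))
  ids <- cages$member
  nh <- length(ids)
  n_cages <- nlevels(cagef)
  uclass <- sort(unique(cages$class))
  class_lev <- matrix(stats::rnorm(length(uclass) * Tm, 0, class_sd),
                      length(uclass), Tm, dimnames = list(uclass, NULL))
  cage_slope <- stats::rnorm(n_cages, 0, sqrt(sigma2_cage_slope))
  cage_month <- matrix(stats::rnorm(n_cages * Tm, 0, sqrt(sigma2_cage_month)),
                       n_cages, Tm)
  pe <- stats::rnorm(nh, 0, sqrt(sigma2_pe_slope))
  a_d <- unname(effects[ids, "a_d"])
  a_i <- unname(effects[ids, "a_i"])
  cage_ai <- rowsum(a_i, cagef)[, 1L]
  mate_sum <- cage_ai[as.integer(cagef)] - a_i
  g_slope <- a_d + mate_sum

  ## records: nh x T
  y <- class_lev[match(cages$class, uclass), , drop = FALSE] +
    outer(g_slope + pe + cage_slope[as.integer(cagef)], tm) +
    cage_month[as.integer(cagef), , drop = FALSE] +
    matrix(stats::rnorm(nh * Tm, 0, rep(sqrt(resid), each = nh)), nh, Tm)

  mates_static <- vapply(seq_len(nh), function(i) {
    same <- which(as.integer(cagef) == as.integer(cagef)[i])
    paste(ids[setdiff(same, i)], collapse = ",")
  }, character(1))
  monthly <- data.frame(
    id = rep(ids, each = Tm),
    cage = rep(cages$cage, each = Tm),
    class = rep(cages$class, each = Tm),
    month = rep(tm, nh),
    value = as.vector(t(y)),
    mates = rep(mates_static, each = Tm),
    stringsAsFactors = FALSE)
  days <- data.frame(
    id = ids, cage = cages$cage, class = cages$class,
    days = c_day * rowSums(y), censored = FALSE,
    stringsAsFactors = FALSE)
  truth <- list(
    sigma2_ad_slope = NA_real_, # caller knows the C it drew effects with
    sigma2_cage_month = sigma2_cage_month,
    sigma2_cage_slope = sigma2_cage_slope,
    sigma2_pe_slope = sigma2_pe_slope,
    resid = resid)
  structure(list(monthly = monthly, days = days, months = Tm,
                 days_per_month = c_day, cutoff_days = config$cutoff_days,
                 coding = "linear", truth = truth),
            class = "survival_table")
}

#' Write / read a simulated dataset directory
#'
#' Plain-text interchange: `pedigree.csv` (pedigree dialect), `cages.csv`
#' (`cage,class,member1..n,death_month1..n`; empty death month = censored),
#' `monthly.csv` (long format incl. the comma-separated alive-mate set),
#' `days.csv`, and `truth.json` holding whatever true parameters the
#' generators recorded.
#'
#' @param ped a [pedigree()]; `pop` the [generate_population()] output whose
#'   cages match `table`.
#' @param table a `survival_table`.
#' @param dir output directory (created if missing).
#' @export
write_simdata <- function(ped, pop, table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(ped, file.path(dir, "pedigree.csv"))
  cages <- pop$cages
  n <- max(cages$slot)
  wide <- data.frame(cage = unique(cages$cage), stringsAsFactors = FALSE)
  wide$class <- cages$class[match(wide$cage, cages$cage)]
  dmo <- table$truth$death_month
  for (s in seq_len(n)) {
    mem <- cages$member[cages$slot == s]
    wide[[paste0("member", s)]] <- mem
    wide[[paste0("death_month", s)]] <-
      if (is.null(dmo)) NA_integer_ else unname(dmo[mem])
  }
  utils::write.csv(wide, file.path(dir, "cages.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(table$monthly, file.path(dir, "monthly.csv"),
                   row.names = FALSE, na = "",
                   quote = which(names(table$monthly) == "mates"))
  utils::write.csv(table$days, file.path(dir, "days.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  meta <- list(months = table$months, days_per_month = table$days_per_month,
               cutoff_days = table$cutoff_days, coding = table$coding,
               truth = table$truth)
  jsonlite::write_json(meta, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(dir)
}

#' @rdname write_simdata
#' @export
read_simdata <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  monthly <- utils::read.csv(file.path(dir, "monthly.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = c(id = "character",
                                            cage = "character",
                                            class = "character",
                                            mates = "character"))
  days <- utils::read.csv(file.path(dir, "days.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(id = "character",
                                         cage = "character",
                                         class = "character"))
  meta <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  tab <- structure(list(monthly = monthly, days = days, months = meta$months,
                        days_per_month = meta$days_per_month,
                        cutoff_days = meta$cutoff_days, coding = meta$coding,
                        truth = meta$truth),
                   class = "survival_table")
  list(ped = ped, table = tab)
}

#' Default logit-scale genetic covariance for the binary generator
#'
#' Direct/indirect genetic (co)variances on the logit scale chosen so that a
#' survival-time analysis of the generated data lands near the magnitudes
#' typical of a commercial White Leghorn line: direct SD ~ 25-30 d, indirect
#' SD ~ 10 d, genetic correlation ~ 0.2, phenotypic SD ~ 135 d, ~57 %
#' survival over 13 months.
#'
#' @return 2x2 covariance matrix (direct, indirect).
#' @export
logit_genetic_defaults <- function() {
  matrix(c(0.112, 0.012, 0.012, 0.03), 2, 2,
         dimnames = list(c("direct", "indirect"), c("direct", "indirect")))
}
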