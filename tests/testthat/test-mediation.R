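test_that("a mediator with no outcome effect transmits exactly zero", {
  tab <- bare_table()
  med <- manual_fit("mediator", c(`(Intercept)` = -0.5, T = 1.2), sigma = 0.8)
  out <- manual_fit("outcome", c(`(Intercept)` = -0.2, T = 0.9, M = 0,
                                 `T:M` = 0), sigma = 0.5)
  est <- estimate_natural_effects(tab, med, out, n_sims = 300, seed = 2)
  # common random numbers make the structural zero exact, not just small
  expect_identical(est$delta0, 0)
  expect_identical(est$delta1, 0)
  expect_gt(est$zeta0, 0)
})

test_that("no treatment effect on the mediator gives deltas within MC error of zero", {
  tab <- bare_table()
  med <- manual_fit("mediator", c(`(Intercept)` = -0.3, T = 0), sigma = 0)
  out <- manual_fit("outcome", c(`(Intercept)` = -0.2, T = 0.7, M = 0.6,
                                 `T:M` = 0.3), sigma = 0)
  est <- estimate_natural_effects(tab, med, out, n_sims = 2000, seed = 3)
  expect_lt(abs(est$delta0), 0.01)
  expect_lt(abs(est$delta1), 0.01)
})

test_that("engine matches the Gauss-Hermite closed form on covariate-free models", {
  a <- c(-0.6, 1.1); th <- c(-0.4, 0.7, 0.5, -0.3)
  sv <- 1.2; su <- 0.6
  med <- manual_fit("mediator", c(`(Intercept)` = a[1], T = a[2]), sigma = sv)
  out <- manual_fit("outcome", c(`(Intercept)` = th[1], T = th[2], M = th[3],
                                 `T:M` = th[4]), sigma = su)
  tab <- bare_table()
  n_sims <- 2000
  est <- estimate_natural_effects(tab, med, out, n_sims = n_sims, seed = 11)
  orc <- oracle_effects(a, th, sv, su)
  # binomial-style MC standard error for each cell mean
  mcse <- sqrt(0.25 / (nrow(tab) * n_sims))
  for (nm in c("delta0", "delta1", "zeta0", "zeta1", "tau",
               "cde_m0", "cde_m1")) {
    expect_lt(abs(est[[nm]] - orc[[nm]]), 3 * (2 * mcse) + 0.004)
  }
  ctl <- estimate_controlled_effects(tab, out, n_sims = n_sims, seed = 12)
  expect_lt(abs(ctl$cde_m0 - orc$cde_m0), 0.01)
  expect_lt(abs(ctl$cde_m1 - orc$cde_m1), 0.01)
})

test_that("composition identities hold to 1e-12 for every engine run", {
  tab <- bare_table()
  set.seed(77)
  for (k in 1:5) {
    med <- manual_fit("mediator",
                      c(`(Intercept)` = rnorm(1), T = rnorm(1)),
                      sigma = runif(1, 0, 2))
    out <- manual_fit("outcome",
                      c(`(Intercept)` = rnorm(1), T = rnorm(1), M = rnorm(1),
                        `T:M` = rnorm(1)), sigma = runif(1))
    est <- estimate_natural_effects(tab, med, out, n_sims = 150, seed = k)
    expect_equal(est$tau, est$delta1 + est$zeta0, tolerance = 1e-12)
    expect_equal(est$tau, est$delta0 + est$zeta1, tolerance = 1e-12)
    expect_equal(est$delta_avg, (est$delta0 + est$delta1) / 2,
                 tolerance = 1e-12)
    expect_equal(est$zeta_avg, (est$zeta0 + est$zeta1) / 2,
                 tolerance = 1e-12)
    expect_true(all(abs(unlist(est[c("delta0", "delta1", "zeta0", "zeta1",
                                     "tau")])) <= 1))
  }
})

test_that("controlled effects without interaction coincide and nulls vanish", {
  tab <- bare_table()
  out0 <- manual_fit("outcome", c(`(Intercept)` = 0.1, T = 0, M = 0.5,
                                  `T:M` = 0), sigma = 0.4)
  ctl0 <- estimate_controlled_effects(tab, out0, n_sims = 2000, seed = 5)
  expect_lt(abs(ctl0$cde_m0), 0.012)   # theta1 = theta3 = 0
  expect_lt(abs(ctl0$cde_m1), 0.012)

  out1 <- manual_fit("outcome", c(`(Intercept)` = -0.3, T = 0.8, M = 0.5,
                                  `T:M` = 0), sigma = 0.4)
  ctl1 <- estimate_controlled_effects(tab, out1, n_sims = 3000, seed = 6)
  expect_lt(abs(ctl1$cde_m0 - ctl1$cde_m1), 0.015)  # no interaction
})

test_that("MC noise shrinks like 1/sqrt(n_sims)", {
  tab <- bare_table(n_per_arm = 60)
  med <- manual_fit("mediator", c(`(Intercept)` = -0.5, T = 1), sigma = 1)
  out <- manual_fit("outcome", c(`(Intercept)` = -0.2, T = 0.6, M = 0.4,
                                 `T:M` = 0.2), sigma = 0.6)
  taus <- function(ns) {
    vapply(1:12, function(s) {
      estimate_natural_effects(tab, med, out, n_sims = ns, seed = 100 + s)$tau
    }, numeric(1))
  }
  suppressWarnings({
    sd_small <- sd(taus(50))
  })
  sd_big <- sd(taus(800))
  expect_lt(sd_big, sd_small)  # 16x replicates must cut the spread
  expect_lt(sd_big, sd_small / 1.8)
})

test_that("moderation: zero interactions give a flat profile equal to the unmoderated one", {
  trial <- generate_trial(trial_config(n_patients = 120, n_clusters = 4,
                                       seed = 14))
  tab <- trial$table
  med <- manual_fit("mediator",
                    c(`(Intercept)` = -0.4, T = 1.1, age = 0, `T:age` = 0),
                    formula = M ~ T + age + T:age)
  out <- manual_fit("outcome",
                    c(`(Intercept)` = -0.1, T = 0.6, M = 0.3, age = 0,
                      `T:M` = 0.4, `T:age` = 0, `M:age` = 0),
                    formula = Y ~ T + M + T:M + age + T:age + M:age)
  grid <- c(60, 70, 80)
  mod <- estimate_moderated_effects(tab, med, out, "age", grid,
                                    n_sims = 300, seed = 4)
  base <- estimate_natural_effects(tab, med, out, n_sims = 300, seed = 4)
  for (e in mod$estimates) {
    expect_equal(e$zeta_avg, base$zeta_avg, tolerance = 1e-12)
    expect_equal(e$delta_avg, base$delta_avg, tolerance = 1e-12)
  }
})

test_that("moderation: negative T:age outcome interaction makes the NDE decline with age", {
  trial <- generate_trial(trial_config(n_patients = 300, n_clusters = 6,
                                       seed = 15))
  tab <- trial$table
  med <- manual_fit("mediator",
                    c(`(Intercept)` = -0.4, T = 1.1, age = 0, `T:age` = 0),
                    formula = M ~ T + age + T:age)
  out <- manual_fit("outcome",
                    c(`(Intercept)` = 3.0, T = 4.0, M = 0.3, age = -0.04,
                      `T:M` = 0.2, `T:age` = -0.05, `M:age` = 0),
                    formula = Y ~ T + M + T:M + age + T:age + M:age)
  mod <- estimate_moderated_effects(tab, med, out, "age",
                                    grid = c(55, 65, 75, 85),
                                    n_sims = 1500, seed = 5)
  prof <- as.data.frame(mod)$zeta_avg
  expect_true(all(diff(prof) < 0))

  # single-point grid at any value reproduces the unmoderated run with the
  # moderator pinned there
  single <- estimate_moderated_effects(tab, med, out, "age", grid = 70,
                                       n_sims = 300, seed = 6)
  tab70 <- tab; tab70$age <- 70
  direct <- estimate_natural_effects(tab70, med, out, n_sims = 300, seed = 6)
  expect_equal(single$estimates[[1]]$zeta_avg, direct$zeta_avg,
               tolerance = 1e-12)

  expect_error(estimate_moderated_effects(tab, med, out, "bmi", c(1, 2),
                                          n_sims = 100, seed = 1),
               "not a covariate")
})
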