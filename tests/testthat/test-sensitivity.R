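make_fitted_pair <- function(seed = 19, n = 352) {
  trial <- generate_trial(trial_config(n_patients = n, seed = seed))
  list(tab = trial$table,
       med = fit_glmm(trial$table, glmm_spec("mediator"), quad_points = 1),
       out = fit_glmm(trial$table, glmm_spec("outcome"), quad_points = 1))
}

test_that("adjustment identities: beta = 0 or lambda = 0 reproduce the unadjusted run exactly", {
  fp <- make_fitted_pair()
  base <- estimate_natural_effects(fp$tab, fp$med, fp$out, n_sims = 300,
                                   seed = 8)
  for (pars in list(sensitivity_params(0, 0.7, -0.4),
                    sensitivity_params(1.5, 0, 0))) {
    adj <- adjusted_effects(fp$tab, fp$med, fp$out, pars, n_sims = 300,
                            seed = 8)
    for (nm in c("delta0", "delta1", "delta_avg", "zeta0", "zeta1",
                 "zeta_avg", "tau", "cde_m0", "cde_m1")) {
      expect_equal(adj[[nm]], base[[nm]], tolerance = 1e-12)
    }
  }
  expect_warning(sensitivity_params(6, 0), "outside the plausible range")
  expect_warning(sensitivity_params(1, 2.5), "outside the plausible range")
})

test_that("adjusted NDE agrees with the discrete-U enumeration oracle to first order", {
  # a confounded discrete world; the package sees only its implied observed
  # models and must recover the de-confounded effects from (beta, lambda)
  a <- c(-0.9, 1.1); th <- c(-0.3, 0.6, 0.4, 0.2)
  check_world <- function(g, b, tol_ratio = 0.5) {
    w <- discrete_u_world(a, th, g, b)
    med <- manual_fit("mediator", c(`(Intercept)` = w$a_obs[1],
                                    T = w$a_obs[2]))
    out <- manual_fit("outcome", c(`(Intercept)` = w$th_obs[1],
                                   T = w$th_obs[2], M = w$th_obs[3],
                                   `T:M` = w$th_obs[4]))
    tab <- bare_table(n_per_arm = 400,
                      m1_arm0 = round(400 * w$pm_marg[1]),
                      m1_arm1 = round(400 * w$pm_marg[2]))
    pars <- sensitivity_params(b, w$lambda[1], w$lambda[2] - w$lambda[1])
    unadj <- estimate_natural_effects(tab, med, out, n_sims = 4000, seed = 2)
    adj <- adjusted_effects(tab, med, out, pars, n_sims = 4000, seed = 2)
    err_unadj <- abs(unadj$zeta_avg - w$zeta_avg_true)
    err_adj <- abs(adj$zeta_avg - w$zeta_avg_true)
    mc <- 3 * sqrt(0.25 / (800 * 4000)) + 0.002
    list(err_unadj = err_unadj, err_adj = err_adj, mc = mc)
  }
  r <- check_world(g = 1.0, b = 0.8)
  expect_gt(r$err_unadj, 0.01)             # confounding really biases
  expect_lt(r$err_adj, 0.5 * r$err_unadj)  # adjustment removes most of it

  # residual error is higher order: quartering (g, b) cuts it far more
  # than the ~4x a first-order residual would allow
  r2 <- check_world(g = 0.5, b = 0.4)
  expect_lt(r2$err_adj, r2$err_unadj)
})

test_that("surface origin equals the unadjusted estimate and drift is monotone in beta", {
  fp <- make_fitted_pair()
  sf <- sensitivity_surface(fp$tab, fp$med, fp$out,
                            beta_grid = seq(-1, 1, 0.5),
                            lambda0_grid = seq(-1, 1, 0.5),
                            n_sims = 400, seed = 21)
  base <- estimate_natural_effects(fp$tab, fp$med, fp$out, n_sims = 400,
                                   seed = 21)
  i0 <- which(sf$beta_grid == 0); j0 <- which(sf$lambda0_grid == 0)
  expect_equal(sf$zeta_avg[i0, j0], base$zeta_avg, tolerance = 1e-12)
  expect_equal(sf$delta_avg[i0, j0], base$delta_avg, tolerance = 1e-12)
  expect_equal(dim(sf$zeta_avg), c(5L, 5L))

  # at beta = 0 the whole row equals the unadjusted value
  expect_true(all(abs(sf$zeta_avg[i0, ] - base$zeta_avg) < 1e-12))

  # for lambda0 != 0 the adjusted NDE drifts monotonically in beta
  for (j in which(sf$lambda0_grid != 0)) {
    d <- diff(sf$zeta_avg[, j])
    expect_true(all(d <= 2e-3) || all(d >= -2e-3))
  }

  # zero-extent grids: single origin point equals unadjusted
  sf0 <- sensitivity_surface(fp$tab, fp$med, fp$out, beta_grid = 0,
                             lambda0_grid = 0, n_sims = 400, seed = 21)
  expect_equal(sf0$zeta_avg[1, 1], base$zeta_avg, tolerance = 1e-12)
})

test_that("first-order correction trades NDE against NIE while roughly preserving the total", {
  fp <- make_fitted_pair()
  base <- estimate_natural_effects(fp$tab, fp$med, fp$out, n_sims = 2000,
                                   seed = 13)
  adj <- adjusted_effects(fp$tab, fp$med, fp$out,
                          sensitivity_params(log(2), -0.5), n_sims = 2000,
                          seed = 13)
  # opposite-signed confounding (positive NDE, negative beta*lambda0):
  # direct effect shrinks, indirect grows
  expect_lt(adj$zeta_avg, base$zeta_avg)
  expect_gt(adj$delta_avg, base$delta_avg)
  # total effect moves an order of magnitude less than the NDE does
  expect_lt(abs(adj$tau - base$tau),
            0.35 * abs(adj$zeta_avg - base$zeta_avg))
})

test_that("analysing a truly confounded trial, the adjusted effects beat the naive ones", {
  b_true <- 0.8; l0_true <- -0.6
  cfg0 <- trial_config(
    n_patients = 500, n_clusters = 10, sigma_v = 0.6, sigma_u = 0.3,
    confounder = list(beta_true = b_true, lambda0_true = l0_true,
                      lambda1_true = 0),
    seed = 1)
  cfg_clean <- cfg0; cfg_clean$confounder <- NULL
  truth <- true_effects(cfg_clean, n_mc = 1e5, seed = 1)
  res <- sapply(1:100, function(s) {
    cfg <- cfg0; cfg$seed <- 700 + s
    trial <- generate_trial(cfg)
    med <- fit_glmm(trial$table, glmm_spec("mediator"), quad_points = 1)
    out <- fit_glmm(trial$table, glmm_spec("outcome"), quad_points = 1)
    naive <- estimate_natural_effects(trial$table, med, out, n_sims = 300,
                                      seed = 2)
    adj <- adjusted_effects(trial$table, med, out,
                            sensitivity_params(b_true, l0_true, 0),
                            n_sims = 300, seed = 2)
    c(naive_z = naive$zeta_avg, naive_d = naive$delta_avg,
      adj_z = adj$zeta_avg, adj_d = adj$delta_avg)
  })
  m <- rowMeans(res)
  err_naive <- abs(m["naive_z"] - truth$zeta_avg) +
    abs(m["naive_d"] - truth$delta_avg)
  err_adj <- abs(m["adj_z"] - truth$zeta_avg) +
    abs(m["adj_d"] - truth$delta_avg)
  expect_lt(err_adj, err_naive)
  # the naive NIE is materially biased; the adjusted one is not
  expect_lt(abs(m[["adj_d"]] - truth$delta_avg),
            0.5 * abs(m[["naive_d"]] - truth$delta_avg))
})
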