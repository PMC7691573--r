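test_that("with no clustering the fit matches an independent Newton-Raphson oracle", {
  cfg <- trial_config(n_patients = 1500, sigma_v = 0, sigma_u = 0, seed = 21)
  trial <- generate_trial(cfg)
  tab <- trial$table

  fit <- fit_glmm(tab, glmm_spec("mediator", cluster = NULL))
  X <- model.matrix(M ~ T + age + baseline_sr, as.data.frame(tab))
  beta_nr <- newton_logistic(X, tab$M)
  expect_equal(unname(coef(fit)), unname(beta_nr), tolerance = 1e-5)
  expect_equal(fit$sigma, 0)
  expect_equal(fit$icc, 0)

  # mixed fit on sigma_v = 0 data lands near the same coefficients
  mixed <- fit_glmm(tab, glmm_spec("mediator"), quad_points = 7)
  se <- sqrt(diag(mixed$vcov))
  expect_true(all(abs(coef(mixed) - beta_nr) < 3 * se))
  expect_lt(mixed$sigma, 0.25)
})

test_that("coefficients recover the generating values and the ICC identity holds", {
  cfg <- trial_config(n_patients = 2000, n_clusters = 20, seed = 8)
  trial <- generate_trial(cfg)
  fit <- fit_glmm(trial$table, glmm_spec("mediator"), quad_points = 7)
  se <- sqrt(diag(fit$vcov))
  truth <- c(cfg$alpha0, cfg$alpha1, cfg$alpha2[["age"]],
             cfg$alpha2[["baseline_sr"]])
  expect_true(all(abs(coef(fit) - truth) < 3.5 * se))
  # strong surgeon preference: latent ICC of order 0.5
  expect_gt(fit$icc, 0.3)
  expect_equal(fit$icc, fit$sigma^2 / (fit$sigma^2 + pi^2 / 3),
               tolerance = 1e-12)
})

test_that("7 and 15 quadrature points agree to < 1e-3 at trial scale", {
  trial <- generate_trial(trial_config(seed = 4))
  f7 <- fit_glmm(trial$table, glmm_spec("outcome"), quad_points = 7)
  f15 <- fit_glmm(trial$table, glmm_spec("outcome"), quad_points = 15)
  expect_lt(max(abs(coef(f7) - coef(f15))), 1e-3)
  expect_lt(abs(f7$sigma - f15$sigma), 1e-3)
})

test_that("likelihood at the estimate is at least the likelihood at the truth", {
  for (s in 1:3) {
    cfg <- trial_config(n_patients = 400, n_clusters = 10, seed = 40 + s)
    trial <- generate_trial(cfg)
    fit <- fit_glmm(trial$table, glmm_spec("mediator"), quad_points = 15)
    X <- model.matrix(M ~ T + age + baseline_sr, as.data.frame(trial$table))
    y <- trial$table$M
    cl <- trial$table$cluster
    ll_hat <- glmm_loglik(coef(fit), fit$sigma, X, y, cl)
    ll_true <- glmm_loglik(c(cfg$alpha0, cfg$alpha1, cfg$alpha2[["age"]],
                             cfg$alpha2[["baseline_sr"]]),
                           cfg$sigma_v, X, y, cl)
    expect_gte(ll_hat, ll_true - 1e-4)
  }
})

test_that("a perfectly separating covariate raises the separation error", {
  set.seed(12)
  y <- rbinom(120, 1, 0.5)
  df <- data.frame(Y = y, M = rbinom(120, 1, 0.4), T = rep(0:1, 60),
                   cluster = rep(c("a", "b"), 60),
                   marker = ifelse(y == 1, rnorm(120, 4), rnorm(120, -4)))
  tab <- trial_table(df)
  expect_error(
    suppressWarnings(fit_glmm(tab, glmm_spec("outcome", cluster = NULL))),
    "separation")
})

test_that("rank deficiency is reported with the aliased column", {
  trial <- generate_trial(trial_config(seed = 3))
  df <- as.data.frame(trial$table)
  df$age_copy <- df$age
  tab <- trial_table(df)
  expect_error(fit_glmm(tab, glmm_spec("mediator")),
               "rank deficient.*age_copy")
})

test_that("odds ratio tables are exp of coefficients with Wald limits", {
  fit <- manual_fit("outcome", c(`(Intercept)` = 0, T = log(2), M = -0.5,
                                 `T:M` = 0.25))
  fit$vcov <- diag(c(0.04, 0, 0.09, 0.01))
  tab <- odds_ratio_table(fit, level = 0.95)
  expect_equal(tab$or[tab$term == "T"], 2)
  expect_equal(tab$lo[tab$term == "T"], 2)  # zero SE -> zero-width CI
  expect_equal(tab$or[tab$term == "(Intercept)"], 1)
  z <- qnorm(0.975)
  expect_equal(tab$lo[tab$term == "M"], exp(-0.5 - z * 0.3))
  expect_equal(tab$hi[tab$term == "M"], exp(-0.5 + z * 0.3))
  # CI symmetric around 1 on the log scale for a zero coefficient
  i <- which(tab$term == "(Intercept)")
  expect_equal(log(tab$lo[i]), -log(tab$hi[i]))
})

test_that("predict_prob follows the linear predictor and the re rule", {
  fit <- manual_fit("outcome", c(`(Intercept)` = 0, T = 0, M = 0, `T:M` = 0))
  tab <- tiny_table()
  expect_equal(predict_prob(fit, tab, re = "zero"), rep(0.5, 4))

  fit2 <- manual_fit("outcome", c(`(Intercept)` = -1, T = 2, M = 0.5,
                                  `T:M` = -0.25))
  p <- predict_prob(fit2, tab[1, , drop = FALSE], t_override = 1,
                    m_override = 1, re = "zero")
  expect_equal(p, expit_(-1 + 2 + 0.5 - 0.25))  # hand-computed

  # sigma = 0 makes the draw rule identical to the zero rule
  expect_equal(predict_prob(fit2, tab, re = "draw", seed = 1),
               predict_prob(fit2, tab, re = "zero"))

  # unknown cluster under the mode rule
  fit2$cluster_modes <- c(zzz = 0.1)
  expect_error(predict_prob(fit2, tab, re = "mode"), "unknown cluster")
})
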