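# Shared fixtures and independent oracles. Everything here is deliberately
# written without reusing package internals, so oracle and implementation
# can disagree.

expit_ <- function(x) 1 / (1 + exp(-x))

# -- fixtures ---------------------------------------------------------------

tiny_table <- function() {
  trial_table(data.frame(
    Y = c(1, 0, 1, 0), M = c(1, 0, 0, 1), T = c(1, 1, 0, 0),
    cluster = c("a", "a", "b", "b"), age = c(70, 65, 72, 80)))
}

# covariate-free table: Y values are irrelevant to the engine (it only uses
# the fits); arm M-counts are controlled so sensitivity centering is exact.
bare_table <- function(n_per_arm = 200, m1_arm0 = round(0.3 * n_per_arm),
                       m1_arm1 = round(0.55 * n_per_arm)) {
  df <- data.frame(
    Y = rep(c(1, 0), length.out = 2 * n_per_arm),
    M = c(rep(c(1, 0), c(m1_arm0, n_per_arm - m1_arm0)),
          rep(c(1, 0), c(m1_arm1, n_per_arm - m1_arm1))),
    T = rep(c(0, 1), each = n_per_arm),
    cluster = rep(c("c1", "c2"), length.out = 2 * n_per_arm))
  trial_table(df)
}

# hand-built glmm_fit with known coefficients (for oracle comparisons)
manual_fit <- function(response, coefs, sigma = 0, formula = NULL,
                       clusters = c("c1", "c2")) {
  if (is.null(formula)) {
    formula <- if (response == "mediator") M ~ T else Y ~ T + M + T:M
  }
  structure(list(coefficients = coefs,
                 vcov = diag(1e-4, length(coefs)),
                 sigma = sigma,
                 icc = sigma^2 / (sigma^2 + pi^2 / 3),
                 cluster_modes = stats::setNames(rep(0, length(clusters)),
                                                 clusters),
                 loglik = NA_real_, converged = TRUE, n_used = 0L,
                 quad_points = 0L,
                 spec = glmm_spec(response, covariates = character(),
                                  cluster = NULL),
                 formula = formula),
            class = "glmm_fit")
}

# -- Gauss-Hermite closed forms for covariate-free models -------------------

# E[expit(a + s*Z)], Z ~ N(0,1), by adaptive quadrature (independent of the
# simulation engine).
probit_mix <- function(a, s) {
  if (s == 0) return(expit_(a))
  stats::integrate(function(z) expit_(a + s * z) * stats::dnorm(z),
                   -10, 10, rel.tol = 1e-10)$value
}

# P(t, t') table and all effects for covariate-free mediator/outcome models
# with coefficients (a0, a1) / (t0, t1, t2, t3) and random-intercept SDs.
oracle_effects <- function(a, th, sv, su) {
  pm <- vapply(0:1, function(t) probit_mix(a[1] + a[2] * t, sv), numeric(1))
  py <- function(t, m) probit_mix(th[1] + th[2] * t + th[3] * m +
                                    th[4] * t * m, su)
  P <- matrix(NA_real_, 2, 2)
  for (t in 0:1) for (tp in 0:1) {
    P[t + 1, tp + 1] <- pm[tp + 1] * py(t, 1) + (1 - pm[tp + 1]) * py(t, 0)
  }
  list(P = P,
       delta0 = P[1, 2] - P[1, 1], delta1 = P[2, 2] - P[2, 1],
       zeta0 = P[2, 1] - P[1, 1], zeta1 = P[2, 2] - P[1, 2],
       tau = P[2, 2] - P[1, 1],
       cde_m0 = py(1, 0) - py(0, 0), cde_m1 = py(1, 1) - py(0, 1))
}

# -- independent Newton-Raphson logistic regression -------------------------

newton_logistic <- function(X, y, tol = 1e-12, maxit = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- expit_(eta)
    W <- p * (1 - p)
    score <- crossprod(X, y - p)
    info <- crossprod(X * W, X)
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# -- GLMM log-likelihood by brute-force Gauss-Hermite -----------------------

gh_nodes <- function(k = 40) {
  # Golub-Welsch from the Hermite recurrence; standard-normal weights
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values * sqrt(2), w = e$vectors[1, ]^2)
}

glmm_loglik <- function(beta, sigma, X, y, cluster, nodes = gh_nodes(40)) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (cl in unique(cluster)) {
    idx <- cluster == cl
    contrib <- vapply(seq_along(nodes$x), function(q) {
      p <- expit_(eta[idx] + sigma * nodes$x[q])
      exp(sum(y[idx] * log(p) + (1 - y[idx]) * log1p(-p)))
    }, numeric(1))
    ll <- ll + log(sum(nodes$w * contrib))
  }
  ll
}

# -- discrete-U enumeration oracle for the sensitivity module ---------------
#
# World: U = +/-1 with prob 1/2 (variance 1); covariate-free;
# true mediator model  logit P(M=1|T,U) = a0 + a1*T + g*U;
# true outcome model   logit P(Y=1|T,M,U) = t0 + t1*T + t2*M + t3*T*M + b*U.
# Returns the exact confounded "observed" model coefficients, the exact
# lambda contrasts, and the true (de-confounded) natural effects.
discrete_u_world <- function(a, th, g, b) {
  u <- c(-1, 1)
  pm_u <- function(t) expit_(a[1] + a[2] * t + g * u)     # P(M=1|T=t,U=u)
  pm_marg <- function(t) mean(pm_u(t))
  lam <- vapply(0:1, function(t) {
    pu_m1 <- pm_u(t) * 0.5 / pm_marg(t)                   # P(U=u|M=1,T=t)
    pu_m0 <- (1 - pm_u(t)) * 0.5 / (1 - pm_marg(t))
    sum(u * pu_m1) - sum(u * pu_m0)
  }, numeric(1))
  py_u <- function(t, m) expit_(th[1] + th[2] * t + th[3] * m +
                                  th[4] * t * m + b * u)
  pobs <- function(t, m) {                                # E[Y|T=t,M=m]
    pu <- if (m == 1) pm_u(t) * 0.5 / pm_marg(t)
          else (1 - pm_u(t)) * 0.5 / (1 - pm_marg(t))
    sum(pu * py_u(t, m))
  }
  q <- stats::qlogis
  th_obs <- c(q(pobs(0, 0)),
              q(pobs(1, 0)) - q(pobs(0, 0)),
              q(pobs(0, 1)) - q(pobs(0, 0)),
              q(pobs(1, 1)) - q(pobs(1, 0)) - q(pobs(0, 1)) + q(pobs(0, 0)))
  a_obs <- c(q(pm_marg(0)), q(pm_marg(1)) - q(pm_marg(0)))
  # true counterfactual P(Y(t, M(t'))): joint over (U, M(t'))
  Ptrue <- matrix(NA_real_, 2, 2)
  for (t in 0:1) for (tp in 0:1) {
    Ptrue[t + 1, tp + 1] <- sum(0.5 * (pm_u(tp) * py_u(t, 1) +
                                         (1 - pm_u(tp)) * py_u(t, 0)))
  }
  list(a_obs = a_obs, th_obs = th_obs, lambda = lam,
       pm_marg = c(pm_marg(0), pm_marg(1)),
       Ptrue = Ptrue,
       zeta_avg_true = ((Ptrue[2, 1] - Ptrue[1, 1]) +
                          (Ptrue[2, 2] - Ptrue[1, 2])) / 2,
       delta_avg_true = ((Ptrue[1, 2] - Ptrue[1, 1]) +
                           (Ptrue[2, 2] - Ptrue[2, 1])) / 2)
}
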