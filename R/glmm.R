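#' Specify a mediator or outcome mixed-effects logistic model
#'
#' The analysis rests on two models: a mediator model
#' `M ~ T + covariates + (1 | cluster)` and an outcome model
#' `Y ~ T + M + T:M + covariates + (1 | cluster)`, each a logistic
#' regression with a Gaussian surgeon random intercept.  The
#' treatment-by-mediator interaction is included in the outcome model unless
#' explicitly disabled.
#'
#' @param response `"mediator"` (models `M`) or `"outcome"` (models `Y`).
#' @param covariates character vector of covariate columns to adjust for;
#'   `NULL` (default) means every covariate in the table at fit time.
#' @param interactions character vector of extra interaction terms in
#'   formula syntax, e.g. `c("T:age", "M:age")`, used for moderation
#'   analyses.
#' @param tm_interaction include `T:M` in the outcome model (default TRUE;
#'   ignored for the mediator model).
#' @param cluster name of the cluster column, or `NULL` for a model with no
#'   random intercept (ordinary logistic regression, the sigma = 0 special
#'   case).
#' @return an object of class `glmm_spec`.
#' @export
glmm_spec <- function(response = c("mediator", "outcome"),
                      covariates = NULL,
                      interactions = character(),
                      tm_interaction = TRUE,
                      cluster = "cluster") {
  response <- match.arg(response)
  structure(list(response = response, covariates = covariates,
                 interactions = interactions,
                 tm_interaction = isTRUE(tm_interaction),
                 cluster = cluster),
            class = "glmm_spec")
}

spec_fixed_formula <- function(spec, table) {
  covs <- spec$covariates %||% covariate_names(table)
  lhs <- if (spec$response == "mediator") "M" else "Y"
  rhs <- if (spec$response == "mediator") "T" else {
    if (spec$tm_interaction) "T + M + T:M" else "T + M"
  }
  terms <- c(rhs, covs, spec$interactions)
  stats::as.formula(paste(lhs, "~", paste(terms, collapse = " + ")))
}

#' Fit a mixed-effects logistic regression with a surgeon random intercept
#'
#' Maximum (approximate) likelihood via adaptive Gauss--Hermite quadrature
#' over the single random intercept, with `quad_points = 1` giving the
#' Laplace approximation.  Fitting is delegated to [lme4::glmer()]; when the
#' spec has `cluster = NULL` the model is an ordinary logistic regression
#' (the sigma = 0 special case) fitted by [stats::glm()].  The intra-cluster
#' correlation is reported on the latent log-odds scale,
#' `icc = sigma^2 / (sigma^2 + pi^2/3)`, the level-1 residual variance of the
#' logistic latent-variable formulation being `pi^2/3`.  Estimated random
#' intercept SDs below 1e-4 are reported as 0 with `icc = 0`, at which point
#' the fit coincides with ordinary logistic regression.
#'
#' @param table a [trial_table()].
#' @param spec a [glmm_spec()].
#' @param quad_points number of adaptive quadrature points (default 7).
#' @param tol convergence tolerance passed to the optimizer.
#' @return an object of class `glmm_fit` with elements `coefficients` (log
#'   odds scale), `vcov`, `sigma` (random-intercept SD), `icc`,
#'   `cluster_modes` (posterior modes of the random intercepts), `loglik`,
#'   `converged`, `n_used`, `spec` and the fixed-effects `formula`.
#'   Non-convergence yields a flagged fit, not an error.
#' @examples
#' trial <- generate_trial(trial_config(seed = 7))
#' fit <- fit_glmm(trial$table, glmm_spec("mediator"))
#' fit$icc
#' @export
fit_glmm <- function(table, spec, quad_points = 7, tol = 1e-8) {
  stopifnot(inherits(table, "trial_table"), inherits(spec, "glmm_spec"))
  fixed <- spec_fixed_formula(spec, table)
  dat <- as.data.frame(table)

  mm <- stats::model.matrix(fixed, dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop_msg("model error: design matrix is rank deficient; aliased column(s): ",
             paste(aliased, collapse = ", "))
  }

  if (is.null(spec$cluster)) {
    y <- dat[[as.character(fixed[[2]])]]
    fit <- suppressWarnings(
      stats::glm.fit(mm, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = tol, maxit = 100)))
    beta <- stats::setNames(fit$coefficients, colnames(mm))
    check_separation(beta, y, fit$fitted.values)
    w <- fit$weights
    vc <- solve(crossprod(mm * w, mm))
    dimnames(vc) <- list(colnames(mm), colnames(mm))
    p <- fit$fitted.values
    ll <- sum(y * log(p) + (1 - y) * log1p(-p))
    out <- list(coefficients = beta,
                vcov = vc,
                sigma = 0, icc = 0,
                cluster_modes = stats::setNames(
                  rep(0, length(attr(table, "cluster_index"))),
                  names(attr(table, "cluster_index"))),
                loglik = ll,
                converged = fit$converged,
                n_used = nrow(dat),
                quad_points = 0L,
                spec = spec, formula = fixed)
    return(structure(out, class = "glmm_fit"))
  }

  full <- stats::update(
    fixed, stats::as.formula(paste(". ~ . + (1 |", spec$cluster, ")")))
  glmer_once <- function(optimizer) {
    ok <- TRUE
    # the default absolute gradient check (0.002) flags fits whose
    # parameters are settled far beyond any tolerance that matters here;
    # 0.05 still catches real failures (degenerate Hessians warn
    # separately)
    grad_cc <- lme4::.makeCC("warning", tol = 0.05)
    ctl <- if (is.null(optimizer)) {
      lme4::glmerControl(check.conv.singular = "ignore",
                         check.conv.grad = grad_cc)
    } else {
      lme4::glmerControl(optimizer = optimizer,
                         check.conv.singular = "ignore",
                         check.conv.grad = grad_cc)
    }
    fit <- withCallingHandlers(
      lme4::glmer(full, data = dat, family = stats::binomial(),
                  nAGQ = as.integer(quad_points), control = ctl),
      warning = function(w) {
        if (grepl("converge|unidentifiable", conditionMessage(w),
                  ignore.case = TRUE)) {
          ok <<- FALSE
        }
        invokeRestart("muffleWarning")
      })
    list(fit = fit, ok = ok)
  }
  # one restart under bobyqa resolves most convergence complaints on hard
  # likelihood surfaces (large random-intercept SD)
  res_fit <- glmer_once(NULL)
  if (!res_fit$ok) res_fit <- glmer_once("bobyqa")
  fit <- res_fit$fit
  converged <- res_fit$ok
  beta <- lme4::fixef(fit)
  check_separation(beta, dat[[as.character(fixed[[2]])]],
                   stats::fitted(fit))
  sigma <- sqrt(as.numeric(lme4::VarCorr(fit)[[spec$cluster]][1, 1]))
  if (sigma < 1e-4) sigma <- 0
  modes <- lme4::ranef(fit)[[spec$cluster]][["(Intercept)"]]
  names(modes) <- rownames(lme4::ranef(fit)[[spec$cluster]])
  out <- list(coefficients = beta,
              vcov = suppressWarnings(as.matrix(stats::vcov(fit))),
              sigma = sigma,
              icc = sigma^2 / (sigma^2 + LOGIT_RESID_VAR),
              cluster_modes = modes,
              loglik = as.numeric(stats::logLik(fit)),
              converged = converged,
              n_used = nrow(dat),
              quad_points = as.integer(quad_points),
              spec = spec, formula = fixed)
  structure(out, class = "glmm_fit")
}

# Complete separation: the fit classifies every observation essentially
# perfectly, so the MLE is at infinity.  Quasi-separated cells (a handful of
# saturated fitted values among ordinary ones, common in bootstrap
# resamples) are finite and usable and are deliberately not flagged; a
# coefficient blowing past 25 on the logit scale is flagged as a backstop.
check_separation <- function(beta, y = NULL, fitted = NULL) {
  if (!is.null(y) && !is.null(fitted) && all(abs(y - fitted) < 1e-3)) {
    stop_msg("complete separation: the model classifies every observation ",
             "perfectly, so maximum likelihood estimates do not exist; ",
             "penalized regression is out of scope")
  }
  if (any(abs(beta) > 25)) {
    stop_msg("complete separation suspected (|coefficient| > 25 for ",
             paste(names(beta)[abs(beta) > 25], collapse = ", "),
             "); penalized regression is out of scope")
  }
  invisible(TRUE)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("Mixed logistic fit (%s model, %s): n=%d, %s\n",
              x$spec$response,
              if (x$quad_points == 0) "no random intercept"
              else sprintf("adaptive GH quadrature, %d points", x$quad_points),
              x$n_used,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$coefficients, 4))
  cat(sprintf("Random-intercept SD %.4f, ICC (latent scale) %.3f\n",
              x$sigma, x$icc))
  invisible(x)
}

#' @export
coef.glmm_fit <- function(object, ...) object$coefficients

#' @export
vcov.glmm_fit <- function(object, ...) object$vcov

#' @export
summary.glmm_fit <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- data.frame(estimate = object$coefficients, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  structure(list(coef_table = tab,
                 or_table = odds_ratio_table(object, level = level),
                 icc = object$icc, sigma = object$sigma,
                 response = object$spec$response,
                 converged = object$converged),
            class = "summary.glmm_fit")
}

#' @export
print.summary.glmm_fit <- function(x, ...) {
  cat(sprintf("%s model (%s)\n", x$response,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$coef_table, 4))
  cat("\nOdds ratios:\n")
  print(x$or_table)
  cat(sprintf("\nICC(cluster) = %.3f  [latent scale, level-1 variance pi^2/3]\n",
              x$icc))
  invisible(x)
}

#' Odds ratios with Wald confidence intervals
#'
#' @param fit a converged `glmm_fit`.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `term`, `or`, `lo`, `hi` (`exp(coef)` and
#'   `exp(coef +/- z * se)`); the latent-scale ICC is carried as attribute
#'   `icc`.
#' @export
odds_ratio_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "glmm_fit"))
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(term = names(fit$coefficients),
                    or = exp(unname(fit$coefficients)),
                    lo = exp(unname(fit$coefficients) - z * se),
                    hi = exp(unname(fit$coefficients) + z * se),
                    row.names = NULL)
  attr(out, "icc") <- fit$icc
  attr(out, "level") <- level
  out
}

# Fixed-effect linear predictor for table rows with T and/or M overridden.
fixed_eta <- function(fit, table, t_override = NULL, m_override = NULL) {
  dat <- as.data.frame(table)
  if (!is.null(t_override)) dat$T <- t_override
  if (!is.null(m_override)) dat$M <- m_override
  if (!("M" %in% names(dat))) dat$M <- 0   # mediator model ignores M anyway
  mm <- stats::model.matrix(fit$formula[-2], dat)
  keep <- names(fit$coefficients)
  if (!all(keep %in% colnames(mm))) {
    stop_msg("schema mismatch: fit terms ",
             paste(setdiff(keep, colnames(mm)), collapse = ", "),
             " not constructible from the table")
  }
  as.vector(mm[, keep, drop = FALSE] %*% fit$coefficients)
}

#' Per-record success probabilities from a fitted model
#'
#' Evaluates `expit` of the fixed-effect linear predictor, with `T` and/or
#' `M` optionally overridden, under one of three random-intercept rules:
#' `"zero"` (population-median surgeon), `"draw"` (a fresh
#' `N(0, sigma^2)` draw per record, the population-of-surgeons marginal
#' rule) or `"mode"` (each record's own cluster posterior mode).
#'
#' @param fit a `glmm_fit`.
#' @param records a `trial_table` (or compatible data.frame) of records.
#' @param t_override,m_override optional scalar or vector overrides for the
#'   treatment and mediator columns.
#' @param re one of `"zero"`, `"draw"`, `"mode"`.
#' @param seed seed used when `re = "draw"`.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(fit, records, t_override = NULL, m_override = NULL,
                         re = c("zero", "draw", "mode"), seed = NULL) {
  re <- match.arg(re)
  eta <- fixed_eta(fit, records, t_override, m_override)
  b <- switch(re,
    zero = 0,
    draw = with_seed(seed, stats::rnorm(length(eta), 0, fit$sigma)),
    mode = {
      cl <- as.character(records$cluster)
      unknown <- setdiff(unique(cl), names(fit$cluster_modes))
      if (length(unknown)) {
        stop_msg("unknown cluster(s) for re = 'mode': ",
                 paste(unknown, collapse = ", "),
                 "; use re = 'draw' or 'zero'")
      }
      unname(fit$cluster_modes[cl])
    })
  expit(eta + b)
}

#' @export
predict.glmm_fit <- function(object, newdata, ...) {
  predict_prob(object, newdata, ...)
}
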