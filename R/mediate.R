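#' Causal mediation analysis of a clustered surgical trial
#'
#' The package's central fitting function: fits the mediator and outcome
#' mixed-effects logistic models, runs the potential-outcome Monte Carlo
#' engine for natural direct/indirect, total and controlled direct effects
#' on the probability-difference scale, and (optionally) attaches
#' nonparametric bootstrap percentile confidence intervals.
#'
#' @param table a [trial_table()].
#' @param covariates covariate columns to adjust for (default: all).
#' @param tm_interaction include the treatment-by-mediator interaction in
#'   the outcome model (default TRUE).
#' @param n_sims engine simulation replicates (default 2000).
#' @param seed integer seed for all randomness.
#' @param re_rule random-intercept rule for potential-outcome draws, see
#'   [estimate_natural_effects()].
#' @param quad_points adaptive quadrature points for the model fits.
#' @param n_boot bootstrap replicates (0 = point estimates only).
#' @param level confidence level for bootstrap intervals.
#' @param resample_unit `"patient"` or `"cluster"`.
#' @return an object of class `mediation_fit`: list with `med_fit`,
#'   `out_fit`, `estimates` (a `mediation_estimates`), `controlled` (a
#'   `controlled_effects`) and `boot` (or `NULL`).
#' @examples
#' trial <- generate_trial(trial_config(seed = 11))
#' fit <- mediate_trial(trial$table, n_sims = 200, seed = 1, quad_points = 1)
#' fit
#' @export
mediate_trial <- function(table, covariates = NULL, tm_interaction = TRUE,
                          n_sims = 2000, seed = 1L,
                          re_rule = c("draw", "zero", "mode"),
                          quad_points = 7, n_boot = 0, level = 0.95,
                          resample_unit = c("patient", "cluster")) {
  re_rule <- match.arg(re_rule)
  resample_unit <- match.arg(resample_unit)
  med_spec <- glmm_spec("mediator", covariates = covariates)
  out_spec <- glmm_spec("outcome", covariates = covariates,
                        tm_interaction = tm_interaction)
  if (n_boot > 0) {
    bt <- bootstrap_effects(table, med_spec, out_spec, n_boot = n_boot,
                            level = level, seed = seed,
                            resample_unit = resample_unit, n_sims = n_sims,
                            re_rule = re_rule, quad_points = quad_points)
    med_fit <- fit_glmm(table, med_spec, quad_points = quad_points)
    out_fit <- fit_glmm(table, out_spec, quad_points = quad_points)
    est <- bt$estimates
    ctl <- bt$controlled
    boot <- bt$boot
  } else {
    med_fit <- fit_glmm(table, med_spec, quad_points = quad_points)
    out_fit <- fit_glmm(table, out_spec, quad_points = quad_points)
    est <- estimate_natural_effects(table, med_fit, out_fit,
                                    n_sims = n_sims, seed = seed,
                                    re_rule = re_rule)
    ctl <- structure(list(cde_m0 = est$cde_m0, cde_m1 = est$cde_m1,
                          n_sims = n_sims, seed = seed, re_rule = re_rule,
                          ci = NULL),
                     class = "controlled_effects")
    boot <- NULL
  }
  structure(list(table = table, med_fit = med_fit, out_fit = out_fit,
                 estimates = est, controlled = ctl, boot = boot,
                 level = level),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("Causal mediation analysis of a clustered two-arm trial\n")
  cat(sprintf("  mediator model ICC %.3f | outcome model ICC %.3f\n",
              x$med_fit$icc, x$out_fit$icc))
  print(x$estimates)
  invisible(x)
}

#' @export
summary.mediation_fit <- function(object, ...) {
  structure(list(med = summary(object$med_fit),
                 out = summary(object$out_fit),
                 estimates = object$estimates,
                 controlled = object$controlled,
                 boot = object$boot),
            class = "summary.mediation_fit")
}

#' @export
print.summary.mediation_fit <- function(x, ...) {
  cat("== Mediator model ==\n"); print(x$med)
  cat("\n== Outcome model ==\n"); print(x$out)
  cat("\n== Causal effects ==\n"); print(x$estimates)
  print(x$controlled)
  if (!is.null(x$boot)) {
    cat(sprintf("\nBootstrap: %d replicates, %d failed refits\n",
                x$boot$n_boot, x$boot$failed))
  }
  invisible(x)
}

#' @export
coef.mediation_fit <- function(object, ...) {
  nms <- c(effect_names(), "cde_m0", "cde_m1")
  vapply(nms, function(nm) object$estimates[[nm]], numeric(1))
}

#' @export
confint.mediation_fit <- function(object, parm, level, ...) {
  confint(object$estimates)
}

#' @export
plot.mediation_fit <- function(x, ...) plot(x$estimates, ...)
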