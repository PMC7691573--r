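#' @rdname estimate_natural_effects
#' @name mediation_estimates
NULL

new_mediation_estimates <- function(eff, ptable, n_sims, seed, re_rule,
                                    cde_m0 = NULL, cde_m1 = NULL, ci = NULL) {
  structure(c(eff,
              list(cde_m0 = cde_m0, cde_m1 = cde_m1,
                   ptable = ptable, n_sims = n_sims, seed = seed,
                   re_rule = re_rule, ci = ci)),
            class = "mediation_estimates")
}

effect_names <- function() {
  c("delta0", "delta1", "delta_avg", "zeta0", "zeta1", "zeta_avg", "tau")
}

effect_labels <- function() {
  c(delta0 = "NIE delta(0)", delta1 = "NIE delta(1)",
    delta_avg = "NIE delta(a*)",
    zeta0 = "NDE zeta(0)", zeta1 = "NDE zeta(1)",
    zeta_avg = "NDE zeta(a*)", tau = "TE tau",
    cde_m0 = "CDE zeta_c(0)", cde_m1 = "CDE zeta_c(1)")
}

#' @export
print.mediation_estimates <- function(x, digits = 4, ...) {
  cat(sprintf("Causal mediation estimates (probability-difference scale, %s sims, re rule: %s)\n",
              format(x$n_sims, big.mark = ","), x$re_rule))
  labs <- effect_labels()
  nms <- c(effect_names(),
           if (!is.null(x$cde_m0)) c("cde_m0", "cde_m1"))
  for (nm in nms) {
    line <- sprintf("  %-14s %+.*f", labs[[nm]], digits, x[[nm]])
    if (!is.null(x$ci) && !is.null(x$ci[[nm]])) {
      line <- sprintf("%s  (%.*f, %.*f)", line, digits, x$ci[[nm]][1],
                      digits, x$ci[[nm]][2])
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' @export
confint.mediation_estimates <- function(object, parm, level, ...) {
  if (is.null(object$ci)) {
    stop_msg("no confidence intervals attached; run bootstrap_effects()")
  }
  nms <- names(object$ci)
  out <- do.call(rbind, object$ci)
  rownames(out) <- nms
  colnames(out) <- c("lower", "upper")
  out
}

#' @export
plot.mediation_estimates <- function(x, ...) {
  nms <- c(effect_names(), if (!is.null(x$cde_m0)) c("cde_m0", "cde_m1"))
  est <- vapply(nms, function(nm) x[[nm]], numeric(1))
  labs <- effect_labels()[nms]
  yy <- rev(seq_along(nms))
  xr <- range(c(0, est, if (!is.null(x$ci)) unlist(x$ci[nms])))
  graphics::plot(est, yy, xlab = "Probability difference", ylab = "",
                 yaxt = "n", pch = 19, xlim = xr, ...)
  graphics::axis(2, at = yy, labels = labs, las = 1, cex.axis = 0.8)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  if (!is.null(x$ci)) {
    for (i in seq_along(nms)) {
      ci <- x$ci[[nms[i]]]
      if (!is.null(ci)) graphics::segments(ci[1], yy[i], ci[2], yy[i])
    }
  }
  invisible(x)
}

# Random-intercept realisations for one engine replicate.
engine_re <- function(rule, n, fit, table) {
  switch(rule,
    draw = stats::rnorm(n, 0, fit$sigma),
    zero = rep(0, n),
    mode = {
      cl <- as.character(table$cluster)
      unknown <- setdiff(unique(cl), names(fit$cluster_modes))
      if (length(unknown)) {
        stop_msg("unknown cluster(s) for re rule 'mode': ",
                 paste(unknown, collapse = ", "))
      }
      unname(fit$cluster_modes[cl])
    })
}

# Potential-outcome Monte Carlo core.
#
# Simulates, per replicate and patient, potential mediators M(0), M(1) from
# the mediator model with treatment forced to 0 and 1 (same uniform and the
# same random-intercept realisation within a replicate), then the four
# potential outcomes Y(t, M(t')) and the four interventional outcomes
# Y(t, m) from the outcome model, with one shared uniform coupling all
# outcome cells (common random numbers).  `shift` is a 2x2 matrix of
# logit-scale offsets for the interventional cells (rows t = 0,1, columns
# m = 0,1), zero for the unadjusted analysis and used by the sensitivity
# module.  Returns the 2x2 table P(t, t'), the controlled-effect cell means
# and the assembled effects.
run_engine <- function(table, med_fit, out_fit, n_sims, seed,
                       re_rule = c("draw", "zero", "mode"),
                       shift = matrix(0, 2, 2)) {
  re_rule <- match.arg(re_rule)
  if (n_sims < 100) warn_msg("n_sims < 100: Monte Carlo error will be large")
  n <- nrow(table)
  eta_med <- lapply(0:1, function(t) fixed_eta(med_fit, table, t_override = t))
  eta_out <- lapply(0:1, function(t) lapply(0:1, function(m) {
    fixed_eta(out_fit, table, t_override = t, m_override = m) + shift[t + 1, m + 1]
  }))
  fixed_re <- re_rule != "draw"
  with_seed(seed, {
    if (fixed_re) {
      v0 <- engine_re(re_rule, n, med_fit, table)
      u0 <- engine_re(re_rule, n, out_fit, table)
    }
    acc_P <- matrix(0, 2, 2)
    acc_C <- matrix(0, 2, 2)
    # replicates are vectorised in blocks of at most ~5e5 patient-replicates
    block <- max(1L, min(n_sims, as.integer(ceiling(5e5 / n))))
    done <- 0L
    while (done < n_sims) {
      S <- min(block, n_sims - done)
      nS <- n * S
      # n x S matrices, patients down columns; linear predictors recycle
      v <- if (fixed_re) v0 else stats::rnorm(nS, 0, med_fit$sigma)
      u <- if (fixed_re) u0 else stats::rnorm(nS, 0, out_fit$sigma)
      u_m <- stats::runif(nS)
      u_y <- stats::runif(nS)
      M0 <- (u_m < expit(eta_med[[1]] + v)) + 0
      M1 <- (u_m < expit(eta_med[[2]] + v)) + 0
      Yc <- lapply(1:2, function(t) lapply(1:2, function(m) {
        (u_y < expit(eta_out[[t]][[m]] + u)) + 0
      }))
      for (t in 1:2) {
        for (m in 1:2) acc_C[t, m] <- acc_C[t, m] + sum(Yc[[t]][[m]])
        acc_P[t, 1] <- acc_P[t, 1] +
          sum(M0 * Yc[[t]][[2]] + (1 - M0) * Yc[[t]][[1]])
        acc_P[t, 2] <- acc_P[t, 2] +
          sum(M1 * Yc[[t]][[2]] + (1 - M1) * Yc[[t]][[1]])
      }
      done <- done + S
    }
    P <- acc_P / (n * n_sims)
    Cm <- acc_C / (n * n_sims)
    dimnames(P) <- list(t = 0:1, tprime = 0:1)
    list(P = P,
         cde_m0 = Cm[2, 1] - Cm[1, 1],
         cde_m1 = Cm[2, 2] - Cm[1, 2],
         effects = effects_from_ptable(P))
  })
}

check_engine_inputs <- function(table, med_fit, out_fit) {
  stopifnot(inherits(table, "trial_table"))
  if (!is.null(med_fit)) {
    stopifnot(inherits(med_fit, "glmm_fit"))
    if (med_fit$spec$response != "mediator") {
      stop_msg("med_fit must be a mediator-model fit")
    }
  }
  stopifnot(inherits(out_fit, "glmm_fit"))
  if (out_fit$spec$response != "outcome") {
    stop_msg("out_fit must be an outcome-model fit")
  }
  invisible(TRUE)
}

#' Natural direct, indirect and total effects by Monte Carlo simulation
#'
#' Estimates the causal effects on the probability-difference scale from the
#' fitted mediator and outcome models.  For each of `n_sims` replicates and
#' each patient, potential mediators `M(0)` and `M(1)` are simulated from
#' the mediator model with treatment forced to each arm (sharing the random
#' intercept realisation and the mediator uniform within a replicate); the
#' four potential outcomes `Y(t, M(t'))` are then simulated from the outcome
#' model with common random numbers across the four cells.  Averaging over
#' patients and replicates gives the table `P(t, t') = P(Y(t, M(t')) = 1)`,
#' from which
#' \itemize{
#'   \item `delta1 = P(1,1) - P(1,0)`, `delta0 = P(0,1) - P(0,0)` (natural
#'     indirect effects),
#'   \item `zeta0 = P(1,0) - P(0,0)`, `zeta1 = P(1,1) - P(0,1)` (natural
#'     direct effects),
#'   \item `tau = P(1,1) - P(0,0)` (total effect),
#' }
#' with `delta_avg` and `zeta_avg` the arm averages.  The composition
#' `tau = delta1 + zeta0 = delta0 + zeta1` holds exactly by construction.
#' The estimand is marginal over covariates (the empirical covariate
#' distribution of `table`) and over surgeons.
#'
#' @param table a [trial_table()] supplying the covariate distribution.
#' @param med_fit,out_fit converged [fit_glmm()] fits of the mediator and
#'   outcome models sharing the table's covariate schema.
#' @param n_sims number of simulation replicates (default 2000).
#' @param seed integer seed.
#' @param re_rule random-intercept rule for potential-outcome draws:
#'   `"draw"` (default; fresh `N(0, sigma^2)` surgeon effects per replicate,
#'   the population-of-surgeons marginal estimand), `"zero"` or `"mode"`.
#' @return a `mediation_estimates` object; confidence intervals are attached
#'   by [bootstrap_effects()].
#' @examples
#' trial <- generate_trial(trial_config(seed = 3))
#' med <- fit_glmm(trial$table, glmm_spec("mediator"), quad_points = 1)
#' out <- fit_glmm(trial$table, glmm_spec("outcome"), quad_points = 1)
#' estimate_natural_effects(trial$table, med, out, n_sims = 200, seed = 1)
#' @export
estimate_natural_effects <- function(table, med_fit, out_fit, n_sims = 2000,
                                     seed = 1L,
                                     re_rule = c("draw", "zero", "mode")) {
  re_rule <- match.arg(re_rule)
  check_engine_inputs(table, med_fit, out_fit)
  res <- run_engine(table, med_fit, out_fit, n_sims, seed, re_rule)
  new_mediation_estimates(res$effects, ptable = res$P, n_sims = n_sims,
                          seed = seed, re_rule = re_rule,
                          cde_m0 = res$cde_m0, cde_m1 = res$cde_m1)
}

#' Controlled direct effects with the mediator mandated or prohibited
#'
#' Simulates the interventional outcomes `Y(t, m)` from the outcome model
#' with the mediator set to `m` for every patient (the mediator model plays
#' no role) and reports `cde_m = P(Y(1, m) = 1) - P(Y(0, m) = 1)` for
#' `m = 0` (co-intervention prohibited) and `m = 1` (mandated).
#'
#' @inheritParams estimate_natural_effects
#' @return an object of class `controlled_effects` with fields `cde_m0`,
#'   `cde_m1`, `n_sims`, `seed` and (after bootstrapping) `ci`.
#' @export
estimate_controlled_effects <- function(table, out_fit, n_sims = 2000,
                                        seed = 1L,
                                        re_rule = c("draw", "zero", "mode")) {
  re_rule <- match.arg(re_rule)
  check_engine_inputs(table, NULL, out_fit)
  if (n_sims < 100) warn_msg("n_sims < 100: Monte Carlo error will be large")
  n <- nrow(table)
  eta_out <- lapply(0:1, function(t) lapply(0:1, function(m) {
    fixed_eta(out_fit, table, t_override = t, m_override = m)
  }))
  fixed_re <- re_rule != "draw"
  with_seed(seed, {
    if (fixed_re) u0 <- engine_re(re_rule, n, out_fit, table)
    acc <- matrix(0, 2, 2)
    block <- max(1L, min(n_sims, as.integer(ceiling(5e5 / n))))
    done <- 0L
    while (done < n_sims) {
      S <- min(block, n_sims - done)
      nS <- n * S
      u <- if (fixed_re) u0 else stats::rnorm(nS, 0, out_fit$sigma)
      u_y <- stats::runif(nS)
      for (t in 1:2) for (m in 1:2) {
        acc[t, m] <- acc[t, m] + sum(u_y < expit(eta_out[[t]][[m]] + u))
      }
      done <- done + S
    }
    Cm <- acc / (n * n_sims)
    structure(list(cde_m0 = Cm[2, 1] - Cm[1, 1],
                   cde_m1 = Cm[2, 2] - Cm[1, 2],
                   n_sims = n_sims, seed = seed, re_rule = re_rule,
                   ci = NULL),
              class = "controlled_effects")
  })
}

#' @export
print.controlled_effects <- function(x, digits = 4, ...) {
  cat("Controlled direct effects (probability-difference scale)\n")
  for (nm in c("cde_m0", "cde_m1")) {
    lab <- if (nm == "cde_m0") "mediator prohibited (m=0)" else "mediator mandated  (m=1)"
    line <- sprintf("  %s: %+.*f", lab, digits, x[[nm]])
    if (!is.null(x$ci) && !is.null(x$ci[[nm]])) {
      line <- sprintf("%s  (%.*f, %.*f)", line, digits, x$ci[[nm]][1],
                      digits, x$ci[[nm]][2])
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' Moderated mediation: effect profiles along a continuous covariate
#'
#' Recomputes the natural-effect estimates with every patient's moderator
#' value set to each point of `grid` (all other covariates at their observed
#' values), giving effect-versus-moderator profiles.  The supplied fits must
#' include the moderator and its interactions with treatment (and, for the
#' outcome model, with the mediator); with all interaction coefficients at
#' zero the profile is flat and equals the unmoderated analysis.
#'
#' @inheritParams estimate_natural_effects
#' @param moderator name of a covariate column of `table`.
#' @param grid strictly increasing numeric vector of moderator values.
#' @return an object of class `moderated_effects`: list with `moderator`,
#'   `grid` and `estimates` (one `mediation_estimates` per grid value).
#' @export
estimate_moderated_effects <- function(table, med_fit, out_fit, moderator,
                                       grid, n_sims = 2000, seed = 1L,
                                       re_rule = c("draw", "zero", "mode")) {
  re_rule <- match.arg(re_rule)
  check_engine_inputs(table, med_fit, out_fit)
  if (!(moderator %in% covariate_names(table))) {
    stop_msg("moderator '", moderator, "' is not a covariate of the table")
  }
  for (fit in list(med_fit, out_fit)) {
    if (!any(grepl(moderator, names(fit$coefficients), fixed = TRUE))) {
      stop_msg("moderator '", moderator, "' is absent from the ",
               fit$spec$response, " fit")
    }
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_msg("grid must be strictly increasing")
  }
  est <- lapply(grid, function(g) {
    tab_g <- table
    tab_g[[moderator]] <- g
    estimate_natural_effects(tab_g, med_fit, out_fit, n_sims = n_sims,
                             seed = seed, re_rule = re_rule)
  })
  structure(list(moderator = moderator, grid = grid, estimates = est),
            class = "moderated_effects")
}

#' @export
print.moderated_effects <- function(x, digits = 4, ...) {
  cat(sprintf("Moderated mediation profile over '%s' (%d grid points)\n",
              x$moderator, length(x$grid)))
  tab <- as.data.frame(x)
  print(round(tab, digits))
  invisible(x)
}

#' @export
as.data.frame.moderated_effects <- function(x, ...) {
  out <- do.call(rbind, lapply(seq_along(x$grid), function(i) {
    e <- x$estimates[[i]]
    data.frame(moderator = x$grid[i],
               delta_avg = e$delta_avg, zeta_avg = e$zeta_avg, tau = e$tau)
  }))
  names(out)[1] <- x$moderator
  out
}

#' @export
plot.moderated_effects <- function(x, which = c("zeta_avg", "delta_avg"), ...) {
  tab <- as.data.frame(x)
  graphics::matplot(tab[[1]], tab[, which, drop = FALSE], type = "l",
                    lty = 1, xlab = x$moderator,
                    ylab = "Probability difference", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::legend("topright", legend = which, lty = 1,
                   col = seq_along(which), bty = "n")
  invisible(x)
}
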