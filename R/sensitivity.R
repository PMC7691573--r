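#' Sensitivity parameters for unmeasured mediator-outcome confounding
#'
#' The sensitivity model postulates a continuous unobserved confounder `U`,
#' scaled to variance 1, with `beta` the log odds ratio of `U` on the
#' outcome conditional on treatment and mediator, and mean contrasts across
#' mediator levels `E(U|M=1,T=t) - E(U|M=0,T=t) = lambda0 + lambda1 * t`.
#' `(0, 0, 0)` is the no-confounding point; values of `beta` or `lambda0`
#' around +/-1 represent large effects.
#'
#' @param beta log odds ratio of U on outcome.
#' @param lambda0 U-mediator mean contrast in the control arm.
#' @param lambda1 additional contrast in the intervention arm.
#' @return an object of class `sensitivity_params`.
#' @export
sensitivity_params <- function(beta, lambda0, lambda1 = 0) {
  stopifnot(is.finite(beta), is.finite(lambda0), is.finite(lambda1))
  if (abs(beta) > 5) warn_msg("|beta| > 5 is outside the plausible range")
  if (abs(lambda0) > 2 || abs(lambda1) > 2) {
    warn_msg("|lambda| > 2 is outside the plausible range")
  }
  structure(list(beta = beta, lambda0 = lambda0, lambda1 = lambda1),
            class = "sensitivity_params")
}

# Logit-scale offsets for the interventional outcome cells implied by the
# postulated confounder.  Fitting the outcome model without U makes the
# observed cell logit absorb beta * E(U|M=m, T=t); under randomisation
# E(U|T=t) = 0, so E(U|M=m,T=t) = (lambda0 + lambda1*t) * (m - p_t) with
# p_t the arm-t mediator uptake.  The de-confounded interventional logit
# (U restored to its marginal N(0,1) and integrated out via the
# logistic-normal factor) is the observed logit minus
# beta * (lambda0 + lambda1*t) * (m - p_t) / sqrt(1 + beta^2 * c2).
sens_shift <- function(params, uptake) {
  s <- sqrt(1 + params$beta^2 * LOGISTIC_NORMAL_C2)
  shift <- matrix(0, 2, 2, dimnames = list(t = 0:1, m = 0:1))
  for (t in 0:1) for (m in 0:1) {
    shift[t + 1, m + 1] <-
      -params$beta * (params$lambda0 + params$lambda1 * t) *
      (m - uptake[t + 1]) / s
  }
  shift
}

arm_uptake <- function(table) {
  c(mean(table$M[table$T == 0]), mean(table$M[table$T == 1]))
}

#' Mediation effects adjusted for postulated unmeasured confounding
#'
#' Re-runs the potential-outcome engine with the outcome model corrected for
#' an unobserved confounder `U` with sensitivity parameters
#' `(beta, lambda0, lambda1)`.  The correction is first-order: the observed
#' mediator coefficient absorbs `beta*lambda0` and the observed
#' treatment-by-mediator coefficient absorbs `beta*lambda1` (with arm-level
#' centering so that `E(U|T) = 0`, as randomisation guarantees), and the
#' restored confounder is integrated out of the interventional outcome
#' probabilities through the standard logistic-normal scaling divisor
#' `sqrt(1 + beta^2 * 16*sqrt(3)/(15*pi))`.  At `beta = 0`, or at
#' `lambda0 = lambda1 = 0`, the adjusted effects are identical to the
#' unadjusted ones (same seed, same draws).
#'
#' @inheritParams estimate_natural_effects
#' @param params a [sensitivity_params()].
#' @return a `mediation_estimates` object with attribute `sensitivity` set
#'   to `params`.
#' @export
adjusted_effects <- function(table, med_fit, out_fit, params,
                             n_sims = 2000, seed = 1L,
                             re_rule = c("draw", "zero", "mode")) {
  re_rule <- match.arg(re_rule)
  check_engine_inputs(table, med_fit, out_fit)
  stopifnot(inherits(params, "sensitivity_params"))
  shift <- sens_shift(params, arm_uptake(table))
  res <- run_engine(table, med_fit, out_fit, n_sims, seed, re_rule,
                    shift = shift)
  out <- new_mediation_estimates(res$effects, ptable = res$P,
                                 n_sims = n_sims, seed = seed,
                                 re_rule = re_rule,
                                 cde_m0 = res$cde_m0, cde_m1 = res$cde_m1)
  attr(out, "sensitivity") <- params
  out
}

# Marginalised (probability-averaging) engine evaluating many shift
# configurations at once; used for bootstrap significance masks where the
# per-cell success probabilities are averaged directly instead of drawing
# binary outcomes (same expectation, lower noise, K shifts vectorised).
surface_core <- function(table, med_fit, out_fit, shifts, n_sims, seed,
                         re_rule = "draw") {
  n <- nrow(table)
  K <- length(shifts)
  eta_med <- lapply(0:1, function(t) fixed_eta(med_fit, table, t_override = t))
  eta_out <- lapply(0:1, function(t) lapply(0:1, function(m) {
    fixed_eta(out_fit, table, t_override = t, m_override = m)
  }))
  shift_vec <- function(t, m) {
    vapply(shifts, function(s) s[t + 1, m + 1], numeric(1))
  }
  fixed_re <- re_rule != "draw"
  with_seed(seed, {
    if (fixed_re) {
      v0 <- engine_re(re_rule, n, med_fit, table)
      u0 <- engine_re(re_rule, n, out_fit, table)
    }
    acc_zeta <- numeric(K)
    acc_delta <- numeric(K)
    ones <- rep(1, K)
    for (j in seq_len(n_sims)) {
      v <- if (fixed_re) v0 else stats::rnorm(n, 0, med_fit$sigma)
      u <- if (fixed_re) u0 else stats::rnorm(n, 0, out_fit$sigma)
      pM <- lapply(1:2, function(t) expit(eta_med[[t]] + v))   # n-vectors
      # n x K matrices of interventional cell probabilities
      Ecell <- lapply(0:1, function(t) lapply(0:1, function(m) {
        expit(outer(eta_out[[t + 1]][[m + 1]] + u, shift_vec(t, m), "+"))
      }))
      P <- function(t, tp) {   # K-vector of mean P(Y(t, M(tp)) = 1)
        colMeans(pM[[tp + 1]] * Ecell[[t + 1]][[2]] +
                   (1 - pM[[tp + 1]]) * Ecell[[t + 1]][[1]])
      }
      p00 <- P(0, 0); p01 <- P(0, 1); p10 <- P(1, 0); p11 <- P(1, 1)
      acc_zeta <- acc_zeta + ((p10 - p00) + (p11 - p01)) / 2
      acc_delta <- acc_delta + ((p01 - p00) + (p11 - p10)) / 2
    }
    list(zeta_avg = acc_zeta / n_sims, delta_avg = acc_delta / n_sims)
  })
}

#' Sensitivity surface of adjusted effects over a (beta, lambda0) grid
#'
#' Computes adjusted average natural direct and indirect effects at every
#' point of a `beta` x `lambda0` grid with `lambda1` held fixed, plus an
#' optional bootstrap significance mask and the crossing frontier (grid
#' cells where the adjusted direct effect changes sign or loses
#' significance).  Point estimates reuse the engine with identical draws at
#' every grid point (common random numbers), so the surface is smooth and
#' its value at the no-confounding origin equals the unadjusted estimate
#' exactly.  The bootstrap mask resamples and refits `n_boot` times and
#' evaluates the whole grid per replicate with the marginalised
#' (probability-averaging) engine.
#'
#' @inheritParams adjusted_effects
#' @param beta_grid,lambda0_grid sorted numeric grids (defaults
#'   `seq(-1, 1, 0.25)`, 0 meaning no unexplained confounding and +/-1 large
#'   effects).
#' @param lambda1 fixed value of the intervention-arm extra contrast
#'   (default 0).
#' @param med_spec,out_spec model specs used for bootstrap refits.
#' @param n_boot bootstrap replicates for the significance mask (0 = no
#'   mask).
#' @param level significance level for the mask (default 0.95).
#' @param resample_unit bootstrap resampling unit.
#' @param boot_n_sims engine replicates per bootstrap refit (default 100).
#' @param quad_points quadrature points for bootstrap refits.
#' @return an object of class `sensitivity_grid`: list with `beta_grid`,
#'   `lambda0_grid`, `lambda1`, matrices `zeta_avg` and `delta_avg` (rows =
#'   beta, columns = lambda0), logical matrix `significant` (or `NULL`),
#'   `ci_lo`/`ci_hi` matrices for the adjusted NDE, and `frontier` (data
#'   frame of grid cells where the adjusted NDE changes sign relative to
#'   the unadjusted estimate or is non-significant).
#' @export
sensitivity_surface <- function(table, med_fit, out_fit,
                                beta_grid = seq(-1, 1, 0.25),
                                lambda0_grid = seq(-1, 1, 0.25),
                                lambda1 = 0,
                                n_sims = 2000, seed = 1L,
                                re_rule = c("draw", "zero", "mode"),
                                med_spec = glmm_spec("mediator"),
                                out_spec = glmm_spec("outcome"),
                                n_boot = 0, level = 0.95,
                                resample_unit = c("patient", "cluster"),
                                boot_n_sims = 100, quad_points = 1) {
  re_rule <- match.arg(re_rule)
  resample_unit <- match.arg(resample_unit)
  if (!length(beta_grid) || !length(lambda0_grid)) {
    stop_msg("grids must be non-empty")
  }
  if (is.unsorted(beta_grid) || is.unsorted(lambda0_grid)) {
    stop_msg("grids must be sorted increasing")
  }
  check_engine_inputs(table, med_fit, out_fit)
  nb <- length(beta_grid); nl <- length(lambda0_grid)
  dn <- list(beta = format(beta_grid), lambda0 = format(lambda0_grid))
  zeta <- delta <- matrix(NA_real_, nb, nl, dimnames = dn)
  for (i in seq_len(nb)) for (j in seq_len(nl)) {
    pars <- suppressWarnings(
      sensitivity_params(beta_grid[i], lambda0_grid[j], lambda1))
    est <- adjusted_effects(table, med_fit, out_fit, pars,
                            n_sims = n_sims, seed = seed, re_rule = re_rule)
    zeta[i, j] <- est$zeta_avg
    delta[i, j] <- est$delta_avg
  }

  signif_mat <- ci_lo <- ci_hi <- NULL
  if (n_boot > 0) {
    uptake_shifts <- function(tab) {
      up <- arm_uptake(tab)
      lapply(seq_len(nb * nl), function(k) {
        i <- (k - 1) %% nb + 1; j <- (k - 1) %/% nb + 1
        pars <- list(beta = beta_grid[i], lambda0 = lambda0_grid[j],
                     lambda1 = lambda1)
        sens_shift(pars, up)
      })
    }
    reps <- matrix(NA_real_, n_boot, nb * nl)
    failed <- 0L
    with_seed(sub_seed(seed, 1001), {
      for (b in seq_len(n_boot)) {
        z_b <- tryCatch({
          tab_b <- resample_table(table, resample_unit)
          mf <- fit_glmm(tab_b, med_spec, quad_points = quad_points)
          of <- fit_glmm(tab_b, out_spec, quad_points = quad_points)
          if (!mf$converged || !of$converged) stop("refit did not converge")
          surface_core(tab_b, mf, of, uptake_shifts(tab_b),
                       n_sims = boot_n_sims, seed = sub_seed(seed, b),
                       re_rule = re_rule)$zeta_avg
        }, error = function(e) NULL)
        if (is.null(z_b)) failed <- failed + 1L else reps[b, ] <- z_b
      }
    })
    if (failed > 0.2 * n_boot) {
      stop_msg(failed, "/", n_boot, " bootstrap refits failed during the ",
               "sensitivity surface")
    }
    reps <- reps[stats::complete.cases(reps), , drop = FALSE]
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    qs <- apply(reps, 2, stats::quantile, probs = probs, names = FALSE)
    ci_lo <- matrix(qs[1, ], nb, nl, dimnames = dn)
    ci_hi <- matrix(qs[2, ], nb, nl, dimnames = dn)
    signif_mat <- ci_lo > 0 | ci_hi < 0
  }

  i0 <- match(0, beta_grid); if (is.na(i0)) i0 <- 1L
  j0 <- match(0, lambda0_grid); if (is.na(j0)) j0 <- 1L
  zeta0_ref <- zeta[i0, j0]
  frontier <- NULL
  cross <- (sign(zeta) != sign(zeta0_ref)) |
    (if (is.null(signif_mat)) matrix(FALSE, nb, nl) else !signif_mat)
  if (any(cross)) {
    idx <- which(cross, arr.ind = TRUE)
    frontier <- data.frame(beta = beta_grid[idx[, 1]],
                           lambda0 = lambda0_grid[idx[, 2]],
                           zeta_avg = zeta[cross],
                           significant = if (is.null(signif_mat)) NA
                                         else signif_mat[cross])
  }
  structure(list(beta_grid = beta_grid, lambda0_grid = lambda0_grid,
                 lambda1 = lambda1, zeta_avg = zeta, delta_avg = delta,
                 significant = signif_mat, ci_lo = ci_lo, ci_hi = ci_hi,
                 frontier = frontier, level = level),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, digits = 3, ...) {
  cat(sprintf("Sensitivity surface: adjusted NDE zeta(a*) over beta x lambda0 (lambda1 = %g)\n",
              x$lambda1))
  print(round(x$zeta_avg, digits))
  if (!is.null(x$significant)) {
    cat(sprintf("\nNon-significant at the %g%% level (bootstrap):\n",
                100 * (1 - x$level)))
    print(x$significant == FALSE)
  }
  if (!is.null(x$frontier)) {
    cat("\nCrossing frontier cells:", nrow(x$frontier), "\n")
  }
  invisible(x)
}

#' @export
plot.sensitivity_grid <- function(x, ...) {
  graphics::contour(x$beta_grid, x$lambda0_grid, x$zeta_avg,
                    xlab = expression(beta), ylab = expression(lambda[0]),
                    ...)
  if (!is.null(x$significant) && any(!x$significant)) {
    idx <- which(!x$significant, arr.ind = TRUE)
    graphics::points(x$beta_grid[idx[, 1]], x$lambda0_grid[idx[, 2]],
                     pch = 4, col = "red")
  }
  invisible(x)
}
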