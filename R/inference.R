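#' Monte Carlo standard error of a replicate vector
#'
#' @param replicates numeric vector of at least 2 replicate estimates.
#' @return the standard deviation of the replicates.
#' @export
mc_standard_error <- function(replicates) {
  if (length(replicates) < 2) stop_msg("need at least 2 replicates")
  stats::sd(replicates)
}

resample_table <- function(table, unit) {
  if (unit == "patient") {
    # stratified by arm: resample patients with replacement within each arm
    idx <- unlist(lapply(c(0L, 1L), function(a) {
      rows <- which(table$T == a)
      sample(rows, length(rows), replace = TRUE)
    }))
    df <- as.data.frame(table)[idx, , drop = FALSE]
  } else {
    cl_idx <- attr(table, "cluster_index")
    labs <- names(cl_idx)
    take <- sample(labs, length(labs), replace = TRUE)
    pieces <- lapply(seq_along(take), function(i) {
      piece <- as.data.frame(table)[cl_idx[[take[i]]], , drop = FALSE]
      piece$cluster <- paste0(take[i], ".", i)  # drawn copies are new clusters
      piece
    })
    df <- do.call(rbind, pieces)
  }
  rownames(df) <- NULL
  # rows are drawn from an already-validated table, so only the structural
  # invariants that resampling can break are rechecked
  arm_sizes <- c(`0` = sum(df$T == 0L), `1` = sum(df$T == 1L))
  if (any(arm_sizes == 0)) stop_msg("degenerate resample: an arm is empty")
  cluster_index <- split(seq_len(nrow(df)), df$cluster)
  if (length(cluster_index) < 2L) {
    stop_msg("degenerate resample: fewer than 2 clusters")
  }
  structure(df,
            schema = attr(table, "schema"),
            arm_sizes = arm_sizes,
            cluster_index = cluster_index,
            class = c("trial_table", "data.frame"))
}

#' Nonparametric bootstrap confidence intervals for all mediation effects
#'
#' For each bootstrap replicate the data are resampled (patients with
#' replacement within arm, or whole surgeon clusters with replacement, drawn
#' copies treated as new clusters), both models are refitted, and the Monte
#' Carlo engine is rerun with a replicate-specific sub-seed.  Percentile
#' confidence intervals are formed from the replicate distribution of each
#' effect.  Refits that fail or do not converge are dropped and counted;
#' more than 20% failures is an error.
#'
#' @param table a [trial_table()].
#' @param med_spec,out_spec [glmm_spec()]s for the two models.
#' @param n_boot number of bootstrap replicates (>= 199; default 999).
#' @param level confidence level (default 0.95).
#' @param seed integer seed driving resampling and all engine sub-seeds.
#' @param resample_unit `"patient"` (default, stratified by arm) or
#'   `"cluster"`.
#' @param n_sims engine replicates per bootstrap refit.
#' @param re_rule random-intercept rule passed to the engine.
#' @param quad_points quadrature points for the refits.
#' @return an object of class `mediation_boot`: list with `estimates` (a
#'   `mediation_estimates` with percentile CIs attached), `controlled` (a
#'   `controlled_effects` with CIs) and `boot` (replicate matrix, failure
#'   count, `n_boot`, `level`, `seed`).  Percentile intervals need not
#'   contain the point estimate in finite samples.
#' @examples
#' \donttest{
#' trial <- generate_trial(trial_config(n_patients = 200, seed = 5))
#' bootstrap_effects(trial$table, n_boot = 199, seed = 1,
#'                   n_sims = 200, quad_points = 1)
#' }
#' @export
bootstrap_effects <- function(table,
                              med_spec = glmm_spec("mediator"),
                              out_spec = glmm_spec("outcome"),
                              n_boot = 999, level = 0.95, seed = 1L,
                              resample_unit = c("patient", "cluster"),
                              n_sims = 2000,
                              re_rule = c("draw", "zero", "mode"),
                              quad_points = 7) {
  resample_unit <- match.arg(resample_unit)
  re_rule <- match.arg(re_rule)
  if (n_boot < 199) stop_msg("n_boot must be >= 199 for percentile intervals")

  med_fit <- fit_glmm(table, med_spec, quad_points = quad_points)
  out_fit <- fit_glmm(table, out_spec, quad_points = quad_points)
  point <- estimate_natural_effects(table, med_fit, out_fit, n_sims = n_sims,
                                    seed = seed, re_rule = re_rule)

  nms <- c(effect_names(), "cde_m0", "cde_m1")
  reps <- matrix(NA_real_, n_boot, length(nms), dimnames = list(NULL, nms))
  failed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      est_b <- tryCatch({
        tab_b <- resample_table(table, resample_unit)
        mf <- fit_glmm(tab_b, med_spec, quad_points = quad_points)
        of <- fit_glmm(tab_b, out_spec, quad_points = quad_points)
        if (!mf$converged || !of$converged) stop("refit did not converge")
        estimate_natural_effects(tab_b, mf, of, n_sims = n_sims,
                                 seed = sub_seed(seed, b), re_rule = re_rule)
      }, error = function(e) NULL)
      if (is.null(est_b)) failed <- failed + 1L
      else reps[b, ] <- vapply(nms, function(nm) est_b[[nm]], numeric(1))
    }
  })
  if (failed > 0.2 * n_boot) {
    stop_msg(failed, "/", n_boot, " bootstrap refits failed; ",
             "consider larger data or a simpler model")
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- lapply(as.data.frame(reps), stats::quantile, probs = probs,
               names = FALSE)
  point$ci <- ci
  controlled <- structure(list(cde_m0 = point$cde_m0, cde_m1 = point$cde_m1,
                               n_sims = n_sims, seed = seed,
                               re_rule = re_rule,
                               ci = ci[c("cde_m0", "cde_m1")]),
                          class = "controlled_effects")
  structure(list(estimates = point, controlled = controlled,
                 boot = list(replicates = reps, n_boot = n_boot,
                             failed = failed, level = level, seed = seed,
                             resample_unit = resample_unit)),
            class = "mediation_boot")
}

#' @export
print.mediation_boot <- function(x, ...) {
  cat(sprintf("Bootstrap inference: %d replicates (%d failed refits dropped), %g%% percentile CIs, %s resampling\n",
              x$boot$n_boot, x$boot$failed, 100 * x$boot$level,
              x$boot$resample_unit))
  print(x$estimates)
  invisible(x)
}
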