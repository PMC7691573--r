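# Internal helpers shared across modules.

#' Inverse logit
#'
#' @param x numeric vector on the log-odds scale.
#' @return numeric vector of probabilities.
#' @keywords internal
expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) stats::qlogis(p)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-stream seeds: a Lehmer step keeps derived seeds spread over
# the 31-bit range while staying reproducible from (seed, k).
sub_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

# Latent-scale residual variance of the logistic distribution.
LOGIT_RESID_VAR <- pi^2 / 3

# Scaling constant of the logistic-normal marginalisation approximation
# expit(x/sqrt(1 + c2 * v)) ~= E[expit(x + Z)], Z ~ N(0, v).
LOGISTIC_NORMAL_C2 <- 16 * sqrt(3) / (15 * pi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_msg <- function(...) stop(..., call. = FALSE)
warn_msg <- function(...) warning(..., call. = FALSE)
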