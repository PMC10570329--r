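#' @importFrom rlang %||% .data abort warn inform
#' @importFrom stats lm lm.fit glm coef vcov median quantile sd var cor
#'   rnorm runif rbinom qnorm pnorm plogis qt pt rchisq complete.cases
#'   binomial predict model.matrix setNames uniroot weighted.mean
#' @importFrom utils head tail
NULL

# Deterministic child-seed scheme: every stage draws its own seed from the
# master seed and a stage counter, so stages are independently reproducible
# and inserting a stage never perturbs the streams of later ones.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  # LCG step keeps the result in [0, 2^31 - 2] (valid R integer seed)
  as.integer((as.double(seed) * 48271 + 9157 * as.double(stage)) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Truncated normal via inverse-CDF; degenerate bounds collapse to the bound.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Log-normal with an upper cap, truncated by inverse-CDF on the log scale.
rlnorm_capped <- function(n, meanlog, sdlog, upper = Inf) {
  hi <- if (is.finite(upper)) pnorm(log(upper), meanlog, sdlog) else 1
  exp(qnorm(runif(n, 0, hi), meanlog, sdlog))
}

# Multivariate normal draw (rows = draws) via Cholesky.
rmvnorm_chol <- function(n, sigma) {
  p <- ncol(sigma)
  z <- matrix(rnorm(n * p), n, p)
  z %*% chol(sigma)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
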