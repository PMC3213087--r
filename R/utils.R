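# Internal numerical helpers shared across modules.

#' @importFrom stats rnorm runif dnorm sd var qnorm density setNames
#' @importFrom utils head modifyList packageVersion
NULL

#' Cholesky factorisation with a single bounded jitter rescue
#'
#' Attempts `chol(S)`; on failure adds `1e-10 * mean(diag(S))` to the diagonal
#' once and retries.  A second failure is a hard error naming the matrix as
#' numerically degenerate, so silent inflation of the covariance is impossible.
#'
#' @param S symmetric matrix.
#' @param label character used in the error message.
#' @return upper-triangular Cholesky factor, with attribute `"jittered"`
#'   (logical) recording whether the rescue was applied.
#' @keywords internal
#' @noRd
chol_jitter <- function(S, label = "covariance matrix") {
  R <- tryCatch(chol(S), error = function(e) NULL)
  jittered <- FALSE
  if (is.null(R)) {
    eps <- 1e-10 * mean(diag(S))
    R <- tryCatch(chol(S + diag(eps, nrow(S))), error = function(e) NULL)
    jittered <- TRUE
    if (is.null(R)) {
      stop("Cholesky factorisation of ", label, " failed even after jitter; ",
           "parameter values give a numerically degenerate covariance.",
           call. = FALSE)
    }
  }
  attr(R, "jittered") <- jittered
  R
}

# log density of N(mean, Sigma) at y, given the upper Cholesky factor of Sigma
log_dmvnorm_chol <- function(y, mean, R) {
  r <- backsolve(R, y - mean, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(r * r)
}

log_dmvnorm <- function(y, mean, Sigma, label = "covariance matrix") {
  log_dmvnorm_chol(y, mean, chol_jitter(Sigma, label))
}

# one draw from N(mean, Sigma) given the upper Cholesky factor
rmvnorm_chol <- function(mean, R) {
  drop(mean + crossprod(R, rnorm(length(mean))))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# triangular prior density 1 - |psi| on (-1, 1), log scale
log_dtriangular <- function(psi) {
  ifelse(abs(psi) < 1, log1p(-abs(psi)), -Inf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
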