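# Closed-form Gaussian computations with the regression coefficients
# integrated out.  These are what make the reversible-jump move "partial
# analytic": a model move needs only the marginal (integrated) likelihood
# p(y | M_k, theta) = N(y; X_k m_k, X_k V_k X_k' + Sigma(theta)),
# so no coefficient proposal is ever drawn.

#' Normal prior on the regression coefficients
#'
#' Prior over the full candidate coefficient vector; for a model the
#' sub-vector/sub-matrix indexed by the inclusion indicator is used.
#'
#' @param mean numeric p-vector of prior means.
#' @param cov prior covariance: a p x p symmetric positive-definite matrix or
#'   a length-p vector of variances (diagonal prior).
#' @return object of class `coef_prior` with elements `mean` and `cov`.
#' @export
coef_prior <- function(mean, cov) {
  p <- length(mean)
  if (is.vector(cov) && !is.matrix(cov)) {
    if (length(cov) == 1L) cov <- rep(cov, p)
    stopifnot(length(cov) == p, all(cov > 0))
    cov <- diag(cov, p)
  }
  stopifnot(all(dim(cov) == p), isSymmetric(unname(cov), tol = 1e-8))
  structure(list(mean = as.numeric(mean), cov = unname(cov)), class = "coef_prior")
}

# restrict a coef_prior to the columns of a model
restrict_prior <- function(prior, keep) {
  list(mean = prior$mean[keep], cov = prior$cov[keep, keep, drop = FALSE])
}

#' Integrated (marginal) log likelihood of a Gaussian spatial model
#'
#' With coefficients \eqn{\beta \sim N(m, V)} integrated out analytically,
#' the marginal of the response is
#' \eqn{y \sim N(X m,\; X V X^\top + \Sigma)}, evaluated via Cholesky.
#' `X` with zero columns (the all-excluded model with no forced covariates)
#' is supported and gives the mean-zero evidence \eqn{N(y; 0, \Sigma)}.
#'
#' @param y numeric response vector of length n.
#' @param X n x q model design matrix (q may be 0).
#' @param Sigma n x n spatial covariance matrix.
#' @param prior_mean,prior_cov prior mean (length q) and covariance (q x q)
#'   of the included coefficients.
#' @return log marginal likelihood (scalar).
#' @export
integrated_log_likelihood <- function(y, X, Sigma, prior_mean, prior_cov) {
  n <- length(y)
  if (is.null(X)) X <- matrix(0, n, 0)
  X <- as.matrix(X)
  q <- ncol(X)
  if (nrow(X) != n || nrow(Sigma) != n || ncol(Sigma) != n) {
    stop("dimension mismatch between `y`, `X`, and `Sigma`.", call. = FALSE)
  }
  if (q == 0L) {
    return(log_dmvnorm(y, rep(0, n), Sigma))
  }
  prior_cov <- as.matrix(prior_cov)
  if (length(prior_mean) != q || any(dim(prior_cov) != q)) {
    stop("coefficient prior dimensions do not match the design matrix.",
         call. = FALSE)
  }
  M <- Sigma + X %*% prior_cov %*% t(X)
  log_dmvnorm(y, drop(X %*% prior_mean), M, label = "marginal covariance")
}

#' Conditional log posterior of a model given the spatial parameters
#'
#' Up to a constant, \eqn{\log p(M_k \mid y, \theta) =
#' \log p(y \mid M_k, \theta) + \log p(M_k)}: the integrated likelihood of
#' the model's design columns plus the Bernoulli-product model prior.
#' Normalising `exp()` of these values over an enumerated model set yields
#' exact posterior model probabilities for fixed `theta`.
#'
#' @param y Gaussian response (or, in the Poisson branch of the sampler, the
#'   current latent field).
#' @param gamma 0/1 inclusion vector over the columns of `X_all`.
#' @param Sigma n x n spatial covariance at the current `theta`.
#' @param X_all n x p full candidate design matrix.
#' @param prior [coef_prior] on the full candidate coefficient vector.
#' @param prior_inclusion prior inclusion probabilities (scalar or p-vector).
#' @param forced logical mask of forced covariates.
#' @return unnormalised log posterior (may be `-Inf` if the model has prior
#'   probability zero).
#' @export
log_conditional_model_posterior <- function(y, gamma, Sigma, X_all, prior,
                                            prior_inclusion = 0.5,
                                            forced = NULL) {
  forced <- forced %||% attr(gamma, "forced") %||% rep(FALSE, length(gamma))
  if (length(prior_inclusion) == 1L) {
    prior_inclusion <- rep(prior_inclusion, length(gamma))
  }
  prior_inclusion[forced] <- 1      # forced columns are in every model
  lp <- log_model_prior(gamma, prior_inclusion, forced)
  if (!is.finite(lp)) return(-Inf)
  keep <- as.integer(gamma) == 1L
  pr <- restrict_prior(prior, keep)
  ll <- integrated_log_likelihood(y, X_all[, keep, drop = FALSE], Sigma,
                                  pr$mean, pr$cov)
  ll + lp
}

#' Full conditional of the included coefficients
#'
#' Conjugate normal update: posterior covariance
#' \eqn{(X^\top \Sigma^{-1} X + V^{-1})^{-1}} and mean
#' \eqn{\mathrm{cov} \, (X^\top \Sigma^{-1} y + V^{-1} m)}, computed through
#' Cholesky factorisations (no explicit n x n inverse).
#'
#' @inheritParams integrated_log_likelihood
#' @return list with `mean` (length q) and `cov` (q x q symmetric PD).
#' @export
beta_full_conditional <- function(y, X, Sigma, prior_mean, prior_cov) {
  X <- as.matrix(X)
  q <- ncol(X)
  stopifnot(q >= 1L, length(prior_mean) == q)
  prior_cov <- as.matrix(prior_cov)
  Rs <- attr(Sigma, "chol") %||% chol_jitter(Sigma, "spatial covariance")
  # whitened design and response: Sigma^{-1/2} X, Sigma^{-1/2} y
  Xw <- backsolve(Rs, X, transpose = TRUE)
  yw <- backsolve(Rs, y, transpose = TRUE)
  Rv <- chol_jitter(prior_cov, "coefficient prior covariance")
  V_inv <- chol2inv(Rv)
  prec <- crossprod(Xw) + V_inv
  prec <- (prec + t(prec)) / 2
  Rp <- chol_jitter(prec, "coefficient full-conditional precision")
  cov <- chol2inv(Rp)
  cov <- (cov + t(cov)) / 2
  mean <- drop(cov %*% (crossprod(Xw, yw) + V_inv %*% prior_mean))
  list(mean = mean, cov = cov)
}

#' Draw coefficients from their full conditional
#'
#' One multivariate-normal draw from the Gibbs full conditional returned by
#' [beta_full_conditional()].
#'
#' @param fc list with `mean` and `cov`.
#' @return numeric vector of the same length as `fc$mean`.
#' @export
draw_beta <- function(fc) {
  R <- chol_jitter(fc$cov, "full-conditional covariance")
  rmvnorm_chol(fc$mean, R)
}

#' Exact model posterior by enumeration (fixed spatial parameters)
#'
#' Enumerates every model over the selectable covariates and normalises
#' their conditional posteriors [log_conditional_model_posterior()], giving
#' the exact distribution \eqn{p(M_k \mid y, \theta)} that the reversible-
#' jump move targets when the spatial parameters are held fixed.  Feasible
#' for modest covariate sets only (at most 20 selectable covariates).
#'
#' @inheritParams log_conditional_model_posterior
#' @return tibble with columns `model` (bit-string over all candidate
#'   columns), `log_post` (unnormalised), and `prob`.
#' @export
enumerate_model_posterior <- function(y, Sigma, X_all, prior,
                                      prior_inclusion = 0.5, forced = NULL) {
  p <- ncol(X_all)
  forced <- forced %||% rep(FALSE, p)
  sel <- which(!forced)
  models <- enumerate_model_space(length(sel), forced = rep(TRUE, sum(forced)))
  # enumerate_model_space orders columns forced-first; remap onto X_all order
  remap <- function(m) {
    g <- integer(p)
    g[forced] <- 1L
    g[sel] <- as.integer(m)[(sum(forced) + 1):length(m)]
    g
  }
  lp <- vapply(models, function(m) {
    g <- remap(m)
    log_conditional_model_posterior(y, g, Sigma, X_all, prior,
                                    prior_inclusion, forced)
  }, numeric(1))
  bits <- vapply(models, function(m) paste(remap(m), collapse = ""), character(1))
  prob <- exp(lp - logsumexp(lp))
  tibble::tibble(model = bits, log_post = lp, prob = prob / sum(prob)) |>
    dplyr::arrange(dplyr::desc(.data$prob))
}
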