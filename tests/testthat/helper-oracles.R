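# Independent oracles used across the suite.  These deliberately avoid the
# package's Cholesky-based computation path: densities go through
# determinant() + solve(), and marginal likelihoods through nested adaptive
# quadrature over the coefficients.

# reference multivariate-normal log density (determinant + linear solve)
dmvn_log_ref <- function(y, mean, S) {
  r <- y - mean
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * length(y) * log(2 * pi) - 0.5 * ld - 0.5 * sum(r * solve(S, r))
}

# log evidence  log \int N(y; X beta, Sigma) N(beta; m, V) d beta
# by numerical integration in mode-centred, curvature-scaled coordinates:
# adaptive quadrature for q <= 2, a Gauss-Hermite product rule for q = 3
oracle_evidence <- function(y, X, Sigma, m, V, half_width = 10) {
  X <- as.matrix(X)
  q <- ncol(X)
  if (q == 0L) return(dmvn_log_ref(y, rep(0, length(y)), Sigma))
  logf <- function(beta) {
    dmvn_log_ref(y, drop(X %*% beta), Sigma) + dmvn_log_ref(beta, m, V)
  }
  opt <- stats::optim(m, function(b) -logf(b), method = "BFGS", hessian = TRUE)
  mode <- opt$par
  M <- -opt$value
  Hinv <- solve(opt$hessian)
  B <- t(chol((Hinv + t(Hinv)) / 2))       # beta = mode + B u, |u| ~ N(0, I)
  ldetB <- sum(log(diag(B)))
  h <- function(u) exp(logf(mode + drop(B %*% u)) - M)
  val <- if (q == 1L) {
    stats::integrate(Vectorize(h), -half_width, half_width,
                     rel.tol = 1e-10, abs.tol = 0)$value
  } else if (q == 2L) {
    stats::integrate(Vectorize(function(u1) {
      stats::integrate(Vectorize(function(u2) h(c(u1, u2))),
                       -half_width, half_width,
                       rel.tol = 1e-9, abs.tol = 0)$value
    }), -half_width, half_width, rel.tol = 1e-9, abs.tol = 0)$value
  } else if (q <= 4L) {
    # Gauss-Hermite product rule in the scaled coordinates:
    # \int h(u) du = sqrt(2)^q sum_grid prod(w) e^{|x|^2} h(sqrt(2) x)
    gh <- pracma::gaussHermite(20)
    idx <- as.matrix(do.call(expand.grid, rep(list(seq_along(gh$x)), q)))
    terms <- apply(idx, 1, function(ii) {
      x <- gh$x[ii]
      prod(gh$w[ii]) * exp(sum(x^2)) * h(sqrt(2) * x)
    })
    sqrt(2)^q * sum(terms)
  } else {
    stop("oracle supports q <= 4")
  }
  M + ldetB + log(val)
}

# random Gaussian spatial fixture with an exponential-covariance Sigma built
# by plain base-R arithmetic (double loop free: dist())
random_fixture <- function(n, q, seed, sill = 1, nugget = 0.3, range = 0.5,
                           prior_var = 2) {
  set.seed(seed)
  coords <- cbind(runif(n), runif(n))
  D <- as.matrix(stats::dist(coords))
  Sigma <- sill * exp(-D / range) + diag(nugget, n)
  X <- if (q > 0) cbind(1, matrix(rnorm(n * (q - 1)), n, q - 1))[, seq_len(q), drop = FALSE]
       else matrix(0, n, 0)
  m <- rnorm(q, 0, 0.5)
  V <- diag(prior_var, q)
  beta_true <- rnorm(q)
  y <- drop(X %*% beta_true) + drop(rnorm(n) %*% chol(Sigma))
  list(coords = coords, Sigma = Sigma, X = X, y = y, m = m, V = V)
}

# Kolmogorov-Smirnov distance between draws and a reference CDF
ks_distance <- function(draws, cdf) {
  s <- sort(draws)
  n <- length(s)
  u <- cdf(s)
  max(abs(u - seq_len(n) / n), abs(u - (seq_len(n) - 1) / n))
}

# CDF of the triangular density 1 - |x| on (-1, 1)
ptriangular <- function(x) {
  ifelse(x < -1, 0,
         ifelse(x < 0, (x + 1)^2 / 2,
                ifelse(x < 1, 1 - (1 - x)^2 / 2, 1)))
}

# total-variation distance between two discrete distributions keyed by name
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  p2 <- setNames(rep(0, length(keys)), keys); p2[names(p)] <- p
  q2 <- setNames(rep(0, length(keys)), keys); q2[names(q)] <- q
  0.5 * sum(abs(p2 - q2))
}

# a small Gaussian dataset + parj_data pair used by several sampler tests
tiny_gaussian_data <- function(seed = 42) {
  sc <- recovery_scenario("tiny-enum", seed = seed)
  d <- simulate_gaussian_data(sc)
  list(df = d, pd = parj_data(d, coords = c("x", "y"), response = "resp"),
       truth = attr(d, "truth"))
}
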