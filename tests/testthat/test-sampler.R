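# correctness checks for each kernel of the PARJ sweep, plus whole-chain
# validation against exact enumeration and a successive-conditional
# (Geweke-style) prior-invariance run

poisson_fixture <- function(n = 30, seed = 500) {
  sc <- sim_scenario(
    n_sites = n,
    true_theta = cov_params(sill = 0.4, nugget = NULL, ranges = 0.3),
    true_beta = c(`(Intercept)` = 1, x1 = 0.5, x2 = 0),
    family = "poisson", seed = seed)
  d <- simulate_poisson_data(sc)
  pd <- parj_data(d, coords = c("x", "y"), response = "resp",
                  family = "poisson")
  cfg <- parj_config(n_iter = 200, burn_in = 50, include_nugget = FALSE,
                     seed = seed)
  list(pd = pd, cfg = cfg, state = init_chain_state(pd, cfg))
}

test_that("log joint is deterministic and finite on valid states", {
  tg <- tiny_gaussian_data()
  cfg <- parj_config(n_iter = 100, burn_in = 10, seed = 1)
  st <- init_chain_state(tg$pd, cfg)
  lj1 <- log_joint(st, tg$pd, cfg)
  lj2 <- log_joint(st, tg$pd, cfg)
  expect_identical(lj1, lj2)
  expect_true(is.finite(lj1))
  fx <- poisson_fixture()
  expect_true(is.finite(log_joint(fx$state, fx$pd, fx$cfg)))
})

test_that("poisson observation term contributes y*z - exp(z) - log(y!)", {
  fx <- poisson_fixture(n = 12, seed = 501)
  st <- fx$state
  lj0 <- log_joint(st, fx$pd, fx$cfg)
  st2 <- st
  st2$z <- st$z + c(0.3, rep(0, 11))   # perturb one site only
  lj1 <- log_joint(st2, fx$pd, fx$cfg)
  y1 <- fx$pd$y[1]
  # difference decomposes into the Poisson term plus the Gaussian-layer term
  mu <- drop(fx$pd$X[, st$gamma == 1, drop = FALSE] %*% st$beta[st$gamma == 1])
  R <- attr(st$Sigma, "chol")
  gauss_diff <- geobma:::log_dmvnorm_chol(st2$z, mu, R) -
    geobma:::log_dmvnorm_chol(st$z, mu, R)
  pois_diff <- (y1 * st2$z[1] - exp(st2$z[1])) - (y1 * st$z[1] - exp(st$z[1]))
  expect_equal(lj1 - lj0, gauss_diff + pois_diff, tolerance = 1e-10)
})

test_that("gaussian joint satisfies the marginal-likelihood identity", {
  tg <- tiny_gaussian_data()
  cfg <- parj_config(n_iter = 100, burn_in = 10, seed = 2)
  st <- init_chain_state(tg$pd, cfg)
  pr <- st$priors
  keep <- st$gamma == 1
  X <- tg$pd$X[, keep, drop = FALSE]
  rp <- geobma:::restrict_prior(pr$coef_prior, keep)
  ll_int <- integrated_log_likelihood(tg$pd$y, X, st$Sigma, rp$mean, rp$cov)
  fc <- beta_full_conditional(tg$pd$y, X, st$Sigma, rp$mean, rp$cov)
  b <- st$beta[keep]
  ident <- dmvn_log_ref(tg$pd$y, drop(X %*% b), st$Sigma) +
    dmvn_log_ref(b, rp$mean, rp$cov) - dmvn_log_ref(b, fc$mean, fc$cov)
  expect_equal(ll_int, ident, tolerance = 1e-8)
})

test_that("latent gradient vanishes at the joint stationary point", {
  fx <- poisson_fixture(n = 10, seed = 502)
  st <- fx$state
  st$beta <- numeric(3)               # mean zero
  st$z <- rep(0, 10)
  pd0 <- fx$pd
  pd0$y <- rep(1L, 10)                # y = exp(z) at z = 0
  g <- latent_log_gradient(st, pd0)
  expect_equal(g, rep(0, 10), tolerance = 1e-12)
  tg <- tiny_gaussian_data()
  cfgg <- parj_config(n_iter = 100, burn_in = 10)
  expect_error(latent_log_gradient(init_chain_state(tg$pd, cfgg), tg$pd),
               "poisson")
})

test_that("latent gradient matches central finite differences of the log joint", {
  fx <- poisson_fixture(n = 8, seed = 503)
  st <- fx$state
  g <- latent_log_gradient(st, fx$pd)
  eps <- 1e-5
  fd <- vapply(1:8, function(i) {
    zp <- st$z; zp[i] <- zp[i] + eps
    zm <- st$z; zm[i] <- zm[i] - eps
    stp <- st; stp$z <- zp
    stm <- st; stm$z <- zm
    (log_joint(stp, fx$pd, fx$cfg) - log_joint(stm, fx$pd, fx$cfg)) / (2 * eps)
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-5)
})

test_that("MALA acceptance approaches one as the step size vanishes", {
  fx <- poisson_fixture(n = 15, seed = 504)
  st <- fx$state
  set.seed(1)
  acc <- vapply(1:1000, function(i) {
    st2 <- mala_update_latent(st, fx$pd, fx$cfg, h = 1e-8)
    attr(st2, "accepted")
  }, logical(1))
  expect_gt(mean(acc), 0.999)
})

test_that("psi never leaves (-1, 1) under the truncated-uniform walk", {
  tg <- tiny_gaussian_data()
  cfg <- parj_config(n_iter = 100, burn_in = 10, include_anisotropy = TRUE,
                     psi_halfwidth = 0.6, seed = 3)
  st <- init_chain_state(tg$pd, cfg)
  set.seed(4)
  psis <- numeric(5000)
  for (i in 1:5000) {
    st <- update_spatial_params(st, tg$pd, cfg, use_likelihood = FALSE)
    psis[i] <- st$theta[["psi"]]
  }
  expect_true(all(abs(psis) < 1))
  # with a wide proposal the walk must actually traverse the support
  expect_gt(max(psis), 0.5)
  expect_lt(min(psis), -0.5)
})

test_that("likelihood-free Metropolis blocks recover their prior marginals", {
  tg <- tiny_gaussian_data()
  cfg <- parj_config(n_iter = 100, burn_in = 10, include_anisotropy = TRUE,
                     logvar_prior_mean = 0.5, logvar_prior_var = 10,
                     tune = FALSE, seed = 5)
  st <- init_chain_state(tg$pd, cfg)
  # near-optimal scalar random-walk scales (~2.4 x target sd) for this
  # prior-only validation run
  scales <- c(log_sill = 7.6, log_nugget = 7.6, log_range1 = 2.4,
              log_range2 = 2.4, psi = 1)
  set.seed(6)
  n_draws <- 20000
  sill_draws <- numeric(n_draws); psi_draws <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    st <- update_spatial_params(st, tg$pd, cfg, scales = scales,
                                use_likelihood = FALSE)
    sill_draws[i] <- st$theta[["log_sill"]]
    psi_draws[i] <- st$theta[["psi"]]
  }
  ks_sill <- ks_distance(sill_draws, function(x) pnorm(x, 0.5, sqrt(10)))
  expect_lt(ks_sill, 0.05)
  ks_psi <- ks_distance(psi_draws, ptriangular)
  expect_lt(ks_psi, 0.05)
})

test_that("covariates with prior inclusion zero never enter the model", {
  tg <- tiny_gaussian_data()
  cfg <- parj_config(n_iter = 2000, burn_in = 200,
                     prior_inclusion = c(x2 = 0), seed = 7)
  fit <- run_parj(tg$pd, cfg)
  expect_true(all(fit$gamma[, "x2"] == 0L))
  expect_true(any(fit$gamma[, "x1"] == 1L))
})

test_that("chain output is bit-reproducible under a fixed seed", {
  tg <- tiny_gaussian_data()
  cfg <- parj_config(n_iter = 400, burn_in = 100, seed = 11)
  f1 <- run_parj(tg$pd, cfg)
  f2 <- run_parj(tg$pd, cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$beta, f2$beta)
  fx <- poisson_fixture()
  cfgp <- fx$cfg; cfgp$store_z <- TRUE
  p1 <- run_parj(fx$pd, cfgp)
  p2 <- run_parj(fx$pd, cfgp)
  expect_identical(p1$z, p2$z)
  expect_identical(p1$beta, p2$beta)
})

test_that("stored states respect the chain-state invariants", {
  tg <- tiny_gaussian_data()
  cfg <- parj_config(n_iter = 800, burn_in = 100, seed = 13)
  fit <- run_parj(tg$pd, cfg)
  expect_null(fit$z)                               # gaussian: no latent field
  expect_true(all(fit$beta[fit$gamma == 0L] == 0))
  expect_true(all(fit$beta[, "(Intercept)"] != 0))
  expect_true(all(fit$theta[, c("sill", "nugget", "range1")] > 0))
  fx <- poisson_fixture()
  cfgp <- fx$cfg; cfgp$store_z <- TRUE
  fitp <- run_parj(fx$pd, cfgp)
  expect_equal(dim(fitp$z), c(150, 30))
  # latent field must actually move every so often (MALA updates each sweep)
  expect_gt(mean(diff(fitp$z[, 1]) != 0), 0.2)
})

test_that("with the full model forced, posterior means track the GLS estimate", {
  sc <- sim_scenario(
    n_sites = 100,
    true_theta = cov_params(sill = 1, nugget = 0.25, ranges = 0.25),
    true_beta = c(`(Intercept)` = 0.5, x1 = 1, x2 = -0.7), seed = 31)
  d <- simulate_gaussian_data(sc)
  pd <- parj_data(d, coords = c("x", "y"), response = "resp")
  th <- attr(d, "truth")$theta
  cfg <- parj_config(n_iter = 1500, burn_in = 300, prior_inclusion = 1,
                     fix_theta = th, seed = 32)
  fit <- run_parj(pd, cfg)
  expect_true(all(fit$gamma == 1L))
  S <- build_covariance_matrix(pd$coords, th)
  gls <- solve(t(pd$X) %*% solve(S, pd$X), t(pd$X) %*% solve(S, pd$y))
  post_mean <- colMeans(fit$beta)
  post_sd <- apply(fit$beta, 2, sd)
  expect_true(all(abs(post_mean - drop(gls)) < 2 * post_sd))
})

test_that("model-visit frequencies match exact enumeration at fixed theta", {
  tg <- tiny_gaussian_data(seed = 77)
  th <- tg$truth$theta
  cfg <- parj_config(n_iter = 32000, burn_in = 2000, fix_theta = th,
                     seed = 78)
  fit <- run_parj(tg$pd, cfg)
  pmp <- compute_pmp(fit)
  st <- init_chain_state(tg$pd, cfg)
  exact <- enumerate_model_posterior(tg$pd$y, st$Sigma, tg$pd$X,
                                     st$priors$coef_prior,
                                     st$priors$pi, tg$pd$forced)
  tv <- tv_distance(setNames(pmp$pmp, pmp$model),
                    setNames(exact$prob, exact$model))
  expect_lt(tv, 0.05)
  # the PMP/PIP identity must hold exactly on the same chain
  pip <- compute_pip(fit)
  for (j in which(!tg$pd$forced)) {
    in_model <- substr(pmp$model, j, j) == "1"
    expect_identical(pip$pip[j], sum(pmp$n_visits[in_model]) / sum(pmp$n_visits))
  }
})

test_that("the full kernel leaves the prior invariant (successive-conditional run)", {
  set.seed(91)
  n <- 15
  coords <- cbind(runif(n), runif(n))
  df <- data.frame(x = coords[, 1], y = coords[, 2],
                   x1 = rnorm(n), x2 = rnorm(n), resp = rnorm(n))
  pd <- parj_data(df, response = "resp")
  cfg <- parj_config(n_iter = 100, burn_in = 10, include_nugget = FALSE,
                     logvar_prior_mean = 0, logvar_prior_var = 1,
                     logrange_prior_mean = log(0.5), logrange_prior_var = 0.25,
                     coef_prior_mean = rep(0, 3), coef_prior_var = 1,
                     tune = FALSE, seed = 92)
  st <- init_chain_state(pd, cfg)
  n_sweep <- 20000
  sill_draws <- numeric(n_sweep)
  incl_x2 <- logical(n_sweep)
  scales <- c(log_sill = 2.4, log_range = 1.2)
  for (s in seq_len(n_sweep)) {
    # data replacement step: y | state  ~ N(X_g beta_g, Sigma(theta))
    keep <- st$gamma == 1L
    mu <- drop(pd$X[, keep, drop = FALSE] %*% st$beta[keep])
    R <- attr(st$Sigma, "chol")
    pd$y <- mu + drop(crossprod(R, rnorm(n)))
    st$lp_model <- NULL                  # conditional posterior cache is stale
    # one full posterior sweep given the fresh data
    st <- update_spatial_params(st, pd, cfg, scales = scales)
    st <- parj_model_update(st, pd, cfg)
    st <- gibbs_beta_update(st, pd, cfg)
    sill_draws[s] <- st$theta[["log_sill"]]
    incl_x2[s] <- st$gamma[3] == 1L
  }
  drop_burn <- -(1:500)
  ks <- ks_distance(sill_draws[drop_burn], function(x) pnorm(x, 0, 1))
  expect_lt(ks, 0.05)
  # marginal inclusion of a (null) covariate must match its Bernoulli prior
  expect_lt(abs(mean(incl_x2[drop_burn]) - 0.5), 0.05)
})
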