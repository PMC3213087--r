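# summaries operate on a hand-built chain with known visit counts, plus a
# short real chain for the cross-identities

fake_fit <- function(gamma, beta, forced = NULL, names = NULL) {
  p <- ncol(gamma)
  names <- names %||% c("(Intercept)", paste0("x", seq_len(p - 1)))
  forced <- forced %||% c(TRUE, rep(FALSE, p - 1))
  colnames(gamma) <- names; colnames(beta) <- names
  structure(
    list(theta = matrix(1, nrow(gamma), 1, dimnames = list(NULL, "sill")),
         gamma = gamma, beta = beta, z = NULL,
         covariate_names = names, forced = forced, family = "gaussian",
         n_sites = 10,
         acceptance = tibble::tibble(block = "model", rate = 0.3),
         config = NULL, seed = 1),
    class = "parj_fit")
}

test_that("posterior model probabilities are visit fractions", {
  gamma <- rbind(matrix(rep(c(1L, 1L, 0L), 6), 6, 3, byrow = TRUE),
                 matrix(rep(c(1L, 0L, 1L), 4), 4, 3, byrow = TRUE))
  beta <- matrix(0, 10, 3)
  fit <- fake_fit(gamma, beta)
  pmp <- compute_pmp(fit)
  expect_equal(pmp$pmp, c(0.6, 0.4))
  expect_equal(pmp$model, c("110", "101"))
  expect_equal(pmp$terms, c("x1", "x2"))
  expect_equal(attr(pmp, "n_models_visited"), 2)
  expect_equal(sum(pmp$pmp), 1)
  # degenerate single-model chain
  fit1 <- fake_fit(gamma[1:6, ], beta[1:6, ])
  expect_equal(compute_pmp(fit1)$pmp, 1)
})

test_that("PIP equals the sum of PMPs of models containing the covariate", {
  set.seed(2)
  gamma <- cbind(1L, matrix(rbinom(200 * 3, 1, 0.4), 200, 3))
  beta <- matrix(rnorm(200 * 4), 200, 4) * gamma
  fit <- fake_fit(gamma, beta)
  pip <- compute_pip(fit)
  pmp <- compute_pmp(fit)
  expect_equal(pip$pip[1], 1)          # forced intercept
  for (j in 2:4) {
    in_model <- vapply(pmp$model, function(bs) {
      substr(bs, j, j) == "1"
    }, logical(1))
    expect_identical(pip$pip[j], sum(pmp$n_visits[in_model]) / sum(pmp$n_visits))
    expect_equal(pip$pip[j], sum(pmp$pmp[in_model]), tolerance = 1e-12)
  }
})

test_that("coefficient mixture splits mass at zero and conditional draws", {
  gamma <- cbind(1L, c(1L, 1L, 0L, 0L, 0L))
  beta <- cbind(rnorm(5), c(2, 3, 0, 0, 0))
  fit <- fake_fit(gamma, beta)
  mix <- coefficient_posterior_mixture(fit, "x1")
  expect_equal(mix$mass_at_zero, 0.6)
  expect_equal(mix$conditional_draws, c(2, 3))
  # never-included and always-included extremes
  g0 <- cbind(1L, rep(0L, 5)); fit0 <- fake_fit(g0, beta * 0)
  mix0 <- coefficient_posterior_mixture(fit0, "x1")
  expect_equal(mix0$mass_at_zero, 1)
  expect_length(mix0$conditional_draws, 0)
  g1 <- cbind(1L, rep(1L, 5)); fit1 <- fake_fit(g1, beta)
  mix1 <- coefficient_posterior_mixture(fit1, "x1")
  expect_equal(mix1$mass_at_zero, 0)
  expect_length(mix1$conditional_draws, 5)
  # mixture mean identity: (1 - mass0) * E[draws | included] = plain mean
  set.seed(3)
  g <- cbind(1L, rbinom(500, 1, 0.7))
  b <- cbind(rnorm(500), rnorm(500, 2)) * g
  fitm <- fake_fit(g, b)
  mm <- coefficient_posterior_mixture(fitm, "x1")
  expect_equal((1 - mm$mass_at_zero) * mean(mm$conditional_draws),
               mean(b[, 2]), tolerance = 1e-14)
})

test_that("HPD interval is the shortest contiguous credible interval", {
  expect_error(hpd_interval(1:10, 0.95), "50")
  iv <- hpd_interval(1:100, 0.95)
  expect_equal(unname(iv["upper"] - iv["lower"]), 94)    # 95 grid points
  set.seed(4)
  z <- rnorm(10000)
  iv <- hpd_interval(z, 0.95)
  expect_lt(abs(iv[["lower"]] + 1.96), 0.1)
  expect_lt(abs(iv[["upper"]] - 1.96), 0.1)
  # asymmetric distribution: HPD must beat the equal-tailed interval
  x <- rexp(10000)
  hp <- hpd_interval(x, 0.9)
  eq <- quantile(x, c(0.05, 0.95))
  expect_lte(hp[["upper"]] - hp[["lower"]], eq[[2]] - eq[[1]])
  expect_lt(hp[["lower"]], 0.05)
})

test_that("coefficient ratio posterior matches a direct recount", {
  set.seed(5)
  n <- 400
  g <- cbind(1L, rbinom(n, 1, 0.8), rbinom(n, 1, 0.6))
  b <- cbind(rnorm(n), rnorm(n, -2), rnorm(n, 1)) * g
  fit <- fake_fit(g, b)
  out <- coefficient_ratio_posterior(fit, "x1", "x2")
  both <- g[, 2] == 1 & g[, 3] == 1
  expect_equal(out$n_coincluded, sum(both))
  expect_equal(out$p_first_larger, mean(abs(b[both, 2]) > abs(b[both, 3])))
  expect_equal(out$ratio_draws, abs(b[both, 3]) / abs(b[both, 2]))
  expect_false(out$empty)
  # constant coefficients give a deterministic answer
  gc <- cbind(1L, rep(1L, 5), rep(1L, 5))
  bc <- cbind(0, rep(2, 5), rep(1, 5))
  fitc <- fake_fit(gc, bc)
  outc <- coefficient_ratio_posterior(fitc, "x1", "x2")
  expect_equal(outc$p_first_larger, 1)
  expect_equal(unique(outc$ratio_draws), 0.5)
  # never co-included is flagged, not an error
  gn <- cbind(1L, c(1L, 0L), c(0L, 1L))
  fitn <- fake_fit(gn, matrix(0, 2, 3))
  expect_true(coefficient_ratio_posterior(fitn, "x1", "x2")$empty)
  expect_error(coefficient_ratio_posterior(fit, "x1", "x1"), "differ")
})

test_that("summaries are equivariant under covariate relabelling", {
  set.seed(6)
  n <- 100
  g <- cbind(1L, rbinom(n, 1, 0.3), rbinom(n, 1, 0.7), rbinom(n, 1, 0.5))
  b <- matrix(rnorm(n * 4), n, 4) * g
  fit <- fake_fit(g, b)
  perm <- c(1, 4, 2, 3)   # keep forced intercept first
  fitp <- fake_fit(g[, perm], b[, perm],
                   names = fit$covariate_names[perm])
  pip <- compute_pip(fit); pipp <- compute_pip(fitp)
  expect_equal(pipp$pip, pip$pip[perm])
  expect_equal(pipp$term, pip$term[perm])
  expect_equal(sort(compute_pmp(fit)$pmp), sort(compute_pmp(fitp)$pmp))
})

test_that("tidy and glance surface the chain summaries coherently", {
  set.seed(7)
  n <- 300
  g <- cbind(1L, rbinom(n, 1, 0.9), rbinom(n, 1, 0.1))
  b <- cbind(rnorm(n), rnorm(n, 1.5), rnorm(n)) * g
  fit <- fake_fit(g, b)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, fit$covariate_names)
  expect_equal(td$pip, colMeans(g))
  expect_equal(td$estimate, colMeans(b))
  gl <- glance(fit)
  expect_equal(gl$n_draws, n)
  expect_equal(gl$n_models_visited, nrow(compute_pmp(fit)))
  expect_equal(gl$top_pmp, compute_pmp(fit)$pmp[1])
})

test_that("autoplot builds a spike-plus-density panel without evaluation errors", {
  set.seed(8)
  n <- 200
  g <- cbind(1L, rbinom(n, 1, 0.8), rbinom(n, 1, 0.4))
  b <- cbind(rnorm(n), rnorm(n, 1), rnorm(n, -1)) * g
  fit <- fake_fit(g, b)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gte(length(built$data), 2)   # density layer + spike layer
})
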