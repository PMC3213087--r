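# The PARJ MCMC engine.  One sweep is: Metropolis random-walk updates of the
# spatial covariance parameters, a partial-analytic reversible-jump model
# move (coefficients integrated out analytically, so no coefficient proposal
# is needed), a Gibbs draw of the included coefficients, and — for the
# Poisson family — a Langevin-Hastings (MALA) update of the whole latent
# Gaussian field.

# ---- prior resolution -------------------------------------------------------

# Resolve data-dependent prior defaults once per run.
resolve_priors <- function(data, config) {
  y <- data$y
  n <- length(y)
  p <- ncol(data$X)
  # response on the latent (Gaussian) scale for variance heuristics
  y_lat <- if (data$family == "poisson") log(y + 0.5) else y
  logvar_mean <- config$logvar_prior_mean %||% log(max(stats::var(y_lat), 1e-8) / 2)
  maxdist <- sqrt(max(
    outer(data$coords[, 1], data$coords[, 1], "-")^2 +
      outer(data$coords[, 2], data$coords[, 2], "-")^2))
  logrange_mean <- config$logrange_prior_mean %||% log(maxdist / 2)
  m <- config$coef_prior_mean
  if (is.null(m)) {
    m <- rep(0, p)
    m[1] <- if (data$family == "poisson") log(mean(y) + 0.5) else mean(y)
  }
  stopifnot(length(m) == p)
  cp <- coef_prior(m, rep(config$coef_prior_var, p))
  # per-covariate prior inclusion probabilities; forced columns have pi = 1
  pi_raw <- config$prior_inclusion
  pi <- rep(if (length(pi_raw) == 1L && is.null(names(pi_raw))) pi_raw else 0.5, p)
  if (!is.null(names(pi_raw))) {
    hit <- match(names(pi_raw), colnames(data$X))
    if (anyNA(hit)) {
      stop("prior_inclusion names not among covariates: ",
           paste(names(pi_raw)[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    pi[hit] <- unname(pi_raw)
  }
  pi[data$forced] <- 1
  list(coef_prior = cp, pi = pi,
       logvar_mean = logvar_mean, logvar_var = config$logvar_prior_var,
       logrange_mean = logrange_mean, logrange_var = config$logrange_prior_var,
       maxdist = maxdist)
}

# ---- chain state ------------------------------------------------------------

# covariance build using the dataset's cached coordinate differences
data_cov <- function(data, params) {
  if (!is.null(data$dx2)) {
    build_covariance_cached(data$dx2, data$dxdy, data$dy2, params)
  } else {
    build_covariance_matrix(data$coords, params)
  }
}

theta_to_cov_params <- function(th, config) {
  structure(
    list(log_sill = th[["log_sill"]],
         log_nugget = if (config$include_nugget) th[["log_nugget"]] else NULL,
         log_ranges = c(th[["log_range1"]], th[["log_range2"]]),
         psi = if (config$include_anisotropy) th[["psi"]] else 0,
         family = config$family,
         smoothness = if (config$family == "matern") config$smoothness else NULL),
    class = "cov_params")
}

#' Initialise the PARJ chain state
#'
#' Builds a valid starting state: spatial parameters at their prior means
#' (or at `config$fix_theta`), all covariates with positive prior inclusion
#' probability included, coefficients drawn from their full conditional, and
#' (Poisson family) the latent field initialised at `log(y + 0.5)`.
#'
#' @param data a [parj_data] object.
#' @param config a [parj_config()].
#' @return a `chain_state` list with elements `theta` (named vector on the
#'   sampling scale), `gamma`, `beta` (full-length, zeros where excluded),
#'   `z` (`NULL` for the Gaussian family), `Sigma` (current covariance with
#'   Cholesky attribute), and `priors` (resolved prior settings).
#' @export
init_chain_state <- function(data, config) {
  pr <- resolve_priors(data, config)
  fixed <- !is.null(config$fix_theta)
  if (fixed) {
    ft <- config$fix_theta
    th <- c(log_sill = ft$log_sill,
            log_nugget = if (config$include_nugget) {
              if (is.null(ft$log_nugget))
                stop("`fix_theta` lacks a nugget but `include_nugget` is TRUE.",
                     call. = FALSE)
              ft$log_nugget
            } else NA_real_,
            log_range1 = ft$log_ranges[1], log_range2 = ft$log_ranges[2],
            psi = ft$psi)
  } else {
    th <- c(log_sill = pr$logvar_mean,
            log_nugget = if (config$include_nugget) pr$logvar_mean else NA_real_,
            log_range1 = pr$logrange_mean, log_range2 = pr$logrange_mean,
            psi = 0)
  }
  Sigma <- data_cov(data, if (fixed) config$fix_theta else theta_to_cov_params(th, config))
  gamma <- as.integer(pr$pi > 0)
  gamma[data$forced] <- 1L
  z <- if (data$family == "poisson") log(data$y + 0.5) else NULL
  resp <- z %||% data$y
  keep <- gamma == 1L
  rp <- restrict_prior(pr$coef_prior, keep)
  fc <- beta_full_conditional(resp, data$X[, keep, drop = FALSE], Sigma,
                              rp$mean, rp$cov)
  beta <- numeric(ncol(data$X))
  beta[keep] <- fc$mean
  structure(
    list(theta = th, gamma = gamma, beta = beta, z = z, Sigma = Sigma,
         priors = pr, theta_fixed = fixed, lp_model = NULL),
    class = "chain_state")
}

# mean of the latent/observed Gaussian layer under the current state
state_mean <- function(state, data) {
  keep <- state$gamma == 1L
  drop(data$X[, keep, drop = FALSE] %*% state$beta[keep])
}

gauss_response <- function(state, data) {
  if (data$family == "poisson") state$z else data$y
}

# log prior density of the spatial parameters on the sampling scale
log_theta_prior <- function(th, config, pr) {
  out <- 0
  if (config$variance_param == "total_proportion" && config$include_nugget) {
    v <- exp(th[["log_sill"]]) + exp(th[["log_nugget"]])
    w <- exp(th[["log_nugget"]]) / v
    # log total variance ~ Normal, nugget proportion ~ Uniform(0,1) on w
    # (density w(1-w) on the logit scale)
    out <- out + dnorm(log(v), pr$logvar_mean + log(2), sqrt(pr$logvar_var),
                       log = TRUE) + log(w) + log1p(-w)
  } else {
    out <- out + dnorm(th[["log_sill"]], pr$logvar_mean, sqrt(pr$logvar_var),
                       log = TRUE)
    if (config$include_nugget) {
      out <- out + dnorm(th[["log_nugget"]], pr$logvar_mean,
                         sqrt(pr$logvar_var), log = TRUE)
    }
  }
  if (config$include_anisotropy) {
    out <- out + dnorm(th[["log_range1"]], pr$logrange_mean,
                       sqrt(pr$logrange_var), log = TRUE) +
      dnorm(th[["log_range2"]], pr$logrange_mean, sqrt(pr$logrange_var),
            log = TRUE) +
      log_dtriangular(th[["psi"]])
  } else {
    out <- out + dnorm(th[["log_range1"]], pr$logrange_mean,
                       sqrt(pr$logrange_var), log = TRUE)
  }
  unname(out)
}

#' Joint log density of the chain state
#'
#' Gaussian family: \eqn{\log N(y; X_\gamma \beta_\gamma, \Sigma(\theta))}
#' plus all priors.  Poisson family:
#' \eqn{\sum_i [y_i z_i - e^{z_i} - \log y_i!]} plus
#' \eqn{\log N(z; X_\gamma \beta_\gamma, \Sigma(\theta))} plus priors.
#'
#' @param state a `chain_state` (see [init_chain_state()]).
#' @param data a [parj_data] object.
#' @param config a [parj_config()].
#' @return scalar log density (unnormalised posterior).
#' @export
log_joint <- function(state, data, config) {
  pr <- state$priors %||% resolve_priors(data, config)
  mu <- state_mean(state, data)
  R <- attr(state$Sigma, "chol")
  out <- 0
  if (data$family == "poisson") {
    out <- out + sum(data$y * state$z - exp(state$z) - lfactorial(data$y))
    out <- out + log_dmvnorm_chol(state$z, mu, R)
  } else {
    out <- out + log_dmvnorm_chol(data$y, mu, R)
  }
  keep <- state$gamma == 1L
  rp <- restrict_prior(pr$coef_prior, keep)
  out <- out + log_dmvnorm(state$beta[keep], rp$mean, rp$cov)
  out <- out + log_model_prior(state$gamma, pr$pi, data$forced)
  out <- out + log_theta_prior(state$theta, config, pr)
  out
}

# ---- Metropolis updates of the spatial parameters ---------------------------

# which scalar blocks are active for this configuration
theta_blocks <- function(config) {
  if (config$variance_param == "total_proportion" && config$include_nugget) {
    blocks <- c("log_total", "logit_prop")
  } else {
    blocks <- c("log_sill", if (config$include_nugget) "log_nugget")
  }
  if (config$include_anisotropy) {
    blocks <- c(blocks, "log_range1", "log_range2", "psi")
  } else {
    blocks <- c(blocks, "log_range")
  }
  blocks
}

default_scales <- function(config) {
  blocks <- theta_blocks(config)
  sc <- vapply(blocks, function(b) {
    switch(b, psi = config$psi_halfwidth,
           log_range = , log_range1 = , log_range2 = config$prop_sd_logrange,
           config$prop_sd_logvar)
  }, numeric(1))
  stats::setNames(sc, blocks)
}

# apply a scalar block proposal to the theta vector; returns proposed theta
# and the log Hastings correction (nonzero only for the truncated psi walk)
propose_theta_block <- function(th, block, scale) {
  corr <- 0
  if (block == "psi") {
    lo <- max(-1, th[["psi"]] - scale); hi <- min(1, th[["psi"]] + scale)
    prop <- runif(1, lo, hi)
    lo2 <- max(-1, prop - scale); hi2 <- min(1, prop + scale)
    corr <- log(hi - lo) - log(hi2 - lo2)
    th[["psi"]] <- prop
  } else if (block == "log_range") {
    step <- rnorm(1, 0, scale)
    th[["log_range1"]] <- th[["log_range1"]] + step
    th[["log_range2"]] <- th[["log_range1"]]
  } else if (block == "log_total") {
    v <- exp(th[["log_sill"]]) + exp(th[["log_nugget"]])
    w <- exp(th[["log_nugget"]]) / v
    v2 <- exp(log(v) + rnorm(1, 0, scale))
    th[["log_sill"]] <- log(v2 * (1 - w)); th[["log_nugget"]] <- log(v2 * w)
  } else if (block == "logit_prop") {
    v <- exp(th[["log_sill"]]) + exp(th[["log_nugget"]])
    w <- exp(th[["log_nugget"]]) / v
    w2 <- stats::plogis(stats::qlogis(w) + rnorm(1, 0, scale))
    th[["log_sill"]] <- log(v * (1 - w2)); th[["log_nugget"]] <- log(v * w2)
  } else {
    th[[block]] <- th[[block]] + rnorm(1, 0, scale)
  }
  list(theta = th, log_correction = corr)
}

#' Metropolis update of the spatial covariance parameters
#'
#' Updates each active scalar block (log sill, log nugget, log range(s),
#' \eqn{\psi}) by a random-walk Metropolis step: Gaussian proposals for the
#' log-scale parameters and a truncated-uniform walk on \eqn{(-1, 1)} for
#' \eqn{\psi} with the truncation correction in the Hastings ratio.
#' Acceptance uses the difference of [log_joint()] terms that involve
#' \eqn{\theta}; a proposal whose covariance fails to factorise is rejected.
#'
#' @inheritParams log_joint
#' @param scales named per-block proposal scales; default from `config`.
#' @param use_likelihood if `FALSE` the Gaussian-layer likelihood term is
#'   dropped and each block targets its prior (used to validate the
#'   Metropolis kernels against their prior marginals).
#' @return updated `chain_state`, with attribute `"accepted"` (named logical
#'   per block).
#' @export
update_spatial_params <- function(state, data, config, scales = NULL,
                                  use_likelihood = TRUE) {
  if (state$theta_fixed) return(state)
  pr <- state$priors %||% resolve_priors(data, config)
  scales <- scales %||% default_scales(config)
  blocks <- theta_blocks(config)
  mu <- state_mean(state, data)
  resp <- gauss_response(state, data)
  cur_ll <- if (use_likelihood) {
    log_dmvnorm_chol(resp, mu, attr(state$Sigma, "chol"))
  } else 0
  cur_lp <- log_theta_prior(state$theta, config, pr)
  accepted <- stats::setNames(logical(length(blocks)), blocks)
  for (b in blocks) {
    prop <- propose_theta_block(state$theta, b, scales[[b]])
    prop_lp <- log_theta_prior(prop$theta, config, pr)
    if (!is.finite(prop_lp)) next
    if (use_likelihood) {
      S_prop <- tryCatch(
        data_cov(data, theta_to_cov_params(prop$theta, config)),
        error = function(e) NULL)
      if (is.null(S_prop)) next             # numerically degenerate: reject
      prop_ll <- log_dmvnorm_chol(resp, mu, attr(S_prop, "chol"))
    } else {
      S_prop <- NULL                        # prior target: covariance unused
      prop_ll <- 0
    }
    log_alpha <- (prop_ll + prop_lp) - (cur_ll + cur_lp) + prop$log_correction
    if (log(runif(1)) < log_alpha) {
      state$theta <- prop$theta
      if (!is.null(S_prop)) state$Sigma <- S_prop
      state$lp_model <- NULL                # conditional model posterior stale
      cur_ll <- prop_ll; cur_lp <- prop_lp
      accepted[[b]] <- TRUE
    }
  }
  attr(state, "accepted") <- accepted
  state
}

# ---- partial-analytic reversible-jump model move ----------------------------

#' Partial-analytic reversible-jump model move
#'
#' Proposes toggling one selectable covariate and accepts with probability
#' \eqn{\min\{1, \exp[\Delta \log p(M \mid y, \theta)]\}}, the coefficients
#' having been integrated out analytically
#' ([log_conditional_model_posterior()]).  In the Poisson family the current
#' latent field plays the role of the Gaussian response.  On acceptance the
#' coefficients are redrawn from their full conditional under the new model.
#'
#' @inheritParams log_joint
#' @return updated `chain_state` with attribute `"accepted"` (logical).
#' @export
parj_model_update <- function(state, data, config) {
  pr <- state$priors %||% resolve_priors(data, config)
  resp <- gauss_response(state, data)
  if (is.null(state$lp_model)) {
    state$lp_model <- log_conditional_model_posterior(
      resp, state$gamma, state$Sigma, data$X, pr$coef_prior, pr$pi, data$forced)
  }
  prop <- propose_model_move(state$gamma, data$forced)
  lp_prop <- log_conditional_model_posterior(
    resp, prop$gamma, state$Sigma, data$X, pr$coef_prior, pr$pi, data$forced)
  accepted <- is.finite(lp_prop) &&
    log(runif(1)) < (lp_prop - state$lp_model + prop$log_proposal_ratio)
  if (accepted) {
    state$gamma <- as.integer(prop$gamma)
    state$lp_model <- lp_prop
    state <- gibbs_beta_update(state, data, config)
  }
  attr(state, "accepted") <- accepted
  state
}

#' Gibbs update of the included coefficients
#'
#' Draws the coefficients of the currently included columns from their
#' conjugate normal full conditional; excluded entries are exactly zero.
#'
#' @inheritParams log_joint
#' @return updated `chain_state`.
#' @export
gibbs_beta_update <- function(state, data, config) {
  pr <- state$priors %||% resolve_priors(data, config)
  resp <- gauss_response(state, data)
  keep <- state$gamma == 1L
  rp <- restrict_prior(pr$coef_prior, keep)
  fc <- beta_full_conditional(resp, data$X[, keep, drop = FALSE], state$Sigma,
                              rp$mean, rp$cov)
  beta <- numeric(length(state$gamma))
  beta[keep] <- draw_beta(fc)
  state$beta <- beta
  state
}

# ---- Langevin-Hastings latent-field update (Poisson family) -----------------

#' Gradient of the log joint with respect to the latent field
#'
#' \eqn{\nabla_z \log p = (y - e^z) - \Sigma(\theta)^{-1}(z - X_\gamma
#' \beta_\gamma)}, the drift used by the Langevin-Hastings proposal.
#'
#' @inheritParams log_joint
#' @return numeric vector of length n.
#' @export
latent_log_gradient <- function(state, data) {
  if (data$family != "poisson") {
    stop("the latent field exists only for the poisson family.", call. = FALSE)
  }
  mu <- state_mean(state, data)
  R <- attr(state$Sigma, "chol")
  r <- state$z - mu
  prec_r <- backsolve(R, backsolve(R, r, transpose = TRUE))
  (data$y - exp(state$z)) - prec_r
}

# log target in z (terms depending on z only)
latent_log_target <- function(z, state, data) {
  mu <- state_mean(state, data)
  R <- attr(state$Sigma, "chol")
  sum(data$y * z - exp(z)) + log_dmvnorm_chol(z, mu, R)
}

#' MALA update of the whole latent field
#'
#' Proposes \eqn{z^* = z + (h/2)\nabla + \sqrt{h}\,\varepsilon} with
#' standard-normal \eqn{\varepsilon} and accepts via the full
#' Metropolis-Hastings ratio including both asymmetric proposal densities.
#'
#' @inheritParams log_joint
#' @param h step size; default `config$mala_step`.
#' @return updated `chain_state` with attribute `"accepted"` (logical).
#' @export
mala_update_latent <- function(state, data, config, h = NULL) {
  if (data$family != "poisson") {
    stop("MALA latent update applies only to the poisson family.", call. = FALSE)
  }
  h <- h %||% config$mala_step %||% (0.1 * length(state$z)^(-1 / 3))
  z <- state$z
  g <- latent_log_gradient(state, data)
  z_star <- z + (h / 2) * g + sqrt(h) * rnorm(length(z))
  state_star <- state
  state_star$z <- z_star
  g_star <- latent_log_gradient(state_star, data)
  lt_cur <- latent_log_target(z, state, data)
  lt_star <- latent_log_target(z_star, state, data)
  log_q_fwd <- -sum((z_star - z - (h / 2) * g)^2) / (2 * h)
  log_q_rev <- -sum((z - z_star - (h / 2) * g_star)^2) / (2 * h)
  accepted <- is.finite(lt_star) &&
    log(runif(1)) < (lt_star - lt_cur + log_q_rev - log_q_fwd)
  if (accepted) {
    state$z <- z_star
    state$lp_model <- NULL                  # model move conditions on z
  }
  attr(state, "accepted") <- accepted
  state
}

# ---- main loop --------------------------------------------------------------

#' Run the PARJ sampler
#'
#' Executes, per sweep: the Metropolis spatial-parameter blocks, the
#' partial-analytic reversible-jump model move, the Gibbs coefficient draw,
#' and (Poisson family) the MALA latent-field update.  Proposal scales are
#' adapted during burn-in (random walks towards acceptance 0.2–0.5, MALA
#' towards 0.5–0.6) and frozen afterwards, so the post-burn-in kernel is a
#' fixed Markov kernel with the correct stationary distribution.
#'
#' @param data a [parj_data] object.
#' @param config a [parj_config()].
#' @param verbose print per-1000-iteration block acceptance summaries?
#' @return a `parj_fit` object; see [parj()] for the user-level entry point.
#' @export
run_parj <- function(data, config = parj_config(), verbose = FALSE) {
  stopifnot(inherits(data, "parj_data"))
  config <- validate_parj_config(unclass(config))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- init_chain_state(data, config)
  p <- ncol(data$X)
  n <- nrow(data$coords)
  poisson <- data$family == "poisson"
  blocks <- if (state$theta_fixed) character(0) else theta_blocks(config)
  scales <- default_scales(config)
  h <- config$mala_step %||% (0.1 * n^(-1 / 3))
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  theta_names <- c("sill", if (config$include_nugget) "nugget",
                   "range1", "range2", if (config$include_anisotropy) "psi")
  theta_draws <- matrix(NA_real_, n_keep, length(theta_names),
                        dimnames = list(NULL, theta_names))
  gamma_draws <- matrix(NA_integer_, n_keep, p,
                        dimnames = list(NULL, colnames(data$X)))
  beta_draws <- matrix(NA_real_, n_keep, p,
                       dimnames = list(NULL, colnames(data$X)))
  z_draws <- if (poisson && config$store_z) matrix(NA_real_, n_keep, n) else NULL
  all_blocks <- c(blocks, "model", if (poisson) "mala")
  acc_post <- att_post <- stats::setNames(numeric(length(all_blocks)), all_blocks)
  acc_win <- att_win <- acc_post      # tuning window counters
  tune_window <- 0L
  keep_idx <- 0L
  for (iter in seq_len(config$n_iter)) {
    in_burn <- iter <= config$burn_in
    if (length(blocks) > 0) {
      state <- update_spatial_params(state, data, config, scales = scales)
      acc_b <- attr(state, "accepted")
      for (b in blocks) {
        att_win[[b]] <- att_win[[b]] + 1; acc_win[[b]] <- acc_win[[b]] + acc_b[[b]]
        if (!in_burn) {
          att_post[[b]] <- att_post[[b]] + 1
          acc_post[[b]] <- acc_post[[b]] + acc_b[[b]]
        }
      }
    }
    state <- parj_model_update(state, data, config)
    acc_m <- attr(state, "accepted")
    att_win[["model"]] <- att_win[["model"]] + 1
    acc_win[["model"]] <- acc_win[["model"]] + acc_m
    if (!in_burn) {
      att_post[["model"]] <- att_post[["model"]] + 1
      acc_post[["model"]] <- acc_post[["model"]] + acc_m
    }
    state <- gibbs_beta_update(state, data, config)
    if (poisson) {
      state <- mala_update_latent(state, data, config, h = h)
      acc_z <- attr(state, "accepted")
      att_win[["mala"]] <- att_win[["mala"]] + 1
      acc_win[["mala"]] <- acc_win[["mala"]] + acc_z
      if (!in_burn) {
        att_post[["mala"]] <- att_post[["mala"]] + 1
        acc_post[["mala"]] <- acc_post[["mala"]] + acc_z
      }
    }
    # burn-in-only adaptation, frozen afterwards
    if (in_burn && config$tune && iter %% config$tune_interval == 0L) {
      tune_window <- tune_window + 1L
      for (b in blocks) {
        rate <- acc_win[[b]] / max(att_win[[b]], 1)
        if (rate < 0.2) scales[[b]] <- scales[[b]] * exp(-0.2)
        if (rate > 0.5) scales[[b]] <- scales[[b]] * exp(0.2)
        if (b == "psi") scales[[b]] <- min(scales[[b]], 1)
      }
      if (poisson && is.null(config$mala_step)) {
        rate <- acc_win[["mala"]] / max(att_win[["mala"]], 1)
        # diminishing-gain step towards the 0.5-0.6 acceptance band, so the
        # frozen value reflects an average over burn-in rather than the
        # last window
        gain <- 1.5 / sqrt(tune_window)
        h <- min(max(h * exp(gain * (rate - 0.55)), 1e-6), 10)
      }
      acc_win[] <- 0; att_win[] <- 0
    }
    if (verbose && iter %% 1000L == 0L) {
      message(sprintf("iter %d | model acc %.2f%s", iter,
                      acc_win[["model"]] / max(att_win[["model"]], 1),
                      if (poisson) sprintf(" | mala acc %.2f",
                                           acc_win[["mala"]] / max(att_win[["mala"]], 1))
                      else ""))
    }
    if (!in_burn && (iter - config$burn_in) %% config$thin == 0L) {
      keep_idx <- keep_idx + 1L
      th <- state$theta
      theta_draws[keep_idx, ] <- c(
        exp(th[["log_sill"]]),
        if (config$include_nugget) exp(th[["log_nugget"]]),
        exp(th[["log_range1"]]), exp(th[["log_range2"]]),
        if (config$include_anisotropy) th[["psi"]])
      gamma_draws[keep_idx, ] <- state$gamma
      beta_draws[keep_idx, ] <- state$beta
      if (!is.null(z_draws)) z_draws[keep_idx, ] <- state$z
    }
  }
  acceptance <- tibble::tibble(
    block = all_blocks,
    rate = ifelse(att_post > 0, acc_post / att_post, NA_real_))
  structure(
    list(theta = theta_draws[seq_len(keep_idx), , drop = FALSE],
         gamma = gamma_draws[seq_len(keep_idx), , drop = FALSE],
         beta = beta_draws[seq_len(keep_idx), , drop = FALSE],
         z = if (!is.null(z_draws)) z_draws[seq_len(keep_idx), , drop = FALSE],
         covariate_names = colnames(data$X),
         forced = data$forced,
         family = data$family,
         n_sites = n,
         acceptance = acceptance,
         scales_final = c(scales, if (poisson) c(mala_step = h)),
         config = config,
         priors = state$priors,
         seed = config$seed),
    class = "parj_fit")
}

#' Fit a geostatistical regression with Bayesian model averaging
#'
#' The user-level entry point: takes a site-by-row data frame, validates it
#' into a spatial dataset ([parj_data()]), and runs the PARJ sampler
#' ([run_parj()]).  The result supports [tidy()][generics::tidy] (posterior
#' inclusion probabilities and model-averaged coefficient summaries),
#' [glance()][generics::glance], [compute_pmp()], [compute_pip()], and
#' [ggplot2::autoplot()].
#'
#' @inheritParams parj_data
#' @param config a [parj_config()]; chain length, priors, proposal scales.
#' @param verbose print progress?
#' @return a `parj_fit` object.
#' @examples
#' \donttest{
#' sc <- recovery_scenario("tiny-enum")
#' fit <- simulate_gaussian_data(sc) |>
#'   parj(coords = c("x", "y"), response = "resp",
#'        config = parj_config(n_iter = 2000, burn_in = 500, seed = 1))
#' tidy(fit)
#' }
#' @export
parj <- function(data, coords = c("x", "y"), response = "resp",
                 covariates = NULL, family = c("gaussian", "poisson"),
                 config = parj_config(), standardize = TRUE,
                 verbose = FALSE) {
  d <- parj_data(data, coords = coords, response = response,
                 covariates = covariates, family = family,
                 standardize = standardize)
  run_parj(d, config, verbose = verbose)
}

#' @export
print.parj_fit <- function(x, ...) {
  cat("<parj_fit>", x$family, "family,", x$n_sites, "sites,",
      nrow(x$theta), "stored draws\n")
  cat("  candidate covariates:",
      paste(x$covariate_names[!x$forced], collapse = ", "), "\n")
  pip <- colMeans(x$gamma)[!x$forced]
  top <- sort(pip, decreasing = TRUE)
  cat("  top inclusion probabilities:",
      paste(sprintf("%s=%.2f", names(head(top, 3)), head(top, 3)),
            collapse = ", "), "\n")
  invisible(x)
}
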