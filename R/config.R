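# Sampler configuration: priors, proposal scales, chain settings.  All
# validation happens up front so a misconfigured run fails before iteration 1.

#' Configure the PARJ sampler
#'
#' Collects every tunable of the sampler with field-standard defaults.
#' Prior settings left `NULL` are resolved from the data at fit time:
#' the log-variance prior means default to the log of half the response
#' variance, the log-range prior mean to the log of half the maximum
#' inter-site distance, and the intercept prior mean to the sample mean of
#' the response (log mean count for the Poisson family).
#'
#' @param n_iter total MCMC iterations (including burn-in).
#' @param burn_in iterations discarded before storage; must be `< n_iter`.
#' @param thin keep every `thin`-th post-burn-in draw (default 1: no
#'   thinning).
#' @param family correlation family passed to [cov_params()].
#' @param smoothness Matern smoothness, fixed (not sampled); default 1.5.
#' @param include_nugget include a nugget variance \eqn{\tau^2}?
#' @param include_anisotropy sample per-axis ranges and the anisotropy
#'   correlation \eqn{\psi}?  `FALSE` gives an isotropic model with a single
#'   range.
#' @param prior_inclusion Bernoulli prior inclusion probability: scalar or a
#'   named per-covariate vector (unnamed selectable covariates fall back to
#'   0.5).
#' @param coef_prior_var prior variance of each slope coefficient (diagonal
#'   normal prior on standardized covariates); default 100 ("flat" style).
#' @param coef_prior_mean optional full prior mean vector; default zero
#'   slopes with a data-informed intercept mean.
#' @param logvar_prior_mean,logvar_prior_var normal prior on the log sill and
#'   log nugget; variance defaults to 10, mean resolved from the data.
#' @param logrange_prior_mean,logrange_prior_var normal prior on the log
#'   range(s); variance defaults to 1, mean resolved from the maximum
#'   observed distance.
#' @param variance_param `"sill_nugget"` samples (log sill, log nugget)
#'   directly; `"total_proportion"` samples the log total variance and the
#'   logit nugget proportion, an alternative parameterisation that can
#'   reduce posterior correlation between the two variance components.
#' @param prop_sd_logvar,prop_sd_logrange Gaussian random-walk proposal
#'   standard deviations for the log-variance and log-range blocks.
#' @param psi_halfwidth half-width of the truncated-uniform random walk on
#'   \eqn{\psi} (proposals outside \eqn{(-1,1)} are handled by the
#'   truncation correction in the Hastings ratio).
#' @param mala_step Langevin-Hastings step size `h` for the latent-field
#'   update (Poisson family); `NULL` auto-tunes during burn-in towards an
#'   acceptance rate of about 0.5-0.6 and then freezes.
#' @param tune adapt random-walk scales during burn-in towards acceptance in
#'   0.2-0.5 (0.5-0.6 for MALA), freezing at the end of burn-in so the
#'   stationary distribution is untouched?
#' @param tune_interval iterations between tuning updates.
#' @param fix_theta optional [cov_params()]: hold the spatial covariance
#'   parameters fixed at these values (no Metropolis updates) — used for
#'   validation against exact model-space enumeration.
#' @param store_z store the latent-field draws (Poisson family)?  Off by
#'   default; latent draws are the one place thinning-scale storage matters.
#' @param seed integer seed for the run; `NULL` leaves the RNG state alone.
#' @return object of class `parj_config` (a validated list).
#' @export
parj_config <- function(n_iter = 10000, burn_in = 2000, thin = 1,
                        family = c("exponential", "spherical", "matern"),
                        smoothness = 1.5,
                        include_nugget = TRUE, include_anisotropy = FALSE,
                        prior_inclusion = 0.5,
                        coef_prior_var = 100, coef_prior_mean = NULL,
                        logvar_prior_mean = NULL, logvar_prior_var = 10,
                        logrange_prior_mean = NULL, logrange_prior_var = 1,
                        variance_param = c("sill_nugget", "total_proportion"),
                        prop_sd_logvar = 0.3, prop_sd_logrange = 0.3,
                        psi_halfwidth = 0.2, mala_step = NULL,
                        tune = TRUE, tune_interval = 50,
                        fix_theta = NULL, store_z = FALSE, seed = NULL) {
  cfg <- list(
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin),
    family = match.arg(family), smoothness = smoothness,
    include_nugget = isTRUE(include_nugget),
    include_anisotropy = isTRUE(include_anisotropy),
    prior_inclusion = prior_inclusion,
    coef_prior_var = coef_prior_var, coef_prior_mean = coef_prior_mean,
    logvar_prior_mean = logvar_prior_mean, logvar_prior_var = logvar_prior_var,
    logrange_prior_mean = logrange_prior_mean,
    logrange_prior_var = logrange_prior_var,
    variance_param = match.arg(variance_param),
    prop_sd_logvar = prop_sd_logvar, prop_sd_logrange = prop_sd_logrange,
    psi_halfwidth = psi_halfwidth, mala_step = mala_step,
    tune = isTRUE(tune), tune_interval = as.integer(tune_interval),
    fix_theta = fix_theta, store_z = isTRUE(store_z),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_parj_config(cfg)
}

validate_parj_config <- function(cfg) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (cfg$n_iter <= cfg$burn_in) note("`n_iter` must exceed `burn_in`.")
  if (cfg$burn_in < 0) note("`burn_in` must be nonnegative.")
  if (cfg$thin < 1) note("`thin` must be a positive integer.")
  if (!all(cfg$prior_inclusion >= 0 & cfg$prior_inclusion <= 1)) {
    note("`prior_inclusion` values must lie in [0, 1].")
  }
  for (nm in c("prop_sd_logvar", "prop_sd_logrange", "psi_halfwidth",
               "logvar_prior_var", "logrange_prior_var", "coef_prior_var",
               "smoothness")) {
    if (!is.numeric(cfg[[nm]]) || any(cfg[[nm]] <= 0)) {
      note(sprintf("`%s` must be positive.", nm))
    }
  }
  if (!is.null(cfg$mala_step) && cfg$mala_step <= 0) {
    note("`mala_step` must be positive (or NULL for auto-tuning).")
  }
  if (!is.null(cfg$fix_theta) && !inherits(cfg$fix_theta, "cov_params")) {
    note("`fix_theta` must be a cov_params object or NULL.")
  }
  if (length(problems) > 0) {
    stop("invalid sampler configuration:\n",
         paste0("  - ", problems, collapse = "\n"), call. = FALSE)
  }
  structure(cfg, class = "parj_config")
}

#' @export
print.parj_config <- function(x, ...) {
  cat("<parj_config>\n")
  cat("  iterations:", x$n_iter, " burn-in:", x$burn_in, " thin:", x$thin, "\n")
  cat("  correlation:", x$family,
      if (x$include_anisotropy) "anisotropic" else "isotropic",
      if (x$include_nugget) "+ nugget" else "(no nugget)", "\n")
  cat("  variance parameterisation:", x$variance_param, "\n")
  if (!is.null(x$fix_theta)) cat("  spatial parameters held fixed\n")
  invisible(x)
}

#' Read a sampler configuration from YAML or JSON
#'
#' An empty file yields the all-defaults configuration.  Unknown keys are
#' rejected, and all validation failures are reported together.
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yml`/`.yaml`).
#' @return a [parj_config()] object.
#' @export
read_parj_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(parj_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$fix_theta)) {
    raw$fix_theta <- do.call(cov_params, raw$fix_theta)
  }
  if (!is.null(raw$prior_inclusion) && is.list(raw$prior_inclusion)) {
    raw$prior_inclusion <- unlist(raw$prior_inclusion)
  }
  do.call(parj_config, raw)
}

#' Serialise a sampler configuration
#'
#' Writes the configuration as YAML (or JSON by extension) such that
#' [read_parj_config()] recovers an identical object.
#'
#' @param config a [parj_config()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parj_config <- function(config, path) {
  stopifnot(inherits(config, "parj_config"))
  out <- unclass(config)
  if (!is.null(out$fix_theta)) {
    th <- out$fix_theta
    out$fix_theta <- list(
      sill = exp(th$log_sill),
      nugget = if (is.null(th$log_nugget)) NULL else exp(th$log_nugget),
      ranges = exp(th$log_ranges), psi = th$psi, family = th$family,
      smoothness = th$smoothness)
    out$fix_theta <- out$fix_theta[!vapply(out$fix_theta, is.null, logical(1))]
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
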