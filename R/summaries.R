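# Posterior summaries of PARJ chain output: posterior model probabilities
# (visit fractions), posterior inclusion probabilities, model-averaged
# coefficient mixtures, HPD intervals, and coefficient-ratio functionals.

#' Posterior model probabilities
#'
#' The PMP of each visited model is its visit fraction in the stored chain.
#' Models are labelled both by the inclusion bit-string over all candidate
#' columns and by the comma-joined names of the selectable covariates they
#' contain.
#'
#' @param fit a `parj_fit` object (from [parj()] / [run_parj()]).
#' @return tibble with columns `model` (bit-string), `terms`, `n_visits`,
#'   and `pmp`, sorted by decreasing `pmp`; the number of distinct visited
#'   models is attached as attribute `"n_models_visited"`.
#' @export
compute_pmp <- function(fit) {
  stopifnot(inherits(fit, "parj_fit"))
  if (nrow(fit$gamma) == 0) stop("empty chain.", call. = FALSE)
  bits <- apply(fit$gamma, 1, paste, collapse = "")
  tab <- table(bits)
  sel_names <- fit$covariate_names[!fit$forced]
  label_terms <- function(bs) {
    g <- as.integer(strsplit(bs, "")[[1]])
    inc <- fit$covariate_names[g == 1L & !fit$forced]
    if (length(inc) == 0) "(none)" else paste(inc, collapse = ", ")
  }
  out <- tibble::tibble(
    model = names(tab),
    terms = unname(vapply(names(tab), label_terms, character(1))),
    n_visits = as.integer(tab),
    pmp = as.integer(tab) / nrow(fit$gamma)) |>
    dplyr::arrange(dplyr::desc(.data$pmp))
  attr(out, "n_models_visited") <- nrow(out)
  out
}

#' Posterior inclusion probabilities
#'
#' The PIP of covariate j is the fraction of stored draws that include it,
#' identically the sum of the PMPs of all models containing it.  Forced
#' covariates have PIP exactly 1.
#'
#' @param fit a `parj_fit` object.
#' @return tibble with columns `term`, `pip`, and `forced`.
#' @export
compute_pip <- function(fit) {
  stopifnot(inherits(fit, "parj_fit"))
  if (nrow(fit$gamma) == 0) stop("empty chain.", call. = FALSE)
  tibble::tibble(
    term = fit$covariate_names,
    pip = unname(colMeans(fit$gamma)),
    forced = fit$forced)
}

#' Model-averaged coefficient posterior as a spike-plus-density mixture
#'
#' The model-averaged posterior of a coefficient is a mixture of a point
#' mass at zero (weight `1 - PIP`) and the continuous conditional-on-
#' inclusion posterior.
#'
#' @param fit a `parj_fit` object.
#' @param term covariate name or column index.
#' @return list with `term`, `mass_at_zero`, and `conditional_draws` (the
#'   coefficient draws from iterations where the covariate was included;
#'   empty when it never was).
#' @export
coefficient_posterior_mixture <- function(fit, term) {
  stopifnot(inherits(fit, "parj_fit"))
  j <- if (is.character(term)) match(term, fit$covariate_names) else as.integer(term)
  if (is.na(j) || j < 1 || j > ncol(fit$beta)) {
    stop("unknown covariate: ", term, call. = FALSE)
  }
  inc <- fit$gamma[, j] == 1L
  list(term = fit$covariate_names[j],
       mass_at_zero = 1 - mean(inc),
       conditional_draws = fit$beta[inc, j])
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(level * m)` of the
#' `m` sorted draws.
#'
#' @param draws numeric vector of at least 50 posterior draws.
#' @param level coverage level in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(rnorm(1e4), 0.95)
#' @export
hpd_interval <- function(draws, level = 0.95) {
  stopifnot(level > 0, level < 1)
  m <- length(draws)
  if (m < 50) stop("need at least 50 draws for an HPD interval.", call. = FALSE)
  s <- sort(draws)
  k <- ceiling(level * m)
  widths <- s[k:m] - s[1:(m - k + 1)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + k - 1])
}

#' Posterior of the magnitude ratio of two coefficients
#'
#' Over the draws in which both covariates are included, returns the
#' posterior probability that the first has the larger magnitude, and the
#' draws of the ratio `|beta[denominator]| / |beta[numerator]|` (i.e. the
#' second argument's magnitude relative to the first's).  Returns an
#' empty-flagged result (not an error) when the two are never co-included.
#'
#' @param fit a `parj_fit` object.
#' @param numerator,denominator covariate names or indices; must differ.
#' @return list with `p_first_larger`, `ratio_draws`, `n_coincluded`, and
#'   `empty`.
#' @export
coefficient_ratio_posterior <- function(fit, numerator, denominator) {
  stopifnot(inherits(fit, "parj_fit"))
  j <- if (is.character(numerator)) match(numerator, fit$covariate_names) else as.integer(numerator)
  k <- if (is.character(denominator)) match(denominator, fit$covariate_names) else as.integer(denominator)
  if (is.na(j) || is.na(k)) stop("unknown covariate name.", call. = FALSE)
  if (j == k) stop("`numerator` and `denominator` must differ.", call. = FALSE)
  both <- fit$gamma[, j] == 1L & fit$gamma[, k] == 1L
  if (!any(both)) {
    return(list(p_first_larger = NA_real_, ratio_draws = numeric(0),
                n_coincluded = 0L, empty = TRUE))
  }
  bj <- fit$beta[both, j]; bk <- fit$beta[both, k]
  list(p_first_larger = mean(abs(bj) > abs(bk)),
       ratio_draws = abs(bk) / abs(bj),
       n_coincluded = sum(both), empty = FALSE)
}

# ---- broom-style methods ----------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PARJ fit
#'
#' One row per candidate covariate: posterior inclusion probability,
#' model-averaged posterior mean (zeros included), conditional-on-inclusion
#' mean, and conditional HPD interval bounds.
#'
#' @param x a `parj_fit` object.
#' @param level HPD coverage for the conditional interval.
#' @param ... unused.
#' @return a tibble with columns `term`, `pip`, `estimate` (model-averaged
#'   mean), `conditional_mean`, `conf.low`, `conf.high`, `forced`.
#' @export
tidy.parj_fit <- function(x, level = 0.95, ...) {
  pip <- compute_pip(x)
  rows <- purrr::map(seq_along(x$covariate_names), function(j) {
    mix <- coefficient_posterior_mixture(x, j)
    cd <- mix$conditional_draws
    ci <- if (length(cd) >= 50) hpd_interval(cd, level) else c(lower = NA_real_, upper = NA_real_)
    tibble::tibble(
      term = x$covariate_names[j],
      pip = 1 - mix$mass_at_zero,
      estimate = mean(x$beta[, j]),
      conditional_mean = if (length(cd) > 0) mean(cd) else NA_real_,
      conf.low = ci[["lower"]], conf.high = ci[["upper"]])
  })
  out <- dplyr::bind_rows(rows)
  out$forced <- x$forced
  out
}

#' Glance at a PARJ fit
#'
#' @param x a `parj_fit` object.
#' @param ... unused.
#' @return one-row tibble: draw count, number of distinct visited models,
#'   top-model PMP, and the model-move (and MALA, if present) acceptance
#'   rates.
#' @export
glance.parj_fit <- function(x, ...) {
  pmp <- compute_pmp(x)
  acc <- x$acceptance
  tibble::tibble(
    n_draws = nrow(x$gamma),
    n_sites = x$n_sites,
    family = x$family,
    n_models_visited = nrow(pmp),
    top_pmp = pmp$pmp[1],
    top_model = pmp$terms[1],
    accept_model = acc$rate[acc$block == "model"],
    accept_mala = if ("mala" %in% acc$block) acc$rate[acc$block == "mala"] else NA_real_)
}

#' Spike-plus-density plot of model-averaged coefficient posteriors
#'
#' For each requested covariate, draws a vertical bar at zero of height
#' `P(beta_j = 0 | y) = 1 - PIP` and a kernel density estimate of the
#' conditional-on-inclusion draws, the standard display for a
#' model-averaged coefficient posterior.
#'
#' @param object a `parj_fit` object.
#' @param terms covariates to plot; default the four with the highest PIP
#'   among selectable covariates.
#' @param ... unused.
#' @return a ggplot object (facetted by covariate).
#' @export
autoplot.parj_fit <- function(object, terms = NULL, ...) {
  pip <- compute_pip(object)
  if (is.null(terms)) {
    sel <- pip[!pip$forced, ]
    terms <- sel$term[order(-sel$pip)][seq_len(min(4, nrow(sel)))]
  }
  dens <- purrr::map_dfr(terms, function(tm) {
    mix <- coefficient_posterior_mixture(object, tm)
    if (length(mix$conditional_draws) < 2) return(tibble::tibble())
    d <- stats::density(mix$conditional_draws, bw = "nrd0")  # Silverman
    tibble::tibble(term = tm, value = d$x,
                   density = d$y * (1 - mix$mass_at_zero))
  })
  spikes <- purrr::map_dfr(terms, function(tm) {
    mix <- coefficient_posterior_mixture(object, tm)
    tibble::tibble(term = tm, mass = mix$mass_at_zero)
  })
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$value, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_segment(
      data = spikes,
      ggplot2::aes(x = 0, xend = 0, y = 0, yend = .data$mass),
      linewidth = 1.2, colour = "grey30") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "coefficient", y = "posterior density / P(= 0)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
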