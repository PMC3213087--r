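# Model space: binary inclusion indicators, Bernoulli-product model prior,
# exhaustive enumeration for small covariate sets, and the discrete
# random-walk (single-toggle) model proposal used by the reversible-jump move.

#' Model inclusion indicator
#'
#' A candidate model is identified by a binary vector `gamma` over the
#' candidate covariates, with `gamma[j] = 1` when covariate `j` enters the
#' mean.  Covariates flagged in `forced` (typically the intercept) are never
#' subject to selection and always have `gamma[j] = 1`.
#'
#' @param gamma integer/logical vector of 0/1 inclusion indicators.
#' @param forced logical vector of the same length; `TRUE` marks covariates
#'   exempt from selection.
#' @return an object of class `model_indicator` (named integer vector with a
#'   `forced` attribute).
#' @export
model_indicator <- function(gamma, forced = rep(FALSE, length(gamma))) {
  gamma <- as.integer(gamma)
  forced <- as.logical(forced)
  stopifnot(length(forced) == length(gamma),
            all(gamma %in% c(0L, 1L)))
  if (any(forced & gamma == 0L)) {
    stop("forced covariates must have gamma = 1.", call. = FALSE)
  }
  structure(gamma, forced = forced, class = "model_indicator")
}

#' Log Bernoulli-product model prior
#'
#' Treats inclusion of each selectable covariate as an independent Bernoulli
#' trial with probability `pi[j]`, so the log prior is
#' \eqn{\sum_j \gamma_j \log \pi_j + (1 - \gamma_j)\log(1 - \pi_j)} over the
#' selectable covariates.  Degenerate probabilities are handled exactly:
#' `pi[j] = 0` (or 1) contributes 0 when the indicator agrees and `-Inf`
#' when it disagrees.  Forced covariates contribute nothing (their prior
#' inclusion probability is 1 by definition).
#'
#' @param gamma 0/1 inclusion vector (or [model_indicator]).
#' @param pi prior inclusion probabilities, scalar (recycled) or one per
#'   covariate.
#' @param forced logical mask of forced covariates; defaults to the `forced`
#'   attribute of `gamma`, else all-`FALSE`.
#' @return log prior probability (may be `-Inf`).
#' @examples
#' log_model_prior(c(1, 0, 1), 0.5)         # log(1/8)
#' log_model_prior(c(1, 0), c(0.75, 0.5))   # log(0.375)
#' @export
log_model_prior <- function(gamma, pi, forced = NULL) {
  forced <- forced %||% attr(gamma, "forced") %||% rep(FALSE, length(gamma))
  gamma <- as.integer(gamma)
  p <- length(gamma)
  if (length(pi) == 1L) pi <- rep(pi, p)
  if (length(pi) != p || length(forced) != p) {
    stop("`gamma`, `pi`, and `forced` must have matching lengths.", call. = FALSE)
  }
  stopifnot(all(pi >= 0 & pi <= 1))
  if (any(forced & pi != 1)) {
    stop("forced covariates require prior inclusion probability 1.", call. = FALSE)
  }
  sel <- !forced
  g <- gamma[sel]
  pr <- pi[sel]
  terms <- ifelse(g == 1L,
                  ifelse(pr == 0, -Inf, log(pr)),
                  ifelse(pr == 1, -Inf, log1p(-pr)))
  sum(terms)
}

#' Enumerate the model space
#'
#' Lists all `2^p_selectable` candidate models over the selectable
#' covariates.  With the 7 selectable lizard-style indicators this gives 128
#' models; with 9 covariates, 512.  Refuses more than 20 selectable
#' covariates — beyond that the space must be explored by sampling, which is
#' the sampler's job.
#'
#' @param p_selectable number of selectable covariates.
#' @param forced logical vector of forced covariates to prepend (all set to 1
#'   in every enumerated model); default none.
#' @return a list of [model_indicator] objects of length `2^p_selectable`.
#' @examples
#' length(enumerate_model_space(3))  # 8
#' @export
enumerate_model_space <- function(p_selectable, forced = logical(0)) {
  stopifnot(p_selectable >= 0L)
  if (p_selectable > 20L) {
    stop("model space with > 20 selectable covariates is too large to ",
         "enumerate; use the PARJ sampler to explore it instead.", call. = FALSE)
  }
  n_forced <- length(forced)
  if (n_forced > 0L) stopifnot(all(forced))
  n_models <- 2L^p_selectable
  grid <- if (p_selectable == 0L) {
    matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    as.matrix(expand.grid(rep(list(0:1), p_selectable)))
  }
  mask <- c(rep(TRUE, n_forced), rep(FALSE, p_selectable))
  lapply(seq_len(n_models), function(k) {
    model_indicator(c(rep(1L, n_forced), as.integer(grid[k, ])), forced = mask)
  })
}

#' Single-toggle model proposal (discrete random walk)
#'
#' Chooses one selectable covariate uniformly at random and flips its
#' inclusion indicator: a covariate already in the model is removed, one
#' absent is added.  The kernel is symmetric, so the log proposal ratio is
#' exactly zero.
#'
#' @param gamma current 0/1 inclusion vector (or [model_indicator]).
#' @param forced logical mask of forced covariates (default from attribute).
#' @return list with elements `gamma` (proposed indicator), `toggled` (index
#'   flipped), and `log_proposal_ratio` (always 0).
#' @export
propose_model_move <- function(gamma, forced = NULL) {
  forced <- forced %||% attr(gamma, "forced") %||% rep(FALSE, length(gamma))
  sel <- which(!forced)
  if (length(sel) == 0L) {
    stop("no selectable covariates to propose a model move for.", call. = FALSE)
  }
  j <- if (length(sel) == 1L) sel else sel[sample.int(length(sel), 1L)]
  prop <- as.integer(gamma)
  prop[j] <- 1L - prop[j]
  list(gamma = model_indicator(prop, forced = forced),
       toggled = j,
       log_proposal_ratio = 0)
}

# compact bit-string label for a model, e.g. "1011"
model_bitstring <- function(gamma) paste(as.integer(gamma), collapse = "")
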