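# Anisotropic spatial covariance: sigma^2 * rho(||s_i - s_j||_A) + tau^2 * 1{i=j}
#
# Geometric anisotropy is parameterised through A = D R D with
# D = diag(1/d1, 1/d2) holding inverse per-axis ranges and R a 2x2 correlation
# matrix with off-diagonal psi in (-1, 1).  With equal ranges and psi = 0 this
# reduces to the familiar isotropic exponential exp(-h / d).

#' Spatial covariance parameters
#'
#' Container for the covariance block of the chain state: partial sill
#' \eqn{\sigma^2}, optional nugget \eqn{\tau^2}, per-axis ranges
#' \eqn{d_1, d_2}, anisotropy correlation \eqn{\psi}, and correlation family.
#' Variance and range parameters are stored on the log scale, the scale on
#' which the sampler proposes them.
#'
#' @param sill positive partial-sill variance \eqn{\sigma^2}.
#' @param nugget nonnegative nugget variance \eqn{\tau^2}, or `NULL` to
#'   disable the nugget entirely.
#' @param ranges length-1 or length-2 positive range parameter(s) in the
#'   distance units of the coordinates; a single value is isotropic.
#' @param psi anisotropy correlation in \eqn{(-1, 1)}; `0` with equal ranges
#'   gives an isotropic model.
#' @param family correlation family: `"exponential"`, `"spherical"`, or
#'   `"matern"`.
#' @param smoothness Matern smoothness \eqn{\nu > 0}; only used (and only
#'   allowed) when `family = "matern"`.
#' @return an object of class `cov_params`.
#' @examples
#' cov_params(sill = 1, nugget = 0.25, ranges = 2)
#' cov_params(sill = 2, nugget = NULL, ranges = c(1, 3), psi = 0.4)
#' @export
cov_params <- function(sill, nugget = NULL, ranges = 1, psi = 0,
                       family = c("exponential", "spherical", "matern"),
                       smoothness = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(sill), length(sill) == 1L, sill > 0)
  if (!is.null(nugget)) stopifnot(is.numeric(nugget), length(nugget) == 1L, nugget >= 0)
  stopifnot(is.numeric(ranges), length(ranges) %in% c(1L, 2L), all(ranges > 0))
  if (length(ranges) == 1L) ranges <- rep(ranges, 2L)
  if (abs(psi) >= 1) {
    stop("`psi` must lie strictly inside (-1, 1): got ", psi, call. = FALSE)
  }
  if (family == "matern") {
    smoothness <- smoothness %||% 1.5
    stopifnot(smoothness > 0)
  } else if (!is.null(smoothness)) {
    stop("`smoothness` is only meaningful for the Matern family.", call. = FALSE)
  }
  structure(
    list(log_sill = log(sill),
         log_nugget = if (is.null(nugget)) NULL else log(nugget),
         log_ranges = log(ranges),
         psi = psi,
         family = family,
         smoothness = smoothness),
    class = "cov_params"
  )
}

#' @export
print.cov_params <- function(x, ...) {
  cat("<cov_params> family =", x$family,
      if (x$family == "matern") paste0("(nu = ", x$smoothness, ")"), "\n")
  cat("  sill =", signif(exp(x$log_sill), 4),
      " nugget =", if (is.null(x$log_nugget)) "none" else signif(exp(x$log_nugget), 4),
      " ranges =", paste(signif(exp(x$log_ranges), 4), collapse = ", "),
      " psi =", signif(x$psi, 4), "\n")
  invisible(x)
}

#' Build the 2x2 anisotropy matrix A = D R D
#'
#' `D = diag(1/d1, 1/d2)` holds inverse ranges so that larger ranges give
#' slower correlation decay, and `R` is the 2x2 correlation matrix with
#' off-diagonal `psi`.  The result is symmetric positive definite for any
#' positive ranges and `|psi| < 1`, which is what frees the sampler from
#' awkward joint constraints on the entries of `A`.
#'
#' @param log_ranges length-2 numeric, log per-axis ranges.
#' @param psi anisotropy correlation, strictly inside \eqn{(-1, 1)}.
#' @return 2x2 symmetric positive-definite matrix.
#' @examples
#' build_anisotropy_matrix(c(0, 0), 0)        # identity
#' build_anisotropy_matrix(log(c(2, 2)), 0)   # diag(1/4, 1/4)
#' @export
build_anisotropy_matrix <- function(log_ranges, psi) {
  stopifnot(length(log_ranges) == 2L, is.finite(log_ranges))
  if (!is.finite(psi) || abs(psi) >= 1) {
    stop("anisotropy correlation `psi` must lie strictly inside (-1, 1): got ",
         psi, call. = FALSE)
  }
  inv_d <- exp(-log_ranges)
  D <- diag(inv_d, 2L)
  R <- matrix(c(1, psi, psi, 1), 2L, 2L)
  D %*% R %*% D
}

#' Anisotropic (Mahalanobis-type) distance between two sites
#'
#' Computes \eqn{\sqrt{(s_i - s_j)^\top A (s_i - s_j)}}, the effective
#' distance at which the isotropic correlation function is evaluated.
#'
#' @param s_i,s_j numeric length-2 coordinates.
#' @param A 2x2 positive-definite anisotropy matrix.
#' @return nonnegative scalar, zero iff the sites coincide.
#' @examples
#' effective_distance(c(0, 0), c(3, 4), diag(2))  # 5
#' @export
effective_distance <- function(s_i, s_j, A) {
  stopifnot(length(s_i) == 2L, length(s_j) == 2L, all(dim(A) == 2L))
  h <- s_i - s_j
  sqrt(max(0, drop(t(h) %*% A %*% h)))
}

# full n x n effective-distance matrix; vectorised over site pairs
effective_distance_matrix <- function(coords, A) {
  dx <- outer(coords[, 1], coords[, 1], "-")
  dy <- outer(coords[, 2], coords[, 2], "-")
  d2 <- A[1, 1] * dx * dx + 2 * A[1, 2] * dx * dy + A[2, 2] * dy * dy
  sqrt(pmax(d2, 0))
}

# hot path used by the sampler: precomputed coordinate differences, no
# input validation, correlation family dispatched without match.arg
build_covariance_cached <- function(dx2, dxdy, dy2, params) {
  sill <- exp(params$log_sill)
  nugget <- if (is.null(params$log_nugget)) 0 else exp(params$log_nugget)
  inv_d <- exp(-params$log_ranges)
  a11 <- inv_d[1]^2; a22 <- inv_d[2]^2; a12 <- params$psi * inv_d[1] * inv_d[2]
  d <- sqrt(pmax(a11 * dx2 + 2 * a12 * dxdy + a22 * dy2, 0))
  S <- sill * correlation_value(d, params$family, params$smoothness %||% 1.5)
  diag(S) <- sill + nugget
  R <- chol_jitter(S, "spatial covariance")
  attr(S, "chol") <- R
  S
}

#' Isotropic correlation function on the effective distance
#'
#' All families are evaluated on the effective (anisotropic) distance, so the
#' range parameters live in the anisotropy matrix: exponential is
#' \eqn{\exp(-d)}, spherical has support exactly \eqn{d < 1}, and Matern is
#' \eqn{2^{1-\nu} d^\nu K_\nu(d) / \Gamma(\nu)} with \eqn{\rho(0) = 1}.
#'
#' @param d nonnegative distance(s) on the effective scale.
#' @param family `"exponential"`, `"spherical"`, or `"matern"`.
#' @param smoothness Matern smoothness; ignored otherwise.
#' @return correlation value(s) in \eqn{[0, 1]}.
#' @examples
#' correlation_value(1, "exponential")   # exp(-1)
#' correlation_value(1.5, "spherical")   # 0
#' @export
correlation_value <- function(d, family = c("exponential", "spherical", "matern"),
                              smoothness = 1.5) {
  family <- match.arg(family)
  if (any(d < 0)) stop("distances must be nonnegative.", call. = FALSE)
  switch(family,
    exponential = exp(-d),
    spherical = ifelse(d < 1, 1 - 1.5 * d + 0.5 * d^3, 0),
    matern = {
      out <- ifelse(d == 0, 1,
                    2^(1 - smoothness) / gamma(smoothness) *
                      d^smoothness * besselK(pmax(d, .Machine$double.eps), smoothness))
      # besselK underflows to 0 for large d; correlation then is 0
      out[!is.finite(out)] <- 0
      pmin(pmax(out, 0), 1)
    }
  )
}

#' Build the n x n spatial covariance matrix
#'
#' \eqn{\Sigma_{ij} = \sigma^2 \rho(\|s_i - s_j\|_A) + \tau^2 1\{i = j\}}.
#' The diagonal is exactly `sill + nugget`.  If the Cholesky factorisation
#' fails, a single diagonal jitter of `1e-10 * (sill + nugget)` is applied;
#' a second failure raises an error naming the offending parameters.
#'
#' @param coords n x 2 matrix of planar coordinates.
#' @param params a [cov_params] object.
#' @return n x n symmetric positive-definite covariance matrix with attribute
#'   `"chol"` carrying its upper Cholesky factor.
#' @examples
#' xy <- cbind(runif(5), runif(5))
#' S <- build_covariance_matrix(xy, cov_params(sill = 1, nugget = 0.5, ranges = 1))
#' all.equal(diag(S), rep(1.5, 5))
#' @export
build_covariance_matrix <- function(coords, params) {
  stopifnot(inherits(params, "cov_params"))
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 1L, all(is.finite(coords)))
  sill <- exp(params$log_sill)
  nugget <- if (is.null(params$log_nugget)) 0 else exp(params$log_nugget)
  A <- build_anisotropy_matrix(params$log_ranges, params$psi)
  d <- effective_distance_matrix(coords, A)
  S <- sill * correlation_value(d, params$family, params$smoothness %||% 1.5)
  diag(S) <- sill + nugget
  R <- chol_jitter(S, label = sprintf(
    "spatial covariance (sill=%.4g, nugget=%.4g, ranges=%.4g/%.4g, psi=%.4g)",
    sill, nugget, exp(params$log_ranges[1]), exp(params$log_ranges[2]), params$psi))
  attr(S, "chol") <- R
  S
}
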