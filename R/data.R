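# Spatial dataset container: a site-by-row table validated and split into
# coordinates, candidate design matrix (intercept prepended and forced), and
# response.  Covariate standardization is applied here and recorded so
# coefficients can be mapped back to the raw scale.

#' Validate a site-by-row table as a spatial regression dataset
#'
#' @param data data frame with one row per site.
#' @param coords names of the two planar coordinate columns (projected
#'   units).
#' @param response name of the response column.
#' @param covariates names of the candidate covariate columns; default every
#'   remaining numeric column.
#' @param family `"gaussian"` or `"poisson"` (counts with log link).
#' @param standardize centre/scale the covariates to sample mean 0 and
#'   variance 1 (the scaling both worked examples use)?  The applied centres
#'   and scales are recorded in the result.
#' @return object of class `parj_data`: list with `coords` (n x 2 matrix),
#'   `X` (n x p candidate design including a forced intercept), `y`,
#'   `family`, `forced` (logical mask over columns of `X`), `covariate_names`
#'   (selectable columns), and `standardization`.
#' @examples
#' df <- tibble::tibble(x = runif(10), y = runif(10),
#'                      a = rnorm(10), b = rnorm(10), resp = rnorm(10))
#' d <- parj_data(df, coords = c("x", "y"), response = "resp")
#' d$covariate_names
#' @export
parj_data <- function(data, coords = c("x", "y"), response = "y",
                      covariates = NULL, family = c("gaussian", "poisson"),
                      standardize = TRUE) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(coords, response), names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in `data`: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  covariates <- covariates %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))],
            c(coords, response))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    stop("covariate column(s) not found in `data`: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  used <- c(coords, response, covariates)
  na_cols <- used[vapply(used, function(cl) anyNA(data[[cl]]), logical(1))]
  if (length(na_cols) > 0) {
    stop("missing values in column(s): ", paste(na_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(data)
  if (n < 3) stop("need at least 3 sites.", call. = FALSE)
  y <- as.numeric(data[[response]])
  if (family == "poisson") {
    if (any(y < 0) || any(y != round(y))) {
      bad <- which(y < 0 | y != round(y))[1]
      stop("poisson family requires nonnegative integer response; ",
           "offending row ", bad, " in column `", response, "`.",
           call. = FALSE)
    }
    y <- as.integer(round(y))
  }
  Xcov <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(Xcov) <- "double"
  v <- apply(Xcov, 2, stats::var)
  if (any(!is.finite(v)) || any(v == 0)) {
    stop("covariate(s) with zero or non-finite variance: ",
         paste(covariates[!is.finite(v) | v == 0], collapse = ", "),
         call. = FALSE)
  }
  std <- NULL
  if (standardize && length(covariates) > 0) {
    ctr <- colMeans(Xcov)
    scl <- apply(Xcov, 2, stats::sd)
    Xcov <- sweep(sweep(Xcov, 2, ctr), 2, scl, "/")
    std <- list(center = ctr, scale = scl)
  }
  X <- cbind(`(Intercept)` = 1, Xcov)
  cc <- unname(as.matrix(data[, coords]))
  dx <- outer(cc[, 1], cc[, 1], "-")
  dy <- outer(cc[, 2], cc[, 2], "-")
  structure(
    list(coords = cc,
         dx2 = dx * dx, dxdy = dx * dy, dy2 = dy * dy,
         X = X, y = y, family = family,
         forced = c(TRUE, rep(FALSE, length(covariates))),
         covariate_names = covariates,
         coord_names = coords, response_name = response,
         standardization = std),
    class = "parj_data"
  )
}

#' @export
print.parj_data <- function(x, ...) {
  cat("<parj_data>", nrow(x$coords), "sites,", length(x$covariate_names),
      "candidate covariates,", x$family, "response\n")
  invisible(x)
}

#' @export
as_tibble.parj_data <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$coords))
  names(out) <- x$coord_names
  out[[x$response_name]] <- x$y
  cov_df <- tibble::as_tibble(as.data.frame(x$X[, -1, drop = FALSE]))
  dplyr::bind_cols(out, cov_df)
}
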