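# Mahalanobis-distance applicability domain.
#
# D_M(x) = sqrt((x - mu)' Sigma^-1 (x - mu)) with mu and Sigma estimated
# from the (scaled) training features. The outlier threshold is the 95th
# percentile of the training distances; "relative MD" is the distance
# divided by that threshold, so 1.0 marks the domain boundary.

#' Fit the applicability domain on training features
#'
#' Constant (zero-variance) feature columns are dropped with a warning; the
#' covariance inverse is ridge-regularized with eps = 1e-8 * trace/dim for
#' determinism near singularity.
#'
#' @param x Training feature matrix (rows > columns recommended); typically
#'   min-max scaled features, matching the model input space.
#' @param percentile Threshold percentile of the training distances.
#' @return Object of class `xb_md_model` with `mu`, `sigma`, `sigma_inv`,
#'   `scale` (the percentile distance), `keep` (retained columns).
#' @export
fit_md <- function(x, percentile = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit the applicability domain")
  v <- apply(x, 2, stats::var)
  keep <- which(v > 0)
  if (!length(keep)) stop("degenerate training features: all columns constant")
  if (length(keep) < ncol(x))
    warning("dropping ", ncol(x) - length(keep), " constant feature column(s)")
  xk <- x[, keep, drop = FALSE]
  mu <- colMeans(xk)
  sigma <- stats::cov(xk)
  eps <- 1e-8 * sum(diag(sigma)) / ncol(sigma)
  sigma_inv <- solve(sigma + diag(eps, ncol(sigma)))
  m <- structure(list(mu = mu, sigma = sigma, sigma_inv = sigma_inv,
                      keep = keep, percentile = percentile, scale = NULL,
                      n_features = ncol(x)),
                 class = "xb_md_model")
  m$scale <- unname(stats::quantile(mahalanobis_distance(xk, m,
                                                         subset_done = TRUE),
                                    percentile))
  if (m$scale <= 0) stop("degenerate training features: zero percentile distance")
  m
}

#' Mahalanobis distance to the training distribution
#'
#' @param x Feature matrix or single vector (same space the domain was
#'   fitted in).
#' @param m `xb_md_model`.
#' @param relative Also return the distance divided by the training
#'   percentile (`scale`).
#' @param subset_done Internal: `x` already restricted to retained columns.
#' @return Numeric vector of distances, or a data.frame with `md` and
#'   `relative_md` when `relative = TRUE`.
#' @export
mahalanobis_distance <- function(x, m, relative = FALSE, subset_done = FALSE) {
  stopifnot(inherits(m, "xb_md_model"))
  if (is.null(dim(x))) x <- matrix(x, 1)
  x <- as.matrix(x)
  if (!subset_done) {
    if (ncol(x) != m$n_features)
      stop("feature width ", ncol(x), " does not match fitted width ",
           m$n_features)
    x <- x[, m$keep, drop = FALSE]
  }
  xc <- sweep(x, 2, m$mu)
  md <- sqrt(pmax(rowSums((xc %*% m$sigma_inv) * xc), 0))
  if (relative) data.frame(md = md, relative_md = md / m$scale) else md
}

#' Flag applicability-domain outliers
#'
#' A point is flagged when its relative Mahalanobis distance exceeds 1.0,
#' i.e. it lies beyond the training 95th percentile.
#'
#' @param x Feature matrix.
#' @param m `xb_md_model`.
#' @return Logical vector.
#' @export
flag_outliers <- function(x, m) {
  mahalanobis_distance(x, m, relative = TRUE)$relative_md > 1.0
}
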