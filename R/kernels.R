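#' Gaussian kernel specification for discrepancy estimates
#'
#' All discrepancies in the package use an average of Gaussian RBF kernels,
#' `k(x, y) = mean_sigma exp(-||x - y||^2 / (2 sigma^2))`. Bandwidths are
#' either fixed positive numbers or resolved per batch by the median
#' heuristic: the median pairwise Euclidean distance of the pooled samples,
#' scaled by `multipliers`. Averaging several bandwidths makes the estimate
#' robust to the scale of the feature space.
#'
#' @param bandwidths Positive numeric vector of kernel widths, or
#'   `"median-heuristic"` (default) to resolve them from the data.
#' @param multipliers Multipliers applied to the median distance when the
#'   heuristic is used.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(bandwidths = "median-heuristic",
                        multipliers = c(0.5, 1, 2)) {
  if (is.numeric(bandwidths)) {
    if (length(bandwidths) == 0L) stop("at least one bandwidth", call. = FALSE)
    if (any(bandwidths <= 0)) stop("bandwidths must be > 0", call. = FALSE)
  } else if (!identical(bandwidths, "median-heuristic")) {
    stop("bandwidths must be numeric or \"median-heuristic\"", call. = FALSE)
  }
  structure(list(bandwidths = bandwidths, multipliers = multipliers),
            class = "kernel_spec")
}

#' Resolve the bandwidths of a kernel spec on pooled data
#'
#' @param spec A [kernel_spec()].
#' @param pooled Numeric matrix whose pairwise distances drive the median
#'   heuristic (ignored for fixed bandwidths).
#' @return Numeric vector of positive bandwidths.
#' @export
resolve_bandwidths <- function(spec, pooled = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (is.numeric(spec$bandwidths)) return(spec$bandwidths)
  if (is.null(pooled) || nrow(pooled) < 2L) {
    stop("median heuristic needs at least two pooled samples", call. = FALSE)
  }
  med <- stats::median(stats::dist(pooled))
  if (!is.finite(med) || med <= 0) med <- 1 # degenerate batch: all points equal
  med * spec$multipliers
}

# Squared Euclidean cross-distances, clamped at zero (kills negative float
# residue before exponentiation).
cross_sqdist <- function(x, y) {
  d <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  d[d < 0] <- 0
  d
}

#' Multi-bandwidth Gaussian kernel matrix
#'
#' @param x,y Numeric matrices `[n x d]` and `[m x d]`.
#' @param spec A [kernel_spec()]; median-heuristic bandwidths are resolved on
#'   the rows of `x` and `y` pooled.
#' @param bandwidths Optional pre-resolved bandwidths (overrides `spec`).
#' @return Kernel matrix `[n x m]` with entries in `(0, 1]`; `k(x, x) = 1`.
#' @export
gaussian_kernel <- function(x, y, spec = kernel_spec(), bandwidths = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("dimension mismatch", call. = FALSE)
  if (is.null(bandwidths)) bandwidths <- resolve_bandwidths(spec, rbind(x, y))
  if (any(bandwidths <= 0)) stop("bandwidths must be > 0", call. = FALSE)
  d2 <- cross_sqdist(x, y)
  k <- matrix(0, nrow(x), nrow(y))
  for (s in bandwidths) k <- k + exp(-d2 / (2 * s^2))
  k / length(bandwidths)
}

# Kernel matrix together with the gradient weight matrix
# G = mean_sigma K_sigma / sigma^2, so that d k(x,y)/dx = G * (y - x).
gaussian_kernel_pair <- function(x, y, bandwidths) {
  d2 <- cross_sqdist(x, y)
  k <- matrix(0, nrow(x), nrow(y))
  g <- matrix(0, nrow(x), nrow(y))
  for (s in bandwidths) {
    ks <- exp(-d2 / (2 * s^2))
    k <- k + ks
    g <- g + ks / s^2
  }
  list(k = k / length(bandwidths), g = g / length(bandwidths))
}

# Gradients of S = sum_ij w_ij k(x_i, y_j) with respect to x and y, where
# wg = w * G (elementwise). For a symmetric within-set sum pass the combined
# contribution by calling with x twice and summing the two returned pieces.
weighted_kernel_grad <- function(wg, x, y) {
  dx <- wg %*% y - rowSums(wg) * x
  dy <- crossprod(wg, x) - colSums(wg) * y
  list(dx = dx, dy = dy)
}
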