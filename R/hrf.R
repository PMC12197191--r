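#' Canonical-style hemodynamic response model
#'
#' A double-gamma-shaped impulse response: the difference of two gamma-shaped
#' curves, the first peaking at `peak_seconds`, the second (the post-stimulus
#' undershoot) peaking later and subtracted with weight `undershoot_ratio`.
#' The curve is normalized to unit peak and is exactly zero at `t = 0`.
#'
#' Each gamma component uses the shape/scale pair whose mode sits at the
#' requested peak and whose standard deviation equals the requested width.
#'
#' @param peak_seconds Time to peak of the positive lobe (default 6 s).
#' @param width_seconds Spread (SD) of the positive lobe (default 3 s).
#' @param undershoot_ratio Relative depth of the undershoot (default 1/6).
#' @param undershoot_peak_seconds Time to peak of the undershoot (default 16 s).
#' @param hbr_ratio Scale of the (negated) HbR response relative to HbO.
#' @return An object of class `hrf_model`.
#' @export
hrf_model <- function(peak_seconds = 6, width_seconds = 3,
                      undershoot_ratio = 1 / 6,
                      undershoot_peak_seconds = 16,
                      hbr_ratio = 1 / 3) {
  stopifnot(peak_seconds > 0, width_seconds > 0,
            undershoot_ratio >= 0, undershoot_peak_seconds > peak_seconds,
            hbr_ratio > 0)
  model <- list(
    peak_seconds = peak_seconds,
    width_seconds = width_seconds,
    undershoot_ratio = undershoot_ratio,
    undershoot_peak_seconds = undershoot_peak_seconds,
    hbr_ratio = hbr_ratio
  )
  class(model) <- "hrf_model"
  model
}

# Gamma-shaped lobe with mode `peak` and SD `width`, scaled to unit peak.
gamma_lobe <- function(t, peak, width) {
  theta <- (-peak + sqrt(peak^2 + 4 * width^2)) / 2 # solves (k-1)theta=peak, k theta^2=width^2
  k <- peak / theta + 1
  stats::dgamma(t, shape = k, scale = theta) /
    stats::dgamma(peak, shape = k, scale = theta)
}

#' Evaluate the unit-peak hemodynamic impulse response
#'
#' @param t Numeric vector of times in seconds, `t >= 0`.
#' @param model An [hrf_model()].
#' @return Numeric vector: the response, with maximum 1 (attained near
#'   `peak_seconds`) and value 0 at `t = 0`.
#' @export
hrf_response <- function(t, model = hrf_model()) {
  stopifnot(inherits(model, "hrf_model"))
  if (any(t < 0)) stop("hrf_response is defined for t >= 0", call. = FALSE)
  raw <- function(u) {
    gamma_lobe(u, model$peak_seconds, model$width_seconds) -
      model$undershoot_ratio *
        gamma_lobe(u, model$undershoot_peak_seconds, model$width_seconds * 1.6)
  }
  # peak of the difference curve sits close to, but not exactly at, peak_seconds;
  # normalize on a dense grid so max == 1 exactly at the grid resolution
  grid <- seq(0, model$undershoot_peak_seconds + 10 * model$width_seconds,
              length.out = 4096L)
  raw(t) / max(raw(grid))
}

#' Saturating response to a sustained stimulus
#'
#' The running integral of the impulse response, normalized by its asymptote:
#' the hemodynamic response to a task sustained from time 0, ramping up over
#' the first few seconds and plateauing near 1.
#'
#' @param t Numeric vector of times in seconds since task onset, `t >= 0`.
#' @param model An [hrf_model()].
#' @return Numeric vector in `[0, ~1]`.
#' @export
hrf_sustained <- function(t, model = hrf_model()) {
  hrf_sustained_fun(model, horizon = max(t, 1))(t)
}

# Build the sustained-response interpolator once (used per-corpus by the
# generator to avoid re-integrating the impulse response for every trial).
hrf_sustained_fun <- function(model, horizon = 0) {
  stopifnot(inherits(model, "hrf_model"))
  top <- max(model$undershoot_peak_seconds + 10 * model$width_seconds,
             horizon + 1)
  grid <- seq(0, top, length.out = 8192L)
  h <- hrf_response(grid, model)
  dt <- grid[2] - grid[1]
  cum <- c(0, cumsum((h[-1] + h[-length(h)]) / 2) * dt) # trapezoid
  f <- stats::approxfun(grid, cum / cum[length(cum)], rule = 2)
  function(t) {
    if (any(t < 0)) stop("hrf_sustained is defined for t >= 0", call. = FALSE)
    f(t)
  }
}
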