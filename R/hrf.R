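#' Two-gamma hemodynamic response parameters
#'
#' Parameter set for the canonical two-gamma hemodynamic response function
#' (cHRF) and its boxcar convolution (the designed HRF, dHRF).  The kernel is
#'
#' \deqn{h(t) = \alpha_1\left[\frac{(t/\tau_1)^{\phi_1-1} e^{-t/\tau_1}}
#'   {\tau_1(\phi_1-1)!} - \alpha_2 \frac{(t/\tau_2)^{\phi_2-1} e^{-t/\tau_2}}
#'   {\tau_2(\phi_2-1)!}\right]}
#'
#' i.e. a gamma-density response minus a scaled gamma-density undershoot.
#' With the factorial form the shape parameters `phi1`, `phi2` must be
#' positive integers; set `use_gamma_fn = TRUE` to generalize `(phi-1)!` to
#' `gamma(phi)` and allow non-integer shapes.
#'
#' Defaults are the standard canonical parameterization: `phi1 = 6`,
#' `phi2 = 16`, `tau1 = tau2 = 1` s, undershoot ratio `alpha2 = 1/6`, and
#' `alpha1 = NULL` meaning "normalize the kernel peak to 1".  `k1` scales the
#' designed HRF (default 10).
#'
#' @param alpha1 response amplitude; `NULL` (default) normalizes the kernel
#'   peak to 1 on a dense grid.
#' @param alpha2 undershoot-to-response ratio, in `[0, 1)`.
#' @param tau1,tau2 time scales of response and undershoot, seconds (> 0).
#' @param phi1,phi2 shape parameters (positive integers unless
#'   `use_gamma_fn`).
#' @param k1 dHRF amplitude scaling (default 10).
#' @param use_gamma_fn logical; generalize the factorial with the gamma
#'   function (permits non-integer `phi`).
#' @return An object of class `gamma_params`.
#' @export
gamma_params <- function(alpha1 = NULL, alpha2 = 1 / 6, tau1 = 1, tau2 = 1,
                         phi1 = 6, phi2 = 16, k1 = 10, use_gamma_fn = FALSE) {
  if (tau1 <= 0 || tau2 <= 0) stop("tau1 and tau2 must be positive")
  if (alpha2 < 0 || alpha2 >= 1) stop("alpha2 must lie in [0, 1)")
  if (!use_gamma_fn) {
    if (phi1 != round(phi1) || phi2 != round(phi2))
      stop("phi1 and phi2 must be integers for the factorial form; ",
           "set use_gamma_fn = TRUE for the gamma-function generalization")
  }
  if (phi1 < 1 || phi2 < 1) stop("phi1 and phi2 must be >= 1")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, tau1 = tau1, tau2 = tau2,
                 phi1 = phi1, phi2 = phi2, k1 = k1,
                 use_gamma_fn = use_gamma_fn),
            class = "gamma_params")
}

## raw (un-normalized, alpha1 = 1) kernel
.hrf_raw <- function(t, p) {
  g <- function(t, tau, phi) {
    out <- numeric(length(t))
    pos <- t >= 0
    # (phi-1)! == gamma(phi) for integer phi; gamma() is used for both forms
    out[pos] <- (t[pos] / tau)^(phi - 1) * exp(-t[pos] / tau) /
      (tau * gamma(phi))
    out
  }
  g(t, p$tau1, p$phi1) - p$alpha2 * g(t, p$tau2, p$phi2)
}

.hrf_alpha1 <- function(p) {
  if (!is.null(p$alpha1)) return(p$alpha1)
  grid <- seq(0, 60, by = 0.01)
  pk <- max(.hrf_raw(grid, p))
  if (pk <= 0) stop("degenerate kernel: non-positive peak")
  1 / pk
}

#' Canonical two-gamma hemodynamic response function
#'
#' Evaluates the cHRF kernel `h` at times `t` (seconds; `h = 0` for `t < 0`).
#' See [gamma_params()] for the functional form.
#'
#' @param t numeric vector of times in seconds.
#' @param params a [gamma_params()] object.
#' @return numeric vector `h(t)`.
#' @export
#' @examples
#' t <- seq(0, 30, by = 0.1)
#' h <- canonical_hrf(t)
#' t[which.max(h)]  # peak near 5 s
canonical_hrf <- function(t, params = gamma_params()) {
  stopifnot(inherits(params, "gamma_params"))
  .hrf_alpha1(params) * .hrf_raw(t, params)
}

## shared weighted causal convolution: u(k) = k1 * sum_{n=0}^{k-1} h(n) s(k-n)
.dhrf_conv <- function(h, s, k1) {
  n <- length(s)
  z <- stats::convolve(h, rev(s), type = "open")[seq_len(n)]
  # the open convolution at index k additionally carries the n = k term
  # h(k) s(0), which the causal sum excludes
  k1 * (z - h * s[1])
}

#' Designed hemodynamic response (boxcar-convolved HRF)
#'
#' Discrete causal convolution of the canonical kernel with the stimulus
#' boxcar on the schedule's clock:
#' `u(k) = k1 * sum_{n=0}^{k-1} h(n) s(k - n)`, with `h` evaluated at the
#' sample times `n / rate`.  `u` is identically zero before the first task
#' onset.
#'
#' @param params a [gamma_params()] object.
#' @param schedule a [paradigm_schedule()] (supplies `s(k)` and the clock).
#' @return numeric vector `u` of the schedule's length.
#' @export
designed_hrf <- function(params = gamma_params(), schedule) {
  stopifnot(inherits(params, "gamma_params"),
            inherits(schedule, "paradigm_schedule"))
  h <- canonical_hrf(schedule$times, params)
  .dhrf_conv(h, as.numeric(schedule$s), params$k1)
}

#' Ideal noise-free vector-diagram trajectory
#'
#' Under the two-gamma model with a fixed deoxy/oxy coupling ratio `r`, the
#' ideal trajectory in the oxy-/deoxy-hemoglobin plane is the straight line
#' `hbr = -r * hbo`: `hbo = u(k)`, `hbr = -r * u(k)`.  While `u > 0` every
#' point lies in the fourth quadrant (phases 7/8 of the vector diagram).
#'
#' @param params a [gamma_params()] object.
#' @param schedule a [paradigm_schedule()].
#' @param r deoxy-to-oxy magnitude ratio, in `(0, 1]` (default 1/3).
#' @return A data frame of phase points (see [phase_points()]) with the
#'   schedule times attached.
#' @export
ideal_trajectory <- function(params = gamma_params(), schedule, r = 1 / 3) {
  if (r <= 0 || r > 1) stop("r must lie in (0, 1]")
  u <- designed_hrf(params, schedule)
  pts <- phase_points(u, -r * u)
  pts$time <- schedule$times
  pts
}
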