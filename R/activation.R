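#' Samples per trial epoch under the truncating convention
#'
#' `floor(duration_s * rate)`: a 30-s trial at 9.19 Hz holds 275 samples.
#'
#' @param duration_s epoch duration in seconds (default 30).
#' @param rate sampling rate in Hz (default 9.19).
#' @return integer sample count.
#' @export
samples_per_trial <- function(duration_s = 30, rate = 9.19) {
  as.integer(floor(duration_s * rate + 1e-9))
}

#' One-tailed critical t value
#'
#' Upper-`alpha` quantile of Student's t.  At the trial-epoch degrees of
#' freedom `N - 1 = 274` (N = 275 samples of a 30-s trial at 9.19 Hz) and
#' `alpha = 0.05` one-tailed this is 1.65 to two decimals.
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha significance level (default 0.05).
#' @param one_tailed logical (default `TRUE`); `FALSE` gives the two-tailed
#'   quantile at the same overall level.
#' @return scalar critical value.
#' @export
critical_t <- function(df, alpha = 0.05, one_tailed = TRUE) {
  if (df < 1) stop("df must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stats::qt(1 - if (one_tailed) alpha else alpha / 2, df)
}

#' Robust GLM fit of a hemodynamic series to the designed HRF
#'
#' Iteratively reweighted least squares with Tukey bisquare weights (tuning
#' constant 4.685, via [MASS::rlm()]) regressing dHbO on `[1, u]`; the
#' t value is the slope coefficient over its standard error.  The reported
#' degrees of freedom follow the trial-epoch convention `N - 1` by default
#' (`df_convention = "n_minus_p"` selects the conventional `N - 2` of a
#' two-regressor model).
#'
#' @param y numeric response (measured dHbO).
#' @param u designed HRF regressor, same length (non-constant).
#' @param df_convention `"n_minus_1"` (default) or `"n_minus_p"`.
#' @return list `beta, se, t, df` for the `u` coefficient.
#' @export
robust_t <- function(y, u, df_convention = c("n_minus_1", "n_minus_p")) {
  df_convention <- match.arg(df_convention)
  if (length(y) != length(u)) stop("y and u lengths differ")
  if (length(y) < 3) stop("need at least 3 samples")
  if (stats::sd(u) < 1e-15)
    stop("constant regressor u: design is rank deficient")
  ## on (near-)exact data the IRLS scale estimate degenerates and the
  ## bisquare iteration cannot converge; robust and least squares coincide
  ## there, so take the OLS answer directly
  ols <- stats::lm(y ~ u)
  if (stats::sigma(ols) < 1e-10 * (stats::sd(y) + 1e-300)) {
    cf <- suppressWarnings(summary(ols))$coefficients  # perfect-fit note
    beta <- cf["u", "Estimate"]; se <- cf["u", "Std. Error"]
  } else {
    fit <- MASS::rlm(y ~ u, psi = MASS::psi.bisquare, c = 4.685,
                     maxit = 100)
    cf <- summary(fit)$coefficients
    beta <- cf["u", "Value"]; se <- cf["u", "Std. Error"]
  }
  n <- length(y)
  list(beta = beta, se = se, t = beta / se,
       df = if (df_convention == "n_minus_1") n - 1L else n - 2L)
}

#' Per-channel t-value activation map
#'
#' Offline validation map: per channel, the trial-averaged dHbO epoch is fit
#' to the single-trial designed HRF by [robust_t()]; channels whose t exceeds
#' the critical value are flagged active.  By default the fit runs on the
#' Beer-Lambert-converted but *not* narrowband-filtered concentrations (see
#' the methods vignette: band-passing to the task frequency band would make
#' the nominal t threshold anticonservative).
#'
#' @param hemo list of [hemo_series()] (one per channel, raw concentration
#'   scale).
#' @param sched the session's [paradigm_schedule()].
#' @param params [gamma_params()] for the analysis dHRF (canonical defaults).
#' @param t_crt critical t; default [critical_t()] at the epoch df.
#' @param geometry optional [probe_geometry()] for the spatial grid export.
#' @param df_convention passed to [robust_t()].
#' @return object of class `tvalue_map`: data frame `channel_id, beta, se,
#'   t, active` plus attributes `t_crt`, `df`, and (when geometry is given)
#'   `grid`, a 12 x 3 emitter-by-detector matrix of t values.
#' @export
activation_tmap <- function(hemo, sched, params = gamma_params(),
                            t_crt = NULL,
                            geometry = NULL,
                            df_convention = "n_minus_1") {
  stopifnot(inherits(sched, "paradigm_schedule"))
  rate <- hemo[[1]]$rate
  n_ep <- samples_per_trial(sched$trial_s, rate)
  df <- if (df_convention == "n_minus_1") n_ep - 1L else n_ep - 2L
  if (is.null(t_crt)) t_crt <- critical_t(df)

  sched1 <- paradigm_schedule(1, sched$task_s, sched$rest_s, 0, 0, rate)
  u <- designed_hrf(params, sched1)[seq_len(n_ep)]

  onset_idx <- floor(sched$onsets * rate + 1e-9) + 1L
  avg_epoch <- function(x) {
    ep <- vapply(onset_idx, function(i) x[i:(i + n_ep - 1L)],
                 numeric(n_ep))
    rowMeans(ep)
  }
  rows <- lapply(hemo, function(h) {
    ft <- robust_t(avg_epoch(h$hbo), u, df_convention)
    data.frame(channel_id = h$channel_id, beta = ft$beta, se = ft$se,
               t = ft$t)
  })
  out <- do.call(rbind, rows)
  out$active <- out$t > t_crt
  attr(out, "t_crt") <- t_crt
  attr(out, "df") <- df
  if (!is.null(geometry)) {
    grid <- matrix(NA_real_, 12, 3,
                   dimnames = list(paste0("E", 1:12), paste0("D", 1:3)))
    cht <- geometry$channels
    for (i in seq_len(nrow(out))) {
      r <- cht[cht$channel_id == out$channel_id[i], ]
      if (nrow(r) == 0)
        stop("channel ", out$channel_id[i], " has no probe coordinates")
      grid[r$emitter_id, r$detector_id] <- out$t[i]
    }
    attr(out, "grid") <- grid
  }
  class(out) <- c("tvalue_map", "data.frame")
  out
}

#' @export
print.tvalue_map <- function(x, ...) {
  cat("Activation t-map:", nrow(x), "channels; t_crt =",
      round(attr(x, "t_crt"), 3), "(df =", attr(x, "df"), ")\n")
  act <- x$channel_id[x$active]
  cat("  active channels:",
      if (length(act)) paste(act, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @export
plot.tvalue_map <- function(x, ...) {
  grid <- attr(x, "grid")
  if (is.null(grid)) stop("no spatial grid: rebuild the map with geometry")
  graphics::image(seq_len(nrow(grid)), seq_len(ncol(grid)), grid,
                  xlab = "emitter", ylab = "detector",
                  main = "channel t-map", ...)
  invisible(x)
}

#' Write the activation map and its spatial grid
#'
#' @param tmap a [activation_tmap()] result (built with geometry).
#' @param path base path; writes `<path>.tsv` (per-channel stats) and
#'   `<path>_grid.tsv` (emitter x detector t matrix).
#' @return invisibly, the paths.
#' @export
write_tmap <- function(tmap, path) {
  data.table::fwrite(as.data.frame(tmap), paste0(path, ".tsv"), sep = "\t")
  grid <- attr(tmap, "grid")
  if (!is.null(grid))
    utils::write.table(grid, paste0(path, "_grid.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
  invisible(paste0(path, c(".tsv", "_grid.tsv")))
}
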