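#' 45-degree rotation to total-hemoglobin / oxygen-exchange coordinates
#'
#' Rotates the (dHbO, dHbR) coordinate system by 45 degrees counterclockwise:
#' `hbt = (hbo + hbr) / sqrt(2)` (total hemoglobin change) and
#' `coe = (hbr - hbo) / sqrt(2)` (cerebral oxygen exchange).  The transform is
#' norm-preserving: `hbt^2 + coe^2 == hbo^2 + hbr^2`.
#'
#' @param hbo,hbr numeric vectors (same length) of oxy-/deoxy-hemoglobin
#'   changes.
#' @return list with components `hbt` and `coe`.
#' @export
#' @examples
#' hbt_coe(1, 1)   # hbt = sqrt(2), coe = 0
hbt_coe <- function(hbo, hbr) {
  stopifnot(length(hbo) == length(hbr))
  list(hbt = (hbo + hbr) / sqrt(2), coe = (hbr - hbo) / sqrt(2))
}

#' Phase points in the vector diagram
#'
#' Assembles, per sample, the four components (dHbO, dHbR, dHbT, dCOE), the
#' vector magnitude `|p| = sqrt(hbo^2 + hbr^2)`, the angle
#' `atan2(hbr, hbo)` in degrees in `(-180, 180]`, and the octant phase label
#' (`NA` at the origin, where the phase is undefined).
#'
#' @inheritParams hbt_coe
#' @return data frame with columns `hbo, hbr, hbt, coe, magnitude, angle_deg,
#'   phase`.
#' @export
phase_points <- function(hbo, hbr) {
  rot <- hbt_coe(hbo, hbr)
  data.frame(hbo = hbo, hbr = hbr, hbt = rot$hbt, coe = rot$coe,
             magnitude = sqrt(hbo^2 + hbr^2),
             angle_deg = atan2(hbr, hbo) * 180 / pi,
             phase = classify_phase(hbo, hbr, origin = "na"))
}

#' Eight-phase octant classification of the vector diagram
#'
#' The (dHbO, dHbR) plane is split into eight 45-degree octants.  Phase 1 is
#' the octant `(0, 45]` degrees above the positive dHbO axis and numbering
#' proceeds counterclockwise, so Phase 8 is `(-45, 0]`.  Octants are half-open,
#' closed on their counterclockwise edge, which fixes boundary angles
#' deterministically.  Phases 3-5 flag initial dips (dCOE > 0 with the vector
#' away from the first quadrant); phases 7 and 8 (fourth quadrant: dHbO > 0,
#' dHbR < 0) flag canonical hemodynamic responses.
#'
#' @inheritParams hbt_coe
#' @param origin behaviour at the zero vector: `"error"` (default, the phase
#'   is undefined) or `"na"`.
#' @return integer vector of phases 1..8.
#' @export
#' @examples
#' classify_phase(1, 0.5)    # 1
#' classify_phase(1, -0.5)   # 8 (hemodynamic)
classify_phase <- function(hbo, hbr, origin = c("error", "na")) {
  origin <- match.arg(origin)
  stopifnot(length(hbo) == length(hbr))
  zero <- hbo == 0 & hbr == 0
  if (any(zero) && origin == "error")
    stop("phase undefined at the zero vector (sample ",
         which(zero)[1], ")")
  theta <- atan2(hbr, hbo) * 180 / pi     # (-180, 180]
  k <- ceiling(theta / 45)
  k[theta <= 0] <- k[theta <= 0] + 8L     # map (-180, 0] onto phases 5..8
  k <- as.integer(k)
  k[zero] <- NA_integer_
  k
}

#' Initial-dip / hemodynamic flags for a phase label
#'
#' @param phase integer vector of phases 1..8.
#' @return data frame with logical columns `dip` (phases 3-5) and `hemo`
#'   (phases 7-8).
#' @export
phase_flags <- function(phase) {
  data.frame(dip = phase %in% 3:5, hemo = phase %in% 7:8)
}

#' Resting-state threshold circle radius
#'
#' `r1 = max_t sqrt(hbo(t)^2 + hbr(t)^2)`: the maximum paired per-sample
#' vector magnitude over the resting baseline.
#'
#' @inheritParams hbt_coe
#' @return scalar radius `r1 >= 0`.
#' @export
#' @examples
#' resting_radius(c(0.1, -0.2), c(0.05, 0.1))  # 0.2236
resting_radius <- function(hbo, hbr) {
  stopifnot(length(hbo) == length(hbr))
  if (length(hbo) == 0) stop("empty baseline segment")
  max(sqrt(hbo^2 + hbr^2))
}

#' EEG-activation-window (inner) circle radius
#'
#' `r2 = sqrt(max_t |hbo(t)|^2 + max_t |hbr(t)|^2)` over the 1-s window that
#' triggered the EEG gate.  Unlike the resting radius the two component
#' maxima are taken separately; absolute values are used so that the formula
#' defines a radius in the fourth quadrant where dHbR < 0.
#'
#' @inheritParams hbt_coe
#' @return scalar radius `r2 >= 0`.
#' @export
#' @examples
#' eeg_window_radius(c(0.1, 0.3), c(-0.2, -0.1))  # 0.3606
eeg_window_radius <- function(hbo, hbr) {
  stopifnot(length(hbo) == length(hbr))
  if (length(hbo) == 0) stop("empty window")
  sqrt(max(abs(hbo))^2 + max(abs(hbr))^2)
}

#' Per-sample trajectory record relative to both threshold circles
#'
#' @param h a [hemo_series()].
#' @param r1 resting-state circle radius.
#' @param r2 EEG-window circle radius.
#' @param start_index first (1-based) sample to include.
#' @return data frame `time, hbo, hbr, hbt, coe, magnitude, angle_deg, phase,
#'   in_r2, in_r1` (inside = magnitude <= radius), ordered in time.
#' @export
track_trajectory <- function(h, r1, r2, start_index = 1L) {
  stopifnot(inherits(h, "hemo_series"))
  n <- length(h$hbo)
  if (start_index < 1 || start_index > n)
    stop("start_index beyond series end (n = ", n, ")")
  idx <- start_index:n
  pts <- phase_points(h$hbo[idx], h$hbr[idx])
  pts$time <- (idx - 1) / h$rate
  pts$in_r2 <- pts$magnitude <= r2
  pts$in_r1 <- pts$magnitude <= r1
  pts[, c("time", "hbo", "hbr", "hbt", "coe", "magnitude", "angle_deg",
          "phase", "in_r2", "in_r1")]
}

#' Export a trajectory and its threshold circles
#'
#' Writes the trajectory as a tab-separated table and the two circles
#' (origin-centred, radius only) as JSON alongside.
#'
#' @param traj data frame from [track_trajectory()].
#' @param r1,r2 circle radii.
#' @param path output path for the table; the circles go to
#'   `paste0(path, ".circles.json")`.
#' @return invisibly, the two paths.
#' @export
write_trajectory <- function(traj, r1, r2, path) {
  data.table::fwrite(traj, path, sep = "\t")
  cpath <- paste0(path, ".circles.json")
  jsonlite::write_json(
    list(r1 = list(center = c(0, 0), radius = r1),
         r2 = list(center = c(0, 0), radius = r2)),
    cpath, auto_unbox = TRUE, digits = NA)
  invisible(c(path, cpath))
}
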