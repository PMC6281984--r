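#' Default probe geometry: 12 emitters, 3 detectors, 36 channels, 5 electrodes
#'
#' Emitters are laid out row-major on a 4-row x 3-column grid (0.7 cm pitch)
#' over the left motor cortex; the three detectors sit along the grid's
#' centre column at increasing depth rows.  Emitter e paired with detector d
#' forms channel `e + 12 * (d - 1)` (emitter 1 + detector 1 = channel 1,
#' emitter 1 + detector 2 = channel 13, ...).  Five EEG electrodes surround
#' the patch: ids 1-2 horizontal (above the grid), ids 3-5 vertical (beside
#' it).
#'
#' @param pitch_cm emitter grid spacing in cm (default 0.7).
#' @return object of class `probe_geometry`: lists of emitter, detector and
#'   electrode positions plus the 36-row channel table
#'   (`channel_id, emitter_id, detector_id, x, y, distance_cm`).
#' @export
probe_geometry <- function(pitch_cm = 0.7) {
  if (pitch_cm <= 0) stop("pitch_cm must be positive")
  em <- data.frame(
    emitter_id = 1:12,
    x = rep(0:2, times = 4) * pitch_cm,
    y = rep(0:3, each = 3) * pitch_cm
  )
  det <- data.frame(
    detector_id = 1:3,
    x = rep(1 * pitch_cm, 3),
    y = c(0.5, 1.5, 2.5) * pitch_cm
  )
  ch <- do.call(rbind, lapply(1:3, function(d) {
    dx <- em$x - det$x[d]; dy <- em$y - det$y[d]
    data.frame(channel_id = em$emitter_id + 12 * (d - 1),
               emitter_id = em$emitter_id, detector_id = d,
               x = (em$x + det$x[d]) / 2, y = (em$y + det$y[d]) / 2,
               distance_cm = sqrt(dx^2 + dy^2))
  }))
  el <- data.frame(
    electrode_id = 1:5,
    group = c("horizontal", "horizontal", "vertical", "vertical", "vertical"),
    x = c(1.5, 0.5, -0.7, -0.7, -0.7) * pitch_cm,
    y = c(-0.7, -0.7, 2.5, 1.5, 0.5) * pitch_cm
  )
  structure(list(emitters = em, detectors = det, channels = ch,
                 electrodes = el, pitch_cm = pitch_cm),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat("Probe geometry:", nrow(x$emitters), "emitters x",
      nrow(x$detectors), "detectors =", nrow(x$channels), "channels;",
      nrow(x$electrodes), "EEG electrodes\n")
  invisible(x)
}

#' Validate a probe geometry against the patch conventions
#'
#' Report-based check of the pairing rule (`channel = emitter + 12 *
#' (detector - 1)`), the 12 x 3 = 36 channel count, unique channel ids,
#' positive source-detector distances, and the electrode grouping
#' (ids 1-2 horizontal, 3-5 vertical).
#'
#' @param g a [probe_geometry()]-like object.
#' @return character vector of violations (length 0 when clean), invisibly
#'   printed.
#' @export
validate_geometry <- function(g) {
  v <- character(0)
  ch <- g$channels
  if (nrow(g$emitters) != 12)
    v <- c(v, sprintf("expected 12 emitters, found %d", nrow(g$emitters)))
  if (nrow(g$detectors) != 3)
    v <- c(v, sprintf("expected 3 detectors, found %d", nrow(g$detectors)))
  if (nrow(ch) != 36)
    v <- c(v, sprintf("expected 36 channels, found %d", nrow(ch)))
  if (anyDuplicated(ch$channel_id))
    v <- c(v, "duplicated channel ids")
  bad <- ch$channel_id != ch$emitter_id + 12 * (ch$detector_id - 1)
  if (any(bad))
    v <- c(v, sprintf("pairing rule violated for channel(s) %s",
                      paste(ch$channel_id[bad], collapse = ", ")))
  if (any(ch$distance_cm <= 0))
    v <- c(v, "non-positive source-detector distance")
  el <- g$electrodes
  want <- c("horizontal", "horizontal", "vertical", "vertical", "vertical")
  if (nrow(el) != 5 || any(el$group[order(el$electrode_id)] != want))
    v <- c(v, "electrode grouping must be ids 1-2 horizontal, 3-5 vertical")
  v
}
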