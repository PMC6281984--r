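#' Extinction coefficients for 690/830 nm
#'
#' The 2x2 extinction matrix used by the modified Beer-Lambert law, rows
#' indexed by wavelength (690, 830 nm) and columns by chromophore (HbO, HbR),
#' in mM^-1 cm^-1: 0.95 / 4.93 at 690 nm and 2.135 / 1.791 at 830 nm.
#'
#' @return 2x2 numeric matrix with dimnames `("690","830") x ("HbO","HbR")`.
#' @export
extinction_defaults <- function() {
  matrix(c(0.95, 4.93,
           2.135, 1.791),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("690", "830"), c("HbO", "HbR")))
}

.check_extinction <- function(ext) {
  if (!is.matrix(ext) || any(dim(ext) != 2))
    stop("extinction table must be a 2x2 matrix (wavelengths x chromophores)")
  d <- ext[1, 1] * ext[2, 2] - ext[1, 2] * ext[2, 1]
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("singular extinction matrix for wavelength pair (",
         paste(rownames(ext) %||% c("1", "2"), collapse = ", "),
         ") nm: chromophores are not separable")
  invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optical-density change from raw intensity
#'
#' `dOD(t) = -log10(I(t) / mean(I[baseline]))` per wavelength.  Intensities
#' must be strictly positive.
#'
#' @param intensity numeric vector of raw detector intensities.
#' @param baseline_idx integer indices of the baseline window used for the
#'   reference intensity (default: the whole series).
#' @return numeric vector of optical-density changes.
#' @export
intensity_to_od <- function(intensity, baseline_idx = seq_along(intensity)) {
  if (length(baseline_idx) == 0) stop("baseline window is empty")
  bad <- which(!is.finite(intensity) | intensity <= 0)
  if (length(bad))
    stop("non-positive intensity at sample ", bad[1])
  i0 <- mean(intensity[baseline_idx])
  -log10(intensity / i0)
}

#' Chromophore concentration changes from optical density (MBLL inversion)
#'
#' Solves the modified Beer-Lambert law per sample:
#' `(dHbO, dHbR) = E^-1 (dOD_690, dOD_830) / (d * DPF)` with `E` the 2x2
#' extinction matrix, `d` the source-detector distance (cm) and `DPF` the
#' differential pathlength factor.  With the mM^-1 cm^-1 extinction table and
#' `d`, `DPF` set, output units are mM; with `pathlength_cm = dpf = 1` the
#' output is on the molar-absorbance (mM cm) scale.
#'
#' @param od690,od830 optical-density change series (equal length).
#' @param ext extinction matrix, see [extinction_defaults()].
#' @param pathlength_cm source-detector distance in cm (> 0).
#' @param dpf differential pathlength factor (> 0); 6.0 is the package-wide
#'   continuous-wave default.
#' @param rate sampling rate (Hz) stored on the result.
#' @param channel_id channel index stored on the result.
#' @return a [hemo_series()].
#' @export
od_to_hemo <- function(od690, od830, ext = extinction_defaults(),
                       pathlength_cm = 1, dpf = 1, rate = 9.19,
                       channel_id = NA_integer_) {
  stopifnot(length(od690) == length(od830))
  if (pathlength_cm <= 0 || dpf <= 0)
    stop("pathlength_cm and dpf must be positive")
  .check_extinction(ext)
  conc <- solve(ext, rbind(od690, od830)) / (pathlength_cm * dpf)
  hemo_series(hbo = conc[1, ], hbr = conc[2, ], rate = rate,
              channel_id = channel_id)
}

#' Forward modified Beer-Lambert model
#'
#' Maps concentration changes to dual-wavelength intensities:
#' `dOD(lambda) = (eps_HbO dHbO + eps_HbR dHbR) d DPF`,
#' `I = I0 * 10^-dOD`.  This is the exact inverse of [od_to_hemo()] composed
#' with [intensity_to_od()] (given the same baseline reference), and is what
#' the synthetic generator uses to fold ground-truth concentrations into raw
#' intensities.
#'
#' @param hbo,hbr concentration change series (mM).
#' @param ext extinction matrix.
#' @param pathlength_cm,dpf as in [od_to_hemo()].
#' @param i0 length-2 baseline intensities for (690, 830) nm.
#' @return list with numeric vectors `wl690` and `wl830`.
#' @export
forward_mbll <- function(hbo, hbr, ext = extinction_defaults(),
                         pathlength_cm = 1, dpf = 1, i0 = c(1, 1)) {
  stopifnot(length(hbo) == length(hbr), length(i0) == 2)
  .check_extinction(ext)
  od <- (ext %*% rbind(hbo, hbr)) * pathlength_cm * dpf
  list(wl690 = i0[1] * 10^(-od[1, ]), wl830 = i0[2] * 10^(-od[2, ]))
}

#' Paired oxy-/deoxy-hemoglobin time series for one channel
#'
#' @param hbo,hbr numeric vectors of equal length.
#' @param rate sampling rate in Hz (> 0).
#' @param channel_id channel index.
#' @return object of class `hemo_series`.
#' @export
hemo_series <- function(hbo, hbr, rate, channel_id = NA_integer_) {
  if (length(hbo) != length(hbr)) stop("hbo and hbr lengths differ")
  if (rate <= 0) stop("rate must be positive")
  structure(list(hbo = as.numeric(hbo), hbr = as.numeric(hbr),
                 rate = rate, channel_id = channel_id),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat("Hemodynamic series", if (!is.na(x$channel_id))
    paste0("(channel ", x$channel_id, ")"), "\n")
  cat("  ", length(x$hbo), "samples at", x$rate, "Hz (",
      round(length(x$hbo) / x$rate, 1), "s )\n")
  cat("   dHbO range:", signif(range(x$hbo), 3), "\n")
  cat("   dHbR range:", signif(range(x$hbr), 3), "\n")
  invisible(x)
}
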