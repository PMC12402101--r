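#' Camera model
#'
#' Describes the affine photoelectron response of an sCMOS (or EMCCD)
#' detector. Photoelectrons are reported as photons throughout the package,
#' the usual convention when brightness is printed as "photons (counts)";
#' quantum efficiency is not re-applied.
#'
#' @param gain photoelectrons per camera count (dimensionless, > 0).
#' @param offset camera offset in counts (>= 0).
#' @param read_noise read noise, photoelectrons rms (>= 0).
#' @param bit_depth ADC bit depth.
#'
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(gain = 0.6, offset = 100)
#' counts_to_photons(172, cam, background_subtracted = TRUE)  # 103.2
#' @export
camera_model <- function(gain = 0.6, offset = 100, read_noise = 1.6,
                         bit_depth = 16) {
  stopifnot(is.numeric(gain), length(gain) == 1L, gain > 0,
            is.numeric(offset), length(offset) == 1L, offset >= 0,
            is.numeric(read_noise), length(read_noise) == 1L, read_noise >= 0,
            is.numeric(bit_depth), length(bit_depth) == 1L, bit_depth >= 1)
  structure(list(gain = gain, offset = offset, read_noise = read_noise,
                 bit_depth = bit_depth),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: gain %.3g e-/count, offset %g counts, read noise %.3g e- rms, %d-bit\n",
              x$gain, x$offset, x$read_noise, as.integer(x$bit_depth)))
  invisible(x)
}

#' Convert camera counts to photons
#'
#' Applies the affine detector response `photons = (counts - offset) * gain`.
#' Background-subtracted intensities (the offset cancels in the subtraction)
#' are converted with the gain alone via `background_subtracted = TRUE`.
#' Negative results are preserved, not clipped, so that background noise
#' statistics stay unbiased.
#'
#' @param x numeric vector/array of counts, or an [image_stack()] whose
#'   `units` are `"counts"`.
#' @param camera a [camera_model()].
#' @param background_subtracted if `TRUE` the offset is assumed already
#'   removed and only the gain is applied.
#'
#' @return Same shape as `x`, in photons; for a stack, a stack with
#'   `units = "photons"`.
#' @export
counts_to_photons <- function(x, camera, background_subtracted = FALSE) {
  stopifnot(inherits(camera, "camera_model"))
  off <- if (background_subtracted) 0 else camera$offset
  if (inherits(x, "image_stack")) {
    if (x$units != "counts")
      stop("stack units are '", x$units, "', expected 'counts'")
    x$frames <- (x$frames - off) * camera$gain
    x$units <- "photons"
    return(x)
  }
  (x - off) * camera$gain
}

#' Convert photons back to camera counts
#'
#' Exact inverse of [counts_to_photons()] (no rounding or clipping).
#'
#' @inheritParams counts_to_photons
#' @export
photons_to_counts <- function(x, camera, background_subtracted = FALSE) {
  stopifnot(inherits(camera, "camera_model"))
  off <- if (background_subtracted) 0 else camera$offset
  if (inherits(x, "image_stack")) {
    if (x$units != "photons")
      stop("stack units are '", x$units, "', expected 'photons'")
    x$frames <- x$frames / camera$gain + off
    x$units <- "counts"
    return(x)
  }
  x / camera$gain + off
}

#' Expected single-molecule signal-to-noise ratio
#'
#' The per-pixel SNR expected for a spot of total brightness `brightness`
#' photons spread over `focus_area` pixels on a Poisson background of
#' `background` photons/pixel: `(brightness / focus_area) / sqrt(background)`.
#' Used to sanity-check sifting thresholds against the characteristic
#' molecular brightness and the measured autofluorescence level.
#'
#' @param brightness total spot photons per frame.
#' @param focus_area effective spot footprint, pixels.
#' @param background mean background, photons/pixel (Poisson, so its
#'   standard deviation is `sqrt(background)`).
#' @return Expected SNR (dimensionless).
#' @examples
#' expected_snr(76, 30, 26)   # ~0.50, single YFP on root autofluorescence
#' expected_snr(103, 30, 45)  # ~0.51, single GFP
#' @export
expected_snr <- function(brightness, focus_area, background) {
  stopifnot(brightness >= 0, focus_area > 0, background > 0)
  (brightness / focus_area) / sqrt(background)
}
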