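#' Simulation parameters
#'
#' Defines the synthetic imaging conditions: diffusing molecular assemblies,
#' each carrying one fluorophore per labelled molecule, undergoing stepwise
#' photobleaching on a uniform autofluorescent background with full camera
#' noise. All fluorophores of an assembly are rendered coincident (assemblies
#' are far below the diffraction limit).
#'
#' @param field_size field width/height, pixels (square field).
#' @param pixel_size pixel width, nm.
#' @param frame_interval,exposure_time ms.
#' @param psf_sigma PSF Gaussian sigma, nm (~170 nm FWHM / 2.355 by default).
#' @param n_assemblies number of assemblies seeded in the field.
#' @param stoichiometry either a fixed integer count per assembly, or
#'   `list(subunit = m, mean_multiple = lambda)` for Poisson-distributed
#'   multiples of an oligomeric subunit (multiples conditioned >= 1). The
#'   default emulates in-tissue oligomeric assemblies (dimer-built, mean
#'   ~16 molecules); single fluorophores on this autofluorescence level sit
#'   below the sifting threshold by design, as in the adverse imaging case.
#' @param brightness per-fluorophore mean emission, photons/frame.
#' @param bleach_prob per-fluorophore photobleaching probability per frame.
#' @param diffusivity um^2/s.
#' @param background uniform autofluorescence, photons/pixel/frame.
#' @param camera a [camera_model()].
#' @param n_frames frames to simulate.
#' @param units output stack units: `"counts"` applies the full camera
#'   conversion (rounding to integer counts); `"photons"` skips it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(field_size = 96, pixel_size = 53,
                       frame_interval = 10, exposure_time = 10,
                       psf_sigma = 170 / 2.355,
                       n_assemblies = 20,
                       stoichiometry = list(subunit = 2, mean_multiple = 8),
                       brightness = 76,
                       bleach_prob = 0.05,
                       diffusivity = 0.1,
                       background = 26,
                       camera = camera_model(),
                       n_frames = 100,
                       units = "counts") {
  stopifnot(field_size >= 16, pixel_size > 0, psf_sigma > 0,
            psf_sigma / pixel_size < field_size,
            n_assemblies >= 0, brightness >= 0,
            bleach_prob >= 0, bleach_prob <= 1,
            diffusivity >= 0, background >= 0, n_frames >= 1,
            inherits(camera, "camera_model"))
  structure(list(field_size = field_size, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 exposure_time = exposure_time,
                 psf_sigma = psf_sigma, n_assemblies = n_assemblies,
                 stoichiometry = stoichiometry, brightness = brightness,
                 bleach_prob = bleach_prob, diffusivity = diffusivity,
                 background = background, camera = camera,
                 n_frames = n_frames,
                 units = match.arg(units, c("counts", "photons"))),
            class = "sim_params")
}

draw_stoichiometries <- function(dist, n) {
  if (is.numeric(dist) && length(dist) == 1L) return(rep(as.integer(dist), n))
  if (is.list(dist) && !is.null(dist$subunit)) {
    k <- stats::rpois(n, dist$mean_multiple)
    while (any(k < 1)) k[k < 1] <- stats::rpois(sum(k < 1), dist$mean_multiple)
    return(as.integer(dist$subunit * k))
  }
  stop("invalid stoichiometry distribution")
}

# Add one pixel-integrated Gaussian PSF of `total` expected photons at
# continuous 0-based (x, y) to matrix `img` (modified copy returned).
add_psf <- function(img, x, y, total, sigma_px) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(4 * sigma_px)
  cx <- round(x); cy <- round(y)
  cols <- max(0, cx - r):min(nc - 1, cx + r)
  rows <- max(0, cy - r):min(nr - 1, cy + r)
  if (!length(cols) || !length(rows)) return(img)
  # pixel i (0-based centre) spans [i - 0.5, i + 0.5]
  px <- stats::pnorm(cols + 0.5, x, sigma_px) - stats::pnorm(cols - 0.5, x, sigma_px)
  py <- stats::pnorm(rows + 0.5, y, sigma_px) - stats::pnorm(rows - 0.5, y, sigma_px)
  img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + total * (py %o% px)
  img
}

#' Simulate a photobleaching image stack with ground truth
#'
#' Per frame, each surviving fluorophore contributes an expected
#' `brightness` photons as a pixel-integrated 2D Gaussian PSF at its
#' assembly's position; assemblies move by isotropic Gaussian steps of
#' per-axis variance `2 * D * dt` with reflecting field boundaries; each
#' fluorophore photobleaches independently with probability `bleach_prob`
#' per frame. Uniform background is added, Poisson shot noise is applied to
#' the expected photon image, then Gaussian read noise, then (for
#' `units = "counts"`) the affine camera conversion with rounding. Ground
#' truth (positions, stoichiometries, per-fluorophore bleach frames, noise-
#' free expected photon totals) is recorded before any noise.
#'
#' @param params a [sim_params()].
#' @param seed integer RNG seed (optional; set for reproducibility).
#' @return List with `stack` (an [image_stack()]) and `truth`, a list of:
#'   `assemblies` (data.frame: id, stoichiometry), `positions` (data.frame:
#'   id, frame, x, y in 0-based pixels), `bleach` (data.frame: id, fluor,
#'   last_frame = last frame the fluorophore emits), `active` (matrix of
#'   surviving fluorophores, frame x assembly), `expected_signal` (vector of
#'   expected signal photons per frame, excluding background).
#' @export
simulate_stack <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  n <- p$field_size
  sigma_px <- p$psf_sigma / p$pixel_size
  dt <- p$frame_interval / 1000                    # s
  step_sd_um <- sqrt(2 * p$diffusivity * dt)       # per axis
  step_sd_px <- step_sd_um / (p$pixel_size / 1000)

  S <- draw_stoichiometries(p$stoichiometry, p$n_assemblies)
  margin <- 6
  x <- stats::runif(p$n_assemblies, margin, n - 1 - margin)
  y <- stats::runif(p$n_assemblies, margin, n - 1 - margin)

  # fluorophore lifetimes: emits in frames 1..L, L = 1 + Geometric(p_b)
  fl_id <- rep(seq_len(p$n_assemblies), times = S)
  L <- if (p$bleach_prob > 0)
    1L + stats::rgeom(length(fl_id), p$bleach_prob) else
    rep(p$n_frames, length(fl_id))
  L <- pmin(L, p$n_frames)

  frames <- array(0, dim = c(n, n, p$n_frames))
  pos <- matrix(0, nrow = p$n_assemblies * p$n_frames, ncol = 4)
  active <- matrix(0L, nrow = p$n_frames, ncol = p$n_assemblies)
  exp_signal <- numeric(p$n_frames)

  reflect <- function(z) {
    lo <- 0; hi <- n - 1
    z <- abs(z - lo) + lo
    over <- z > hi
    z[over] <- 2 * hi - z[over]
    pmin(pmax(z, lo), hi)
  }

  for (t in seq_len(p$n_frames)) {
    img <- matrix(p$background, n, n)
    alive_per <- tabulate(fl_id[L >= t], nbins = p$n_assemblies)
    active[t, ] <- alive_per
    exp_signal[t] <- sum(alive_per) * p$brightness
    for (a in seq_len(p$n_assemblies)) {
      if (alive_per[a] > 0)
        img <- add_psf(img, x[a], y[a], alive_per[a] * p$brightness, sigma_px)
      pos[(t - 1) * p$n_assemblies + a, ] <- c(a, t, x[a], y[a])
    }
    noisy <- matrix(stats::rpois(n * n, img), n, n)
    if (p$camera$read_noise > 0)
      noisy <- noisy + matrix(stats::rnorm(n * n, 0, p$camera$read_noise), n, n)
    if (p$units == "counts") {
      noisy <- round(noisy / p$camera$gain + p$camera$offset)
      noisy <- pmin(pmax(noisy, 0), 2^p$camera$bit_depth - 1)
    }
    frames[, , t] <- noisy
    if (p$n_assemblies > 0) {
      x <- reflect(x + stats::rnorm(p$n_assemblies, 0, step_sd_px))
      y <- reflect(y + stats::rnorm(p$n_assemblies, 0, step_sd_px))
    }
  }

  stack <- image_stack(frames, pixel_size = p$pixel_size,
                       frame_interval = p$frame_interval,
                       exposure_time = p$exposure_time,
                       units = p$units)
  truth <- list(
    assemblies = data.frame(id = seq_len(p$n_assemblies), stoichiometry = S),
    positions = stats::setNames(as.data.frame(pos), c("id", "frame", "x", "y")),
    bleach = data.frame(id = fl_id, fluor = seq_along(fl_id), last_frame = L),
    active = active,
    expected_signal = exp_signal)
  list(stack = stack, truth = truth, params = p)
}

#' Simulate a sparse single-molecule positive control
#'
#' Convenience wrapper around [simulate_stack()] with stoichiometry fixed at
#' one fluorophore per assembly and slow (or zero) diffusion, for
#' positive-control calibration of sifting thresholds and PPV/recall
#' scoring. Setting `brightness = 0` gives the matching noise-only negative
#' control in which every detected track is a false positive by
#' construction.
#'
#' @param n_emitters single fluorophores per field.
#' @param brightness photons/frame per fluorophore.
#' @param background photons/pixel.
#' @param diffusivity um^2/s (default slow).
#' @param bleach_prob per-frame bleach probability.
#' @param n_frames,field_size,camera,seed,... passed to [sim_params()].
#' @return As [simulate_stack()].
#' @export
simulate_single_molecule_control <- function(n_emitters = 20, brightness = 76,
                                             background = 2,
                                             diffusivity = 0.01,
                                             bleach_prob = 0.03,
                                             n_frames = 100, field_size = 96,
                                             camera = camera_model(),
                                             seed = NULL, ...) {
  p <- sim_params(n_assemblies = n_emitters, stoichiometry = 1,
                  brightness = brightness, background = background,
                  diffusivity = diffusivity, bleach_prob = bleach_prob,
                  n_frames = n_frames, field_size = field_size,
                  camera = camera, ...)
  simulate_stack(p, seed = seed)
}

#' Simulate stoichiometry samples (periodic or aperiodic)
#'
#' Periodic positive controls are noisy Poisson-distributed multiples of an
#' oligomeric subunit: `s = m * k + e` with `k ~ Poisson(mean_multiple)`
#' conditioned `k >= 1` and `e ~ Normal(0, noise_sd)`. Aperiodic negative
#' controls are uniform on `[lo, hi]`.
#'
#' @param kind `"periodic"` or `"aperiodic"`.
#' @param n sample size.
#' @param subunit oligomeric subunit size m (periodic only).
#' @param mean_multiple Poisson mean of the multiple k (periodic only).
#' @param noise_sd Gaussian noise on each value, molecules (periodic only).
#' @param lo,hi uniform range (aperiodic only), molecules.
#' @param seed integer RNG seed (optional).
#' @return Numeric vector of stoichiometries.
#' @export
simulate_stoichiometries <- function(kind = c("periodic", "aperiodic"), n,
                                     subunit = 2, mean_multiple = 8,
                                     noise_sd = 0.6, lo = 1, hi = 30,
                                     seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "aperiodic") return(stats::runif(n, lo, hi))
  stopifnot(subunit >= 1, mean_multiple > 0, noise_sd >= 0)
  k <- stats::rpois(n, mean_multiple)
  while (any(k < 1)) k[k < 1] <- stats::rpois(sum(k < 1), mean_multiple)
  subunit * k + stats::rnorm(n, 0, noise_sd)
}
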