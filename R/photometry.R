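# Photobleaching photometry: edge-preserving filtering of intensity traces,
# characteristic single-fluorophore brightness from photobleached track
# tails, initial track intensity by backward extrapolation, stoichiometry,
# and the photobleach decay constant.

#' Chung-Kennedy edge-preserving filter
#'
#' Each point is replaced by a weighted combination of the means of a
#' backward window (the `W` points up to and including it) and a forward
#' window (it and the `W - 1` points after), weights proportional to the inverse `p`-th power
#' of each window's variance. At a step edge the window that straddles the
#' edge has large variance and is down-weighted, so step positions and
#' levels are preserved while flat stretches are smoothed. Edges of the
#' series use truncated windows.
#'
#' @param series numeric vector (length >= 2).
#' @param W window length, samples (default 10).
#' @param p variance weight exponent (default 2).
#' @return Filtered series, same length.
#' @export
chung_kennedy <- function(series, W = 10L, p = 2) {
  n <- length(series)
  stopifnot(n >= 2, W >= 1)
  out <- numeric(n)
  eps <- 1e-12
  for (i in seq_len(n)) {
    back <- series[max(1, i - W + 1):i]
    fwd <- series[i:min(n, i + W - 1)]
    mb <- mean(back)
    mf <- mean(fwd)
    # single-point windows carry no variance information: defer to the other
    gb <- if (length(back) > 1) 1 / (stats::var(back) + eps)^p else NA
    gf <- if (length(fwd) > 1) 1 / (stats::var(fwd) + eps)^p else NA
    if (is.na(gb) && is.na(gf)) { out[i] <- (mb + mf) / 2; next }
    if (is.na(gb)) { out[i] <- mf; next }
    if (is.na(gf)) { out[i] <- mb; next }
    out[i] <- (gb * mb + gf * mf) / (gb + gf)
  }
  out
}

#' Characteristic molecular brightness from photobleached track tails
#'
#' The characteristic brightness B of a single fluorophore is the most
#' common terminal intensity level of tracks that bleach down to their last
#' step: the intensity series of each track is Chung-Kennedy filtered, its
#' last filtered level taken as the terminal intensity, tracks whose
#' terminal level exceeds `qualify_factor` times the running (median)
#' estimate are excluded (they likely vanished by diffusion mid-bleach
#' rather than bleaching to a single fluorophore), and B is the mode of a
#' Gaussian kernel density over the qualifying terminal levels. The
#' standard error is a bootstrap over tracks.
#'
#' @param linked sifted foci data.frame with `track_id` (or a list of
#'   per-track data.frames).
#' @param W,p Chung-Kennedy filter parameters.
#' @param kernel_factor KDE bandwidth as a fraction of the median terminal
#'   level (default 0.3).
#' @param qualify_factor terminal levels above this multiple of the running
#'   median are excluded (default 2.5).
#' @param min_tracks minimum qualifying tracks (default 10).
#' @param n_boot bootstrap resamples for the standard error.
#' @return List of class `brightness_estimate`: `B`, `se`, `n_tracks`,
#'   `terminal_levels`, `kde` (density object).
#' @export
estimate_characteristic_brightness <- function(linked, W = 10L, p = 2,
                                               kernel_factor = 0.3,
                                               qualify_factor = 2.5,
                                               min_tracks = 10L,
                                               n_boot = 200L) {
  tracks <- if (is.data.frame(linked)) split_tracks(linked) else linked
  term <- vapply(tracks, function(tr) {
    v <- tr$intensity
    if (length(v) < 2) return(v[length(v)])
    f <- chung_kennedy(v, W = W, p = p)
    f[length(f)]
  }, 0)
  term <- term[is.finite(term) & term > 0]
  med <- stats::median(term)
  term <- term[term <= qualify_factor * med]
  if (length(term) < min_tracks)
    stop("only ", length(term), " qualifying tracks (need >= ", min_tracks,
         "); pool tracks across acquisitions of the same sample")
  mode_of <- function(v) {
    bw <- max(kernel_factor * stats::median(v), 1e-6)
    d <- stats::density(v, bw = bw, n = 1024)
    d$x[which.max(d$y)]
  }
  B <- mode_of(term)
  boots <- vapply(seq_len(n_boot), function(i)
    mode_of(sample(term, replace = TRUE)), 0)
  bw <- max(kernel_factor * stats::median(term), 1e-6)
  structure(list(B = B, se = stats::sd(boots), n_tracks = length(term),
                 terminal_levels = term,
                 kde = stats::density(term, bw = bw, n = 1024)),
            class = "brightness_estimate")
}

#' @export
print.brightness_estimate <- function(x, ...) {
  cat(sprintf("characteristic molecular brightness: %.1f +/- %.1f photons/frame (n = %d tracks)\n",
              x$B, x$se, x$n_tracks))
  invisible(x)
}

#' Initial track intensity by backward extrapolation
#'
#' Straight-line fit of intensity against frame over the first
#' `min(5, n_foci)` foci, evaluated at the first exposure of the
#' acquisition (`first_frame`, default frame of index 1), i.e. a virgin
#' timepoint before any photobleaching. Photobleaching cannot brighten a
#' track, so a positive fitted slope falls back to the mean of the fitted
#' foci.
#'
#' @param track one track's focus data.frame (>= 3 foci).
#' @param first_frame frame index of the first exposure (default 1).
#' @param n_points maximum leading foci used in the fit (default 5).
#' @return Initial intensity I0, photons.
#' @export
initial_track_intensity <- function(track, first_frame = 1L, n_points = 5L) {
  if (nrow(track) < 3L) stop("need at least 3 foci to extrapolate")
  k <- min(n_points, nrow(track))
  head_tr <- track[order(track$frame), ][seq_len(k), ]
  fit <- stats::lm(intensity ~ frame, data = head_tr)
  slope <- stats::coef(fit)[["frame"]]
  if (slope > 0) return(mean(head_tr$intensity))
  unname(stats::predict(fit, newdata = data.frame(frame = first_frame)))
}

#' Stoichiometry of a tracked assembly
#'
#' The number of labelled molecules in the assembly: initial track intensity
#' divided by the characteristic molecular brightness. Continuous, not
#' rounded. Tracks starting later than a quarter of the photobleach decay
#' time are flagged as biased low (molecules have already bleached).
#'
#' @param track one track's focus data.frame, or a precomputed I0 via `I0`.
#' @param B characteristic molecular brightness, photons/frame (> 0).
#' @param I0 optional precomputed initial intensity (skips extrapolation).
#' @param bleach_time photobleach decay constant in frames (optional, for
#'   the late-start flag).
#' @param first_frame first exposure frame of the acquisition.
#' @return Numeric S with attribute `late_start` when `bleach_time` given.
#' @export
stoichiometry <- function(track = NULL, B, I0 = NULL, bleach_time = NULL,
                          first_frame = 1L) {
  if (B <= 0) stop("B must be positive")
  if (is.null(I0)) I0 <- initial_track_intensity(track, first_frame)
  S <- I0 / B
  if (!is.null(bleach_time) && !is.null(track))
    attr(S, "late_start") <-
      (min(track$frame) - first_frame) > bleach_time / 4
  S
}

#' Photobleach decay constant from an intensity series
#'
#' Single-exponential fit (offset allowed) of integrated intensity against
#' frame: `I(t) = A exp(-t / tau) + C`. Returns the decay constant in
#' frames, and in ms when `frame_interval` is given.
#'
#' @param intensity integrated ROI (or pooled track) intensity per frame.
#' @param frame_interval ms per frame (optional).
#' @return List: `tau_frames`, `tau_ms` (or NA), `fit` coefficients.
#' @export
photobleach_decay_time <- function(intensity, frame_interval = NULL) {
  n <- length(intensity)
  stopifnot(n >= 5)
  t <- seq_len(n) - 1
  if (stats::sd(intensity) == 0 || stats::cor(t, intensity) >= 0)
    stop("series does not decay; cannot fit a photobleach constant")
  C0 <- min(intensity)
  A0 <- max(intensity) - C0
  pos <- intensity - C0 + A0 * 1e-3
  tau0 <- tryCatch({
    f <- stats::lm(log(pos) ~ t)
    max(1, -1 / stats::coef(f)[["t"]])
  }, error = function(e) n / 3)
  fit <- tryCatch(
    stats::nls(intensity ~ A * exp(-t / tau) + C,
               start = list(A = A0, tau = tau0, C = C0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE,
                                            scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) stop("exponential fit failed")
  cf <- stats::coef(fit)
  if (cf[["tau"]] <= 0) stop("fitted decay constant not positive")
  list(tau_frames = unname(cf[["tau"]]),
       tau_ms = if (is.null(frame_interval)) NA_real_
                else unname(cf[["tau"]]) * frame_interval,
       fit = cf)
}
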