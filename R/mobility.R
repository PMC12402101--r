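# Diffusivity from mean-squared displacements: D is a quarter of the
# initial slope of the time-averaged MSD against lag time (2D random walk).

#' Time-averaged mean-squared displacement of a track
#'
#' Overlapping-pair MSD at every lag from 1 to `n_foci - 1`, with positions
#' converted to micrometres.
#'
#' @param track one track's focus data.frame (>= 3 foci, consecutive
#'   frames).
#' @param pixel_size nm per pixel.
#' @param frame_interval ms per frame (per channel, for alternating
#'   excitation).
#' @return data.frame: `lag` (frames), `tau_s` (s), `msd` (um^2), `n_pairs`.
#' @export
msd <- function(track, pixel_size, frame_interval) {
  n <- nrow(track)
  if (n < 3) stop("need at least 3 foci for an MSD")
  track <- track[order(track$frame), ]
  um <- pixel_size / 1000
  x <- track$x * um; y <- track$y * um
  lags <- seq_len(n - 1)
  ms <- vapply(lags, function(L) {
    dx <- x[(1 + L):n] - x[1:(n - L)]
    dy <- y[(1 + L):n] - y[1:(n - L)]
    mean(dx^2 + dy^2)
  }, 0)
  data.frame(lag = lags, tau_s = lags * frame_interval / 1000,
             msd = ms, n_pairs = n - lags)
}

#' Per-track diffusivity
#'
#' Unweighted straight-line fit of the MSD over the first `n_fit_lags` lag
#' times (free intercept, absorbing static localisation error);
#' `D = slope / 4`. A negative fitted slope returns `D = 0` flagged via
#' attribute `negative_slope` (exclude such tracks from means).
#'
#' @param track one track's focus data.frame.
#' @param pixel_size nm.
#' @param frame_interval ms.
#' @param n_fit_lags lags used in the fit (default 4).
#' @return D in um^2/s, with attributes `intercept` (um^2) and
#'   `negative_slope`.
#' @export
diffusivity <- function(track, pixel_size, frame_interval, n_fit_lags = 4L) {
  stopifnot(n_fit_lags >= 2)
  if (nrow(track) < n_fit_lags + 1)
    stop("need at least n_fit_lags + 1 foci")
  m <- msd(track, pixel_size, frame_interval)
  m <- m[m$lag <= n_fit_lags, ]
  fit <- stats::lm(msd ~ tau_s, data = m)
  slope <- stats::coef(fit)[["tau_s"]]
  D <- slope / 4
  neg <- D < 0
  if (neg) D <- 0
  attr(D, "intercept") <- unname(stats::coef(fit)[["(Intercept)"]])
  attr(D, "negative_slope") <- neg
  D
}

#' Does a diffusivity match a reference mobility?
#'
#' True iff `D` lies in the closed interval
#' `[D_ref - D_err, D_ref + D_err]`, the per-track measurement-error window
#' around the reference (e.g. a chromosomal locus at 0.20 +/- 0.07 um^2/s
#' giving [0.13, 0.27]).
#'
#' @param D diffusivity, um^2/s (vectorised).
#' @param D_ref reference diffusivity, um^2/s.
#' @param D_err per-track measurement error, um^2/s.
#' @return Logical.
#' @export
matches_reference <- function(D, D_ref = 0.20, D_err = 0.07) {
  stopifnot(D_ref > 0, D_err >= 0)
  D >= D_ref - D_err & D <= D_ref + D_err
}
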