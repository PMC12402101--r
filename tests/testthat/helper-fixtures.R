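# Fixtures built in code: synthetic frames, spots and tracks.

# A frame with pixel-integrated Gaussian spots; `spots` is a data.frame with
# x, y (0-based), total (photons), sigma (px).
spot_frame <- function(nrow = 64, ncol = nrow, background = 0, spots = NULL,
                       poisson = FALSE) {
  fr <- matrix(background, nrow, ncol)
  if (!is.null(spots))
    for (i in seq_len(nrow(spots)))
      fr <- moltrack:::add_psf(fr, spots$x[i], spots$y[i], spots$total[i],
                               spots$sigma[i])
  if (poisson) fr <- matrix(stats::rpois(length(fr), fr), nrow, ncol)
  fr
}

# A minimal focus row for linker tests.
mk_focus <- function(frame, x, y, intensity = 100, snr = 1,
                     sigma_x = 1.5, sigma_y = 1.5) {
  data.frame(frame = frame, x = x, y = y, intensity = intensity,
             bg_mean = 0, bg_sd = 1, snr = snr,
             sigma_x = sigma_x, sigma_y = sigma_y,
             n_mask_pixels = 81, converged = TRUE)
}

mk_foci <- function(...) do.call(rbind, list(...))

# A synthetic track data.frame with given per-frame intensities and a
# static or linear position.
mk_track <- function(intensities, frames = seq_along(intensities),
                     x = 10, y = 10, vx = 0, vy = 0, track_id = 1L) {
  k <- seq_along(frames) - 1
  n <- length(frames)
  data.frame(track_id = rep(track_id, n), frame = frames,
             x = x + vx * k, y = y + vy * k,
             intensity = intensities, bg_mean = rep(0, n),
             bg_sd = rep(1, n), snr = rep(1, n),
             sigma_x = rep(1.5, n), sigma_y = rep(1.5, n),
             n_mask_pixels = rep(81, n), converged = rep(TRUE, n))
}

# Brownian track positions (px) at diffusivity D (um^2/s).
brownian_track <- function(n, D, pixel_size = 53, frame_interval = 10,
                           x0 = 50, y0 = 50, track_id = 1L) {
  sd_px <- sqrt(2 * D * frame_interval / 1000) / (pixel_size / 1000)
  mk_track(rep(100, n), x = 0, y = 0, track_id = track_id) |>
    transform(x = x0 + cumsum(c(0, stats::rnorm(n - 1, 0, sd_px))),
              y = y0 + cumsum(c(0, stats::rnorm(n - 1, 0, sd_px))))
}
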