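# Spot detection and photometry.
#
# Foci are local intensity maxima measured by aperture photometry: the spot
# signal is integrated over a circular mask of radius 5 px and the local
# background is taken from the remainder of a 17 x 17 px window. SNR uses
# the per-pixel form: (I / mask area) / background sd. Candidates whose
# window leaves the frame are discarded.

FOCUS_RADIUS <- 5L
WINDOW_HALF <- 8L  # 17 x 17 window

focus_cols <- c("frame", "x", "y", "intensity", "bg_mean", "bg_sd", "snr",
                "sigma_x", "sigma_y", "n_mask_pixels", "converged")

# 17 x 17 window geometry, shared by all photometry calls
.window_inmask <- local({
  off <- expand.grid(dy = -WINDOW_HALF:WINDOW_HALF,
                     dx = -WINDOW_HALF:WINDOW_HALF)
  off$dx^2 + off$dy^2 <= FOCUS_RADIUS^2
})

# Fast photometry core: returns c(I, bg_mean, bg_sd, snr, n_mask) or NULL
# at the edge.
measure_core <- function(frame, cx, cy, per_pixel = TRUE) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (cx - WINDOW_HALF < 0 || cx + WINDOW_HALF > nc - 1 ||
      cy - WINDOW_HALF < 0 || cy + WINDOW_HALF > nr - 1)
    return(NULL)
  vals <- frame[(cy - WINDOW_HALF):(cy + WINDOW_HALF) + 1,
                (cx - WINDOW_HALF):(cx + WINDOW_HALF) + 1]
  inm <- .window_inmask
  n_mask <- sum(inm)
  bg <- vals[!inm]
  bg_mean <- mean(bg)
  bg_sd <- stats::sd(bg)
  I <- sum(vals[inm]) - n_mask * bg_mean
  snr <- if (bg_sd > 0) {
    if (per_pixel) (I / n_mask) / bg_sd else I / bg_sd
  } else Inf * sign(I)
  c(I, bg_mean, bg_sd, snr, n_mask)
}

empty_foci <- function() {
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(focus_cols)),
                                      focus_cols))
  df$converged <- logical(0)
  df
}

disk_offsets <- function(r = FOCUS_RADIUS) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, ]
}

# Separable Gaussian smoothing used only for maxima finding (photometry is
# always done on the raw frame).
gauss_smooth <- function(m, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma); k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(mm, n, side) {
    if (side == "top") rbind(mm[rep(1, n), , drop = FALSE], mm)
    else if (side == "bottom") rbind(mm, mm[rep(nrow(mm), n), , drop = FALSE])
    else if (side == "left") cbind(mm[, rep(1, n), drop = FALSE], mm)
    else cbind(mm, mm[, rep(ncol(mm), n), drop = FALSE])
  }
  mp <- pad(pad(m, r, "top"), r, "bottom")
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) out <- out + k[j] * mp[(j - 1) + seq_len(nr), ]
  mp <- pad(pad(out, r, "left"), r, "right")
  out2 <- matrix(0, nr, nc)
  for (j in seq_along(k)) out2 <- out2 + k[j] * mp[, (j - 1) + seq_len(nc)]
  out2
}

# Strict 8-connected local maxima of a matrix, excluding a border.
local_maxima <- function(m, border) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(cbind(row = integer(0), col = integer(0)))
  ok <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs, cs] <- m[rs - dr, cs - dc]
    ok <- ok & (m > shifted)
  }
  b <- border
  if (b > 0) {
    ok[c(seq_len(min(b, nr)), seq(max(1, nr - b + 1), nr)), ] <- FALSE
    ok[, c(seq_len(min(b, nc)), seq(max(1, nc - b + 1), nc))] <- FALSE
  }
  which(ok, arr.ind = TRUE)
}

#' Aperture photometry of one focus
#'
#' Integrates pixel intensity within a circular mask of radius 5 px centred
#' on an integer pixel position and subtracts the mean background estimated
#' over the remainder of the surrounding 17 x 17 px window. The SNR is the
#' mean per-pixel signal divided by the background standard deviation:
#' `snr = (I / n_mask) / sd(background)`. With `snr_mode = "total"` the
#' integrated intensity is divided by the background sd directly.
#'
#' @param frame numeric matrix in photons.
#' @param x,y integer 0-based pixel position of the focus centre.
#' @param frame_index frame number recorded in the result.
#' @param snr_mode `"per_pixel"` (default) or `"total"`.
#' @return One-row focus data.frame, or `NULL` when the 17 x 17 window
#'   leaves the frame (edge policy: discard).
#' @export
measure_focus <- function(frame, x, y, frame_index = 1L,
                          snr_mode = c("per_pixel", "total")) {
  snr_mode <- match.arg(snr_mode)
  m <- measure_core(frame, round(x), round(y),
                    per_pixel = snr_mode == "per_pixel")
  if (is.null(m)) return(NULL)
  data.frame(frame = frame_index, x = round(x), y = round(y),
             intensity = m[1], bg_mean = m[2], bg_sd = m[3], snr = m[4],
             sigma_x = NA_real_, sigma_y = NA_real_,
             n_mask_pixels = m[5], converged = NA)
}

#' Refine a focus to sub-pixel precision by iterative Gaussian masking
#'
#' Repeatedly recomputes the centroid of the background-subtracted window
#' weighted by a Gaussian mask centred on the current estimate, until the
#' centroid moves by less than `tol` px or `max_iter` iterations. Elliptical
#' Gaussian semi-axes `sigma_x`, `sigma_y` are estimated from the
#' mask-weighted second central moments, corrected for the shrinkage the
#' mask itself induces (for Gaussian signal of width s under a Gaussian mask
#' of width w the weighted variance is `s^2 w^2 / (s^2 + w^2)`).
#'
#' @param frame numeric matrix in photons.
#' @param focus one-row focus data.frame from [measure_focus()].
#' @param psf_sigma initial mask sigma, px.
#' @param tol convergence tolerance on the centroid shift, px.
#' @param max_iter iteration cap; non-convergence flags the focus.
#' @return The focus row with sub-pixel `x`, `y`, `sigma_x`, `sigma_y` and
#'   `converged` filled in.
#' @export
refine_gaussian_mask <- function(frame, focus, psf_sigma = 1.4,
                                 tol = 0.01, max_iter = 20L) {
  nr <- nrow(frame); nc <- ncol(frame)
  cx0 <- round(focus$x); cy0 <- round(focus$y)
  cols <- (cx0 - WINDOW_HALF):(cx0 + WINDOW_HALF)
  rows <- (cy0 - WINDOW_HALF):(cy0 + WINDOW_HALF)
  win <- frame[rows + 1, cols + 1]
  sig <- pmax(win - focus$bg_mean, 0)
  X <- matrix(cols, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  Y <- matrix(rows, nrow = length(rows), ncol = length(cols))
  x <- focus$x; y <- focus$y
  w_sigma <- psf_sigma
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    w <- exp(-((X - x)^2 + (Y - y)^2) / (2 * w_sigma^2))
    sw <- sig * w
    tot <- sum(sw)
    if (tot <= 0) break
    nx <- sum(X * sw) / tot
    ny <- sum(Y * sw) / tot
    shift <- sqrt((nx - x)^2 + (ny - y)^2)
    x <- nx; y <- ny
    if (shift < tol) { converged <- TRUE; break }
  }
  w <- exp(-((X - x)^2 + (Y - y)^2) / (2 * w_sigma^2))
  sw <- sig * w
  tot <- sum(sw)
  if (tot > 0) {
    vx <- sum((X - x)^2 * sw) / tot
    vy <- sum((Y - y)^2 * sw) / tot
    # invert the mask shrinkage: v = s^2 w^2 / (s^2 + w^2)
    unshrink <- function(v) {
      if (v >= w_sigma^2) return(sqrt(v))  # wider than mask: moments direct
      sqrt(v * w_sigma^2 / (w_sigma^2 - v))
    }
    focus$sigma_x <- unshrink(vx)
    focus$sigma_y <- unshrink(vy)
  }
  focus$x <- x; focus$y <- y
  focus$converged <- converged
  focus
}

#' Find candidate foci in one frame
#'
#' Local maxima (8-connected, on a lightly Gaussian-smoothed copy of the
#' frame; photometry uses the raw frame) are measured by [measure_focus()],
#' refined with [refine_gaussian_mask()], and returned if their SNR exceeds
#' the permissive threshold. Maxima closer than the integration radius are
#' merged, keeping the brighter. Results are sorted by intensity,
#' descending.
#'
#' @param frame numeric matrix in photons.
#' @param frame_index frame number recorded in each focus.
#' @param permissive_snr initial acceptance threshold (default 0.2).
#' @param roi optional logical matrix restricting the search.
#' @param psf_sigma PSF sigma in px for the refinement mask.
#' @param snr_mode see [measure_focus()].
#' @param refine set `FALSE` to skip sub-pixel refinement.
#' @return Focus data.frame (possibly empty).
#' @export
find_candidate_foci <- function(frame, frame_index = 1L, permissive_snr = 0.2,
                                roi = NULL, psf_sigma = 1.4,
                                snr_mode = c("per_pixel", "total"),
                                refine = TRUE) {
  snr_mode <- match.arg(snr_mode)
  sm <- gauss_smooth(frame, 1)
  mx <- local_maxima(sm, border = WINDOW_HALF)
  if (nrow(mx) == 0L) return(empty_foci())
  if (!is.null(roi)) {
    keep <- roi[mx]
    mx <- mx[keep, , drop = FALSE]
    if (nrow(mx) == 0L) return(empty_foci())
  }
  per_pixel <- snr_mode == "per_pixel"
  meas <- matrix(NA_real_, nrow(mx), 5)
  for (i in seq_len(nrow(mx))) {
    m <- measure_core(frame, mx[i, 2] - 1L, mx[i, 1] - 1L, per_pixel)
    if (!is.null(m)) meas[i, ] <- m
  }
  ok <- !is.na(meas[, 4]) & meas[, 4] > permissive_snr
  if (!any(ok)) return(empty_foci())
  foci <- data.frame(frame = frame_index, x = mx[ok, 2] - 1L,
                     y = mx[ok, 1] - 1L, intensity = meas[ok, 1],
                     bg_mean = meas[ok, 2], bg_sd = meas[ok, 3],
                     snr = meas[ok, 4], sigma_x = NA_real_,
                     sigma_y = NA_real_, n_mask_pixels = meas[ok, 5],
                     converged = NA)
  foci <- foci[order(-foci$intensity), , drop = FALSE]
  # merge maxima within the integration radius, keeping the brighter
  keep <- rep(TRUE, nrow(foci))
  for (i in seq_len(nrow(foci))) {
    if (!keep[i]) next
    if (i < nrow(foci)) {
      j <- (i + 1):nrow(foci)
      d2 <- (foci$x[j] - foci$x[i])^2 + (foci$y[j] - foci$y[i])^2
      keep[j[d2 <= FOCUS_RADIUS^2]] <- FALSE
    }
  }
  foci <- foci[keep, , drop = FALSE]
  if (refine) {
    foci <- do.call(rbind, lapply(seq_len(nrow(foci)), function(i)
      refine_gaussian_mask(frame, foci[i, ], psf_sigma = psf_sigma)))
    foci <- foci[foci$converged, , drop = FALSE]
  }
  rownames(foci) <- NULL
  foci
}

#' Detect foci in every frame of a stack
#'
#' @param stack an [image_stack()] in photons (convert counts first with
#'   [counts_to_photons()]).
#' @param ... passed to [find_candidate_foci()].
#' @return Focus data.frame over all frames.
#' @export
detect_foci <- function(stack, ...) {
  if (stack$units != "photons")
    stop("stack must be in photons; apply counts_to_photons() first")
  out <- lapply(seq_len(n_frames(stack)), function(t)
    find_candidate_foci(get_frame(stack, t), frame_index = t, ...))
  res <- do.call(rbind, out)
  if (is.null(res)) empty_foci() else res
}
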