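# Track linking and sifting.
#
# Foci in consecutive frames are linked when their centroids lie within a
# capture radius and their widths and intensities are compatible; among
# suitable candidates the nearest is chosen. Tracks are then sifted on mean
# SNR and a minimum number of consecutive foci.

#' Link per-frame foci into tracks
#'
#' Greedy nearest-suitable-neighbour linking between consecutive frames: a
#' focus in frame t+1 may extend a track ending at frame t iff the centroid
#' distance is at most `max_distance` px, the width ratio (new/old, using
#' the mean of the Gaussian semi-axes) lies in `width_ratio`, and the
#' intensity ratio (new/old) lies in `intensity_ratio`. Candidate links are
#' resolved in ascending distance order; each focus joins at most one track;
#' unlinked foci start new tracks. No gap closing: track frames are strictly
#' consecutive.
#'
#' @param foci focus data.frame (as produced by [detect_foci()]).
#' @param max_distance linking radius, px.
#' @param width_ratio,intensity_ratio acceptance bands for new/old ratios.
#' @param symmetric_ratios if `TRUE`, the bands are also applied to the
#'   old/new direction (a stricter, direction-free variant).
#' @return The foci data.frame with a `track_id` column, ordered by track
#'   then frame.
#' @export
link_foci <- function(foci, max_distance = 8,
                      width_ratio = c(0.5, 2), intensity_ratio = c(0.5, 3),
                      symmetric_ratios = FALSE) {
  if (nrow(foci) == 0L) {
    foci$track_id <- integer(0)
    return(foci)
  }
  foci <- foci[order(foci$frame, -foci$intensity), , drop = FALSE]
  rownames(foci) <- NULL
  foci$track_id <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(foci$frame))
  idx_by_frame <- split(seq_len(nrow(foci)), foci$frame)
  # start tracks in the first populated frame
  first <- idx_by_frame[[as.character(frames[1])]]
  foci$track_id[first] <- seq_along(first)
  next_id <- length(first) + 1L
  width_of <- function(i) {
    w <- (foci$sigma_x[i] + foci$sigma_y[i]) / 2
    ifelse(is.finite(w) & w > 0, w, NA_real_)
  }
  for (fi in seq_along(frames)[-1]) {
    t_prev <- frames[fi - 1]; t_cur <- frames[fi]
    cur <- idx_by_frame[[as.character(t_cur)]]
    if (t_cur != t_prev + 1) {
      foci$track_id[cur] <- next_id - 1L + seq_along(cur)
      next_id <- next_id + length(cur)
      next
    }
    prev <- idx_by_frame[[as.character(t_prev)]]
    # candidate pairs within radius
    pairs <- NULL
    for (i in prev) {
      d <- sqrt((foci$x[cur] - foci$x[i])^2 + (foci$y[cur] - foci$y[i])^2)
      ok <- d <= max_distance
      ir <- foci$intensity[cur] / foci$intensity[i]
      ok <- ok & is.finite(ir) & ir >= intensity_ratio[1] & ir <= intensity_ratio[2]
      if (symmetric_ratios)
        ok <- ok & (1 / ir) >= intensity_ratio[1] & (1 / ir) <= intensity_ratio[2]
      wr <- width_of(cur) / width_of(i)
      okw <- is.na(wr) | (wr >= width_ratio[1] & wr <= width_ratio[2] &
                          (!symmetric_ratios |
                           (1 / wr >= width_ratio[1] & 1 / wr <= width_ratio[2])))
      ok <- ok & okw
      if (any(ok))
        pairs <- rbind(pairs, cbind(i = i, j = cur[ok], d = d[ok]))
    }
    used_prev <- logical(nrow(foci)); used_cur <- logical(nrow(foci))
    if (!is.null(pairs)) {
      pairs <- pairs[order(pairs[, "d"]), , drop = FALSE]
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, "i"]; j <- pairs[r, "j"]
        if (used_prev[i] || used_cur[j]) next
        foci$track_id[j] <- foci$track_id[i]
        used_prev[i] <- TRUE; used_cur[j] <- TRUE
      }
    }
    new <- cur[is.na(foci$track_id[cur])]
    if (length(new)) {
      foci$track_id[new] <- next_id - 1L + seq_along(new)
      next_id <- next_id + length(new)
    }
  }
  foci <- foci[order(foci$track_id, foci$frame), , drop = FALSE]
  rownames(foci) <- NULL
  foci
}

#' Split linked foci into a list of per-track data.frames
#' @param linked output of [link_foci()].
#' @return Named list of focus data.frames, one per track.
#' @export
split_tracks <- function(linked) {
  if (nrow(linked) == 0L) return(list())
  split(linked, linked$track_id)
}

#' Sift tracks on SNR and length
#'
#' Retains tracks whose mean focus SNR reaches `snr_threshold` and which
#' contain at least `min_consecutive` foci (frames are consecutive by
#' construction of [link_foci()]).
#'
#' @param linked foci data.frame with `track_id`.
#' @param snr_threshold strict SNR threshold (see
#'   [determine_snr_threshold()]).
#' @param min_consecutive minimum foci per track (default 3).
#' @return Sifted foci data.frame (same columns).
#' @export
sift_tracks <- function(linked, snr_threshold, min_consecutive = 3L) {
  if (nrow(linked) == 0L) return(linked)
  stats_by <- tapply(linked$snr, linked$track_id, mean)
  len_by <- tapply(linked$snr, linked$track_id, length)
  keep_ids <- names(stats_by)[stats_by >= snr_threshold &
                              len_by >= min_consecutive]
  out <- linked[linked$track_id %in% as.integer(keep_ids), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-track summary table
#'
#' @param linked foci data.frame with `track_id`.
#' @return data.frame: track_id, n_foci, first_frame, mean_snr, mean
#'   intensity, mean position.
#' @export
track_summary <- function(linked) {
  linked <- linked[!is.na(linked$track_id), , drop = FALSE]
  if (nrow(linked) == 0L)
    return(data.frame(track_id = integer(0), n_foci = integer(0),
                      first_frame = integer(0), mean_snr = numeric(0),
                      mean_intensity = numeric(0), x = numeric(0),
                      y = numeric(0)))
  agg <- do.call(rbind, lapply(split(linked, linked$track_id), function(tr)
    data.frame(track_id = tr$track_id[1], n_foci = nrow(tr),
               first_frame = min(tr$frame), mean_snr = mean(tr$snr),
               mean_intensity = mean(tr$intensity),
               x = mean(tr$x), y = mean(tr$y))))
  rownames(agg) <- NULL
  agg
}

#' Determine the sifting SNR threshold from controls
#'
#' Scans thresholds over the observed SNR range and returns the value at
#' which retained positives and retained negatives occur at equal
#' per-acquisition frequency (linear interpolation at the crossing of the
#' two frequency curves; ties resolved toward the higher threshold). The
#' positive control contains only single molecules; the negative control
#' contains only noise, so its retained tracks estimate the false-positive
#' frequency. Fully separated controls return the flagged midpoint between
#' the negative maximum and the positive minimum.
#'
#' @param positive_snr per-track SNR values from the positive control.
#' @param negative_snr per-track SNR values from the negative control.
#' @param n_pos_acq,n_neg_acq number of acquisitions in each control, used
#'   to express the curves as tracks per acquisition.
#' @return List: `threshold`, `flagged` (TRUE when no crossing existed),
#'   `grid`, `freq_positive`, `freq_negative`.
#' @export
determine_snr_threshold <- function(positive_snr, negative_snr,
                                    n_pos_acq = 1L, n_neg_acq = 1L) {
  stopifnot(length(positive_snr) > 0, length(negative_snr) > 0)
  if (max(negative_snr) < min(positive_snr)) {
    return(list(threshold = (max(negative_snr) + min(positive_snr)) / 2,
                flagged = TRUE, grid = numeric(0),
                freq_positive = numeric(0), freq_negative = numeric(0)))
  }
  lo <- min(positive_snr, negative_snr)
  hi <- max(positive_snr, negative_snr)
  grid <- seq(lo, hi, length.out = 512)
  fp <- vapply(grid, function(th) sum(positive_snr >= th), 0) / n_pos_acq
  fn <- vapply(grid, function(th) sum(negative_snr >= th), 0) / n_neg_acq
  diffc <- fn - fp   # positive where false positives dominate
  s <- sign(diffc)
  cross <- which(s[-1] * s[-length(s)] < 0 | (s[-length(s)] != 0 & s[-1] == 0))
  if (length(cross) == 0L) {
    if (all(diffc <= 0)) {
      # negatives never dominate: effectively separated
      return(list(threshold = (max(negative_snr) + min(positive_snr)) / 2,
                  flagged = TRUE, grid = grid, freq_positive = fp,
                  freq_negative = fn))
    }
    # negatives dominate everywhere observed: take the top of the range
    return(list(threshold = hi, flagged = TRUE, grid = grid,
                freq_positive = fp, freq_negative = fn))
  }
  k <- max(cross)  # ties toward the higher threshold
  d1 <- diffc[k]; d2 <- diffc[k + 1]
  th <- if (d1 == d2) grid[k + 1] else
    grid[k] + (grid[k + 1] - grid[k]) * d1 / (d1 - d2)
  list(threshold = th, flagged = FALSE, grid = grid,
       freq_positive = fp, freq_negative = fn)
}

#' End-to-end detection, linking and sifting of a stack
#'
#' @param stack an [image_stack()]; counts are converted via `camera`.
#' @param camera a [camera_model()] (needed when the stack is in counts).
#' @param snr_threshold,min_consecutive sifting parameters.
#' @param ... passed to [detect_foci()].
#' @return Sifted foci data.frame with `track_id`.
#' @export
track_stack <- function(stack, camera = camera_model(),
                        snr_threshold = 0.4, min_consecutive = 3L, ...) {
  if (stack$units == "counts") stack <- counts_to_photons(stack, camera)
  foci <- detect_foci(stack, ...)
  linked <- link_foci(foci)
  sift_tracks(linked, snr_threshold, min_consecutive)
}
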