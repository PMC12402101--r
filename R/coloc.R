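# Two-colour colocalisation: channel registration from bead images,
# reference-locus candidate selection, track-pair overlap scoring, residence
# times, and the random-coincidence expectation.

#' Least-squares affine channel registration
#'
#' Fits the affine transform mapping moving-channel coordinates onto the
#' reference channel from >= 3 matched (non-collinear) point pairs, e.g.
#' sub-pixel localisations of multicolour beads detected in both channels.
#'
#' @param ref 2-column matrix (x, y) of reference-channel positions.
#' @param mov matching positions in the moving channel.
#' @return List of class `affine_transform`: `A` (2x2), `t` (length-2
#'   offset), `rmse` (residual, px).
#' @export
register_channels <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  stopifnot(ncol(ref) == 2, ncol(mov) == 2, nrow(ref) == nrow(mov))
  if (nrow(ref) < 3) stop("need at least 3 matched point pairs")
  X <- cbind(mov, 1)
  if (qr(X)$rank < 3) stop("bead positions are collinear")
  beta <- qr.solve(X, ref)           # 3 x 2
  fitted <- X %*% beta
  rmse <- sqrt(mean(rowSums((ref - fitted)^2)))
  structure(list(A = t(beta[1:2, ]), t = as.numeric(beta[3, ]), rmse = rmse),
            class = "affine_transform")
}

#' Apply an affine transform to (x, y) positions
#' @param transform an `affine_transform` from [register_channels()].
#' @param xy 2-column matrix or data.frame of positions.
#' @return Transformed 2-column matrix.
#' @export
apply_transform <- function(transform, xy) {
  xy <- as.matrix(xy)
  sweep(xy %*% t(transform$A), 2, -transform$t)
}

#' Select reference-locus candidate tracks
#'
#' Keeps slow, bright tracks: diffusivity at most `D_max` and stoichiometry
#' above `S_min`, then the `k_brightest` highest initial intensities (all if
#' fewer). Used to pick locus-tethered reporter tracks from a background of
#' freely diffusing label.
#'
#' @param summary data.frame with columns `track_id`, `D`, `S`, `I0`.
#' @param D_max maximum diffusivity, um^2/s.
#' @param S_min minimum stoichiometry (exclusive), molecules.
#' @param k_brightest tracks retained per nucleus (default 8).
#' @return Filtered, intensity-sorted subset of `summary`.
#' @export
select_locus_candidates <- function(summary, D_max = 0.20, S_min = 12,
                                    k_brightest = 8L) {
  keep <- summary[summary$D <= D_max & summary$S > S_min, , drop = FALSE]
  keep <- keep[order(-keep$I0), , drop = FALSE]
  out <- utils::head(keep, k_brightest)
  rownames(out) <- NULL
  out
}

#' Gaussian intensity overlap of two foci
#'
#' Normalised cross-correlation of the two fitted elliptical Gaussian
#' profiles at their measured separation (1 at zero separation). For
#' circular spots this reduces to `exp(-d^2 / (2 (s1^2 + s2^2)))`, which
#' makes a 50% overlap correspond to a lateral distance of about 3 px at
#' typical widths of ~1.6 px.
#'
#' @param dx,dy separation, px.
#' @param sx1,sy1,sx2,sy2 Gaussian semi-axes of the two foci, px.
#' @return Overlap fraction in (0, 1].
#' @export
gaussian_overlap <- function(dx, dy, sx1, sy1, sx2, sy2) {
  exp(-dx^2 / (2 * (sx1^2 + sx2^2)) - dy^2 / (2 * (sy1^2 + sy2^2)))
}

#' Colocalise two sets of tracks
#'
#' For each pair of tracks (one per channel, positions already registered to
#' a common frame), frames are matched by index (for alternating excitation
#' pass foci with the original acquisition frame indices: each channel-A
#' frame is compared with the nearest channel-B frame via
#' `frame_tolerance = 1`). A pair is colocalised over every maximal run of
#' at least `min_frames` matched frames in which the Gaussian intensity
#' overlap is at least `overlap_threshold` and the centroid distance at most
#' `max_distance` px. Residence time is the run length times
#' `frame_interval`.
#'
#' @param tracks_a,tracks_b foci data.frames with `track_id` (channel B
#'   already transformed onto channel A).
#' @param overlap_threshold minimum overlap fraction (default 0.5).
#' @param max_distance maximum centroid distance, px (default 7).
#' @param min_frames minimum consecutive colocalised frames (default 3).
#' @param frame_interval per-channel frame interval, ms (for residence
#'   times).
#' @param frame_tolerance frame-index difference treated as simultaneous
#'   (default 1, suiting alternating excitation).
#' @return data.frame of events: `track_a`, `track_b`, `start_frame`,
#'   `end_frame`, `n_frames`, `mean_overlap`, `residence_ms`.
#' @export
colocalise <- function(tracks_a, tracks_b, overlap_threshold = 0.5,
                       max_distance = 7, min_frames = 3L,
                       frame_interval = 20, frame_tolerance = 1L) {
  empty <- data.frame(track_a = integer(0), track_b = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      n_frames = integer(0), mean_overlap = numeric(0),
                      residence_ms = numeric(0))
  if (nrow(tracks_a) == 0L || nrow(tracks_b) == 0L) return(empty)
  la <- split_tracks(tracks_a); lb <- split_tracks(tracks_b)
  events <- list()
  for (ta in la) for (tb in lb) {
    # match each A-focus with the nearest B-focus in time
    j <- vapply(ta$frame, function(f) {
      d <- abs(tb$frame - f)
      if (min(d) <= frame_tolerance) which.min(d) else NA_integer_
    }, 1L)
    ok <- !is.na(j)
    if (sum(ok) < min_frames) next
    dx <- ta$x - tb$x[j]; dy <- ta$y - tb$y[j]
    sx1 <- ifelse(is.finite(ta$sigma_x), ta$sigma_x, 1.6)
    sy1 <- ifelse(is.finite(ta$sigma_y), ta$sigma_y, 1.6)
    sx2 <- ifelse(is.finite(tb$sigma_x[j]), tb$sigma_x[j], 1.6)
    sy2 <- ifelse(is.finite(tb$sigma_y[j]), tb$sigma_y[j], 1.6)
    ov <- gaussian_overlap(dx, dy, sx1, sy1, sx2, sy2)
    good <- ok & ov >= overlap_threshold & sqrt(dx^2 + dy^2) <= max_distance
    # maximal runs of consecutive matched frames satisfying the condition
    r <- rle(as.vector(good))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] < min_frames) next
      span <- starts[k]:ends[k]
      events[[length(events) + 1]] <- data.frame(
        track_a = ta$track_id[1], track_b = tb$track_id[1],
        start_frame = ta$frame[span[1]],
        end_frame = ta$frame[span[length(span)]],
        n_frames = length(span),
        mean_overlap = mean(ov[span]),
        residence_ms = length(span) * frame_interval)
    }
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Random-coincidence probability under Poisson point statistics
#'
#' Probability that a random point has a neighbour of a homogeneous Poisson
#' process of density `lambda` within radius `r`:
#' `P = 1 - exp(-lambda pi r^2)`. The expected chance-colocalisation rate
#' for uniformly distributed tracks.
#'
#' @param lambda track number density, per um^2 (>= 0).
#' @param r coincidence radius, um (> 0).
#' @return Probability.
#' @export
random_coincidence_probability <- function(lambda, r) {
  stopifnot(all(lambda >= 0), all(r > 0))
  1 - exp(-lambda * pi * r^2)
}

#' Augment a channel with a prescan best frame
#'
#' Builds a static copy of the channel in which every frame is the prescan
#' image `I_star` (the z-stack frame with the brightest reference foci),
#' tracks it, and appends the resulting static tracks to the live track
#' list, deduplicating against live tracks whose mean position lies within
#' `dedup_radius` px. Recovers reference loci that photobleached before the
#' alternating acquisition began.
#'
#' @param live_tracks foci data.frame with `track_id` from the live channel.
#' @param I_star prescan frame, matrix in photons (same size as the channel
#'   frames).
#' @param n_frames frames in the static copy (match the live acquisition).
#' @param dedup_radius px (default 1).
#' @param ... passed to [track_stack()] (snr_threshold etc.).
#' @return Combined foci data.frame with re-numbered `track_id`.
#' @export
augment_with_prescan <- function(live_tracks, I_star, n_frames = 10L,
                                 dedup_radius = 1, ...) {
  stopifnot(is.matrix(I_star))
  frames <- array(rep(I_star, n_frames),
                  dim = c(nrow(I_star), ncol(I_star), n_frames))
  static_stack <- image_stack(frames, pixel_size = 53, frame_interval = 20,
                              units = "photons")
  static <- track_stack(static_stack, ...)
  if (nrow(static) == 0L) return(live_tracks)
  live_sum <- track_summary(live_tracks)
  stat_sum <- track_summary(static)
  keep_ids <- stat_sum$track_id
  if (nrow(live_sum) > 0) {
    dup <- vapply(seq_len(nrow(stat_sum)), function(i)
      any(sqrt((live_sum$x - stat_sum$x[i])^2 +
               (live_sum$y - stat_sum$y[i])^2) < dedup_radius), logical(1))
    keep_ids <- stat_sum$track_id[!dup]
  }
  static <- static[static$track_id %in% keep_ids, , drop = FALSE]
  if (nrow(static) == 0L) return(live_tracks)
  offset <- if (nrow(live_tracks)) max(live_tracks$track_id) else 0L
  static$track_id <- static$track_id + offset
  out <- rbind(live_tracks, static)
  rownames(out) <- NULL
  out
}

#' Contingency table of colocalisation against partner stoichiometry
#'
#' Tallies reference-locus candidate tracks by whether they were colocalised
#' and whether their partner assembly's stoichiometry exceeds `S_threshold`,
#' ready for [fisher_exact()]. Non-colocalised candidates have no partner
#' and count in the below-threshold column.
#'
#' @param events event data.frame from [colocalise()].
#' @param candidates data.frame of locus candidates with `track_id`.
#' @param partner_S named numeric: stoichiometry of each channel-B track,
#'   names = track ids.
#' @param S_threshold molecules (default 6).
#' @return 2x2 integer matrix (colocalised x above-threshold).
#' @export
partition_by_stoichiometry <- function(events, candidates, partner_S,
                                       S_threshold = 6) {
  coloc_ids <- unique(events$track_a)
  above <- vapply(candidates$track_id, function(id) {
    ev <- events[events$track_a == id, , drop = FALSE]
    if (nrow(ev) == 0L) return(FALSE)
    any(partner_S[as.character(ev$track_b)] > S_threshold, na.rm = TRUE)
  }, logical(1))
  is_coloc <- candidates$track_id %in% coloc_ids
  table(factor(is_coloc, levels = c(TRUE, FALSE),
               labels = c("colocalised", "not")),
        factor(above, levels = c(TRUE, FALSE),
               labels = c("above", "below")))
}
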