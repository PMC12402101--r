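# Nucleus-level quantification: integrated nuclear intensity in molecular
# equivalents, autofluorescence-corrected total protein number, nucleoplasmic
# concentration and track density.

AVOGADRO <- 6.02214076e23

#' Integrated nuclear intensity in molecular equivalents
#'
#' Sums the offset-corrected, gain-converted pixel photons over the nuclear
#' mask in the first fluorescence frame of the channel (pre-bleach) and
#' divides by the characteristic molecular brightness B. Optionally averages
#' the first `k_frames` frames with exponential bleach back-correction to
#' frame 1 when the photobleach constant `tau_frames` is supplied.
#'
#' @param stack an [image_stack()] (counts or photons).
#' @param mask logical matrix (nucleus segment), same frame size.
#' @param B characteristic molecular brightness, photons/frame.
#' @param camera a [camera_model()], used when the stack is in counts.
#' @param k_frames frames to average (default 1: first frame only).
#' @param tau_frames photobleach constant for back-correction when
#'   `k_frames > 1`.
#' @return Integrated intensity, molecular equivalents (dimensionless).
#' @export
integrated_nuclear_intensity <- function(stack, mask, B,
                                         camera = camera_model(),
                                         k_frames = 1L, tau_frames = NULL) {
  stopifnot(B > 0)
  d <- dim(stack$frames)
  if (!all(dim(mask) == d[1:2])) stop("mask does not match the frame size")
  if (stack$units == "counts") stack <- counts_to_photons(stack, camera)
  k <- min(k_frames, n_frames(stack))
  if (k > 1 && is.null(tau_frames))
    stop("tau_frames is required to back-correct a multi-frame average")
  vals <- vapply(seq_len(k), function(t) {
    s <- sum(get_frame(stack, t)[mask])
    if (k > 1) s * exp((t - 1) / tau_frames) else s
  }, 0)
  mean(vals) / B
}

#' Autofluorescence-corrected total protein number
#'
#' The mean integrated nuclear intensity of the unlabelled control estimates
#' the autofluorescence contribution; it is scaled by the ratio of mean
#' segment areas before subtraction:
#' `N = mean(labelled) - mean(control) * mean(area_labelled) / mean(area_control)`.
#' The standard error propagates the two s.e.m.s.
#'
#' @param labelled numeric vector of labelled-nucleus molecular equivalents.
#' @param control numeric vector of unlabelled-control equivalents.
#' @param area_labelled,area_control matching nuclear segment areas (any
#'   common unit); defaults assume equal areas.
#' @return List: `N`, `se`, `n_labelled`, `n_control`, `area_factor`.
#' @export
total_protein_number <- function(labelled, control,
                                 area_labelled = NULL, area_control = NULL) {
  stopifnot(length(labelled) > 0, length(control) > 0)
  f <- if (!is.null(area_labelled) && !is.null(area_control))
    mean(area_labelled) / mean(area_control) else 1
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  N <- mean(labelled) - mean(control) * f
  se <- sqrt(sem(labelled)^2 + (f * sem(control))^2)
  list(N = N, se = se, n_labelled = length(labelled),
       n_control = length(control), area_factor = f)
}

#' Correct a labelled-only copy number for the unlabelled fraction
#'
#' When only a fraction of the protein pool carries the fluorescent label
#' (e.g. one labelled and one unlabelled allele expressing equally gives
#' fraction 0.5), the total is the labelled estimate divided by that
#' fraction.
#'
#' @param N_labelled labelled-molecule count (or relative level).
#' @param labelled_fraction fraction of the pool that is labelled, in
#'   (0, 1].
#' @return Corrected total.
#' @export
copy_number_correction <- function(N_labelled, labelled_fraction) {
  if (labelled_fraction <= 0 || labelled_fraction > 1)
    stop("labelled_fraction must lie in (0, 1]")
  N_labelled / labelled_fraction
}

#' Nucleoplasmic concentration from a protein number
#'
#' Divides the total protein number by the nuclear volume — a prolate
#' spheroid with the in-plane major semi-axis `a` as the unique long axis
#' and the minor semi-axis `b` for both short axes, `V = (4/3) pi a b^2` —
#' and by Avogadro's number, returning molar concentration.
#'
#' @param N number of molecules (>= 0).
#' @param segment a `nuclear_segment` from [segment_ellipse()], or `NULL`
#'   when `a` and `b` are given directly.
#' @param a,b semi-axes, um (used when `segment` is NULL).
#' @return Concentration, mol/L.
#' @export
nuclear_concentration <- function(N, segment = NULL, a = NULL, b = NULL) {
  stopifnot(N >= 0)
  if (!is.null(segment)) { a <- segment$a; b <- segment$b }
  if (is.null(a) || is.null(b) || a <= 0 || b <= 0)
    stop("degenerate nuclear axes")
  V_um3 <- (4 / 3) * pi * a * b^2
  V_L <- V_um3 * 1e-15
  N / (AVOGADRO * V_L)
}

#' Track count and density within a nuclear segment
#'
#' Counts sifted tracks whose first focus lies inside the mask and divides
#' by the mask area in um^2.
#'
#' @param linked sifted foci data.frame with `track_id`.
#' @param segment a `nuclear_segment` from [segment_ellipse()].
#' @return List: `count`, `density` (per um^2).
#' @export
track_density <- function(linked, segment) {
  stopifnot(inherits(segment, "nuclear_segment"), segment$area_um2 > 0)
  if (nrow(linked) == 0L) return(list(count = 0L, density = 0))
  firsts <- do.call(rbind, lapply(split_tracks(linked), function(tr)
    tr[which.min(tr$frame), c("x", "y")]))
  inside <- vapply(seq_len(nrow(firsts)), function(i) {
    r <- round(firsts$y[i]) + 1L; c <- round(firsts$x[i]) + 1L
    r >= 1 && r <= nrow(segment$mask) && c >= 1 && c <= ncol(segment$mask) &&
      segment$mask[r, c]
  }, logical(1))
  n <- sum(inside)
  list(count = n, density = n / segment$area_um2)
}
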