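#' Image stack container
#'
#' A time-ordered sequence of 2D frames with acquisition metadata. Frames are
#' stored as a numeric array with dimensions `[row, col, frame]`. User-facing
#' coordinates are 0-based with `(x, y) = (column, row)` and pixel centres at
#' integer positions, so the top-left pixel centre is (0, 0).
#'
#' @param frames numeric 3D array `[row, col, frame]`, or a list of equal-size
#'   matrices.
#' @param pixel_size pixel width, nm.
#' @param frame_interval time between frame starts, ms.
#' @param exposure_time exposure per frame, ms (<= frame_interval).
#' @param channel_pattern character vector of channel labels cycled over
#'   frames (e.g. `c("yellow", "red")` for alternating excitation); its
#'   length must divide the frame count.
#' @param units `"counts"` or `"photons"`.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval,
                        exposure_time = frame_interval,
                        channel_pattern = "0", units = "photons") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("inconsistent frame shapes")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            is.numeric(pixel_size), pixel_size > 0,
            frame_interval > 0, exposure_time > 0,
            frame_interval >= exposure_time)
  units <- match.arg(units, c("photons", "counts"))
  n <- dim(frames)[3]
  if (n %% length(channel_pattern) != 0L)
    stop("channel_pattern length must divide the frame count")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 exposure_time = exposure_time,
                 channel_pattern = as.character(channel_pattern),
                 units = units),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frame(s) of %d x %d px [%s], %g nm/px, %g ms/frame, channels {%s}\n",
              d[3], d[1], d[2], x$units, x$pixel_size, x$frame_interval,
              paste(unique(x$channel_pattern), collapse = ", ")))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

#' Extract one frame as a matrix
#' @param stack an [image_stack()].
#' @param i frame index (1-based).
#' @return Numeric matrix `[row, col]`.
#' @export
get_frame <- function(stack, i) {
  stopifnot(i >= 1, i <= n_frames(stack))
  stack$frames[, , i]
}

#' Channel labels per frame
#' @param stack an [image_stack()].
#' @return Character vector, one label per frame.
#' @export
frame_channels <- function(stack) {
  rep(stack$channel_pattern, length.out = n_frames(stack))
}

#' Split an interleaved stack into per-channel stacks
#'
#' With alternating excitation the effective frame interval of each channel
#' is the camera interval times the number of channels.
#'
#' @param stack an [image_stack()].
#' @return Named list of single-channel `image_stack` objects.
#' @export
split_channels <- function(stack) {
  ch <- frame_channels(stack)
  k <- length(unique(stack$channel_pattern))
  lapply(stats::setNames(nm = unique(stack$channel_pattern)), function(lab) {
    image_stack(stack$frames[, , ch == lab, drop = FALSE],
                pixel_size = stack$pixel_size,
                frame_interval = stack$frame_interval * k,
                exposure_time = stack$exposure_time,
                channel_pattern = lab, units = stack$units)
  })
}

#' Read an image stack from a multi-page TIFF
#'
#' Pixel values are restored to their stored integer counts (the TIFF reader
#' normalises to \[0, 1\]). Required acquisition metadata (pixel size, frame
#' interval) is not carried by plain TIFF tags and must be supplied.
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval,exposure_time,channel_pattern,units
#'   acquisition metadata; see [image_stack()]. `pixel_size` and
#'   `frame_interval` are required.
#' @param bits_per_sample integer scale used when the file was written
#'   (default 16).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       exposure_time = NULL, channel_pattern = "0",
                       units = "counts", bits_per_sample = 16) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  if (is.null(pixel_size)) stop("pixel_size metadata is required")
  if (is.null(frame_interval)) stop("frame_interval metadata is required")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop("inconsistent frame shapes in '", path, "'")
  image_stack(pages, pixel_size = pixel_size,
              frame_interval = frame_interval,
              exposure_time = if (is.null(exposure_time)) frame_interval
                              else exposure_time,
              channel_pattern = channel_pattern, units = units)
}

#' Write an image stack to a multi-page TIFF
#'
#' Values are rounded to integers and stored at the camera bit depth;
#' integer counts round-trip exactly through [read_stack()].
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 16) {
  top <- 2^bits_per_sample - 1
  pages <- lapply(seq_len(n_frames(stack)), function(i) {
    m <- round(get_frame(stack, i))
    pmin(pmax(m, 0), top) / top
  })
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write '", path, "'")
  invisible(path)
}

#' Read a binary nucleus mask image
#'
#' Accepts 8-bit PNG or TIFF; any non-zero pixel is inside the mask.
#'
#' @param path image file path.
#' @return Logical matrix `[row, col]`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}

#' Fit an ellipse to a nuclear mask
#'
#' Moment-based ellipse fit: semi-axes are derived from the eigenvalues of
#' the second central moment matrix of the mask pixels (for a filled ellipse
#' the eigenvalues equal a^2/4 and b^2/4). Used for the prolate-spheroid
#' nuclear volume model, with the in-plane major axis as the unique long
#' axis.
#'
#' @param mask logical or 0/1 matrix.
#' @param pixel_size pixel width, nm.
#' @param label segment identifier.
#' @return A `nuclear_segment`: list with `mask`, `area` (pixels),
#'   `a`, `b` (semi-axes, um, `a >= b`), `area_um2`, `label`.
#' @export
segment_ellipse <- function(mask, pixel_size, label = "segment") {
  mask <- mask > 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  if (nrow(idx) < 3L) stop("degenerate mask: fewer than 3 pixels")
  xy <- cbind(idx[, 2], idx[, 1])  # x = col, y = row
  ctr <- colMeans(xy)
  d <- sweep(xy, 2, ctr)
  cov2 <- crossprod(d) / nrow(d)
  ev <- eigen(cov2, symmetric = TRUE)$values
  if (min(ev) <= 0) stop("degenerate mask: collinear pixels")
  ax_px <- 2 * sqrt(ev)            # semi-axes in px, decreasing
  um <- pixel_size / 1000
  structure(list(mask = mask, area = nrow(idx),
                 area_um2 = nrow(idx) * um^2,
                 a = ax_px[1] * um, b = ax_px[2] * um,
                 pixel_size = pixel_size, label = label),
            class = "nuclear_segment")
}

#' @export
print.nuclear_segment <- function(x, ...) {
  cat(sprintf("nuclear_segment '%s': %d px (%.2f um^2), semi-axes %.2f x %.2f um\n",
              x$label, x$area, x$area_um2, x$a, x$b))
  invisible(x)
}
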