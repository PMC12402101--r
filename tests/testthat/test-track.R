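test_that("a steadily moving focus links into one track", {
  foci <- do.call(rbind, lapply(1:10, function(t)
    mk_focus(t, 10 + 2 * t, 20, intensity = 100)))
  linked <- link_foci(foci)
  expect_equal(length(unique(linked$track_id)), 1)
  expect_equal(linked$frame, 1:10)
})

test_that("the 8-pixel capture radius is a hard limit", {
  near <- link_foci(rbind(mk_focus(1, 10, 10), mk_focus(2, 17.9, 10)))
  expect_equal(length(unique(near$track_id)), 1)
  far <- link_foci(rbind(mk_focus(1, 10, 10), mk_focus(2, 19.1, 10)))
  expect_equal(length(unique(far$track_id)), 2)
})

test_that("width and intensity ratio gates block incompatible links", {
  # intensity ratio must lie in [0.5, 3]
  dim_ <- link_foci(rbind(mk_focus(1, 10, 10, intensity = 100),
                          mk_focus(2, 11, 10, intensity = 40)))
  expect_equal(length(unique(dim_$track_id)), 2)
  bright <- link_foci(rbind(mk_focus(1, 10, 10, intensity = 100),
                            mk_focus(2, 11, 10, intensity = 250)))
  expect_equal(length(unique(bright$track_id)), 1)
  too_bright <- link_foci(rbind(mk_focus(1, 10, 10, intensity = 100),
                                mk_focus(2, 11, 10, intensity = 400)))
  expect_equal(length(unique(too_bright$track_id)), 2)
  # width ratio must lie in [0.5, 2]
  wide <- link_foci(rbind(mk_focus(1, 10, 10, sigma_x = 1, sigma_y = 1),
                          mk_focus(2, 11, 10, sigma_x = 3, sigma_y = 3)))
  expect_equal(length(unique(wide$track_id)), 2)
})

test_that("nearest suitable neighbour wins when several links are possible", {
  foci <- rbind(mk_focus(1, 10, 10),
                mk_focus(2, 12, 10),   # 2 px away
                mk_focus(2, 15, 10))   # 5 px away
  linked <- link_foci(foci)
  t1 <- linked$track_id[linked$frame == 1]
  expect_equal(linked$track_id[linked$frame == 2 & linked$x == 12], t1)
  expect_false(linked$track_id[linked$frame == 2 & linked$x == 15] == t1)
})

test_that("crossing particles follow a global nearest-neighbour oracle", {
  set.seed(20)
  agree <- replicate(20, {
    n <- 15
    # two particles crossing with jitter, separation > 4 px except briefly
    xa <- seq(10, 40, length.out = n) + stats::rnorm(n, 0, 0.3)
    xb <- seq(40, 10, length.out = n) + stats::rnorm(n, 0, 0.3)
    ya <- rep(20, n); yb <- rep(26, n)   # 6 px apart in y
    foci <- rbind(
      do.call(rbind, lapply(1:n, function(t) mk_focus(t, xa[t], ya[t]))),
      do.call(rbind, lapply(1:n, function(t) mk_focus(t, xb[t], yb[t]))))
    linked <- link_foci(foci)
    # oracle: per frame-pair, optimal assignment by brute force (2 particles)
    ok <- vapply(2:n, function(t) {
      prev <- linked[linked$frame == t - 1, ]
      cur <- linked[linked$frame == t, ]
      d11 <- sqrt((prev$x[1] - cur$x[1])^2 + (prev$y[1] - cur$y[1])^2)
      d22 <- sqrt((prev$x[2] - cur$x[2])^2 + (prev$y[2] - cur$y[2])^2)
      d12 <- sqrt((prev$x[1] - cur$x[2])^2 + (prev$y[1] - cur$y[2])^2)
      d21 <- sqrt((prev$x[2] - cur$x[1])^2 + (prev$y[2] - cur$y[1])^2)
      straight <- d11 + d22 <= d12 + d21
      if (straight)
        prev$track_id[1] == cur$track_id[1] && prev$track_id[2] == cur$track_id[2]
      else
        prev$track_id[1] == cur$track_id[2] && prev$track_id[2] == cur$track_id[1]
    }, logical(1))
    mean(ok)
  })
  expect_gte(mean(agree), 0.9)
})

test_that("sifting enforces minimum length and mean SNR, never adds tracks", {
  short <- mk_track(c(100, 95), frames = 1:2, track_id = 1L)
  long_lo <- mk_track(rep(100, 5), track_id = 2L)
  long_lo$snr <- 0.2
  long_hi <- mk_track(rep(100, 5), track_id = 3L)
  long_hi$snr <- 0.6
  all3 <- rbind(short, long_lo, long_hi)
  sifted <- sift_tracks(all3, snr_threshold = 0.4)
  expect_equal(unique(sifted$track_id), 3L)
  expect_equal(nrow(sift_tracks(all3[0, ], 0.4)), 0)
  for (th in c(0.1, 0.4, 0.7))
    expect_lte(length(unique(sift_tracks(all3, th)$track_id)),
               length(unique(all3$track_id)))
})

test_that("threshold determination finds the control crossing", {
  # fully separated controls: flagged midpoint
  sep <- determine_snr_threshold(positive_snr = c(1, 1.2, 1.4),
                                 negative_snr = c(0.1, 0.2))
  expect_true(sep$flagged)
  expect_equal(sep$threshold, (0.2 + 1) / 2)

  # overlapping controls: matches a brute-force scan of the two curves
  set.seed(21)
  pos <- stats::rnorm(400, 0.8, 0.25)
  neg <- stats::rnorm(2000, 0.25, 0.12)   # many dim false positives
  r <- determine_snr_threshold(pos, neg, n_pos_acq = 4, n_neg_acq = 4)
  expect_false(r$flagged)
  # oracle: exhaustive scan over a fine grid for the equal-frequency point
  grid <- seq(min(c(pos, neg)), max(c(pos, neg)), length.out = 20000)
  gap <- vapply(grid, function(th) sum(neg >= th) / 4 - sum(pos >= th) / 4, 0)
  cross <- grid[max(which(gap > 0))]
  expect_equal(r$threshold, cross, tolerance = 0.01)
  # frequencies are (nearly) equal at the returned threshold
  f_pos <- sum(pos >= r$threshold) / 4
  f_neg <- sum(neg >= r$threshold) / 4
  expect_lt(abs(f_pos - f_neg), 2)
})

test_that("linking is deterministic under within-frame reordering", {
  set.seed(22)
  foci <- do.call(rbind, lapply(1:6, function(t)
    rbind(mk_focus(t, 10 + t, 10), mk_focus(t, 30 - t, 35),
          mk_focus(t, 20, 20 + t))))
  a <- link_foci(foci)
  b <- link_foci(foci[sample(nrow(foci)), ])
  key <- function(d) d[order(d$frame, d$x, d$y), c("frame", "x", "y", "track_id")]
  ka <- key(a); kb <- key(b)
  # same partition of foci into tracks (ids may be permuted)
  expect_equal(ka[, 1:3], kb[, 1:3], ignore_attr = TRUE)
  expect_equal(length(unique(ka$track_id)), length(unique(kb$track_id)))
  grp <- function(k) unname(split(seq_len(nrow(k)), k$track_id))
  expect_setequal(sapply(grp(ka), paste, collapse = ","),
                  sapply(grp(kb), paste, collapse = ","))
})
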