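test_that("affine registration recovers identity and known transforms", {
  set.seed(70)
  pts <- cbind(stats::runif(12, 0, 100), stats::runif(12, 0, 100))
  ident <- register_channels(pts, pts)
  expect_equal(ident$A, diag(2), tolerance = 1e-9)
  expect_equal(ident$t, c(0, 0), tolerance = 1e-9)
  expect_lt(ident$rmse, 1e-9)

  # known shift + scale + rotation
  th <- 0.05; s <- 1.01
  A <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mov <- t(solve(A) %*% (t(pts) - c(3.2, -1.7)))
  tf <- register_channels(pts, mov)
  expect_lt(tf$rmse, 0.05)
  expect_equal(apply_transform(tf, mov), pts, tolerance = 1e-6)

  # noisy beads: residual reflects the noise level
  noisy <- mov + matrix(stats::rnorm(24, 0, 0.1), ncol = 2)
  tfn <- register_channels(pts, noisy)
  expect_equal(tfn$rmse, 0.1, tolerance = 0.6)

  expect_error(register_channels(pts[1:2, ], pts[1:2, ]), "3 matched")
  line <- cbind(1:5, 2 * (1:5) + 1)
  expect_error(register_channels(line, line), "collinear")
})

test_that("locus candidate selection filters and ranks like the oracle", {
  set.seed(71)
  n <- 40
  summ <- data.frame(track_id = 1:n, D = stats::runif(n, 0, 0.5),
                     S = stats::runif(n, 1, 30),
                     I0 = stats::runif(n, 100, 3000))
  sel <- select_locus_candidates(summ, D_max = 0.20, S_min = 12,
                                 k_brightest = 8)
  oracle <- summ[summ$D <= 0.20 & summ$S > 12, ]
  oracle <- head(oracle[order(-oracle$I0), ], 8)
  expect_equal(sel$track_id, oracle$track_id)
  expect_lte(nrow(sel), 8)
  # more than 8 qualifying: exactly the 8 brightest
  summ$D <- 0.1; summ$S <- 20
  sel2 <- select_locus_candidates(summ)
  expect_equal(nrow(sel2), 8)
  expect_equal(sel2$I0, sort(summ$I0, decreasing = TRUE)[1:8])
  # none qualifying: empty
  expect_equal(nrow(select_locus_candidates(summ, D_max = -1)), 0)
})

test_that("gaussian overlap makes 50% correspond to ~3 px at sigma 1.6", {
  d50 <- sqrt(2 * (1.6^2 + 1.6^2) * log(2))
  expect_equal(gaussian_overlap(d50, 0, 1.6, 1.6, 1.6, 1.6), 0.5)
  expect_equal(d50, 2.66, tolerance = 0.15)   # "~3 pixels"
  expect_equal(gaussian_overlap(0, 0, 1.6, 1.6, 1.6, 1.6), 1)
})

test_that("coincident tracks colocalise fully; short coincidences do not", {
  a <- mk_track(rep(100, 8), x = 20, y = 20, track_id = 1L)
  b <- mk_track(rep(100, 8), x = 20, y = 20, track_id = 1L)
  ev <- colocalise(a, b, frame_interval = 20)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_frames, 8)
  expect_equal(ev$mean_overlap, 1)
  expect_equal(ev$residence_ms, 8 * 20)

  # a 2-frame coincidence is below the >= 3 frame requirement
  b2 <- mk_track(rep(100, 8), x = 20, y = 20, track_id = 1L)
  b2$x[3:8] <- 40   # only frames 1-2 coincide
  ev2 <- colocalise(a, b2, frame_interval = 20)
  expect_equal(nrow(ev2), 0)

  # drifting beyond 7 px breaks the event even at high overlap threshold 0
  b3 <- mk_track(rep(100, 8), x = 20, y = 20, track_id = 1L)
  b3$x <- 20 + c(0, 0, 0, 10, 10, 10, 10, 10)
  ev3 <- colocalise(a, b3, overlap_threshold = 0, frame_interval = 20)
  expect_equal(ev3$n_frames, 3)
})

test_that("colocalisation is symmetric in the two channels", {
  set.seed(72)
  a <- brownian_track(12, 0.05, track_id = 1L)
  b <- a; b$x <- b$x + 0.5
  ab <- colocalise(a, b, frame_interval = 20)
  ba <- colocalise(b, a, frame_interval = 20)
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(ab$n_frames, ba$n_frames)
  expect_equal(ab$mean_overlap, ba$mean_overlap)
})

test_that("random track seeding matches the Poisson coincidence model", {
  expect_equal(random_coincidence_probability(0, 1), 0)
  lam <- 0.02; r <- 0.8
  expect_equal(random_coincidence_probability(lam, r), lam * pi * r^2,
               tolerance = 0.05)  # first-order series limit
  # Monte-Carlo oracle: uniform points, nearest-neighbour within r
  set.seed(73)
  side <- 60; lam2 <- 0.5; r2 <- 0.35
  n_rep <- 200
  hits <- vapply(1:n_rep, function(i) {
    n <- stats::rpois(1, lam2 * side^2)
    px <- stats::runif(n, 0, side); py <- stats::runif(n, 0, side)
    q <- c(stats::runif(1, r2, side - r2), stats::runif(1, r2, side - r2))
    any((px - q[1])^2 + (py - q[2])^2 <= r2^2)
  }, logical(1))
  p_hat <- mean(hits)
  p_th <- random_coincidence_probability(lam2, r2)
  expect_lt(abs(p_hat - p_th), 3 * sqrt(p_th * (1 - p_th) / n_rep))
})

test_that("prescan augmentation adds static tracks and deduplicates", {
  blank <- matrix(0, 48, 48)
  live <- mk_track(rep(500, 5), x = 12, y = 12, track_id = 1L)
  expect_identical(augment_with_prescan(live, blank, snr_threshold = 0.3),
                   live)
  istar <- spot_frame(48, background = 1,
                      spots = data.frame(x = 30, y = 25, total = 2000,
                                         sigma = 1.5))
  aug <- augment_with_prescan(live, istar, n_frames = 6, snr_threshold = 0.3)
  expect_equal(length(unique(aug$track_id)), 2)
  added <- aug[aug$track_id != 1L, ]
  expect_lt(abs(mean(added$x) - 30), 0.5)
  # a prescan spot duplicating the live track is removed
  istar2 <- spot_frame(48, background = 1,
                       spots = data.frame(x = 12, y = 12, total = 2000,
                                          sigma = 1.5))
  aug2 <- augment_with_prescan(live, istar2, n_frames = 6,
                               snr_threshold = 0.3)
  expect_equal(length(unique(aug2$track_id)), 1)
})

test_that("stoichiometry partition builds the expected contingency table", {
  ev <- data.frame(track_a = c(1, 2), track_b = c(10, 11),
                   start_frame = 1, end_frame = 4, n_frames = 4,
                   mean_overlap = 0.9, residence_ms = 80)
  cand <- data.frame(track_id = 1:4)
  pS <- c("10" = 9, "11" = 3)
  tab <- partition_by_stoichiometry(ev, cand, pS, S_threshold = 6)
  expect_equal(as.vector(tab), c(1, 0, 1, 2))  # hand-tallied
  # all colocalised above threshold: off-diagonal zeros
  pS2 <- c("10" = 9, "11" = 8)
  tab2 <- partition_by_stoichiometry(ev, cand[1:2, , drop = FALSE], pS2, 6)
  expect_equal(tab2["colocalised", "above"], 2L)
  expect_equal(tab2["not", "above"], 0L)
  expect_equal(tab2["colocalised", "below"], 0L)
})

test_that("independent random channels colocalise at about the chance rate", {
  set.seed(74)
  side <- 80; n_each <- 12; n_frames <- 6
  n_rep <- 30
  rate <- vapply(1:n_rep, function(i) {
    mk_static <- function(ids) do.call(rbind, lapply(ids, function(k)
      mk_track(rep(100, n_frames), x = stats::runif(1, 5, side - 5),
               y = stats::runif(1, 5, side - 5), track_id = k)))
    a <- mk_static(1:n_each); b <- mk_static(1:n_each)
    ev <- colocalise(a, b, frame_interval = 20)
    length(unique(ev$track_a)) / n_each
  }, 0)
  # chance rate for sigma-1.5 spots: overlap >= 0.5 within d50 ~ 2.5 px
  d50 <- sqrt(2 * (1.5^2 + 1.5^2) * log(2))
  lam <- n_each / (side - 10)^2
  p_th <- random_coincidence_probability(lam, d50)
  expect_lt(abs(mean(rate) - p_th),
            3 * sqrt(p_th / (n_rep * n_each)) + 0.01)
})
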