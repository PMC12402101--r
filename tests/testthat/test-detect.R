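test_that("blank and constant frames yield no candidates", {
  expect_equal(nrow(find_candidate_foci(matrix(5, 64, 64))), 0)
  expect_equal(nrow(find_candidate_foci(matrix(0, 64, 64))), 0)
})

test_that("single and well-separated spots are recovered near truth", {
  set.seed(10)
  fr <- spot_frame(64, background = 10,
                   spots = data.frame(x = 30, y = 27, total = 1000,
                                      sigma = 1.5),
                   poisson = TRUE)
  f <- find_candidate_foci(fr)
  near <- abs(f$x - 30) < 1 & abs(f$y - 27) < 1
  expect_equal(sum(near), 1)   # exactly one focus at the true position
  expect_true(near[1])         # and it is the brightest candidate
  # noise maxima passing the permissive threshold stay below sift level
  expect_true(all(f$snr[!near] < 0.35))

  fr2 <- spot_frame(64, background = 10,
                    spots = data.frame(x = c(20, 40), y = c(30, 30),
                                       total = 800, sigma = 1.5),
                    poisson = TRUE)
  f2 <- find_candidate_foci(fr2)
  for (x0 in c(20, 40))
    expect_equal(sum(abs(f2$x - x0) < 1 & abs(f2$y - 30) < 1), 1)
})

test_that("aperture photometry recovers integrated intensity", {
  # noiseless spot: intensity recovered almost exactly, uniform frame ~ 0
  fr <- spot_frame(64, background = 3,
                   spots = data.frame(x = 32, y = 32, total = 500,
                                      sigma = 1.5))
  f <- measure_focus(fr, 32, 32)
  expect_equal(f$intensity, 500, tolerance = 0.01)
  u <- measure_focus(matrix(7, 64, 64), 32, 32)
  expect_equal(u$intensity, 0)
  # shot-noise case: within 3 sd of sqrt(N + area * b)
  set.seed(11)
  errs <- vapply(1:25, function(i) {
    frn <- spot_frame(64, background = 0,
                      spots = data.frame(x = 32, y = 32, total = 500,
                                         sigma = 1.5), poisson = TRUE)
    measure_focus(frn, 32, 32)$intensity - 500
  }, 0)
  expect_lt(abs(mean(errs)), 3 * sqrt(500 / 25))
})

test_that("SNR definition matches the per-pixel worked example", {
  # (76 photons / 30 px) / sqrt(26) = 0.50; measured SNR on a simulated
  # single molecule over that background agrees within sampling error
  set.seed(12)
  snrs <- vapply(1:200, function(i) {
    fr <- spot_frame(48, background = 26,
                     spots = data.frame(x = 24, y = 24, total = 76,
                                        sigma = 1.5), poisson = TRUE)
    measure_focus(fr, 24, 24)$snr
  }, 0)
  # the aperture (81 px) spreads the same photons wider than the 30-px
  # effective footprint; per-pixel SNR is lower by that area ratio
  expect_equal(mean(snrs) * 81 / 30, expected_snr(76, 30, 26),
               tolerance = 0.12)
  # total-intensity mode differs from per-pixel mode by the mask area
  frq <- spot_frame(48, background = 26,
                    spots = data.frame(x = 24, y = 24, total = 760,
                                       sigma = 1.5), poisson = TRUE)
  a <- measure_focus(frq, 24, 24, snr_mode = "per_pixel")
  b <- measure_focus(frq, 24, 24, snr_mode = "total")
  expect_equal(b$snr / a$snr, a$n_mask_pixels)
})

test_that("integrated intensity scales linearly with signal", {
  base <- spot_frame(64, background = 5,
                     spots = data.frame(x = 32, y = 32, total = 100,
                                        sigma = 1.5))
  scaled <- spot_frame(64, background = 5,
                       spots = data.frame(x = 32, y = 32, total = 300,
                                          sigma = 1.5))
  f1 <- measure_focus(base, 32, 32)
  f3 <- measure_focus(scaled, 32, 32)
  expect_equal(f3$intensity / f1$intensity, 3, tolerance = 1e-6)
})

test_that("edge candidates whose window leaves the frame are discarded", {
  fr <- spot_frame(64, background = 0,
                   spots = data.frame(x = 3, y = 30, total = 1000,
                                      sigma = 1.5))
  expect_null(measure_focus(fr, 3, 30))
  expect_equal(nrow(find_candidate_foci(fr + 1e-9)), 0)
})

test_that("Gaussian-mask refinement reaches sub-pixel truth", {
  # symmetric noiseless spot at a pixel centre
  fr <- spot_frame(48, background = 2,
                   spots = data.frame(x = 24, y = 24, total = 2000,
                                      sigma = 1.5))
  f <- refine_gaussian_mask(fr, measure_focus(fr, 24, 24), psf_sigma = 1.5)
  expect_lt(abs(f$x - 24), 0.02)
  expect_lt(abs(f$y - 24), 0.02)
  expect_equal(f$sigma_x, f$sigma_y, tolerance = 0.01)

  # off-centre sub-pixel truth at high SNR
  fr2 <- spot_frame(48, background = 2,
                    spots = data.frame(x = 10.3, y = 7.6 + 10, total = 5000,
                                       sigma = 1.5))
  f2 <- refine_gaussian_mask(fr2, measure_focus(fr2, 10, 18),
                             psf_sigma = 1.5)
  expect_lt(abs(f2$x - 10.3), 0.1)
  expect_lt(abs(f2$y - 17.6), 0.1)
})

test_that("refined widths agree with a nonlinear least-squares fit", {
  skip_if_not_installed("minpack.lm")
  set.seed(13)
  rel_err <- vapply(1:30, function(i) {
    sx <- stats::runif(1, 1.2, 2.0)
    x0 <- 24 + stats::runif(1, -0.4, 0.4)
    y0 <- 24 + stats::runif(1, -0.4, 0.4)
    fr <- spot_frame(48, background = 5,
                     spots = data.frame(x = x0, y = y0, total = 20000,
                                        sigma = sx), poisson = TRUE)
    f <- refine_gaussian_mask(fr, measure_focus(fr, 24, 24), psf_sigma = 1.5)
    # independent oracle: full nonlinear Gaussian fit over the window
    win <- fr[(24 - 8):(24 + 8) + 1, (24 - 8):(24 + 8) + 1]
    d <- expand.grid(y = (24 - 8):(24 + 8), x = (24 - 8):(24 + 8))
    d$z <- as.vector(win)
    fit <- minpack.lm::nlsLM(
      z ~ b + A * exp(-((x - mx)^2 + (y - my)^2) / (2 * s^2)), data = d,
      start = list(b = 5, A = max(d$z), mx = 24, my = 24, s = 1.5))
    (mean(c(f$sigma_x, f$sigma_y)) - coef(fit)[["s"]]) / coef(fit)[["s"]]
  }, 0)
  expect_lt(mean(abs(rel_err)), 0.05)
})

test_that("localisation precision scales like sigma/sqrt(N)", {
  set.seed(14)
  prec <- vapply(c(400, 3600), function(N) {
    err <- vapply(1:25, function(i) {
      fr <- spot_frame(48, background = 0,
                       spots = data.frame(x = 24.3, y = 24.1, total = N,
                                          sigma = 1.5), poisson = TRUE)
      f <- refine_gaussian_mask(fr, measure_focus(fr, 24, 24),
                                psf_sigma = 1.5)
      c(f$x - 24.3, f$y - 24.1)
    }, c(0, 0))
    sqrt(mean(err^2))   # per-axis RMS
  }, 0)
  # per-axis theory: sigma/sqrt(N) -> 0.075 and 0.025 px; allow a factor of 2
  expect_lt(prec[1], 2 * 1.5 / sqrt(400))
  expect_lt(prec[2], 2 * 1.5 / sqrt(3600))
  # 53 nm pixels, N ~ 400-3600 photons: the 40-80 nm regime
  expect_gt(prec[1] / prec[2], 2)
})
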