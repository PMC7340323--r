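test_that("expected decay counts follow the saturation law", {
  # no elapsed time, one half-life, and the infinite-time plateau
  expect_equal(expected_counts(1000, 0.5, 0.97, elapsed_min = 0), 0)
  expect_equal(expected_counts(1000, 0.5, 0.97, elapsed_min = 110,
                               half_life_min = 110),
               0.5 * 0.97 * 1000 / 2)
  expect_equal(expected_counts(1000, 0.5, 0.97, elapsed_min = 1e9),
               0.5 * 0.97 * 1000, tolerance = 1e-12)
  # strictly increasing in every factor
  t <- c(1, 5, 20, 100, 400)
  d <- expected_counts(1000, 0.5, 0.97, elapsed_min = t)
  expect_true(all(diff(d) > 0))
  expect_true(expected_counts(2000, 0.5, 0.97, 50) >
                expected_counts(1000, 0.5, 0.97, 50))
  expect_true(expected_counts(1000, 0.6, 0.97, 50) >
                expected_counts(1000, 0.5, 0.97, 50))
  expect_error(expected_counts(-1, 0.5, 0.97, 50),
               class = "rlmsim_invalid_argument")
})

test_that("decay correction factor matches the 21-minute worked value", {
  expect_equal(decay_correction_factor(21, 110), 1.14, tolerance = 0.005)
  expect_equal(decay_correction_factor(0, 110), 1)
  expect_equal(decay_correction_factor(110, 110), 2)
})

test_that("sensitivity ratio composes counts with the decay correction", {
  expect_equal(sensitivity_ratio(74, 37, delta_t_min = 0)$ratio, 2)
  # equal counts 21 minutes apart recover exactly the correction factor
  r <- sensitivity_ratio(37, 37, delta_t_min = 21, half_life_min = 110)
  expect_equal(r$ratio, 1.14, tolerance = 0.005)
  expect_equal(r$correction_factor, r$ratio)
  expect_error(sensitivity_ratio(10, 0), class = "rlmsim_undefined_ratio")
  # simulated symmetric dual vs single Poisson tallies: CI covers 2
  set.seed(4)
  d1 <- rpois(1, 10000)
  d2 <- rpois(1, 20000)
  ci <- sensitivity_ratio(d2, d1, delta_t_min = 0, conf_level = 0.99)
  expect_lt(ci$ci_low, 2)
  expect_gt(ci$ci_high, 2)
  expect_lt(ci$ci_low, ci$ratio)
  expect_gt(ci$ci_high, ci$ratio)
})

test_that("ROI counts agree with a brute-force pixel membership oracle", {
  expect_equal(roi_counts(toy_image(matrix(0L, 20, 20)),
                          centers = cbind(0, 0))$raw, 0)
  # single hot pixel at an ROI centre
  m <- matrix(0L, 21, 21)
  m[11, 11] <- 7L
  img <- event_image(m, 10)
  rc <- roi_counts(img, centers = cbind(5, 5), diameter_um = 90)
  expect_equal(rc$raw, 7)
  expect_equal(rc$corrected, 7)
  # randomised toy images vs exhaustive per-pixel loop
  set.seed(42)
  for (rep in 1:10) {
    n <- 16
    pitch <- 5
    cts <- matrix(rpois(n * n, 2), n, n)
    img <- event_image(cts, pitch)
    cx <- runif(1, -20, 20); cy <- runif(1, -20, 20)
    dia <- runif(1, 10, 50)
    oracle <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      px <- -n * pitch / 2 + (j - 0.5) * pitch
      py <- -n * pitch / 2 + (i - 0.5) * pitch
      if ((px - cx)^2 + (py - cy)^2 <= (dia / 2)^2) {
        oracle <- oracle + cts[i, j]
      }
    }
    got <- roi_counts(img, centers = cbind(cx, cy), diameter_um = dia)
    expect_equal(got$raw, oracle)
  }
  expect_error(roi_counts(img, centers = cbind(1e4, 0), diameter_um = 10),
               class = "rlmsim_invalid_argument")
})

test_that("background correction subtracts the mean of background ROIs", {
  m <- matrix(2L, 30, 30) # uniform field: every equal ROI sees the same sum
  img <- event_image(m, 10)
  rc <- roi_counts(img, centers = cbind(0, 0), diameter_um = 60,
                   background_rois = cbind(c(-80, 80), c(-80, 80)))
  cell <- rc[rc$label == "cell", ]
  expect_equal(cell$corrected, 0)
  expect_gt(cell$raw, 0)
})

test_that("2-D Gaussian fit recovers known width, centre and FWHM", {
  # noiseless sampled Gaussian, sigma = 10 px
  img <- event_image(gaussian_counts(n = 61, sigma = 10, amp = 200), 1)
  f <- fit_gaussian2d(img)
  expect_equal(f$fwhm, 2 * sqrt(2 * log(2)) * 10, tolerance = 0.1)
  expect_equal(f$fwhm, 2 * sqrt(2 * log(2)) * f$sigma, tolerance = 1e-9)
  expect_equal(unname(f$center), c(0, 0), tolerance = 0.05)
  # translation equivariance under whole-pixel shifts
  m <- gaussian_counts(n = 61, sigma = 8, amp = 150)
  sh <- matrix(0, 61, 61)
  sh[6:61, 4:61] <- m[1:56, 1:58] # shift +5 rows (y), +3 cols (x)
  f0 <- fit_gaussian2d(event_image(m, 1))
  f1 <- fit_gaussian2d(event_image(sh, 1))
  expect_equal(unname(f1$center - f0$center), c(3, 5), tolerance = 0.05)
  expect_equal(f1$sigma, f0$sigma, tolerance = 0.05)
  # Poisson-noised recovery, median relative sigma error < 5%
  set.seed(9)
  errs <- replicate(60, {
    noisy <- matrix(rpois(61^2, gaussian_counts(n = 61, sigma = 10,
                                                amp = 60, offset = 1)),
                    61, 61)
    abs(fit_gaussian2d(event_image(noisy, 1))$sigma - 10) / 10
  })
  expect_lt(median(errs), 0.05)
  expect_error(fit_gaussian2d(event_image(matrix(0L, 9, 9), 1)),
               class = "rlmsim_invalid_argument")
})

test_that("line profiles integrate a rotated band and normalise", {
  img <- event_image(matrix(3L, 40, 40), 10)
  p <- line_profile(img, c(-120, 0), c(120, 0), width_um = 60,
                    normalize = TRUE)
  expect_true(all(p$value == 1))
  # two separated blobs give two maxima with an interior minimum
  m <- matrix(0L, 40, 40)
  m[19:22, 8:11] <- 40L
  m[19:22, 30:33] <- 40L
  img2 <- event_image(m, 10)
  pr <- line_profile(img2, c(-180, 0), c(180, 0), width_um = 80)
  imax <- range(which(pr$value > max(pr$value) * 0.8))
  valley <- min(pr$value[imax[1]:imax[2]])
  expect_lt(valley, max(pr$value) * 0.5)
  expect_error(line_profile(img, c(0, 0), c(0, 0)),
               class = "rlmsim_invalid_argument")
})

test_that("line profile sums match a brute-force rotated-rectangle oracle", {
  set.seed(7)
  n <- 24; pitch <- 8
  cts <- matrix(rpois(n * n, 3), n, n)
  img <- event_image(cts, pitch)
  p0 <- c(-60, -40); p1 <- c(70, 55); width <- 50
  prof <- line_profile(img, p0, p1, width_um = width)
  seg <- p1 - p0; len <- sqrt(sum(seg^2)); u <- seg / len
  v <- c(-u[2], u[1])
  oracle_total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    px <- -n * pitch / 2 + (j - 0.5) * pitch - p0[1]
    py <- -n * pitch / 2 + (i - 0.5) * pitch - p0[2]
    a <- px * u[1] + py * u[2]
    b <- px * v[1] + py * v[2]
    if (a >= -pitch / 2 && a < len + pitch / 2 && abs(b) <= width / 2) {
      oracle_total <- oracle_total + cts[i, j]
    }
  }
  expect_equal(sum(prof$value), oracle_total, tolerance = 0.02)
})

test_that("efflux difference image is zero for a doubled copy and linear", {
  set.seed(3)
  s <- matrix(rpois(400, 5), 20, 20)
  img_s <- event_image(s, 10)
  img_d <- event_image(2L * s, 10)
  expect_true(all(efflux_difference_image(img_d, img_s, 0) == 0))
  d1 <- efflux_difference_image(img_d, img_s, delta_t_min = 21)
  img_s3 <- event_image(3L * s, 10)
  img_d3 <- event_image(6L * s, 10)
  d3 <- efflux_difference_image(img_d3, img_s3, delta_t_min = 21)
  expect_equal(d3, 3 * d1, tolerance = 1e-12)
  expect_error(efflux_difference_image(event_image(s[1:10, ], 10), img_s, 0),
               class = "rlmsim_invalid_argument")
})

test_that("OLS regression matches the closed-form solution", {
  x <- c(1, 2, 3, 4, 5)
  r <- linear_regression(x, 2 * x)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  rc <- linear_regression(x, rep(3, 5))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)
  set.seed(10)
  xs <- rnorm(40); ys <- 1.3 * xs + rnorm(40)
  rr <- linear_regression(xs, ys)
  b <- cov(xs, ys) / var(xs)
  a <- mean(ys) - b * mean(xs)
  expect_equal(rr$slope, b, tolerance = 1e-10)
  expect_equal(rr$intercept, a, tolerance = 1e-10)
  expect_equal(rr$r_squared, cor(xs, ys)^2, tolerance = 1e-10)
  expect_error(linear_regression(rep(1, 5), rnorm(5)),
               class = "rlmsim_invalid_argument")
})
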