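test_that("background estimation computes per-pixel temporal moments", {
  a <- array(7L, dim = c(4, 5, 10))
  bg <- estimate_background(a)
  expect_equal(bg$mean, matrix(7, 4, 5))
  expect_equal(bg$sd, matrix(0, 4, 5))
  # two frames {0, 2}: mean 1, sample sd (n - 1 denominator) sqrt(2)
  b <- array(c(rep(0L, 6), rep(2L, 6)), dim = c(2, 3, 2))
  bg2 <- estimate_background(b)
  expect_equal(bg2$mean, matrix(1, 2, 3))
  expect_equal(bg2$sd, matrix(sqrt(2), 2, 3))
  expect_error(estimate_background(array(0L, dim = c(2, 2, 1))),
               class = "rlmsim_insufficient_data")
  # simulated dark stack mean agrees with the camera noise model
  cam <- camera_model(dark_rate_e_s = 30, read_noise_e = 10)
  dk <- make_dark_stack(cam, c(12, 12), 800, seed = 5)
  bg3 <- estimate_background(dk)
  mean_true <- cam$dark_rate_e_s * cam$exposure_s * cam$em_gain /
    cam$sensitivity_e_adu + cam$bias_adu
  lam <- cam$dark_rate_e_s * cam$exposure_s
  se <- sqrt((lam * 2 * cam$em_gain^2 + cam$read_noise_e^2) /
               cam$sensitivity_e_adu^2 / (800 * 144))
  expect_lt(abs(mean(bg3$mean) - mean_true), 3 * se)
})

flat_bg <- function(ny, nx, sd = 1) {
  structure(list(mean = matrix(0, ny, nx), sd = matrix(sd, ny, nx),
                 n_frames = 2L), class = "background_model")
}

test_that("flash detection finds isolated blobs at their centres", {
  bg <- flat_bg(16, 16)
  expect_identical(nrow(detect_flashes(matrix(0L, 16, 16), bg,
                                       pixel_pitch = 10)), 0L)
  # one symmetric 3x3 blob above threshold
  fr <- matrix(0L, 16, 16)
  fr[7:9, 10:12] <- 50L
  ev <- detect_flashes(fr, bg, pixel_pitch = 10, frame_index = 3L)
  expect_identical(nrow(ev), 1L)
  # centre of the blob in object coordinates (centred grid)
  expect_equal(ev$x_um, -16 * 10 / 2 + (11 - 0.5) * 10)
  expect_equal(ev$y_um, -16 * 10 / 2 + (8 - 0.5) * 10)
  expect_identical(ev$frame_index, 3L)
  expect_identical(ev$n_pixels, 9L)
})

test_that("component labelling matches an independent flood-fill oracle", {
  set.seed(31)
  for (rep in 1:8) {
    mask <- matrix(runif(64 * 64) < 0.08, 64, 64)
    got <- rlmsim:::label_components8(mask)
    oracle <- label_partition(flood_fill_labels(mask))
    got_sorted <- lapply(got, sort)
    got_sorted <- got_sorted[order(vapply(got_sorted, min, numeric(1)))]
    expect_identical(got_sorted, unname(oracle))
  }
})

test_that("raising the threshold never adds events", {
  set.seed(32)
  bg <- flat_bg(32, 32)
  fr <- matrix(rpois(1024, 2), 32, 32)
  fr[10:11, 20:21] <- 30L
  n_prev <- Inf
  for (k in c(3, 5, 8, 12)) {
    n_k <- nrow(detect_flashes(fr, bg, k_sigma = k, pixel_pitch = 10,
                               cluster_radius_um = 0))
    expect_lte(n_k, n_prev)
    n_prev <- n_k
  }
})

test_that("fragment clustering joins split flashes but not isolated noise", {
  bg <- flat_bg(24, 24)
  fr <- matrix(0L, 24, 24)
  fr[10:11, 5:6] <- 40L   # seed component
  fr[12, 9] <- 25L        # nearby 1-px fragment: should attach
  fr[3, 20] <- 25L        # far 1-px fragment: should be dropped
  ev <- detect_flashes(fr, bg, pixel_pitch = 10, cluster_radius_um = 60)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$n_pixels, 5L)
  # two isolated 1-px spikes never form an event between them
  fr2 <- matrix(0L, 24, 24)
  fr2[5, 5] <- 30L; fr2[5, 8] <- 30L
  ev2 <- detect_flashes(fr2, bg, pixel_pitch = 10, cluster_radius_um = 60)
  expect_identical(nrow(ev2), 0L)
  # without clustering the split flash is two events (one below min size)
  ev3 <- detect_flashes(fr, bg, pixel_pitch = 10, cluster_radius_um = 0)
  expect_identical(nrow(ev3), 1L)
  expect_identical(ev3$n_pixels, 4L)
})

test_that("reconstruction conserves the event count and recovers positions", {
  cam <- quiet_camera()
  st <- scintillator_stack(light_yield = 3)
  op <- optical_system()
  pitch <- pixel_pitch_object(cam, op)
  # inject flashes at known well-separated positions over several frames
  truth <- data.frame(x = c(-120, 100, 0, -50), y = c(-100, 110, 30, 90),
                      z = -10,
                      energy_kev = 150, time_s = c(0.01, 0.04, 0.07, 0.10))
  fr <- render_frames(truth, st, op, cam, fov_um = c(420, 420),
                      n_frames = 4, seed = 33)
  dark <- make_dark_stack(camera_model(), dim(fr$frames)[1:2], 100,
                          seed = 34, pixel_pitch = pitch)
  rec <- reconstruct(fr, dark)
  expect_identical(sum(rec$image$counts), nrow(rec$events))
  expect_identical(nrow(rec$events), 4L)
  ord <- order(rec$events$frame_index)
  expect_lt(max(abs(rec$events$x_um[ord] - truth$x)), pitch)
  expect_lt(max(abs(rec$events$y_um[ord] - truth$y)), pitch)
  # a zero-event stack reconstructs to an all-zero image
  fr0 <- render_frames(NULL, st, op, cam, fov_um = c(420, 420),
                       n_frames = 5, seed = 35)
  rec0 <- reconstruct(fr0, dark)
  expect_true(all(rec0$image$counts == 0))
  expect_identical(nrow(rec0$events), 0L)
})

test_that("event-count conservation holds on random stacks", {
  set.seed(36)
  for (rep in 1:25) {
    ny <- sample(8:20, 1); nx <- sample(8:20, 1); nf <- sample(2:6, 1)
    frames <- array(rpois(ny * nx * nf, 3), dim = c(ny, nx, nf))
    frames[sample(length(frames), 5)] <- 60L
    stack <- frame_stack(frames, pixel_pitch = 10, exposure_s = 0.03)
    dark <- frame_stack(array(rpois(ny * nx * 40, 3), dim = c(ny, nx, 40)),
                        pixel_pitch = 10, exposure_s = 0.03)
    rec <- reconstruct(stack, dark, k_sigma = 4, min_pixels = 1)
    expect_identical(sum(rec$image$counts), nrow(rec$events))
  }
})

test_that("pure dark stacks produce almost no false events", {
  cam <- camera_model()
  dark_ref <- make_dark_stack(cam, c(32, 32), 400, seed = 37)
  dark_probe <- make_dark_stack(cam, c(32, 32), 2000, seed = 38)
  rec <- reconstruct(dark_probe, dark_ref, k_sigma = 5, min_pixels = 2)
  # expected false events per frame bounded by the Gaussian tail implied
  # by a 5-sigma threshold over all pixels
  bound <- 2000 * 32 * 32 * pnorm(-5)
  expect_lte(nrow(rec$events), max(1, ceiling(3 * bound)))
})

test_that("shape mismatches are rejected", {
  stack <- frame_stack(array(0L, dim = c(8, 8, 3)), 10, 0.03)
  dark <- frame_stack(array(0L, dim = c(9, 9, 3)), 10, 0.03)
  expect_error(reconstruct(stack, dark), class = "rlmsim_invalid_argument")
})
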