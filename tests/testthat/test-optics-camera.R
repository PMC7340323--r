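test_that("depth of field reproduces the reference system value", {
  dof <- depth_of_field(optical_system(), camera_model())
  expect_equal(dof, 24.5, tolerance = 0.1)
  # wave-optics term only when the pixel term vanishes
  tiny_px <- camera_model(pixel_size_um = 1e-9)
  expect_equal(depth_of_field(optical_system(), tiny_px),
               1 * 0.475 / 0.75^2, tolerance = 1e-6)
  # doubling M halves only the geometric term; verify by direct formula
  d1 <- depth_of_field(optical_system(magnification = 3.6), camera_model())
  d2 <- depth_of_field(optical_system(magnification = 7.2), camera_model())
  wave <- 0.475 / 0.75^2
  geom <- 4 * 16 / (3.6 * 0.75)
  expect_equal(d1, wave + geom, tolerance = 1e-9)
  expect_equal(d2, wave + geom / 2, tolerance = 1e-9)
})

test_that("object-space pixel pitch is pixel_size * binning / magnification", {
  expect_equal(pixel_pitch_object(camera_model(), optical_system()),
               16 * 4 / 3.6, tolerance = 1e-9)
})

test_that("PSF width grows symmetrically with defocus", {
  op <- optical_system()
  expect_equal(psf_sigma(op, 0), 0.21 * 0.475 / 0.75, tolerance = 1e-9)
  expect_equal(psf_sigma(op, 15), psf_sigma(op, -15))
  expect_true(all(diff(psf_sigma(op, c(0, 5, 10, 40))) > 0))
})

test_that("noise-free rendering of nothing is exactly zero", {
  fs <- render_frames(NULL, scintillator_stack(), optical_system(),
                      quiet_camera(), fov_um = c(200, 200), n_frames = 4,
                      seed = 1)
  expect_true(all(fs$frames == 0))
  expect_error(render_frames(NULL, scintillator_stack(), optical_system(),
                             quiet_camera(), fov_um = c(1, 1),
                             n_frames = 1),
               class = "rlmsim_invalid_argument")
})

test_that("a flash conserves expected light and lands at the true position", {
  st <- scintillator_stack(light_yield = 2)
  op <- optical_system()
  cam <- quiet_camera()
  dep <- data.frame(x = 3, y = -4, z = -10, energy_kev = 200, time_s = 0.01)
  npe_true <- st$light_yield * 200 * cam$quantum_efficiency
  # Poisson conservation of the total signal, converted back to electrons
  tot <- replicate(40, {
    fs <- render_frames(dep, st, op, cam, fov_um = c(400, 400),
                        n_frames = 1)
    sum(fs$frames) * cam$sensitivity_e_adu / cam$em_gain
  })
  expect_lt(abs(mean(tot) - npe_true),
            3 * sqrt(npe_true * 2 / length(tot))) # x2: EM excess noise
  # centroid averaged over replicates within half a pixel of the truth
  set.seed(21)
  cent <- replicate(60, {
    fs <- render_frames(dep, st, op, cam, fov_um = c(400, 400),
                        n_frames = 1)
    m <- fs$frames[, , 1]
    ctr_x <- -ncol(m) * fs$pixel_pitch / 2 +
      (seq_len(ncol(m)) - 0.5) * fs$pixel_pitch
    ctr_y <- -nrow(m) * fs$pixel_pitch / 2 +
      (seq_len(nrow(m)) - 0.5) * fs$pixel_pitch
    c(sum(colSums(m) * ctr_x), sum(rowSums(m) * ctr_y)) / sum(m)
  })
  err <- rowMeans(cent) - c(3, -4)
  expect_lt(max(abs(err)), 17.78 / 2)
})

test_that("expected light spread is shift-invariant to 1 percent", {
  st <- scintillator_stack()
  op <- optical_system()
  cam <- camera_model()
  pitch <- pixel_pitch_object(cam, op)
  sums <- sapply(c(0, 0.25, 0.5, 0.77), function(frac) {
    dep <- data.frame(x = frac * pitch, y = 0, z = -20, energy_kev = 150,
                      time_s = 0)
    lam <- rlmsim:::expected_signal_array(dep, st, op, cam, nx = 21,
                                          ny = 21, pitch = pitch,
                                          n_frames = 1, t_start_s = 0)
    sum(lam)
  })
  expect_lt(diff(range(sums)) / mean(sums), 0.01)
})

test_that("deposits equidistant from the focal plane blur identically", {
  st <- scintillator_stack()
  op <- optical_system(focal_plane_z = 0)
  cam <- camera_model()
  pitch <- pixel_pitch_object(cam, op)
  lam <- function(z) {
    dep <- data.frame(x = 0, y = 0, z = z, energy_kev = 100, time_s = 0)
    rlmsim:::expected_signal_array(dep, st, op, cam, nx = 15, ny = 15,
                                   pitch = pitch, n_frames = 1,
                                   t_start_s = 0)
  }
  expect_equal(lam(12), lam(-12), tolerance = 1e-12)
})

test_that("dark stacks follow the camera noise model", {
  cam0 <- quiet_camera()
  d0 <- make_dark_stack(cam0, c(8, 8), 5, seed = 2)
  expect_true(all(d0$frames == 0))
  # per-pixel mean vs closed form of the amplified dark current
  cam <- camera_model(dark_rate_e_s = 40, read_noise_e = 5)
  dk <- make_dark_stack(cam, c(16, 16), 1000, seed = 3)
  mean_true <- cam$dark_rate_e_s * cam$exposure_s * cam$em_gain /
    cam$sensitivity_e_adu + cam$bias_adu
  lam <- cam$dark_rate_e_s * cam$exposure_s
  var_e <- lam * 2 * cam$em_gain^2 + cam$read_noise_e^2
  se <- sqrt(var_e / cam$sensitivity_e_adu^2 / (1000 * 256))
  expect_lt(abs(mean(dk$frames) - mean_true), 3 * se)
  # bit-identical repeat under a fixed seed
  dk2 <- make_dark_stack(cam, c(16, 16), 1000, seed = 3)
  expect_identical(dk$frames, dk2$frames)
})

test_that("frames are assigned by exposure window", {
  st <- scintillator_stack(light_yield = 5)
  cam <- quiet_camera()
  dep <- data.frame(x = 0, y = 0, z = -10, energy_kev = c(100, 100),
                    time_s = c(0.010, 0.075)) # frames 1 and 3
  fs <- render_frames(dep, st, optical_system(), cam,
                      fov_um = c(200, 200), n_frames = 3, seed = 4)
  per_frame <- apply(fs$frames, 3, sum)
  expect_gt(per_frame[1], 0)
  expect_identical(per_frame[2], 0L)
  expect_gt(per_frame[3], 0)
})
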