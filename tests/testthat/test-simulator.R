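test_that("decay time sampling matches Poisson expectations", {
  src0 <- source_model(activity_bq = 0)
  expect_identical(sample_decay_times(src0, 100), numeric(0))
  expect_error(sample_decay_times(source_model(1), -5),
               class = "rlmsim_invalid_argument")

  # 1 Bq for 20,000 s: count within 4*sqrt(20,000) of expectation
  src <- source_model(activity_bq = 1)
  t1 <- sample_decay_times(src, 20000, seed = 1)
  expect_lt(abs(length(t1) - 20000), 4 * sqrt(20000))
  expect_true(!is.unsorted(t1))
  expect_true(all(t1 >= 0 & t1 < 20000))

  # decaying-rate clock: expected count equals the numeric integral of the
  # exponential rate over one half-life
  half_s <- src$half_life_min * 60
  rate_fn <- function(t) exp(-log(2) * t / half_s)
  expected <- integrate(rate_fn, 0, half_s)$value
  expect_equal(expected, half_s / log(2) * 0.5, tolerance = 1e-6)
  t2 <- sample_decay_times(src, half_s, decay_clock = TRUE, seed = 2)
  expect_lt(abs(length(t2) - expected), 4 * sqrt(expected))
  # early-heavy: more decays in the first half of the window
  expect_gt(mean(t2 < half_s / 2), 0.5)
})

test_that("beta spectrum sampling matches its own density", {
  expect_identical(sample_beta_spectrum(0), numeric(0))
  e <- sample_beta_spectrum(1e5, seed = 3)
  expect_true(all(e > 0 & e <= 633.5))
  # oracle: numeric integration of the implemented density
  norm <- integrate(f18_beta_density, 0, 633.5)$value
  mean_true <- integrate(function(x) x * f18_beta_density(x), 0,
                         633.5)$value / norm
  var_true <- integrate(function(x) (x - mean_true)^2 * f18_beta_density(x),
                        0, 633.5)$value / norm
  se <- sqrt(var_true / length(e))
  expect_lt(abs(mean(e) - mean_true), 3 * se)
})

test_that("emission directions are isotropic", {
  expect_identical(nrow(emit_direction(0)), 0L)
  d1 <- emit_direction(1, seed = 5)
  expect_equal(sum(d1^2), 1, tolerance = 1e-9)
  d <- emit_direction(1e5, seed = 6)
  expect_equal(rowSums(d^2)[1:100], rep(1, 100), tolerance = 1e-9)
  frac_dn <- mean(d[, 3] < 0)
  expect_lt(abs(frac_dn - 0.5), 3 * sqrt(0.25 / nrow(d)))
  ks <- suppressWarnings(ks.test(d[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("ray-slab intersections agree with an independent analytic oracle", {
  set.seed(11)
  for (i in 1:200) {
    oz <- runif(1, -4, 4)
    dz <- runif(1, -1, 1)
    zlo <- -105; zhi <- -5
    got <- ray_slab_interval(oz, dz, zlo, zhi)
    # oracle: direct parametric solution
    if (dz == 0) {
      expect_true(is.na(got[1]))
    } else {
      ta <- (zlo - oz) / dz; tb <- (zhi - oz) / dz
      lo <- max(min(ta, tb), 0); hi <- max(ta, tb)
      if (hi <= lo) {
        expect_true(is.na(got[1]))
      } else {
        expect_equal(unname(got[1, 1]), lo, tolerance = 1e-6)
        expect_equal(unname(got[1, 2]), hi, tolerance = 1e-6)
      }
    }
  }
})

test_that("single positron transport respects geometry and conservation", {
  single <- scintillator_stack(gap_top = NULL)
  up <- list(origin = c(0, 0, 0), direction = c(0, 0, 1), energy = 250)
  expect_identical(nrow(transport_positron(up, single, seed = 1)), 0L)

  dn <- list(origin = c(0, 0, 0), direction = c(0, 0, -1), energy = 250)
  dep <- transport_positron(dn, single, seed = 2)
  expect_true(nrow(dep) > 0)
  expect_true(all(dep$slab == "bottom"))
  expect_true(all(dep$z <= -5 + 1e-9 & dep$z >= -105 - 1e-9))
  expect_lte(sum(dep$energy_kev), 250 + 1e-9)

  inside <- list(origin = c(0, 0, -50), direction = c(0, 0, -1), energy = 100)
  expect_error(transport_positron(inside, single),
               class = "rlmsim_invalid_geometry")
})

test_that("energy is conserved for every positron in a batch", {
  stack <- scintillator_stack()
  set.seed(12)
  n <- 2000
  en <- sample_beta_spectrum(n)
  res <- transport_batch(matrix(0, n, 3), emit_direction(n), en, stack,
                         seed = 13)
  tot <- tapply(res$deposits$energy_kev, res$deposits$event_id, sum)
  ids <- as.integer(names(tot))
  expect_true(all(tot <= en[ids] + 1e-6))
  # summary totals agree with the deposit table
  summ <- res$summary
  agg <- tapply(res$deposits$energy_kev,
                paste(res$deposits$event_id, res$deposits$slab), sum)
  key <- paste(summ$event_id, summ$slab)
  expect_equal(as.numeric(agg[key]), summ$e_total_kev, tolerance = 1e-6)
})

test_that("mean deposition depth is calibrated to ~25 um", {
  d <- mean_deposit_depth(n = 1e4, seed = 14)
  expect_lt(abs(d - 25) / 25, 0.15)
})

test_that("decay batches are deterministic and geometrically bounded", {
  src <- source_model(1)
  single <- scintillator_stack(gap_top = NULL)
  r1 <- run_decay_batch(src, single, 500, seed = 7)
  r2 <- run_decay_batch(src, single, 500, seed = 7)
  expect_identical(r1$tally, r2$tally)
  expect_identical(r1$deposits, r2$deposits)
  # only the downward hemisphere can reach the single slab
  r3 <- run_decay_batch(src, single, 8000, seed = 8, keep_deposits = FALSE)
  expect_lte(r3$tally[["bottom"]] / 8000, 0.5 + 0.02)
  expect_identical(r3$tally[["top"]], 0L)
})

test_that("mirrored dual geometry gives statistically equal slab tallies", {
  src <- source_model(1)
  dual <- scintillator_stack()
  r <- run_decay_batch(src, dual, 20000, seed = 9, keep_deposits = FALSE)
  nb <- r$tally[["bottom"]]; nt <- r$tally[["top"]]
  # binomial symmetry between the two hemispheres
  expect_lt(abs(nb - nt), 4 * sqrt((nb + nt) / 2))
})

test_that("dual vs single detected decays differ by a factor of two", {
  src <- source_model(1)
  dual <- scintillator_stack()
  single <- scintillator_stack(gap_top = NULL)
  rd <- run_decay_batch(src, dual, 10000, seed = 10, keep_deposits = FALSE)
  rs <- run_decay_batch(src, single, 10000, seed = 10,
                        keep_deposits = FALSE)
  ratio <- rd$tally[["any"]] / rs$tally[["bottom"]]
  expect_gt(ratio, 1.85)
  expect_lt(ratio, 2.15)
})
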