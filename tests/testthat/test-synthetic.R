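test_that("reference surfaces satisfy their defining values", {
  flat <- reference_surface("flat")
  expect_equal(flat$fun(c(-3, 0, 2.7)), c(0, 0, 0))
  expect_equal(flat$grad(c(-3, 0, 2.7)), c(0, 0, 0))

  mdw <- reference_surface("membrane_double_well", D = 40, B = 25,
                           z_min = 1.4)
  expect_equal(mdw$fun(1.4), -40)
  expect_equal(mdw$fun(-1.4), -40)
  expect_equal(mdw$fun(4.0), 0)
  expect_equal(mdw$fun(0), -15)
  # zero slope at the stationary points
  expect_equal(mdw$grad(c(0, 1.4, 4)), c(0, 0, 0))
  # gradient matches a numeric derivative on the smooth parts
  zs <- c(-2.2, -0.7, 0.9, 1.9, 2.3)
  num <- (mdw$fun(zs + 1e-6) - mdw$fun(zs - 1e-6)) / 2e-6
  expect_equal(mdw$grad(zs), num, tolerance = 1e-4)

  sw <- reference_surface("square_well", depth = 40, z_lo = 1.0, z_hi = 1.5)
  expect_equal(sw$fun(c(0.99, 1.0, 1.25, 1.49)), c(0, -40, -40, -40))
  expect_equal(sw$fun(1.5), 0)  # half-open interval
  expect_equal(sw$grad(c(0.5, 1.2)), c(0, 0))

  expect_error(reference_surface("bogus"), "valid names")
})

test_that("biased sampler reproduces the harmonic Boltzmann variance", {
  # flat surface: stationary distribution is Gaussian with var RT/k
  w <- sample_biased_window(reference_surface("flat"), bias_spec(1.0, 3000),
                            n_steps = 4e5, dt = 0.033, seed = 42)
  expect_equal(var(w$z), RT(298.15) / 3000, tolerance = 0.05)
  expect_equal(mean(w$z), 1.0, tolerance = 0.01)
})

test_that("sampler contracts: determinism, zero diffusion, stability", {
  s <- reference_surface("harmonic", k_surface = 50)
  b <- bias_spec(0.5, 1000)
  w1 <- sample_biased_window(s, b, 500, dt = 0.05, seed = 9)
  w2 <- sample_biased_window(s, b, 500, dt = 0.05, seed = 9)
  expect_identical(w1$z, w2$z)

  w0 <- sample_biased_window(s, b, 200, dt = 0.05, diffusion = 0, seed = 1,
                             z0 = 0.3)
  expect_true(all(w0$z == 0.3))

  expect_error(sample_biased_window(s, bias_spec(0, 3000), 100, dt = 10),
               "stability contract")
  expect_error(sample_biased_window(s, bias_spec(0, 0), 100, dt = 0.01),
               "k > 0")
})

test_that("stationary samples follow exp(-U/RT) (KS on thinned series)", {
  # biased flat surface: target law is Gaussian(z_ref, sqrt(RT/k)).
  # thin to ~independent samples (spacing >> relaxation time RT/(k D))
  k <- 3000
  w <- sample_biased_window(reference_surface("flat"), bias_spec(0.8, k),
                            n_steps = 2e5, dt = 0.033, seed = 17)
  thin <- w$z[seq(1, length(w$z), by = 1000)]
  ks <- stats::ks.test(thin, "pnorm", mean = 0.8, sd = sqrt(RT(298.15) / k))
  expect_gt(ks$p.value, 0.01)
})

test_that("burn-in discards the stated fraction and times stay consistent", {
  w <- sample_biased_window(reference_surface("flat"), bias_spec(0, 100),
                            n_steps = 1000, dt = 0.1, seed = 2,
                            burn_in = 0.1)
  expect_length(w$z, 900)
  expect_equal(w$times[1], 101 * 0.1)
})

test_that("toy bilayer frames conserve atoms and recover stated statistics", {
  spec <- toy_bilayer_spec(n_lipids = 16, n_probes = 4, n_waters = 6,
                           probe_depth = c(1.5, 0.4))
  traj <- generate_membrane_frames(spec, n_frames = 60, seed = 3)
  counts <- vapply(traj$frames, function(f) nrow(f$xyz), 0L)
  expect_true(all(counts == nrow(traj$atoms)))

  sel <- default_selections(traj)
  ap <- average_positions(traj, sel, groups = "probe")
  # Monte-Carlo oracle: folded Gaussian(1.5, 0.4) has mean ~1.5 at this
  # depth/sd ratio; require agreement within 3 standard errors
  se <- ap$sd / sqrt(ap$n)
  expect_lt(abs(ap$mean - 1.5), 3 * se + 1e-9)

  # delta orientation: all long axes at exactly 90 degrees
  spec90 <- toy_bilayer_spec(n_lipids = 8, n_probes = 4, n_waters = 4,
                             probe_orientation = list(kind = "fixed",
                                                      theta = 90))
  t90 <- generate_membrane_frames(spec90, n_frames = 10, seed = 4)
  td <- tilt_distribution(t90, "xanthene_long", default_selections(t90))
  expect_equal(td$mean, 90, tolerance = 1e-6)
  expect_true(all(abs(td$samples - 90) < 1e-6))

  empty <- generate_membrane_frames(spec, n_frames = 0, seed = 1)
  expect_s3_class(empty, "md_trajectory")
  expect_length(empty$frames, 0)
  expect_identical(nrow(empty$atoms), nrow(traj$atoms))

  expect_error(toy_bilayer_spec(n_lipids = 7), "even")
})

test_that("titration generator matches the partition equation", {
  m <- partition_model(S_W = 100, S_M = 10, K_P = 190, V_bar = 0.8)
  # zero lipid: I = S_W exactly; saturating lipid: I -> S_M
  noisefree <- generate_titration(m, c(0, 1e6), noise_cv = 0, seed = 1)
  expect_equal(noisefree$intensities[1], 100)
  expect_equal(noisefree$intensities[2], 10, tolerance = 1e-4)

  # direct hand evaluation of the partition equation
  C <- 1.316e-2
  x <- 190 * 0.8 * C
  expect_equal(partition_intensity(m, C), (100 + 10 * x) / (1 + x))
  expect_equal(partition_intensity(m, C), 39.9968, tolerance = 1e-4)

  # noise-free generation reproduces the model to machine tolerance
  cc <- titration_concs()
  tt <- generate_titration(m, cc, noise_cv = 0, seed = 5)
  expect_equal(tt$intensities, partition_intensity(m, cc), tolerance = 1e-12)

  # multiplicative noise: sd scales with the signal, seeded determinism
  t1 <- generate_titration(m, cc, noise_cv = 0.02, seed = 7)
  t2 <- generate_titration(m, cc, noise_cv = 0.02, seed = 7)
  expect_identical(t1$intensities, t2$intensities)
  expect_error(generate_titration(m, c(-1e-3, 0.1)), "negative")
})
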