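test_that("histogram binning: counts, grid arithmetic, outside samples", {
  w <- umbrella_window(1:5, rep(0.55, 5), bias_spec(0.5, 3000))
  h <- build_histograms(list(w), bin_width = 0.1, z_range = c(0, 4))
  expect_equal(ncol(h$counts), 40)        # (0,4) at 0.1 -> 40 bins
  expect_equal(sum(h$counts), 5)
  expect_equal(max(h$counts), 5)          # all samples in one bin
  expect_equal(h$n_outside, 0L)

  w2 <- umbrella_window(1:4, c(-0.5, 0.5, 4.5, 1.0), bias_spec(0.5, 3000))
  h2 <- build_histograms(list(w2), bin_width = 0.1, z_range = c(0, 4))
  expect_equal(h2$n_outside, 2L)          # counted, not binned
  expect_equal(h2$n_samples, 2)

  expect_error(build_histograms(list(umbrella_window(1, 1,
                                                     bias_spec(0, 1))[c(1, 2, 3)])),
               "umbrella_window")
})

test_that("adjacent-window overlap matches the closed-form Gaussian value", {
  sd <- 0.05
  wins <- lapply(1:3, function(i) {
    gaussian_window(4e4, mean = 0.9 + 0.1 * i, sd = sd, k = 3000,
                    z_ref = 0.9 + 0.1 * i, seed = i)
  })
  ov <- window_overlap(build_histograms(wins, bin_width = 0.005))
  # analytic overlap of equal-sd Gaussians separated by delta:
  # 2 * Phi(-delta / (2 sd))
  expected <- 2 * pnorm(-0.1 / (2 * sd))
  expect_equal(ov, rep(expected, 2), tolerance = 0.03)
})

test_that("WHAM on one unbiased window recovers -RT log p", {
  mu <- 1.5; sigma <- 0.12
  w <- gaussian_window(2e5, mu, sigma, k = 0, z_ref = mu, seed = 8)
  prof <- solve_wham(build_histograms(list(w), bin_width = 0.02),
                     anchor = "min")
  # analytic oracle: G(z) = RT (z - mu)^2 / (2 sigma^2) + const
  rt <- RT(298.15)
  keep <- is.finite(prof$G) & abs(prof$z - mu) < 1.5 * sigma
  expected <- rt * (prof$z[keep] - mu)^2 / (2 * sigma^2)
  expected <- expected - min(expected)
  expect_lt(max(abs(prof$G[keep] - expected)), 0.15)
})

test_that("WHAM is invariant under window replication and anchors at zero", {
  surf <- reference_surface("harmonic", k_surface = 30)
  wins <- sample_window_ladder(surf, z_refs = seq(0, 1, by = 0.1),
                               k = 2000, n_steps = 2e4, seed = 21)
  h1 <- build_histograms(wins, z_range = c(0, 1))
  p1 <- solve_wham(h1)
  p2 <- solve_wham(build_histograms(c(wins, wins), z_range = c(0, 1)))
  expect_equal(p1$G, p2$G, tolerance = 1e-6)
  # anchor convention: exactly zero at the last defined grid point
  lastdef <- max(which(is.finite(p1$G)))
  expect_identical(p1$G[lastdef], 0)
})

test_that("WHAM refuses disconnected windows, naming the gap", {
  w1 <- gaussian_window(1000, 0.5, 0.03, k = 3000, z_ref = 0.5, seed = 1)
  w2 <- gaussian_window(1000, 3.5, 0.03, k = 3000, z_ref = 3.5, seed = 2)
  expect_error(solve_wham(build_histograms(list(w1, w2))),
               "do not overlap")
})

test_that("bootstrap band: determinism, zero for constant data, n shrinkage", {
  # identical deterministic data in every window (shared populated bin)
  const <- lapply(seq(0.55, 0.65, by = 0.05), function(zr) {
    umbrella_window(1:500, rep(0.6, 500), bias_spec(zr, 3000))
  })
  b1 <- bootstrap_uncertainty(const, n_boot = 8, seed = 3,
                              z_range = c(0.3, 0.9), bin_width = 0.05)
  expect_true(all(b1$err[is.finite(b1$err)] < 1e-9))
  b2 <- bootstrap_uncertainty(const, n_boot = 8, seed = 3,
                              z_range = c(0.3, 0.9), bin_width = 0.05)
  expect_identical(b1$err, b2$err)
  expect_error(bootstrap_uncertainty(const, n_boot = 1), "n_boot")

  # Monte-Carlo comparison: quadrupling samples shrinks the average band
  surf <- reference_surface("harmonic", k_surface = 40)
  small <- sample_window_ladder(surf, z_refs = seq(0, 1, by = 0.1), k = 2000,
                                n_steps = 4e3, seed = 5)
  big <- sample_window_ladder(surf, z_refs = seq(0, 1, by = 0.1), k = 2000,
                              n_steps = 1.6e4, seed = 6)
  e_small <- bootstrap_uncertainty(small, n_boot = 12, seed = 7,
                                   z_range = c(0, 1))$err
  e_big <- bootstrap_uncertainty(big, n_boot = 12, seed = 7,
                                 z_range = c(0, 1))$err
  expect_lt(mean(e_big, na.rm = TRUE), mean(e_small, na.rm = TRUE))
})

test_that("barrier extraction: arithmetic, ties, masked endpoints", {
  z <- seq(0, 4, by = 0.1)
  G <- rep(0, length(z)); G[which.min(abs(z - 1.4))] <- -60; G[1] <- -20
  prof <- free_energy_profile(z, G, anchor = "as_is")
  b <- extract_barriers(prof)
  expect_equal(b$z_min, 1.4)
  expect_equal(b$translocation, 40)
  expect_equal(b$desorption, 60)

  flat <- free_energy_profile(z, rep(0, length(z)), anchor = "as_is")
  bf <- extract_barriers(flat)
  expect_equal(bf$translocation, 0)
  expect_equal(bf$desorption, 0)
  expect_equal(bf$z_min, z[1])            # tie-break: smallest z

  # analytic double well: barriers equal the construction parameters
  surf <- reference_surface("membrane_double_well", D = 40, B = 25)
  ba <- extract_barriers(surface_profile(surf))
  expect_equal(ba$translocation, 25, tolerance = 1e-6)
  expect_equal(ba$desorption, 40, tolerance = 1e-6)

  Gm <- G; Gm[1] <- NA
  expect_error(extract_barriers(free_energy_profile(z, Gm, anchor = "as_is")),
               "masked")
})

test_that("convergence scan: identity range and drift detection", {
  surf <- reference_surface("harmonic", k_surface = 40)
  wins <- sample_window_ladder(surf, z_refs = seq(0, 1, by = 0.1), k = 2000,
                               n_steps = 1e4, seed = 31)
  span <- diff(range(wins[[1]]$times))
  sc <- convergence_scan(wins, "discard_initial", increment = span,
                         z_range = c(0, 1))
  expect_equal(nrow(sc), 1L)
  direct <- extract_barriers(solve_wham(build_histograms(wins,
                                                         z_range = c(0, 1))))
  expect_equal(sc$desorption, direct$desorption, tolerance = 1e-9)

  sc2 <- convergence_scan(wins, "discard_final", increment = span / 4,
                          z_range = c(0, 1))
  expect_gte(nrow(sc2), 3L)
  expect_true(all(diff(sc2$t_end) < 0))
})
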