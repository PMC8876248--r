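test_that("density profile: point mass, symmetrization, mass conservation", {
  # one probe atom of mass m at z0, two lipid atoms bracketing the center
  m <- 100
  xyz <- rbind(c(1, 1, 1.25), c(0, 0, 1.8), c(0, 0, -1.8))
  traj <- tiny_traj(xyz, c("X1", "P", "P"), c("RHD", "POPC", "POPC"),
                    c(1L, 2L, 3L), c(m, 31, 31), box = c(4, 5, 8))
  sel <- selection_spec(list(probe = 1L, lipids = 2:3), 3)
  dp <- density_profile(traj, sel, groups = "probe", bin_width = 0.1)
  occupied <- which(dp$density[, 1] > 0)
  expect_length(occupied, 1)
  expect_equal(unname(dp$density[occupied, 1]),
               m * 1.66054 / (4 * 5 * 0.1))
  expect_equal(dp$z[occupied], 1.25)

  # symmetrize: half-weight peaks at +/- z0
  ds <- density_profile(traj, sel, groups = "probe", bin_width = 0.1,
                        symmetrize = TRUE)
  occ2 <- which(ds$density[, 1] > 0)
  expect_length(occ2, 2)
  expect_equal(ds$z[occ2], c(-1.25, 1.25))
  expect_equal(unname(ds$density[occ2, 1]),
               rep(m * 1.66054 / (4 * 5 * 0.1) / 2, 2))
  # symmetrized profile is exactly even on the grid
  expect_equal(ds$density[, 1], rev(ds$density[, 1]))

  # mass conservation across a random many-atom selection
  spec <- toy_bilayer_spec(n_lipids = 8, n_probes = 2, n_waters = 2)
  tr <- generate_membrane_frames(spec, n_frames = 5, seed = 12)
  sl <- default_selections(tr)
  dp2 <- density_profile(tr, sl, groups = "lipids", bin_width = 0.05)
  recovered <- sum(dp2$density[, 1]) * 0.05 * spec$box[1] * spec$box[2] /
    1.66054
  expect_equal(recovered, sum(tr$atoms$mass[sl$lipids]), tolerance = 1e-9)
})

test_that("average positions fold leaflets and reduce to the COM", {
  xyz <- rbind(c(0, 0, 1.5), c(2, 2, -1.5), c(0, 0, 2.0), c(0, 0, -2.0))
  traj <- tiny_traj(xyz, c("X1", "X1", "P", "P"),
                    c("RHD", "RHD", "POPC", "POPC"),
                    c(1L, 2L, 3L, 4L), c(10, 10, 31, 31))
  sel <- selection_spec(list(probe = 1:2, lipids = 3:4), 4)
  ap <- average_positions(traj, sel, groups = "probe")
  expect_equal(ap$mean, 1.5)
  expect_equal(ap$sd, 0)

  # a polyatomic group's depth is the mass-weighted COM of its members
  xyz2 <- rbind(c(0, 0, 1.0), c(0, 0, 2.0), c(0, 0, 1.6), c(0, 0, -1.6))
  tr2 <- tiny_traj(xyz2, c("X1", "X2", "P", "P"),
                   c("RHD", "RHD", "POPC", "POPC"),
                   c(1L, 1L, 2L, 3L), c(10, 30, 31, 31))
  sel2 <- selection_spec(list(probe = 1:2, lipids = 3:4), 4)
  ap2 <- average_positions(tr2, sel2, groups = "probe")
  expect_equal(ap2$mean, (10 * 1.0 + 30 * 2.0) / 40)
})

test_that("area per lipid arithmetic and fluctuation tracking", {
  frames <- list(list(box = c(8, 8, 7), xyz = matrix(0, 1, 3)))
  traj <- tiny_traj(matrix(0, 1, 3), "P", "POPC", 1L, 31, frames = frames)
  a <- area_per_lipid(traj, 128)
  expect_equal(a$mean, 1.0)
  expect_equal(a$sd, 0)

  # +/-1% box fluctuation propagates to the sd of the area series
  scales <- c(0.99, 1.00, 1.01)
  fl <- lapply(scales, function(s) list(box = c(8 * s, 8 * s, 7),
                                        xyz = matrix(0, 1, 3)))
  traj2 <- tiny_traj(matrix(0, 1, 3), "P", "POPC", 1L, 31, frames = fl)
  a2 <- area_per_lipid(traj2, 128)
  expect_equal(a2$values, 64 * scales^2 / 64)
  expect_equal(a2$sd, sd(scales^2), tolerance = 1e-12)

  expect_error(area_per_lipid(traj, 0), "> 0")
  expect_error(area_per_lipid(traj, 127), "even")
})

test_that("order parameters: closed-form rigid chains and isotropy", {
  # all-trans chain along the bilayer normal: reconstructed C-H vectors are
  # perpendicular to z, so -S_CD = 0.5 for every interior carbon
  tr_z <- chain_traj(zigzag_chain(8, d = c(0, 0, 1), e = c(1, 0, 0)))
  sel <- default_selections(tr_z)
  op <- order_parameters(tr_z, sel)
  expect_equal(nrow(op), 6)               # terminals omitted
  expect_equal(op$minus_S_CD, rep(0.5, 6), tolerance = 1e-9)

  # chain lying in the bilayer plane: geometric oracle gives
  # cos(theta_CH) = +/- sin(54.735 deg), hence -S_CD = -0.5
  tr_x <- chain_traj(zigzag_chain(8, d = c(1, 0, 0), e = c(0, 1, 0)))
  opx <- order_parameters(tr_x, default_selections(tr_x))
  expect_equal(opx$minus_S_CD, rep(-0.5, 6), tolerance = 1e-9)

  # isotropically tumbling chains: S_CD -> 0; values bounded in [-0.5, 1]
  set.seed(42)
  frames <- lapply(1:300, function(i) {
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    perp <- rnorm(3); perp <- perp - sum(perp * axis) * axis
    perp <- perp / sqrt(sum(perp^2))
    ch <- zigzag_chain(8, d = axis, e = perp)
    list(box = c(4, 4, 8), xyz = rbind(ch, c(0, 0, 1.8), c(0, 0, -1.8)))
  })
  tr_i <- chain_traj(zigzag_chain(8))
  tr_i$frames <- frames
  opi <- order_parameters(tr_i, default_selections(tr_i))
  expect_lt(max(abs(opi$minus_S_CD)), 0.06)
  expect_true(all(opi$minus_S_CD >= -1 & opi$minus_S_CD <= 0.5))

  short <- chain_traj(zigzag_chain(2))
  expect_error(order_parameters(short, default_selections(short)), ">= 3")
})

test_that("tilt distributions: trivial axes, isotropy, leaflet symmetry", {
  # one probe with N1 -> N2 along +z in the upper leaflet: theta = 0
  mk_probe <- function(n1, n2, com_z) {
    xyz <- rbind(n1, n2, c(0, 0, 1.8), c(0, 0, -1.8))
    tiny_traj(xyz, c("N1", "N2", "P", "P"),
              c("RHD", "RHD", "POPC", "POPC"),
              c(1L, 1L, 2L, 3L), c(14, 14, 31, 31))
  }
  tr_up <- mk_probe(c(0, 0, 1.0), c(0, 0, 1.8), 1.4)
  sel <- default_selections(tr_up)
  td <- tilt_distribution(tr_up, "xanthene_long", sel)
  expect_equal(td$mean, 0, tolerance = 1e-9)

  tr_pl <- mk_probe(c(0, 0, 1.2), c(0.8, 0, 1.2), 1.2)
  td_pl <- tilt_distribution(tr_pl, "xanthene_long", default_selections(tr_pl))
  expect_equal(td_pl$mean, 90, tolerance = 1e-9)
  # density integrates to one
  expect_equal(sum(td_pl$density) * diff(td_pl$theta[1:2]), 1,
               tolerance = 1e-12)

  # mirror-symmetric orientations across the leaflets: with the
  # leaflet-outward normal convention both probes report the same angle
  # and the distribution is symmetric with mean 90
  spec <- toy_bilayer_spec(n_lipids = 8, n_probes = 2, n_waters = 2,
                           probe_orientation = list(kind = "fixed",
                                                    theta = 90),
                           probe_leaflets = c(1, -1))
  tr_m <- generate_membrane_frames(spec, n_frames = 30, seed = 9)
  td_m <- tilt_distribution(tr_m, "xanthene_long",
                            default_selections(tr_m))
  expect_equal(td_m$mean, 90, tolerance = 1e-6)

  # isotropic orientations: mean 90, <cos theta> ~ 0
  spec_i <- toy_bilayer_spec(n_lipids = 8, n_probes = 4, n_waters = 4,
                             probe_orientation = list(kind = "isotropic"))
  tr_i <- generate_membrane_frames(spec_i, n_frames = 400, seed = 10)
  td_i <- tilt_distribution(tr_i, "xanthene_long",
                            default_selections(tr_i), bins = 18)
  expect_equal(td_i$mean, 90, tolerance = 2.5)
  expect_lt(abs(mean(cos(td_i$samples * pi / 180))), 0.03)
})

test_that("hydrogen bonds: trivial geometries and brute-force equality", {
  # ideal linear bond at 0.28 nm counts once; 0.40 nm does not
  mk <- function(da_dist) {
    xyz <- rbind(c(1, 1, 1), c(1, 1, 1.1), c(1, 1, 1 + da_dist))
    tiny_traj(xyz, c("ND", "HD", "OW"), c("RHD", "RHD", "SOL"),
              c(1L, 1L, 2L), c(14, 1, 16), box = c(3, 3, 3))
  }
  don <- selection_spec(list(probe_N = 1L), 3)
  acc <- selection_spec(list(water = 3L), 3)
  hb1 <- hydrogen_bonds(mk(0.28), don, acc)
  expect_equal(hb1$avg_bonds, 1)
  expect_equal(hb1$partner_class, "water")
  hb0 <- hydrogen_bonds(mk(0.40), don, acc)
  expect_equal(sum(hb0$avg_bonds), 0)

  # donor without hydrogen is an error naming the atom
  bad <- tiny_traj(rbind(c(1, 1, 1), c(1, 1, 1.3)),
                   c("ND", "OW"), c("RHD", "SOL"), c(1L, 2L), c(14, 16),
                   box = c(3, 3, 3))
  expect_error(hydrogen_bonds(bad, selection_spec(list(g = 1L), 2),
                              selection_spec(list(w = 2L), 2)),
               "no attached hydrogen")

  # random dense fixtures: implementation equals the all-pairs oracle
  for (seed in 1:25) {
    tr <- random_hbond_fixture(seed)
    nd <- 12
    don_i <- selection_spec(list(d = 1:nd), nrow(tr$atoms))
    acc_i <- selection_spec(list(a = (2 * nd + 1):nrow(tr$atoms)),
                            nrow(tr$atoms))
    got <- hydrogen_bonds(tr, don_i, acc_i, r_cut = 0.35, angle_cut = 30)
    want <- hbond_oracle(tr$frames[[1]], tr$atoms,
                         data.frame(d = 1:nd, h = nd + (1:nd)),
                         (2 * nd + 1):nrow(tr$atoms), 0.35, 30)
    expect_equal(sum(got$avg_bonds) * nd, want)
  }
})

test_that("local bilayer COM and probe depth series", {
  # flat symmetric bilayer: local reference equals the midplane (and the
  # global COM) wherever the cylinder sits
  nl <- 16
  set.seed(31)
  xy <- cbind(runif(nl, 0, 4), runif(nl, 0, 4))
  lip <- rbind(cbind(xy[1:(nl / 2), ], 1.8), cbind(xy[(nl / 2 + 1):nl, ], -1.8))
  xyz <- rbind(lip, c(2, 2, 1.2))
  traj <- tiny_traj(xyz, c(rep("P", nl), "X1"),
                    c(rep("POPC", nl), "RHD"),
                    c(1:nl, nl + 1L), c(rep(31, nl), 40))
  z_ref <- local_bilayer_com(traj$frames[[1]], traj$atoms, nl + 1L, 1:nl,
                             radius = 10)
  expect_equal(z_ref, 0, tolerance = 1e-12)

  # undulating bilayer: local cylinder tracks the imposed offset, the
  # global COM does not
  off <- function(x) 0.4 * sin(2 * pi * x / 4)
  lip2 <- do.call(rbind, lapply(seq(0.125, 3.875, by = 0.25), function(x) {
    rbind(c(x, 2, off(x) + 1.8), c(x, 2, off(x) - 1.8))
  }))
  n2 <- nrow(lip2)
  xyz2 <- rbind(lip2, c(1, 2, 1.5))   # probe at x = 1: offset 0.4
  tr2 <- tiny_traj(xyz2, c(rep("P", n2), "X1"),
                   c(rep("POPC", n2), "RHD"),
                   c(1:n2, n2 + 1L), c(rep(31, n2), 40))
  local <- local_bilayer_com(tr2$frames[[1]], tr2$atoms, n2 + 1L, 1:n2,
                             radius = 0.3)
  expect_equal(local, off(1), tolerance = 0.02)
  expect_error(local_bilayer_com(tr2$frames[[1]], tr2$atoms, n2 + 1L, 1:n2,
                                 radius = 0.01), "increase radius")

  # static probe above a static flat bilayer: constant depth series
  sel <- selection_spec(list(probe = nl + 1L, lipids = 1:nl),
                        nrow(traj$atoms))
  traj$frames <- rep(traj$frames, 3)
  traj$times <- 0:2
  pds <- probe_depth_series(traj, sel, radius = 10)
  expect_length(pds, 1)
  expect_length(pds[[1]]$z, 3)
  expect_equal(pds[[1]]$z, rep(1.2, 3), tolerance = 1e-12)
})

test_that("descriptors are invariant under in-plane translation", {
  spec <- toy_bilayer_spec(n_lipids = 8, n_probes = 2, n_waters = 2)
  tr <- generate_membrane_frames(spec, n_frames = 4, seed = 13)
  sel <- default_selections(tr)
  shift <- function(traj, dx, dy, wrap) {
    traj$frames <- lapply(traj$frames, function(f) {
      f$xyz[, 1] <- f$xyz[, 1] + dx
      f$xyz[, 2] <- f$xyz[, 2] + dy
      if (wrap) {
        f$xyz[, 1] <- f$xyz[, 1] %% f$box[1]
        f$xyz[, 2] <- f$xyz[, 2] %% f$box[2]
      }
      f
    })
    traj
  }
  tr2 <- shift(tr, 1.7, 2.9, wrap = FALSE)
  expect_equal(average_positions(tr, sel, "probe")$mean,
               average_positions(tr2, sel, "probe")$mean, tolerance = 1e-12)
  expect_equal(order_parameters(tr, sel)$minus_S_CD,
               order_parameters(tr2, sel)$minus_S_CD, tolerance = 1e-12)
  # pairwise distances go through the minimum image, so wrapping across the
  # periodic boundary must not change the hydrogen-bond counts
  tr3 <- shift(tr, 1.7, 2.9, wrap = TRUE)
  don <- selection_spec(list(N1 = get_group(sel, "N1")), nrow(tr$atoms))
  acc <- selection_spec(list(w = get_group(sel, "water")), nrow(tr$atoms))
  expect_equal(hydrogen_bonds(tr, don, acc)$avg_bonds,
               hydrogen_bonds(tr3, don, acc)$avg_bonds)
})
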