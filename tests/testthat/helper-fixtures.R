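# Shared fixtures, all built in code.

# window of iid Gaussian "samples" (no dynamics), unbiased unless k given
gaussian_window <- function(n, mean, sd, k = 0, z_ref = mean, seed = 1) {
  set.seed(seed)
  umbrella_window(times = seq_len(n), z = rnorm(n, mean, sd),
                  bias = bias_spec(z_ref, k))
}

# minimal trajectory: one frame, explicit atoms/coordinates
tiny_traj <- function(xyz, names, resnames, resids, masses,
                      box = c(4, 4, 8), times = NULL, frames = NULL) {
  atoms <- data.frame(name = names, resname = resnames, resid = resids,
                      mass = masses, stringsAsFactors = FALSE)
  if (is.null(frames)) frames <- list(list(box = box, xyz = xyz))
  md_trajectory(atoms, frames, times)
}

# all-trans zigzag acyl chain: n carbons, director d (unit), zigzag offset
# perpendicular; bond geometry of a tetrahedral chain
zigzag_chain <- function(n = 8, d = c(0, 0, 1), e = c(1, 0, 0),
                         start = c(0, 0, 0)) {
  t(vapply(seq_len(n), function(j) {
    start + (j - 1) * 0.127 * d + ((-1)^j) * 0.0436 * e
  }, numeric(3)))
}

# trajectory holding a single lipid chain plus two dummy "lipids" bracketing
# z = 0 so the bilayer center is well defined
chain_traj <- function(chain_xyz) {
  n <- nrow(chain_xyz)
  xyz <- rbind(chain_xyz, c(0, 0, 1.8), c(0, 0, -1.8))
  tiny_traj(xyz,
            names = c(paste0("C", seq_len(n) + 1L), "P", "P"),
            resnames = c(rep("POPC", n), "POPC", "POPC"),
            resids = c(rep(1L, n), 2L, 3L),
            masses = c(rep(14, n), 31, 31))
}

# brute-force all-pairs hydrogen bond oracle (naive nested loops).
# donors: data.frame(d = heavy atom index, h = hydrogen index)
hbond_oracle <- function(frame, atoms, donors, acceptor_idx, r_cut, angle_cut) {
  total <- 0L
  box <- frame$box
  mi <- function(v) v - box * round(v / box)
  for (r in seq_len(nrow(donors))) {
    d <- donors$d[r]; h <- donors$h[r]
    best <- NA; best_dist <- Inf
    for (a in acceptor_idx) {
      if (atoms$resid[a] == atoms$resid[d]) next
      dv <- mi(frame$xyz[a, ] - frame$xyz[d, ])
      dist <- sqrt(sum(dv^2))
      if (dist > r_cut || dist < 1e-9) next
      hv <- mi(frame$xyz[h, ] - frame$xyz[d, ])
      ang <- acos(max(-1, min(1, sum(dv * hv) /
                                (dist * sqrt(sum(hv^2)))))) * 180 / pi
      if (ang > angle_cut) next
      if (dist < best_dist) { best <- a; best_dist <- dist }
    }
    if (!is.na(best)) total <- total + 1L
  }
  total
}

# random donor/acceptor fixture for the hydrogen-bond equivalence tests
random_hbond_fixture <- function(seed, n_donors = 12, n_acceptors = 25,
                                 box = c(2.5, 2.5, 2.5)) {
  set.seed(seed)
  nd <- n_donors; na <- n_acceptors
  d_pos <- cbind(runif(nd) * box[1], runif(nd) * box[2], runif(nd) * box[3])
  # attach H at 0.1 nm in a random direction
  dir <- matrix(rnorm(nd * 3), nd)
  dir <- dir / sqrt(rowSums(dir^2))
  h_pos <- d_pos + 0.1 * dir
  a_pos <- cbind(runif(na) * box[1], runif(na) * box[2], runif(na) * box[3])
  xyz <- rbind(d_pos, h_pos, a_pos)
  atoms <- data.frame(
    name = c(rep("ND", nd), rep("HD", nd), rep("OA", na)),
    resname = c(rep("RHD", 2 * nd), rep("POPC", na)),
    resid = c(seq_len(nd), seq_len(nd), nd + seq_len(na)),
    mass = c(rep(14, nd), rep(1, nd), rep(16, na)),
    stringsAsFactors = FALSE)
  md_trajectory(atoms, list(list(box = box, xyz = xyz)))
}
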