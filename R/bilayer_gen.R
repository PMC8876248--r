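#' Toy bilayer + probe specification
#'
#' Describes the synthetic bilayer/probe system the frame generator draws
#' from: pseudo-atoms with realistic names and masses but no bonded physics,
#' since the structural descriptors only need geometry. Defaults emulate a
#' 128-POPC bilayer carrying 4 probe molecules: headgroup phosphate at
#' (1.88 +/- 0.10) nm, probe center of mass at (1.5 +/- 0.4) nm per leaflet.
#'
#' @param box Box edges (Lx, Ly, Lz) in nm, all > 0.
#' @param n_lipids Even lipid count (two leaflets).
#' @param n_probes Probe molecule count.
#' @param lipid_depths Named list of per-atom depth (mean, sd) in nm for the
#'   headgroup atoms `P`, `N`, `O8`, `O9`, `O12`, `O14`.
#' @param chain_start Depth (nm) of the first acyl carbon.
#' @param chain_tilt_sd SD (degrees) of the acyl-chain director tilt about
#'   the inward bilayer normal.
#' @param pn_tilt `c(mean, sd)` in degrees for the P-N vector tilt relative
#'   to the outward leaflet normal.
#' @param probe_depth `c(mean, sd)` in nm for the probe COM depth (per
#'   leaflet).
#' @param probe_orientation Orientation law of the probe long axis relative
#'   to the outward leaflet normal: `list(kind = "isotropic")`,
#'   `list(kind = "fixed", theta = 90)` or
#'   `list(kind = "gaussian", mean = 90, sd = 15)` (degrees).
#' @param probe_leaflets `"alternate"` (default), `"upper"`, `"lower"`, or
#'   an explicit vector of +1/-1 per probe. How probes distribute between
#'   leaflets is exposed as a parameter because it is a free design choice
#'   of the emulated systems.
#' @param hbond_rate Probability, per probe and frame, that a contact water
#'   is placed at ideal hydrogen-bond geometry on the probe's N1-H donor.
#' @param n_waters Number of water molecules in the water slab (>=
#'   `n_probes`; the first `n_probes` double as H-bond contact waters).
#' @return Object of class `toy_bilayer_spec`.
#' @export
toy_bilayer_spec <- function(box = c(6.4, 6.4, 7.0),
                             n_lipids = 128,
                             n_probes = 4,
                             lipid_depths = list(
                               N = c(2.00, 0.10), P = c(1.88, 0.10),
                               O8 = c(1.85, 0.10), O9 = c(1.85, 0.10),
                               O12 = c(1.60, 0.10), O14 = c(1.58, 0.10)),
                             chain_start = 1.45,
                             chain_tilt_sd = 25,
                             pn_tilt = c(76, 20),
                             probe_depth = c(1.5, 0.4),
                             probe_orientation = list(kind = "gaussian",
                                                      mean = 90, sd = 15),
                             probe_leaflets = "alternate",
                             hbond_rate = 0.5,
                             n_waters = 20) {
  stopifnot(length(box) == 3L, all(box > 0))
  if (n_lipids %% 2 != 0) stop("n_lipids must be even (two leaflets)")
  sds <- c(vapply(lipid_depths, `[`, 0, 2), pn_tilt[2], probe_depth[2],
           chain_tilt_sd)
  if (any(sds < 0)) stop("all sds must be >= 0")
  stopifnot(n_probes >= 0, hbond_rate >= 0, hbond_rate <= 1,
            n_waters >= n_probes)
  structure(list(box = box, n_lipids = n_lipids, n_probes = n_probes,
                 lipid_depths = lipid_depths, chain_start = chain_start,
                 chain_tilt_sd = chain_tilt_sd, pn_tilt = pn_tilt,
                 probe_depth = probe_depth,
                 probe_orientation = probe_orientation,
                 probe_leaflets = probe_leaflets,
                 hbond_rate = hbond_rate, n_waters = n_waters),
            class = "toy_bilayer_spec")
}

.CHAIN_CARBONS <- paste0("C", 2:16)

## atom table of one toy lipid: headgroup + sn-1 chain pseudo-atoms
.lipid_atoms <- function() {
  data.frame(
    name = c("N", "P", "O8", "O9", "O12", "O14", .CHAIN_CARBONS),
    mass = c(14.007, 30.974, rep(15.999, 4),
             rep(14.027, 14), 15.035),   # united-atom CH2 / terminal CH3
    stringsAsFactors = FALSE)
}

## probe template in local coordinates: long axis u = x, short axis v = y.
## N1/N2 terminate the long (amino-bearing) axis; X* are xanthene ring
## dummies; B* benzoic ring dummies (COM offset along +v); E1 ester/COO;
## HN1/HN2 explicit donor hydrogens.
.probe_template <- function() {
  pos <- rbind(
    N1  = c(-0.62, 0, 0),
    N2  = c( 0.62, 0, 0),
    HN1 = c(-0.72, 0, 0),
    HN2 = c( 0.72, 0, 0),
    X1  = c(-0.35, 0, 0),
    X2  = c(-0.12, 0, 0),
    X3  = c( 0.12, 0, 0),
    X4  = c( 0.35, 0, 0),
    B1  = c( 0.00, 0.30, 0),
    B2  = c( 0.08, 0.42, 0),
    B3  = c(-0.08, 0.42, 0),
    E1  = c( 0.00, 0.55, 0))
  mass <- c(N1 = 14.007, N2 = 14.007, HN1 = 1.008, HN2 = 1.008,
            X1 = 40, X2 = 40, X3 = 40, X4 = 40,
            B1 = 26, B2 = 26, B3 = 26, E1 = 44)
  list(pos = pos, mass = mass)
}

## random unit vector with polar angle theta (deg) about axis `n` (unit)
.tilted_unit <- function(theta_deg, n, phi = runif(1, 0, 2 * pi)) {
  th <- theta_deg * pi / 180
  # orthonormal frame around n
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  cos(th) * n + sin(th) * (cos(phi) * e1 + sin(phi) * e2)
}

.draw_theta <- function(law) {
  switch(law$kind,
         fixed = law$theta,
         gaussian = {
           th <- rnorm(1, law$mean, law$sd)
           while (th < 0 || th > 180) th <- rnorm(1, law$mean, law$sd)
           th
         },
         isotropic = acos(runif(1, -1, 1)) * 180 / pi,
         stop("unknown orientation kind '", law$kind, "'"))
}

#' Generate toy bilayer + probe frames
#'
#' Draws `n_frames` independent frames from a [toy_bilayer_spec()]: lipid
#' pseudo-atoms (headgroup P/N/oxygens at Gaussian depths, an all-trans
#' zigzag sn-1 chain C2...C16 along a tilted director), probe
#' pseudo-molecules (rigid template placed at the spec's depth and long-axis
#' orientation law) and a water slab whose first `n_probes` molecules double
#' as hydrogen-bond contact partners, placed at ideal donor geometry with
#' probability `hbond_rate`. Atom identity and count are constant across
#' frames. Probe depths beyond the box are wrapped by the periodic
#' convention with a warning.
#'
#' @param spec A [toy_bilayer_spec()].
#' @param n_frames Frame count (0 gives an empty, valid trajectory).
#' @param seed Integer seed; frames are deterministic given the seed.
#' @param dt Frame spacing in ps (metadata).
#' @return An [md_trajectory()].
#' @export
generate_membrane_frames <- function(spec, n_frames, seed = 1L, dt = 10) {
  stopifnot(inherits(spec, "toy_bilayer_spec"), n_frames >= 0)
  set.seed(as.integer(seed))
  lat <- .lipid_atoms()
  tmpl <- .probe_template()
  nl <- spec$n_lipids
  np <- spec$n_probes
  nw <- spec$n_waters

  atoms <- list()
  for (i in seq_len(nl)) {
    atoms[[length(atoms) + 1L]] <-
      data.frame(name = lat$name, resname = "POPC", resid = as.integer(i),
                 mass = lat$mass, stringsAsFactors = FALSE)
  }
  for (p in seq_len(np)) {
    atoms[[length(atoms) + 1L]] <-
      data.frame(name = rownames(tmpl$pos), resname = "RHD",
                 resid = as.integer(nl + p),
                 mass = unname(tmpl$mass), stringsAsFactors = FALSE)
  }
  for (w in seq_len(nw)) {
    atoms[[length(atoms) + 1L]] <-
      data.frame(name = c("OW", "HW1", "HW2"), resname = "SOL",
                 resid = as.integer(nl + np + w),
                 mass = c(15.999, 1.008, 1.008),
                 stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms)
  natoms <- nrow(atoms)

  leaflet_lipid <- rep(c(1, -1), each = nl / 2)
  leaflet_probe <- switch(
    as.character(spec$probe_leaflets[1]),
    alternate = rep_len(c(1, -1), np),
    upper = rep(1, np),
    lower = rep(-1, np),
    { stopifnot(length(spec$probe_leaflets) == np)
      as.numeric(spec$probe_leaflets) })

  box <- spec$box
  wrapped <- FALSE
  frames <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    xyz <- matrix(0, natoms, 3)
    row <- 0L
    for (i in seq_len(nl)) {
      s <- leaflet_lipid[i]
      xy <- runif(2) * box[1:2]
      hg <- vapply(spec$lipid_depths, function(ms) rnorm(1, ms[1], ms[2]), 0)
      # P sets the anchor; N placed on the P-N vector at the drawn tilt
      pz <- hg[["P"]] * s
      ppos <- c(xy, pz)
      pn_theta <- .draw_theta(list(kind = "gaussian",
                                   mean = spec$pn_tilt[1],
                                   sd = spec$pn_tilt[2]))
      npos <- ppos + 0.45 * .tilted_unit(pn_theta, c(0, 0, s))
      atpos <- rbind(
        N = npos, P = ppos,
        O8 = c(xy + rnorm(2, 0, 0.05), s * hg[["O8"]]),
        O9 = c(xy + rnorm(2, 0, 0.05), s * hg[["O9"]]),
        O12 = c(xy + rnorm(2, 0, 0.05), s * hg[["O12"]]),
        O14 = c(xy + rnorm(2, 0, 0.05), s * hg[["O14"]]))
      # all-trans zigzag chain along a director tilted about the inward normal
      alpha <- abs(rnorm(1, 0, spec$chain_tilt_sd))
      d <- .tilted_unit(alpha, c(0, 0, -s))
      e2 <- .tilted_unit(90, d)
      start <- c(xy, s * spec$chain_start)
      ch <- t(vapply(seq_along(.CHAIN_CARBONS), function(j) {
        start + (j - 1) * 0.127 * d + ((-1)^j) * 0.0436 * e2
      }, numeric(3)))
      xyz[row + seq_len(nrow(atpos) + nrow(ch)), ] <- rbind(atpos, ch)
      row <- row + nrow(atpos) + nrow(ch)
    }
    probe_anchor <- matrix(0, max(np, 1L), 3)  # N1-H tip, for contact waters
    probe_udir <- matrix(0, max(np, 1L), 3)
    for (p in seq_len(np)) {
      s <- leaflet_probe[p]
      depth <- rnorm(1, spec$probe_depth[1], spec$probe_depth[2])
      zc <- s * depth
      if (abs(zc) > box[3] / 2) {
        zc <- zc - box[3] * round(zc / box[3])
        wrapped <- TRUE
      }
      comp <- c(runif(2) * box[1:2], zc)
      theta <- .draw_theta(spec$probe_orientation)
      u <- .tilted_unit(theta, c(0, 0, s))
      v <- .tilted_unit(90, u)
      wv <- c(u[2] * v[3] - u[3] * v[2],
              u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
      Rm <- cbind(u, v, wv)
      local <- tmpl$pos %*% t(Rm)
      com_local <- colSums(local * tmpl$mass) / sum(tmpl$mass)
      pos <- sweep(local, 2, com_local) + rep(comp, each = nrow(local))
      xyz[row + seq_len(nrow(pos)), ] <- pos
      row <- row + nrow(pos)
      probe_anchor[p, ] <- pos[rownames(tmpl$pos) == "HN1", ]
      probe_udir[p, ] <- -u    # N1-H points along -u from N1
    }
    for (w in seq_len(nw)) {
      bonded <- w <= np && runif(1) < spec$hbond_rate
      if (bonded) {
        ow <- probe_anchor[w, ] + 0.18 * probe_udir[w, ]
      } else {
        zw <- sample(c(-1, 1), 1) *
          runif(1, min(2.6, box[3] / 2 - 0.3), box[3] / 2)
        ow <- c(runif(2) * box[1:2], zw)
      }
      hw1 <- ow + 0.1 * .tilted_unit(acos(runif(1, -1, 1)) * 180 / pi,
                                     c(0, 0, 1))
      hw2 <- ow + 0.1 * .tilted_unit(acos(runif(1, -1, 1)) * 180 / pi,
                                     c(0, 0, 1))
      xyz[row + 1:3, ] <- rbind(ow, hw1, hw2)
      row <- row + 3L
    }
    frames[[fr]] <- list(box = box, xyz = xyz)
  }
  if (wrapped) warning("probe depth beyond box: wrapped by periodic convention")
  md_trajectory(atoms, frames, times = (seq_len(n_frames) - 1) * dt)
}
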