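#' Mass density profile along the bilayer normal
#'
#' Per frame, depths are re-centered on the lipid center of mass (z = 0 at
#' the bilayer center), atom masses are histogrammed and divided by the bin
#' volume (box area x bin width), then averaged over frames. Optionally the
#' profile is symmetrized, rho(z) <- (rho(z) + rho(-z))/2, and a scale
#' factor applied (probe profiles are conventionally magnified for display
#' next to the lipid profile).
#'
#' @param traj An `md_trajectory`.
#' @param sel A `selection_spec`; `groups` names the selections profiled.
#' @param groups Character vector of group names (default all groups).
#' @param bin_width nm (default 0.1).
#' @param symmetrize Logical (default FALSE).
#' @param scale Multiplicative factor applied to the densities (default 1).
#' @param center_group Group defining the bilayer center (default
#'   `"lipids"`).
#' @param z_range Profile extent (default symmetric, half the smallest box
#'   height).
#' @return Object of class `density_profile`: `z` (bin centers), `density`
#'   (bins x groups, kg/m^3 before `scale`), `symmetrized`, `scale`.
#' @export
density_profile <- function(traj, sel, groups = names(sel), bin_width = 0.1,
                            symmetrize = FALSE, scale = 1,
                            center_group = "lipids", z_range = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(sel, "selection_spec"),
            bin_width > 0, length(traj$frames) >= 1L)
  if (any(vapply(traj$frames, function(f) any(f$box <= 0), TRUE))) {
    stop("zero-thickness box")
  }
  cen_idx <- get_group(sel, center_group)
  mass <- traj$atoms$mass
  if (is.null(z_range)) {
    h <- min(vapply(traj$frames, function(f) f$box[3], 0)) / 2
    z_range <- c(-h, h)
  }
  half <- max(abs(z_range))
  edges <- seq(-half, half, by = bin_width)   # symmetric grid about 0
  if (edges[length(edges)] < half - 1e-12) edges <- c(edges, half)
  nb <- length(edges) - 1L
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- matrix(0, nb, length(groups), dimnames = list(NULL, groups))
  nf <- length(traj$frames)
  for (f in traj$frames) {
    z0 <- .com(f$xyz, mass, cen_idx)[3]
    area <- f$box[1] * f$box[2]
    for (g in seq_along(groups)) {
      idx <- get_group(sel, groups[g])
      zz <- f$xyz[idx, 3] - z0
      bin <- findInterval(zz, edges, rightmost.closed = TRUE)
      ok <- bin >= 1L & bin <= nb
      # amu/nm^3 -> kg/m^3 : 1 amu/nm^3 = 1.66054 kg/m^3
      add <- tapply(mass[idx][ok], factor(bin[ok], levels = seq_len(nb)),
                    sum, default = 0)
      dens[, g] <- dens[, g] + as.numeric(add) * 1.66054 /
        (area * bin_width)
    }
  }
  dens <- dens / nf
  if (symmetrize) dens <- (dens + dens[rev(seq_len(nb)), , drop = FALSE]) / 2
  structure(list(z = mid, density = dens * scale, symmetrized = symmetrize,
                 scale = scale, bin_width = bin_width),
            class = "density_profile")
}

#' Average transverse positions of atom groups
#'
#' Per group and molecule, the center-of-mass depth relative to the bilayer
#' center, folded by absolute value so the two leaflets merge (reported
#' depths are single positive numbers); mean and sd are taken over frames
#' and molecules.
#'
#' @param traj An `md_trajectory`.
#' @param sel A `selection_spec`.
#' @param groups Group names (default all except the centering group).
#' @param center_group Bilayer-center selection (default `"lipids"`).
#' @return data.frame with `group`, `mean`, `sd`, `n` (molecule-frame
#'   observations).
#' @export
average_positions <- function(traj, sel, groups = NULL,
                              center_group = "lipids") {
  stopifnot(inherits(traj, "md_trajectory"), inherits(sel, "selection_spec"))
  if (is.null(groups)) groups <- setdiff(names(sel), center_group)
  cen_idx <- get_group(sel, center_group)
  mass <- traj$atoms$mass
  resid <- traj$atoms$resid
  rows <- lapply(groups, function(g) {
    idx <- get_group(sel, g)
    bymol <- split(idx, resid[idx])
    vals <- unlist(lapply(traj$frames, function(f) {
      z0 <- .com(f$xyz, mass, cen_idx)[3]
      vapply(bymol, function(m) abs(.com(f$xyz, mass, m)[3] - z0), 0)
    }), use.names = FALSE)
    data.frame(group = g, mean = mean(vals), sd = sd(vals),
               n = length(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Area per lipid
#'
#' Per frame, the in-plane box area divided by the lipids per leaflet,
#' Lx * Ly / (n_lipids / 2); reported as time mean and sd.
#'
#' @param traj An `md_trajectory`.
#' @param n_lipids Total (even) lipid count.
#' @return List with `mean`, `sd` (nm^2) and per-frame `values`.
#' @export
area_per_lipid <- function(traj, n_lipids) {
  if (n_lipids <= 0) stop("n_lipids must be > 0")
  if (n_lipids %% 2 != 0) stop("n_lipids must be even (two leaflets)")
  a <- vapply(traj$frames, function(f) f$box[1] * f$box[2] / (n_lipids / 2), 0)
  list(mean = mean(a), sd = if (length(a) > 1) sd(a) else 0, values = a)
}

.TETRA <- 54.735610317245346 * pi / 180   # half the tetrahedral H-C-H angle

#' Deuterium order parameter profile (united-atom reconstruction)
#'
#' For each interior chain carbon i the two C-H directions are rebuilt from
#' the backbone geometry (united-atom force fields carry no aliphatic
#' hydrogens): with unit bond vectors a1 = C(i)->C(i-1) and
#' a2 = C(i)->C(i+1), the H's lie in the plane spanned by the inverted
#' bisector -s (s = unit(a1+a2)) and the backbone-plane normal
#' w = unit(a1 x a2), at the tetrahedral half-angle:
#' h+/- = -cos(54.74) s +/- sin(54.74) w. Then
#' S_CD = <(3 cos^2 theta_CH - 1)/2> over molecules, frames and both H's,
#' with theta_CH measured against the bilayer normal (z); the profile is
#' reported as -S_CD per carbon index. Terminal carbons (no two neighbors)
#' are omitted.
#'
#' @param traj An `md_trajectory`.
#' @param sel A `selection_spec` with a `chain` group of carbons named
#'   `C<n>`; carbons are ordered by `n` within each lipid.
#' @param chain_group Group name (default `"chain"`).
#' @return Object of class `order_parameter_profile`: data.frame `carbon`
#'   (index n), `minus_S_CD`; attribute `chain = "sn-1"`.
#' @export
order_parameters <- function(traj, sel, chain_group = "chain") {
  idx <- get_group(sel, chain_group)
  at <- traj$atoms
  num <- as.integer(sub("^C", "", at$name[idx]))
  bymol <- split(data.frame(idx = idx, num = num),
                 at$resid[idx])
  if (min(vapply(bymol, nrow, 0L)) < 3) {
    stop("chain needs >= 3 carbons (interior carbons require both neighbors)")
  }
  acc <- list()
  for (f in traj$frames) {
    for (m in bymol) {
      m <- m[order(m$num), ]
      xyz <- f$xyz[m$idx, , drop = FALSE]
      for (i in 2:(nrow(m) - 1L)) {
        a1 <- xyz[i - 1, ] - xyz[i, ]
        a2 <- xyz[i + 1, ] - xyz[i, ]
        a1 <- a1 / sqrt(sum(a1^2))
        a2 <- a2 / sqrt(sum(a2^2))
        s <- a1 + a2
        ns <- sqrt(sum(s^2))
        w <- c(a1[2] * a2[3] - a1[3] * a2[2],
               a1[3] * a2[1] - a1[1] * a2[3],
               a1[1] * a2[2] - a1[2] * a2[1])
        nw <- sqrt(sum(w^2))
        if (ns < 1e-8 || nw < 1e-8) next   # collinear backbone: undefined
        s <- s / ns; w <- w / nw
        hz <- c(-cos(.TETRA) * s[3] + sin(.TETRA) * w[3],
                -cos(.TETRA) * s[3] - sin(.TETRA) * w[3])
        key <- as.character(m$num[i])
        acc[[key]] <- c(acc[[key]], (3 * hz^2 - 1) / 2)
      }
    }
  }
  carbons <- sort(as.integer(names(acc)))
  scd <- vapply(as.character(carbons), function(k) mean(acc[[k]]), 0)
  out <- data.frame(carbon = carbons, minus_S_CD = -unname(scd))
  attr(out, "chain") <- "sn-1"
  class(out) <- c("order_parameter_profile", "data.frame")
  out
}

#' Axis tilt distribution relative to the bilayer normal
#'
#' Computes, per molecule and frame, the angle between a molecular axis and
#' the outward normal of the molecule's leaflet (+z for the upper leaflet,
#' -z for the lower; for a symmetric bilayer this makes the distribution of
#' a symmetric probe peak at 90 degrees; set `normal = "z"` for the raw +z
#' convention). Axes:
#'
#' * `"xanthene_long"`: N1 -> N2, the vector through the two amino-bearing
#'   ring termini.
#' * `"xanthene_short"`: COM(xanthene) -> COM(benzoic ring).
#' * `"PN"`: lipid P -> N headgroup vector.
#'
#' @param traj An `md_trajectory`.
#' @param axis One of the three axis labels.
#' @param sel A `selection_spec` with the needed groups.
#' @param bins Histogram bin count over \[0, 180\] degrees (default 36).
#' @param normal `"leaflet"` (default) or `"z"`.
#' @param center_group Bilayer-center selection (default `"lipids"`).
#' @return Object of class `tilt_distribution`: `theta` (bin centers,
#'   degrees), `density` (integrates to 1 over degrees), `mean`,
#'   `axis`, `samples` (all angles).
#' @export
tilt_distribution <- function(traj, axis = c("xanthene_long",
                                             "xanthene_short", "PN"),
                              sel, bins = 36, normal = c("leaflet", "z"),
                              center_group = "lipids") {
  axis <- match.arg(axis)
  normal <- match.arg(normal)
  stopifnot(bins >= 2)
  at <- traj$atoms
  mass <- at$mass
  cen_idx <- get_group(sel, center_group)
  vec_fun <- switch(axis,
    xanthene_long = {
      n1 <- get_group(sel, "N1"); n2 <- get_group(sel, "N2")
      mols <- intersect(at$resid[n1], at$resid[n2])
      function(f, r) {
        f$xyz[n2[at$resid[n2] == r], ] - f$xyz[n1[at$resid[n1] == r], ]
      }
    },
    xanthene_short = {
      xa <- get_group(sel, "xanthene"); bz <- get_group(sel, "benzoic_ring")
      mols <- intersect(at$resid[xa], at$resid[bz])
      function(f, r) {
        .com(f$xyz, mass, bz[at$resid[bz] == r]) -
          .com(f$xyz, mass, xa[at$resid[xa] == r])
      }
    },
    PN = {
      pp <- get_group(sel, "P"); nn <- get_group(sel, "N")
      mols <- intersect(at$resid[pp], at$resid[nn])
      function(f, r) {
        f$xyz[nn[at$resid[nn] == r], ] - f$xyz[pp[at$resid[pp] == r], ]
      }
    })
  mol_group <- switch(axis, PN = get_group(sel, "lipids"),
                      get_group(sel, "probe"))
  ang <- numeric(0)
  skipped <- 0L
  for (f in traj$frames) {
    z0 <- .com(f$xyz, mass, cen_idx)[3]
    for (r in mols) {
      v <- as.numeric(vec_fun(f, r))
      nv <- sqrt(sum(v^2))
      if (nv < 1e-10) { skipped <- skipped + 1L; next }
      sgn <- if (normal == "leaflet") {
        midx <- mol_group[at$resid[mol_group] == r]
        sign(.com(f$xyz, mass, midx)[3] - z0)
      } else 1
      if (sgn == 0) sgn <- 1
      ct <- max(-1, min(1, v[3] * sgn / nv))
      ang <- c(ang, acos(ct) * 180 / pi)
    }
  }
  if (skipped > 0) warning(skipped, " zero-length axis vectors skipped")
  if (length(ang) == 0L) stop("no angles computed")
  edges <- seq(0, 180, length.out = bins + 1L)
  h <- tabulate(findInterval(ang, edges, rightmost.closed = TRUE),
                nbins = bins)
  dens <- h / (sum(h) * diff(edges)[1])
  structure(list(theta = (edges[-1] + edges[-length(edges)]) / 2,
                 density = dens, mean = mean(ang), axis = axis,
                 samples = ang),
            class = "tilt_distribution")
}

#' Geometric hydrogen-bond counts
#'
#' A hydrogen bond is counted when the donor-acceptor distance (minimum
#' image) is <= `r_cut` and the H-donor-acceptor angle is <= `angle_cut`
#' (GROMACS-style defaults 0.35 nm, 30 degrees). Hydrogens are attached to
#' each declared donor heavy atom by proximity in the first frame
#' (<= 0.12 nm, names starting with "H"); a donor without hydrogens is an
#' error. Each donor H binds at most one acceptor per frame (the closest
#' qualifying one). Intramolecular pairs (same residue) are excluded.
#' Partners are classed by the acceptor's atom name for lipid oxygens
#' (O8/O9/O12/O14), `"water"` for solvent and `"other_probe"` for other
#' probe molecules.
#'
#' @param traj An `md_trajectory`.
#' @param donors A `selection_spec` whose groups list donor heavy atoms.
#' @param acceptors A `selection_spec` whose groups list acceptor atoms.
#' @param r_cut nm (default 0.35).
#' @param angle_cut Degrees (default 30).
#' @return Object of class `hbond_summary`: data.frame `donor_group`,
#'   `partner_class`, `avg_bonds` (mean instantaneous bonds per frame,
#'   divided by the number of donor atoms in the group); attribute
#'   `"per_frame"` holds total counts per frame and group.
#' @export
hydrogen_bonds <- function(traj, donors, acceptors, r_cut = 0.35,
                           angle_cut = 30) {
  stopifnot(r_cut > 0, angle_cut > 0)
  at <- traj$atoms
  f1 <- traj$frames[[1]]
  is_h <- grepl("^H", at$name)
  h_of <- function(d) {
    cand <- which(is_h & at$resid == at$resid[d])
    if (length(cand) == 0L) return(integer(0))
    dd <- sqrt(colSums((t(f1$xyz[cand, , drop = FALSE]) - f1$xyz[d, ])^2))
    cand[dd <= 0.12]
  }
  acc_idx <- sort(unique(unlist(unclass(acceptors), use.names = FALSE)))
  acc_class <- ifelse(at$resname[acc_idx] == "SOL", "water",
               ifelse(at$resname[acc_idx] == "RHD", "other_probe",
                      at$name[acc_idx]))
  cosc <- cos(angle_cut * pi / 180)
  res <- list()
  per_frame <- list()
  for (gname in names(donors)) {
    dset <- donors[[gname]]
    hmap <- lapply(dset, h_of)
    bad <- vapply(hmap, length, 0L) == 0L
    if (any(bad)) {
      stop("donor atom ", at$name[dset[bad][1]], " (residue ",
           at$resid[dset[bad][1]], ") has no attached hydrogen")
    }
    counts_class <- setNames(numeric(0), character(0))
    tot_frames <- numeric(length(traj$frames))
    for (fi in seq_along(traj$frames)) {
      f <- traj$frames[[fi]]
      for (di in seq_along(dset)) {
        d <- dset[di]
        ok_acc <- acc_idx[at$resid[acc_idx] != at$resid[d]]
        if (length(ok_acc) == 0L) next
        dv <- t(f$xyz[ok_acc, , drop = FALSE]) - f$xyz[d, ]
        dv <- dv - f$box * round(dv / f$box)   # min image, columnwise
        dist <- sqrt(colSums(dv^2))
        near <- which(dist <= r_cut & dist > 1e-9)
        if (length(near) == 0L) next
        for (h in hmap[[di]]) {
          hv <- .min_image(f$xyz[h, ] - f$xyz[d, ], f$box)
          hvn <- hv / sqrt(sum(hv^2))
          ca <- colSums(dv[, near, drop = FALSE] * hvn) / dist[near]
          hit <- near[ca >= cosc]
          if (length(hit) == 0L) next
          best <- hit[which.min(dist[hit])]   # uniqueness: one bond per H
          cls <- acc_class[match(ok_acc[best], acc_idx)]
          counts_class[cls] <- (if (is.na(counts_class[cls])) 0
                                else counts_class[cls]) + 1
          tot_frames[fi] <- tot_frames[fi] + 1
        }
      }
    }
    nf <- length(traj$frames)
    nd <- length(dset)
    if (length(counts_class)) {
      res[[gname]] <- data.frame(donor_group = gname,
                                 partner_class = names(counts_class),
                                 avg_bonds = as.numeric(counts_class) /
                                   (nf * nd),
                                 stringsAsFactors = FALSE)
    } else {
      res[[gname]] <- data.frame(donor_group = gname,
                                 partner_class = NA_character_,
                                 avg_bonds = 0, stringsAsFactors = FALSE)
    }
    per_frame[[gname]] <- tot_frames
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "per_frame") <- per_frame
  class(out) <- c("hbond_summary", "data.frame")
  out
}

#' Local-cylinder bilayer center of mass
#'
#' The depth reference of the umbrella-sampling reaction coordinate: the
#' center of mass (z) of only those lipids whose in-plane COM lies within
#' `radius` (minimum image) of the probe's in-plane COM. Using a local
#' reference makes the coordinate insensitive to bilayer undulations far
#' from the probe.
#'
#' @param frame A single frame (list with `box`, `xyz`).
#' @param atoms Atom table of the trajectory.
#' @param probe_idx Atom indices of the probe molecule.
#' @param lipid_idx Atom indices of the lipids.
#' @param radius Cylinder radius in nm (default 1.1).
#' @return The local bilayer COM z (nm).
#' @export
local_bilayer_com <- function(frame, atoms, probe_idx, lipid_idx,
                              radius = 1.1) {
  stopifnot(radius > 0)
  mass <- atoms$mass
  pxy <- .com(frame$xyz, mass, probe_idx)[1:2]
  bymol <- split(lipid_idx, atoms$resid[lipid_idx])
  sel <- unlist(lapply(bymol, function(m) {
    lxy <- .com(frame$xyz, mass, m)[1:2]
    d <- .min_image(lxy - pxy, frame$box[1:2])
    if (sqrt(sum(d^2)) <= radius) m else NULL
  }), use.names = FALSE)
  if (length(sel) == 0L) {
    stop("no lipid inside the ", radius, " nm cylinder; increase radius")
  }
  .com(frame$xyz, mass, sel)[3]
}

#' Probe depth time series (umbrella-style reaction coordinate)
#'
#' Per probe molecule and frame, the probe COM z minus the local-cylinder
#' bilayer COM z - the reaction coordinate of the umbrella-sampling
#' analysis - emitted as unbiased [umbrella_window()] series (k = 0).
#'
#' @param traj An `md_trajectory`.
#' @param sel A `selection_spec` with `probe` and `lipids` groups.
#' @param radius Cylinder radius (default 1.1 nm).
#' @return Named list of `umbrella_window` (one per probe residue).
#' @export
probe_depth_series <- function(traj, sel, radius = 1.1) {
  at <- traj$atoms
  probes <- split(get_group(sel, "probe"), at$resid[get_group(sel, "probe")])
  lip <- get_group(sel, "lipids")
  lapply(probes, function(pidx) {
    z <- vapply(traj$frames, function(f) {
      .com(f$xyz, at$mass, pidx)[3] -
        local_bilayer_com(f, at, pidx, lip, radius)
    }, 0)
    umbrella_window(times = traj$times, z = z, bias = bias_spec(0, 0))
  })
}
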