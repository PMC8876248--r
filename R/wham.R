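#' Free-energy profile container
#'
#' A potential of mean force G(z) on a depth grid, optionally with a
#' pointwise error band. Undefined (unsampled) grid points carry `NA`.
#'
#' @param z Grid in nm, strictly increasing.
#' @param G Free energy in kJ/mol (NA where undefined).
#' @param err Optional pointwise error band (kJ/mol).
#' @param temperature K.
#' @param anchor Convention label: `"zmax"` (G = 0 at the last defined grid
#'   point, the water phase), `"min"` (G = 0 at the minimum) or `"as_is"`.
#'   For `"zmax"`/`"min"` the shift is applied on construction.
#' @return Object of class `free_energy_profile`.
#' @export
free_energy_profile <- function(z, G, err = NULL, temperature = 298.15,
                                anchor = c("zmax", "min", "as_is")) {
  anchor <- match.arg(anchor)
  stopifnot(length(z) == length(G), length(z) >= 2L, all(diff(z) > 0))
  if (!is.null(err)) stopifnot(length(err) == length(G))
  G <- as.numeric(G)
  def <- which(is.finite(G))
  if (length(def) == 0L) stop("profile has no defined points")
  shift <- switch(anchor,
                  zmax = G[def[length(def)]],
                  min = min(G[def]),
                  as_is = 0)
  structure(list(z = as.numeric(z), G = G - shift, err = err,
                 temperature = temperature, anchor = anchor),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  def <- is.finite(x$G)
  cat(sprintf("free-energy profile: %d/%d defined points, z in [%g, %g] nm, anchor '%s'\n",
              sum(def), length(x$G), min(x$z), max(x$z), x$anchor))
  if (any(def)) {
    cat(sprintf("  min G = %.2f kJ/mol at z = %.3f nm\n",
                min(x$G[def]), x$z[def][which.min(x$G[def])]))
  }
  invisible(x)
}

#' Bin umbrella windows on a shared grid
#'
#' @param windows List of [umbrella_window()].
#' @param bin_width Bin width in nm (default 0.02, i.e. 5 bins per 0.1 nm
#'   window spacing so adjacent windows overlap over several bins).
#' @param z_range Numeric length-2, the analysis domain (default `c(0, 4)`).
#' @return Object of class `window_histograms`: `bin_edges`, `bin_mid`,
#'   `counts` (windows x bins), `biases`, `n_samples` (in-range counts per
#'   window) and `n_outside` (samples falling outside `z_range`, counted but
#'   not binned).
#' @export
build_histograms <- function(windows, bin_width = 0.02, z_range = c(0, 4)) {
  stopifnot(is.list(windows), length(windows) >= 1L, bin_width > 0,
            length(z_range) == 2L, z_range[2] > z_range[1])
  edges <- seq(z_range[1], z_range[2], by = bin_width)
  if (edges[length(edges)] < z_range[2] - 1e-12) {
    edges <- c(edges, z_range[2])
  }
  nb <- length(edges) - 1L
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  nw <- length(windows)
  counts <- matrix(0L, nw, nb)
  n_out <- integer(nw)
  biases <- vector("list", nw)
  for (i in seq_len(nw)) {
    w <- windows[[i]]
    if (!inherits(w, "umbrella_window")) stop("window ", i,
                                              " is not an umbrella_window")
    if (length(w$z) == 0L) stop("window ", i, " has an empty series")
    # half-open bins [e_j, e_{j+1}); last bin closed at the top edge
    idx <- findInterval(w$z, edges, rightmost.closed = TRUE)
    inside <- idx >= 1L & idx <= nb
    n_out[i] <- sum(!inside)
    counts[i, ] <- tabulate(idx[inside], nbins = nb)
    biases[[i]] <- w$bias
  }
  structure(list(bin_edges = edges, bin_mid = mid, counts = counts,
                 biases = biases, n_samples = rowSums(counts),
                 n_outside = n_out),
            class = "window_histograms")
}

#' Adjacent-window histogram overlap
#'
#' Overlap coefficient between consecutive windows' normalized histograms,
#' sum_b min(p_i(b), p_j(b)) - the standard sanity check that neighbouring
#' umbrella windows sample overlapping regions of the reaction coordinate
#' (for two equal-sd Gaussians separated by delta the coefficient is
#' 2*Phi(-delta/(2*sd))).
#'
#' @param hists A [build_histograms()] result.
#' @return Numeric vector of length n_windows - 1.
#' @export
window_overlap <- function(hists) {
  stopifnot(inherits(hists, "window_histograms"))
  p <- hists$counts / pmax(hists$n_samples, 1)
  vapply(seq_len(nrow(p) - 1L), function(i) {
    sum(pmin(p[i, ], p[i + 1L, ]))
  }, 0)
}

## Overlap connectivity: windows sharing at least one populated bin must form
## a single connected component, otherwise WHAM cannot stitch the profile.
.check_overlap <- function(counts) {
  nw <- nrow(counts)
  occ <- counts > 0
  comp <- rep(NA_integer_, nw)
  cur <- 0L
  for (s in seq_len(nw)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      link <- which(is.na(comp) &
                    (occ %*% occ[i, ] > 0))
      comp[link] <- cur
      queue <- c(queue, link)
    }
  }
  if (cur > 1L) {
    grp <- split(seq_len(nw), comp)
    stop("window histograms do not overlap into a single connected set; ",
         "components: ",
         paste(vapply(grp, function(g) paste0("{", paste(g, collapse = ","),
                                              "}"), ""), collapse = " "),
         " - add windows or widen sampling in the gap")
  }
  invisible(TRUE)
}

#' Solve the WHAM equations
#'
#' Self-consistent Weighted Histogram Analysis Method: with per-window bias
#' energies c_ib = k_i/2 (z_b - z_ref,i)^2 evaluated at bin centers, iterate
#' p_b proportional to (sum_i n_ib) / (sum_i N_i exp((f_i - c_ib)/RT)) and
#' f_i = -RT log sum_b p_b exp(-c_ib/RT) until max_i |delta f_i| < tol.
#' The profile is G(z_b) = -RT log p_b, shifted to the anchor convention;
#' empty bins are masked (NA).
#'
#' @param hists A [build_histograms()] result.
#' @param temperature K.
#' @param tol Convergence tolerance on the window free energies f_i, kJ/mol.
#' @param max_iter Maximum iterations.
#' @param anchor Passed to [free_energy_profile()] (default `"zmax"`: G = 0
#'   in the water phase, where the Boltzmann factor of the partition
#'   integral must approach 1).
#' @return A `free_energy_profile`, with attribute `"f_windows"` (converged
#'   window free energies) and `"iterations"`.
#' @export
solve_wham <- function(hists, temperature = 298.15, tol = 1e-6,
                       max_iter = 1e5, anchor = "zmax") {
  stopifnot(inherits(hists, "window_histograms"), tol > 0, max_iter >= 1)
  counts <- hists$counts
  .check_overlap(counts)
  rt <- RT(temperature)
  mid <- hists$bin_mid
  nw <- nrow(counts)
  zr <- vapply(hists$biases, function(b) b$z_ref, 0)
  kk <- vapply(hists$biases, function(b) b$k, 0)
  # bias energy at bin centers, windows x bins
  cmat <- 0.5 * kk * (matrix(mid, nw, length(mid), byrow = TRUE) - zr)^2
  expB <- exp(-cmat / rt)                # may underflow to 0 harmlessly
  tot <- colSums(counts)
  pop <- tot > 0
  N <- hists$n_samples
  f <- numeric(nw)
  it <- 0L
  repeat {
    it <- it + 1L
    wgt <- N * exp(f / rt)               # length nw
    denom <- as.numeric(crossprod(expB, wgt))  # per bin
    p <- ifelse(pop & denom > 0, tot / denom, 0)
    p <- p / sum(p)
    inner <- as.numeric(expB %*% p)
    if (any(inner <= 0)) {
      stop("window ", which(inner <= 0)[1],
           " has no support on populated bins; check overlaps")
    }
    f_new <- -rt * log(inner)
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
    if (it >= max_iter) {
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
                   as.integer(max_iter), delta))
    }
  }
  G <- ifelse(pop, -rt * log(p), NA_real_)
  prof <- free_energy_profile(mid, G, temperature = temperature,
                              anchor = anchor)
  attr(prof, "f_windows") <- f
  attr(prof, "iterations") <- it
  prof
}

#' Block-bootstrap error band for a WHAM profile
#'
#' Resamples each window's series in contiguous time blocks (drawn with
#' replacement, within each window independently), re-solves WHAM for each
#' replicate and reports the pointwise standard deviation across replicates.
#'
#' @param windows List of [umbrella_window()].
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed (the band is deterministic given the seed).
#' @param block_length Block length in ps; default one twentieth of the
#'   shortest window span (balances decorrelation against block count).
#' @param bin_width,z_range,temperature,tol,max_iter,anchor Solver
#'   parameters, as in [build_histograms()] and [solve_wham()].
#' @return The full-data `free_energy_profile` with `err` filled in
#'   (NA where any replicate left the bin unsampled).
#' @export
bootstrap_uncertainty <- function(windows, n_boot = 50, seed = 1L,
                                  block_length = NULL, bin_width = 0.02,
                                  z_range = c(0, 4), temperature = 298.15,
                                  tol = 1e-6, max_iter = 1e5,
                                  anchor = "zmax") {
  if (n_boot < 2) stop("n_boot must be >= 2")
  base <- solve_wham(build_histograms(windows, bin_width, z_range),
                     temperature, tol, max_iter, anchor)
  if (is.null(block_length)) {
    span <- min(vapply(windows, function(w) diff(range(w$times)), 0))
    block_length <- span / 20
  }
  set.seed(as.integer(seed))
  mats <- matrix(NA_real_, n_boot, length(base$z))
  for (b in seq_len(n_boot)) {
    res <- lapply(windows, .resample_blocks, block_length = block_length)
    prof <- solve_wham(build_histograms(res, bin_width, z_range),
                       temperature, tol, max_iter, anchor)
    mats[b, ] <- prof$G
  }
  err <- apply(mats, 2, function(col) {
    if (any(!is.finite(col))) NA_real_ else sd(col)
  })
  base$err <- err
  base
}

.resample_blocks <- function(w, block_length) {
  n <- length(w$z)
  dt <- if (n > 1) (w$times[n] - w$times[1]) / (n - 1) else 1
  bl <- max(1L, round(block_length / dt))
  starts <- seq.int(1L, n, by = bl)
  nb <- length(starts)
  pick <- sample.int(nb, nb, replace = TRUE)
  idx <- unlist(lapply(starts[pick], function(s) s:min(s + bl - 1L, n)),
                use.names = FALSE)
  idx <- idx[seq_len(min(length(idx), n))]
  umbrella_window(times = w$times[seq_along(idx)], z = w$z[idx],
                  bias = w$bias)
}

#' Convergence scan over sampling-time ranges
#'
#' Re-solves WHAM on sub-ranges of the window time series, the standard
#' diagnostic for umbrella-sampling convergence: progressively discarding
#' initial time, progressively discarding final time, or splitting into
#' consecutive blocks of fixed length. A stationary (converged) data set
#' shows no systematic trend of the extracted barriers across blocks.
#'
#' @param windows List of [umbrella_window()].
#' @param scheme `"discard_initial"`, `"discard_final"` or `"block"`.
#' @param increment Time increment in ps (ranges for discard schemes).
#' @param block_length Block length in ps (for `scheme = "block"`).
#' @param ... Solver parameters forwarded to [build_histograms()] /
#'   [solve_wham()] (`bin_width`, `z_range`, `temperature`, `tol`,
#'   `max_iter`, `anchor`).
#' @return A data.frame with one row per analyzed range: `scheme`,
#'   `t_start`, `t_end`, `z_min`, `G_min`, `translocation`, `desorption`;
#'   the profiles as attribute `"profiles"`. Ranges where some window has no
#'   samples are skipped with a warning.
#' @export
convergence_scan <- function(windows,
                             scheme = c("discard_initial", "discard_final",
                                        "block"),
                             increment = NULL, block_length = NULL, ...) {
  scheme <- match.arg(scheme)
  t0 <- max(vapply(windows, function(w) w$times[1], 0))
  t1 <- min(vapply(windows, function(w) w$times[length(w$times)], 0))
  span <- t1 - t0
  if (scheme == "block") {
    if (is.null(block_length)) stop("block scheme requires block_length")
    starts <- seq(t0, t1 - block_length + 1e-9, by = block_length)
    ranges <- lapply(starts, function(s) c(s, s + block_length))
  } else {
    if (is.null(increment)) stop("discard schemes require increment")
    ks <- seq(0, span - increment + 1e-9, by = increment)
    # keep at least one increment of data in the retained range
    ranges <- if (scheme == "discard_initial") {
      lapply(ks, function(d) c(t0 + d, t1))
    } else {
      lapply(ks, function(d) c(t0, t1 - d))
    }
  }
  dots <- list(...)
  arg_or <- function(name, default) {
    if (!is.null(dots[[name]])) dots[[name]] else default
  }
  rows <- list()
  profiles <- list()
  for (r in ranges) {
    sub <- lapply(windows, function(w) {
      sel <- w$times >= r[1] - 1e-9 & w$times <= r[2] + 1e-9
      if (!any(sel)) return(NULL)
      umbrella_window(w$times[sel], w$z[sel], w$bias)
    })
    if (any(vapply(sub, is.null, TRUE))) {
      warning(sprintf("range [%g, %g] ps skipped: empty window", r[1], r[2]))
      next
    }
    prof <- solve_wham(build_histograms(sub,
                                        arg_or("bin_width", 0.02),
                                        arg_or("z_range", c(0, 4))),
                       arg_or("temperature", 298.15),
                       arg_or("tol", 1e-6),
                       arg_or("max_iter", 1e5),
                       arg_or("anchor", "zmax"))
    bar <- extract_barriers(prof)
    rows[[length(rows) + 1L]] <-
      data.frame(scheme = scheme, t_start = r[1], t_end = r[2],
                 z_min = bar$z_min, G_min = bar$G_min,
                 translocation = bar$translocation,
                 desorption = bar$desorption)
    profiles[[length(profiles) + 1L]] <- prof
  }
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- profiles
  out
}

#' Extract translocation and desorption barriers from a profile
#'
#' The free-energy minimum z_min is the argmin of G over the grid (smallest
#' z on ties); the translocation barrier is G(z = 0) - G(z_min) (cost of
#' reaching the bilayer center, en route to the opposite leaflet) and the
#' desorption barrier is G(z_max) - G(z_min) (cost of leaving the membrane
#' into water). Both are non-negative whenever z_min is the global minimum.
#'
#' @param profile A `free_energy_profile` defined at its first (z ~ 0) and
#'   last (z = z_max) grid points.
#' @return A list of class `barrier_summary`: `z_min`, `G_min`,
#'   `translocation`, `desorption`.
#' @export
extract_barriers <- function(profile) {
  stopifnot(inherits(profile, "free_energy_profile"))
  G <- profile$G
  z <- profile$z
  if (!is.finite(G[1])) stop("profile is masked at the bilayer center (z = ",
                             z[1], ")")
  if (!is.finite(G[length(G)])) stop("profile is masked in the water phase (z = ",
                                     z[length(z)], ")")
  def <- which(is.finite(G))
  imin <- def[which.min(G[def])]   # which.min takes the first tie: smallest z
  structure(list(z_min = z[imin], G_min = G[imin],
                 translocation = G[1] - G[imin],
                 desorption = G[length(G)] - G[imin]),
            class = "barrier_summary")
}

#' @export
print.barrier_summary <- function(x, ...) {
  cat(sprintf("minimum %.2f kJ/mol at z = %.3f nm; translocation %.2f, desorption %.2f kJ/mol\n",
              x$G_min, x$z_min, x$translocation, x$desorption))
  invisible(x)
}
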