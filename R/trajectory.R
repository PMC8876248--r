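#' Trajectory container
#'
#' Minimal in-memory trajectory: a fixed atom table plus per-frame
#' orthorhombic boxes and coordinates (nm).
#'
#' @param atoms data.frame with columns `name`, `resname`, `resid`, `mass`.
#' @param frames List; each element a list with `box` (length-3 numeric,
#'   nm, positive) and `xyz` (natoms x 3 matrix, nm).
#' @param times Optional frame times in ps (default 0, 1, 2, ...).
#' @return Object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, frames, times = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "resname", "resid", "mass") %in% names(atoms)))
  for (f in frames) {
    stopifnot(length(f$box) == 3L, all(f$box > 0),
              is.matrix(f$xyz), nrow(f$xyz) == nrow(atoms),
              ncol(f$xyz) == 3L)
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  stopifnot(length(times) == length(frames))
  structure(list(atoms = atoms, frames = frames, times = as.numeric(times)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, residues: %s\n",
              nrow(x$atoms), length(x$frames),
              paste(unique(x$atoms$resname), collapse = ", ")))
  invisible(x)
}

#' Named atom selections
#'
#' @param groups Named list of integer atom-index vectors; all groups must
#'   be non-empty and indices valid for `n_atoms`.
#' @param n_atoms Total atom count used for validation (optional).
#' @return Object of class `selection_spec`.
#' @export
selection_spec <- function(groups, n_atoms = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1L,
            !is.null(names(groups)), all(nzchar(names(groups))))
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) == 0L) stop("selection group '", g, "' is empty")
    if (!is.null(n_atoms) && (any(idx < 1L) || any(idx > n_atoms))) {
      stop("selection group '", g, "' has out-of-range indices")
    }
  }
  structure(lapply(groups, as.integer), class = "selection_spec")
}

#' Resolve a named group from a selection
#'
#' @param sel A `selection_spec`.
#' @param name Group name.
#' @return Integer indices.
#' @export
get_group <- function(sel, name) {
  if (!(name %in% names(sel))) {
    stop("unknown selection group '", name, "'; available: ",
         paste(names(sel), collapse = ", "))
  }
  sel[[name]]
}

#' Standard selections for lipid/probe systems
#'
#' Builds the canonical named groups from atom and residue names: per-lipid
#' headgroup atoms (`P`, `N`, phosphate oxygens `O8`, `O9`, carbonyl oxygens
#' `O12`, `O14`), the acyl `chain` carbons (C2...C16), `lipids` (all lipid
#' atoms); probe groups `xanthene`, `benzoic_ring`, `N1`, `N2`, `ester`
#' (ester/COO site), `probe` (all probe atoms); `water` when present.
#'
#' @param traj An `md_trajectory`.
#' @param lipid_resname,probe_resname,water_resname Residue names (defaults
#'   "POPC", "RHD", "SOL").
#' @return A `selection_spec` (only groups actually present are included).
#' @export
default_selections <- function(traj, lipid_resname = "POPC",
                               probe_resname = "RHD",
                               water_resname = "SOL") {
  at <- traj$atoms
  lip <- at$resname == lipid_resname
  prb <- at$resname == probe_resname
  wat <- at$resname == water_resname
  groups <- list()
  add <- function(groups, nm, idx) {
    if (length(idx)) groups[[nm]] <- idx
    groups
  }
  for (nm in c("P", "N", "O8", "O9", "O12", "O14")) {
    groups <- add(groups, nm, which(lip & at$name == nm))
  }
  groups <- add(groups, "chain", which(lip & grepl("^C[0-9]+$", at$name)))
  groups <- add(groups, "lipids", which(lip))
  groups <- add(groups, "xanthene", which(prb & grepl("^X", at$name)))
  groups <- add(groups, "benzoic_ring", which(prb & grepl("^B", at$name)))
  groups <- add(groups, "N1", which(prb & at$name == "N1"))
  groups <- add(groups, "N2", which(prb & at$name == "N2"))
  groups <- add(groups, "ester", which(prb & at$name == "E1"))
  groups <- add(groups, "probe", which(prb))
  groups <- add(groups, "water", which(wat))
  selection_spec(groups, n_atoms = nrow(at))
}

## mass-weighted center of mass (rows of xyz), optionally one coordinate
.com <- function(xyz, mass, idx = NULL) {
  if (!is.null(idx)) { xyz <- xyz[idx, , drop = FALSE]; mass <- mass[idx] }
  colSums(xyz * mass) / sum(mass)
}

## minimum-image displacement for orthorhombic boxes
.min_image <- function(d, box) {
  d - box * round(d / box)
}
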