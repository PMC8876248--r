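#' Write a trajectory as (multi-frame) GRO
#'
#' Fixed-column GRO records (positions in nm, 3 decimals); frames are
#' concatenated, each with its own title/count/box lines.
#'
#' @param traj An `md_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(traj$frames)) {
    f <- traj$frames[[fi]]
    writeLines(sprintf("toy bilayer, t= %.3f", traj$times[fi]), con)
    writeLines(sprintf("%5d", nrow(at)), con)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     at$resid %% 100000L, at$resname,
                     substr(at$name, 1, 5),
                     seq_len(nrow(at)) %% 100000L,
                     f$xyz[, 1], f$xyz[, 2], f$xyz[, 3])
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]),
               con)
  }
  invisible(path)
}

#' Read a (multi-frame) GRO file
#'
#' @param path GRO file (positions in nm; velocities, if present, ignored).
#' @param masses Optional named vector mapping atom names to masses; by
#'   default masses are inferred from the leading element letter of the
#'   atom name (C/N/O/P/H/S), with united-atom CH2/CH3 for lipid chain
#'   carbons named `C<n>`.
#' @return An `md_trajectory`.
#' @export
read_gro <- function(path, masses = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GRO file: fewer than 3 lines")
  frames <- list()
  times <- numeric(0)
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (i + 1L > length(lines)) stop("truncated GRO file at line ", i)
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 0) stop("invalid atom count at line ", i + 1L)
    if (i + 1L + nat + 1L > length(lines)) {
      stop("truncated GRO file: frame starting at line ", i,
           " declares ", nat, " atoms")
    }
    rec <- lines[i + 1L + seq_len(nat)]
    resid <- as.integer(substr(rec, 1, 5))
    resname <- trimws(substr(rec, 6, 10))
    name <- trimws(substr(rec, 11, 15))
    x <- as.numeric(substr(rec, 21, 28))
    y <- as.numeric(substr(rec, 29, 36))
    z <- as.numeric(substr(rec, 37, 44))
    if (any(is.na(c(x, y, z)))) {
      bad <- which(is.na(x) | is.na(y) | is.na(z))[1]
      stop("unparsable coordinates at line ", i + 1L + bad)
    }
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + nat]),
                                   "\\s+")[[1]])
    if (length(boxline) < 3L || any(is.na(boxline[1:3]))) {
      stop("invalid box line at line ", i + 2L + nat)
    }
    tm <- regmatches(title, regexpr("t=\\s*[0-9.eE+-]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm))
               else length(frames))
    if (is.null(atoms)) {
      atoms <- data.frame(name = name, resname = resname, resid = resid,
                          mass = .guess_mass(name, masses),
                          stringsAsFactors = FALSE)
    } else if (nat != nrow(atoms)) {
      stop("atom-count mismatch between frames: ", nrow(atoms), " vs ", nat)
    }
    frames[[length(frames) + 1L]] <- list(box = boxline[1:3],
                                          xyz = cbind(x, y, z))
    i <- i + nat + 3L
  }
  if (any(diff(times) <= 0)) times <- seq_along(frames) - 1
  md_trajectory(atoms, frames, times)
}

.guess_mass <- function(name, masses = NULL) {
  if (!is.null(masses)) {
    m <- masses[name]
    if (!any(is.na(m))) return(as.numeric(m))
  }
  vapply(name, function(nm) {
    if (!is.null(masses) && nm %in% names(masses)) return(masses[[nm]])
    if (grepl("^C[0-9]+$", nm)) {
      return(if (nm == "C16") 15.035 else 14.027)  # united-atom chain
    }
    el <- substr(nm, 1, 1)
    switch(el, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           H = 1.008, S = 32.06, X = 40, B = 26, E = 44, 12.011)
  }, 0)
}

#' Load a trajectory plus standard selections
#'
#' @param coord_path GRO coordinate (or multi-frame trajectory) file.
#' @param traj_path Optional second multi-frame GRO whose frames are
#'   appended; must match the atom count.
#' @param selection_config Optional named list of atom-name/resname rules
#'   passed to [default_selections()] (`lipid_resname`, `probe_resname`,
#'   `water_resname`).
#' @return List with `trajectory` and `selections`.
#' @export
load_trajectory <- function(coord_path, traj_path = NULL,
                            selection_config = list()) {
  traj <- read_gro(coord_path)
  if (!is.null(traj_path)) {
    more <- read_gro(traj_path)
    if (nrow(more$atoms) != nrow(traj$atoms)) {
      stop("atom-count mismatch: coordinates have ", nrow(traj$atoms),
           " atoms, trajectory has ", nrow(more$atoms))
    }
    traj <- md_trajectory(traj$atoms, c(traj$frames, more$frames))
  }
  sel <- do.call(default_selections, c(list(traj), selection_config))
  list(trajectory = traj, selections = sel)
}

#' Write an umbrella window series in pull-XVG dialect
#'
#' Two columns, time (ps) and reaction coordinate (nm), with '#'/'@' header
#' lines carrying the bias parameters.
#'
#' @param window An `umbrella_window`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pull_xvg <- function(window, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# umbrella window: z_ref = %.6g nm, k = %.6g kJ/mol/nm^2",
            window$bias$z_ref, window$bias$k),
    "@    title \"pull coordinate\"",
    "@    xaxis  label \"Time (ps)\"",
    "@    yaxis  label \"Position (nm)\""), con)
  # %.17g guarantees exact double round-trip through the text format
  writeLines(sprintf("%.17g\t%.17g", window$times, window$z), con)
  invisible(path)
}

#' Read umbrella window series from pull-XVG files
#'
#' Lines starting with '#' or '@' are skipped; the first two numeric
#' columns are time (ps) and position (nm). Bias parameters are taken from
#' the file's own header when written by [write_pull_xvg()], otherwise from
#' `z_refs`/`k`.
#'
#' @param paths Character vector of files, one window each.
#' @param z_refs Optional reference positions (recycled header fallback).
#' @param k Bias force constant fallback (default 3000).
#' @return List of `umbrella_window`.
#' @export
read_pull_series <- function(paths, z_refs = NULL, k = 3000) {
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    lines <- readLines(paths[i])
    hdr <- lines[grepl("^[#@]", lines)]
    dat <- lines[!grepl("^[#@]", lines) & nzchar(trimws(lines))]
    if (length(dat) == 0L) stop("no data records in ", paths[i])
    fields <- strsplit(trimws(dat), "[\\s,]+", perl = TRUE)
    tt <- as.numeric(vapply(fields, `[`, "", 1L))
    zz <- as.numeric(vapply(fields, `[`, "", 2L))
    if (any(is.na(tt)) || any(is.na(zz))) {
      stop("unparsable record in ", paths[i])
    }
    if (any(diff(tt) <= 0)) stop("non-monotone times in ", paths[i])
    zr <- NA_real_; kk <- NA_real_
    bh <- hdr[grepl("z_ref", hdr)]
    if (length(bh)) {
      num <- regmatches(bh[1],
                        gregexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                                 bh[1]))[[1]]
      if (length(num) >= 2) { zr <- as.numeric(num[1]); kk <- as.numeric(num[2]) }
    }
    if (is.na(zr)) zr <- if (!is.null(z_refs)) z_refs[i] else
      stop("no bias header in ", paths[i], " and no z_refs given")
    if (is.na(kk)) kk <- k
    out[[i]] <- umbrella_window(tt, zz, bias_spec(zr, kk))
  }
  out
}

#' Write a free-energy profile as CSV or XVG
#'
#' @param profile A `free_energy_profile`.
#' @param path Output file; format chosen by extension (`.csv` else XVG).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(z = profile$z, G = profile$G)
  if (!is.null(profile$err)) df$err <- profile$err
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# free-energy profile (z nm, G kJ/mol[, err])",
                 sprintf("@    anchor \"%s\"", profile$anchor)), con)
    writeLines(do.call(sprintf,
                       c(list(paste(rep("%.8g", ncol(df)), collapse = "\t")),
                         unname(as.list(df)))), con)
  }
  invisible(path)
}

#' Read a titration CSV
#'
#' Expected columns: `lipid_conc` (mol/dm^3), `intensity`, optional
#' `replicate`. Returns one [titration_series()] per replicate.
#'
#' @param path CSV file.
#' @return List of `titration_series`.
#' @export
read_titration_csv <- function(path) {
  df <- read.csv(path)
  need <- c("lipid_conc", "intensity")
  if (!all(need %in% names(df))) {
    stop("titration CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(df$lipid_conc)) || !all(is.finite(df$intensity))) {
    stop("malformed titration record (non-numeric field)")
  }
  rep_id <- if ("replicate" %in% names(df)) df$replicate else "r1"
  lapply(split(df, rep_id), function(d) {
    titration_series(d$lipid_conc, d$intensity, replicate_id =
                       as.character(d$replicate[1] %||% "r1"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write titration series to CSV
#'
#' @param titrations A `titration_series` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(titrations, path) {
  if (inherits(titrations, "titration_series")) titrations <- list(titrations)
  df <- do.call(rbind, lapply(titrations, function(tt) {
    data.frame(lipid_conc = tt$lipid_concs, intensity = tt$intensities,
               replicate = tt$replicate_id %||% "r1")
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
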