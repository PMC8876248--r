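#' Validate a pipeline run configuration
#'
#' A run configuration is a plain named list (typically deserialized from a
#' JSON file): `out_dir`, `seed`, `temperature`, and per-stage blocks
#' `simulate` (surface name/params, `z_refs`, `k`, `n_steps`, `dt`,
#' `diffusion`), `wham` (`bin_width`, `z_range`, `tol`), `kp` (`a`),
#' `titration` (`path` to a CSV, or `generate` parameters), `trajectory`
#' (`path` to a GRO, or `generate` toy-bilayer parameters) and `hbond`
#' cutoffs. All referenced input paths must exist at validation time.
#'
#' @param config A named list or a path to a JSON file.
#' @return The validated config (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config requires out_dir")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$temperature)) config$temperature <- 298.15
  for (blk in c("titration", "trajectory")) {
    p <- config[[blk]]$path
    if (!is.null(p) && !file.exists(p)) {
      stop("config ", blk, "$path does not exist: ", p)
    }
  }
  if (!is.null(config$windows$paths) &&
      !all(file.exists(config$windows$paths))) {
    stop("missing window file(s): ",
         paste(config$windows$paths[!file.exists(config$windows$paths)],
               collapse = ", "))
  }
  class(config) <- c("run_config", "list")
  config
}

#' Run the analysis pipeline
#'
#' Executes one stage (or `"all"`) of the standard workflow on a validated
#' [run_config()], writing CSV/XVG/JSON outputs plus a `metadata.json`
#' capturing package version, seeds and parameters so that a rerun with the
#' same config reproduces the outputs byte for byte.
#'
#' Stages: `simulate` (synthetic umbrella windows), `wham` (PMF +
#' barriers), `kp` (profile partition integral), `fit-titration`,
#' `density`, `order`, `tilt`, `hbond`, `all`.
#'
#' @param config A [run_config()] (or list/path coercible to one).
#' @param stage Stage name.
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "wham", "kp",
                                           "fit-titration", "density",
                                           "order", "tilt", "hbond")) {
  stage <- match.arg(stage)
  config <- run_config(unclass(config))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  temperature <- config$temperature
  stages <- if (stage == "all") {
    c("simulate", "wham", "kp", "fit-titration", "density", "order",
      "tilt", "hbond")
  } else stage

  get_windows <- function() {
    if (!is.null(config$windows$paths)) {
      read_pull_series(config$windows$paths)
    } else {
      wdir <- file.path(out, "windows")
      files <- sort(list.files(wdir, pattern = "\\.xvg$", full.names = TRUE))
      if (length(files) == 0L) {
        stop("no umbrella windows available: run the simulate stage or set ",
             "windows$paths")
      }
      read_pull_series(files)
    }
  }
  get_traj <- function() {
    tb <- config$trajectory
    if (!is.null(tb$path)) {
      load_trajectory(tb$path)
    } else {
      spec <- do.call(toy_bilayer_spec, tb$generate %||% list())
      traj <- generate_membrane_frames(spec,
                                       n_frames = tb$n_frames %||% 50,
                                       seed = config$seed)
      list(trajectory = traj, selections = default_selections(traj),
           spec = spec)
    }
  }

  for (st in stages) {
    if (st == "simulate") {
      sim <- config$simulate %||% list()
      surf <- do.call(reference_surface,
                      c(list(sim$surface %||% "membrane_double_well"),
                        sim$surface_params %||% list()))
      z_refs <- sim$z_refs %||% seq(0, 4, by = 0.1)
      wins <- sample_window_ladder(
        surf, z_refs = z_refs, k = sim$k %||% 3000,
        n_steps = sim$n_steps %||% 2e4, dt = sim$dt %||% 0.033,
        diffusion = sim$diffusion %||% 5e-4, temperature = temperature,
        seed = config$seed)
      wdir <- file.path(out, "windows")
      dir.create(wdir, showWarnings = FALSE)
      wp <- character(length(wins))
      for (i in seq_along(wins)) {
        wp[i] <- file.path(wdir, sprintf("window_%03d.xvg", i))
        write_pull_xvg(wins[[i]], wp[i])
      }
      paths$windows <- wp
    } else if (st == "wham") {
      wins <- get_windows()
      wb <- config$wham %||% list()
      prof <- solve_wham(build_histograms(wins,
                                          wb$bin_width %||% 0.02,
                                          wb$z_range %||% c(0, 4)),
                         temperature, wb$tol %||% 1e-6,
                         wb$max_iter %||% 1e5)
      paths$pmf <- file.path(out, "pmf.csv")
      write_profile(prof, paths$pmf)
      bar <- extract_barriers(prof)
      paths$barriers <- file.path(out, "barriers.json")
      jsonlite::write_json(unclass(bar), paths$barriers, auto_unbox = TRUE,
                           digits = NA)
    } else if (st == "kp") {
      pmf_path <- file.path(out, "pmf.csv")
      if (!file.exists(pmf_path)) stop("kp stage needs pmf.csv (run wham)")
      df <- read.csv(pmf_path)
      prof <- free_energy_profile(df$z, df$G, temperature = temperature,
                                  anchor = "as_is")
      val <- kp_integral(prof, a = (config$kp$a %||% 4.0), temperature)
      paths$kp <- file.path(out, "kp.json")
      jsonlite::write_json(list(kp_integral = val,
                                a = config$kp$a %||% 4.0),
                           paths$kp, auto_unbox = TRUE, digits = NA)
    } else if (st == "fit-titration") {
      tb <- config$titration %||% list()
      tits <- if (!is.null(tb$path)) {
        read_titration_csv(tb$path)
      } else {
        gen <- tb$generate %||% list()
        model <- partition_model(gen$S_W %||% 100,
                                 gen$S_M %||% 10,
                                 gen$K_P %||% 190,
                                 gen$V_bar %||% 0.8)
        n_rep <- gen$n_replicates %||% 3
        lapply(seq_len(n_rep), function(r) {
          generate_titration(model, titration_concs(),
                             noise_cv = gen$noise_cv %||% 0.02,
                             seed = config$seed + r - 1L,
                             replicate_id = paste0("r", r))
        })
      }
      fits <- lapply(tits, fit_partition_model,
                     V_bar = config$titration$V_bar %||% 0.8)
      tab <- do.call(rbind, lapply(fits, function(f) {
        data.frame(replicate = f$replicate_id %||% NA,
                   S_W = f$estimate[["S_W"]], S_M = f$estimate[["S_M"]],
                   K_P = f$estimate[["K_P"]], se_K_P = f$se[["K_P"]],
                   converged = f$converged)
      }))
      paths$fits <- file.path(out, "titration_fits.csv")
      write.csv(tab, paths$fits, row.names = FALSE)
      if (sum(tab$converged) >= 2) {
        agg <- aggregate_kp(fits, confidence = tb$confidence %||% 0.90)
        paths$kp_aggregate <- file.path(out, "kp_aggregate.json")
        jsonlite::write_json(unclass(agg), paths$kp_aggregate,
                             auto_unbox = TRUE, digits = NA)
      }
    } else {
      tr <- get_traj()
      traj <- tr$trajectory
      sel <- tr$selections
      if (st == "density") {
        prof <- density_profile(traj, sel,
                                groups = intersect(c("lipids", "probe",
                                                     "water"), names(sel)),
                                symmetrize = TRUE)
        paths$density <- file.path(out, "density.csv")
        write.csv(data.frame(z = prof$z, prof$density), paths$density,
                  row.names = FALSE)
      } else if (st == "order") {
        op <- order_parameters(traj, sel)
        paths$order <- file.path(out, "order_parameters.csv")
        write.csv(op, paths$order, row.names = FALSE)
      } else if (st == "tilt") {
        res <- lapply(c("xanthene_long", "xanthene_short", "PN"),
                      function(ax) {
                        td <- tilt_distribution(traj, ax, sel)
                        data.frame(axis = ax, theta = td$theta,
                                   density = td$density, mean = td$mean)
                      })
        paths$tilt <- file.path(out, "tilt.csv")
        write.csv(do.call(rbind, res), paths$tilt, row.names = FALSE)
      } else if (st == "hbond") {
        hb <- config$hbond %||% list()
        don <- selection_spec(list(probe_N1 = get_group(sel, "N1"),
                                   probe_N2 = get_group(sel, "N2")),
                              nrow(traj$atoms))
        acc_groups <- list()
        for (g in intersect(c("O8", "O9", "O12", "O14", "water"),
                            names(sel))) {
          acc_groups[[g]] <- get_group(sel, g)
        }
        acc <- selection_spec(acc_groups, nrow(traj$atoms))
        res <- hydrogen_bonds(traj, don, acc,
                              r_cut = hb$r_cut %||% 0.35,
                              angle_cut = hb$angle_cut %||% 30)
        paths$hbond <- file.path(out, "hbonds.csv")
        write.csv(as.data.frame(res), paths$hbond, row.names = FALSE)
      }
    }
  }
  meta <- list(package = "memprobe",
               version = as.character(utils::packageVersion("memprobe")),
               seed = config$seed, temperature = temperature,
               stage = stage,
               config = unclass(config))
  jsonlite::write_json(meta, file.path(out, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$metadata <- file.path(out, "metadata.json")
  invisible(paths)
}
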