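#' Partition model for fluorescence titrations
#'
#' The observed fluorescence of a dye titrated with lipid vesicles follows
#' the partition equation
#' I_f = (S_W + S_M * K_P * Vbar * L) / (1 + K_P * Vbar * L),
#' where L = \[POPC\] is the lipid concentration (mol/dm^3), S_W and S_M the
#' signal when the dye is fully aqueous or fully membrane-bound, K_P the
#' (dimensionless) lipid/water partition coefficient and Vbar the lipid
#' molar volume in the membrane (0.8 dm^3/mol for POPC).
#'
#' @param S_W,S_M Signal levels (arbitrary fluorescence units).
#' @param K_P Partition coefficient, > 0.
#' @param V_bar Lipid molar volume, dm^3/mol (default 0.8).
#' @return Object of class `partition_model`.
#' @export
partition_model <- function(S_W, S_M, K_P, V_bar = 0.8) {
  stopifnot(is.finite(S_W), is.finite(S_M), K_P > 0, V_bar > 0)
  structure(list(S_W = S_W, S_M = S_M, K_P = K_P, V_bar = V_bar),
            class = "partition_model")
}

#' Evaluate the partition equation
#'
#' @param model A [partition_model()].
#' @param lipid_concs Lipid concentrations, mol/dm^3, >= 0.
#' @return Predicted intensities.
#' @export
partition_intensity <- function(model, lipid_concs) {
  stopifnot(inherits(model, "partition_model"))
  if (any(lipid_concs < 0)) stop("negative lipid concentration")
  x <- model$K_P * model$V_bar * lipid_concs
  (model$S_W + model$S_M * x) / (1 + x)
}

#' Relative partition coefficient from a free-energy profile
#'
#' K_P is taken proportional to the integral of exp(-G(z)/RT) from the
#' bilayer center to a point `a` in the water phase, accounting for both the
#' depth and the width of the free-energy well. The profile must be anchored
#' so that G ~ 0 in water (the integrand there is ~1 and negligible next to
#' the well contribution). The result is a relative, nm-weighted quantity:
#' only ratios between profiles are physically meaningful.
#'
#' @param profile A `free_energy_profile` on \[0, a\].
#' @param a Upper integration limit in nm (default 4.0; its choice is not
#'   critical since the water-phase integrand is ~1).
#' @param temperature K.
#' @return The trapezoidal integral (nm). Masked interior points are
#'   linearly interpolated with a warning.
#' @export
kp_integral <- function(profile, a = 4.0, temperature = 298.15) {
  stopifnot(inherits(profile, "free_energy_profile"), a > 0)
  z <- profile$z
  G <- profile$G
  binw <- if (length(z) > 1) min(diff(z)) else Inf
  if (a > z[length(z)] + binw + 1e-9 || a < z[1] - 1e-9) {
    stop(sprintf("a = %g nm lies outside the profile grid [%g, %g]",
                 a, z[1], z[length(z)]))
  }
  if (any(!is.finite(G))) {
    if (all(!is.finite(G))) stop("profile entirely masked")
    warning("masked profile points interpolated linearly")
    G <- approx(z[is.finite(G)], G[is.finite(G)], xout = z, rule = 2)$y
  }
  keep <- z <= a + 1e-12
  z <- z[keep]; G <- G[keep]
  # extend by the edge value to cover [0, a] exactly (at most one bin width)
  if (z[1] > 0) { z <- c(0, z); G <- c(G[1], G) }
  if (z[length(z)] < a) { z <- c(z, a); G <- c(G, G[length(G)]) }
  y <- exp(-G / RT(temperature))
  sum(diff(z) * (y[-1] + y[-length(y)]) / 2)
}

#' Normalize relative partition coefficients to a reference entry
#'
#' The proportionality constant of the profile integral is undefined, so
#' comparisons are made after dividing by a reference species (conventionally
#' the dominant form of the reference dye), which maps to exactly 1.
#'
#' @param values Positive numeric vector.
#' @param reference_index Index of the reference entry (default 1).
#' @return `values / values[reference_index]`.
#' @export
normalize_kp <- function(values, reference_index = 1L) {
  stopifnot(length(values) >= 1L, reference_index >= 1L,
            reference_index <= length(values))
  ref <- values[reference_index]
  if (!is.finite(ref) || ref <= 0) stop("reference value must be > 0")
  values / ref
}

#' Fit the partition equation to a titration
#'
#' Nonlinear least squares for (S_W, S_M, K_P) with K_P constrained positive
#' through a log parameterization. Standard errors come from the local
#' quadratic approximation at the optimum (Gauss-Newton covariance
#' sigma^2 (J'J)^-1; the K_P error is delta-method from ln K_P). When S_M is
#' indistinguishable from S_W the model carries no information on K_P and
#' the fit is flagged through an exploding standard error.
#'
#' @param titration A [titration_series()] (or list with `lipid_concs`,
#'   `intensities`, `replicate_id`).
#' @param V_bar Lipid molar volume, dm^3/mol, held fixed (default 0.8).
#' @param start Optional named list of starting values `S_W`, `S_M`, `K_P`;
#'   by default taken from the data (signal at zero / highest lipid, K_P
#'   from the mid-rise concentration).
#' @return Object of class `partition_fit`: `estimate` (named vector S_W,
#'   S_M, K_P), `se`, `residual_norm`, `converged`, `replicate_id`, `model`
#'   (a [partition_model()] at the optimum), `n`.
#' @export
fit_partition_model <- function(titration, V_bar = 0.8, start = NULL) {
  L <- titration$lipid_concs
  I <- titration$intensities
  stopifnot(length(L) == length(I), all(is.finite(I)), all(L >= 0))
  if (length(unique(L)) < 4) {
    stop("need >= 4 distinct lipid concentrations")
  }
  if (min(L) > 1e-4 * max(L)) {
    warning("no zero or near-zero lipid concentration; S_W poorly anchored")
  }
  if (is.null(start)) {
    S_W0 <- mean(I[L == min(L)])
    S_M0 <- mean(I[L == max(L)])
    # concentration of half signal change ~ 1/(K_P V_bar)
    half <- (S_W0 + S_M0) / 2
    Lh <- suppressWarnings(approx(I, L, xout = half, ties = "ordered")$y)
    K0 <- if (is.finite(Lh) && !is.na(Lh) && Lh > 0) 1 / (V_bar * Lh) else
      1 / (V_bar * stats::median(L[L > 0]))
    start <- list(S_W = S_W0, S_M = S_M0, K_P = max(K0, 1e-6))
  }
  df <- data.frame(L = L, I = I)
  fit <- tryCatch(
    nls(I ~ (sw + sm * exp(lk) * V_bar * L) / (1 + exp(lk) * V_bar * L),
        data = df,
        start = list(sw = start$S_W, sm = start$S_M, lk = log(start$K_P)),
        control = stats::nls.control(maxiter = 500, scaleOffset = 1,
                                     warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # retry with a tolerant Gauss-Newton; flag non-convergence
    # tolerant retry; its non-convergence is reported through the flag,
    # not through console warnings
    fit2 <- tryCatch(
      suppressWarnings(
        nls(I ~ (sw + sm * exp(lk) * V_bar * L) / (1 + exp(lk) * V_bar * L),
            data = df,
            start = list(sw = start$S_W, sm = start$S_M,
                         lk = log(start$K_P)),
            control = stats::nls.control(maxiter = 500, scaleOffset = 1,
                                         warnOnly = TRUE))),
      error = function(e) e)
    if (inherits(fit2, "error")) {
      return(structure(list(
        estimate = c(S_W = NA_real_, S_M = NA_real_, K_P = NA_real_),
        se = c(S_W = NA_real_, S_M = NA_real_, K_P = NA_real_),
        residual_norm = NA_real_, converged = FALSE,
        replicate_id = titration$replicate_id, model = NULL,
        n = length(L), message = conditionMessage(fit)),
        class = "partition_fit"))
    }
    fit <- fit2
    converged <- FALSE
  } else {
    converged <- fit$convInfo$isConv
  }
  cf <- coef(fit)
  sum_se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    rep(NA_real_, 3))
  est <- c(S_W = unname(cf["sw"]), S_M = unname(cf["sm"]),
           K_P = unname(exp(cf["lk"])))
  se <- c(S_W = unname(sum_se[1]), S_M = unname(sum_se[2]),
          K_P = unname(est["K_P"] * sum_se[3]))   # delta method on ln K_P
  structure(list(
    estimate = est, se = se,
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    converged = isTRUE(converged),
    replicate_id = titration$replicate_id,
    model = partition_model(est[["S_W"]], est[["S_M"]], est[["K_P"]], V_bar),
    n = length(L)),
    class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("partition fit (%s, n = %d, %s):\n",
              if (is.null(x$replicate_id)) "unnamed" else x$replicate_id,
              x$n, if (x$converged) "converged" else "NOT converged"))
  est <- rbind(estimate = x$estimate, se = x$se)
  print(signif(est, 4))
  invisible(x)
}

#' Aggregate partition coefficients across replicate titrations
#'
#' The characteristic K_P is the geometric mean exp(mean(ln K_P)) over the
#' converged replicate fits, with a Student-t confidence interval on ln K_P:
#' exp(mean +/- t_{1-(1-conf)/2, n-1} sd(ln K_P)/sqrt(n)).
#'
#' @param fits List of [fit_partition_model()] results (or numeric K_P
#'   values); at least 2 converged fits required.
#' @param confidence Confidence level (default 0.90).
#' @return Object of class `aggregate_kp`: `K_P`, `lower`, `upper`,
#'   `confidence`, `n`.
#' @export
aggregate_kp <- function(fits, confidence = 0.90) {
  stopifnot(confidence > 0, confidence < 1)
  kp <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) {
      if (!isTRUE(f$converged)) NA_real_ else f$estimate[["K_P"]]
    }, 0)
  kp <- kp[is.finite(kp) & kp > 0]
  n <- length(kp)
  if (n < 2) stop("need >= 2 converged fits to aggregate")
  lk <- log(kp)
  m <- mean(lk)
  s <- sd(lk)
  half <- qt(1 - (1 - confidence) / 2, df = n - 1) * s / sqrt(n)
  structure(list(K_P = exp(m), lower = exp(m - half), upper = exp(m + half),
                 confidence = confidence, n = n),
            class = "aggregate_kp")
}

#' @export
print.aggregate_kp <- function(x, ...) {
  cat(sprintf("K_P = %.3g (IC%d%% [%.3g, %.3g], n = %d titrations)\n",
              x$K_P, round(100 * x$confidence), x$lower, x$upper, x$n))
  invisible(x)
}

#' Ionization state fractions (Henderson-Hasselbalch)
#'
#' For a single transition the basic (deprotonated) fraction is
#' 1/(1 + 10^(pKa - pH)); chains of transitions are composed sequentially,
#' giving one fraction per species from fully protonated to fully
#' deprotonated. Rhodamine bookkeeping: Rh123 cation/neutral pKa 7.2; RhB
#' cation/zwitterion pKa ~3.2 (Ka = 6e-4).
#'
#' @param pKa Numeric vector of transition pKa values, ordered from the
#'   first (most acidic species') deprotonation onward.
#' @param pH Finite numeric scalar.
#' @param species Optional character labels, length `length(pKa) + 1`,
#'   from fully protonated to fully deprotonated.
#' @return Named numeric vector of fractions summing to 1.
#' @export
species_fractions <- function(pKa, pH, species = NULL) {
  stopifnot(all(is.finite(pKa)), is.finite(pH))
  nsp <- length(pKa) + 1L
  if (is.null(species)) species <- paste0("species", seq_len(nsp) - 1L)
  stopifnot(length(species) == nsp)
  # log10 relative abundance of species j (j deprotonations)
  lw <- c(0, cumsum(pH - pKa))
  w <- 10^(lw - max(lw))
  setNames(w / sum(w), species)
}
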