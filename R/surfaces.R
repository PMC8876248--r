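#' Canonical free-energy surfaces with analytic gradients
#'
#' Constructs a one-dimensional free-energy surface G(z) used as ground truth
#' by the synthetic umbrella-sampling module. `z` is the depth coordinate in
#' nm (0 = bilayer center), `G` is in kJ/mol. Four canonical shapes are
#' available:
#'
#' * `"flat"`: G(z) = 0 everywhere.
#' * `"harmonic"`: G(z) = k_s/2 * z^2, parameter `k_surface` (kJ mol^-1 nm^-2).
#' * `"square_well"`: G(z) = -depth on the half-open interval
#'   \[`z_lo`, `z_hi`), 0 elsewhere. The gradient is defined as 0 away from
#'   the edges (and, by convention, at them).
#' * `"membrane_double_well"`: a smooth, even surface mimicking the potential
#'   of mean force of an amphiphilic probe across a symmetric bilayer: minima
#'   of depth `D` at z = +/-`z_min`, a central (translocation) barrier of
#'   height `B` above the minima so that G(0) = -(D - B), and G = 0 in the
#'   water phase (|z| >= `z_wall`), reached by zero-slope cubic (Hermite)
#'   segments. Desorption barrier G(z_max) - G(z_min) equals `D` exactly and
#'   the translocation barrier G(0) - G(z_min) equals `B` exactly.
#'
#' @param name One of `"flat"`, `"harmonic"`, `"square_well"`,
#'   `"membrane_double_well"`.
#' @param ... Surface parameters (see Details): `k_surface`; `depth`, `z_lo`,
#'   `z_hi`; `D`, `B`, `z_min`, `z_wall`. All surfaces accept `z_max`
#'   (domain half-width, default 4 nm).
#' @return An object of class `fes_surface`: a list with `name`, `params`,
#'   `fun(z)` and `grad(z)` (both vectorised), and `z_max`.
#' @examples
#' s <- reference_surface("membrane_double_well", D = 40, B = 25, z_min = 1.4)
#' s$fun(c(0, 1.4, 4)) # -15, -40, 0
#' @export
reference_surface <- function(name, ...) {
  valid <- c("flat", "harmonic", "square_well", "membrane_double_well")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown surface name; valid names: ", paste(valid, collapse = ", "))
  }
  dots <- list(...)
  z_max <- if (!is.null(dots$z_max)) dots$z_max else 4.0
  stopifnot(is.numeric(z_max), z_max > 0)

  out <- switch(name,
    flat = list(
      params = list(z_max = z_max),
      fun = function(z) rep(0, length(z)),
      grad = function(z) rep(0, length(z))
    ),
    harmonic = {
      ks <- if (!is.null(dots$k_surface)) dots$k_surface else 10
      stopifnot(ks >= 0)
      list(
        params = list(k_surface = ks, z_max = z_max),
        fun = function(z) 0.5 * ks * z^2,
        grad = function(z) ks * z
      )
    },
    square_well = {
      depth <- if (!is.null(dots$depth)) dots$depth else 40
      z_lo <- if (!is.null(dots$z_lo)) dots$z_lo else 1.0
      z_hi <- if (!is.null(dots$z_hi)) dots$z_hi else z_lo +
        (if (!is.null(dots$width)) dots$width else 0.5)
      stopifnot(z_hi > z_lo)
      list(
        params = list(depth = depth, z_lo = z_lo, z_hi = z_hi, z_max = z_max),
        fun = function(z) ifelse(z >= z_lo & z < z_hi, -depth, 0),
        grad = function(z) rep(0, length(z))
      )
    },
    membrane_double_well = {
      D <- if (!is.null(dots$D)) dots$D else 40
      B <- if (!is.null(dots$B)) dots$B else 25
      z_min <- if (!is.null(dots$z_min)) dots$z_min else 1.4
      z_wall <- if (!is.null(dots$z_wall)) dots$z_wall else 2.6
      stopifnot(D > 0, B > 0, B <= D + B, z_min > 0, z_wall > z_min,
                z_wall <= z_max)
      p <- list(D = D, B = B, z_min = z_min, z_wall = z_wall, z_max = z_max)
      list(
        params = p,
        fun = function(z) .mdw_eval(z, p, deriv = FALSE),
        grad = function(z) .mdw_eval(z, p, deriv = TRUE)
      )
    }
  )
  structure(c(list(name = name), out, list(z_max = z_max)),
            class = "fes_surface")
}

## Piecewise cubic Hermite segments with zero end slopes; even in z.
.mdw_eval <- function(z, p, deriv = FALSE) {
  az <- abs(z)
  g0 <- -(p$D - p$B)      # value at the bilayer center
  val <- numeric(length(z))
  seg1 <- az <= p$z_min   # center -> well
  seg2 <- az > p$z_min & az < p$z_wall  # well -> water
  if (deriv) {
    val[seg1] <- .hermite01(az[seg1], 0, p$z_min, g0, -p$D, deriv = TRUE)
    val[seg2] <- .hermite01(az[seg2], p$z_min, p$z_wall, -p$D, 0, deriv = TRUE)
    val <- val * sign(z)  # chain rule through |z|
  } else {
    val[seg1] <- .hermite01(az[seg1], 0, p$z_min, g0, -p$D)
    val[seg2] <- .hermite01(az[seg2], p$z_min, p$z_wall, -p$D, 0)
    # beyond z_wall: exactly 0
  }
  val
}

.hermite01 <- function(x, x0, x1, y0, y1, deriv = FALSE) {
  t <- (x - x0) / (x1 - x0)
  if (deriv) (y1 - y0) * (6 * t - 6 * t^2) / (x1 - x0)
  else y0 + (y1 - y0) * (3 * t^2 - 2 * t^3)
}

#' @export
print.fes_surface <- function(x, ...) {
  cat("Free-energy surface:", x$name, "\n")
  pp <- x$params
  cat("  params:", paste(names(pp), signif(unlist(pp), 4), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a free-energy surface on a grid
#'
#' Convenience wrapper returning a [free_energy_profile()] sampled from an
#' analytic surface, e.g. to feed [kp_integral()] or [extract_barriers()]
#' with exact ground truth.
#'
#' @param surface A `fes_surface`.
#' @param z Grid in nm (default `seq(0, surface$z_max, by = 0.02)`).
#' @param temperature K (metadata only).
#' @return A `free_energy_profile`.
#' @export
surface_profile <- function(surface, z = NULL, temperature = 298.15) {
  stopifnot(inherits(surface, "fes_surface"))
  if (is.null(z)) z <- seq(0, surface$z_max, by = 0.02)
  free_energy_profile(z, surface$fun(z), temperature = temperature,
                      anchor = "as_is")
}
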