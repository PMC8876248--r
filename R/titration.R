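#' Titration series container
#'
#' Lipid concentrations and fluorescence intensities for one replicate
#' titration of a dye with lipid vesicles.
#'
#' @param lipid_concs mol/dm^3, >= 0.
#' @param intensities Arbitrary fluorescence units, same length.
#' @param replicate_id Optional label.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(lipid_concs, intensities, replicate_id = NULL) {
  stopifnot(length(lipid_concs) == length(intensities))
  if (any(lipid_concs < 0)) stop("negative lipid concentration")
  structure(list(lipid_concs = as.numeric(lipid_concs),
                 intensities = as.numeric(intensities),
                 replicate_id = replicate_id),
            class = "titration_series")
}

#' Generate a noisy synthetic titration
#'
#' Evaluates the partition equation at the given lipid concentrations and
#' applies multiplicative Gaussian noise, I = I_model * (1 + noise_cv * xi),
#' xi ~ N(0,1) - fluorescence error scales with signal. With `noise_cv = 0`
#' the model values are reproduced exactly.
#'
#' @param model A [partition_model()].
#' @param lipid_concs mol/dm^3, >= 0.
#' @param noise_cv Coefficient of variation, >= 0 (default 0.02).
#' @param seed Integer seed.
#' @param replicate_id Optional label.
#' @return A [titration_series()].
#' @export
generate_titration <- function(model, lipid_concs, noise_cv = 0.02,
                               seed = 1L, replicate_id = NULL) {
  stopifnot(inherits(model, "partition_model"), noise_cv >= 0)
  if (any(lipid_concs < 0)) stop("negative lipid concentration")
  mu <- partition_intensity(model, lipid_concs)
  set.seed(as.integer(seed))
  I <- mu * (1 + noise_cv * rnorm(length(mu)))
  titration_series(lipid_concs, I, replicate_id)
}

#' Standard titration concentration ladder
#'
#' Log-spaced lipid concentrations plus a zero point, the usual design of a
#' vesicle titration (default 12 points from 1e-5 to 1e-2 mol/dm^3).
#'
#' @param n Number of nonzero points.
#' @param from,to Concentration range, mol/dm^3.
#' @param include_zero Prepend a zero-lipid point (default TRUE).
#' @return Numeric vector of concentrations.
#' @export
titration_concs <- function(n = 12, from = 1e-5, to = 1e-2,
                            include_zero = TRUE) {
  stopifnot(n >= 1, from > 0, to > from)
  cc <- 10^seq(log10(from), log10(to), length.out = n)
  if (include_zero) c(0, cc) else cc
}
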