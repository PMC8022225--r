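#' Mass-scaling power law of free diffusion
#'
#' Fits `D_free = c * M^alpha` by ordinary least squares of `log10(D)` on
#' `log10(M)`. The Stokes-Einstein prediction for a spherical particle in
#' a homogeneous medium is `alpha = -1/3`; in the crowded bacterial
#' cytoplasm the measured exponent is much steeper.
#'
#' @param mass Molecular masses of the labeled protein complexes (kDa).
#' @param D Free diffusion coefficients (µm²/s).
#' @return An object of class `scaling_fit`: list with `alpha` (exponent),
#'   `log10_c` (intercept on the `log10 D` scale), `c` (prefactor of
#'   `D = c M^alpha`), `fit` (the underlying `lm`), and the data.
#' @examples
#' fit <- fit_power_law(c(1006, 478, 220, 128, 102),
#'                      c(1.2, 2.7, 3.3, 6.6, 6.9))
#' fit$alpha
#' @export
fit_power_law <- function(mass, D) {
  if (length(mass) != length(D)) stop("mass and D must have equal length")
  if (length(mass) < 2L) stop("need at least 2 (mass, D) pairs")
  if (any(mass <= 0) || any(D <= 0)) stop("mass and D must be positive")
  if (length(unique(mass)) < 2L) stop("need at least 2 distinct masses")
  df <- data.frame(logM = log10(mass), logD = log10(D))
  fit <- stats::lm(logD ~ logM, data = df)
  alpha <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  structure(list(alpha = alpha, log10_c = intercept,
                 c = 10^intercept, fit = fit,
                 data = data.frame(mass_kda = mass, D_free = D),
                 residuals = unname(stats::residuals(fit))),
            class = "scaling_fit")
}

#' Predict a free diffusion coefficient from the mass-scaling law
#'
#' Evaluates the fitted power law at a given molecular mass; used to
#' extrapolate `D_free` for proteins whose diffusion was not measured in
#' chromosome-free cells.
#'
#' @param mass Molecular mass (kDa, > 0); vectorized.
#' @param fit A [fit_power_law()] result.
#' @return Predicted D_free (µm²/s).
#' @export
predict_Dfree <- function(mass, fit) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (any(mass <= 0)) stop("mass must be positive")
  10^(fit$log10_c + fit$alpha * log10(mass))
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling_fit: D = %.3g * M^(%.2f)  [n = %d]\n",
              x$c, x$alpha, nrow(x$data)))
  invisible(x)
}
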