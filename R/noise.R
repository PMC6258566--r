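#' Measurement-noise parameters
#'
#' The trial-level measurement x is Gaussian around the true orientation s
#' with s.d. sigma(c, s) that decreases with stimulus reliability c and, via a
#' rectified 2-cycle sinusoid, increases away from the cardinal orientations:
#'
#'   sigma(c, s) = sqrt(base_var(c)) + psi * |sin(pi * s / 90)|.
#'
#' In parametric mode the base variance follows a reparameterized power law
#' anchored at the lowest and highest reliabilities used (c_L, c_H):
#'
#'   base_var(c) = sigma_L^2 + (sigma_L^2 - sigma_H^2) *
#'                 (c^-beta - c_L^-beta) / (c_L^-beta - c_H^-beta),
#'
#' so that sigma_L and sigma_H are exactly the measurement s.d.s at c_L and
#' c_H and beta sets the curvature in between. In nonparametric mode each of
#' the six reliability levels gets its own free s.d. and beta is unused.
#'
#' @param sigma_low,sigma_high Measurement s.d. (degrees) at the lowest /
#'   highest reliability (parametric mode).
#' @param beta Curvature exponent of the power law (> 0).
#' @param psi Amplitude (degrees) of the orientation-dependent noise term.
#' @param reliability_range `c(c_L, c_H)`: lowest and highest calibrated
#'   physical reliabilities.
#' @param sigma_per_level Six per-level s.d.s (degrees) for nonparametric
#'   mode; supply instead of `sigma_low`/`sigma_high`/`beta`.
#' @param reliability_values The six physical reliabilities the per-level
#'   s.d.s correspond to (nonparametric mode).
#' @return An object of class `co_noise`.
#' @examples
#' np <- noise_params(sigma_low = 12, sigma_high = 2, beta = 1.2)
#' sigma_of(np, 0.004)   # exactly 12 at c_L
#' sigma_of(np, 0.135)   # exactly 2 at c_H
#' @export
noise_params <- function(sigma_low = NULL, sigma_high = NULL, beta = 1,
                         psi = 0, reliability_range = range(reliability_preset()),
                         sigma_per_level = NULL,
                         reliability_values = reliability_preset()) {
  if (!is.null(sigma_per_level)) {
    stopifnot(length(sigma_per_level) == 6, all(sigma_per_level > 0),
              length(reliability_values) == 6, psi >= 0)
    out <- list(mode = "nonparametric",
                sigma_per_level = as.numeric(sigma_per_level),
                reliability_values = as.numeric(reliability_values),
                psi = psi)
  } else {
    stopifnot(is.numeric(sigma_low), is.numeric(sigma_high),
              sigma_low > 0, sigma_high > 0, beta > 0, psi >= 0,
              length(reliability_range) == 2,
              reliability_range[1] < reliability_range[2])
    out <- list(mode = "parametric", sigma_low = sigma_low,
                sigma_high = sigma_high, beta = beta, psi = psi,
                reliability_range = as.numeric(reliability_range))
  }
  structure(out, class = "co_noise")
}

#' Measurement s.d. at a given reliability and orientation
#'
#' @param noise A [noise_params()] object.
#' @param reliability Physical reliability value(s). In parametric mode these
#'   must lie inside the calibrated range `[c_L, c_H]` unless
#'   `extrapolate = TRUE`; in nonparametric mode they must match one of the
#'   six calibrated levels (or be an integer level index 1-6).
#' @param orientation Stimulus orientation(s) in degrees (recycled).
#' @param extrapolate Allow reliabilities outside the calibrated range
#'   (parametric mode); the value is clamped to the range boundary.
#' @return Numeric vector of measurement s.d.s (degrees).
#' @export
sigma_of <- function(noise, reliability, orientation = 0, extrapolate = FALSE) {
  stopifnot(inherits(noise, "co_noise"))
  n <- max(length(reliability), length(orientation))
  reliability <- rep_len(reliability, n)
  orientation <- rep_len(orientation, n)
  if (noise$mode == "parametric") {
    cl <- noise$reliability_range[1]
    ch <- noise$reliability_range[2]
    out_of_range <- reliability < cl | reliability > ch
    if (any(out_of_range)) {
      if (!extrapolate)
        stop("reliability outside the calibrated range [",
             signif(cl, 3), ", ", signif(ch, 3),
             "]; set extrapolate = TRUE to clamp", call. = FALSE)
      reliability <- pmin(pmax(reliability, cl), ch)
    }
    b <- noise$beta
    frac <- (reliability^(-b) - cl^(-b)) / (cl^(-b) - ch^(-b))
    base_var <- noise$sigma_low^2 +
      (noise$sigma_low^2 - noise$sigma_high^2) * frac
    base <- sqrt(pmax(base_var, 0))
  } else {
    if (all(reliability %in% 1:6)) {
      lvl <- as.integer(reliability)
    } else {
      lvl <- match_reliability_level(reliability, noise$reliability_values)
    }
    base <- noise$sigma_per_level[lvl]
  }
  base + noise$psi * abs(sin(pi * orientation / 90))
}

# Match physical reliability values to the calibrated levels (small relative
# tolerance); error on anything that is not one of the six levels.
match_reliability_level <- function(reliability, values) {
  idx <- vapply(reliability, function(r) {
    j <- which(abs(values - r) <= 1e-8 + 1e-6 * abs(r))
    if (length(j) != 1) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx))
    stop("reliability value not among the calibrated levels", call. = FALSE)
  idx
}
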