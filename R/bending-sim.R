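#' Forward simulation of a three-point bending test
#'
#' Generates a force-deflection record from a known ground-truth flexural
#' stiffness. Weights are added cumulatively, so the force at step k is
#' `F_k = g * sum(masses[1:k])` with `g = 9.81 m/s^2`. The midspan deflection
#' follows the Timoshenko form
#' `delta = F l^3 / (48 EI) + f_s F l / (4 G A)`:
#' the first term is the Euler-Bernoulli bending deflection, the second the
#' shear contribution that contaminates tests at low span-to-depth ratio
#' (`f_s` is the shear correction factor, 10/9 for a solid circular section;
#' `G = E / (E/G)`). Optional Gaussian noise is added to the recorded
#' deflections and to the caliper radius readings. A noise-free, shear-free
#' record inverts exactly under `EI = l^3 b / 48`.
#'
#' @param EI Ground-truth flexural stiffness (N mm^2), > 0.
#' @param span Span (mm), > 0.
#' @param masses Masses added per step (kg), 3 to 7 steps.
#' @param a,b True vertical/horizontal semi-axes of the section (mm); used for
#'   the caliper readings and, when `shear` is given, for the shear area
#'   `A = pi a b` and modulus `G`.
#' @param shear `NULL` for pure bending, or a list with `E_over_G` (default
#'   20) and `shear_factor` (default 10/9).
#' @param noise `NULL`, or a list with `deflection_sd` and `radius_sd` (mm).
#'   Noise draws use the current RNG state; seed externally for
#'   reproducibility.
#' @param specimen_id Optional identifier.
#' @param elastic_window Deflection window (mm) within which loading is
#'   considered safely elastic; excursions flag the record (see
#'   [bending_test()]).
#' @return A [bending_test()].
#' @export
simulate_bending <- function(EI, span, masses, a, b,
                             shear = NULL, noise = NULL,
                             specimen_id = NULL,
                             elastic_window = c(0.2, 5)) {
  stopifnot(EI > 0, span > 0)
  n <- length(masses)
  if (n < 3L || n > 7L) stop("number of loading steps must be between 3 and 7")
  if (any(masses <= 0)) stop("masses must be positive")
  g <- 9.81
  force <- g * cumsum(masses)
  defl <- force * span^3 / (48 * EI)
  if (!is.null(shear)) {
    defl <- defl + force * span * shear_compliance(EI, a, b, shear)
  }
  a_meas <- rep(a, 3)[1:3]
  b_meas <- rep(b, 3)[1:3]
  if (!is.null(noise)) {
    if (!is.null(noise$deflection_sd) && noise$deflection_sd > 0) {
      defl <- defl + stats::rnorm(n, 0, noise$deflection_sd)
    }
    if (!is.null(noise$radius_sd) && noise$radius_sd > 0) {
      a_meas <- pmax(a_meas + stats::rnorm(3, 0, noise$radius_sd), 0.05 * a)
      b_meas <- pmax(b_meas + stats::rnorm(3, 0, noise$radius_sd), 0.05 * b)
    }
  }
  bending_test(span = span, a = a_meas, b = b_meas,
               force = force, deflection = defl,
               specimen_id = specimen_id,
               elastic_window = elastic_window)
}

# shear compliance per unit force and span: f_s / (4 G A), in 1/N
shear_compliance <- function(EI, a, b, shear) {
  E_over_G <- if (is.null(shear$E_over_G)) 20 else shear$E_over_G
  f_s <- if (is.null(shear$shear_factor)) 10 / 9 else shear$shear_factor
  I <- (pi / 4) * a^3 * b
  A <- pi * a * b
  E <- EI / I
  G <- E / E_over_G
  f_s / (4 * G * A)
}

#' Apparent flexural stiffness under the shear forward model
#'
#' Closed form of what the bending reduction recovers from a noise-free test
#' simulated with shear: `EI_app = EI / (1 + 48 EI c / l^2)` where `c` is the
#' shear compliance. Strictly increasing in span, approaching the true EI.
#'
#' @inheritParams simulate_bending
#' @return Apparent EI in N mm^2.
#' @export
apparent_EI <- function(EI, span, a, b, shear) {
  cshear <- if (is.null(shear)) 0 else shear_compliance(EI, a, b, shear)
  EI / (1 + 48 * EI * cshear / span^2)
}
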