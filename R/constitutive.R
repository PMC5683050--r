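#' Yeoh strain energy density
#'
#' Evaluates \eqn{\Psi(I_1) = c_1 (I_1-3) + c_2 (I_1-3)^2 + c_3 (I_1-3)^3}
#' (kPa).  The energy is zero in the reference state \eqn{I_1 = 3} and does not
#' depend on the stress convention flag.
#'
#' @param I1 First strain invariant(s), must be `>= 3` (any incompressible
#'   uniaxial state satisfies this).
#' @param params A [yeoh_params()] object.
#' @return Energy density in kPa, vectorized over `I1`.
#' @export
strain_energy <- function(I1, params) {
  stopifnot(is_yeoh_params(params))
  if (any(I1 < 3 - 1e-12))
    stop("I1 < 3 is outside the domain of the strain energy function")
  x <- I1 - 3
  params$c1 * x + params$c2 * x^2 + params$c3 * x^3
}

#' Kinematics of incompressible uniaxial stretch
#'
#' For an incompressible homogeneous uniaxial state with axial stretch
#' \eqn{\lambda}, the deformation gradient is
#' \eqn{F = \mathrm{diag}(\lambda^{-1/2}, \lambda^{-1/2}, \lambda)}, so the
#' first invariant is \eqn{I_1 = \lambda^2 + 2/\lambda} and the transverse
#' stretch is \eqn{1/\sqrt{\lambda}}.
#'
#' @param lambda Axial stretch ratio(s), `> 0`.
#' @return A data frame with columns `lambda`, `I1`, `lambda_transverse`.
#' @examples
#' uniaxial_invariant(c(1, 2, 5))
#' @export
uniaxial_invariant <- function(lambda) {
  if (any(lambda <= 0)) stop("stretch ratio must be positive")
  data.frame(lambda = lambda,
             I1 = lambda^2 + 2 / lambda,
             lambda_transverse = 1 / sqrt(lambda))
}

#' Degree-9 polynomial coefficients of the closed-form uniaxial stress
#'
#' The incompressible uniaxial axial Cauchy stress of the cubic Yeoh model can
#' be written \eqn{\sigma_z = \wp^{[9]}(\lambda)/\lambda^3} where
#' \eqn{\wp^{[9]}} is a degree-9 polynomial in \eqn{\lambda} whose coefficients
#' are linear in the material constants.  This returns the ten coefficients for
#' powers 9 down to 0:
#' \deqn{[\,3c_3,\ 0,\ 2c_2-18c_3,\ 9c_3,\ 27c_3-6c_2+c_1,\ 2c_2-18c_3,\ 0,\
#'   -27c_3+6c_2-c_1,\ 36c_3-4c_2,\ -12c_3\,].}
#' They sum to zero, so \eqn{\sigma_z(1) = 0} for every parameter set.
#'
#' @param params A [yeoh_params()] object.
#' @return Named numeric vector of length 10 (kPa), names `"l9"` ... `"l0"`.
#' @export
p9_coefficients <- function(params) {
  stopifnot(is_yeoh_params(params))
  c1 <- params$c1; c2 <- params$c2; c3 <- params$c3
  c(l9 = 3 * c3,
    l8 = 0,
    l7 = 2 * c2 - 18 * c3,
    l6 = 9 * c3,
    l5 = 27 * c3 - 6 * c2 + c1,
    l4 = 2 * c2 - 18 * c3,
    l3 = 0,
    l2 = -27 * c3 + 6 * c2 - c1,
    l1 = 36 * c3 - 4 * c2,
    l0 = -12 * c3)
}

# Horner evaluation of the degree-9 polynomial at lambda (vectorized).
.p9_eval <- function(lambda, params) {
  k <- p9_coefficients(params)
  out <- rep(k[[1]], length(lambda))
  for (i in 2:10) out <- out * lambda + k[[i]]
  out
}

#' Closed-form uniaxial Cauchy stress
#'
#' Axial Cauchy stress of an incompressible uniaxial stretch state under the
#' cubic Yeoh model.  Under the `"as_printed"` convention of the parameter set
#' this is \eqn{\wp^{[9]}(\lambda)/\lambda^3}; under the `"standard"`
#' (textbook) convention it is exactly twice that, equal to
#' \eqn{2\,\Psi'(I_1)(\lambda^2 - 1/\lambda)}.
#'
#' @param lambda Axial stretch ratio(s), `> 0`.  Values below 1 (compression)
#'   are mathematically valid and accepted.
#' @param params A [yeoh_params()] object; its `convention` selects the
#'   formula.
#' @return Axial Cauchy stress in kPa, vectorized over `lambda`.
#' @examples
#' uniaxial_stress(seq(1, 5, by = 0.5), species_preset("aplysia")$params)
#' @export
uniaxial_stress <- function(lambda, params) {
  stopifnot(is_yeoh_params(params))
  if (any(lambda <= 0)) stop("stretch ratio must be positive")
  s <- .p9_eval(lambda, params) / lambda^3
  if (params$convention == "standard") 2 * s else s
}

#' Convert Cauchy to nominal (first Piola-Kirchhoff) uniaxial stress
#'
#' In incompressible uniaxial tension the nominal stress (force per reference
#' area) is the Cauchy stress divided by the axial stretch.
#'
#' @param sigma Cauchy stress (kPa).
#' @param lambda Axial stretch ratio(s).
#' @return Nominal stress in kPa.
#' @export
cauchy_to_nominal <- function(sigma, lambda) {
  if (any(lambda <= 0)) stop("stretch ratio must be positive")
  sigma / lambda
}

#' Uniaxial stress derived directly from the stress tensor relation
#'
#' Independent derivation of the uniaxial stress from
#' \eqn{\sigma = -k I + 2 \Psi'(I_1)\, F F^T}: eliminating the Lagrange
#' multiplier `k` through the traction-free lateral faces gives
#' \eqn{\sigma_z = 2\,\Psi'(I_1)(\lambda^2 - 1/\lambda)}.  This equals the
#' `"standard"`-convention [uniaxial_stress()] and exactly twice the
#' `"as_printed"` value; it is kept as a separate code path so the two can be
#' checked against each other.
#'
#' @inheritParams uniaxial_stress
#' @return Axial Cauchy stress in kPa.
#' @export
derive_stress_from_sef <- function(lambda, params) {
  stopifnot(is_yeoh_params(params))
  if (any(lambda <= 0)) stop("stretch ratio must be positive")
  I1 <- lambda^2 + 2 / lambda
  x <- I1 - 3
  dpsi <- params$c1 + 2 * params$c2 * x + 3 * params$c3 * x^2
  2 * dpsi * (lambda^2 - 1 / lambda)
}

#' Drucker stability margin of the uniaxial response
#'
#' Minimum of \eqn{d\sigma_z/d\lambda} over a stretch interval, computed from
#' the exact derivative of the rational closed form on a dense grid.  A
#' positive margin certifies that the stress is strictly increasing over the
#' range (Drucker stability of the uniaxial response), which keeps the FE
#' boundary value problems well posed.
#'
#' @param params A [yeoh_params()] object.
#' @param lambda_range Length-2 numeric, `1 <= lower < upper`.
#' @param n Number of grid points for the minimization.
#' @return Minimum slope `d sigma / d lambda` (kPa) over the range.
#' @examples
#' drucker_margin(species_preset("pig")$params, c(1, 1.08))
#' @export
drucker_margin <- function(params, lambda_range, n = 2001L) {
  stopifnot(is_yeoh_params(params))
  if (length(lambda_range) != 2 || any(!is.finite(lambda_range)))
    stop("lambda_range must be two finite values")
  if (lambda_range[1] < 1 || lambda_range[2] <= lambda_range[1])
    stop("lambda_range must satisfy 1 <= lower < upper")
  lam <- seq(lambda_range[1], lambda_range[2], length.out = n)
  # d/dlambda [p9(l)/l^3] = p9'(l)/l^3 - 3 p9(l)/l^4, p9' by exact coefficient shift
  k <- p9_coefficients(params)
  pow <- 9:0
  dk <- (k * pow)[1:9]             # coefficients of the degree-8 derivative
  p  <- .p9_eval(lam, params)
  dp <- rep(dk[[1]], n)
  for (i in 2:9) dp <- dp * lam + dk[[i]]
  slope <- dp / lam^3 - 3 * p / lam^4
  if (params$convention == "standard") slope <- 2 * slope
  min(slope)
}
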