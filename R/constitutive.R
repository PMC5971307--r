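# Constitutive laws: passive transversely isotropic hyperelasticity for
# myocardial tissue and the active uniaxial fibre-stress law.

#' Passive material parameters for myocardium
#'
#' Parameters of the polynomial strain-energy function
#' \deqn{W = \sum_{i=1}^{3} a_i (I_1 - 3)^i + b_1 (I_4 - 1)^2 + b_2 (I_4 - 1)^4}
#' where `I1` is the first invariant of the right Cauchy-Green tensor and `I4`
#' the squared stretch along the fibre direction. The defaults are the
#' constants obtained from biaxial tests of passive myocardium at quasi-static
#' rate; `rate_factor` (default 6) scales all stress-like coefficients to the
#' stiffer response at physiological strain rates and is applied by
#' [apply_rate_factor()], never at construction. `kappa` is the volumetric
#' penalty modulus enforcing near-incompressibility.
#'
#' @param a1,a2,a3 isotropic coefficients, kPa.
#' @param b1,b2 fibre-term coefficients for `(I4-1)^2` and `(I4-1)^4`, kPa.
#' @param rate_factor dimensionless multiplier for dynamic stiffening.
#' @param kappa penalty bulk modulus, kPa.
#' @return Object of class `passive_params`.
#' @export
passive_params <- function(a1 = 0.347, a2 = 13.438, a3 = 48.846,
                           b1 = 0.436, b2 = 27.692,
                           rate_factor = 6, kappa = 1000) {
  p <- list(a1 = a1, a2 = a2, a3 = a3, b1 = b1, b2 = b2,
            rate_factor = rate_factor, kappa = kappa)
  if (any(unlist(p[1:5]) < 0)) stop("stress coefficients must be non-negative")
  if (rate_factor <= 0) stop("rate_factor must be positive")
  if (kappa <= 10 * a1) stop("kappa must be much larger than a1")
  structure(p, class = "passive_params")
}

#' @export
print.passive_params <- function(x, ...) {
  cat(sprintf("passive myocardium: a = (%.4g, %.4g, %.4g) kPa, b = (%.4g, %.4g) kPa\n",
              x$a1, x$a2, x$a3, x$b1, x$b2))
  cat(sprintf("  rate factor %g (apply with apply_rate_factor()), kappa = %g kPa\n",
              x$rate_factor, x$kappa))
  invisible(x)
}

#' Apply the strain-rate stiffening factor
#'
#' Multiplies all stress-like coefficients (`a1..a3`, `b1`, `b2`) by
#' `factor` (default: the stored `rate_factor`), leaving the penalty modulus
#' unchanged. Used to convert quasi-static fitted constants to the response at
#' beating-heart strain rates.
#'
#' @param params a [passive_params()] object.
#' @param factor multiplier; defaults to `params$rate_factor`.
#' @return A new `passive_params` object with `rate_factor = 1`.
#' @export
apply_rate_factor <- function(params, factor = params$rate_factor) {
  passive_params(params$a1 * factor, params$a2 * factor, params$a3 * factor,
                 params$b1 * factor, params$b2 * factor,
                 rate_factor = 1, kappa = params$kappa)
}

#' Active fibre material parameters
#'
#' @param E0 initial Young's modulus of the fully activated myocyte stress-
#'   strain relation, kPa.
#' @param fibre_volume_fraction volume fraction of myocytes in the wall
#'   carrying the active stress.
#' @return Object of class `active_params`.
#' @export
active_params <- function(E0 = 200, fibre_volume_fraction = 0.8) {
  if (E0 <= 0) stop("E0 must be positive")
  if (fibre_volume_fraction <= 0 || fibre_volume_fraction > 1)
    stop("fibre_volume_fraction must lie in (0, 1]")
  structure(list(E0 = E0, fibre_volume_fraction = fibre_volume_fraction),
            class = "active_params")
}

#' Passive strain-energy density
#'
#' Evaluates the polynomial strain-energy function at given invariants.
#' Vectorized over `I1` and `I4`.
#'
#' @param I1 first invariant of the right Cauchy-Green tensor (>= 3 at J = 1).
#' @param I4 squared fibre stretch (> 0).
#' @param params a [passive_params()] object.
#' @return Energy density, kPa.
#' @export
passive_energy <- function(I1, I4, params) {
  if (any(!is.finite(I1)) || any(!is.finite(I4)))
    stop("non-finite invariants passed to passive_energy")
  x1 <- I1 - 3; x4 <- I4 - 1
  params$a1 * x1 + params$a2 * x1^2 + params$a3 * x1^3 +
    params$b1 * x4^2 + params$b2 * x4^4
}

#' Passive Cauchy stress from a deformation gradient
#'
#' Computes the Cauchy stress of the passive law for a deformation gradient
#' `F` and reference fibre direction `f0`, using the isochoric-volumetric
#' split: the polynomial energy acts on the isochoric invariants and
#' near-incompressibility is enforced by the penalty `kappa/2 (J-1)^2`, which
#' contributes a hydrostatic stress `kappa (J-1) I`.
#'
#' @param F 3 x 3 deformation gradient (det F > 0).
#' @param f0 reference unit fibre direction.
#' @param params a [passive_params()] object.
#' @return 3 x 3 symmetric Cauchy stress, kPa.
#' @export
passive_stress <- function(F, f0, params) {
  J <- det(F)
  if (J <= 0) stop("deformation gradient with non-positive determinant")
  f0 <- f0 / sqrt(sum(f0^2))
  C <- t(F) %*% F
  Ci <- solve(C)
  I1 <- sum(diag(C)); I4 <- drop(t(f0) %*% C %*% f0)
  Jm23 <- J^(-2 / 3)
  x1 <- Jm23 * I1 - 3; x4 <- Jm23 * I4 - 1
  W1 <- params$a1 + 2 * params$a2 * x1 + 3 * params$a3 * x1^2
  W4 <- 2 * params$b1 * x4 + 4 * params$b2 * x4^3
  S <- 2 * W1 * (Jm23 * diag(3) - (Jm23 * I1 / 3) * Ci) +
       2 * W4 * (Jm23 * (f0 %o% f0) - (Jm23 * I4 / 3) * Ci)
  sig <- F %*% S %*% t(F) / J + params$kappa * (J - 1) * diag(3)
  (sig + t(sig)) / 2
}

#' Total strain-energy density for a deformation gradient
#'
#' Isochoric polynomial energy plus volumetric penalty; the differentiation
#' oracle for [passive_stress()].
#'
#' @inheritParams passive_stress
#' @return Energy density, kPa.
#' @export
passive_energy_F <- function(F, f0, params) {
  J <- det(F)
  f0 <- f0 / sqrt(sum(f0^2))
  C <- t(F) %*% F
  I1 <- sum(diag(C)); I4 <- drop(t(f0) %*% C %*% f0)
  Jm23 <- J^(-2 / 3)
  passive_energy(Jm23 * I1, Jm23 * I4, params) + params$kappa / 2 * (J - 1)^2
}

#' Active fibre Cauchy stress
#'
#' Uniaxial tension generated by an activated myocyte as a function of its
#' elastic logarithmic strain: `sigma = E0 exp(eps) (exp(eps) - 1)` for
#' `eps > 0` and zero otherwise (no compressive stiffness). The slope at
#' `eps = 0+` equals `E0`. Vectorized over `eps`.
#'
#' @param eps elastic logarithmic strain along the fibre.
#' @param params an [active_params()] object.
#' @return Cauchy stress, kPa (0 for non-positive strain).
#' @export
active_fibre_stress <- function(eps, params) {
  ifelse(eps > 0, params$E0 * exp(eps) * (exp(eps) - 1), 0)
}
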