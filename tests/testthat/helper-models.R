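# Shared fixtures, memoized so expensive solves run once per test session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# coarse LV pipeline for unit tests (224 elements; runs in seconds)
coarse_mesh <- function() memo("coarse_mesh",
  build_lv_mesh(n_circ = 8, n_long = 4))

coarse_model <- function() memo("coarse_model",
  prepare_lv_model(mesh = coarse_mesh()))

# full default-resolution pipeline used by the acceptance checks: unloading,
# control calibration and the five activation scenarios
acc_model <- function() memo("acc_model", prepare_lv_model())

acc_suite <- function() memo("acc_suite",
  run_experiment_suite(acc_model(),
                       scenarios = c("control", "const_emd", "const_msv",
                                     "const_both", "intramural")))

# random deformation gradient with J in [0.95, 1.05]
random_F <- function() {
  F <- diag(3) + matrix(stats::rnorm(9, 0, 0.04), 3)
  F * (stats::runif(1, 0.95, 1.05) / det(F))^(1 / 3)
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# finite-difference Cauchy stress from the energy (oracle for passive_stress)
fd_cauchy <- function(F, f0, params, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (passive_energy_F(Fp, f0, params) -
                passive_energy_F(Fm, f0, params)) / (2 * h)
  }
  s <- P %*% t(F) / det(F)
  (s + t(s)) / 2
}

# semi-analytic inflation pressure of an incompressible isotropic thick-walled
# sphere: deformed inner radius ratio lam_i = r_i / R_i, reference radii R_i,
# R_o. Radial equilibrium d(sigma_r)/dr = 2 (sigma_theta - sigma_r) / r with
# sigma_theta - sigma_r = 2 W1 (lam^2 - lam^-4), integrated in the reference
# radius (dr/dR = (R/r)^2 by incompressibility).
sphere_pressure <- function(lam_i, R_i, R_o, params) {
  r_i3 <- (lam_i * R_i)^3
  integrand <- function(R) {
    r <- (R^3 + r_i3 - R_i^3)^(1 / 3)
    lam <- r / R
    I1 <- 2 * lam^2 + lam^-4
    W1 <- params$a1 + 2 * params$a2 * (I1 - 3) + 3 * params$a3 * (I1 - 3)^2
    4 * W1 * (lam^2 - lam^-4) / r * (R / r)^2
  }
  stats::integrate(integrand, R_i, R_o, rel.tol = 1e-9)$value
}
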