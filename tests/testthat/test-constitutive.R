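test_that("passive energy matches hand-evaluated polynomial values", {
  p <- passive_params()
  expect_equal(passive_energy(3, 1, p), 0)
  expect_equal(passive_energy(3.01, 1, p),
               0.347 * 0.01 + 13.438 * 1e-4 + 48.846 * 1e-6, tolerance = 1e-12)
  expect_equal(passive_energy(3, 1.1, p),
               0.436 * 0.1^2 + 27.692 * 0.1^4, tolerance = 1e-12)
  expect_error(passive_energy(NaN, 1, p), "non-finite")
})

test_that("energy is even in (I4 - 1)", {
  p <- passive_params()
  for (x in c(0.01, 0.05, 0.2))
    expect_equal(passive_energy(3, 1 + x, p), passive_energy(3, 1 - x, p))
})

test_that("rate factor scales stress coefficients only", {
  p <- passive_params()
  p6 <- apply_rate_factor(p)
  expect_equal(p6$a1, 0.347 * 6)
  expect_equal(p6$b2, 27.692 * 6)
  expect_equal(p6$kappa, p$kappa)
  p1 <- apply_rate_factor(p, 1)
  expect_equal(p1$a2, p$a2)
})

test_that("passive stress is zero at identity and frame indifferent", {
  p <- apply_rate_factor(passive_params())
  f0 <- c(1, 0, 0)
  expect_equal(passive_stress(diag(3), f0, p), matrix(0, 3, 3))
  # pure rotation: zero stress, rotated configurations give rotated stress
  th <- 0.7
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(max(abs(passive_stress(Q, f0, p))), 0, tolerance = 1e-10)
  set.seed(42)
  for (k in 1:10) {
    F <- random_F()
    expect_equal(passive_energy_F(Q %*% F, f0, p), passive_energy_F(F, f0, p),
                 tolerance = 1e-12)
  }
})

test_that("passive stress equals numerical differentiation of the energy", {
  p <- apply_rate_factor(passive_params())
  set.seed(7)
  worst <- 0
  for (k in 1:100) {
    F <- random_F()
    f0 <- random_unit()
    s <- passive_stress(F, f0, p)
    s_fd <- fd_cauchy(F, f0, p)
    worst <- max(worst, max(abs(s - s_fd)) / max(abs(s_fd)))
  }
  expect_lt(worst, 1e-5)
})

test_that("incompressible equibiaxial stretch matches the finite-difference oracle", {
  p <- passive_params()
  lam <- 1.05
  F <- diag(c(lam, lam, 1 / lam^2))
  f0 <- c(1, 0, 0)
  s <- passive_stress(F, f0, p)
  expect_equal(s, fd_cauchy(F, f0, p), tolerance = 1e-6)
  expect_true(abs(s[1, 2]) < 1e-12 && abs(s[1, 3]) < 1e-12)
})

test_that("active law follows sigma = E0 exp(eps)(exp(eps)-1) with no compressive stress", {
  a <- active_params()
  expect_equal(active_fibre_stress(0, a), 0)
  expect_equal(active_fibre_stress(0.1, a), 200 * exp(0.1) * (exp(0.1) - 1),
               tolerance = 1e-12)
  expect_equal(active_fibre_stress(-0.05, a), 0)
  # monotone increasing and convex for positive strain
  eps <- seq(1e-4, 0.3, length.out = 200)
  s <- active_fibre_stress(eps, a)
  expect_true(all(diff(s) > 0))
  expect_true(all(diff(diff(s)) > 0))
  # initial slope E0: sigma/eps -> E0 as eps -> 0+
  expect_equal(active_fibre_stress(1e-8, a) / 1e-8, 200, tolerance = 1e-6)
})

test_that("parameter validation catches invalid inputs", {
  expect_error(passive_params(a1 = -1), "non-negative")
  expect_error(passive_params(kappa = 1), "kappa")
  expect_error(active_params(E0 = 0), "E0")
  expect_error(active_params(fibre_volume_fraction = 1.2), "fraction")
  expect_error(passive_stress(diag(c(1, 1, -1)), c(1, 0, 0), passive_params()),
               "determinant")
})
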