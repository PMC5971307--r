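# Single-element patch test, thick-walled-sphere benchmark and the behaviour
# of the filling / isovolumic solvers.

unit_cube_system <- function(material) {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  elems <- matrix(1:8, 1)
  fibres <- matrix(c(1, 0, 0), 1)
  face <- matrix(c(2L, 6L, 7L, 3L), 1)   # x = 1 face, inward (-x) load normal
  fixed <- c(3 * (c(1, 4, 5, 8) - 1) + 1,  # u_x = 0 on x = 0
             3 * (c(1, 2, 5, 6) - 1) + 2,  # u_y = 0 on y = 0
             3 * (c(1, 2, 3, 4) - 1) + 3)  # u_z = 0 on z = 0
  ivcsim:::.fe_system_raw(nodes, elems, fibres, face, face, sort(fixed),
                          material)
}

test_that("single-element patch test: uniform pressure gives the homogeneous stress state", {
  mat <- apply_rate_factor(passive_params())
  sys <- unit_cube_system(mat)
  p <- 0.5
  cfg <- solver_config()
  sol <- ivcsim:::.newton_fixed_p(sys, matrix(0, 8, 3), p,
                                  ivcsim:::.no_activation(sys), cfg)
  expect_true(sol$ok)
  U <- sol$U
  # homogeneous deformation: recover F from the corner displacements
  F <- diag(c(1 + U[2, 1] - U[1, 1], 1 + U[3, 2] - U[2, 2],
              1 + U[5, 3] - U[1, 3]))
  expect_lt(abs(U[7, 1] - U[2, 1]), 1e-10)       # face moves rigidly
  sig <- passive_stress(F, c(1, 0, 0), mat)
  expect_equal(sig[1, 1], -p, tolerance = 1e-5)  # fibre-axis stress = -p
  expect_equal(sig[2, 2], 0, tolerance = 1e-5 * p)
  expect_equal(sig[3, 3], 0, tolerance = 1e-5 * p)
  # the element's recovered fibre stress agrees with the constitutive oracle
  expect_equal(sol$asm$sig_ff[1], sig[1, 1], tolerance = 1e-4)
})

test_that("thick-walled sphere inflation matches the semi-analytic relation within 2%", {
  mat <- apply_rate_factor(passive_params(b1 = 0, b2 = 0))  # isotropic
  sphere <- build_lv_mesh(lv_dimensions(30, 30, 9, 0), n_circ = 16, n_long = 8,
                          target_volume_ml = NULL)
  sys <- fe_system(sphere, mat, basal_bc = "symmetry")
  st <- solve_filling(sys, 1.3)
  lam_i <- (st$V_ml / cavity_volume(sphere))^(1 / 3)
  expect_gt(lam_i, 1.01)
  p_an <- sphere_pressure(lam_i, 30, 39, mat)
  expect_lt(abs(p_an - 1.3) / 1.3, 0.02)
})

test_that("filling with zero pressure returns the reference state", {
  model <- coarse_model()
  sys <- model$system
  st0 <- solve_filling(sys, 0)
  expect_equal(max(abs(st0$U)), 0)
  expect_equal(st0$V_ml, cavity_volume(model$unloaded$mesh), tolerance = 1e-9)
})

test_that("re-inflation of the unloaded geometry restores the end-diastolic volume", {
  model <- coarse_model()
  expect_equal(model$ed_state$V_ml, 122, tolerance = 0.01)
  expect_lt(max(abs(model$ed_state$Jbar - 1)), 0.01)  # near-incompressible
})

test_that("isovolumic phase without activation keeps the end-diastolic pressure", {
  model <- coarse_model()
  sc <- scenario_spec("control", msv_scale = 1e-3)
  sched <- build_schedule(model$mesh, sc)
  sched$onset <- sched$onset + 1e6  # never activates
  cfg <- solver_config(t_max = 8)
  res <- solve_ivc(model$system, model$ed_state, sched, cfg)
  expect_false(res$reached_p_stop)
  expect_equal(res$trace$pressure_kPa, rep(1.3, nrow(res$trace)))
  expect_true(all(res$layer_stress_active == 0))
})

test_that("control run conserves cavity volume and raises pressure monotonically", {
  model <- coarse_model()
  res <- run_scenario(model, "control", 2e-3)
  expect_true(res$reached_p_stop)
  tr <- res$trace
  expect_lt(max(abs(tr$volume_ml - tr$volume_ml[1])) / tr$volume_ml[1], 1e-6)
  after <- tr$time_ms >= min(res$schedule$onset)
  expect_true(all(diff(tr$pressure_kPa[after]) >= -1e-9))
  # active stress appears in every layer after global activation
  expect_true(all(res$layer_stress_active[nrow(res$layer_stress_active), ] > 0))
})

test_that("IVC duration is stable under mesh refinement (same contraction rate)", {
  res_c <- run_scenario(coarse_model(), "control", 2e-3)
  res_f <- run_scenario(acc_model(), "control", 2e-3)
  d_c <- ivc_duration(res_c$trace)$duration_ms
  d_f <- ivc_duration(res_f$trace)$duration_ms
  expect_lt(abs(d_c - d_f) / d_f, 0.03)
})

test_that("pressure trace export includes unit conversions", {
  model <- coarse_model()
  res <- run_scenario(model, "control", 2e-3)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(res$trace, f)
  df <- utils::read.csv(f)
  expect_equal(df$pressure_mmHg, df$pressure_kPa * 7.50062, tolerance = 1e-9)
  expect_true(all(c("time_ms", "volume_ml", "dpdt_mmHg_per_s") %in% names(df)))
  unlink(f)
})
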