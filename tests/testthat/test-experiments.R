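linear_trace <- function(t0, t1, p0, p1, dt = 1, lead = 0) {
  t <- seq(0, t1, by = dt)
  p <- ifelse(t < t0, p0, p0 + (p1 - p0) * (t - t0) / (t1 - t0))
  data.frame(time_ms = t, pressure_kPa = p)
}

test_that("IVC duration on constructed traces excludes the latent period", {
  # pure ramp 1.3 -> 10.7 kPa over exactly 60 ms
  tr <- linear_trace(0, 60, 1.3, 10.7)
  expect_equal(ivc_duration(tr)$duration_ms, 60, tolerance = 1e-9)
  # 47 ms latent period, then the same ramp ending at 107 ms
  tr2 <- linear_trace(47, 107, 1.3, 10.7)
  d2 <- ivc_duration(tr2)
  expect_equal(d2$duration_ms, 60, tolerance = 1e-9)
  expect_equal(d2$t_onset_ms, 47, tolerance = 1e-9)
  # plateau below the aortic pressure is an error reporting the maximum
  tr3 <- linear_trace(0, 60, 1.3, 9)
  expect_error(ivc_duration(tr3), "9")
})

test_that("dp/dt maximum via central differences with unit conversion", {
  tr <- linear_trace(0, 60, 1.3, 10.7)
  dp <- dpdt_max(tr)
  expect_equal(dp$dpdt_max_kPa_s, 9.4 / 0.060, tolerance = 1e-9)
  expect_equal(dp$dpdt_max_mmHg_s, 9.4 / 0.060 * 7.50062, tolerance = 1e-6)
  # constant trace: zero slope
  trc <- data.frame(time_ms = 0:10, pressure_kPa = rep(1.3, 11))
  expect_equal(dpdt_max(trc)$dpdt_max_mmHg_s, 0)
  # convex (quadratic) rise: maximum at the last interior sample
  t <- 0:50
  trq <- data.frame(time_ms = t, pressure_kPa = 1.3 + 0.004 * t^2)
  expect_equal(dpdt_max(trq)$t_at_max_ms, 49)
})

test_that("doubling the contraction rate shortens IVC (calibration monotonicity)", {
  model <- coarse_model()
  d1 <- ivc_duration(run_scenario(model, "control", 1.5e-3)$trace)$duration_ms
  d2 <- ivc_duration(run_scenario(model, "control", 3.0e-3)$trace)$duration_ms
  expect_lt(d2, d1)
})

test_that("calibration is deterministic and independent of the initial guess", {
  model <- coarse_model()
  c1 <- memo("coarse_cal", calibrate_msv_scale(model, init = 1.4e-3))
  expect_lte(abs(c1$ivc_ms - 60), 0.5)
  c2 <- calibrate_msv_scale(model, init = 3e-3)
  expect_lt(abs(c1$msv_scale - c2$msv_scale) / c1$msv_scale, 0.01)
  # bit-identical metrics on re-run with the same scale
  r1 <- run_scenario(model, "control", c1$msv_scale)
  r2 <- run_scenario(model, "control", c1$msv_scale)
  expect_identical(r1$trace$pressure_kPa, r2$trace$pressure_kPa)
})

test_that("scenario suite assembles metrics, percent changes and output files", {
  model <- coarse_model()
  scale <- memo("coarse_cal", calibrate_msv_scale(model, init = 1.4e-3))$msv_scale
  dir <- tempfile()
  suite <- run_experiment_suite(model, scenarios = c("control", "const_emd"),
                                msv_scale = scale, output_dir = dir)
  met <- suite$metrics
  expect_equal(met$scenario, c("control", "const_emd"))
  expect_equal(met$ivc_change_pct[1], 0)
  expect_equal(met$dpdt_change_pct[1], 0)
  expect_gt(met$ivc_ms[2], met$ivc_ms[1])
  expect_true(file.exists(file.path(dir, "summary_metrics.csv")))
  expect_true(file.exists(file.path(dir, "control", "trace.csv")))
  expect_true(file.exists(file.path(dir, "const_emd", "profile_end_ivc.csv")))
  mj <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(mj$msv_scale, scale, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("layer stress summary is tidy and carries the transmural profile", {
  model <- coarse_model()
  res <- run_scenario(model, "control", 2e-3)
  ls <- layer_stress_summary(res)
  expect_equal(nrow(ls), nrow(res$trace) * 7)
  prof <- attr(ls, "profile")
  expect_equal(nrow(prof), 7)
  expect_true(all(diff(prof$depth_pct) > 0))
})

test_that("run configuration files override model defaults", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(mesh = list(n_circ = 8, n_long = 4),
                            material = list(a1 = 0.5),
                            scenario = list(name = "const_emd"),
                            p_ao = 11),
                       f, auto_unbox = TRUE)
  cfg <- read_run_config(f)
  args <- config_to_model_args(cfg)
  expect_equal(nrow(args$mesh$elems), 8 * 4 * 7)
  expect_equal(args$material$a1, 0.5 * 6)  # rate-adjusted
  expect_equal(args$scenario$name, "const_emd")
  expect_equal(args$p_ao, 11)
  expect_equal(args$p_ed, 1.3)
  unlink(f)
})
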