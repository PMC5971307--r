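# Contractility metrics, calibration of the contraction rate to the target
# isovolumic duration, and the comparative scenario suite.

KPA_TO_MMHG <- 7.50062

#' Duration of isovolumic contraction from a pressure trace
#'
#' Measures the time from the onset of pressure rise to the pressure reaching
#' the diastolic aortic value `p_ao`. The rise is detected at the first sample
#' exceeding `p_ed + 0.05` kPa; the onset time is then back-extrapolated to
#' the end-diastolic level along the local slope, so a latent period at
#' `p_ed` is excluded exactly. The `p_ao` crossing is linearly interpolated
#' between bracketing samples.
#'
#' @param trace data.frame with `time_ms` and `pressure_kPa` on a uniform
#'   grid.
#' @param p_ed end-diastolic pressure, kPa.
#' @param p_ao diastolic aortic pressure, kPa.
#' @return List with `duration_ms`, `t_onset_ms`, `t_end_ms`.
#' @export
ivc_duration <- function(trace, p_ed = 1.3, p_ao = 10.7) {
  t <- trace$time_ms; p <- trace$pressure_kPa
  if (max(p) < p_ao)
    stop(sprintf("pressure never reaches %.3g kPa (maximum attained: %.3g kPa)",
                 p_ao, max(p)))
  thr <- p_ed + 0.05
  m <- which(p > thr)[1]
  if (is.na(m) || m == 1)
    stop("trace does not start below the onset-detection threshold")
  slope <- (p[m] - p[m - 1]) / (t[m] - t[m - 1])
  t_thr <- t[m - 1] + (thr - p[m - 1]) / slope
  t_onset <- t_thr - (thr - p_ed) / slope
  k <- which(p >= p_ao)[1]
  t_end <- if (p[k] == p_ao || k == 1) t[k] else
    t[k - 1] + (p_ao - p[k - 1]) / (p[k] - p[k - 1]) * (t[k] - t[k - 1])
  list(duration_ms = t_end - t_onset, t_onset_ms = t_onset, t_end_ms = t_end)
}

#' Maximum rate of pressure rise
#'
#' Central-difference dp/dt over the isovolumic window (from the detected
#' onset of pressure rise to the end of the trace), converted to mmHg/s with
#' 1 kPa = 7.50062 mmHg. Also reports the time at which the maximum occurs.
#'
#' @param trace data.frame with `time_ms` and `pressure_kPa` (>= 3 samples).
#' @param p_ed end-diastolic pressure used for onset detection, kPa.
#' @return List with `dpdt_max_mmHg_s`, `dpdt_max_kPa_s`, `t_at_max_ms`.
#' @export
dpdt_max <- function(trace, p_ed = min(trace$pressure_kPa)) {
  t <- trace$time_ms; p <- trace$pressure_kPa
  n <- length(t)
  if (n < 3) stop("need at least 3 samples")
  d <- (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]) # kPa/ms at 2..n-1
  ti <- t[2:(n - 1)]
  m <- which(p > p_ed + 0.05)[1]
  in_win <- if (is.na(m)) rep(TRUE, length(ti)) else ti >= t[max(m - 1, 1)]
  if (!any(in_win)) in_win <- rep(TRUE, length(ti))
  i <- which(in_win)[which.max(d[in_win])]
  list(dpdt_max_mmHg_s = d[i] * 1000 * KPA_TO_MMHG,
       dpdt_max_kPa_s = d[i] * 1000, t_at_max_ms = ti[i])
}

#' Prepare the LV model bundle
#'
#' Builds (or accepts) the end-diastolic mesh, recovers the unloaded geometry
#' by backward-displacement iteration, and inflates it back to the
#' end-diastolic pressure. The returned bundle caches the end-diastolic state
#' so that calibration and all scenarios reuse one unloading computation.
#'
#' @param mesh end-diastolic `lv_mesh` (default: [build_lv_mesh()] defaults).
#' @param material rate-adjusted passive parameters.
#' @param active an [active_params()] object.
#' @param p_ed end-diastolic pressure, kPa.
#' @param p_ao diastolic aortic pressure terminating the isovolumic phase,
#'   kPa.
#' @param unloading an [unloading_config()].
#' @param solver a [solver_config()].
#' @return Object of class `lv_model` with elements `mesh`, `unloaded`,
#'   `system` (on the unloaded reference), `ed_state`, `p_ed`, `p_ao`,
#'   `solver`.
#' @export
prepare_lv_model <- function(mesh = build_lv_mesh(),
                             material = apply_rate_factor(passive_params()),
                             active = active_params(),
                             p_ed = 1.3, p_ao = 10.7,
                             unloading = unloading_config(),
                             solver = solver_config()) {
  unl <- compute_unloaded(mesh, p_ed, material, unloading, solver)
  sys <- unl$system
  sys$active <- active
  structure(list(mesh = mesh, unloaded = unl, system = sys,
                 ed_state = unl$ed_state, material = material, active = active,
                 p_ed = p_ed, p_ao = p_ao, solver = solver),
            class = "lv_model")
}

#' @export
print.lv_model <- function(x, ...) {
  cat(sprintf("LV model bundle: EDV %.1f ml at %.2f kPa, unloaded volume %.1f ml\n",
              x$ed_state$V_ml, x$p_ed, x$unloaded$cavity_volume_ml))
  invisible(x)
}

#' Run one activation scenario
#'
#' @param model an [prepare_lv_model()] bundle.
#' @param scenario a [scenario_spec()] with `msv_scale` set, or a scenario
#'   name (then `msv_scale` must be given).
#' @param msv_scale subendocardial contraction rate, 1/ms; overrides the
#'   scenario's stored value when given.
#' @return A [solve_ivc()] result.
#' @export
run_scenario <- function(model, scenario, msv_scale = NULL) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  if (!is.null(msv_scale)) scenario$msv_scale <- msv_scale
  sched <- build_schedule(model$mesh, scenario)
  solve_ivc(model$system, model$ed_state, sched, model$solver, model$p_ao)
}

#' Calibrate the contraction rate to a target isovolumic duration
#'
#' Finds the subendocardial contraction-strain rate for which the control
#' scenario raises the cavity pressure from its end-diastolic to the
#' diastolic aortic value in `target_ivc` ms, by secant iteration on
#' log(rate) (the duration decreases monotonically with the rate). Runs that
#' never reach the aortic pressure are treated as lasting until the end of
#' the simulated window, which drives the search back towards faster rates.
#'
#' @param model an [prepare_lv_model()] bundle.
#' @param target_ivc target duration, ms.
#' @param tol convergence tolerance on the duration, ms.
#' @param init initial rate guess, 1/ms.
#' @param max_iter maximum secant iterations.
#' @return List with `msv_scale`, `ivc_ms`, `history` (data.frame of
#'   evaluated rates and durations).
#' @export
calibrate_msv_scale <- function(model, target_ivc = 60, tol = 0.5,
                                init = 1.2e-3, max_iter = 12) {
  eval_ivc <- function(scale) {
    res <- run_scenario(model, scenario_spec("control", msv_scale = scale))
    if (!res$reached_p_stop)
      return(model$solver$t_max - min(res$schedule$onset))
    ivc_duration(res$trace, model$p_ed, model$p_ao)$duration_ms
  }
  xs <- log(c(init, init * 1.5))
  fs <- vapply(exp(xs), eval_ivc, numeric(1)) - target_ivc
  hist <- data.frame(msv_scale = exp(xs), ivc_ms = fs + target_ivc)
  for (it in seq_len(max_iter)) {
    i <- length(xs)
    if (abs(fs[i]) <= tol)
      return(list(msv_scale = exp(xs[i]), ivc_ms = fs[i] + target_ivc,
                  history = hist))
    denom <- fs[i] - fs[i - 1]
    x_new <- if (abs(denom) < 1e-12) {
      xs[i] + ifelse(fs[i] > 0, log(1.5), -log(1.5)) # expand monotonically
    } else xs[i] - fs[i] * (xs[i] - xs[i - 1]) / denom
    f_new <- eval_ivc(exp(x_new)) - target_ivc
    xs <- c(xs, x_new); fs <- c(fs, f_new)
    hist <- rbind(hist, data.frame(msv_scale = exp(x_new),
                                   ivc_ms = f_new + target_ivc))
  }
  stop(sprintf("calibration did not converge; last duration %.2f ms",
               fs[length(fs)] + target_ivc))
}

.metrics_one <- function(res, p_ed, p_ao) {
  dur <- ivc_duration(res$trace, p_ed, p_ao)
  dp <- dpdt_max(res$trace, p_ed)
  data.frame(scenario = attr(res$schedule, "scenario")$name,
             ivc_ms = dur$duration_ms,
             dpdt_max_mmHg_s = dp$dpdt_max_mmHg_s,
             dpdt_max_kPa_s = dp$dpdt_max_kPa_s,
             t_dpdt_max_ms = dp$t_at_max_ms,
             t_onset_ms = dur$t_onset_ms, t_end_ms = dur$t_end_ms)
}

#' Run the comparative scenario suite
#'
#' Calibrates the control contraction rate (unless `msv_scale` is given),
#' runs the requested scenarios with the same calibrated rate, and collects
#' the contractility metrics (IVC duration, maximum dp/dt and their changes
#' relative to control) plus pressure traces, per-layer stress histories and
#' end-of-run transmural stress profiles. Scenario failures are reported and
#' do not abort the remaining scenarios.
#'
#' @param model an [prepare_lv_model()] bundle.
#' @param scenarios character vector of scenario names.
#' @param msv_scale calibrated subendocardial rate (1/ms) or `NULL` to
#'   calibrate on the fly.
#' @param target_ivc,calib_tol calibration target and tolerance, ms.
#' @param output_dir if non-NULL, per-scenario CSV/JSON outputs and a summary
#'   table are written there.
#' @return Object of class `ivc_suite`: `metrics` (data.frame), `runs` (list
#'   of [solve_ivc()] results), `msv_scale`, `calibration`.
#' @export
run_experiment_suite <- function(model,
                                 scenarios = c("control", "const_emd",
                                               "const_msv", "const_both"),
                                 msv_scale = NULL, target_ivc = 60,
                                 calib_tol = 0.5, output_dir = NULL) {
  calib <- NULL
  if (is.null(msv_scale)) {
    calib <- calibrate_msv_scale(model, target_ivc, calib_tol)
    msv_scale <- calib$msv_scale
  }
  runs <- list(); rows <- list()
  for (sc in scenarios) {
    res <- tryCatch(run_scenario(model, sc, msv_scale),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("scenario '%s' failed: %s", sc, conditionMessage(res)))
      next
    }
    runs[[sc]] <- res
    rows[[sc]] <- tryCatch(.metrics_one(res, model$p_ed, model$p_ao),
                           error = function(e) {
                             warning(sprintf("metrics for '%s': %s", sc,
                                             conditionMessage(e)))
                             NULL
                           })
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  if (!is.null(metrics) && "control" %in% metrics$scenario) {
    ctl <- metrics[metrics$scenario == "control", ]
    metrics$ivc_change_pct <- 100 * (metrics$ivc_ms / ctl$ivc_ms - 1)
    metrics$dpdt_change_pct <-
      100 * (metrics$dpdt_max_mmHg_s / ctl$dpdt_max_mmHg_s - 1)
  }
  out <- structure(list(metrics = metrics, runs = runs,
                        msv_scale = msv_scale, calibration = calib),
                   class = "ivc_suite")
  if (!is.null(output_dir)) .write_suite(out, model, output_dir)
  out
}

.write_suite <- function(suite, model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(suite$metrics, file.path(dir, "summary_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(msv_scale = suite$msv_scale,
                            metrics = suite$metrics),
                       file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (sc in names(suite$runs)) {
    d <- file.path(dir, sc)
    dir.create(d, showWarnings = FALSE)
    res <- suite$runs[[sc]]
    write_trace_csv(res$trace, file.path(d, "trace.csv"))
    utils::write.csv(layer_stress_summary(res),
                     file.path(d, "layer_stress.csv"), row.names = FALSE)
    utils::write.csv(res$profile, file.path(d, "profile_end_ivc.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.ivc_suite <- function(x, ...) {
  cat(sprintf("scenario suite (msv_scale = %.5g /ms):\n", x$msv_scale))
  if (!is.null(x$metrics)) {
    df <- x$metrics
    df$ivc_ms <- round(df$ivc_ms, 1)
    df$dpdt_max_mmHg_s <- signif(df$dpdt_max_mmHg_s, 3)
    print(df[, intersect(c("scenario", "ivc_ms", "dpdt_max_mmHg_s",
                           "ivc_change_pct", "dpdt_change_pct"), names(df))],
          digits = 3)
  }
  invisible(x)
}

#' Plot the pressure traces of a scenario suite
#'
#' @param x an `ivc_suite`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ivc_suite <- function(x, ...) {
  trs <- lapply(x$runs, function(r) r$trace)
  tmax <- max(vapply(trs, function(tr) max(tr$time_ms), numeric(1)))
  graphics::plot(NULL, xlim = c(0, tmax),
                 ylim = c(0, max(vapply(trs, function(tr) max(tr$pressure_kPa),
                                        numeric(1)))),
                 xlab = "time (ms)", ylab = "cavity pressure (kPa)", ...)
  cols <- seq_along(trs)
  for (i in cols)
    graphics::lines(trs[[i]]$time_ms, trs[[i]]$pressure_kPa, col = i, lwd = 2)
  graphics::legend("topleft", legend = names(trs), col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
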