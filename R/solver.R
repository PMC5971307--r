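# Quasi-static nonlinear FE driver: Newton iteration with a sparse tangent,
# follower pressure on the endocardium, prescribed-pressure filling and the
# cavity-volume-constrained isovolumic phase (pressure = Lagrange multiplier).

#' Solver configuration
#'
#' @param dt time step for the isovolumic phase, ms (controls schedule
#'   resolution; the problem is quasi-static).
#' @param newton_tol relative residual norm for Newton convergence.
#' @param max_newton maximum Newton iterations per step.
#' @param filling_substeps pressure increments for the filling phase.
#' @param volume_tol relative cavity-volume constraint tolerance during the
#'   isovolumic phase.
#' @param t_max maximum simulated time, ms.
#' @param strain_cap safety cap on prescribed shortening magnitude.
#' @param fd_step perturbation for the finite-difference element tangent, mm.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(dt = 1, newton_tol = 1e-8, max_newton = 30,
                          filling_substeps = 6, volume_tol = 1e-9,
                          t_max = 220, strain_cap = 0.25, fd_step = 1e-6) {
  stopifnot(dt > 0, newton_tol > 0, volume_tol > 0)
  structure(list(dt = dt, newton_tol = newton_tol, max_newton = max_newton,
                 filling_substeps = filling_substeps, volume_tol = volume_tol,
                 t_max = t_max, strain_cap = strain_cap, fd_step = fd_step),
            class = "solver_config")
}

# Assembled mechanical system: reference geometry, materials, load surfaces
# and constrained dofs. `press_faces` receive the follower pressure;
# `vol_faces` (press_faces + basal cap) close the cavity for the volume
# functional. Works for any hex mesh, not only the LV (used by benchmarks).
.fe_system_raw <- function(nodes, elems, fibres, press_faces, vol_faces,
                           fixed_dofs, material, active = active_params()) {
  ptr <- fe_precompute(nodes, elems)
  n_dof <- 3 * nrow(nodes)
  free <- setdiff(seq_len(n_dof), fixed_dofs)
  sys <- list(nodes = nodes, elems = elems, fibres = fibres,
              press_faces = press_faces, vol_faces = vol_faces,
              fixed_dofs = fixed_dofs, free = free, n_dof = n_dof,
              material = material, active = active, ptr = ptr,
              elem_vol = as.numeric(fe_elem_volumes(ptr)),
              cache = new.env(parent = emptyenv()))
  .build_pattern(sys)
}

# The triplet ordering of fe_assemble/face_pressure is deterministic, so the
# sparsity pattern of the free-dof tangent is fixed: precompute the mapping
# from triplets to nonzero slots once and refill values each Newton step.
.build_pattern <- function(sys) {
  U0 <- matrix(0, nrow(sys$nodes), 3)
  asm <- .assemble(sys, U0, .no_activation(sys), TRUE)
  fp <- face_pressure(sys$nodes, sys$press_faces, 1, TRUE)
  ti <- c(asm$Ki, fp$Ki); tj <- c(asm$Kj, fp$Kj)
  fmap <- integer(sys$n_dof)
  fmap[sys$free] <- seq_along(sys$free)
  ri <- fmap[ti]; rj <- fmap[tj]
  keep <- ri > 0L & rj > 0L
  nf <- length(sys$free)
  key <- (as.numeric(rj[keep]) - 1) * nf + as.numeric(ri[keep])
  uk <- sort(unique(key))
  slot <- integer(length(ti))
  slot[keep] <- match(key, uk)
  A0 <- Matrix::sparseMatrix(i = as.integer((uk - 1) %% nf + 1),
                             j = as.integer((uk - 1) %/% nf + 1),
                             x = rep(0, length(uk)), dims = c(nf, nf))
  sys$slot <- slot
  sys$nnz <- length(uk)
  sys$A0 <- A0
  sys$n_tri_K <- length(asm$Ki)
  sys
}

# factorize the (symmetric) free-dof tangent and solve for each rhs column;
# reuses the symbolic CHOLMOD factorization across calls
.tangent_solve <- function(sys, asm, fp, p, rhs) {
  vals <- c(asm$Kx, -p * fp$Kx)
  x <- accum_pattern(sys$slot, vals, sys$nnz)
  A <- sys$A0
  A@x <- x
  As <- Matrix::forceSymmetric(A, uplo = "U")
  indefinite <- FALSE
  sol <- tryCatch(
    withCallingHandlers({
      ch <- Matrix::Cholesky(As, LDL = FALSE, perm = TRUE, super = TRUE)
      lapply(rhs, function(b) as.numeric(Matrix::solve(ch, b)))
    }, warning = function(w) {
      indefinite <<- TRUE
      invokeRestart("muffleWarning")
    }),
    error = function(e) NULL)
  if (is.null(sol) || indefinite) # indefinite tangent: fall back to sparse LU
    sol <- tryCatch(lapply(rhs, function(b) as.numeric(Matrix::solve(A, b))),
                    error = function(e) NULL)
  sol
}

#' Build the mechanical system for an LV mesh
#'
#' Wraps the mesh, constitutive parameters and boundary conditions into the
#' structure consumed by [solve_filling()] and [solve_ivc()]. The default
#' boundary condition fixes all basal-plane nodes (firm attachment to the
#' valve skeleton); `basal_bc = "symmetry"` instead suppresses only axial
#' motion (plus rigid in-plane modes), which turns a hemispherical mesh into
#' one half of a full sphere -- used for benchmarking.
#'
#' @param mesh an `lv_mesh`.
#' @param material passive parameters, normally already rate-adjusted via
#'   [apply_rate_factor()].
#' @param active an [active_params()] object.
#' @param basal_bc `"fixed"` or `"symmetry"`.
#' @return Object of class `fe_system`.
#' @export
fe_system <- function(mesh, material = apply_rate_factor(passive_params()),
                      active = active_params(), basal_bc = c("fixed", "symmetry")) {
  basal_bc <- match.arg(basal_bc)
  bn <- mesh$basal_nodes
  if (basal_bc == "fixed") {
    fixed <- as.vector(outer(c(1, 2, 3), 3 * (bn - 1), "+"))
  } else {
    fixed <- 3 * (bn - 1) + 3                    # u_z = 0 on the base plane
    ax <- mesh$apex_nodes                        # keep axis nodes on the axis
    fixed <- c(fixed, 3 * (ax - 1) + 1, 3 * (ax - 1) + 2)
    pin <- bn[which.max(mesh$nodes[bn, 1])]      # block rigid rotation about z
    fixed <- c(fixed, 3 * (pin - 1) + 2)
  }
  cc <- mesh$cap_centre                          # virtual cap node: no stiffness
  fixed <- sort(unique(c(fixed, 3 * (cc - 1) + c(1, 2, 3))))
  sys <- .fe_system_raw(mesh$nodes, mesh$elems, mesh$fibres, mesh$endo_faces,
                        rbind(mesh$endo_faces, mesh$cap_faces), fixed,
                        material, active)
  sys$mesh <- mesh
  class(sys) <- "fe_system"
  sys
}

.mat_vec <- function(m) c(m$a1, m$a2, m$a3, m$b1, m$b2, m$kappa)

# internal force + optional tangent for the current displacement and
# activation state
.assemble <- function(sys, U, act, tangent = TRUE, fd_step = 1e-6) {
  fe_assemble(sys$ptr, U, .mat_vec(sys$material), sys$fibres,
              sys$active$fibre_volume_fraction, sys$active$E0,
              act$s_a, act$flag, act$lam_ref, tangent, fd_step)
}

.no_activation <- function(sys) {
  nE <- nrow(sys$elems)
  list(s_a = numeric(nE), flag = integer(nE), lam_ref = matrix(1, nE, 8))
}

.free_idx <- function(free) cbind((free - 1) %/% 3 + 1, (free - 1) %% 3 + 1)

# one Newton solve at fixed pressure p; returns list(U, asm, fp, ok, res)
.newton_fixed_p <- function(sys, U, p, act, cfg) {
  free <- sys$free
  idx <- .free_idx(free)
  rn <- NA_real_
  for (iter in seq_len(cfg$max_newton)) {
    asm <- tryCatch(.assemble(sys, U, act, TRUE, cfg$fd_step),
                    error = function(e) e)
    if (inherits(asm, "error")) return(list(ok = FALSE, msg = conditionMessage(asm)))
    fp <- face_pressure(sys$nodes + U, sys$press_faces, 1, TRUE)
    R <- asm$f - p * fp$f
    rn <- sqrt(sum(R[free]^2))
    ref <- max(abs(p) * sqrt(sum(fp$f[free]^2)), 1e-6)
    if (rn <= cfg$newton_tol * ref)
      return(list(ok = TRUE, U = U, asm = asm, fp = fp, res = rn, iters = iter))
    sol <- .tangent_solve(sys, asm, fp, p, list(-R[free]))
    if (is.null(sol))
      return(list(ok = FALSE, msg = "linear solver failed (singular tangent)"))
    U[idx] <- U[idx] + sol[[1]]
  }
  list(ok = FALSE, msg = sprintf("Newton did not converge (last residual %.3g)", rn))
}

# one Newton solve of the volume-constrained step; unknowns (U, p). The
# bordered system (tangent + volume-constraint row/column) is solved by a
# Schur complement on the cavity-pressure multiplier.
.newton_isovol <- function(sys, U, p, V_target, act, cfg) {
  free <- sys$free
  idx <- .free_idx(free)
  rn <- NA_real_
  for (iter in seq_len(cfg$max_newton)) {
    asm <- tryCatch(.assemble(sys, U, act, TRUE, cfg$fd_step),
                    error = function(e) e)
    if (inherits(asm, "error")) return(list(ok = FALSE, msg = conditionMessage(asm)))
    x <- sys$nodes + U
    fp <- face_pressure(x, sys$press_faces, 1, TRUE)
    V <- cavity_volume_cpp(x, sys$vol_faces, FALSE)$V
    Rm <- asm$f - p * fp$f
    Rc <- V - V_target
    rn <- sqrt(sum(Rm[free]^2))
    ref <- max(abs(p) * sqrt(sum(fp$f[free]^2)), 1e-6)
    if (rn <= cfg$newton_tol * ref && abs(Rc) <= cfg$volume_tol * V_target)
      return(list(ok = TRUE, U = U, p = p, V = V, asm = asm, res = rn,
                  iters = iter))
    gf <- fp$f[free]
    sol <- .tangent_solve(sys, asm, fp, p, list(Rm[free], gf))
    if (is.null(sol))
      return(list(ok = FALSE, msg = "linear solver failed (singular tangent)"))
    y1 <- sol[[1]]; y2 <- sol[[2]]
    gy2 <- sum(gf * y2)
    if (abs(gy2) < 1e-300)
      return(list(ok = FALSE, msg = "degenerate volume constraint"))
    dp <- (sum(gf * y1) - Rc) / gy2
    U[idx] <- U[idx] - y1 + dp * y2
    p <- p + dp
  }
  list(ok = FALSE,
       msg = sprintf("isovolumic Newton did not converge (last residual %.3g)", rn))
}

#' Solve the passive filling phase
#'
#' Inflates the (unloaded) reference geometry to the end-diastolic pressure by
#' incremental follower-pressure loading with Newton convergence at each
#' substep; contractile elements are inactive and basal nodes are fixed.
#' Substeps that fail to converge are bisected automatically.
#'
#' @param sys an [fe_system()].
#' @param p_ed target end-diastolic pressure, kPa.
#' @param config a [solver_config()].
#' @param U0 optional initial displacement guess (N x 3).
#' @return Object of class `mechanical_state`: displacement `U`, pressure `p`,
#'   cavity volume `V_ml`, fibre stretches `lam`, per-element fibre stress.
#' @export
solve_filling <- function(sys, p_ed = 1.3, config = solver_config(), U0 = NULL) {
  act <- .no_activation(sys)
  U <- if (is.null(U0)) matrix(0, nrow(sys$nodes), 3) else U0
  p_done <- 0
  targets <- if (p_ed == 0) numeric(0) else
    seq(p_ed / config$filling_substeps, p_ed, length.out = config$filling_substeps)
  res <- NULL
  for (pt in targets) {
    depth <- 0
    repeat {
      trial <- .newton_fixed_p(sys, U, pt, act, config)
      if (trial$ok) { U <- trial$U; p_done <- pt; res <- trial; break }
      depth <- depth + 1
      if (depth > 6)
        stop("filling phase failed at p = ", signif(pt, 4), " kPa: ", trial$msg)
      pt_mid <- (p_done + pt) / 2
      mid <- .newton_fixed_p(sys, U, pt_mid, act, config)
      if (mid$ok) { U <- mid$U; p_done <- pt_mid }
      else pt <- pt_mid
    }
  }
  if (is.null(res)) { # p_ed = 0: reference state
    res <- list(asm = .assemble(sys, U, act, FALSE), res = 0, iters = 0)
  }
  V <- cavity_volume_cpp(sys$nodes + U, sys$vol_faces, FALSE)$V
  structure(list(U = U, p = p_ed, V_ml = V / 1000, time_ms = 0,
                 lam = res$asm$lam, sig_ff = res$asm$sig_ff,
                 Jbar = res$asm$Jbar, residual = res$res),
            class = "mechanical_state")
}

#' @export
print.mechanical_state <- function(x, ...) {
  cat(sprintf("mechanical state: p = %.3f kPa, cavity volume = %.2f ml, |J-1|max = %.2e\n",
              x$p, x$V_ml, max(abs(x$Jbar - 1))))
  invisible(x)
}

#' Simulate the isovolumic contraction phase
#'
#' Starting from the converged end-diastolic state, marches time in fixed
#' steps. Elements switch on at their scheduled mechanical onset (their fibre
#' natural length is reset to the stretch at onset, reproducing the
#' strain-free reactivation of the contractile elements after the passive
#' filling phase) and shorten along the scenario's linear ramp. At every step
#' the cavity volume is constrained to its end-diastolic value and the cavity
#' pressure is the corresponding Lagrange multiplier, solved together with the
#' displacements. The march stops when the pressure reaches `p_stop`
#' (aortic-valve opening) or `config$t_max`.
#'
#' @param sys an [fe_system()].
#' @param state end-diastolic [solve_filling()] result.
#' @param schedule an activation schedule from [build_schedule()].
#' @param config a [solver_config()].
#' @param p_stop pressure terminating the isovolumic phase, kPa.
#' @return Object of class `sim_result`: `trace` (data.frame `time_ms`,
#'   `pressure_kPa`, `volume_ml`), per-layer fibre-stress histories
#'   `layer_stress` and `layer_stress_active` (ms x layers), `profile`
#'   (end-of-run transmural stress profile), `reached_p_stop`, `schedule`.
#' @export
solve_ivc <- function(sys, state, schedule, config = solver_config(),
                      p_stop = 10.7) {
  nE <- nrow(sys$elems)
  stopifnot(nrow(schedule) == nE)
  onset <- schedule$onset; rate <- schedule$rate
  layers <- sort(unique(sys$mesh$layer))
  wl <- lapply(layers, function(l) {
    w <- sys$elem_vol * (sys$mesh$layer == l); w / sum(w)
  })
  layer_mean <- function(v) vapply(wl, function(w) sum(w * v), numeric(1))

  act <- list(s_a = numeric(nE), flag = integer(nE),
              lam_ref = matrix(1, nE, 8))
  U <- state$U; p <- state$p
  V_target <- state$V_ml * 1000
  lam_now <- state$lam

  t0 <- max(0, floor(min(onset) / config$dt) * config$dt)
  t0 <- min(t0, config$t_max)
  times <- seq(0, t0, by = config$dt)
  np <- length(times)
  trace_t <- times; trace_p <- rep(p, np); trace_v <- rep(state$V_ml, np)
  ls_tot <- matrix(rep(layer_mean(state$sig_ff), each = np), np)
  ls_act <- matrix(0, np, length(layers))

  t <- t0
  reached <- FALSE
  while (t < config$t_max && !reached) {
    t_new <- t + config$dt
    stepper <- function(U, p, lam_now, act, t_from, t_to, depth = 0) {
      newly <- which(onset <= t_to & act$flag == 0L)
      if (length(newly)) {
        act$flag[newly] <- 1L
        act$lam_ref[newly, ] <- lam_now[newly, , drop = FALSE]
      }
      act$s_a <- pmin(pmax(t_to - onset, 0) * rate, config$strain_cap)
      act$s_a[act$flag == 0L] <- 0
      sol <- .newton_isovol(sys, U, p, V_target, act, config)
      if (!sol$ok) {
        if (depth >= 5)
          stop("isovolumic step to t = ", t_to, " ms failed: ", sol$msg)
        mid <- (t_from + t_to) / 2
        half <- stepper(U, p, lam_now, act, t_from, mid, depth + 1)
        return(stepper(half$U, half$p, half$lam, half$act, mid, t_to, depth + 1))
      }
      list(U = sol$U, p = sol$p, lam = sol$asm$lam, act = act, sol = sol)
    }
    st <- stepper(U, p, lam_now, act, t, t_new)
    U <- st$U; p <- st$p; lam_now <- st$lam; act <- st$act
    t <- t_new
    trace_t <- c(trace_t, t); trace_p <- c(trace_p, p)
    trace_v <- c(trace_v, st$sol$V / 1000)
    ls_tot <- rbind(ls_tot, layer_mean(st$sol$asm$sig_ff))
    ls_act <- rbind(ls_act, layer_mean(st$sol$asm$sig_act))
    if (p >= p_stop) reached <- TRUE
  }

  trace <- data.frame(time_ms = trace_t, pressure_kPa = trace_p,
                      volume_ml = trace_v)
  class(trace) <- c("pressure_trace", "data.frame")
  depth_pct <- 100 * vapply(wl, function(w) sum(w * sys$mesh$depth_frac),
                            numeric(1))
  profile <- data.frame(layer = layers, depth_pct = depth_pct,
                        sigma_ff_kPa = ls_tot[nrow(ls_tot), ],
                        sigma_active_kPa = ls_act[nrow(ls_act), ])
  structure(list(trace = trace, layer_stress = ls_tot,
                 layer_stress_active = ls_act, profile = profile,
                 reached_p_stop = reached, p_stop = p_stop,
                 schedule = schedule, state_end = list(U = U, p = p)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("IVC simulation (%s): %d samples, p %.2f -> %.2f kPa%s\n",
              attr(x$schedule, "scenario")$name, nrow(tr), tr$pressure_kPa[1],
              max(tr$pressure_kPa),
              if (x$reached_p_stop) sprintf(" (reached %.1f kPa)", x$p_stop)
              else " (p_stop not reached)"))
  invisible(x)
}

#' Per-layer fibre-stress time series of a simulation
#'
#' Volume-weighted mean Cauchy stress resolved along the deformed fibre
#' direction, per transmural layer and time sample, in long format; the
#' end-of-run transmural profile is available as `attr(,"profile")` and in
#' `result$profile`.
#'
#' @param result a [solve_ivc()] result.
#' @return data.frame `time_ms`, `layer`, `sigma_ff_kPa`, `sigma_active_kPa`.
#' @export
layer_stress_summary <- function(result) {
  nl <- ncol(result$layer_stress)
  tr <- result$trace
  out <- data.frame(
    time_ms = rep(tr$time_ms, nl),
    layer = rep(seq_len(nl), each = nrow(tr)),
    sigma_ff_kPa = as.vector(result$layer_stress),
    sigma_active_kPa = as.vector(result$layer_stress_active))
  attr(out, "profile") <- result$profile
  out
}

#' Write a pressure trace to CSV
#'
#' Adds mmHg and dp/dt columns in the units conventionally reported.
#'
#' @param trace a `pressure_trace` data.frame.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_trace_csv <- function(trace, file) {
  df <- as.data.frame(trace)
  df$pressure_mmHg <- df$pressure_kPa * 7.50062
  n <- nrow(df)
  dpdt <- rep(NA_real_, n)
  if (n >= 3) {
    dpdt[2:(n - 1)] <- (df$pressure_kPa[3:n] - df$pressure_kPa[1:(n - 2)]) /
      (df$time_ms[3:n] - df$time_ms[1:(n - 2)]) * 1000 * 7.50062
  }
  df$dpdt_mmHg_per_s <- dpdt
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
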