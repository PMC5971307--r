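# Recovery of the zero-pressure reference configuration by backward-
# displacement fixed-point iteration: the imaged (end-diastolic) geometry is
# in equilibrium with the end-diastolic pressure, so the stress-free mesh is
# found by repeatedly subtracting the inflation displacement of the current
# candidate from the target coordinates.

#' Unloading-iteration configuration
#'
#' @param max_iter maximum fixed-point iterations.
#' @param tol convergence tolerance: maximum nodal distance (mm) between the
#'   re-inflated candidate and the end-diastolic mesh.
#' @param relax relaxation factor in (0, 1]; 1 is the plain fixed point.
#' @return Object of class `unloading_config`.
#' @export
unloading_config <- function(max_iter = 30, tol = 0.05, relax = 1) {
  stopifnot(tol > 0, relax > 0, relax <= 1)
  structure(list(max_iter = max_iter, tol = tol, relax = relax),
            class = "unloading_config")
}

#' Compute the unloaded (zero-pressure) geometry
#'
#' Backward-displacement iteration: starting from the end-diastolic mesh
#' `X_ED`, each candidate `X_k` is inflated passively to `p_ed` giving a
#' displacement field `u_k`, and the update is
#' `X_{k+1} = X_k + relax * (X_ED - (X_k + u_k))` (for `relax = 1` this is
#' `X_ED - u_k`). Iteration stops when the re-inflated candidate matches the
#' end-diastolic nodal positions to within `config$tol`. Layer indices and
#' fibre directions are carried over from the end-diastolic mesh.
#'
#' @param ed_mesh the end-diastolic `lv_mesh`.
#' @param p_ed end-diastolic pressure, kPa.
#' @param material rate-adjusted passive parameters.
#' @param config an [unloading_config()].
#' @param solver a [solver_config()].
#' @return List of class `unloading_result`: `mesh` (unloaded `lv_mesh`),
#'   `cavity_volume_ml`, `iterations`, `mismatch_history` (mm), `converged`,
#'   and `ed_state` (the filling solution of the final candidate, i.e. the
#'   end-diastolic state used by the contraction simulations).
#' @export
compute_unloaded <- function(ed_mesh, p_ed = 1.3,
                             material = apply_rate_factor(passive_params()),
                             config = unloading_config(),
                             solver = solver_config()) {
  X_ed <- ed_mesh$nodes
  mesh_k <- ed_mesh
  hist <- numeric(0)
  state <- NULL
  for (it in seq_len(config$max_iter)) {
    sys <- fe_system(mesh_k, material)
    state <- solve_filling(sys, p_ed, solver)
    x_inf <- mesh_k$nodes + state$U
    mm <- sqrt(rowSums((x_inf - X_ed)^2))
    hist <- c(hist, max(mm))
    if (max(mm) <= config$tol) {
      vol <- cavity_volume(mesh_k)
      return(structure(list(mesh = mesh_k, cavity_volume_ml = vol,
                            iterations = it, mismatch_history = hist,
                            converged = TRUE, ed_state = state, system = sys),
                       class = "unloading_result"))
    }
    nodes_new <- mesh_k$nodes + config$relax * (X_ed - x_inf)
    mesh_k$nodes <- nodes_new
    # keep the cap centre on the (fixed) basal ring centroid
    mesh_k$nodes[mesh_k$cap_centre, ] <- ed_mesh$nodes[ed_mesh$cap_centre, ]
    ptr <- fe_precompute(mesh_k$nodes, mesh_k$elems) # raises on inversion
    mesh_k$elem_vol <- as.numeric(fe_elem_volumes(ptr))
  }
  stop(sprintf(
    "unloading did not converge in %d iterations (last mismatch %.3g mm)",
    config$max_iter, hist[length(hist)]))
}

#' @export
print.unloading_result <- function(x, ...) {
  cat(sprintf(
    "unloaded geometry: cavity volume %.1f ml after %d iterations (mismatch %.3g mm)\n",
    x$cavity_volume_ml, x$iterations, x$mismatch_history[x$iterations]))
  invisible(x)
}

#' Write an unloading report as JSON
#'
#' @param result a [compute_unloaded()] result.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_unloading_report <- function(result, file) {
  jsonlite::write_json(list(iterations = result$iterations,
                            final_mismatch_mm = result$mismatch_history[result$iterations],
                            unloaded_volume_ml = result$cavity_volume_ml,
                            converged = result$converged),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
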