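# Truncated-ellipsoid left-ventricle geometry and hexahedral meshing.
#
# Coordinate convention: the long axis is z, the basal (truncation) plane is
# z = base_height (default 0, the equator), the apex points towards negative z.
# The wall is swept between an inner and an outer ellipsoid that share the
# axis of symmetry; transmural "layers" are shells of equal parametric
# thickness, matching the layered fibre architecture of the ventricular wall.

#' Left-ventricle geometric dimensions
#'
#' Container for the idealized LV geometry: two coaxial truncated ellipsoids.
#' The defaults (inner semi-axes 30/30/65 mm, uniform 9 mm wall, truncation at
#' the equator) give an analytic cavity volume of about 122.5 ml, the
#' end-diastolic volume the model is built around.
#'
#' @param inner_short inner (cavity) short semi-axis, mm.
#' @param inner_long inner long semi-axis, mm.
#' @param wall_thickness wall thickness added to both semi-axes, mm.
#' @param base_height z-position of the basal truncation plane relative to the
#'   ellipsoid centre, mm (0 = equatorial truncation).
#' @return An object of class `lv_dimensions`.
#' @export
lv_dimensions <- function(inner_short = 30, inner_long = 65,
                          wall_thickness = 9, base_height = 0) {
  if (inner_short <= 0 || inner_long <= 0)
    stop("ellipsoid semi-axes must be positive")
  if (wall_thickness <= 0)
    stop("outer ellipsoid must strictly enclose the inner one (wall_thickness > 0)")
  if (abs(base_height) >= inner_long)
    stop("base plane lies outside the inner ellipsoid")
  structure(list(inner_short = inner_short, inner_long = inner_long,
                 wall_thickness = wall_thickness, base_height = base_height),
            class = "lv_dimensions")
}

#' @export
print.lv_dimensions <- function(x, ...) {
  cat(sprintf(
    "LV dimensions: inner semi-axes %.1f/%.1f mm, wall %.1f mm, base at z = %.1f mm\n",
    x$inner_short, x$inner_long, x$wall_thickness, x$base_height))
  cat(sprintf("  analytic cavity volume: %.1f ml\n", analytic_cavity_volume(x)))
  invisible(x)
}

#' Analytic cavity volume of a truncated ellipsoid
#'
#' Volume of the region bounded by the inner ellipsoid below the basal plane,
#' closed by the flat basal cap: for equatorial truncation this is the
#' half-ellipsoid volume (2/3) pi a^2 c.
#'
#' @param dims an [lv_dimensions()] object.
#' @param surface `"inner"` or `"outer"`.
#' @return Volume in ml.
#' @export
analytic_cavity_volume <- function(dims, surface = c("inner", "outer")) {
  surface <- match.arg(surface)
  a <- dims$inner_short + if (surface == "outer") dims$wall_thickness else 0
  c_ <- dims$inner_long + if (surface == "outer") dims$wall_thickness else 0
  # cap height measured from the apex: z from -c to zb
  zb <- min(dims$base_height, c_)
  # V = integral_{-c}^{zb} pi a^2 (1 - z^2/c^2) dz
  vol <- pi * a^2 * ((zb + c_) - (zb^3 + c_^3) / (3 * c_^2))
  vol / 1000
}

# latitude parameter of the basal plane for a surface with long semi-axis c:
# z = -c cos(theta) => theta_max = acos(-zb / c)
.theta_max <- function(zb, c_) acos(max(-1, min(1, -zb / c_)))

#' Build the truncated-ellipsoid LV wall mesh
#'
#' Structured mesh of trilinear hexahedra between the inner and outer
#' ellipsoid, with `n_layers` transmural layers, `n_circ` circumferential and
#' `n_long` longitudinal divisions. The apical element ring uses collapsed
#' (wedge) hexahedra so the wall is watertight down to the apex. Each element
#' carries a layer index, a wall-depth coordinate and a unit fibre direction
#' whose helix angle ramps linearly from +60 degrees in the subendocardial
#' layer to -60 degrees in the subepicardial layer.
#'
#' Because a faceted (bilinear-face) surface inscribed in the ellipsoid
#' under-represents the enclosed volume at coarse resolution, and because the
#' physiological anchor of the geometry is the end-diastolic cavity volume
#' rather than the exact semi-axes, the mesh is by default rescaled by a
#' single similarity factor so that its discrete cavity volume equals
#' `target_volume_ml`. Pass `target_volume_ml = NULL` for the raw inscribed
#' mesh (used e.g. in refinement-convergence studies).
#'
#' @param dims an [lv_dimensions()] object.
#' @param n_circ circumferential divisions (>= 8).
#' @param n_long longitudinal divisions from apex to base (>= 4).
#' @param n_layers transmural layers (7 for the standard fibre architecture).
#' @param target_volume_ml calibrate the discrete cavity volume to this value
#'   (ml), or `NULL` to keep nodes exactly on the ellipsoids.
#' @param helix_endo,helix_epi helix angle (degrees, vs the circumferential
#'   direction) at the centres of the innermost and outermost layers.
#' @return An object of class `lv_mesh`; see Details.
#' @details The returned list contains `nodes` (N x 3, mm), `elems` (nE x 8
#'   connectivity), `layer`, `centroid`, `depth_mm`, `depth_frac`,
#'   `thickness_mm` (local wall thickness), `helix_deg`, `fibres` (nE x 3 unit
#'   vectors), `endo_faces`, `cap_faces`, `basal_nodes`, `apex_nodes`,
#'   `elem_vol` and the (possibly rescaled) `dims`.
#' @export
build_lv_mesh <- function(dims = lv_dimensions(), n_circ = 16, n_long = 8,
                          n_layers = 7, target_volume_ml = 122,
                          helix_endo = 60, helix_epi = -60) {
  stopifnot(inherits(dims, "lv_dimensions"))
  if (n_circ < 8) stop("n_circ must be at least 8")
  if (n_long < 4) stop("n_long must be at least 4")
  if (n_layers < 1) stop("n_layers must be at least 1")

  a_in <- dims$inner_short; c_in <- dims$inner_long
  h <- dims$wall_thickness; zb <- dims$base_height

  n_ring <- 1 + n_long * n_circ           # nodes per transmural level
  n_lev <- n_layers + 1
  nodes <- matrix(0, n_ring * n_lev, 3)
  idx <- function(k, j, i) {              # level k (0..n_layers), ring j, sector i
    if (j == 0) return(as.integer(k * n_ring + 1))
    i <- ((i - 1) %% n_circ) + 1
    as.integer(k * n_ring + 1 + (j - 1) * n_circ + i)
  }
  phi <- 2 * pi * (0:(n_circ - 1)) / n_circ
  for (k in 0:n_layers) {
    t <- k / n_layers
    a <- a_in + t * h; c_ <- c_in + t * h
    th_max <- .theta_max(zb, c_)
    nodes[idx(k, 0, 1), ] <- c(0, 0, -c_)
    for (j in 1:n_long) {
      th <- th_max * j / n_long
      rr <- a * sin(th); zz <- -c_ * cos(th)
      for (i in 1:n_circ)
        nodes[idx(k, j, i), ] <- c(rr * cos(phi[i]), rr * sin(phi[i]), zz)
    }
  }

  n_elem <- n_circ * n_long * n_layers
  elems <- matrix(0L, n_elem, 8)
  layer <- integer(n_elem)
  param <- matrix(0, n_elem, 3)           # (phi_mid, theta_frac_mid, t_mid)
  stack_endo <- matrix(0, n_elem, 3)      # discrete endo/epi surface points of
  stack_epi <- matrix(0, n_elem, 3)       # the element's transmural stack
  e <- 0L
  for (k in 1:n_layers) for (j in 1:n_long) for (i in 1:n_circ) {
    e <- e + 1L
    elems[e, ] <- c(idx(k - 1, j - 1, i), idx(k - 1, j - 1, i + 1),
                    idx(k - 1, j, i + 1), idx(k - 1, j, i),
                    idx(k, j - 1, i), idx(k, j - 1, i + 1),
                    idx(k, j, i + 1), idx(k, j, i))
    layer[e] <- k
    phim <- 2 * pi * (i - 0.5) / n_circ
    param[e, ] <- c(phim, (j - 0.5) / n_long, (k - 0.5) / n_layers)
    stack_endo[e, ] <- colMeans(nodes[c(idx(0, j - 1, i), idx(0, j - 1, i + 1),
                                        idx(0, j, i + 1), idx(0, j, i)), ,
                                      drop = FALSE])
    stack_epi[e, ] <- colMeans(nodes[c(idx(n_layers, j - 1, i),
                                       idx(n_layers, j - 1, i + 1),
                                       idx(n_layers, j, i + 1),
                                       idx(n_layers, j, i)), , drop = FALSE])
  }

  # endocardial faces: inner face (zeta = -1) of layer-1 elements, ordered so
  # x_xi x x_eta points out of the cavity (into the wall)
  endo_el <- which(layer == 1L)
  endo_faces <- elems[endo_el, 1:4, drop = FALSE]
  # basal cap: triangles (centre, ring_i, ring_i+1) as degenerate quads,
  # outward (out-of-fluid) normal +z
  ring <- vapply(1:n_circ, function(i) idx(0, n_long, i), integer(1))
  cap_centre_id <- nrow(nodes) + 1L
  nodes <- rbind(nodes, c(0, 0, zb))
  cap_faces <- t(vapply(1:n_circ, function(i) {
    c(cap_centre_id, ring[i], ring[ifelse(i == n_circ, 1L, i + 1L)], cap_centre_id)
  }, integer(4)))

  mesh <- list(nodes = nodes, elems = elems, layer = layer,
               n_circ = n_circ, n_long = n_long, n_layers = n_layers,
               endo_faces = endo_faces, cap_faces = cap_faces,
               cap_centre = cap_centre_id, dims = dims, scale = 1,
               param = param, stack_endo = stack_endo, stack_epi = stack_epi,
               helix_endo = helix_endo, helix_epi = helix_epi)
  class(mesh) <- "lv_mesh"

  if (!is.null(target_volume_ml)) {
    v0 <- cavity_volume(mesh)
    s <- (target_volume_ml / v0)^(1 / 3)
    mesh$nodes <- mesh$nodes * s
    mesh$stack_endo <- mesh$stack_endo * s
    mesh$stack_epi <- mesh$stack_epi * s
    mesh$scale <- s
    mesh$dims <- lv_dimensions(a_in * s, c_in * s, h * s, zb * s)
  }
  mesh <- .mesh_derived(mesh)
  mesh
}

# fills centroids, depths, fibres, element volumes; requires final nodes
.mesh_derived <- function(mesh) {
  elems <- mesh$elems; nodes <- mesh$nodes
  nE <- nrow(elems)
  cx <- matrix(0, nE, 3)
  for (c in 1:3) {
    m <- matrix(nodes[elems, c], nE, 8)
    cx[, c] <- rowMeans(m)
  }
  mesh$centroid <- cx
  d <- mesh$dims
  # depth against the DISCRETE endocardial surface: element centroids and the
  # endo/epi face centres of a transmural stack are collinear in the
  # structured mesh, so the stack distances are the wall-normal distances
  din <- sqrt(rowSums((cx - mesh$stack_endo)^2))
  dout <- sqrt(rowSums((cx - mesh$stack_epi)^2))
  mesh$depth_mm <- din
  mesh$thickness_mm <- sqrt(rowSums((mesh$stack_epi - mesh$stack_endo)^2))
  mesh$depth_frac <- din / (din + dout)

  nl <- mesh$n_layers
  if (nl > 1) {
    mesh$helix_deg <- mesh$helix_endo +
      (mesh$helix_epi - mesh$helix_endo) * (mesh$layer - 1) / (nl - 1)
  } else mesh$helix_deg <- rep(0.5 * (mesh$helix_endo + mesh$helix_epi), nE)

  # local surface tangents at the element's parametric midpoint, evaluated on
  # the mid-layer surface
  t_mid <- mesh$param[, 3]
  a <- d$inner_short + t_mid * d$wall_thickness
  c_ <- d$inner_long + t_mid * d$wall_thickness
  th <- .theta_max(d$base_height, c_) * mesh$param[, 2]
  phim <- mesh$param[, 1]
  e_circ <- cbind(-sin(phim), cos(phim), 0)
  e_long <- cbind(a * cos(th) * cos(phim), a * cos(th) * sin(phim), c_ * sin(th))
  e_long <- e_long / sqrt(rowSums(e_long^2))
  al <- mesh$helix_deg * pi / 180
  f <- cos(al) * e_circ + sin(al) * e_long
  mesh$fibres <- f / sqrt(rowSums(f^2))
  mesh$e_circ <- e_circ; mesh$e_long <- e_long

  mesh$basal_nodes <- which(abs(mesh$nodes[, 3] - d$base_height) < 1e-9)
  mesh$basal_nodes <- setdiff(mesh$basal_nodes, mesh$cap_centre)
  mesh$apex_nodes <- which(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2 < 1e-12 &
                           mesh$nodes[, 3] < 0)
  ptr <- fe_precompute(mesh$nodes, mesh$elems)
  mesh$elem_vol <- as.numeric(fe_elem_volumes(ptr))
  mesh
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("LV mesh: %d hexahedral elements (%d circ x %d long x %d layers), %d nodes\n",
              nrow(x$elems), x$n_circ, x$n_long, x$n_layers, nrow(x$nodes)))
  cat(sprintf("  cavity volume %.2f ml, wall volume %.2f ml, wall thickness %.2f mm (equator)\n",
              cavity_volume(x), sum(x$elem_vol) / 1000,
              x$dims$wall_thickness))
  cat(sprintf("  helix angle %+.0f to %+.0f deg across layers\n",
              x$helix_endo, x$helix_epi))
  invisible(x)
}

#' Cavity volume enclosed by the (deformed) endocardial surface
#'
#' Integrates `(1/3) x . n` over the endocardial faces and the flat basal cap
#' (divergence theorem). With a displacement field the deformed surface is
#' used; the basal cap follows the (normally fixed) basal nodes.
#'
#' @param mesh an `lv_mesh`.
#' @param displacement N x 3 nodal displacement matrix, or `NULL` for the
#'   reference configuration.
#' @return Cavity volume in ml.
#' @export
cavity_volume <- function(mesh, displacement = NULL) {
  x <- mesh$nodes
  if (!is.null(displacement)) {
    if (!is.matrix(displacement) || any(dim(displacement) != dim(x)))
      stop("displacement must be an N x 3 matrix over all mesh nodes")
    x <- x + displacement
  }
  faces <- rbind(mesh$endo_faces, mesh$cap_faces)
  v <- cavity_volume_cpp(x, faces, FALSE)$V / 1000
  if (v <= 0) stop("endocardial surface is not closed by the basal cap (V <= 0)")
  v
}

#' Wall-depth coordinates of the mesh elements
#'
#' Depth is the shortest distance from the element centroid to the endocardial
#' (cavity) surface; the fraction normalizes by the local wall thickness
#' (endocardial + epicardial distance), 0 at the endocardium and 1 at the
#' epicardium.
#'
#' @param mesh an `lv_mesh`.
#' @return data.frame with `element`, `layer`, `depth_mm`, `depth_frac`,
#'   `thickness_mm`.
#' @export
wall_depth <- function(mesh) {
  data.frame(element = seq_len(nrow(mesh$elems)), layer = mesh$layer,
             depth_mm = mesh$depth_mm, depth_frac = mesh$depth_frac,
             thickness_mm = mesh$thickness_mm)
}

#' Export a mesh as a legacy VTK unstructured grid
#'
#' Writes an ASCII VTK file with hexahedral cells and, as cell data, the layer
#' index, helix angle and fibre vectors; optionally point data (e.g. a
#' displacement field).
#'
#' @param mesh an `lv_mesh`.
#' @param file output path.
#' @param point_data named list of per-node vectors/matrices.
#' @param cell_data named list of per-element vectors; layer, helix angle and
#'   fibre vectors are always written.
#' @return Invisibly, `file`.
#' @export
write_mesh_vtk <- function(mesh, file, point_data = NULL, cell_data = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "ivcsim LV mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, 9 * ne), con)
  utils::write.table(cbind(8L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS layer int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$layer), con)
  writeLines(c("SCALARS helix_angle_deg double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(mesh$helix_deg, digits = 8), con)
  writeLines("VECTORS fibre double", con)
  utils::write.table(format(mesh$fibres, digits = 8), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(cell_data[[nm]], digits = 8), con)
  }
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      pd <- point_data[[nm]]
      if (is.matrix(pd) && ncol(pd) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(format(pd, digits = 8), con, row.names = FALSE,
                           col.names = FALSE, quote = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(format(pd, digits = 8), con)
      }
    }
  }
  invisible(file)
}
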