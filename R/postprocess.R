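#' Random area-uniform sample of a triangulated surface
#'
#' Draws points uniformly by area: facets are chosen with probability
#' proportional to their deformed area, then a uniform barycentric point is
#' drawn within the facet. Deterministic for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param surface Integer f x 3 facet matrix.
#' @param coords Node coordinates (reference or deformed), n x 3.
#' @param n_points Number of points (>= 3).
#' @param seed Integer RNG seed (default 0).
#' @return Object of class `surface_sample`: list with `points` (n_points x 3)
#'   and `seed`; the chosen facet of each point is kept as attribute `facet`.
#' @export
sample_surface <- function(surface, coords, n_points, seed = 0) {
  if (is.null(surface) || nrow(surface) == 0) stop("empty surface")
  if (n_points < 3) stop("need at least 3 sample points")
  an <- facet_area_normals(surface, coords)
  areas <- sqrt(rowSums(an^2))
  pts <- with_seed(seed, {
    fi <- sample.int(nrow(surface), n_points, replace = TRUE,
                     prob = areas / sum(areas))
    r1 <- sqrt(stats::runif(n_points))
    r2 <- stats::runif(n_points)
    a <- coords[surface[fi, 1], , drop = FALSE]
    b <- coords[surface[fi, 2], , drop = FALSE]
    c_ <- coords[surface[fi, 3], , drop = FALSE]
    p <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
    attr(p, "facet") <- fi
    p
  })
  structure(list(points = pts, seed = seed), class = "surface_sample")
}

#' Surface-area estimate by Delaunay triangulation of sampled points
#'
#' Reproduces the point-sampling area workflow: the sample is projected onto
#' its least-squares (principal-component) plane, triangulated by a 2D
#' Delaunay triangulation, and the areas of the lifted 3D triangles are
#' accumulated. Valid for patches that are a graph over their best-fit plane;
#' a fold-over (a lifted triangle nearly perpendicular to the plane) raises an
#' error advising the exact per-facet area instead.
#'
#' @param sample A [sample_surface()] result, or an n x 3 point matrix.
#' @return Estimated area, mm^2.
#' @export
delaunay_area <- function(sample) {
  pts <- if (inherits(sample, "surface_sample")) sample$points else as.matrix(sample)
  if (nrow(pts) < 3) stop("need at least 3 points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X, nu = 0)
  if (sv$d[2] <= 1e-10 * sv$d[1]) {
    stop("degenerate sample: points are (nearly) collinear")
  }
  uv <- X %*% sv$v[, 1:2]
  keep <- !duplicated(round(uv, 12))
  uv <- uv[keep, , drop = FALSE]
  p3 <- pts[keep, , drop = FALSE]
  # shull warns about collapsed triangles on highly regular (gridded) input;
  # those triangles carry no area and do not affect the accumulated total
  tri <- withCallingHandlers(
    interp::tri.mesh(uv[, 1], uv[, 2]),
    warning = function(w) {
      if (grepl("triangle collapsed|coincide|collinear", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  T_ <- interp::triangles(tri)[, 1:3, drop = FALSE]
  an <- facet_area_normals(T_, p3)
  areas <- sqrt(rowSums(an^2))
  # fold-over check: the projected Delaunay triangles tile the convex hull
  # exactly once, so for a height field of moderate slope the lifted area
  # exceeds the projected area only by the slope factor (1/cos, about 1.4 at
  # 45 degrees). A folded surface forces the triangulation to jump between
  # sheets and inflates the ratio far beyond that.
  u1 <- uv[T_[, 1], , drop = FALSE]
  u2 <- uv[T_[, 2], , drop = FALSE]
  u3 <- uv[T_[, 3], , drop = FALSE]
  proj_areas <- abs((u2[, 1] - u1[, 1]) * (u3[, 2] - u1[, 2]) -
                    (u3[, 1] - u1[, 1]) * (u2[, 2] - u1[, 2])) / 2
  if (sum(areas) > 2 * sum(proj_areas)) {
    stop("fold-over detected: surface is not a graph over its best-fit ",
         "plane; use exact_surface_area() on the mesh facets instead")
  }
  sum(areas)
}

#' Exact area of the (deformed) mesh surface
#'
#' Sum of the mesh's own triangle areas -- the reference estimator used for
#' the per-step reports (no sampling error).
#'
#' @param surface Integer f x 3 facet matrix.
#' @param coords Node coordinates, n x 3.
#' @return Area, mm^2.
#' @export
exact_surface_area <- function(surface, coords) {
  an <- facet_area_normals(surface, coords)
  sum(sqrt(rowSums(an^2)))
}

#' Per-step area/volume bookkeeping from measured series
#'
#' Applies the delta and cumulative rules to per-step area and volume series:
#' `dS(k) = S(k) - S(k-1)`, `cum_dS(k)` its running sum (step 0 deltas are 0),
#' and the same for volume. The identities hold exactly by construction.
#'
#' @param S Numeric vector of per-step areas (mm^2), step 0 first.
#' @param V Numeric vector of per-step volumes (mm^3), same length.
#' @return data.frame with columns `step`, `S_mm2`, `dS_mm2`, `cum_dS_mm2`,
#'   `V_mm3`, `dV_mm3`, `cum_dV_mm3`.
#' @export
step_table <- function(S, V = rep(NA_real_, length(S))) {
  stopifnot(length(S) == length(V), length(S) >= 1)
  dS <- c(0, diff(S))
  dV <- c(0, diff(V))
  if (length(S) == 1) { dS <- 0; dV <- 0 }
  data.frame(step = seq_along(S) - 1L,
             S_mm2 = S, dS_mm2 = dS, cum_dS_mm2 = cumsum(dS),
             V_mm3 = V, dV_mm3 = dV, cum_dV_mm3 = cumsum(dV))
}

#' Build per-step reports from solved expansion states
#'
#' Area from [exact_surface_area()] and volume from [mesh_volume()], both on
#' the deformed coordinates of each state, assembled into the step table.
#'
#' When an expander `center` is supplied, the columns report the clinically
#' meaningful quantities instead: S is the area of the skin-side surface
#' (facets not facing the expander; the expander-facing face is mirror
#' tissue, not new skin), and V adds the [pocket_volume()] opened under the
#' scalp to the material volume -- the analogue of the head-volume gain that
#' matches the implanted expander volume.
#'
#' @param states List of [deformed_state()]s ordered by step, step 0 first.
#' @param mesh The [scalp_mesh()] the states belong to.
#' @param center Optional expander center for the clinical S/V measures.
#' @return data.frame as in [step_table()].
#' @export
build_step_reports <- function(states, mesh, center = NULL) {
  if (is.null(center)) {
    surf <- mesh$surface_facets
    S <- vapply(states, function(st)
      exact_surface_area(surf, deformed_coords(mesh, st)), 0)
    V <- vapply(states, function(st) mesh_volume(mesh, st), 0)
  } else {
    facing <- expander_facing_facets(mesh, center)
    outer <- if (length(facing)) mesh$surface_facets[-facing, , drop = FALSE]
             else mesh$surface_facets
    S <- vapply(states, function(st)
      exact_surface_area(outer, deformed_coords(mesh, st)), 0)
    V <- vapply(states, function(st)
      mesh_volume(mesh, st) + pocket_volume(mesh, st, center), 0)
  }
  step_table(S, V)
}

#' Per-step strain histories of probe elements
#'
#' For each state and probe tetrahedron, evaluates the Green strain and
#' reports the Frobenius norm of the strain tensor as the scalar measure (the
#' full Voigt tensors are returned as an attribute).
#'
#' @param states List of [deformed_state()]s, step 0 first.
#' @param mesh A [scalp_mesh()].
#' @param probe_elements Integer vector of element (tet row) indices.
#' @return data.frame with columns `step`, `element`, `strain_norm`; attribute
#'   `tensors` holds a step x element list of Voigt strains.
#' @export
strain_history <- function(states, mesh, probe_elements) {
  m <- nrow(mesh$tets)
  if (any(probe_elements < 1 | probe_elements > m)) {
    stop("unknown probe element id")
  }
  elems <- lapply(probe_elements, function(e)
    shape_gradients(mesh$nodes[mesh$tets[e, ], ], node_ids = mesh$tets[e, ]))
  rows <- list()
  tensors <- list()
  for (s in seq_along(states)) {
    u <- states[[s]]$u
    for (p in seq_along(probe_elements)) {
      kin <- green_strain(elems[[p]], u[dof_indices(mesh$tets[probe_elements[p], ])])
      Et <- voigt_to_strain(kin$E)
      rows[[length(rows) + 1]] <- data.frame(
        step = s - 1L, element = probe_elements[p],
        strain_norm = sqrt(sum(Et^2)))
      tensors[[length(tensors) + 1]] <- kin$E
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "tensors") <- tensors
  out
}
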