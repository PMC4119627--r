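#' Construct a reference (undeformed) tetrahedral mesh
#'
#' The Lagrangian reference configuration of the model: node coordinates,
#' tetrahedral connectivity, the free surface, the pinned boundary nodes and
#' (optionally) the reference location of the expander center. Tetrahedra with
#' negative signed volume are reoriented (last two nodes swapped) with a
#' warning; zero-volume tetrahedra are an error.
#'
#' @param nodes Numeric n x 3 matrix of reference coordinates (mm).
#' @param tets Integer m x 4 matrix of node indices (1-based).
#' @param fixed_nodes Integer vector of node indices whose displacements are
#'   pinned to zero (must lie on the surface).
#' @param center_point Length-3 reference coordinate of the expander center, or
#'   `NULL` when supplied later via configuration.
#' @return An object of class `scalp_mesh` with elements `nodes`, `tets`,
#'   `surface_facets` (outward-oriented triangles), `fixed_nodes`,
#'   `center_point`.
#' @export
scalp_mesh <- function(nodes, tets, fixed_nodes = integer(0), center_point = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3) stop("nodes must be an n x 3 coordinate matrix")
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(tets) != 4) {
    stop("element with ", ncol(tets), " nodes is not a tetrahedron")
  }
  n <- nrow(nodes)
  if (any(tets < 1L | tets > n)) stop("tetrahedron refers to a missing node")
  fixed_nodes <- sort(unique(as.integer(fixed_nodes)))
  if (length(fixed_nodes) && any(fixed_nodes < 1L | fixed_nodes > n)) {
    stop("fixed_nodes refers to a missing node")
  }

  v <- tet_volumes(nodes, tets)
  scale <- max(abs(nodes)) + 1
  bad <- which(abs(v) <= 1e-14 * scale^3)
  if (length(bad)) {
    stop("degenerate (zero volume) tetrahedron: element ", bad[1])
  }
  neg <- which(v < 0)
  if (length(neg)) {
    warning(length(neg), " tetrahedra had negative orientation; node order flipped")
    tets[neg, 3:4] <- tets[neg, 4:3]
  }

  mesh <- structure(
    list(nodes = nodes, tets = tets, surface_facets = NULL,
         fixed_nodes = fixed_nodes, center_point = center_point),
    class = "scalp_mesh")
  mesh$surface_facets <- extract_surface(mesh)
  surf_nodes <- unique(as.vector(mesh$surface_facets))
  if (length(fixed_nodes) && !all(fixed_nodes %in% surf_nodes)) {
    stop("fixed_nodes must be a subset of surface nodes")
  }
  mesh
}

#' @export
print.scalp_mesh <- function(x, ...) {
  cat("Tetrahedral reference mesh\n")
  cat("  nodes:         ", nrow(x$nodes), "\n")
  cat("  tetrahedra:    ", nrow(x$tets), "\n")
  cat("  surface facets:", nrow(x$surface_facets), "\n")
  cat("  fixed nodes:   ", length(x$fixed_nodes), "\n")
  if (!is.null(x$center_point)) {
    cat("  expander center:", paste(signif(x$center_point, 6), collapse = ", "), "\n")
  }
  cat("  reference volume:", format(mesh_volume(x)), "mm^3\n")
  invisible(x)
}

# signed volumes of all tets, vectorized
tet_volumes <- function(nodes, tets, coords = nodes) {
  a <- coords[tets[, 1], , drop = FALSE]
  b <- coords[tets[, 2], , drop = FALSE]
  c_ <- coords[tets[, 3], , drop = FALSE]
  d <- coords[tets[, 4], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a; e3 <- d - a
  det3 <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
          e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
          e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  det3 / 6
}

#' Total mesh volume in reference or deformed coordinates
#'
#' Sum of signed tetrahedron volumes, evaluated on the reference coordinates
#' or, when a deformed state is supplied, on the current coordinates
#' \eqn{x = X + u}.
#'
#' @param mesh A [scalp_mesh()].
#' @param state A [deformed_state()] or `NULL` for the reference configuration.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh, state = NULL) {
  coords <- deformed_coords(mesh, state)
  sum(tet_volumes(mesh$nodes, mesh$tets, coords = coords))
}

deformed_coords <- function(mesh, state = NULL) {
  if (is.null(state)) return(mesh$nodes)
  u <- if (inherits(state, "deformed_state")) state$u else state
  if (length(u) != 3 * nrow(mesh$nodes)) {
    stop("displacement dimension (", length(u), ") does not match mesh (",
         3 * nrow(mesh$nodes), " dofs)")
  }
  mesh$nodes + disp_matrix(u, nrow(mesh$nodes))
}

#' Extract the boundary surface of a tetrahedral mesh
#'
#' Returns exactly the triangular faces owned by a single tetrahedron, oriented
#' outward (so the divergence-theorem volume of a closed surface is positive
#' and equals the mesh volume).
#'
#' @param mesh A [scalp_mesh()] or a list with `nodes` and `tets`.
#' @return Integer f x 3 matrix of node indices.
#' @export
extract_surface <- function(mesh) {
  tets <- mesh$tets
  m <- nrow(tets)
  # faces of a positively oriented tet, outward-facing
  faces <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
                 tets[, c(2, 3, 4)], tets[, c(1, 4, 3)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  cnt <- table(key)
  if (any(cnt > 2)) {
    stop("non-manifold face shared by more than two tetrahedra: ",
         names(cnt)[which(cnt > 2)[1]])
  }
  faces[cnt[key] == 1L, , drop = FALSE]
}

#' Create a deformed state
#'
#' @param u Displacement vector, 3 components per node (mm), node-major.
#' @param pseudo_time Load-step index the state belongs to.
#' @param converged Logical convergence flag.
#' @param residual_norm Final residual (unbalanced-force) norm in N.
#' @param iterations Newton iterations used.
#' @return Object of class `deformed_state`.
#' @export
deformed_state <- function(u, pseudo_time = 0, converged = NA,
                           residual_norm = NA_real_, iterations = NA_integer_) {
  structure(list(u = as.numeric(u), pseudo_time = pseudo_time,
                 converged = converged, residual_norm = residual_norm,
                 iterations = iterations),
            class = "deformed_state")
}

#' @export
print.deformed_state <- function(x, ...) {
  cat("Deformed state (step ", x$pseudo_time, "): ",
      length(x$u) / 3, " nodes, |u|_max = ",
      format(max(abs(x$u)), digits = 4), " mm, residual = ",
      format(x$residual_norm, digits = 3), " N",
      if (isTRUE(x$converged)) " (converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Pocket volume opened by the expander under the scalp
#'
#' The expansion displaces the scalp away from the expander, opening a pocket
#' between the expander-facing surface and its reference position. For a
#' surface patch whose rim is pinned, the deformed and reference patches share
#' their boundary curve, so the enclosed (swept) volume is exactly the
#' difference of their signed cone-volume integrals. Together with the
#' (nearly preserved) material volume, the pocket is the analogue of the
#' volume gain a whole-head solid mesh would show, and it is the quantity
#' that matches the implanted expander volume for sizing.
#'
#' @param mesh A [scalp_mesh()].
#' @param state A [deformed_state()] (or displacement vector).
#' @param center Expander center; defaults to `mesh$center_point`.
#' @return Swept volume in mm^3 (positive when the scalp lifts off).
#' @export
pocket_volume <- function(mesh, state, center = mesh$center_point) {
  if (is.null(center)) stop("no expander center available")
  facing <- expander_facing_facets(mesh, center)
  cone_sum <- function(coords) {
    s <- mesh$surface_facets[facing, , drop = FALSE]
    a <- coords[s[, 1], , drop = FALSE]
    b <- coords[s[, 2], , drop = FALSE]
    c_ <- coords[s[, 3], , drop = FALSE]
    sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
        a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  }
  cone_sum(mesh$nodes) - cone_sum(deformed_coords(mesh, state))
}

# facets whose reference outward normal points toward the expander center
# (the inner face of the shell); facets whose plane contains the center --
# the apex facets when the center lies on the inner surface -- count as facing
expander_facing_facets <- function(mesh, center = mesh$center_point) {
  an <- facet_area_normals(mesh$surface_facets, mesh$nodes)
  cen <- facet_centroids(mesh$surface_facets, mesh$nodes)
  d <- sweep(cen, 2, center)
  tol <- 1e-8 * sqrt(rowSums(an^2)) * sqrt(rowSums(d^2))
  which(rowSums(an * d) < tol)
}

# ---- synthetic fixture meshes -------------------------------------------------

# Kuhn (Freudenthal) split of one hexahedral cell into 6 face-compatible tets.
# `corners` indexes the cell's 8 vertices in (i,j,k)-binary order:
# (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),(1,0,1),(0,1,1),(1,1,1).
.kuhn_tets <- local({
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  t(apply(perms, 1, function(p) {
    v <- c(0, 0, 0)
    path <- integer(4)
    path[1] <- 1L
    for (s in 1:3) {
      v[p[s]] <- 1
      path[s + 1] <- 1L + v[1] + 2L * v[2] + 4L * v[3]
    }
    path
  }))
})

hex_to_tets <- function(corners) {
  tets <- matrix(corners[.kuhn_tets], ncol = 4)
  tets
}

#' Structured unit-cube test mesh
#'
#' An axis-aligned `[0,1]^3` cube on an `n x n x n` grid, each cell split into
#' six tetrahedra. Used as a fixture: volume 1, surface area 6, and for n = 1 it
#' is the minimal 8-node, 6-tet, 12-facet decomposition.
#'
#' @param n Grid subdivisions per axis.
#' @param fixed Optional character: `"none"` (default) or `"boundary"` to pin
#'   every boundary node.
#' @return A [scalp_mesh()].
#' @export
make_unit_cube <- function(n = 1, fixed = c("none", "boundary")) {
  fixed <- match.arg(fixed)
  g <- seq(0, 1, length.out = n + 1)
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))[, 1:3]
  dimnames(nodes) <- NULL
  idx <- function(i, j, k) i + (n + 1) * (j - 1 + (n + 1) * (k - 1))
  tets <- vector("list", n^3)
  cell <- 0L
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    cell <- cell + 1L
    corners <- c(idx(i, j, k),     idx(i + 1, j, k),
                 idx(i, j + 1, k), idx(i + 1, j + 1, k),
                 idx(i, j, k + 1), idx(i + 1, j, k + 1),
                 idx(i, j + 1, k + 1), idx(i + 1, j + 1, k + 1))
    tets[[cell]] <- hex_to_tets(corners)
  }
  tets <- do.call(rbind, tets)
  tets <- orient_tets(nodes, tets)
  fixed_nodes <- if (fixed == "boundary") {
    which(apply(nodes, 1, function(p) any(p %in% c(0, 1))))
  } else integer(0)
  scalp_mesh(nodes, tets, fixed_nodes = fixed_nodes)
}

#' Single reference tetrahedron fixture
#'
#' The unit tetrahedron (0,0,0),(1,0,0),(0,1,0),(0,0,1) with volume 1/6, the
#' first three nodes pinned.
#'
#' @return A [scalp_mesh()].
#' @export
make_single_tet <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  scalp_mesh(nodes, matrix(1:4, 1), fixed_nodes = 1:3)
}

# silently fix orientation during fixture generation (generator's own cells)
orient_tets <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  tets[neg, 3:4] <- tets[neg, 4:3]
  tets
}

#' Generate a scalp-like spherical shell patch
#'
#' Builds a spherical shell patch of given thickness around `mid_radius`,
#' meshed with hexahedral cells that are each split into six tetrahedra. The
#' patch is the gnomonic (cubed-sphere) image of a square grid, so every cell
#' is a proper hexahedron with no degeneracy at the apex; `polar_extent` is the
#' angular half-width of the patch along the two tangent axes (corners reach
#' slightly further). The rim nodes are pinned (`fixed_nodes`) and the expander
#' center is placed on the inner surface beneath the apex. The default 3.4 mm
#' thickness reflects the structural thickness of adult scalp.
#'
#' @param mid_radius Mid-surface radius in mm.
#' @param thickness Shell thickness in mm (default 3.4).
#' @param polar_extent Angular half-width of the patch in degrees.
#' @param n_theta,n_phi Grid divisions along the two tangent directions.
#' @param n_layers Element layers through the thickness.
#' @return A [scalp_mesh()] with the cap apex on the +z axis.
#' @export
make_shell_patch <- function(mid_radius = 80, thickness = 3.4,
                             polar_extent = 45, n_theta = 16, n_phi = 16,
                             n_layers = 1) {
  if (!(mid_radius > thickness / 2 && thickness > 0)) {
    stop("need mid_radius > thickness/2 > 0")
  }
  if (polar_extent <= 0 || polar_extent >= 90) {
    stop("polar_extent must be in (0, 90) degrees")
  }
  if (min(n_theta, n_phi, n_layers) < 1) stop("all grid counts must be >= 1")

  r_in <- mid_radius - thickness / 2
  r_out <- mid_radius + thickness / 2
  tmax <- tan(polar_extent * pi / 180)
  a <- tmax * seq(-1, 1, length.out = n_theta + 1)
  b <- tmax * seq(-1, 1, length.out = n_phi + 1)
  r <- seq(r_in, r_out, length.out = n_layers + 1)

  na <- n_theta + 1; nb <- n_phi + 1; nr <- n_layers + 1
  idx <- function(i, j, l) i + na * (j - 1 + nb * (l - 1))
  nodes <- matrix(0, na * nb * nr, 3)
  for (l in 1:nr) for (j in 1:nb) for (i in 1:na) {
    d <- c(a[i], b[j], 1)
    nodes[idx(i, j, l), ] <- r[l] * d / sqrt(sum(d^2))
  }

  tets <- vector("list", n_theta * n_phi * n_layers)
  cell <- 0L
  for (l in 1:n_layers) for (j in 1:n_phi) for (i in 1:n_theta) {
    cell <- cell + 1L
    corners <- c(idx(i, j, l),     idx(i + 1, j, l),
                 idx(i, j + 1, l), idx(i + 1, j + 1, l),
                 idx(i, j, l + 1), idx(i + 1, j, l + 1),
                 idx(i, j + 1, l + 1), idx(i + 1, j + 1, l + 1))
    tets[[cell]] <- hex_to_tets(corners)
  }
  tets <- orient_tets(nodes, do.call(rbind, tets))

  rim <- as.vector(outer(1:nr, 1:nb, function(l, j) idx(1L, j, l)))
  rim <- c(rim, as.vector(outer(1:nr, 1:nb, function(l, j) idx(na, j, l))))
  rim <- c(rim, as.vector(outer(1:nr, 1:na, function(l, i) idx(i, 1L, l))))
  rim <- c(rim, as.vector(outer(1:nr, 1:na, function(l, i) idx(i, nb, l))))

  scalp_mesh(nodes, tets, fixed_nodes = unique(rim),
             center_point = c(0, 0, r_in))
}
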