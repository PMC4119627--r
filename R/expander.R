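#' Virtual ellipsoid tissue expander
#'
#' A growing ellipsoid of fixed axis ratio (default 1.53 : 1 : 1, long axis
#' along x) that models the implanted expander. It starts at volume zero at the
#' configured center; contact with the deforming scalp is decided by the
#' ellipsoid inequality and contacted facets receive the expander's fluid
#' pressure (default 0.3 N/mm^2, i.e. 30 N/cm^2).
#'
#' @param center Reference coordinate of the expander center (mm).
#' @param axis_ratio Length-3 positive axis proportions.
#' @param volume Current ellipsoid volume, mm^3 (>= 0).
#' @param pressure Fluid pressure, N/mm^2.
#' @return Object of class `ellipsoid_expander`.
#' @export
ellipsoid_expander <- function(center, axis_ratio = c(1.53, 1, 1),
                               volume = 0, pressure = 0.3) {
  stopifnot(length(center) == 3, length(axis_ratio) == 3)
  if (any(axis_ratio <= 0)) stop("axis_ratio components must be > 0")
  if (volume < 0) stop("volume must be >= 0")
  structure(list(center = as.numeric(center),
                 axis_ratio = as.numeric(axis_ratio),
                 volume = volume, pressure = pressure),
            class = "ellipsoid_expander")
}

#' @export
print.ellipsoid_expander <- function(x, ...) {
  ax <- ellipsoid_semi_axes(x$volume, x$axis_ratio)
  cat("Ellipsoid expander: volume", format(x$volume), "mm^3,",
      "pressure", x$pressure, "N/mm^2\n")
  cat("  center:", paste(signif(x$center, 6), collapse = ", "), "\n")
  cat("  semi-axes:", paste(signif(ax, 6), collapse = ", "), "mm\n")
  invisible(x)
}

#' Semi-axes of an ellipsoid of given volume and axis ratio
#'
#' Axes proportional to `axis_ratio` with \eqn{(4/3)\pi\,abc} equal to the
#' requested volume; zero volume gives zero axes.
#'
#' @param volume Ellipsoid volume, mm^3.
#' @param axis_ratio Length-3 positive proportions.
#' @return Length-3 numeric vector of semi-axes (mm).
#' @export
ellipsoid_semi_axes <- function(volume, axis_ratio = c(1.53, 1, 1)) {
  if (volume < 0) stop("volume must be >= 0")
  s <- (3 * volume / (4 * pi * prod(axis_ratio)))^(1 / 3)
  axis_ratio * s
}

facet_centroids <- function(facets, coords) {
  (coords[facets[, 1], , drop = FALSE] +
   coords[facets[, 2], , drop = FALSE] +
   coords[facets[, 3], , drop = FALSE]) / 3
}

# area-weighted normals (cross product / 2) of all facets, f x 3
facet_area_normals <- function(facets, coords) {
  a <- coords[facets[, 1], , drop = FALSE]
  b <- coords[facets[, 2], , drop = FALSE]
  c_ <- coords[facets[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
}

#' Facets of the deformed surface contacted by the expander
#'
#' A facet is contacted when its deformed centroid \eqn{q} lies inside the
#' expander, \eqn{\|\Lambda^{-1}(q - c)\| \le 1} with
#' \eqn{\Lambda = \mathrm{diag}} of the semi-axes. A zero-volume expander
#' contacts nothing. The contact set is monotone in expander volume.
#'
#' @param surface Integer f x 3 facet matrix (outward-oriented).
#' @param coords Deformed node coordinates (n x 3).
#' @param expander An [ellipsoid_expander()].
#' @return Integer vector of row indices into `surface`.
#' @export
contact_facets <- function(surface, coords, expander) {
  if (expander$volume <= 0) return(integer(0))
  ax <- ellipsoid_semi_axes(expander$volume, expander$axis_ratio)
  q <- facet_centroids(surface, coords)
  d <- sweep(q, 2, expander$center)
  r2 <- (d[, 1] / ax[1])^2 + (d[, 2] / ax[2])^2 + (d[, 3] / ax[3])^2
  which(r2 <= 1 + 1e-12)
}

#' Equivalent nodal load of a uniform pressure on surface facets
#'
#' Follower pressure load: for each contacted triangle with deformed area
#' \eqn{A} and unit outward normal \eqn{n}, each of its three nodes receives
#' the force \eqn{-p A n / 3} (the pressure acts compressively on the surface,
#' so on facets whose outward normal faces the expander the load pushes the
#' scalp away from it). Areas and normals are evaluated on the deformed
#' coordinates, so the load follows the deforming surface. Degenerate
#' (zero-area) facets are skipped with a warning.
#'
#' @param facets Integer k x 3 matrix of contacted, outward-oriented facets.
#' @param coords Deformed node coordinates (n x 3).
#' @param pressure Pressure in N/mm^2.
#' @param n_nodes Total node count (sets the length of the returned vector).
#' @param jacobian If `TRUE`, the exact load-stiffness matrix
#'   \eqn{\partial R / \partial u} of the follower load is attached as
#'   attribute `"jacobian"` (sparse `3n x 3n`); the Newton solver uses it to
#'   keep quadratic convergence under follower pressure.
#' @return Global load vector of length `3 * n_nodes` (N).
#' @export
pressure_nodal_load <- function(facets, coords, pressure, n_nodes = nrow(coords),
                                jacobian = FALSE) {
  R <- numeric(3 * n_nodes)
  if (is.null(facets) || nrow(facets) == 0) {
    if (jacobian) {
      attr(R, "jacobian") <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                  x = numeric(0),
                                                  dims = c(3 * n_nodes, 3 * n_nodes))
    }
    return(R)
  }
  an <- facet_area_normals(facets, coords)
  areas <- sqrt(rowSums(an^2))
  scale <- max(areas)
  degen <- areas <= 1e-14 * (scale + 1)
  if (any(degen)) {
    warning(sum(degen), " zero-area facet(s) skipped in pressure load")
    an <- an[!degen, , drop = FALSE]
    facets <- facets[!degen, , drop = FALSE]
  }
  f <- -pressure * an / 3                       # per-node force of each facet
  for (k in 1:3) {
    base <- 3 * (facets[, k] - 1)
    for (c_ in 1:3) {
      acc <- rowsum(f[, c_], base + c_)
      at <- as.integer(rownames(acc))
      R[at] <- R[at] + acc[, 1]
    }
  }
  if (jacobian) {
    attr(R, "jacobian") <- .pressure_load_jacobian(facets, coords, pressure,
                                                   n_nodes)
  }
  R
}

# Smoothed expander pressure load used by the incremental driver. A facet's
# pressure is weighted by w(s) of its centroid's ellipsoid coordinate
# s = ||Lambda^-1 (q - c)||^2: w = 1 inside (s <= 1), tapering linearly to 0
# across a thin band (1, 1 + band]. The taper makes the follower load a
# continuous function of the deformation (sharp contact switching chatters in
# the Newton loop) and represents the expander's shoulder, where contact
# pressure physically falls off. The returned Jacobian is exact, including
# the weight-derivative term.
expander_pressure_load <- function(surface, coords, expander, band = 0.2,
                                   n_nodes = nrow(coords)) {
  R <- numeric(3 * n_nodes)
  empty_j <- function() Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                             x = numeric(0),
                                             dims = c(3 * n_nodes, 3 * n_nodes))
  if (expander$volume <= 0) {
    attr(R, "jacobian") <- empty_j()
    return(R)
  }
  ax <- ellipsoid_semi_axes(expander$volume, expander$axis_ratio)
  q <- facet_centroids(surface, coords)
  d <- sweep(q, 2, expander$center)
  s <- (d[, 1] / ax[1])^2 + (d[, 2] / ax[2])^2 + (d[, 3] / ax[3])^2
  an_all <- facet_area_normals(surface, coords)
  # tolerant facing test: facets whose plane contains the center (the apex
  # facets when the center lies on the inner surface) count as facing
  dots <- rowSums(an_all * d)
  tol <- 1e-8 * sqrt(rowSums(an_all^2)) * sqrt(rowSums(d^2))
  facing <- dots < tol
  sel <- which(s <= 1 + band & facing)
  if (!length(sel)) {
    attr(R, "jacobian") <- empty_j()
    return(R)
  }
  w <- pmin(1, (1 + band - s[sel]) / band)
  wp <- ifelse(s[sel] > 1, -1 / band, 0)

  p <- expander$pressure
  skew <- function(v) matrix(c(0, v[3], -v[2],
                               -v[3], 0, v[1],
                               v[2], -v[1], 0), 3, 3)
  nf <- length(sel)
  ii <- integer(81 * nf); jj <- integer(81 * nf); xx <- numeric(81 * nf)
  pos <- 0L
  for (r in seq_len(nf)) {
    fct <- surface[sel[r], ]
    x1 <- coords[fct[1], ]; x2 <- coords[fct[2], ]; x3 <- coords[fct[3], ]
    e1 <- x2 - x1; e2 <- x3 - x1
    an <- an_all[sel[r], ]
    f0 <- -(p / 3) * an                    # unweighted per-node force
    fa <- w[r] * f0
    for (a_ in 1:3) {
      at <- 3 * (fct[a_] - 1) + 1:3
      R[at] <- R[at] + fa
    }
    # geometric part of dR/dx (same role as in .pressure_load_jacobian)
    Mb <- list(-(p / 6) * w[r] * (skew(e2) - skew(e1)),
               (p / 6) * w[r] * skew(e2),
               -(p / 6) * w[r] * skew(e1))
    # taper part: f0 otimes dw/dx_b, dw/dx_b = w'(s) * (2/3) (q-c)/ax^2
    if (wp[r] != 0) {
      g <- wp[r] * (2 / 3) * d[sel[r], ] / ax^2
      G1 <- outer(f0, g)
      for (b_ in 1:3) Mb[[b_]] <- Mb[[b_]] + G1
    }
    for (a_ in 1:3) {
      ra <- 3 * (fct[a_] - 1)
      for (b_ in 1:3) {
        cb <- 3 * (fct[b_] - 1)
        ii[pos + 1:9] <- ra + rep(1:3, 3)
        jj[pos + 1:9] <- cb + rep(1:3, each = 3)
        xx[pos + 1:9] <- Mb[[b_]]
        pos <- pos + 9L
      }
    }
  }
  attr(R, "jacobian") <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                              dims = c(3 * n_nodes, 3 * n_nodes))
  R
}

# Exact derivative of the follower pressure load with respect to nodal
# positions. Per facet the force on each of its three nodes is
# f = -(p/6) (x2 - x1) x (x3 - x1); the derivative w.r.t. each facet node is a
# cross-product (skew) matrix, identical for the three receiving nodes.
.pressure_load_jacobian <- function(facets, coords, pressure, n_nodes) {
  skew <- function(v) matrix(c(0, v[3], -v[2],
                               -v[3], 0, v[1],
                               v[2], -v[1], 0), 3, 3)
  nf <- nrow(facets)
  ii <- integer(81 * nf); jj <- integer(81 * nf); xx <- numeric(81 * nf)
  pos <- 0L
  for (r in seq_len(nf)) {
    x1 <- coords[facets[r, 1], ]; x2 <- coords[facets[r, 2], ]
    x3 <- coords[facets[r, 3], ]
    e1 <- x2 - x1; e2 <- x3 - x1
    Mb <- list(-(pressure / 6) * (skew(e2) - skew(e1)),
               (pressure / 6) * skew(e2),
               -(pressure / 6) * skew(e1))
    for (a_ in 1:3) {
      ra <- 3 * (facets[r, a_] - 1)
      for (b_ in 1:3) {
        cb <- 3 * (facets[r, b_] - 1)
        ii[pos + 1:9] <- ra + rep(1:3, 3)
        jj[pos + 1:9] <- cb + rep(1:3, each = 3)
        xx[pos + 1:9] <- Mb[[b_]]
        pos <- pos + 9L
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(3 * n_nodes, 3 * n_nodes))
}
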