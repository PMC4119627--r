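test_that("surface sampling is deterministic and lands on the surface", {
  mesh <- make_shell_patch(n_theta = 4, n_phi = 4)
  s1 <- sample_surface(mesh$surface_facets, mesh$nodes, 200, seed = 7)
  s2 <- sample_surface(mesh$surface_facets, mesh$nodes, 200, seed = 7)
  expect_identical(s1$points, s2$points)
  s3 <- sample_surface(mesh$surface_facets, mesh$nodes, 200, seed = 8)
  expect_false(identical(s1$points, s3$points))

  # every point lies in the plane of its generating facet
  fi <- attr(s1$points, "facet")
  for (r in seq_len(50)) {
    f <- mesh$surface_facets[fi[r], ]
    a <- mesh$nodes[f[1], ]
    nrm <- scalpexp:::facet_area_normals(matrix(f, 1), mesh$nodes)
    nrm <- nrm / sqrt(sum(nrm^2))
    expect_lt(abs(sum((s1$points[r, ] - a) * nrm)), 1e-10)
  }
  expect_error(sample_surface(mesh$surface_facets, mesh$nodes, 2), "at least 3")
})

test_that("facet hit counts are proportional to facet areas", {
  tet <- make_single_tet()     # four facets with unequal areas
  n <- 1e5
  s <- sample_surface(tet$surface_facets, tet$nodes, n, seed = 1)
  an <- scalpexp:::facet_area_normals(tet$surface_facets, tet$nodes)
  areas <- sqrt(rowSums(an^2))
  counts <- tabulate(attr(s$points, "facet"), nbins = 4)
  pval <- stats::chisq.test(counts, p = areas / sum(areas))$p.value
  expect_gt(pval, 0.001)
})

test_that("sampling leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(sample_surface(make_single_tet()$surface_facets,
                           make_single_tet()$nodes, 10, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("delaunay area is exact for planar point sets", {
  g <- expand.grid(x = seq(0, 1, by = 0.1), y = seq(0, 1, by = 0.1))
  pts <- cbind(g$x, g$y, 0)
  expect_equal(delaunay_area(pts), 1.0, tolerance = 1e-9)
})

test_that("delaunay area rejects degenerate input and detects fold-over", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(delaunay_area(line), "collinear")
  # a surface folded back over itself is not a height field over any plane:
  # random sample of a three-quarter cylinder
  fold <- scalpexp:::with_seed(9, {
    th <- runif(600, 0, 1.5 * pi)
    cbind(cos(th), sin(th), runif(600))
  })
  expect_error(delaunay_area(fold), "fold-over|graph")
})

test_that("delaunay area is invariant under rigid motion", {
  mesh <- make_shell_patch(n_theta = 6, n_phi = 6)
  # sample the skin-side face only (the full shell surface is two sheets)
  outer <- mesh$surface_facets[-scalpexp:::expander_facing_facets(mesh), ]
  s <- sample_surface(outer, mesh$nodes, 600, seed = 3)
  a0 <- delaunay_area(s$points)
  set.seed(61)
  Q <- random_rotation()
  moved <- s$points %*% t(Q) + rep(c(10, -4, 7), each = nrow(s$points))
  expect_equal(delaunay_area(moved), a0, tolerance = 1e-9)
})

test_that("delaunay estimate converges to the analytic spherical cap area", {
  # polar cap of half-angle 45 deg on an 80 mm sphere: area = 2*pi*R*h
  R <- 80; theta <- 45 * pi / 180
  h <- R * (1 - cos(theta))
  cap_area <- 2 * pi * R * h
  sample_cap <- function(n, seed) {
    scalpexp:::with_seed(seed, {
      z <- stats::runif(n, R * cos(theta), R)
      phi <- stats::runif(n, 0, 2 * pi)
      r <- sqrt(R^2 - z^2)
      cbind(r * cos(phi), r * sin(phi), z)
    })
  }
  err <- vapply(c(500, 5000), function(n)
    abs(delaunay_area(sample_cap(n, seed = 42)) - cap_area) / cap_area, 0)
  expect_lt(err[2], err[1])          # estimator converges with n
  expect_lt(err[2], 0.01)
})

test_that("exact surface area agrees with the delaunay estimate on a patch", {
  mesh <- make_shell_patch(n_theta = 10, n_phi = 10)
  exact <- exact_surface_area(mesh$surface_facets, mesh$nodes)
  # estimate only the outer face of the shell: facets with outward radial normal
  an <- scalpexp:::facet_area_normals(mesh$surface_facets, mesh$nodes)
  cen <- scalpexp:::facet_centroids(mesh$surface_facets, mesh$nodes)
  outer <- which(rowSums(an * cen) > 0 &
                 sqrt(rowSums(cen^2)) > 80)
  outer_exact <- sum(sqrt(rowSums(an[outer, ]^2)))
  # the square patch has corners, so the hull deficit dies off more slowly
  # than for a round cap; 8000 points is comfortably in the converged regime
  s <- sample_surface(mesh$surface_facets[outer, ], mesh$nodes, 8000, seed = 5)
  expect_equal(delaunay_area(s), outer_exact, tolerance = 0.01)
  expect_lt(outer_exact, exact)
})

test_that("unit cube has exact surface area 6", {
  cube <- make_unit_cube(2)
  expect_equal(exact_surface_area(cube$surface_facets, cube$nodes), 6.0)
})

test_that("step table identities hold and a single state gives zero deltas", {
  S <- c(100, 110, 125)
  V <- c(1000, 1040, 1100)
  tab <- step_table(S, V)
  expect_equal(tab$dS_mm2, c(0, 10, 15))
  expect_equal(tab$cum_dS_mm2, c(0, 10, 25))
  expect_equal(tab$dV_mm3, c(0, 40, 60))
  expect_equal(tab$cum_dV_mm3[3], V[3] - V[1])

  single <- step_table(100, 1000)
  expect_equal(single$dS_mm2, 0)
  expect_equal(single$cum_dV_mm3, 0)
})

test_that("strain history is zero at rest and uniform under homogeneous stretch", {
  mesh <- make_unit_cube(2)
  n <- nrow(mesh$nodes)
  lam <- 1.25
  u_hom <- as.vector(t(mesh$nodes %*% diag(c(lam, 1, 1)) - mesh$nodes))
  states <- list(deformed_state(numeric(3 * n), 0),
                 deformed_state(u_hom, 1))
  probes <- c(1, 10, 25)
  hist <- strain_history(states, mesh, probes)
  step0 <- hist[hist$step == 0, ]
  expect_equal(step0$strain_norm, rep(0, 3))
  step1 <- hist[hist$step == 1, ]
  expect_equal(diff(range(step1$strain_norm)), 0, tolerance = 1e-12)
  expect_equal(step1$strain_norm[1], (lam^2 - 1) / 2, tolerance = 1e-12)
  expect_error(strain_history(states, mesh, 9999), "unknown probe")

  # probe values equal direct strain evaluation on the stored state
  el <- shape_gradients(mesh$nodes[mesh$tets[10, ], ])
  kin <- green_strain(el, u_hom[scalpexp:::dof_indices(mesh$tets[10, ])])
  Et <- scalpexp:::voigt_to_strain(kin$E)
  expect_equal(step1$strain_norm[2], sqrt(sum(Et^2)), tolerance = 1e-12)
})

test_that("build_step_reports reproduces exact area and volume measures", {
  mesh <- make_unit_cube(2)
  n <- nrow(mesh$nodes)
  lam <- 1.1
  u <- as.vector(t(mesh$nodes %*% diag(c(lam, 1, 1)) - mesh$nodes))
  states <- list(deformed_state(numeric(3 * n), 0), deformed_state(u, 1))
  tab <- build_step_reports(states, mesh)
  expect_equal(tab$V_mm3, c(1, lam), tolerance = 1e-12)
  expect_equal(tab$S_mm2[1], 6)
  expect_equal(tab$S_mm2[2], 2 + 4 * lam, tolerance = 1e-12)
})
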