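test_that("unit tet shape gradients are the closed-form constants", {
  el <- shape_gradients(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(el$grad_N,
               cbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(el$ref_volume, 1 / 6)
})

test_that("gradients satisfy partition of unity and transform affinely", {
  set.seed(3)
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (rep in 1:5) {
    M <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
    if (det(M) < 0.1) next
    coords <- base %*% t(M) + rep(rnorm(3), each = 4)
    el <- shape_gradients(coords)
    expect_equal(rowSums(el$grad_N), c(0, 0, 0), tolerance = 1e-12)
    # affine map: grad wrt x = inv(M)^T grad wrt X
    el0 <- shape_gradients(base)
    expect_equal(el$grad_N, t(solve(M)) %*% el0$grad_N, tolerance = 1e-10)
  }
  expect_error(shape_gradients(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                     c(3, 0, 0))), "singular element")
})

test_that("zero displacement gives zero strain and B reduces to B_L", {
  el <- shape_gradients(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  kin <- green_strain(el, rep(0, 12))
  expect_equal(kin$E, rep(0, 6))
  expect_equal(max(abs(kin$B_N)), 0)
  expect_equal(strain_variation(el, rep(0, 12)), kin$B_L)
  expect_equal(dim(strain_variation(el, rnorm(12))), c(6, 12))
})

test_that("rigid rotation produces numerically zero Green strain", {
  set.seed(5)
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  el <- shape_gradients(coords)
  for (rep in 1:5) {
    Q <- random_rotation(angle = pi / 6)
    u <- as.vector(t(coords %*% t(Q) - coords))
    kin <- green_strain(el, u)
    expect_lt(max(abs(kin$E)), 1e-12)
  }
})

test_that("homogeneous stretch gives the closed-form Green strain", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  el <- shape_gradients(coords)
  lam <- 1.3
  u <- as.vector(t(coords %*% diag(c(lam, 1, 1)) - coords))
  kin <- green_strain(el, u)
  expect_equal(kin$E, c((lam^2 - 1) / 2, 0, 0, 0, 0, 0), tolerance = 1e-12)
})

test_that("kinematic identity E = B_L a + A theta / 2 holds", {
  set.seed(23)
  coords <- rbind(c(0, 0, 0), c(1.2, 0.1, 0), c(0, 0.9, 0.2), c(0.1, 0, 1.1))
  el <- shape_gradients(coords)
  u <- rnorm(12, sd = 0.1)
  kin <- green_strain(el, u)
  expect_equal(kin$theta, as.numeric(kin$G %*% u), tolerance = 1e-14)
  expect_equal(kin$E,
               as.numeric(kin$B_L %*% u + 0.5 * kin$A %*% kin$theta),
               tolerance = 1e-14)
  # against the tensor definition E = (F^T F - I)/2
  U <- matrix(u, 3, 4)
  F <- diag(3) + U %*% t(el$grad_N)
  expect_equal(scalpexp:::voigt_to_strain(kin$E),
               (t(F) %*% F - diag(3)) / 2, tolerance = 1e-13)
})

test_that("B is the exact directional derivative of the Green strain", {
  set.seed(29)
  coords <- rbind(c(0, 0, 0), c(1, 0.2, 0), c(0.1, 1, 0), c(0, 0.1, 0.9))
  el <- shape_gradients(coords)
  u <- rnorm(12, sd = 0.1)
  B <- strain_variation(el, u)
  h <- 1e-6
  for (rep in 1:4) {
    dv <- rnorm(12)
    dE_fd <- (green_strain(el, u + h * dv)$E -
              green_strain(el, u - h * dv)$E) / (2 * h)
    dE_B <- as.numeric(B %*% dv)
    expect_lt(max(abs(dE_fd - dE_B)) / max(abs(dE_B)), 1e-6)
  }
})

test_that("internal force is the gradient of the element energy", {
  set.seed(31)
  mat <- fung_material(a = 0.1, b = 10, kappa = 10)
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  el <- shape_gradients(coords)
  expect_equal(element_internal_force(el, rep(0, 12), mat), rep(0, 12))
  u <- rnorm(12, sd = 0.05)
  f <- element_internal_force(el, u, mat)
  # self-equilibrium: components sum to zero per axis
  expect_lt(max(abs(rowSums(matrix(f, nrow = 3)))), 1e-12)
  en <- function(v) el$ref_volume * strain_energy(green_strain(el, v)$E, mat)
  h <- 1e-6
  f_fd <- vapply(1:12, function(q) {
    e1 <- u; e2 <- u; e1[q] <- e1[q] + h; e2[q] <- e2[q] - h
    (en(e1) - en(e2)) / (2 * h)
  }, 0)
  expect_lt(max(abs(f - f_fd)) / max(abs(f)), 1e-5)
})

test_that("element tangent is the exact symmetric Jacobian of the force", {
  set.seed(37)
  mat <- fung_material(a = 0.1, b = 10, kappa = 10)
  coords <- rbind(c(0, 0, 0), c(1, 0.1, 0), c(0, 1, 0.1), c(0.1, 0, 1))
  el <- shape_gradients(coords)
  u <- rnorm(12, sd = 0.05)
  K <- element_tangent(el, u, mat)
  expect_true(isSymmetric(K, tol = 1e-10))
  h <- 1e-6
  K_fd <- vapply(1:12, function(q) {
    e1 <- u; e2 <- u; e1[q] <- e1[q] + h; e2[q] <- e2[q] - h
    (element_internal_force(el, e1, mat) -
       element_internal_force(el, e2, mat)) / (2 * h)
  }, numeric(12))
  expect_lt(max(abs(K - K_fd)) / max(abs(K)), 1e-4)
})

test_that("tangent at zero displacement is the linear-elastic stiffness", {
  mat <- fung_material(a = 0.1, b = 10, kappa = 10)
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  el <- shape_gradients(coords)
  K0 <- element_tangent(el, rep(0, 12), mat)
  kin <- green_strain(el, rep(0, 12))
  D0 <- tangent_modulus(matrix(0, 3, 3), mat)
  expect_equal(K0, el$ref_volume * t(kin$B_L) %*% D0 %*% kin$B_L,
               tolerance = 1e-12)
})

test_that("internal force is frame indifferent", {
  set.seed(41)
  mat <- fung_material(a = 0.1, b = 10, kappa = 10)
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  el <- shape_gradients(coords)
  u <- rnorm(12, sd = 0.05)
  f <- element_internal_force(el, u, mat)
  Q <- random_rotation()
  xdef <- (coords + matrix(u, 4, 3, byrow = TRUE)) %*% t(Q)
  u_rot <- as.vector(t(xdef - coords))
  f_rot <- element_internal_force(el, u_rot, mat)
  expect_equal(matrix(f_rot, 3), Q %*% matrix(f, 3), tolerance = 1e-9)
})

test_that("an inverted element is reported with its nodes", {
  mat <- fung_material()
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  el <- shape_gradients(coords, node_ids = c(9, 10, 11, 12))
  u <- rep(0, 12); u[12] <- -1.5    # push node 4 through the opposite face
  expect_error(element_internal_force(el, u, mat), "9,10,11,12")
})

test_that("patch test: homogeneous deformation is reproduced exactly", {
  mat <- fung_material(a = 0.1, b = 10, kappa = 10)
  mesh <- make_unit_cube(2, fixed = "boundary")   # has an interior node
  expect_lt(length(mesh$fixed_nodes), nrow(mesh$nodes))
  F <- diag(3) + matrix(c(0.03, 0.01, 0, 0.02, -0.01, 0.015,
                          0, 0.01, 0.02), 3, 3)
  u_hom <- as.vector(t(mesh$nodes %*% t(F) - mesh$nodes))
  u0 <- numeric(length(u_hom))
  fixed_dofs <- scalpexp:::dof_indices(mesh$fixed_nodes)
  u0[fixed_dofs] <- u_hom[fixed_dofs]
  sol <- newton_solve(mesh, mat, numeric(length(u0)), u_init = u0)
  E_exp <- strain_to_voigt((t(F) %*% F - diag(3)) / 2)
  for (e in seq_len(nrow(mesh$tets))) {
    ids <- mesh$tets[e, ]
    el <- shape_gradients(mesh$nodes[ids, ])
    kin <- green_strain(el, sol$state$u[scalpexp:::dof_indices(ids)])
    expect_equal(kin$E, E_exp, tolerance = 1e-10)
  }
})
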