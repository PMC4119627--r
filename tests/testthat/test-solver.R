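test_that("assembly at rest gives zero residual and matches element scatter", {
  mat <- fixture_material()
  mesh <- make_unit_cube(2)
  n_dof <- 3 * nrow(mesh$nodes)
  sys <- assemble(mesh, numeric(n_dof), mat)
  expect_equal(max(abs(sys$phi)), 0)

  # vectorized batch assembly agrees with the per-element reference path
  set.seed(43)
  pre <- scalpexp:::precompute_elements(mesh)
  u <- rnorm(n_dof, sd = 0.02)
  sys <- assemble(mesh, u, mat, pre = pre)
  f_ref <- numeric(n_dof)
  xx <- numeric(144 * pre$m)
  for (e in seq_len(pre$m)) {
    ed <- pre$edofs[e, ]
    f_ref[ed] <- f_ref[ed] + element_internal_force(pre$elems[[e]], u[ed], mat)
    xx[(e - 1) * 144 + 1:144] <- element_tangent(pre$elems[[e]], u[ed], mat)
  }
  expect_equal(sys$f_int, f_ref, tolerance = 1e-12)
  K_ref <- Matrix::sparseMatrix(i = pre$ii, j = pre$jj, x = xx,
                                dims = c(n_dof, n_dof))
  expect_lt(max(abs(sys$K - (K_ref + Matrix::t(K_ref)) / 2)), 1e-11)
})

test_that("global tangent matches finite differences of the residual", {
  mat <- fixture_material()
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  mesh <- scalp_mesh(nodes, rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)),
                     fixed_nodes = c(1, 2))
  set.seed(47)
  n_dof <- 15
  u <- rnorm(n_dof, sd = 0.05)
  sys <- assemble(mesh, u, mat)
  h <- 1e-6
  K_fd <- matrix(0, n_dof, n_dof)
  pre <- scalpexp:::precompute_elements(mesh)
  for (q in 1:n_dof) {
    e1 <- u; e2 <- u
    e1[q] <- e1[q] + h; e2[q] <- e2[q] - h
    K_fd[, q] <- (scalpexp:::global_internal_force(pre, e1, mat) -
                  scalpexp:::global_internal_force(pre, e2, mat)) / (2 * h)
  }
  expect_lt(max(abs(as.matrix(sys$K) - K_fd)) / max(abs(K_fd)), 1e-4)
})

test_that("zero load converges immediately with zero displacement", {
  mesh <- make_single_tet()
  sol <- newton_solve(mesh, fixture_material(), numeric(12))
  expect_equal(sol$state$iterations, 0L)
  expect_equal(sol$state$u, rep(0, 12))
  expect_true(sol$state$converged)
})

test_that("single-element solve matches brute-force energy minimization", {
  mat <- fixture_material()
  mesh <- make_single_tet()
  R <- numeric(12); R[10:12] <- c(0.002, -0.003, 0.01)
  sol <- newton_solve(mesh, mat, R)
  expect_lte(sol$state$residual_norm,
             max(1e-8 * sqrt(sum(R^2)), 1e-10))
  el <- shape_gradients(mesh$nodes)
  energy <- function(p) {
    u <- numeric(12); u[10:12] <- p
    el$ref_volume * strain_energy(green_strain(el, u)$E, mat) -
      sum(R[10:12] * p)
  }
  opt <- stats::optim(c(0, 0, 0), energy, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  expect_lt(max(abs(sol$state$u[10:12] - opt$par)), 1e-6)
})

test_that("Newton residuals decay superlinearly near the solution", {
  mat <- fixture_material()
  mesh <- make_single_tet()
  R <- numeric(12); R[10:12] <- c(0.01, 0.005, 0.03)
  sol <- newton_solve(mesh, mat, R)
  h <- sol$history
  resid <- h$residual[h$residual > 0]
  expect_gte(length(resid), 3)
  r <- tail(resid, 3)
  # superlinear: the contraction factor itself shrinks markedly
  expect_lt(r[3] / r[2], 0.5 * r[2] / r[1])
})

test_that("solver is deterministic: identical inputs, identical output", {
  mat <- fixture_material()
  mesh <- make_unit_cube(2, fixed = "boundary")
  R <- numeric(3 * nrow(mesh$nodes))
  free_node <- setdiff(seq_len(nrow(mesh$nodes)), mesh$fixed_nodes)[1]
  R[3 * free_node] <- 0.01
  s1 <- newton_solve(mesh, mat, R)
  s2 <- newton_solve(mesh, mat, R)
  expect_identical(s1$state$u, s2$state$u)
  expect_identical(s1$history$residual, s2$history$residual)
})

test_that("non-convergence raises a structured error carrying the history", {
  mat <- fixture_material()
  mesh <- make_single_tet()
  # a load far beyond what three iterations can equilibrate on the stiffening
  # material
  R <- numeric(12); R[10:12] <- c(0, 0, 5)
  err <- tryCatch(
    newton_solve(mesh, mat, R, settings = solver_settings(max_iter = 3)),
    error = function(e) e)
  expect_s3_class(err, "scalpexp_no_convergence")
  expect_true(is.data.frame(err$history))
})

test_that("missing constraints are reported as rank deficiency", {
  mesh <- make_unit_cube(1)   # nothing fixed: rigid modes present
  R <- numeric(24); R[3] <- 1e-3
  expect_error(newton_solve(mesh, fixture_material(), R), "rank deficiency")
})

test_that("the 8-step fixture run converges with sensible bookkeeping", {
  fit <- fixture_expansion()
  expect_length(fit$states, 9)
  expect_true(all(vapply(fit$states, function(s) isTRUE(s$converged), TRUE)))
  rep_ <- fit$reports
  expect_equal(rep_$step, 0:8)
  # deltas and cumulative columns satisfy their identities exactly
  expect_equal(rep_$dS_mm2, c(0, diff(rep_$S_mm2)))
  expect_equal(rep_$cum_dS_mm2, cumsum(rep_$dS_mm2))
  expect_equal(rep_$cum_dV_mm3, cumsum(rep_$dV_mm3))
  # the scalp is pushed outward: area grows every step
  expect_true(all(diff(rep_$S_mm2) > 0))
})

test_that("all-zero schedule leaves the mesh untouched", {
  mesh <- make_shell_patch(n_theta = 4, n_phi = 4)
  run <- incremental_expand(mesh, fixture_material(), rep(0, 3))
  rep_ <- build_step_reports(run$states, mesh)
  expect_equal(max(abs(vapply(run$states, function(s) max(abs(s$u)), 0))), 0)
  expect_equal(rep_$dS_mm2, rep(0, 4))
  expect_equal(rep_$dV_mm3, rep(0, 4))
})

test_that("reactions balance the applied pressure loads at every step", {
  fit <- fixture_expansion()
  mesh <- fit$mesh
  pre <- scalpexp:::precompute_elements(mesh)
  fixed_dofs <- scalpexp:::dof_indices(mesh$fixed_nodes)
  for (k in seq_along(fit$loads)) {
    R <- as.numeric(fit$loads[[k]])
    f <- scalpexp:::global_internal_force(pre, fit$states[[k + 1]]$u,
                                          fit$material)
    reactions <- (f - R)[fixed_dofs]
    net_applied <- colSums(matrix(R, ncol = 3, byrow = TRUE))
    net_reaction <- colSums(matrix(reactions, ncol = 3, byrow = TRUE))
    expect_lt(sqrt(sum((net_applied + net_reaction)^2)) /
                sqrt(sum(net_applied^2)), 1e-6)
  }
})

test_that("failure mid-schedule preserves the completed steps", {
  mesh <- make_shell_patch(n_theta = 4, n_phi = 4)
  mat <- fixture_material()
  # steps 1-2 carry no load (converge in 0 iterations); step 3 cannot meet the
  # tolerance within a single permitted iteration at any load sub-increment
  err <- tryCatch(
    incremental_expand(mesh, mat, c(0, 0, 5e4),
                       settings = solver_settings(max_iter = 1)),
    error = function(e) e)
  expect_s3_class(err, "scalpexp_partial_result")
  expect_equal(err$failed_step, 3)
  expect_length(err$states, 3)   # step 0 + two converged steps
})
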