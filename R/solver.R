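#' Solver settings for the incremental Newton solution
#'
#' @param n_steps Number of load increments (default 8).
#' @param rtol Residual tolerance relative to the external load norm
#'   (default 1e-8), with an absolute floor of `abs_floor` N.
#' @param abs_floor Absolute residual floor in N (default 1e-10).
#' @param max_iter Maximum Newton iterations per step (default 30).
#' @param pressure Expander pressure in N/mm^2 (default 0.3, i.e. 30 N/cm^2).
#' @return Object of class `solver_settings`.
#' @export
solver_settings <- function(n_steps = 8, rtol = 1e-8, abs_floor = 1e-10,
                            max_iter = 30, pressure = 0.3) {
  stopifnot(n_steps >= 1, rtol > 0, abs_floor > 0, max_iter >= 1, pressure > 0)
  structure(list(n_steps = as.integer(n_steps), rtol = rtol,
                 abs_floor = abs_floor, max_iter = as.integer(max_iter),
                 pressure = pressure),
            class = "solver_settings")
}

# Precompute per-element shape gradients and global scatter indices once per
# mesh; callers pass the structure around.
precompute_elements <- function(mesh) {
  m <- nrow(mesh$tets)
  elems <- vector("list", m)
  edofs <- matrix(0L, m, 12)
  GN <- array(0, c(m, 3, 4))
  V0 <- numeric(m)
  for (e in seq_len(m)) {
    ids <- mesh$tets[e, ]
    el <- shape_gradients(mesh$nodes[ids, ], node_ids = ids)
    elems[[e]] <- el
    edofs[e, ] <- dof_indices(ids)
    GN[e, , ] <- el$grad_N
    V0[e] <- el$ref_volume
  }
  ii <- matrix(0L, m, 144)
  jj <- matrix(0L, m, 144)
  for (e in seq_len(m)) {
    ii[e, ] <- rep(edofs[e, ], times = 12)
    jj[e, ] <- rep(edofs[e, ], each = 12)
  }
  list(elems = elems, edofs = edofs, GN = GN, V0 = V0, m = m,
       ii = as.vector(t(ii)), jj = as.vector(t(jj)),
       n_dof = 3L * nrow(mesh$nodes),
       free = setdiff(seq_len(3L * nrow(mesh$nodes)),
                      dof_indices(mesh$fixed_nodes)))
}

# Batch evaluation of all element strains, stresses, internal forces and
# (optionally) tangents, vectorized across elements. Mirrors exactly the
# per-element operations of element.R / material.R; the test suite asserts
# agreement between the two paths.
.element_batch <- function(pre, u, mat, want_tangent = TRUE) {
  m <- pre$m
  GN <- pre$GN
  a <- mat$a; b <- mat$b; kap <- mat$kappa

  # displacement gradient H[e, c, i] = du_c/dX_i; F = I + H
  Ue <- array(0, c(m, 3, 4))
  for (k in 1:4) for (c_ in 1:3) {
    Ue[, c_, k] <- u[pre$edofs[, (k - 1) * 3 + c_]]
  }
  H <- array(0, c(m, 3, 3))
  for (c_ in 1:3) for (i in 1:3) {
    acc <- 0
    for (k in 1:4) acc <- acc + Ue[, c_, k] * GN[, i, k]
    H[, c_, i] <- acc
  }
  Fm <- H
  for (c_ in 1:3) Fm[, c_, c_] <- Fm[, c_, c_] + 1

  detF <- Fm[, 1, 1] * (Fm[, 2, 2] * Fm[, 3, 3] - Fm[, 2, 3] * Fm[, 3, 2]) -
          Fm[, 1, 2] * (Fm[, 2, 1] * Fm[, 3, 3] - Fm[, 2, 3] * Fm[, 3, 1]) +
          Fm[, 1, 3] * (Fm[, 2, 1] * Fm[, 3, 2] - Fm[, 2, 2] * Fm[, 3, 1])
  if (any(detF <= 0)) {
    e_bad <- which(detF <= 0)[1]
    stop("invalid state: inverted element (det F <= 0) in element with nodes ",
         paste(pre$elems[[e_bad]]$node_ids, collapse = ","))
  }

  # Green strain tensor components and C = I + 2E
  Ct <- array(0, c(m, 3, 3))
  for (i in 1:3) for (j in i:3) {
    acc <- 0
    for (c_ in 1:3) acc <- acc + Fm[, c_, i] * Fm[, c_, j]
    Ct[, i, j] <- acc
    Ct[, j, i] <- acc
  }
  I1 <- Ct[, 1, 1] + Ct[, 2, 2] + Ct[, 3, 3]
  detC <- detF^2
  J <- detF
  # inverse of symmetric C by adjugate
  Ci <- array(0, c(m, 3, 3))
  Ci[, 1, 1] <- (Ct[, 2, 2] * Ct[, 3, 3] - Ct[, 2, 3]^2) / detC
  Ci[, 2, 2] <- (Ct[, 1, 1] * Ct[, 3, 3] - Ct[, 1, 3]^2) / detC
  Ci[, 3, 3] <- (Ct[, 1, 1] * Ct[, 2, 2] - Ct[, 1, 2]^2) / detC
  Ci[, 1, 2] <- Ci[, 2, 1] <- (Ct[, 1, 3] * Ct[, 2, 3] - Ct[, 1, 2] * Ct[, 3, 3]) / detC
  Ci[, 1, 3] <- Ci[, 3, 1] <- (Ct[, 1, 2] * Ct[, 2, 3] - Ct[, 1, 3] * Ct[, 2, 2]) / detC
  Ci[, 2, 3] <- Ci[, 3, 2] <- (Ct[, 1, 2] * Ct[, 1, 3] - Ct[, 2, 3] * Ct[, 1, 1]) / detC

  expfac <- exp(b / 2 * (I1 - 3))
  s1 <- a * expfac
  s2 <- kap * (J - 1) * J - a
  # stress: Voigt (11,22,33,23,31,12) and tensor components
  Sv <- matrix(0, m, 6)
  for (al in 1:6) {
    i <- .voigt_pairs[al, 1]; j <- .voigt_pairs[al, 2]
    Sv[, al] <- s1 * (i == j) + s2 * Ci[, i, j]
  }

  # B[e, s, (k-1)*3 + c] = F[c,i] dN_k/dX_j + (i != j) F[c,j] dN_k/dX_i
  B <- array(0, c(m, 6, 12))
  for (s in 1:6) {
    i <- .voigt_pairs[s, 1]; j <- .voigt_pairs[s, 2]
    for (k in 1:4) for (c_ in 1:3) {
      v <- Fm[, c_, i] * GN[, j, k]
      if (i != j) v <- v + Fm[, c_, j] * GN[, i, k]
      B[, s, (k - 1) * 3 + c_] <- v
    }
  }

  fe <- matrix(0, m, 12)
  for (p in 1:12) {
    acc <- 0
    for (s in 1:6) acc <- acc + B[, s, p] * Sv[, s]
    fe[, p] <- pre$V0 * acc
  }
  f <- numeric(pre$n_dof)
  for (p in 1:12) {
    accm <- rowsum(fe[, p], pre$edofs[, p])
    at <- as.integer(rownames(accm))
    f[at] <- f[at] + accm[, 1]
  }

  if (!want_tangent) return(list(f = f))

  c1 <- a * b * expfac
  c2 <- kap * (2 * J - 1) * J
  c3 <- -2 * s2
  D <- array(0, c(m, 6, 6))
  for (al in 1:6) {
    i <- .voigt_pairs[al, 1]; j <- .voigt_pairs[al, 2]
    for (be in al:6) {
      k <- .voigt_pairs[be, 1]; l <- .voigt_pairs[be, 2]
      v <- c1 * (i == j) * (k == l) + c2 * Ci[, i, j] * Ci[, k, l] +
        c3 * 0.5 * (Ci[, i, k] * Ci[, j, l] + Ci[, i, l] * Ci[, j, k])
      D[, al, be] <- v
      D[, be, al] <- v
    }
  }
  # T = D B, K1 = B^T T; geometric part K2 = kron(GN^T S GN, I3)
  Tm <- array(0, c(m, 6, 12))
  for (s in 1:6) for (p in 1:12) {
    acc <- 0
    for (r in 1:6) acc <- acc + D[, s, r] * B[, r, p]
    Tm[, s, p] <- acc
  }
  W4 <- array(0, c(m, 4, 4))
  for (k1 in 1:4) for (k2 in k1:4) {
    acc <- 0
    for (i in 1:3) for (j in 1:3) {
      Sij <- if (i == j) Sv[, i] else if ((i == 2 && j == 3) || (i == 3 && j == 2)) Sv[, 4]
             else if ((i == 3 && j == 1) || (i == 1 && j == 3)) Sv[, 5] else Sv[, 6]
      acc <- acc + GN[, i, k1] * Sij * GN[, j, k2]
    }
    W4[, k1, k2] <- acc
    W4[, k2, k1] <- acc
  }
  Kflat <- matrix(0, m, 144)
  for (q in 1:12) for (p in 1:q) {
    acc <- 0
    for (s in 1:6) acc <- acc + B[, s, p] * Tm[, s, q]
    kq <- (q - 1) %/% 3 + 1; cq <- (q - 1) %% 3 + 1
    kp <- (p - 1) %/% 3 + 1; cp <- (p - 1) %% 3 + 1
    if (cq == cp) acc <- acc + W4[, kp, kq]
    v <- pre$V0 * acc
    Kflat[, (q - 1) * 12 + p] <- v
    Kflat[, (p - 1) * 12 + q] <- v
  }
  list(f = f, xx = as.vector(t(Kflat)))
}

global_internal_force <- function(pre, u, mat) {
  .element_batch(pre, u, mat, want_tangent = FALSE)$f
}

#' Assemble the global system at a displacement state
#'
#' Scatters element internal forces and consistent tangents into the global
#' residual \eqn{\varphi = f_{int} - R} and sparse tangent stiffness
#' \eqn{K_T}; fixed degrees of freedom are eliminated symmetrically
#' (`K_free` is `K_T` restricted to the free set).
#'
#' @param mesh A [scalp_mesh()].
#' @param u Global displacement vector (3 per node) or a [deformed_state()].
#' @param mat A [fung_material()].
#' @param R External equivalent nodal load vector (N); default zero.
#' @param pre Optional precomputed element structure (internal reuse).
#' @return List with `K` (full sparse tangent), `K_free`, `f_int`, `phi`,
#'   `free_dofs`.
#' @export
assemble <- function(mesh, u, mat, R = NULL, pre = NULL) {
  if (inherits(u, "deformed_state")) u <- u$u
  if (is.null(pre)) pre <- precompute_elements(mesh)
  if (length(u) != pre$n_dof) stop("displacement dimension mismatch")
  if (is.null(R)) R <- numeric(pre$n_dof)
  batch <- .element_batch(pre, u, mat, want_tangent = TRUE)
  f <- batch$f
  K <- Matrix::sparseMatrix(i = pre$ii, j = pre$jj, x = batch$xx,
                            dims = c(pre$n_dof, pre$n_dof))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  list(K = K, K_free = K[pre$free, pre$free, drop = FALSE],
       f_int = f, phi = f - R, free_dofs = pre$free)
}

#' Newton-Raphson solution of the nonlinear equilibrium equations
#'
#' Solves \eqn{f_{int}(a) - R(a) = 0} on the free degrees of freedom. The
#' first iterate is the tangent predictor at `u_init` (for `u_init = 0` this
#' is exactly the linear-elastic predictor \eqn{K_L a = R}, since the tangent
#' at the stress-free reference state reduces to \eqn{K_L}); subsequent
#' corrections are \eqn{\Delta a = -K_T^{-1} \varphi} with a backtracking
#' halving safeguard when a full step fails to reduce the residual. Fixed
#' degrees of freedom keep their `u_init` values throughout (zero by default;
#' nonzero prescribed displacements are supported).
#'
#' @param mesh A [scalp_mesh()].
#' @param mat A [fung_material()].
#' @param load_builder Function of the current displacement vector returning
#'   the external load vector R (N); a constant numeric vector is also
#'   accepted (dead load).
#' @param u_init Initial displacement vector (default zero); its values on
#'   fixed dofs are held as prescribed displacements.
#' @param settings A [solver_settings()].
#' @param pre Optional precomputed element structure (internal reuse).
#' @return List with `state` (a [deformed_state()]) and `history` (data frame
#'   of per-iteration residual norms and step sizes).
#' @export
newton_solve <- function(mesh, mat, load_builder, u_init = NULL,
                         settings = solver_settings(), pre = NULL,
                         stall_window = NULL, stall_ratio = 0.8) {
  if (is.null(pre)) pre <- precompute_elements(mesh)
  u <- if (is.null(u_init)) numeric(pre$n_dof) else as.numeric(u_init)
  if (length(u) != pre$n_dof) stop("u_init dimension mismatch")
  if (is.numeric(load_builder)) {
    R_const <- load_builder
    load_builder <- function(u) R_const
  }
  free <- pre$free

  res_norm <- function(u, R) {
    f <- global_internal_force(pre, u, mat)
    sqrt(sum((f - R)[free]^2))
  }

  R <- load_builder(u)
  res <- res_norm(u, R)
  tol <- max(settings$rtol * sqrt(sum(R[free]^2)), settings$abs_floor)
  history <- data.frame(iter = 0L, residual = res, step = NA_real_)

  iter <- 0L
  mu <- 0          # Levenberg regularization, 0 = plain Newton
  mu0 <- NA_real_  # scale set from the first assembled tangent
  while (res > tol) {
    if (iter >= settings$max_iter) {
      cond <- structure(
        class = c("scalpexp_no_convergence", "error", "condition"),
        list(message = paste0("Newton did not converge in ",
                              settings$max_iter, " iterations (residual ",
                              format(res, digits = 4), " N, tol ",
                              format(tol, digits = 4), " N)"),
             call = sys.call(-1), history = history))
      stop(cond)
    }
    iter <- iter + 1L
    sys <- assemble(mesh, u, mat, R = R, pre = pre)
    A <- sys$K_free
    Jr <- attr(R, "jacobian")
    if (!is.null(Jr)) A <- A - Jr[free, free, drop = FALSE]
    if (is.na(mu0)) mu0 <- mean(abs(Matrix::diag(A)))^2 * 1e-6
    du <- tryCatch(
      as.numeric(Matrix::solve(A, -sys$phi[free])),
      error = function(e) {
        if (mu == 0) {
          stop("singular tangent stiffness (rank deficiency): check that the ",
               "fixed-node set suppresses all rigid-body motion [",
               conditionMessage(e), "]")
        }
        NULL
      })
    if (!is.null(du) && any(!is.finite(du))) du <- NULL
    if (is.null(du) && mu == 0) {
      stop("singular tangent stiffness (rank deficiency): check that the ",
           "fixed-node set suppresses all rigid-body motion")
    }
    if (mu > 0 && !is.null(du)) {
      # regularized (Levenberg) direction: descent on ||phi||^2 even at an
      # indefinite tangent, used while traversing a pressure limit point
      At <- Matrix::t(A)
      du <- tryCatch(
        as.numeric(Matrix::solve(At %*% A + mu * Matrix::Diagonal(length(free)),
                                 -as.numeric(At %*% sys$phi[free]))),
        error = function(e) du)
    } else if (is.null(du)) {
      At <- Matrix::t(A)
      du <- as.numeric(Matrix::solve(
        At %*% A + max(mu, 1e-8) * Matrix::Diagonal(length(free)),
        -as.numeric(At %*% sys$phi[free])))
    }
    # backtracking: halve until the residual decreases; a state that inverts
    # elements (infinite residual) is never accepted
    step <- 1
    repeat {
      u_try <- u
      u_try[free] <- u[free] + step * du
      R_try <- load_builder(u_try)
      res_try <- tryCatch(res_norm(u_try, R_try), error = function(e) Inf)
      if (!is.finite(res_try)) res_try <- Inf
      if (res_try < res) break
      if (step <= 2^-24) {
        if (is.finite(res_try)) break       # accept a non-reducing tiny step
        # a wildly scaled update that inverts elements at any step length is
        # the signature of an (almost) singular tangent
        if (mu == 0 && nrow(A) <= 5000 &&
            Matrix::rcond(as(as.matrix(A), "denseMatrix")) < 1e-12) {
          stop("singular tangent stiffness (rank deficiency): check that ",
               "the fixed-node set suppresses all rigid-body motion")
        }
        cond <- structure(
          class = c("scalpexp_no_convergence", "error", "condition"),
          list(message = "line search failed: every trial step inverts elements",
               call = sys.call(-1), history = history))
        stop(cond)
      }
      step <- step / 2
    }
    # adapt the regularization: engage when plain Newton's step collapses,
    # relax it as full steps return
    if (step < 2^-6) {
      mu <- if (mu == 0) mu0 else min(mu * 10, 1e8 * mu0)
    } else if (step == 1 && mu > 0) {
      mu <- if (mu <= mu0 * 1e-3) 0 else mu / 30
    }
    u <- u_try; R <- R_try; res <- res_try
    tol <- max(settings$rtol * sqrt(sum(R[free]^2)), settings$abs_floor)
    history <- rbind(history,
                     data.frame(iter = iter, residual = res, step = step))
    # optional stall abort (used by the incremental driver's load ramping)
    if (!is.null(stall_window) && iter >= stall_window) {
      prev <- history$residual[nrow(history) - stall_window]
      if (res > stall_ratio * prev) {
        cond <- structure(
          class = c("scalpexp_no_convergence", "error", "condition"),
          list(message = paste0("Newton stalled: residual reduced only ",
                                format(res / prev, digits = 3), "x over ",
                                stall_window, " iterations"),
               call = sys.call(-1), history = history))
        stop(cond)
      }
    }
  }

  list(state = deformed_state(u, converged = TRUE, residual_norm = res,
                              iterations = iter),
       history = history)
}

# Solve one load step with adaptive sub-incrementation of the load factor.
# Hyperelastic equilibrium is path independent, so ramping the pressure inside
# a step changes nothing about the converged state; it only keeps each Newton
# solve inside its convergence basin when the load increment is violent
# relative to the material stiffness. The returned history concatenates the
# accepted sub-solves.
ramped_solve <- function(mesh, mat, load_builder, u_init, settings, pre) {
  lam <- 0
  dlam <- 1
  u <- u_init
  histories <- list()
  sol <- NULL
  while (lam < 1 - 1e-12) {
    target <- min(1, lam + dlam)
    scaled_load <- function(uv) {
      R <- load_builder(uv)
      Rs <- target * as.numeric(R)
      Jr <- attr(R, "jacobian")
      if (!is.null(Jr)) attr(Rs, "jacobian") <- target * Jr
      Rs
    }
    attempt <- tryCatch(
      newton_solve(mesh, mat, scaled_load, u_init = u, settings = settings,
                   pre = pre, stall_window = 8L),
      scalpexp_no_convergence = function(e) e)
    if (inherits(attempt, "scalpexp_no_convergence")) {
      dlam <- dlam / 2
      if (dlam < 2^-10) stop(attempt)
      next
    }
    sol <- attempt
    u <- sol$state$u
    lam <- target
    histories[[length(histories) + 1]] <- cbind(load_factor = lam,
                                                sol$history)
    if (sol$state$iterations <= 6) dlam <- dlam * 2
  }
  sol$history <- do.call(rbind, histories)
  sol
}

#' Incremental expansion driver
#'
#' Runs the pseudo-time load schedule: at step k the expander is grown to
#' `schedule[k]` mm^3, the contact set is evaluated on the warm-start
#' (previously converged) surface, and equilibrium is solved with the follower
#' pressure load recomputed from the deforming surface at every Newton
#' iteration. Pressure is applied only to contacted facets whose outward
#' normal faces the expander center (the side the expander physically
#' touches). Steps are pure load increments (quasi-static): no inertial terms
#' enter the equations.
#'
#' @param mesh A [scalp_mesh()] with a non-null `center_point` (or pass
#'   `expander`).
#' @param mat A [fung_material()].
#' @param schedule Numeric vector of expander volumes (mm^3), one per step.
#' @param settings A [solver_settings()]; `length(schedule)` overrides
#'   `n_steps`.
#' @param expander Optional [ellipsoid_expander()] template supplying center,
#'   axis ratio and pressure; defaults to the mesh center point with the
#'   standard 1.53:1:1 ratio and `settings$pressure`.
#' @return List with `states` (step 0 = undeformed, then one
#'   [deformed_state()] per step), `histories` (per-step Newton histories),
#'   `loads` (per-step final load vectors) and `expander`. On failure at step
#'   k, an error of class `scalpexp_partial_result` carrying the completed
#'   steps is raised.
#' @export
incremental_expand <- function(mesh, mat, schedule,
                               settings = solver_settings(),
                               expander = NULL) {
  if (is.null(expander)) {
    if (is.null(mesh$center_point)) {
      stop("mesh has no center_point; supply an expander")
    }
    expander <- ellipsoid_expander(mesh$center_point,
                                   pressure = settings$pressure)
  }
  pre <- precompute_elements(mesh)
  n <- nrow(mesh$nodes)
  surface <- mesh$surface_facets

  states <- list(deformed_state(numeric(3 * n), pseudo_time = 0,
                                converged = TRUE, residual_norm = 0,
                                iterations = 0L))
  histories <- list()
  loads <- list()
  u <- numeric(3 * n)

  for (k in seq_along(schedule)) {
    exp_k <- expander
    exp_k$volume <- schedule[k]

    # follower load: contact set, taper weights and facet areas/normals are
    # all recomputed from the current deformed surface at every evaluation,
    # so facets that inflate past the ellipsoid stop being pushed (the load
    # is self-limiting, like the physical expander)
    load_builder <- function(uv) {
      expander_pressure_load(surface, mesh$nodes + disp_matrix(uv, n),
                             exp_k, n_nodes = n)
    }

    sol <- tryCatch(
      ramped_solve(mesh, mat, load_builder, u_init = u,
                   settings = settings, pre = pre),
      error = function(e) {
        cond <- structure(
          class = c("scalpexp_partial_result", "error", "condition"),
          list(message = paste0("expansion failed at step ", k, ": ",
                                conditionMessage(e)),
               call = sys.call(-1), states = states, histories = histories,
               failed_step = k))
        stop(cond)
      })
    u <- sol$state$u
    st <- sol$state
    st$pseudo_time <- k
    states[[k + 1]] <- st
    histories[[k]] <- sol$history
    loads[[k]] <- load_builder(u)
  }

  list(states = states, histories = histories, loads = loads,
       expander = expander, schedule = schedule, pre = pre)
}
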