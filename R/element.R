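#' Shape-function gradients of a linear tetrahedron
#'
#' Computes the constant gradients \eqn{\partial N_k / \partial X} of the four
#' linear barycentric shape functions and the reference volume (coordinate
#' determinant / 6). The columns of `grad_N` sum to zero (partition of unity).
#'
#' @param coords 4x3 matrix of reference node coordinates.
#' @param node_ids Optional global node indices carried along for assembly.
#' @return Object of class `tet4_element` with `grad_N` (3x4), `ref_volume`,
#'   `node_ids`.
#' @export
shape_gradients <- function(coords, node_ids = 1:4) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4, ncol(coords) == 3)
  Jm <- coords[2:4, ] - rep(coords[1, ], each = 3)   # rows: edge vectors
  detJ <- det(Jm)
  scale <- max(abs(coords)) + 1
  if (abs(detJ) <= 1e-14 * scale^3) {
    stop("singular element: coplanar (degenerate) tetrahedron")
  }
  # local derivatives of (N1..N4) wrt barycentric (xi, eta, zeta)
  L <- rbind(c(-1, -1, -1), diag(3))
  grad_N <- solve(Jm, t(L))                          # 3 x 4
  structure(list(node_ids = as.integer(node_ids), grad_N = grad_N,
                 ref_volume = detJ / 6),
            class = "tet4_element")
}

# G (9x12): theta = G u_e with theta = (dU/dX1; dU/dX2; dU/dX3), u_e node-major
.tet4_G <- function(grad_N) {
  G <- matrix(0, 9, 12)
  for (i in 1:3) for (k in 1:4) {
    rows <- 3 * (i - 1) + 1:3
    cols <- 3 * (k - 1) + 1:3
    G[cbind(rows, cols)] <- grad_N[i, k]
  }
  G
}

# B_L (6x12): linear strain-displacement matrix in Voigt (11,22,33,23,31,12)
.tet4_BL <- function(grad_N) {
  B <- matrix(0, 6, 12)
  for (k in 1:4) {
    g <- grad_N[, k]
    c0 <- 3 * (k - 1)
    B[1, c0 + 1] <- g[1]
    B[2, c0 + 2] <- g[2]
    B[3, c0 + 3] <- g[3]
    B[4, c0 + 2] <- g[3]; B[4, c0 + 3] <- g[2]   # gamma_23
    B[5, c0 + 1] <- g[3]; B[5, c0 + 3] <- g[1]   # gamma_31
    B[6, c0 + 1] <- g[2]; B[6, c0 + 2] <- g[1]   # gamma_12
  }
  B
}

# A(theta) (6x9): E_N = A theta / 2, dE_N = A dtheta; h_i = theta[3(i-1)+1:3]
.tet4_A <- function(theta) {
  h1 <- theta[1:3]; h2 <- theta[4:6]; h3 <- theta[7:9]
  z <- c(0, 0, 0)
  rbind(c(h1, z, z),
        c(z, h2, z),
        c(z, z, h3),
        c(z, h3, h2),
        c(h3, z, h1),
        c(h2, h1, z))
}

#' Green strain and kinematic matrices of a displaced tetrahedron
#'
#' Splits the Green strain into its linear and nonlinear parts,
#' \eqn{E = B_L a_e + \frac{1}{2} A \theta} with displacement-gradient vector
#' \eqn{\theta = G a_e}, and returns all kinematic matrices.
#'
#' @param elem A `tet4_element` from [shape_gradients()].
#' @param u_e Element displacement vector, length 12, node-major.
#' @return Object of class `tet4_kinematics` with `theta` (9), `A` (6x9),
#'   `B_L`, `B_N` (6x12), `E` (Voigt-6 Green strain) and `H` (displacement
#'   gradient, 3x3).
#' @export
green_strain <- function(elem, u_e) {
  stopifnot(inherits(elem, "tet4_element"), length(u_e) == 12)
  G <- .tet4_G(elem$grad_N)
  theta <- as.numeric(G %*% u_e)
  A <- .tet4_A(theta)
  B_L <- .tet4_BL(elem$grad_N)
  E <- as.numeric(B_L %*% u_e + 0.5 * A %*% theta)
  H <- matrix(theta, 3, 3)                          # H[j,i] = du_j/dX_i
  structure(list(theta = theta, A = A, B_L = B_L, B_N = A %*% G,
                 G = G, E = E, H = H), class = "tet4_kinematics")
}

#' Strain-variation matrix B = B_L + B_N
#'
#' First-order strain variation: \eqn{\delta E = B\,\delta a_e} at the current
#' displacement, with \eqn{B_N = A(\theta) G}.
#'
#' @inheritParams green_strain
#' @return 6x12 matrix.
#' @export
strain_variation <- function(elem, u_e) {
  kin <- green_strain(elem, u_e)
  kin$B_L + kin$B_N
}

# deformation gradient determinant from theta; errors identify the element
.check_not_inverted <- function(theta, elem) {
  H <- matrix(theta, 3, 3)                          # column i = dU/dX_i
  Jdef <- det(diag(3) + t(H))
  if (Jdef <= 0) {
    stop("invalid state: inverted element (det F <= 0) in element with nodes ",
         paste(elem$node_ids, collapse = ","))
  }
  invisible(Jdef)
}

#' Element internal force vector
#'
#' \eqn{f_{int} = V_0 B^T S} at the element's constant strain (single-point
#' integration is exact for the linear tetrahedron). The components sum to zero
#' per axis (self-equilibrium).
#'
#' @inheritParams green_strain
#' @param mat A [fung_material()].
#' @return Length-12 nodal force vector (N).
#' @export
element_internal_force <- function(elem, u_e, mat) {
  kin <- green_strain(elem, u_e)
  .check_not_inverted(kin$theta, elem)
  S <- second_pk_stress(kin$E, mat)
  as.numeric(elem$ref_volume * t(kin$B_L + kin$B_N) %*% S)
}

#' Element tangent stiffness
#'
#' Consistent tangent \eqn{K_e = V_0 (B^T D_T B + G^T M(S) G)}, where
#' \eqn{M(S)} is the 9x9 expansion of the stress tensor (Kronecker product
#' \eqn{S \otimes I_3}) producing the geometric (stress) stiffness. Exact
#' Jacobian of [element_internal_force()]; symmetric.
#'
#' @inheritParams element_internal_force
#' @return 12x12 symmetric matrix (N/mm).
#' @export
element_tangent <- function(elem, u_e, mat) {
  kin <- green_strain(elem, u_e)
  .check_not_inverted(kin$theta, elem)
  S <- second_pk_stress(kin$E, mat)
  D <- tangent_modulus(kin$E, mat)
  B <- kin$B_L + kin$B_N
  M <- kronecker(voigt_to_stress(S), diag(3))
  K <- elem$ref_volume * (t(B) %*% D %*% B + t(kin$G) %*% M %*% kin$G)
  (K + t(K)) / 2
}
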