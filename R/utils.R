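# Voigt convention used package-wide: component order (11, 22, 33, 23, 31, 12),
# engineering shear for strain (gamma_ij = 2 E_ij, i != j), plain components for
# stress. This matches the strain-displacement matrices of the element module.

.voigt_pairs <- cbind(i = c(1L, 2L, 3L, 2L, 3L, 1L),
                      j = c(1L, 2L, 3L, 3L, 1L, 2L))

#' Convert a symmetric strain tensor to 6-component Voigt form
#'
#' Engineering-shear convention: the last three components are
#' \eqn{2E_{23}, 2E_{31}, 2E_{12}}.
#'
#' @param E 3x3 symmetric matrix.
#' @return Numeric vector of length 6.
#' @export
strain_to_voigt <- function(E) {
  stopifnot(is.matrix(E), all(dim(E) == 3L))
  c(E[1, 1], E[2, 2], E[3, 3], 2 * E[2, 3], 2 * E[3, 1], 2 * E[1, 2])
}

#' Convert a 6-component engineering-Voigt strain to a 3x3 tensor
#'
#' @param e Numeric vector of length 6 in (11, 22, 33, 23, 31, 12) order.
#' @return 3x3 symmetric matrix.
#' @export
voigt_to_strain <- function(e) {
  stopifnot(length(e) == 6L)
  matrix(c(e[1],     e[6] / 2, e[5] / 2,
           e[6] / 2, e[2],     e[4] / 2,
           e[5] / 2, e[4] / 2, e[3]), 3, 3)
}

# Stress has no engineering factor: plain (11,22,33,23,31,12) components.
stress_to_voigt <- function(S) {
  c(S[1, 1], S[2, 2], S[3, 3], S[2, 3], S[3, 1], S[1, 2])
}

voigt_to_stress <- function(s) {
  matrix(c(s[1], s[6], s[5],
           s[6], s[2], s[4],
           s[5], s[4], s[3]), 3, 3)
}

# round-half-up, matching how the planning ratios are reported clinically
# (base::round rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# displacement vector <-> n x 3 matrix (node-major layout: u1x u1y u1z u2x ...)
disp_matrix <- function(u, n_nodes) {
  matrix(u, nrow = n_nodes, ncol = 3, byrow = TRUE)
}

dof_indices <- function(nodes) {
  as.vector(t(cbind(3 * nodes - 2, 3 * nodes - 1, 3 * nodes)))
}
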