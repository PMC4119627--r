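#' Fung-type exponential hyperelastic material
#'
#' Strain-energy density (N mm / mm^3):
#' \deqn{W = \frac{a}{b}\left(e^{(b/2)(I_1 - 3)} - 1\right) - a \ln J +
#'   \frac{\kappa}{2}(J - 1)^2,}
#' with \eqn{I_1 = \lambda_1^2 + \lambda_2^2 + \lambda_3^2} the first invariant
#' of \eqn{C = I + 2E} and \eqn{J = \sqrt{I_3} = \det F}. The exponential term
#' is the strain-stiffening response characteristic of skin; the \eqn{-a\ln J}
#' term makes the undeformed state stress-free, and the \eqn{\kappa}-penalty
#' enforces near-incompressibility weakly (exact incompressibility would
#' require a mixed formulation). For \eqn{b = 0} the analytic limit
#' \eqn{(a/2)(I_1-3)} (neo-Hookean) is used.
#'
#' Defaults are documented, configurable conventions of this package --
#' representative soft-tissue values, not measured scalp constants.
#'
#' @param a Shear-modulus-like stiffness parameter, N/mm^2 (> 0).
#' @param b Dimensionless exponential stiffening rate (>= 0).
#' @param kappa Volumetric penalty modulus, N/mm^2 (>= 0); default `100 * a`.
#' @return Object of class `fung_material`.
#' @export
fung_material <- function(a = 0.1, b = 10, kappa = 100 * a) {
  if (!(a > 0)) stop("a must be > 0")
  if (b < 0) stop("b must be >= 0")
  if (kappa < 0) stop("kappa must be >= 0")
  structure(list(a = a, b = b, kappa = kappa), class = "fung_material")
}

#' @export
print.fung_material <- function(x, ...) {
  cat("Fung exponential hyperelastic material\n")
  cat("  a     =", x$a, "N/mm^2\n")
  cat("  b     =", x$b, "\n")
  cat("  kappa =", x$kappa, "N/mm^2 (volumetric penalty)\n")
  invisible(x)
}

#' Invariants and principal stretches of a Green-strain state
#'
#' Computes \eqn{C = I + 2E} and returns its invariants
#' \eqn{I_1 = \mathrm{tr}\,C}, \eqn{I_2}, \eqn{I_3 = \det C} and the principal
#' stretches \eqn{\lambda_i = \sqrt{\mathrm{eig}(C)}}, sorted descending. At
#' \eqn{E = 0} these are (3, 3, 1) and (1, 1, 1).
#'
#' @param E Green strain: 3x3 symmetric matrix or length-6 engineering-Voigt
#'   vector.
#' @return Object of class `strain_state` with fields `E` (Voigt), `I1`, `I2`,
#'   `I3`, `J`, `stretches`.
#' @export
strain_invariants <- function(E) {
  Et <- if (is.matrix(E)) E else voigt_to_strain(E)
  if (max(abs(Et - t(Et))) > 1e-12 * (1 + max(abs(Et)))) {
    stop("E must be symmetric")
  }
  C <- diag(3) + 2 * Et
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("invalid state: C = I + 2E is not positive definite (inverted state)")
  }
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  I3 <- prod(ev)
  structure(list(E = strain_to_voigt(Et), I1 = I1, I2 = I2, I3 = I3,
                 J = sqrt(I3), stretches = sqrt(sort(ev, decreasing = TRUE))),
            class = "strain_state")
}

#' Strain-energy density of the Fung material
#'
#' @param state A `strain_state` from [strain_invariants()], or a Green strain
#'   accepted by it.
#' @param mat A [fung_material()].
#' @return Energy density in N mm / mm^3 (= MPa).
#' @export
strain_energy <- function(state, mat) {
  if (!inherits(state, "strain_state")) state <- strain_invariants(state)
  a <- mat$a; b <- mat$b; kappa <- mat$kappa
  iso <- if (b > 0) (a / b) * (exp(b / 2 * (state$I1 - 3)) - 1)
         else (a / 2) * (state$I1 - 3)
  iso - a * log(state$J) + kappa / 2 * (state$J - 1)^2
}

# stress and tangent share these coefficients; C-inverse based closed forms
.fung_cinv_terms <- function(E, mat) {
  Et <- if (is.matrix(E)) E else voigt_to_strain(E)
  C <- diag(3) + 2 * Et
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("invalid state: C = I + 2E is not positive definite (inverted state)")
  }
  J <- sqrt(prod(ev))
  I1 <- sum(diag(C))
  Cinv <- chol2inv(chol(C))
  list(C = C, Cinv = Cinv, J = J, I1 = I1,
       s1 = mat$a * exp(mat$b / 2 * (I1 - 3)),          # isochoric coefficient
       s2 = mat$kappa * (J - 1) * J - mat$a)            # C^-1 coefficient
}

#' Second Piola-Kirchhoff stress of the Fung material
#'
#' Exact analytic derivative \eqn{S = \partial W / \partial E}:
#' \deqn{S = a e^{(b/2)(I_1-3)} I + \left[\kappa (J-1) J - a\right] C^{-1}.}
#' Vanishes identically at \eqn{E = 0}.
#'
#' @inheritParams strain_energy
#' @param E Green strain (3x3 matrix or Voigt-6 vector).
#' @return Length-6 Voigt stress (N/mm^2), order (11, 22, 33, 23, 31, 12).
#' @export
second_pk_stress <- function(E, mat) {
  tr <- .fung_cinv_terms(E, mat)
  stress_to_voigt(tr$s1 * diag(3) + tr$s2 * tr$Cinv)
}

#' Material tangent modulus of the Fung material
#'
#' Analytic second derivative \eqn{D_T = \partial^2 W / \partial E \partial E}
#' in 6x6 Voigt form, consistent with the engineering-shear strain convention
#' used by [second_pk_stress()]. Symmetric at every admissible state.
#'
#' @inheritParams second_pk_stress
#' @return 6x6 symmetric matrix (N/mm^2).
#' @export
tangent_modulus <- function(E, mat) {
  tr <- .fung_cinv_terms(E, mat)
  Ci <- tr$Cinv
  c1 <- mat$a * mat$b * exp(mat$b / 2 * (tr$I1 - 3))    # d s1 / dI1 * 2
  c2 <- mat$kappa * (2 * tr$J - 1) * tr$J               # penalty J-term
  c3 <- -2 * tr$s2                                      # from d(C^-1)/dE
  D <- matrix(0, 6, 6)
  for (al in 1:6) {
    i <- .voigt_pairs[al, 1]; j <- .voigt_pairs[al, 2]
    for (be in al:6) {
      k <- .voigt_pairs[be, 1]; l <- .voigt_pairs[be, 2]
      val <- c1 * (i == j) * (k == l) +
        c2 * Ci[i, j] * Ci[k, l] +
        c3 * 0.5 * (Ci[i, k] * Ci[j, l] + Ci[i, l] * Ci[j, k])
      D[al, be] <- val
      D[be, al] <- val
    }
  }
  D
}
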