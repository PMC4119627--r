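# Shared fixtures. The expansion fixture run is expensive, so it is computed
# once per test session and memoized; several test files (solver, postprocess,
# acceptance) interrogate the same run.

fixture_material <- function() fung_material(a = 0.1, b = 10, kappa = 10)

.fixture_cache <- new.env(parent = emptyenv())

# 8-step expansion of the default scalp-like cap (80 mm mid-radius, 3.4 mm
# thick, 45 degree half-width, 1536 tets), expander grown linearly to 200 mL.
fixture_expansion <- function() {
  if (is.null(.fixture_cache$fit)) {
    .fixture_cache$fit <- expand_scalp(make_shell_patch(), fixture_material())
  }
  .fixture_cache$fit
}

# same run with halved load increments (16 steps to the same target volume)
fixture_expansion_halved <- function() {
  if (is.null(.fixture_cache$fit16)) {
    .fixture_cache$fit16 <- expand_scalp(
      make_shell_patch(), fixture_material(),
      settings = solver_settings(n_steps = 16))
  }
  .fixture_cache$fit16
}

# random symmetric Green strain with positive definite C = I + 2E
random_green_strain <- function(sd = 0.05) {
  M <- matrix(stats::rnorm(9, sd = sd), 3, 3)
  (M + t(M)) / 2
}

# central finite difference of a scalar function of a Voigt-6 strain,
# perturbing tensor components so that the engineering Voigt step is h
fd_stress_of_energy <- function(E, mat, h = 1e-6) {
  vapply(1:6, function(al) {
    i <- scalpexp:::.voigt_pairs[al, 1]; j <- scalpexp:::.voigt_pairs[al, 2]
    d <- h / if (i == j) 1 else 2
    Ep <- E; Em <- E
    Ep[i, j] <- Ep[i, j] + d; Ep[j, i] <- Ep[i, j]
    Em[i, j] <- Em[i, j] - d; Em[j, i] <- Em[i, j]
    (strain_energy(Ep, mat) - strain_energy(Em, mat)) / (2 * h)
  }, 0)
}

fd_tangent_of_stress <- function(E, mat, h = 1e-6) {
  D <- matrix(0, 6, 6)
  for (be in 1:6) {
    i <- scalpexp:::.voigt_pairs[be, 1]; j <- scalpexp:::.voigt_pairs[be, 2]
    d <- h / if (i == j) 1 else 2
    Ep <- E; Em <- E
    Ep[i, j] <- Ep[i, j] + d; Ep[j, i] <- Ep[i, j]
    Em[i, j] <- Em[i, j] - d; Em[j, i] <- Em[i, j]
    D[, be] <- (second_pk_stress(Ep, mat) - second_pk_stress(Em, mat)) / (2 * h)
  }
  D
}

# rotation matrix about a random axis
random_rotation <- function(angle = NULL) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- if (is.null(angle)) stats::runif(1, 0, 2 * pi) else angle
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
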