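#' Simulate scalp soft-tissue expansion
#'
#' High-level driver: grows the virtual ellipsoid expander through the volume
#' schedule, solving nonlinear equilibrium at each step, and collects the
#' per-step surface-area / volume reports and Newton histories in a single
#' object.
#'
#' @param mesh A [scalp_mesh()] (e.g. [make_shell_patch()] or [read_mesh()]).
#' @param material A [fung_material()].
#' @param schedule Expander volumes per step (mm^3); default linear growth to
#'   `target_volume` over `settings$n_steps`.
#' @param target_volume Final expander volume, mm^3 (used when `schedule` is
#'   NULL; default 2e5 = 200 mL).
#' @param settings A [solver_settings()].
#' @param expander Optional [ellipsoid_expander()] template (center, axis
#'   ratio, pressure); defaults to the mesh center point.
#' @return Object of class `scalp_expansion`: list with `states`, `reports`
#'   (the step table), `histories`, `loads`, `mesh`, `material`, `expander`,
#'   `schedule`.
#' @examples
#' mesh <- make_shell_patch(n_theta = 6, n_phi = 6)
#' fit <- expand_scalp(mesh, target_volume = 5e4,
#'                     settings = solver_settings(n_steps = 4))
#' summary(fit)
#' @export
expand_scalp <- function(mesh, material = fung_material(), schedule = NULL,
                         target_volume = 2e5, settings = solver_settings(),
                         expander = NULL) {
  if (is.null(schedule)) {
    schedule <- seq_len(settings$n_steps) / settings$n_steps * target_volume
  }
  run <- incremental_expand(mesh, material, schedule, settings = settings,
                            expander = expander)
  structure(list(states = run$states,
                 reports = build_step_reports(run$states, mesh,
                                              center = run$expander$center),
                 histories = run$histories,
                 loads = run$loads,
                 mesh = mesh, material = material,
                 expander = run$expander, schedule = schedule,
                 settings = settings),
            class = "scalp_expansion")
}

#' @export
print.scalp_expansion <- function(x, ...) {
  k <- length(x$states) - 1
  rep_ <- x$reports
  cat("Scalp expansion simulation:", k, "steps,",
      nrow(x$mesh$tets), "tetrahedra\n")
  cat("  area:  ", sprintf("%.2f -> %.2f mm^2 (gain %.2f)", rep_$S_mm2[1],
                           rep_$S_mm2[k + 1], rep_$cum_dS_mm2[k + 1]), "\n")
  cat("  volume:", sprintf("%.2f -> %.2f mm^3 (gain %.2f)", rep_$V_mm3[1],
                           rep_$V_mm3[k + 1], rep_$cum_dV_mm3[k + 1]), "\n")
  invisible(x)
}

#' @export
summary.scalp_expansion <- function(object, ...) {
  iters <- vapply(object$histories, function(h) max(h$iter), 0)
  res <- vapply(object$states[-1], function(s) s$residual_norm, 0)
  out <- cbind(object$reports,
               expander_mm3 = c(0, object$schedule),
               newton_iters = c(NA, iters),
               residual_N = c(NA, res))
  class(out) <- c("summary.scalp_expansion", "data.frame")
  out
}

#' @export
print.summary.scalp_expansion <- function(x, ...) {
  cat("Per-step expansion report\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
as.data.frame.scalp_expansion <- function(x, ...) x$reports

#' Final residual norms of each converged load step
#' @param object A `scalp_expansion`.
#' @param ... Unused.
#' @return Numeric vector of residual norms (N), one per step.
#' @export
residuals.scalp_expansion <- function(object, ...) {
  vapply(object$states[-1], function(s) s$residual_norm, 0)
}

#' Plot expansion curves
#'
#' Base-graphics panels of surface area and volume versus load step, plus the
#' Newton residual decay of each step on a log scale.
#'
#' @param x A `scalp_expansion`.
#' @param ... Passed to `plot`.
#' @export
plot.scalp_expansion <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  r <- x$reports
  graphics::plot(r$step, r$S_mm2, type = "b", xlab = "step",
                 ylab = "S (mm^2)", main = "surface area", ...)
  graphics::plot(r$step, r$V_mm3, type = "b", xlab = "step",
                 ylab = "V (mm^3)", main = "volume", ...)
  graphics::plot(NULL, xlim = c(0, max(vapply(x$histories, nrow, 0L))),
       ylim = range(unlist(lapply(x$histories, function(h)
         pmax(h$residual, 1e-16)))),
       log = "y", xlab = "Newton iteration", ylab = "residual (N)",
       main = "convergence")
  for (h in x$histories) {
    graphics::lines(h$iter, pmax(h$residual, 1e-16), col = "grey40")
  }
  invisible(x)
}

#' Write the per-step report as CSV
#'
#' Column layout: `step,S_mm2,dS_mm2,cum_dS_mm2,V_mm3,dV_mm3,cum_dV_mm3`.
#'
#' @param x A `scalp_expansion` or a step-table data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_step_report <- function(x, path) {
  df <- if (inherits(x, "scalp_expansion")) x$reports else x
  utils::write.csv(df[, c("step", "S_mm2", "dS_mm2", "cum_dS_mm2",
                          "V_mm3", "dV_mm3", "cum_dV_mm3")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
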