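#' Over-expansion factor required to compensate flap shrinkage
#'
#' Expanded skin contracts after the expander is removed; with shrinkage
#' fraction s the new skin must exceed the defect by 1/(1 - s). The factor is
#' reported rounded half-up to two decimals (30% shrinkage gives 1.43).
#'
#' @param shrinkage Fraction in \[0, 1).
#' @return Required area factor, 2 decimals.
#' @export
required_factor <- function(shrinkage) {
  if (shrinkage < 0 || shrinkage >= 1) stop("shrinkage must be in [0, 1)")
  round_half_up(1 / (1 - shrinkage), 2)
}

#' Judge whether the simulated area gain covers the defect
#'
#' @param area_gain Simulated cumulative area gain, mm^2 (>= 0).
#' @param defect_area Defect area to cover, mm^2 (> 0).
#' @param shrinkage Expected flap shrinkage fraction (default 0.30, the usual
#'   clinical figure).
#' @return List with `defect_area`, `shrinkage`, `required_factor`,
#'   `achieved_factor` (both 2 decimals) and logical `sufficient`.
#' @export
sufficiency <- function(area_gain, defect_area, shrinkage = 0.30) {
  if (defect_area <= 0) stop("defect_area must be > 0")
  if (area_gain < 0) stop("area_gain must be >= 0")
  req <- required_factor(shrinkage)
  ach <- round_half_up(area_gain / defect_area, 2)
  list(defect_area = defect_area, shrinkage = shrinkage,
       required_factor = req, achieved_factor = ach,
       sufficient = ach >= req)
}

#' Default expander size catalog (mL)
#' @return Numeric vector, 50 mL increments from 50 to 800.
#' @export
default_catalog <- function() seq(50, 800, by = 50)

#' Recommend the smallest sufficient expander size
#'
#' Smallest catalog size at least as large as the required volume (the
#' simulated volume gain, which matches the implanted expander volume).
#'
#' @param required_volume Required volume in mL (>= 0).
#' @param catalog Ascending vector of available sizes in mL.
#' @return Recommended size, mL.
#' @export
recommend_expander <- function(required_volume, catalog = default_catalog()) {
  if (required_volume < 0) stop("required_volume must be >= 0")
  if (!length(catalog) || is.unsorted(catalog)) {
    stop("catalog must be a non-empty ascending vector")
  }
  ok <- catalog >= required_volume
  if (!any(ok)) {
    stop("required volume ", format(required_volume),
         " mL exceeds catalog maximum ", max(catalog), " mL")
  }
  catalog[which(ok)[1]]
}

#' Full expansion plan from simulated gains
#'
#' Combines [sufficiency()] and [recommend_expander()]: the required expander
#' volume is the final cumulative volume gain converted mm^3 to mL.
#'
#' @param defect_area Defect area, mm^2.
#' @param area_gain Final cumulative area gain, mm^2.
#' @param volume_gain_mm3 Final cumulative volume gain, mm^3.
#' @param shrinkage Flap shrinkage fraction (default 0.30).
#' @param catalog Expander size catalog, mL.
#' @return Object of class `expansion_plan`.
#' @export
plan_expansion <- function(defect_area, area_gain, volume_gain_mm3,
                           shrinkage = 0.30, catalog = default_catalog()) {
  suff <- sufficiency(area_gain, defect_area, shrinkage)
  required_volume <- volume_gain_mm3 / 1000
  suff$required_volume <- required_volume
  suff$recommended_size <- recommend_expander(required_volume, catalog)
  structure(suff, class = "expansion_plan")
}

#' @export
print.expansion_plan <- function(x, ...) {
  cat("Scalp expansion plan\n")
  cat("  defect area:          ", x$defect_area, "mm^2\n")
  cat("  shrinkage allowance:  ", x$shrinkage * 100, "%  -> required factor",
      sprintf("%.2f", x$required_factor), "\n")
  cat("  achieved area factor: ", sprintf("%.2f", x$achieved_factor),
      if (x$sufficient) " (sufficient)" else " (INSUFFICIENT)", "\n")
  cat("  required volume:      ", format(x$required_volume), "mL\n")
  cat("  recommended expander: ", x$recommended_size, "mL\n")
  invisible(x)
}
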