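#' Read a simulation configuration file
#'
#' YAML configuration with blocks `material` (`a`, `b`, `kappa`; N/mm^2),
#' `expander` (`center`, `axis_ratio`, `pressure`, `pressure_unit`,
#' `schedule` or `target_volume`), `solver` (`n_steps`, `rtol`, `max_iter`)
#' and `planning` (`defect_area`, `shrinkage`, `catalog`). All pressures are
#' converted to the internal unit N/mm^2 (= MPa) at this boundary;
#' `pressure_unit` may be `"N/cm2"` (the conventional clinical unit, default),
#' `"N/mm2"`, `"MPa"` or `"kPa"`. Missing entries fall back to package
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return List with elements `material` ([fung_material()]), `expander`
#'   (list: center, axis_ratio, pressure in N/mm^2), `schedule` (volumes,
#'   mm^3), `solver` ([solver_settings()]), `planning` (list).
#' @export
read_expansion_config <- function(path) {
  cfg <- yaml::read_yaml(path)

  m <- cfg$material
  a <- if (!is.null(m$a)) m$a else 0.1
  mat <- fung_material(
    a = a,
    b = if (!is.null(m$b)) m$b else 10,
    kappa = if (!is.null(m$kappa)) m$kappa else 100 * a)

  e <- cfg$expander
  pressure <- convert_pressure(
    if (!is.null(e$pressure)) e$pressure else 30,
    if (!is.null(e$pressure_unit)) e$pressure_unit else "N/cm2")

  s <- cfg$solver
  settings <- solver_settings(
    n_steps = if (!is.null(s$n_steps)) s$n_steps else 8,
    rtol = if (!is.null(s$rtol)) s$rtol else 1e-8,
    max_iter = if (!is.null(s$max_iter)) s$max_iter else 30,
    pressure = pressure)

  schedule <- if (!is.null(e$schedule)) {
    as.numeric(e$schedule)
  } else {
    target <- if (!is.null(e$target_volume)) e$target_volume else 2e5
    seq_len(settings$n_steps) / settings$n_steps * target
  }

  p <- cfg$planning
  planning <- list(
    defect_area = p$defect_area,
    shrinkage = if (!is.null(p$shrinkage)) p$shrinkage else 0.30,
    catalog = if (!is.null(p$catalog)) as.numeric(p$catalog)
              else default_catalog())

  list(material = mat,
       expander = list(center = if (!is.null(e$center)) as.numeric(e$center)
                                else NULL,
                       axis_ratio = if (!is.null(e$axis_ratio))
                                      as.numeric(e$axis_ratio)
                                    else c(1.53, 1, 1),
                       pressure = pressure),
       schedule = schedule, solver = settings, planning = planning)
}

#' Convert a pressure value to N/mm^2
#'
#' @param value Numeric pressure.
#' @param unit One of "N/cm2", "N/mm2", "MPa", "kPa".
#' @return Pressure in N/mm^2.
#' @export
convert_pressure <- function(value, unit = "N/cm2") {
  switch(tolower(gsub("[^a-z0-9/]", "", tolower(unit))),
         "n/cm2" = value / 100,
         "n/mm2" = value,
         "mpa" = value,
         "kpa" = value / 1000,
         stop("unknown pressure unit: ", unit))
}
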