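#' Exposure configuration
#'
#' Chamber and geometry constants entering every dose: the total aerosol
#' volume passed over one insert during the exposure, the insert membrane
#' area, and the deposition efficiency.  Defaults are the 1 h exposure
#' values for a 6.5 mm membrane insert at 36% efficiency.
#'
#' @param volume_cm3 Aerosol volume per insert, cm^3 (default 1500 for 1 h).
#' @param insert_area_cm2 Insert membrane area `SA_insert`, cm^2
#'   (default 0.33, a 6.5 mm diameter membrane).
#' @param efficiency Deposition efficiency `E_SEM`, fraction in (0, 1]
#'   (default 0.36).
#' @param duration_h Exposure duration, h (default 1).
#' @return An object of class `"exposure_config"`.
#' @export
exposure_config <- function(volume_cm3 = 1500, insert_area_cm2 = 0.33,
                            efficiency = 0.36, duration_h = 1) {
  vals <- c(volume_cm3, insert_area_cm2, efficiency, duration_h)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("all exposure parameters must be positive")
  if (efficiency > 1)
    stop_invalid("efficiency must be a fraction in (0, 1]")
  structure(list(volume_cm3 = volume_cm3,
                 insert_area_cm2 = insert_area_cm2,
                 efficiency = efficiency,
                 duration_h = duration_h),
            class = "exposure_config")
}

#' @export
print.exposure_config <- function(x, ...) {
  cat(sprintf(
    "Exposure config: v = %g cm^3, SA_insert = %g cm^2, E = %g, %g h\n",
    x$volume_cm3, x$insert_area_cm2, x$efficiency, x$duration_h))
  invisible(x)
}

#' Insert membrane area from its diameter
#'
#' @param membrane_diameter_mm Membrane diameter, mm (6.5 mm gives 0.33 cm^2).
#' @return Area in cm^2.
#' @export
insert_area <- function(membrane_diameter_mm) {
  if (!is.finite(membrane_diameter_mm) || membrane_diameter_mm <= 0)
    stop_invalid("diameter must be positive")
  pi * (membrane_diameter_mm / 20)^2
}

#' Delivered number dose
#'
#' `N_dose = c_N * v * E_SEM / SA_insert`, the deposited particle number per
#' cm^2 of (confluent) cell layer.
#'
#' @param c_N Average total number concentration entering the chamber,
#'   #/cm^3.
#' @param cfg An [exposure_config].
#' @return `N_dose` in #/cm^2.
#' @export
number_dose <- function(c_N, cfg = exposure_config()) {
  stopifnot(inherits(cfg, "exposure_config"))
  if (!is.finite(c_N) || c_N < 0) stop_invalid("c_N must be >= 0")
  c_N * cfg$volume_cm3 * cfg$efficiency / cfg$insert_area_cm2
}

#' Delivered mass dose
#'
#' `m_dose = c_m * v * E_SEM / SA_insert` with the exact unit conversion
#' 1 mg/m^3 = 1e-3 ug/cm^3.
#'
#' @param c_m_mg_m3 Total mass concentration, mg/m^3.
#' @param cfg An [exposure_config].
#' @return `m_dose` in ug/cm^2.
#' @export
mass_dose <- function(c_m_mg_m3, cfg = exposure_config()) {
  stopifnot(inherits(cfg, "exposure_config"))
  if (!is.finite(c_m_mg_m3) || c_m_mg_m3 < 0) stop_invalid("c_m must be >= 0")
  c_m_mg_m3 * MG_M3_TO_UG_CM3 * cfg$volume_cm3 * cfg$efficiency /
    cfg$insert_area_cm2
}

#' Delivered surface-area dose
#'
#' `SA_dose = c_SA * v * E_SEM / SA_insert`.
#'
#' @param c_SA_cm2_cm3 Total surface-area concentration, cm^2/cm^3.
#' @param cfg An [exposure_config].
#' @return `SA_dose` in cm^2 of particle surface per cm^2 of cell layer.
#' @export
surface_area_dose <- function(c_SA_cm2_cm3, cfg = exposure_config()) {
  stopifnot(inherits(cfg, "exposure_config"))
  if (!is.finite(c_SA_cm2_cm3) || c_SA_cm2_cm3 < 0)
    stop_invalid("c_SA must be >= 0")
  c_SA_cm2_cm3 * cfg$volume_cm3 * cfg$efficiency / cfg$insert_area_cm2
}

#' Exposure record
#'
#' One exposure level: its measured number size distribution plus whatever
#' mass pathway it supports (aggregate with a mass-mobility fit, aggregate
#' with an online TEOM mass concentration, or sintered spheres with a bulk
#' density).
#'
#' @param label Exposure index, e.g. `"Ag_2"`.
#' @param distribution An [nsd] object.
#' @param morphology `"aggregate"` or `"sintered"`.
#' @param material Material label.
#' @param c_m_teom_mg_m3 Optional TEOM mass concentration, mg/m^3.
#' @param bulk_density_g_cm3 Bulk density, g/cm^3; required for sintered
#'   records.
#' @param efficiency Optional record-specific deposition efficiency
#'   (fraction) overriding the configuration value, e.g. after a charger
#'   fault correction.
#' @return An object of class `"exposure_record"`.
#' @export
exposure_record <- function(label, distribution,
                            morphology = c("aggregate", "sintered"),
                            material = "", c_m_teom_mg_m3 = NULL,
                            bulk_density_g_cm3 = NULL, efficiency = NULL) {
  morphology <- match.arg(morphology)
  stopifnot(inherits(distribution, "nsd"))
  if (morphology == "sintered" && is.null(bulk_density_g_cm3))
    stop_invalid("sintered record '", label, "' requires a bulk density")
  if (!is.null(c_m_teom_mg_m3) &&
      (!is.finite(c_m_teom_mg_m3) || c_m_teom_mg_m3 < 0))
    stop_invalid("TEOM mass concentration must be >= 0")
  structure(list(label = label, distribution = distribution,
                 morphology = morphology, material = material,
                 c_m_teom_mg_m3 = c_m_teom_mg_m3,
                 bulk_density_g_cm3 = bulk_density_g_cm3,
                 efficiency = efficiency),
            class = "exposure_record")
}

#' Compute the delivered doses for one exposure
#'
#' Dispatches the mass/surface-area pathway by morphology and available
#' inputs:
#' \describe{
#'   \item{sintered + bulk density}{sphere mass `(pi/6) rho d^3` integrated
#'     over the number distribution; surface area from the geometric
#'     `pi d^2` (pathway `"sphere"`);}
#'   \item{aggregate + mass-mobility fit}{mass from
#'     `dN/dlogDp * k d^D_mm`; surface area additionally needs `ssa_m2_g`
#'     (pathway `"massmob"`);}
#'   \item{aggregate + TEOM}{mass from the online TEOM concentration;
#'     the surface-area dose is not derivable and reported `NA`
#'     (pathway `"teom"`).}
#' }
#' An aggregate record with neither fit nor TEOM value raises an error
#' naming the missing input.
#'
#' @param record An [exposure_record].
#' @param cfg An [exposure_config]; a record-level `efficiency` overrides
#'   the configured one.
#' @param fit Optional `"massmob"` fit for the aggregate pathway.
#' @param ssa_m2_g Optional specific surface area, m^2/g, for the aggregate
#'   surface-area pathway.
#' @return An object of class `"dose_result"` with the exposure summary
#'   (`c_N`, `CMD`, `GSTD`, `c_m`, `c_SA`) and doses `N_dose` (#/cm^2),
#'   `m_dose` (ug/cm^2), `SA_dose` (cm^2/cm^2, possibly `NA`), plus the
#'   pathway used.
#' @export
compute_dose <- function(record, cfg = exposure_config(), fit = NULL,
                         ssa_m2_g = NULL) {
  stopifnot(inherits(record, "exposure_record"),
            inherits(cfg, "exposure_config"))
  if (!is.null(record$efficiency)) {
    if (record$efficiency <= 0 || record$efficiency > 1)
      stop_invalid("record efficiency must be in (0, 1]")
    cfg$efficiency <- record$efficiency
  }
  dist <- record$distribution
  c_N <- total_concentration(dist)

  if (c_N <= 0) {
    res <- list(label = record$label, pathway = "empty",
                c_N = 0, CMD = NA_real_, GSTD = NA_real_,
                c_m = 0, c_SA = 0, N_dose = 0, m_dose = 0, SA_dose = 0,
                config = cfg)
    return(structure(res, class = "dose_result"))
  }

  smry <- summary(dist)

  if (record$morphology == "sintered") {
    pathway <- "sphere"
    sfit <- sphere_massmob(record$bulk_density_g_cm3)
    c_m <- total_mass_concentration(number_to_mass_distribution(dist, sfit))
    c_SA <- total_surface_area_concentration(
      sphere_surface_area_distribution(dist))
  } else if (!is.null(fit)) {
    pathway <- "massmob"
    c_m <- total_mass_concentration(number_to_mass_distribution(dist, fit))
    c_SA <- if (!is.null(ssa_m2_g))
      total_surface_area_concentration(
        surface_area_distribution(dist, fit, ssa_m2_g)) else NA_real_
  } else if (!is.null(record$c_m_teom_mg_m3)) {
    pathway <- "teom"
    c_m <- record$c_m_teom_mg_m3
    c_SA <- NA_real_
  } else {
    stop_invalid("no mass pathway for exposure '", record$label,
                 "': supply a mass-mobility fit, a TEOM mass concentration, ",
                 "or mark the record sintered with a bulk density")
  }

  structure(list(label = record$label, pathway = pathway,
                 c_N = c_N, CMD = smry$CMD, GSTD = smry$GSTD,
                 c_m = c_m, c_SA = c_SA,
                 N_dose = number_dose(c_N, cfg),
                 m_dose = mass_dose(c_m, cfg),
                 SA_dose = if (is.na(c_SA)) NA_real_
                           else surface_area_dose(c_SA, cfg),
                 config = cfg),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("Dose for %s (pathway: %s)\n", x$label, x$pathway))
  cat(sprintf("  c_N = %.4g #/cm^3, CMD = %.1f nm, GSTD = %.2f\n",
              x$c_N, x$CMD, x$GSTD))
  cat(sprintf("  c_m = %.3g mg/m^3%s\n", x$c_m,
              if (is.na(x$c_SA)) "" else
                sprintf(", c_SA = %.3g cm^2/cm^3", x$c_SA)))
  cat(sprintf("  N_dose = %.3g #/cm^2, m_dose = %.2f ug/cm^2, SA_dose = %s\n",
              x$N_dose, x$m_dose,
              if (is.na(x$SA_dose)) "-" else sprintf("%.2f cm^2/cm^2",
                                                     x$SA_dose)))
  invisible(x)
}

#' @export
as.data.frame.dose_result <- function(x, ...) {
  data.frame(label = x$label, c_N = x$c_N, CMD = x$CMD, GSTD = x$GSTD,
             c_m = x$c_m, N_dose = x$N_dose, m_dose = x$m_dose,
             SA_dose = x$SA_dose, pathway = x$pathway,
             stringsAsFactors = FALSE)
}
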