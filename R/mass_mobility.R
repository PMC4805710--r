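#' DMA-APM mass-mobility data
#'
#' Pairs of mobility diameter and mean single-particle mass measured by a
#' DMA-APM tandem.
#'
#' @param diameter_nm Mobility diameters, nm (positive).
#' @param mass_kg Mean single-particle masses, kg (positive).
#' @return A data frame of class `"massmob_data"`.
#' @export
massmob_data <- function(diameter_nm, mass_kg) {
  if (length(diameter_nm) != length(mass_kg))
    stop_invalid("diameter and mass vectors must have equal length")
  if (length(diameter_nm) < 2)
    stop_invalid("at least 2 mass-mobility points are required")
  if (any(!is.finite(diameter_nm)) || any(diameter_nm <= 0) ||
      any(!is.finite(mass_kg)) || any(mass_kg <= 0))
    stop_invalid("all diameters and masses must be positive and finite")
  structure(data.frame(diameter_nm = as.numeric(diameter_nm),
                       mass_kg = as.numeric(mass_kg)),
            class = c("massmob_data", "data.frame"))
}

#' Fit the mass-mobility power law
#'
#' Fits `m(d_me) = k * d_me^D_mm` (SI units) to DMA-APM data by ordinary
#' least squares on (ln d_me, ln m).  `D_mm` is the slope, `k` the
#' exponentiated intercept; the 95% confidence interval on `D_mm` comes from
#' the t distribution on the slope standard error.  For fractal aggregates
#' formed by diffusion-limited cluster aggregation `D_mm` is typically
#' 2.0-2.2; it is 3 for compact spheres.
#'
#' With only two points the slope is the exact two-point closed form and the
#' confidence interval is undefined (`ci_defined = FALSE`, with a warning).
#'
#' @param data A [massmob_data] object, or a data frame with columns
#'   `diameter_nm` and `mass_kg`.
#' @return An object of class `"massmob"` with elements `k` (SI prefactor,
#'   kg m^-D_mm), `D_mm`, `D_mm_se`, `D_mm_ci` (95%), `n`, `ci_defined`,
#'   and the underlying `lm` fit (`model`).
#' @seealso [mass_at], [sphere_massmob]
#' @examples
#' d <- c(50, 100, 200)
#' fit <- fit_massmob(massmob_data(d, sphere_mass(d, 1)))
#' coef(fit)   # D_mm = 3, k = pi/6 * 1000
#' @export
fit_massmob <- function(data) {
  if (!is.data.frame(data) ||
      !all(c("diameter_nm", "mass_kg") %in% names(data)))
    stop_invalid("data must have columns diameter_nm and mass_kg")
  d <- data$diameter_nm
  m <- data$mass_kg
  if (length(d) < 2 || any(d <= 0) || any(m <= 0))
    stop_invalid("fit requires >= 2 positive (diameter, mass) pairs")
  if (diff(range(d)) == 0)
    stop_invalid("degenerate fit: zero diameter spread")
  ld <- log(d * NM_TO_M)
  lmod <- lm(log(m) ~ ld)
  D_mm <- unname(coef(lmod)[2])
  k <- exp(unname(coef(lmod)[1]))
  if (length(d) >= 3) {
    # noiseless data triggers lm's "essentially perfect fit" warning
    se <- suppressWarnings(summary(lmod)$coefficients[2, 2])
    ci <- suppressWarnings(unname(confint(lmod, "ld", level = 0.95)[1, ]))
    ci_defined <- TRUE
  } else {
    warning("only 2 points: slope is exact but its CI is undefined",
            call. = FALSE)
    se <- NA_real_
    ci <- c(NA_real_, NA_real_)
    ci_defined <- FALSE
  }
  structure(list(k = k, D_mm = D_mm, D_mm_se = se, D_mm_ci = ci,
                 n = length(d), ci_defined = ci_defined, model = lmod),
            class = "massmob")
}

#' Mass-mobility relation of compact spheres
#'
#' The exact power law of spheres of a given bulk density: `D_mm = 3`,
#' `k = (pi/6) * rho` in SI.  Used for sintered (near-spherical) particles,
#' for which the mobility diameter is taken as the physical diameter.
#'
#' @param bulk_density_g_cm3 Bulk material density, g/cm^3.
#' @return A `"massmob"` object (exact; zero standard error).
#' @export
sphere_massmob <- function(bulk_density_g_cm3) {
  if (!is.finite(bulk_density_g_cm3) || bulk_density_g_cm3 <= 0)
    stop_invalid("bulk density must be positive")
  structure(list(k = pi / 6 * bulk_density_g_cm3 * 1000, D_mm = 3,
                 D_mm_se = 0, D_mm_ci = c(3, 3), n = Inf,
                 ci_defined = TRUE, model = NULL),
            class = "massmob")
}

#' @export
print.massmob <- function(x, digits = 3, ...) {
  cat("Mass-mobility power law m = k * d_me^D_mm (SI)\n")
  if (x$ci_defined && is.finite(x$D_mm_se) && x$D_mm_se > 0)
    cat(sprintf("  D_mm = %.*g (CI 95%% %.*g-%.*g), k = %.*g, n = %d\n",
                digits, x$D_mm, digits, x$D_mm_ci[1], digits, x$D_mm_ci[2],
                digits, x$k, x$n))
  else
    cat(sprintf("  D_mm = %.*g, k = %.*g, n = %s\n",
                digits, x$D_mm, digits, x$k, format(x$n)))
  invisible(x)
}

#' @export
coef.massmob <- function(object, ...) c(k = object$k, D_mm = object$D_mm)

#' @export
confint.massmob <- function(object, parm = "D_mm", level = 0.95, ...) {
  if (!identical(level, 0.95) && !is.null(object$model))
    return(confint(object$model, "ld", level = level))
  matrix(object$D_mm_ci, nrow = 1,
         dimnames = list("D_mm", c("2.5 %", "97.5 %")))
}

#' @export
predict.massmob <- function(object, diameter_nm, ...) {
  mass_at(object, diameter_nm)
}

#' @export
plot.massmob <- function(x, data = NULL, ...) {
  if (is.null(data) && !is.null(x$model)) {
    ld <- x$model$model$ld
    data <- data.frame(diameter_nm = exp(ld) / NM_TO_M,
                       mass_kg = exp(x$model$model[[1]]))
  }
  if (is.null(data)) stop_invalid("no data to plot")
  plot(data$diameter_nm, data$mass_kg, log = "xy",
       xlab = "mobility diameter (nm)", ylab = "particle mass (kg)", ...)
  dd <- log_grid(min(data$diameter_nm), max(data$diameter_nm), 50)
  lines(dd, mass_at(x, dd))
  invisible(x)
}

#' Evaluate the mass-mobility power law
#'
#' @param fit A `"massmob"` object from [fit_massmob] or [sphere_massmob].
#' @param diameter_nm Mobility diameter(s), nm (> 0).
#' @return Single-particle mass(es) in kg.
#' @export
mass_at <- function(fit, diameter_nm) {
  stopifnot(inherits(fit, "massmob"))
  if (any(!is.finite(diameter_nm)) || any(diameter_nm <= 0))
    stop_invalid("diameter must be positive")
  fit$k * (diameter_nm * NM_TO_M)^fit$D_mm
}

#' Mass of a compact sphere
#'
#' @param diameter_nm Physical diameter, nm.
#' @param bulk_density_g_cm3 Bulk density, g/cm^3.
#' @return Mass in kg, `(pi/6) rho d^3` in SI.
#' @export
sphere_mass <- function(diameter_nm, bulk_density_g_cm3) {
  if (any(!is.finite(diameter_nm)) || any(diameter_nm <= 0) ||
      !is.finite(bulk_density_g_cm3) || bulk_density_g_cm3 <= 0)
    stop_invalid("diameter and density must be positive")
  pi / 6 * bulk_density_g_cm3 * 1000 * (diameter_nm * NM_TO_M)^3
}

#' Convert a number size distribution to a mass size distribution
#'
#' Bin-wise product of the number density with the single-particle mass from
#' the mass-mobility relation: `dm/dlog10 Dp = dN/dlog10 Dp * m(d_me)`.
#'
#' @param dist An [nsd] object.
#' @param fit A `"massmob"` object.
#' @return An object of class `"msd"`: same grid, density `dmdlogdp` in
#'   kg/cm^3 per log10-decade.
#' @export
number_to_mass_distribution <- function(dist, fit) {
  stopifnot(inherits(dist, "nsd"), inherits(fit, "massmob"))
  structure(list(diameter_nm = dist$diameter_nm,
                 dmdlogdp = dist$dndlogdp * mass_at(fit, dist$diameter_nm),
                 label = dist$label),
            class = "msd")
}

#' @export
print.msd <- function(x, ...) {
  cat("Mass size distribution", if (!is.null(x$label)) paste0("'", x$label, "'"),
      "\n")
  cat(sprintf("  %d bins; c_m = %.4g mg/m^3\n", length(x$diameter_nm),
              total_mass_concentration(x)))
  invisible(x)
}

#' Total mass concentration of a mass size distribution
#'
#' Log10-trapezoid integral of the mass density, converted to the TEOM
#' reporting unit mg/m^3.
#'
#' @param mass_dist An `"msd"` object from [number_to_mass_distribution].
#' @return Total mass concentration `c_m`, mg/m^3.
#' @export
total_mass_concentration <- function(mass_dist) {
  stopifnot(inherits(mass_dist, "msd"))
  pracma::trapz(log10(mass_dist$diameter_nm), mass_dist$dmdlogdp) *
    KG_CM3_TO_MG_M3
}
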