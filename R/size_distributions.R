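#' Number size distribution
#'
#' Container for a binned aerosol number size distribution as exported by an
#' SMPS: mobility diameters (bin centres, nm) and the number concentration
#' density per bin, `dN/dlog10 Dp`, in #/cm^3 per log10-decade.
#'
#' @param diameter_nm Numeric vector of bin-centre mobility diameters in nm;
#'   strictly increasing, all positive, at least 2 bins.
#' @param dndlogdp Numeric vector of the same length; number concentration
#'   density per log10-decade (#/cm^3), all non-negative.
#' @param label Optional free-text exposure identifier (e.g. `"Cu_4"`).
#' @return An object of class `"nsd"`.
#' @examples
#' d <- make_lognormal(1e6, CMD = 100, GSTD = 1.6)
#' total_concentration(d)
#' summary(d)
#' @export
nsd <- function(diameter_nm, dndlogdp, label = NULL) {
  if (!is.numeric(diameter_nm) || !is.numeric(dndlogdp))
    stop_invalid("diameter_nm and dndlogdp must be numeric")
  if (length(diameter_nm) != length(dndlogdp))
    stop_invalid("diameter_nm and dndlogdp must have equal length")
  if (length(diameter_nm) < 2)
    stop_invalid("a number size distribution needs at least 2 bins")
  if (any(!is.finite(diameter_nm)) || any(diameter_nm <= 0))
    stop_invalid("all bin diameters must be positive and finite")
  if (any(diff(diameter_nm) <= 0))
    stop_invalid("bin diameters must be strictly increasing")
  if (any(!is.finite(dndlogdp)) || any(dndlogdp < 0))
    stop_invalid("all densities must be finite and non-negative")
  structure(list(diameter_nm = as.numeric(diameter_nm),
                 dndlogdp = as.numeric(dndlogdp),
                 label = label),
            class = "nsd")
}

#' @export
print.nsd <- function(x, ...) {
  cat("Number size distribution", if (!is.null(x$label)) paste0("'", x$label, "'"),
      "\n")
  cat(sprintf("  %d bins, %.3g-%.3g nm\n", length(x$diameter_nm),
              min(x$diameter_nm), max(x$diameter_nm)))
  tot <- total_concentration(x)
  cat(sprintf("  total concentration %.4g #/cm^3\n", tot))
  invisible(x)
}

#' @export
plot.nsd <- function(x, ..., log = "x",
                     xlab = "mobility diameter (nm)",
                     ylab = expression(dN/dlog[10] * D[p] ~ ("#/cm"^3)),
                     type = "l") {
  plot(x$diameter_nm, x$dndlogdp, log = log, xlab = xlab, ylab = ylab,
       type = type, main = x$label %||% "", ...)
  invisible(x)
}

# Trapezoid weights on the log10-diameter axis: interior bins get half the
# span of their neighbours, edge bins half their single neighbour span, so
# the weighted sum equals the log10 trapezoid integral.
log10_weights <- function(diameter_nm) {
  l <- log10(diameter_nm)
  n <- length(l)
  w <- numeric(n)
  w[1] <- (l[2] - l[1]) / 2
  w[n] <- (l[n] - l[n - 1]) / 2
  if (n > 2)
    w[2:(n - 1)] <- (l[3:n] - l[1:(n - 2)]) / 2
  w
}

#' Total number concentration of a size distribution
#'
#' Integrates `dN/dlog10 Dp` over the log10-diameter axis (trapezoid rule),
#' giving the total particle number concentration `c_N` in #/cm^3.
#'
#' @param dist An [nsd] object.
#' @return Total number concentration, #/cm^3.
#' @export
total_concentration <- function(dist) {
  stopifnot(inherits(dist, "nsd"))
  pracma::trapz(log10(dist$diameter_nm), dist$dndlogdp)
}

#' Summarize a number size distribution
#'
#' Computes the total number concentration `c_N`, the count median diameter
#' CMD (geometric mean of the number weighting, which equals the median for
#' a lognormal), and the geometric standard deviation GSTD
#' (`exp(sd(ln d))` of the number weighting).  Moment-based, not a
#' least-squares lognormal fit.
#'
#' @param object An [nsd] object with positive total concentration.
#' @param ... Ignored.
#' @return An object of class `"nsd_summary"` with fields `c_N` (#/cm^3),
#'   `CMD` (nm), `GSTD` (dimensionless, >= 1) and `label`.
#' @export
summary.nsd <- function(object, ...) {
  w <- log10_weights(object$diameter_nm) * object$dndlogdp
  c_N <- sum(w)
  if (c_N <= 0)
    stop_invalid("summary undefined: distribution has zero total concentration")
  ln_d <- log(object$diameter_nm)
  mu <- sum(w * ln_d) / c_N
  sg <- sqrt(sum(w * (ln_d - mu)^2) / c_N)
  structure(list(c_N = c_N, CMD = exp(mu), GSTD = exp(sg),
                 label = object$label),
            class = "nsd_summary")
}

#' @export
print.nsd_summary <- function(x, ...) {
  cat(sprintf("%s c_N = %.4g #/cm^3, CMD = %.1f nm, GSTD = %.2f\n",
              if (is.null(x$label)) "" else paste0(x$label, ":"),
              x$c_N, x$CMD, x$GSTD))
  invisible(x)
}

#' Logarithmically spaced diameter grid
#'
#' @param from_nm,to_nm Grid limits in nm.
#' @param n Number of bins.
#' @return Numeric vector of `n` log10-equally spaced diameters.
#' @export
log_grid <- function(from_nm = 10, to_nm = 1000, n = 64) {
  stopifnot(from_nm > 0, to_nm > from_nm, n >= 2)
  10^seq(log10(from_nm), log10(to_nm), length.out = n)
}

#' Discretized lognormal number size distribution
#'
#' Builds the analytic lognormal density with total concentration `c_N`,
#' count median diameter `CMD` and geometric standard deviation `GSTD`,
#' discretized on a diameter grid.  With `GSTD = 1` a monodisperse spike is
#' placed in the bin nearest `CMD`.
#'
#' @param c_N Total number concentration, #/cm^3 (>= 0).
#' @param CMD Count median diameter, nm (> 0).
#' @param GSTD Geometric standard deviation (>= 1).
#' @param grid Diameter grid in nm (see [log_grid]).
#' @param label Optional exposure label.
#' @return An [nsd] object whose [total_concentration] approximates `c_N`
#'   on a sufficiently wide grid.
#' @export
make_lognormal <- function(c_N, CMD, GSTD, grid = log_grid(), label = NULL) {
  if (!is.finite(c_N) || c_N < 0) stop_invalid("c_N must be >= 0")
  if (!is.finite(CMD) || CMD <= 0) stop_invalid("CMD must be > 0")
  if (!is.finite(GSTD) || GSTD < 1) stop_invalid("GSTD must be >= 1")
  if (GSTD == 1) {
    dens <- numeric(length(grid))
    i <- which.min(abs(log(grid) - log(CMD)))
    dens[i] <- c_N / log10_weights(grid)[i]
  } else {
    # dN/dlog10 d = ln(10) * c_N * phi(ln d; ln CMD, ln GSTD)
    dens <- log(10) * c_N * dnorm(log(grid), log(CMD), log(GSTD))
  }
  nsd(grid, dens, label = label)
}

#' Dilute a number size distribution
#'
#' Divides all densities by the dilution factor; CMD and GSTD are unchanged,
#' matching the behaviour of a well-mixed aerosol dilutor.
#'
#' @param dist An [nsd] object.
#' @param factor Dilution factor, >= 1.
#' @return The diluted [nsd].
#' @export
dilute <- function(dist, factor) {
  stopifnot(inherits(dist, "nsd"))
  if (!is.finite(factor) || factor < 1)
    stop_invalid("dilution factor must be >= 1")
  nsd(dist$diameter_nm, dist$dndlogdp / factor, label = dist$label)
}
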