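#' Count deposited particles on an SEM wafer image
#'
#' Reproduces the classic image-analysis chain for counting deposited
#' particles: smooth with a 3x3 mean filter, binarize at a threshold (Otsu's
#' method on the smoothed image unless a fixed value is given), and count
#' 8-connected foreground components of at least `min_cluster_px` pixels.
#' The pixel-size floor removes the 1-3 pixel noise clusters that wafer
#' backgrounds typically produce.
#'
#' @param image Numeric matrix of grayscale intensities (any range).
#' @param min_cluster_px Minimum component size in pixels counted as a
#'   particle; default 4 (excludes 1-3 px noise).
#' @param threshold Optional fixed intensity threshold applied to the
#'   smoothed image; if `NULL`, Otsu's threshold is used.
#' @return Integer particle count.
#' @export
count_particles <- function(image, min_cluster_px = 4, threshold = NULL) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0)
    stop_invalid("image must be a non-empty numeric matrix")
  if (min_cluster_px < 1) stop_invalid("min_cluster_px must be >= 1")
  sm <- EBImage::imageData(EBImage::filter2(EBImage::Image(image),
                                            matrix(1 / 9, 3, 3),
                                            boundary = "replicate"))
  sm <- matrix(as.numeric(sm), nrow(image), ncol(image))
  if (is.null(threshold)) {
    rng <- range(sm)
    # featureless (uniform) image: nothing to separate.  Note that Otsu
    # always splits an image in two, so on a particle-free but noisy image
    # the automatic threshold is meaningless; pass a fixed threshold when
    # blank frames are possible.
    if (diff(rng) <= 1e-9 * max(1, abs(rng[2]))) return(0L)
    threshold <- EBImage::otsu(EBImage::Image(sm), range = rng)
  }
  fg <- sm > threshold
  sizes <- component_sizes_8(fg)
  sum(sizes >= min_cluster_px)
}

# Sizes of 8-connected foreground components, via igraph on the pixel
# adjacency (EBImage's labeller is 4-connected; 8-connectivity matches the
# imageJ convention the counting procedure assumes).
component_sizes_8 <- function(fg) {
  nfg <- sum(fg)
  if (nfg == 0) return(integer(0))
  nr <- nrow(fg); nc <- ncol(fg)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_len(nfg)
  edges <- list()
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r <- seq_len(nr - dr)
    cs <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    a <- id[r, cs, drop = FALSE]
    b <- id[r + dr, cs + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges[[length(edges) + 1]] <- cbind(a[keep], b[keep])
  }
  g <- igraph::make_empty_graph(n = nfg, directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, as.vector(t(do.call(rbind, edges))))
  igraph::components(g)$csize
}

#' Deposition efficiency from wafer particle counts
#'
#' The deposition efficiency is the fraction of the particles entering the
#' chamber that deposit on the culture surface.  Per image, the deposited
#' areal density `count / imaged_area` is divided by the areal density of
#' particles entering per insert, `c_N * flow_volume / insert_area`.
#' Image-level efficiencies are averaged within each (well, area), and the
#' aggregate estimate is the unweighted mean +/- sample standard deviation
#' across areas.
#'
#' @param counts Data frame with columns `well_id`, `area_id`,
#'   `particle_count` (>= 0) and `imaged_area_cm2` (> 0).
#' @param c_N Number concentration entering the chamber, #/cm^3 (> 0).
#' @param flow_volume_cm3 Total aerosol volume sampled through the chamber
#'   per insert, cm^3 (> 0).
#' @param insert_area_cm2 Insert membrane area, cm^2.
#' @return A `"deposition_estimate"` object; see [aggregate_deposition].
#' @export
efficiency_from_counts <- function(counts, c_N, flow_volume_cm3,
                                   insert_area_cm2 = 0.33) {
  need <- c("well_id", "area_id", "particle_count", "imaged_area_cm2")
  if (!is.data.frame(counts) || !all(need %in% names(counts)))
    stop_invalid("counts must have columns ", paste(need, collapse = ", "))
  if (!is.finite(c_N) || c_N <= 0)
    stop_invalid("undefined efficiency: zero particles entering (c_N <= 0)")
  if (!is.finite(flow_volume_cm3) || flow_volume_cm3 <= 0)
    stop_invalid("flow volume must be positive")
  if (any(counts$particle_count < 0) || any(counts$imaged_area_cm2 <= 0))
    stop_invalid("counts must be >= 0 and imaged areas > 0")
  entering_per_cm2 <- c_N * flow_volume_cm3 / insert_area_cm2
  eff <- (counts$particle_count / counts$imaged_area_cm2) / entering_per_cm2
  per_area <- aggregate(eff * 100,
                        by = list(well_id = counts$well_id,
                                  area_id = counts$area_id),
                        FUN = mean)
  names(per_area)[3] <- "efficiency_pct"
  aggregate_deposition(per_area$efficiency_pct,
                       well = per_area$well_id, area = per_area$area_id)
}

#' Aggregate area-level deposition efficiencies
#'
#' Unweighted mean and sample (n-1) standard deviation across area-level
#' efficiencies, the aggregation used to report a chamber's overall
#' efficiency from wafer analyses of several wells/areas.
#'
#' @param efficiency_pct Area-level efficiencies, percent.
#' @param well,area Optional labels, recycled to length.
#' @return An object of class `"deposition_estimate"` with `per_area`
#'   (data frame), `mean_pct`, `sd_pct` and `n_areas`.
#' @examples
#' aggregate_deposition(c(55, 27, 43, 48, 11, 17, 52))  # 36 +/- 17 %
#' @export
aggregate_deposition <- function(efficiency_pct, well = NULL, area = NULL) {
  if (length(efficiency_pct) < 1 || any(!is.finite(efficiency_pct)))
    stop_invalid("efficiencies must be finite")
  per_area <- data.frame(
    well_id = if (is.null(well)) seq_along(efficiency_pct) else well,
    area_id = if (is.null(area)) seq_along(efficiency_pct) else area,
    efficiency_pct = efficiency_pct)
  structure(list(per_area = per_area,
                 mean_pct = mean(efficiency_pct),
                 sd_pct = if (length(efficiency_pct) >= 2)
                   sd(efficiency_pct) else NA_real_,
                 n_areas = length(efficiency_pct)),
            class = "deposition_estimate")
}

#' @export
print.deposition_estimate <- function(x, ...) {
  cat(sprintf("Deposition efficiency E_SEM = %.0f +/- %.0f %% (n = %d areas)\n",
              x$mean_pct, x$sd_pct, x$n_areas))
  invisible(x)
}

#' Effective deposition efficiency under a charger fault
#'
#' During a unipolar-charger short circuit only the fraction of particles
#' that is charged anyway (about 20% under the equilibrium bipolar charge
#' distribution for these sizes) is deposited electrostatically.  The
#' effective efficiency is the time-weighted mean of the nominal and the
#' faulted efficiency:
#' `E_eff = E * (1 - f_fault) + E * charged_fraction * f_fault`.
#'
#' @param efficiency Nominal deposition efficiency, fraction in \[0, 1\].
#' @param charged_fraction Charged fraction during the fault; default 0.20.
#' @param fault_time_fraction Fraction of the exposure spent in the faulted
#'   state, in \[0, 1\].
#' @return Effective efficiency, fraction.
#' @export
charger_fault_efficiency <- function(efficiency, charged_fraction = 0.20,
                                     fault_time_fraction) {
  vals <- c(efficiency, charged_fraction, fault_time_fraction)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop_invalid("all inputs must be fractions in [0, 1]")
  efficiency * (1 - fault_time_fraction) +
    efficiency * charged_fraction * fault_time_fraction
}
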