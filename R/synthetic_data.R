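#' Synthetic-data scenario
#'
#' A single scenario drives every generator so the synthetic inputs of the
#' different stages are mutually coherent.  The defaults emulate the second
#' Cu exposure series: a lognormal aerosol around 115 nm with GSTD 1.67, a
#' mass-mobility exponent of 2.08 with 5% multiplicative APM noise,
#' lognormal ~4.7 nm primary particles, a 36% deposition efficiency, and a
#' weak linear viability decline with dose.
#'
#' @param seed Integer seed; every stochastic generator derives its stream
#'   from it.
#' @param aerosol List: `c_N` (#/cm^3), `CMD` (nm), `GSTD`.
#' @param massmob List: `k` (SI), `D_mm`, `noise_sigma` (lognormal sd of the
#'   multiplicative mass error), `n` points, `d_range` (nm).
#' @param primaries List: `gm_nm`, `gsd`, `n`, `material`,
#'   `bulk_density_g_cm3`.
#' @param deposition List: `efficiency` (fraction), `n_images`,
#'   `mean_disks` (Poisson mean per image), `disk_radius_px`,
#'   `speck_rate` (Poisson mean of 1-3 px noise clusters per image),
#'   `image_size` (px).
#' @param response List: `baseline` ratio, `slope` per unit of the chosen
#'   dose `metric` (`"N"`, `"m"` or `"SA"`), Gaussian `noise_sd`, `lod`
#'   censoring threshold on the ratio, `replicates` per exposure level.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(seed = 1,
                     aerosol = list(c_N = 2.58e6, CMD = 115.1, GSTD = 1.67),
                     massmob = list(k = 2.9e-4, D_mm = 2.08,
                                    noise_sigma = 0.05, n = 20,
                                    d_range = c(40, 360)),
                     primaries = list(gm_nm = 4.65, gsd = 1.19, n = 886,
                                      material = "Cu",
                                      bulk_density_g_cm3 = 8.96),
                     deposition = list(efficiency = 0.36, n_images = 3,
                                       mean_disks = 50, disk_radius_px = 3,
                                       speck_rate = 200, image_size = 256),
                     response = list(baseline = 1, slope = -0.05,
                                     metric = "m", noise_sd = 0.1,
                                     lod = 0.05, replicates = 3)) {
  pos <- c(aerosol$c_N, aerosol$CMD, aerosol$GSTD, massmob$k, massmob$D_mm,
           primaries$gm_nm, primaries$gsd, primaries$n,
           deposition$efficiency, deposition$image_size)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop_invalid("all scale parameters must be positive")
  if (is.null(seed) || !is.finite(seed))
    stop_invalid("a seed is mandatory")
  structure(list(seed = as.integer(seed), aerosol = aerosol,
                 massmob = massmob, primaries = primaries,
                 deposition = deposition, response = response),
            class = "scenario")
}

#' Generate a synthetic SMPS spectrum
#'
#' Discretizes the scenario's lognormal and, optionally, applies Poisson
#' counting noise per bin: the expected count in a bin is the bin
#' concentration times the counted sample volume, so the noisy density has
#' the analytic lognormal as its expectation.
#'
#' @param scn A [scenario].
#' @param grid Diameter grid, nm.
#' @param noise `"poisson"` (default) or `"none"`.
#' @param sample_cm3 Aerosol volume counted per bin, cm^3; controls the
#'   counting-noise level.
#' @param seed Seed; defaults to the scenario seed.
#' @return An [nsd] object.
#' @export
gen_spectrum <- function(scn, grid = log_grid(10, 1000, 64),
                         noise = c("poisson", "none"), sample_cm3 = 0.01,
                         seed = scn$seed) {
  stopifnot(inherits(scn, "scenario"))
  noise <- match.arg(noise)
  a <- scn$aerosol
  base <- make_lognormal(a$c_N, a$CMD, a$GSTD, grid = grid)
  if (noise == "none") return(base)
  set.seed(seed)
  w <- log10_weights(grid)
  lambda <- base$dndlogdp * w * sample_cm3
  counts <- rpois(length(lambda), lambda)
  nsd(grid, counts / (w * sample_cm3))
}

#' Generate synthetic DMA-APM mass-mobility data
#'
#' Masses follow the scenario power law `k d^D_mm` with multiplicative
#' lognormal noise (APM mass errors are relative), over log-spaced sizes in
#' the scenario diameter range.
#'
#' @param scn A [scenario].
#' @param seed Seed; defaults to the scenario seed.
#' @return A [massmob_data] object; the generating `k` and `D_mm` are
#'   attached as attribute `"truth"`.
#' @export
gen_massmob <- function(scn, seed = scn$seed) {
  stopifnot(inherits(scn, "scenario"))
  m <- scn$massmob
  set.seed(seed)
  d <- log_grid(m$d_range[1], m$d_range[2], m$n)
  mass <- m$k * (d * NM_TO_M)^m$D_mm
  if (m$noise_sigma > 0)
    mass <- mass * rlnorm(length(d), 0, m$noise_sigma)
  out <- massmob_data(d, mass)
  attr(out, "truth") <- c(k = m$k, D_mm = m$D_mm)
  out
}

#' Generate a synthetic primary-particle sample
#'
#' Lognormal diameters with the scenario geometric mean and GSD
#' (`gsd = 1` gives a monodisperse sample).
#'
#' @param scn A [scenario].
#' @param seed Seed; defaults to the scenario seed.
#' @return A [primary_particles] object.
#' @export
gen_primaries <- function(scn, seed = scn$seed) {
  stopifnot(inherits(scn, "scenario"))
  p <- scn$primaries
  set.seed(seed)
  d <- if (p$gsd == 1) rep(p$gm_nm, p$n)
       else rlnorm(p$n, log(p$gm_nm), log(p$gsd))
  primary_particles(d, material = p$material %||% "",
                    bulk_density_g_cm3 = p$bulk_density_g_cm3)
}

place_disks <- function(img, n, radius, intensity) {
  nr <- nrow(img); nc <- ncol(img)
  centres <- matrix(numeric(0), ncol = 2)
  placed <- 0
  tries <- 0
  while (placed < n && tries < 50 * n + 200) {
    tries <- tries + 1
    cx <- runif(1, radius + 2, nr - radius - 1)
    cy <- runif(1, radius + 2, nc - radius - 1)
    if (nrow(centres) > 0 &&
        min((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2) <
          (2 * radius + 3)^2)
      next
    centres <- rbind(centres, c(cx, cy))
    placed <- placed + 1
  }
  for (i in seq_len(nrow(centres))) {
    rs <- max(1, floor(centres[i, 1] - radius)):min(nr, ceiling(centres[i, 1] + radius))
    cs <- max(1, floor(centres[i, 2] - radius)):min(nc, ceiling(centres[i, 2] + radius))
    for (r in rs) for (cc in cs)
      if ((r - centres[i, 1])^2 + (cc - centres[i, 2])^2 <= radius^2)
        img[r, cc] <- intensity
  }
  list(img = img, n = nrow(centres), centres = centres)
}

#' Generate synthetic SEM wafer images
#'
#' Bright non-overlapping disks (the deposited particles) on a noisy dark
#' background, plus small bright speckle blocks that reduce to 1-3 pixel
#' foreground clusters after the counting procedure's smoothing and
#' thresholding, emulating wafer-background noise.  Ground-truth disk
#' counts are returned alongside the images, so counting and efficiency
#' estimation can be validated.
#'
#' @param scn A [scenario].
#' @param seed Seed; defaults to the scenario seed.
#' @return A list with `images` (list of numeric matrices in \[0, 1\]) and
#'   `truth` (integer vector of disk counts per image).
#' @export
gen_wafer_images <- function(scn, seed = scn$seed) {
  stopifnot(inherits(scn, "scenario"))
  dp <- scn$deposition
  set.seed(seed)
  images <- vector("list", dp$n_images)
  truth <- integer(dp$n_images)
  for (i in seq_len(dp$n_images)) {
    sz <- dp$image_size
    img <- matrix(0.15 + rnorm(sz * sz, 0, 0.02), sz, sz)
    n_disks <- rpois(1, dp$mean_disks)
    res <- place_disks(img, n_disks, dp$disk_radius_px, 0.9)
    img <- res$img
    truth[i] <- res$n
    # speckle: bright collinear 3-px runs away from the disks and from
    # each other.  Under the counting procedure's 3x3 mean smoothing only
    # the windows centred on the middle pixel of a run see all three
    # bright pixels, so each run reduces to a 1-3 px foreground cluster
    # after thresholding -- the wafer-background noise the cluster-size
    # floor is meant to reject -- and no two clusters can merge into a
    # countable component.
    n_specks <- rpois(1, dp$speck_rate)
    guard <- (dp$disk_radius_px + 6)^2
    blocked <- matrix(FALSE, sz, sz)
    for (s in seq_len(n_specks)) {
      for (try in 1:30) {
        r <- sample.int(sz - 6, 1) + 2L; cc <- sample.int(sz - 7, 1) + 2L
        near_disk <- res$n > 0 &&
          min((res$centres[, 1] - r)^2 + (res$centres[, 2] - cc)^2) <= guard
        rs <- max(1, r - 4):min(sz, r + 4)
        cs <- max(1, cc - 4):min(sz, cc + 6)
        if (!near_disk && !any(blocked[rs, cs])) break
        r <- NA
      }
      if (is.na(r)) next
      img[r, cc:(cc + 2)] <- 0.9
      blocked[rs, cs] <- TRUE
    }
    images[[i]] <- pmin(pmax(img, 0), 1)
  }
  list(images = images, truth = truth)
}

#' Generate a synthetic response table
#'
#' Linear dose-response with Gaussian noise and LOD censoring:
#' `ratio = baseline + slope * dose + N(0, noise_sd)`, per replicate and
#' exposure level; ratios below the LOD are flagged censored.  Control rows
#' (ratio 1, zero dose) are appended.  The generating slope is attached as
#' attribute `"true_slope"`.
#'
#' @param scn A [scenario].
#' @param doses Data frame with columns `label`, `dose_N`, `dose_m`,
#'   `dose_SA` (from the dosimetry stage), and optionally `morphology`.
#' @param endpoint,cell_line,material Labels written into the table.
#' @param seed Seed; defaults to the scenario seed.
#' @return A validated response table (data frame).
#' @export
gen_responses <- function(scn, doses, endpoint = "WST-1",
                          cell_line = "SAEC", material = "Cu",
                          seed = scn$seed) {
  stopifnot(inherits(scn, "scenario"), is.data.frame(doses))
  rs <- scn$response
  set.seed(seed)
  dose_col <- paste0("dose_", rs$metric)
  if (!dose_col %in% names(doses))
    stop_invalid("doses must have column ", dose_col)
  rep_rows <- doses[rep(seq_len(nrow(doses)), each = rs$replicates), ,
                    drop = FALSE]
  ratio <- rs$baseline + rs$slope * rep_rows[[dose_col]] +
    rnorm(nrow(rep_rows), 0, rs$noise_sd)
  below <- ratio < rs$lod
  tab <- data.frame(
    cell_line = cell_line, endpoint = endpoint, material = material,
    morphology = rep_rows$morphology %||% "aggregate",
    exposure_label = rep_rows$label,
    dose_N = rep_rows$dose_N, dose_m = rep_rows$dose_m,
    dose_SA = rep_rows$dose_SA,
    ratio = ifelse(below, NA_real_, ratio), below_LOD = below,
    stringsAsFactors = FALSE)
  ctrl <- data.frame(
    cell_line = cell_line, endpoint = endpoint, material = "control",
    morphology = "none", exposure_label = "control",
    dose_N = 0, dose_m = 0, dose_SA = 0, ratio = 1, below_LOD = FALSE,
    stringsAsFactors = FALSE)
  out <- rbind(tab, ctrl[rep(1, rs$replicates), ])
  rownames(out) <- NULL
  attr(out, "true_slope") <- rs$slope
  validate_responses(out)
  out
}
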