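#' Read a number size distribution from CSV
#'
#' Expects two columns `diameter_nm, dNdlogDp`, header required; lines
#' starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @param label Optional exposure label; defaults to the file name.
#' @return An [nsd] object.
#' @export
read_nsd_csv <- function(path, label = NULL) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("diameter_nm", "dNdlogDp") %in% names(df)))
    stop_invalid(path, ": need columns diameter_nm, dNdlogDp")
  nsd(df$diameter_nm, df$dNdlogDp,
      label = label %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a number size distribution to CSV
#'
#' @param dist An [nsd] object.
#' @param path Output path.
#' @export
write_nsd_csv <- function(dist, path) {
  stopifnot(inherits(dist, "nsd"))
  write.csv(data.frame(diameter_nm = dist$diameter_nm,
                       dNdlogDp = dist$dndlogdp),
            path, row.names = FALSE)
  invisible(path)
}

#' Read DMA-APM mass-mobility pairs from CSV
#'
#' Columns `diameter_nm` and `mass_kg`, or `mass_fg` (femtograms,
#' auto-converted with 1 fg = 1e-18 kg).
#'
#' @param path CSV file path.
#' @return A [massmob_data] object.
#' @export
read_massmob_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!"diameter_nm" %in% names(df))
    stop_invalid(path, ": need column diameter_nm")
  if ("mass_kg" %in% names(df)) mass <- df$mass_kg
  else if ("mass_fg" %in% names(df)) mass <- df$mass_fg * FG_TO_KG
  else stop_invalid(path, ": need column mass_kg or mass_fg")
  massmob_data(df$diameter_nm, mass)
}

#' Read a primary-particle diameter list
#'
#' Plain text, one diameter (nm) per line; `#` comments allowed.
#'
#' @param path File path.
#' @param material,bulk_density_g_cm3 Passed to [primary_particles].
#' @return A [primary_particles] object.
#' @export
read_primaries_txt <- function(path, material = "",
                               bulk_density_g_cm3 = NULL) {
  d <- scan(path, comment.char = "#", quiet = TRUE)
  primary_particles(d, material = material,
                    bulk_density_g_cm3 = bulk_density_g_cm3)
}

#' Read wafer particle counts from CSV
#'
#' Columns `well_id, area_id, particle_count, imaged_area_cm2`.
#'
#' @param path CSV file path.
#' @return A data frame suitable for [efficiency_from_counts].
#' @export
read_counts_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  need <- c("well_id", "area_id", "particle_count", "imaged_area_cm2")
  if (!all(need %in% names(df)))
    stop_invalid(path, ": need columns ", paste(need, collapse = ", "))
  df
}

#' Read a response table from CSV
#'
#' @param path CSV file path with the columns listed in
#'   [validate_responses].
#' @return A validated response table.
#' @export
read_responses_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  df$below_LOD <- as.logical(df$below_LOD)
  validate_responses(df)
  df
}

#' Read a grayscale image (PNG or TIFF)
#'
#' Multichannel images are averaged to one grayscale channel.
#'
#' @param path Image path ending in `.png`, `.tif` or `.tiff`.
#' @return A numeric matrix of intensities in \[0, 1\].
#' @export
read_grayscale_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop_invalid("unsupported image format: .", ext))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}

pipeline_defaults <- function() {
  list(
    volume_cm3 = 1500,
    insert_area_cm2 = 0.33,
    efficiency = 0.36,
    duration_h = 1,
    densities_g_cm3 = list(Cu = 8.96, Pd = 12.02, Ag = 10.49),
    charged_fraction = 0.20,
    pool_series = TRUE,
    lod_policy = "exclude",
    log_scale = FALSE
  )
}

#' Load a pipeline configuration
#'
#' YAML key/value configuration with explicit units in key names; unknown
#' keys are rejected, missing keys take the defaults (`volume_cm3 = 1500`,
#' `insert_area_cm2 = 0.33`, `efficiency = 0.36`, bulk densities for Cu,
#' Pd, Ag, `charged_fraction = 0.20`).  An empty or missing `path` gives
#' the all-defaults configuration.
#'
#' @param path Optional YAML file path.
#' @return An object of class `"pipeline_config"`.
#' @export
load_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_invalid("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0)
      stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "))
    if (!is.null(user$densities_g_cm3))
      user$densities_g_cm3 <- modifyList(cfg$densities_g_cm3,
                                         user$densities_g_cm3)
    cfg <- modifyList(cfg, user)
  }
  num <- c(cfg$volume_cm3, cfg$insert_area_cm2, cfg$efficiency,
           cfg$duration_h, unlist(cfg$densities_g_cm3))
  if (any(!is.finite(num)) || any(num <= 0))
    stop_invalid("config values must be positive numbers")
  if (cfg$efficiency > 1 || cfg$charged_fraction < 0 ||
      cfg$charged_fraction > 1)
    stop_invalid("efficiency and charged_fraction must be fractions")
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `"pipeline_config"`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full dose and statistics pipeline
#'
#' Computes a dose table for a set of exposure records (dispatching the
#' mass/surface-area pathway per record, see [compute_dose]), optionally
#' runs the three statistical tiers on a response table, and writes
#' deterministic CSV outputs plus a run log recording the pathway and any
#' default substituted for a missing input.
#'
#' @param records List of [exposure_record] objects.
#' @param config A `"pipeline_config"` from [load_config].
#' @param fits Named list of `"massmob"` fits, keyed by material, for the
#'   aggregate mass pathway.
#' @param ssa Named list/vector of specific surface areas (m^2/g) keyed by
#'   material, for the aggregate surface-area pathway.
#' @param responses Optional response table; tiers 1-3 are run for every
#'   (endpoint, cell line) combination present.
#' @param out_dir Optional output directory for `doses.csv`,
#'   `stats_tiers.csv` and `run_log.txt`.
#' @return A list with `doses` (data frame), `stats` (data frame or
#'   `NULL`) and `log` (character vector), invisibly when writing files.
#' @export
run_pipeline <- function(records, config = load_config(), fits = list(),
                         ssa = list(), responses = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- exposure_config(config$volume_cm3, config$insert_area_cm2,
                         config$efficiency, config$duration_h)
  log <- c(sprintf("alidose pipeline, config: v = %g cm^3, SA = %g cm^2, E = %g",
                   cfg$volume_cm3, cfg$insert_area_cm2, cfg$efficiency))
  doses <- lapply(records, function(rec) {
    stopifnot(inherits(rec, "exposure_record"))
    fit <- fits[[rec$material]]
    ssa_i <- if (rec$material %in% names(ssa)) ssa[[rec$material]] else NULL
    res <- tryCatch(
      compute_dose(rec, cfg, fit = fit, ssa_m2_g = ssa_i),
      error = function(e) stop_invalid("dose stage failed for exposure '",
                                       rec$label, "': ", conditionMessage(e)))
    log <<- c(log, sprintf("%s: pathway %s%s", rec$label, res$pathway,
                           if (!is.null(rec$efficiency))
                             sprintf(" (record efficiency %g)",
                                     rec$efficiency) else ""))
    as.data.frame(res)
  })
  doses <- do.call(rbind, doses)

  stats_df <- NULL
  if (!is.null(responses)) {
    validate_responses(responses)
    combos <- unique(responses[responses$material != "control",
                               c("endpoint", "cell_line")])
    stats_rows <- list()
    for (i in seq_len(nrow(combos))) {
      ep <- combos$endpoint[i]; cl <- combos$cell_line[i]
      t1 <- tox_tier1(responses, ep, cl, log_scale = config$log_scale)
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        tier = 1, endpoint = ep, cell_line = cl, group = "all",
        n = t1$n, estimate = t1$mean_ratio, p = t1$p_vs_unity,
        evaluable = t1$evaluable, stringsAsFactors = FALSE)
      t2 <- tox_tier2(responses, ep, cl, log_scale = config$log_scale)
      for (mat in names(t2)) {
        r <- t2[[mat]]
        stats_rows[[length(stats_rows) + 1]] <- data.frame(
          tier = 2, endpoint = ep, cell_line = cl, group = mat,
          n = r$n, estimate = r$mean_ratio, p = r$p_vs_unity,
          evaluable = r$evaluable, stringsAsFactors = FALSE)
      }
      for (metric in c("N", "m", "SA")) {
        t3 <- tox_tier3(responses, ep, cl, dose_metric = metric,
                        log_scale = config$log_scale)
        stats_rows[[length(stats_rows) + 1]] <- data.frame(
          tier = 3, endpoint = ep, cell_line = cl,
          group = paste0(metric, "_dose"),
          n = t3$n, estimate = t3$slope, p = t3$slope_p,
          evaluable = t3$evaluable, stringsAsFactors = FALSE)
      }
    }
    stats_df <- do.call(rbind, stats_rows)
    log <- c(log, sprintf("statistics: %d tier results over %d combos",
                          nrow(stats_df), nrow(combos)))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(doses, file.path(out_dir, "doses.csv"), row.names = FALSE)
    if (!is.null(stats_df))
      write.csv(stats_df, file.path(out_dir, "stats_tiers.csv"),
                row.names = FALSE)
    writeLines(log, file.path(out_dir, "run_log.txt"))
    return(invisible(list(doses = doses, stats = stats_df, log = log)))
  }
  list(doses = doses, stats = stats_df, log = log)
}
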