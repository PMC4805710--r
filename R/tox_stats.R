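#' Validate a response table
#'
#' The response table carries one row per exposed culture insert: the
#' endpoint value expressed as the exposed/control ratio, the exposure's
#' dose metrics, and a below-LOD censoring flag.  Required columns:
#' `cell_line`, `endpoint`, `material`, `morphology`, `exposure_label`,
#' `dose_N`, `dose_m`, `dose_SA`, `ratio`, `below_LOD`.
#'
#' @param table A data frame.
#' @return The table, invisibly, after validation.
#' @export
validate_responses <- function(table) {
  need <- c("cell_line", "endpoint", "material", "morphology",
            "exposure_label", "dose_N", "dose_m", "dose_SA", "ratio",
            "below_LOD")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop_invalid("response table must have columns ",
                 paste(need, collapse = ", "))
  if (!is.logical(table$below_LOD))
    stop_invalid("below_LOD must be logical")
  bad <- !table$below_LOD & (!is.finite(table$ratio) | table$ratio <= 0)
  if (any(bad))
    stop_invalid("quantified ratios must be positive")
  invisible(table)
}

subset_responses <- function(table, endpoint, cell_line) {
  validate_responses(table)
  table[table$endpoint == endpoint & table$cell_line == cell_line &
          table$material != "control", , drop = FALSE]
}

tier_result <- function(group, x, log_scale = FALSE) {
  n <- length(x)
  if (n < 2) {
    return(structure(list(group = group, n = n, mean_ratio = NA_real_,
                          ci95 = c(NA_real_, NA_real_), p_vs_unity = NA_real_,
                          significant = NA, evaluable = FALSE,
                          reason = if (n == 0) "no quantifiable ratios"
                                   else "fewer than 2 quantifiable ratios"),
                     class = "tier_result"))
  }
  if (sd(x) == 0) {
    # degenerate constant sample: no sampling variability to test against
    est <- x[1]
    return(structure(list(group = group, n = n, mean_ratio = est,
                          ci95 = c(est, est),
                          p_vs_unity = if (est == 1) 1 else NA_real_,
                          significant = if (est == 1) FALSE else NA,
                          evaluable = TRUE, reason = NULL),
                     class = "tier_result"))
  }
  if (log_scale) {
    tt <- t.test(log(x), mu = 0)
    est <- exp(unname(tt$estimate)); ci <- exp(tt$conf.int)
  } else {
    tt <- t.test(x, mu = 1)
    est <- unname(tt$estimate); ci <- tt$conf.int
  }
  structure(list(group = group, n = n, mean_ratio = est,
                 ci95 = as.numeric(ci), p_vs_unity = tt$p.value,
                 significant = tt$p.value < 0.05, evaluable = TRUE,
                 reason = NULL),
            class = "tier_result")
}

#' @export
print.tier_result <- function(x, ...) {
  if (!x$evaluable) {
    cat(sprintf("%s: not evaluable (%s)\n", x$group, x$reason))
  } else {
    cat(sprintf(
      "%s: n = %d, mean ratio = %.3f (95%% CI %.3f-%.3f), p = %.3g%s\n",
      x$group, x$n, x$mean_ratio, x$ci95[1], x$ci95[2], x$p_vs_unity,
      if (x$significant) " *" else ""))
  }
  invisible(x)
}

#' Tier 1: pooled exposed-versus-control test
#'
#' All exposed observations for one endpoint and cell line are pooled,
#' disregarding material, dose and morphology, and the mean exposed/control
#' ratio is tested against 1 with a two-sided one-sample t test (t-based
#' 95% CI).  Below-LOD rows are excluded.
#'
#' @param table A response table (see [validate_responses]).
#' @param endpoint,cell_line Endpoint (e.g. `"WST-1"`) and cell line
#'   (e.g. `"SAEC"`) selecting the rows.
#' @param log_scale Analyse `log(ratio)` against 0 instead (results are
#'   back-transformed); default `FALSE`, mirroring the untransformed
#'   exposed/control presentation.
#' @return A `"tier_result"`.
#' @export
tox_tier1 <- function(table, endpoint, cell_line, log_scale = FALSE) {
  rows <- subset_responses(table, endpoint, cell_line)
  x <- rows$ratio[!rows$below_LOD]
  tier_result(sprintf("%s %s (all materials)", cell_line, endpoint),
              x[is.finite(x)], log_scale)
}

#' Tier 2: per-material exposed-versus-control tests
#'
#' As [tox_tier1] but differentiated by particle material (series of the
#' same material are pooled; dose and morphology still disregarded).
#' Materials whose observations are all below the LOD are returned as
#' non-evaluable with an explicit flag.
#'
#' @inheritParams tox_tier1
#' @return A named list of `"tier_result"` objects (class
#'   `"tier2_results"`), one per material present.
#' @export
tox_tier2 <- function(table, endpoint, cell_line, log_scale = FALSE) {
  rows <- subset_responses(table, endpoint, cell_line)
  materials <- unique(rows$material)
  out <- lapply(materials, function(mat) {
    sub <- rows[rows$material == mat, , drop = FALSE]
    if (nrow(sub) > 0 && all(sub$below_LOD)) {
      return(structure(list(group = sprintf("%s %s %s", cell_line, endpoint,
                                            mat),
                            n = 0L, mean_ratio = NA_real_,
                            ci95 = c(NA_real_, NA_real_),
                            p_vs_unity = NA_real_, significant = NA,
                            evaluable = FALSE,
                            reason = "all observations below LOD"),
                       class = "tier_result"))
    }
    x <- sub$ratio[!sub$below_LOD]
    tier_result(sprintf("%s %s %s", cell_line, endpoint, mat),
                x[is.finite(x)], log_scale)
  })
  structure(setNames(out, materials), class = "tier2_results")
}

#' @export
print.tier2_results <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Tier 3: linear dose-response regression
#'
#' Ordinary least-squares regression of the exposed/control ratio on one of
#' the dose metrics (number, mass or surface area).  A dose response is
#' declared when the slope coefficient is statistically significant
#' (p < 0.05, two-sided t test).  Sintered-particle points are included;
#' rows below the LOD or lacking the requested dose metric are dropped.
#' At least 3 distinct dose values are required; otherwise the result is
#' flagged non-evaluable.
#'
#' @inheritParams tox_tier1
#' @param dose_metric `"N"`, `"m"` or `"SA"`, selecting `dose_N`
#'   (#/cm^2), `dose_m` (ug/cm^2) or `dose_SA` (cm^2/cm^2).
#' @param material Optional material label for the differentiated analysis;
#'   `NULL` (default) pools all materials (grouped analysis).
#' @return An object of class `"dose_response"` with `slope`, `slope_se`,
#'   `slope_p`, `intercept`, `n`, `significant`, `evaluable` and the
#'   underlying `lm` fit (`model`).
#' @export
tox_tier3 <- function(table, endpoint, cell_line,
                      dose_metric = c("N", "m", "SA"), material = NULL,
                      log_scale = FALSE) {
  dose_metric <- match.arg(dose_metric)
  rows <- subset_responses(table, endpoint, cell_line)
  if (!is.null(material))
    rows <- rows[rows$material == material, , drop = FALSE]
  dose <- rows[[paste0("dose_", dose_metric)]]
  keep <- !rows$below_LOD & is.finite(dose) & is.finite(rows$ratio)
  rows <- rows[keep, , drop = FALSE]
  dose <- dose[keep]
  group <- sprintf("%s %s vs %s_dose%s", cell_line, endpoint, dose_metric,
                   if (is.null(material)) " (grouped)"
                   else paste0(" (", material, ")"))
  if (length(unique(dose)) < 3) {
    return(structure(list(group = group, dose_metric = dose_metric,
                          material = material, slope = NA_real_,
                          slope_se = NA_real_, slope_p = NA_real_,
                          intercept = NA_real_, n = nrow(rows),
                          significant = NA, evaluable = FALSE,
                          reason = "fewer than 3 distinct dose values",
                          model = NULL),
                     class = "dose_response"))
  }
  y <- if (log_scale) log(rows$ratio) else rows$ratio
  mod <- lm(y ~ dose)
  # noiseless input triggers lm's "essentially perfect fit" warning
  cf <- suppressWarnings(summary(mod)$coefficients)
  structure(list(group = group, dose_metric = dose_metric,
                 material = material,
                 slope = cf["dose", "Estimate"],
                 slope_se = cf["dose", "Std. Error"],
                 slope_p = cf["dose", "Pr(>|t|)"],
                 intercept = cf["(Intercept)", "Estimate"],
                 n = nrow(rows),
                 significant = cf["dose", "Pr(>|t|)"] < 0.05,
                 evaluable = TRUE, reason = NULL, model = mod),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  if (!x$evaluable) {
    cat(sprintf("%s: not evaluable (%s)\n", x$group, x$reason))
  } else {
    cat(sprintf("%s: slope = %.4g +/- %.3g, p = %.3g%s (n = %d)\n",
                x$group, x$slope, x$slope_se, x$slope_p,
                if (x$significant) " [dose response]" else "", x$n))
  }
  invisible(x)
}

#' ANCOVA: material-specific versus common dose-response slope
#'
#' Compares a model with material-specific slopes
#' (`ratio ~ dose * material`) against the common-slope model
#' (`ratio ~ dose + material`) by an F test on the dose-by-material
#' interaction.  Requires at least 2 materials, each with at least 3
#' distinct dose values.
#'
#' @inheritParams tox_tier3
#' @return An object of class `"ancova_result"` with the interaction F
#'   statistic, degrees of freedom, p value and the two fitted models.
#' @export
tox_ancova <- function(table, endpoint, cell_line,
                       dose_metric = c("N", "m", "SA")) {
  dose_metric <- match.arg(dose_metric)
  rows <- subset_responses(table, endpoint, cell_line)
  dose <- rows[[paste0("dose_", dose_metric)]]
  keep <- !rows$below_LOD & is.finite(dose) & is.finite(rows$ratio)
  rows <- rows[keep, , drop = FALSE]
  dose <- dose[keep]
  ok <- vapply(split(dose, rows$material),
               function(d) length(unique(d)) >= 3, logical(1))
  if (sum(ok) < 2)
    stop_invalid("ANCOVA needs >= 2 materials with >= 3 distinct dose ",
                 "levels each")
  sel <- rows$material %in% names(ok)[ok]
  rows <- rows[sel, , drop = FALSE]
  dose <- dose[sel]
  material <- factor(rows$material)
  full <- lm(rows$ratio ~ dose * material)
  reduced <- lm(rows$ratio ~ dose + material)
  cmp <- anova(reduced, full)
  structure(list(dose_metric = dose_metric,
                 materials = levels(material),
                 F = cmp$F[2], df = c(cmp$Df[2], cmp$Res.Df[2]),
                 p_interaction = cmp$`Pr(>F)`[2],
                 n = nrow(rows), full = full, reduced = reduced),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf(
    "ANCOVA (%s_dose, materials: %s): interaction F(%d, %d) = %.3g, p = %.3g\n",
    x$dose_metric, paste(x$materials, collapse = ", "),
    x$df[1], x$df[2], x$F, x$p_interaction))
  invisible(x)
}
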