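# Gas-pocket HU statistics, scanner calibration, GIGED and RED override.

#' HU statistics of a contoured structure
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' the CT values of the voxels inside a mask.
#'
#' @param ct `scalar_volume` in HU.
#' @param mask non-empty [binary_mask()] on the same grid.
#' @return List with `mean`, `sd`, `n`.
#' @export
structure_hu_stats <- function(ct, mask) {
  stopifnot(inherits(ct, "scalar_volume"), ct$unit == "HU")
  .check_same_grid(ct, mask, "CT and mask")
  v <- ct$values[mask$member]
  if (length(v) == 0L) stop("empty structure")
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Kolmogorov-Smirnov normality check
#'
#' Two-sided KS p-value of a sample against a normal distribution with the
#' sample's own mean and SD. Because the parameters are estimated from the
#' data, the plain KS p-value is anti-conservative (the Lilliefors caveat);
#' it is reported as-is, matching common clinical usage.
#'
#' @param values numeric vector, length >= 3, non-constant.
#' @param alpha decision level (default 0.05).
#' @return List with `p_value`, `normal` (logical decision at `alpha`).
#' @export
ks_normality <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("constant input: normality test undefined")
  p <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value)
  list(p_value = p, normal = p > alpha)
}

#' Wilcoxon-Mann-Whitney test for two unpaired samples
#'
#' Two-sided p-value. Exact enumeration of the U distribution when the
#' smaller sample has at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie-corrected variance (no
#' continuity correction, so identical samples give p = 1).
#'
#' @param a,b numeric samples, each non-empty.
#' @return Two-sided p-value.
#' @export
mann_whitney_unpaired <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)$p.value)
}

#' CT calibration curve: linear HU-to-RED segment over -1000 to 0 HU
#'
#' Ordinary least squares through the calibration points whose HU lies in
#' the fit domain; points outside the domain are ignored.
#'
#' @param points data frame with columns `hu`, `red` (as returned by
#'   [read_calibration_table()]), or a 2-column matrix.
#' @param fit_domain HU interval used for the fit.
#' @return An object of class `calibration_curve` with fields `points`,
#'   `slope` (RED per HU), `intercept` (RED at 0 HU), `fit_domain`.
#' @export
fit_calibration_segment <- function(points, fit_domain = c(-1000, 0)) {
  if (is.matrix(points)) points <- data.frame(hu = points[, 1], red = points[, 2])
  stopifnot(all(c("hu", "red") %in% names(points)))
  keep <- points$hu >= fit_domain[1] & points$hu <= fit_domain[2]
  if (sum(keep) < 2L)
    stop("need at least 2 calibration points inside the fit domain")
  fit <- stats::lm(red ~ hu, data = points[keep, , drop = FALSE])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) stop("calibration slope must be positive (RED rises with HU)")
  structure(list(points = points[keep, , drop = FALSE], slope = slope,
                 intercept = intercept, fit_domain = fit_domain),
            class = "calibration_curve")
}

#' Default two-point calibration: (-1000 HU, 0.0) and (0 HU, 1.0)
#'
#' The identity-like line RED = 1 + HU/1000, which maps -620 HU to 0.38.
#' Users should supply their scanner's measured table where available.
#'
#' @return A `calibration_curve`.
#' @export
default_calibration <- function() {
  fit_calibration_segment(data.frame(hu = c(-1000, 0), red = c(0, 1)))
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> RED = %.6g + %.6g * HU on [%g, %g] HU (%d points)\n",
              x$intercept, x$slope, x$fit_domain[1], x$fit_domain[2],
              nrow(x$points)))
  invisible(x)
}

#' Convert HU to relative electron density on a calibration curve
#'
#' @param curve a `calibration_curve`.
#' @param hu numeric HU value(s); values outside the fit domain trigger a
#'   warning and are linearly extrapolated.
#' @return RED value(s), clamped below at 0.
#' @export
hu_to_red <- function(curve, hu) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(hu < curve$fit_domain[1] | hu > curve$fit_domain[2]))
    warning("HU outside calibration fit domain; extrapolating the linear segment")
  pmax(curve$slope * hu + curve$intercept, 0)
}

# Silent volume-scale conversion used by the plan-triplet builder: soft
# tissue sits slightly above 0 HU, so the segment is extended without the
# per-voxel warning.
.ct_to_red_volume <- function(curve, ct) {
  scalar_volume(pmax(curve$slope * ct$values + curve$intercept, 0),
                ct$grid, unit = "RED")
}

#' Gastrointestinal gas relative electron density (GIGED)
#'
#' The pooled mean gas-pocket HU converted through the calibration curve
#' and reported to two decimals.
#'
#' @param curve a `calibration_curve`.
#' @param mean_hu pooled mean HU of the GAS structure (default -620 HU).
#' @return GIGED as a 2-decimal RED value.
#' @export
giged <- function(curve = default_calibration(), mean_hu = -620) {
  round(hu_to_red(curve, mean_hu), 2)
}

#' Override the relative electron density inside a mask
#'
#' Returns a copy of the RED volume with member voxels set to `value`;
#' the input is not modified.
#'
#' @param red `scalar_volume` in RED.
#' @param mask [binary_mask()] on the same grid.
#' @param value replacement RED (>= 0).
#' @return A new `scalar_volume` in RED.
#' @export
override_red <- function(red, mask, value) {
  stopifnot(inherits(red, "scalar_volume"), red$unit == "RED", value >= 0)
  .check_same_grid(red, mask, "RED volume and mask")
  out <- red$values
  out[mask$member] <- value
  scalar_volume(out, red$grid, unit = "RED")
}

#' Cohort gas-HU report
#'
#' Per-structure HU statistics over a cohort of cases, the per-structure
#' normality p-values of the distribution of per-patient mean HU, the
#' pairwise Mann-Whitney comparisons between organ gas compartments, and
#' the pooled GIGED.
#'
#' For each case the GAS structure and its per-organ partitions are
#' rasterized (GAS, and the intersections of GAS with ST, SB and LB giving
#' STG, SBG, LBG); gas outside the three organs is reported as the
#' residual-GAS partition.
#'
#' @param cases list of `patient_case` objects with GAS, ST, SB and LB
#'   structures contoured.
#' @param calibration a `calibration_curve`.
#' @return A list of class `gas_hu_report`: `structures` (data frame with
#'   mean/sd/n of pooled voxels and mean-of-patient-means per structure),
#'   `normality_p` (named, KS p on per-patient means), `pairwise_p`
#'   (named Mann-Whitney p-values), `giged`, `pooled_gas_mean_hu`.
#' @export
gas_hu_report <- function(cases, calibration = default_calibration()) {
  stopifnot(length(cases) >= 1)
  parts <- c("GAS", "STG", "SBG", "LBG", "GASresidual")
  per_patient <- list()
  pooled <- stats::setNames(vector("list", length(parts)), parts)
  for (case in cases) {
    stopifnot(inherits(case, "patient_case"))
    g <- case$ct$grid
    gas <- rasterize_structure(case$structures$GAS, g)
    organ_masks <- lapply(case$structures[c("ST", "SB", "LB")],
                          rasterize_structure, grid = g)
    m <- list(
      GAS = gas,
      STG = mask_intersection(gas, organ_masks$ST),
      SBG = mask_intersection(gas, organ_masks$SB),
      LBG = mask_intersection(gas, organ_masks$LB))
    resid <- gas$member & !(m$STG$member | m$SBG$member | m$LBG$member)
    m$GASresidual <- binary_mask(resid, g)
    row <- vapply(parts, function(p) {
      v <- case$ct$values[m[[p]]$member]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    per_patient[[length(per_patient) + 1L]] <- row
    for (p in parts)
      pooled[[p]] <- c(pooled[[p]], case$ct$values[m[[p]]$member])
  }
  pm <- do.call(rbind, per_patient)
  structures <- data.frame(
    structure = parts,
    mean_hu = vapply(pooled, function(v) if (length(v)) mean(v) else NA_real_, numeric(1)),
    sd_hu = vapply(pooled, function(v) if (length(v) > 1) stats::sd(v) else NA_real_, numeric(1)),
    n_voxels = vapply(pooled, length, integer(1)),
    mean_of_patient_means = colMeans(pm, na.rm = TRUE),
    row.names = NULL)
  normality_p <- vapply(c("GAS", "STG", "SBG", "LBG"), function(p) {
    v <- pm[, p]; v <- v[!is.na(v)]
    if (length(v) >= 3 && stats::sd(v) > 0) ks_normality(v)$p_value else NA_real_
  }, numeric(1))
  pairs <- list(c("STG", "LBG"), c("STG", "SBG"), c("SBG", "LBG"))
  pairwise_p <- vapply(pairs, function(pr) {
    x <- pm[, pr[1]]; y <- pm[, pr[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) && length(y)) mann_whitney_unpaired(x, y) else NA_real_
  }, numeric(1))
  names(pairwise_p) <- vapply(pairs, paste, character(1), collapse = "vs")
  pooled_gas <- structures$mean_hu[structures$structure == "GAS"]
  structure(list(structures = structures, normality_p = normality_p,
                 pairwise_p = pairwise_p,
                 pooled_gas_mean_hu = pooled_gas,
                 giged = giged(calibration, pooled_gas)),
            class = "gas_hu_report")
}

#' @export
print.gas_hu_report <- function(x, ...) {
  cat("<gas_hu_report>\n")
  print(x$structures, digits = 4)
  cat("KS normality p (per-patient means):",
      paste(sprintf("%s=%.2f", names(x$normality_p), x$normality_p), collapse = ", "), "\n")
  cat("Mann-Whitney p:",
      paste(sprintf("%s=%.2f", names(x$pairwise_p), x$pairwise_p), collapse = ", "), "\n")
  cat(sprintf("pooled GAS mean %.1f HU -> GIGED %.2f\n",
              x$pooled_gas_mean_hu, x$giged))
  invisible(x)
}
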