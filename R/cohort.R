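# Cohort-level aggregation: GPR summaries, GPR-vs-AGV correlation, linear
# trends and the AGV threshold at which the fitted GPR crosses 90%.

.COMPARISONS <- c(WPLANvsAPLAN = "gprWA", WPLANvsGPLAN = "gprWG",
                  GPLANvsAPLAN = "gprGA")

.gpr_column <- function(comparison) {
  col <- .COMPARISONS[comparison]
  if (is.na(col)) stop(sprintf("unknown comparison '%s' (expected %s)",
                               comparison, paste(names(.COMPARISONS), collapse = ", ")))
  unname(col)
}

.check_records <- function(records) {
  need <- c("patient", unname(.COMPARISONS), "agv_cc")
  if (!all(need %in% names(records)))
    stop(sprintf("records need columns: %s", paste(need, collapse = ", ")))
  for (col in unname(.COMPARISONS))
    if (any(records[[col]] < 0 | records[[col]] > 100))
      stop("GPR values must lie in [0, 100]")
  if (any(records$agv_cc < 0)) stop("AGV must be non-negative")
  invisible(records)
}

#' The published 21-patient GPR / AGV cohort table
#'
#' Per-patient mean gamma passing rates (1%/1 mm, % rounded to integers as
#' published) for the three density-override plan comparisons, and the
#' Active Gas Volume in cc.
#'
#' @return Data frame with columns `patient`, `gprWA` (WPLANvsAPLAN),
#'   `gprWG` (WPLANvsGPLAN), `gprGA` (GPLANvsAPLAN), `agv_cc`; 21 rows.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_gpr_agv.csv", package = "gasdose",
                      mustWork = TRUE)
  read_agv_records(path)
}

#' Read / write AGV record tables
#'
#' CSV schema: `patient,gprWA,gprWG,gprGA,agv_cc`.
#'
#' @param file CSV path.
#' @return `read_agv_records` returns the validated data frame.
#' @export
read_agv_records <- function(file) {
  rec <- utils::read.csv(file, stringsAsFactors = FALSE)
  .check_records(rec)
}

#' @rdname read_agv_records
#' @param records AGV records data frame.
#' @export
write_agv_records <- function(records, file) {
  .check_records(records)
  utils::write.csv(records, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Cohort GPR summary for one plan comparison
#'
#' @param records AGV records data frame.
#' @param comparison one of `"WPLANvsAPLAN"`, `"WPLANvsGPLAN"`,
#'   `"GPLANvsAPLAN"`.
#' @return List with `mean` (rounded to integer %, as reported), `min`,
#'   `max`, and `mean_raw`.
#' @export
cohort_summary <- function(records, comparison) {
  .check_records(records)
  g <- records[[.gpr_column(comparison)]]
  stopifnot(length(g) >= 1)
  list(mean = round(mean(g)), min = min(g), max = max(g), mean_raw = mean(g))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return Correlation coefficient (unrounded; report to 2 decimals).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  stats::cor(x, y)
}

#' Linear GPR-vs-AGV trend and the 90%-GPR AGV threshold
#'
#' Fits GPR (%) against AGV (cc) by ordinary least squares (the line drawn
#' through the cohort scatter) and locates the AGV at which the fitted
#' trend crosses a GPR of 90%, the plan-acceptance level recommended for
#' IMRT gamma tests.
#'
#' Two threshold conventions are available. `"inverse"` (default) regresses
#' AGV on GPR and evaluates the fit at 90% — the calibration-style
#' interpolation that treats AGV as the quantity being solved for.
#' `"forward"` inverts the GPR-on-AGV line in closed form,
#' `(90 - intercept) / slope`. Both are reported; `agv_at_90` follows the
#' chosen method.
#'
#' @param records AGV records data frame.
#' @param comparison plan comparison name.
#' @param threshold_method `"inverse"` or `"forward"`.
#' @return Object of class `trend_fit`: `comparison`, `slope` (%/cc),
#'   `intercept` (%), `r_squared`, `pearson_r`, `agv_at_90` (cc, `NA` with
#'   `threshold_defined = FALSE` when the trend is non-decreasing),
#'   `agv_at_90_forward`, `agv_at_90_inverse`, `threshold_method`.
#' @export
fit_trend <- function(records, comparison,
                      threshold_method = c("inverse", "forward")) {
  threshold_method <- match.arg(threshold_method)
  .check_records(records)
  stopifnot(nrow(records) >= 3)
  g <- records[[.gpr_column(comparison)]]
  a <- records$agv_cc
  fwd <- stats::lm(g ~ a)
  slope <- unname(stats::coef(fwd)[2])
  intercept <- unname(stats::coef(fwd)[1])
  if (slope == 0) stop("degenerate fit: zero slope")
  r <- pearson_r(a, g)
  defined <- slope < 0
  fwd90 <- if (defined) (90 - intercept) / slope else NA_real_
  inv <- stats::lm(a ~ g)
  inv90 <- if (defined) unname(stats::coef(inv)[1] + 90 * stats::coef(inv)[2])
           else NA_real_
  structure(list(
    comparison = comparison, slope = slope, intercept = intercept,
    r_squared = r^2, pearson_r = r,
    agv_at_90 = if (threshold_method == "inverse") inv90 else fwd90,
    agv_at_90_forward = fwd90, agv_at_90_inverse = inv90,
    threshold_method = threshold_method, threshold_defined = defined),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s: GPR = %.2f %+.4f * AGV (R2 %.2f, r %.2f)\n",
              x$comparison, x$intercept, x$slope, x$r_squared, x$pearson_r))
  if (x$threshold_defined) {
    cat(sprintf("  GPR falls below 90%% at AGV ~ %d cc (%s interpolation)\n",
                round(x$agv_at_90), x$threshold_method))
  } else {
    cat("  non-decreasing trend: 90% threshold undefined\n")
  }
  invisible(x)
}
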