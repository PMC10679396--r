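# Cumulative DVH construction, Dx/Vx metrics and the Active Gas Volume.

#' Cumulative dose-volume histogram of a structure
#'
#' Exact voxel counting: the curve gives, at each dose level, the fraction
#' of the structure's volume receiving at least that dose. No sub-voxel
#' partial-volume weighting is applied.
#'
#' @param dose `scalar_volume` in Gy.
#' @param mask non-empty [binary_mask()] on the dose grid.
#' @param bin_width histogram bin width in Gy (default 0.01).
#' @param structure structure name carried through to the metrics.
#' @return Object of class `cumulative_dvh` with `edges` (Gy),
#'   `fraction` (volume fraction >= edge), `total_cc`, `structure`,
#'   and the voxel doses (`doses`) used to build it.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.01, structure = "structure") {
  stopifnot(inherits(dose, "scalar_volume"), dose$unit == "Gy", bin_width > 0)
  .check_same_grid(dose, mask, "dose and mask")
  v <- dose$values[mask$member]
  if (length(v) == 0L) stop("empty structure")
  edges <- seq(0, max(v) + 2 * bin_width, by = bin_width)
  # fraction of voxels with dose >= edge
  cnt <- length(v) - findInterval(edges - 1e-12, sort(v))
  structure(list(structure = structure, edges = edges,
                 fraction = cnt / length(v),
                 total_cc = mask_volume_cc(mask),
                 bin_width = bin_width, doses = v),
            class = "cumulative_dvh")
}

#' Dose covering a given volume fraction (Dx)
#'
#' The highest dose level at which the covered-volume fraction is still at
#' least `q` percent, interpolated linearly between histogram bins.
#'
#' @param dvh a [cumulative_dvh()].
#' @param q volume percentage in (0, 100]; `q = 98` gives D98.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, q) {
  stopifnot(inherits(dvh, "cumulative_dvh"), q > 0, q <= 100)
  target <- q / 100
  f <- dvh$fraction; e <- dvh$edges
  i <- which(f >= target - 1e-12)
  if (!length(i)) return(e[1])
  i <- max(i)
  if (i == length(e) || f[i] <= target) return(e[i])
  # interpolate on the falling curve between edge i and i+1
  drop <- f[i] - f[i + 1]
  if (drop <= 0) return(e[i])
  e[i] + (f[i] - target) / drop * (e[i + 1] - e[i])
}

#' Volume fraction receiving at least a dose (Vd)
#'
#' @param dvh a [cumulative_dvh()].
#' @param d dose in Gy (>= 0).
#' @return Covered volume as % of the structure volume.
#' @export
volume_at_dose <- function(dvh, d) {
  stopifnot(inherits(dvh, "cumulative_dvh"), d >= 0)
  100 * mean(dvh$doses >= d - 1e-12)
}

#' DVH metrics of a structure (D98/D50/D2, min/mean/max, optional V95)
#'
#' @param dose `scalar_volume` in Gy.
#' @param mask non-empty [binary_mask()].
#' @param prescription prescription dose in Gy; when given, `v95` (% of
#'   the structure receiving at least 95% of prescription, the PTV
#'   coverage metric) is included.
#' @param bin_width DVH bin width in Gy.
#' @param structure structure name.
#' @return Object of class `dvh_metrics`.
#' @export
dvh_metrics <- function(dose, mask, prescription = NA_real_, bin_width = 0.01,
                        structure = "structure") {
  dvh <- cumulative_dvh(dose, mask, bin_width, structure)
  v <- dvh$doses
  out <- list(structure = structure,
              d98 = dose_at_volume(dvh, 98),
              d50 = dose_at_volume(dvh, 50),
              d2 = dose_at_volume(dvh, 2),
              dmin = min(v), dmean = mean(v), dmax = max(v),
              v95 = if (is.na(prescription)) NA_real_ else
                volume_at_dose(dvh, 0.95 * prescription),
              prescription = prescription)
  class(out) <- "dvh_metrics"
  out
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("<dvh_metrics> %s: D98 %.2f, D50 %.2f, D2 %.2f Gy; min/mean/max %.2f/%.2f/%.2f Gy",
              x$structure, x$d98, x$d50, x$d2, x$dmin, x$dmean, x$dmax))
  if (!is.na(x$v95)) cat(sprintf("; V95 %.1f%%", x$v95))
  cat("\n")
  invisible(x)
}

#' Field-wise DVH metric differences (first minus second)
#'
#' @param metrics_a,metrics_b `dvh_metrics` for the same structure; the
#'   sign convention is first-named plan minus second.
#' @return Named numeric vector of differences.
#' @export
dvh_delta <- function(metrics_a, metrics_b) {
  stopifnot(inherits(metrics_a, "dvh_metrics"), inherits(metrics_b, "dvh_metrics"))
  if (!identical(metrics_a$structure, metrics_b$structure))
    stop("DVH metrics refer to different structures")
  fields <- c("d98", "d50", "d2", "dmin", "dmean", "dmax", "v95")
  vapply(fields, function(f) metrics_a[[f]] - metrics_b[[f]], numeric(1))
}

#' Active Gas Volume (AGV)
#'
#' Volume, in cc, of the gas structure intersected with the isodose region
#' at a fraction (default 5%) of the prescription dose: the gas actually
#' traversed by the beams. The dose threshold is inclusive.
#'
#' @param gas [binary_mask()] of the GAS structure.
#' @param dose `scalar_volume` in Gy on the same grid (resample first via
#'   [resample_to_grid()] if needed).
#' @param prescription prescription dose in Gy (> 0).
#' @param isodose_fraction fraction of prescription defining the active
#'   region (default 0.05).
#' @return AGV in cc.
#' @export
compute_agv <- function(gas, dose, prescription, isodose_fraction = 0.05) {
  stopifnot(inherits(gas, "binary_mask"), inherits(dose, "scalar_volume"),
            dose$unit == "Gy", prescription > 0)
  .check_same_grid(gas, dose, "gas mask and dose")
  active <- gas$member & (dose$values >= isodose_fraction * prescription - 1e-12)
  sum(active) * prod(gas$grid$spacing) / 1000
}
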