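# 2-D gamma-index dose comparison on the orthogonal planes through the
# target centroid, with TG-218-style global normalization.

#' Gamma-analysis acceptance criteria
#'
#' @param dose_tol dose-difference tolerance, % of the normalization dose
#'   (global maximum of the reference plane).
#' @param dta distance-to-agreement tolerance in mm.
#' @param low_dose_threshold reference pixels below this % of the
#'   normalization dose are excluded from scoring.
#' @param search_radius_factor search radius as a multiple of `dta`.
#' @param step_factor interpolation step of the evaluated distribution as
#'   a fraction of `dta`.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol = 1, dta = 1, low_dose_threshold = 10,
                           search_radius_factor = 3, step_factor = 0.1) {
  stopifnot(dose_tol > 0, dta > 0, low_dose_threshold > 0,
            search_radius_factor > 0, step_factor > 0)
  structure(list(dose_tol = dose_tol, dta = dta,
                 low_dose_threshold = low_dose_threshold,
                 search_radius_factor = search_radius_factor,
                 step_factor = step_factor),
            class = "gamma_criteria")
}

# Bilinear interpolation of matrix m (spacing dx, dy; pixel (1,1) centre at
# (0,0)) at query points; NA outside the extent.
.interp2 <- function(m, dx, dy, qx, qy) {
  nx <- nrow(m); ny <- ncol(m)
  gx <- qx / dx; gy <- qy / dy
  valid <- gx >= 0 & gx <= nx - 1 & gy >= 0 & gy <= ny - 1
  out <- rep(NA_real_, length(qx))
  if (!any(valid)) return(out)
  gx <- gx[valid]; gy <- gy[valid]
  x0 <- pmin(floor(gx), nx - 2); fx <- gx - x0
  y0 <- pmin(floor(gy), ny - 2); fy <- gy - y0
  if (nx == 1) { x0 <- rep(0, length(gx)); fx <- rep(0, length(gx)) }
  if (ny == 1) { y0 <- rep(0, length(gy)); fy <- rep(0, length(gy)) }
  i00 <- x0 + y0 * nx + 1
  v <- m[i00] * (1 - fx) * (1 - fy)
  if (nx > 1) v <- v + m[i00 + 1] * fx * (1 - fy)
  if (ny > 1) v <- v + m[i00 + nx] * (1 - fx) * fy
  if (nx > 1 && ny > 1) v <- v + m[i00 + nx + 1] * fx * fy
  out[valid] <- v
  out
}

#' 2-D gamma analysis between two planar dose distributions
#'
#' For every reference pixel at or above the low-dose threshold, the gamma
#' index is the minimum over nearby evaluated positions of
#' `sqrt((dose difference / dose tolerance)^2 + (distance / dta)^2)`,
#' with the evaluated distribution bilinearly interpolated on a grid of
#' `step_factor * dta` within `search_radius_factor * dta` of the pixel.
#' Offsets are visited in order of increasing distance with per-pixel
#' early termination (a pixel whose current gamma cannot be improved by
#' more distant offsets stops searching), which returns the same minimum
#' as the full scan. The dose tolerance and threshold are percentages of
#' the global maximum of the reference plane.
#'
#' @param reference,evaluated numeric matrices of equal dimension, dose
#'   in Gy; `reference` defines the included pixels and the normalization.
#' @param spacing pixel pitch in mm, length 1 or 2 `(dx, dy)`.
#' @param criteria a [gamma_criteria()].
#' @return List with `gamma` (matrix, `NA` below threshold), `gpr`
#'   (passing rate in %), `included` (logical matrix).
#' @export
gamma_2d <- function(reference, evaluated, spacing = c(1, 1),
                     criteria = gamma_criteria()) {
  stopifnot(is.matrix(reference), is.matrix(evaluated))
  if (!all(dim(reference) == dim(evaluated)))
    stop("reference and evaluated planes differ in shape")
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  refmax <- max(reference)
  if (refmax <= 0) stop("reference maximum dose must be positive")
  dd <- criteria$dose_tol / 100 * refmax
  thr <- criteria$low_dose_threshold / 100 * refmax
  included <- reference >= thr
  if (!any(included)) stop("no pixels above dose threshold")
  dta <- criteria$dta
  step <- criteria$step_factor * dta
  radius <- criteria$search_radius_factor * dta
  nsteps <- floor(radius / step)
  off <- expand.grid(ox = (-nsteps:nsteps) * step, oy = (-nsteps:nsteps) * step)
  r2 <- (off$ox^2 + off$oy^2) / dta^2
  keep <- r2 <= (radius / dta)^2 + 1e-12
  off <- off[keep, ]; r2 <- r2[keep]
  ord <- order(r2)
  off <- off[ord, ]; r2 <- r2[ord]
  idx <- which(included)
  px <- ((idx - 1) %% nrow(reference)) * spacing[1]
  py <- ((idx - 1) %/% nrow(reference)) * spacing[2]
  refv <- reference[idx]
  best <- rep(Inf, length(idx))
  active <- seq_along(idx)
  # chunk offsets into distance shells so the vectorised pass can retire
  # pixels between shells
  shell <- findInterval(sqrt(r2), seq(0, radius / dta + 1, by = 0.25))
  for (s in unique(shell)) {
    sel <- which(shell == s)
    rmin2 <- min(r2[sel])
    active <- active[best[active] > rmin2]
    if (!length(active)) break
    for (m in sel) {
      ev <- .interp2(evaluated, spacing[1], spacing[2],
                     px[active] + off$ox[m], py[active] + off$oy[m])
      ok <- !is.na(ev)
      if (!any(ok)) next
      cand <- ((ev[ok] - refv[active][ok]) / dd)^2 + r2[m]
      upd <- cand < best[active][ok]
      if (any(upd)) {
        tgt <- active[ok][upd]
        best[tgt] <- cand[upd]
      }
    }
  }
  gamma_vals <- sqrt(best)
  gmap <- matrix(NA_real_, nrow(reference), ncol(reference))
  gmap[idx] <- gamma_vals
  gpr <- 100 * mean(gamma_vals <= 1 + 1e-9)
  list(gamma = gmap, gpr = gpr, included = included)
}

#' Extract the axial, sagittal and coronal planes through a point
#'
#' Nearest-slice extraction (no interpolation): each plane is the stored
#' grid plane closest to the point along the corresponding axis.
#'
#' @param dose a `scalar_volume`.
#' @param point numeric length-3 position (x, y, z) in mm, inside the grid.
#' @return Named list `axial`, `sagittal`, `coronal`; each with `values`
#'   (matrix), `spacing` (mm), and `index` of the extracted slice.
#' @export
extract_orthogonal_planes <- function(dose, point) {
  stopifnot(inherits(dose, "scalar_volume"), length(point) == 3)
  g <- dose$grid
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$shape - 0.5) * g$spacing
  if (any(point < lo | point > hi))
    stop("point lies outside the dose grid")
  nearest <- pmin(pmax(round((point - g$origin) / g$spacing) + 1, 1), g$shape)
  list(
    axial = list(values = dose$values[, , nearest[3]],
                 spacing = g$spacing[1:2], index = nearest[3]),
    sagittal = list(values = dose$values[nearest[1], , ],
                    spacing = g$spacing[2:3], index = nearest[1]),
    coronal = list(values = dose$values[, nearest[2], ],
                   spacing = g$spacing[c(1, 3)], index = nearest[2]))
}

#' Compare two plans of a case by planar gamma analysis
#'
#' The three orthogonal planes through the GTV centroid are extracted from
#' both dose volumes; a 2-D gamma analysis is run per plane with `plan_a`
#' (the first-named plan of the comparison) as reference, and the mean of
#' the three gamma passing rates is reported.
#'
#' @param case a `patient_case` with both plans and a GTV structure.
#' @param plan_a,plan_b plan names in `case$doses`; `plan_a` is the
#'   reference.
#' @param criteria a [gamma_criteria()].
#' @return An object of class `gamma_result`: `comparison`, `planes`
#'   (per-plane gamma maps and GPRs), `gpr` (per-plane, %), `mean_gpr`.
#' @export
compare_plans <- function(case, plan_a, plan_b, criteria = gamma_criteria()) {
  stopifnot(inherits(case, "patient_case"))
  for (p in c(plan_a, plan_b))
    if (is.null(case$doses[[p]])) stop(sprintf("plan '%s' missing from case", p))
  if (is.null(case$structures$GTV)) stop("GTV structure missing from case")
  dose_a <- case$doses[[plan_a]]
  dose_b <- case$doses[[plan_b]]
  gtv <- rasterize_structure(case$structures$GTV, case$ct$grid)
  centroid <- mask_centroid(gtv)
  pa <- extract_orthogonal_planes(dose_a, centroid)
  pb <- extract_orthogonal_planes(dose_b, centroid)
  planes <- lapply(names(pa), function(nm) {
    g <- gamma_2d(pa[[nm]]$values, pb[[nm]]$values, pa[[nm]]$spacing, criteria)
    c(g, list(plane = nm))
  })
  names(planes) <- names(pa)
  gpr <- vapply(planes, `[[`, numeric(1), "gpr")
  structure(list(comparison = paste0(plan_a, "vs", plan_b), planes = planes,
                 gpr = gpr, mean_gpr = mean(gpr), centroid = centroid),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %s: axial %.1f%%, sagittal %.1f%%, coronal %.1f%% -> mean GPR %.1f%%\n",
              x$comparison, x$gpr[1], x$gpr[2], x$gpr[3], x$mean_gpr))
  invisible(x)
}
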