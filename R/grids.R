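#' Axis-aligned voxel grid
#'
#' Geometry shared by CT, relative-electron-density and dose volumes:
#' an axial, axis-aligned grid described by the physical position of the
#' first voxel centre, the voxel pitch, and the voxel counts. The centre
#' of voxel `(i, j, k)` (1-based) is `origin + (i-1, j-1, k-1) * spacing`,
#' in mm, patient coordinates, with `z` the slice axis.
#'
#' @param origin numeric length-3, position (x, y, z) of the first voxel
#'   centre in mm.
#' @param spacing numeric length-3, voxel pitch (dx, dy, dz) in mm,
#'   strictly positive.
#' @param shape integer length-3, voxel counts (nx, ny, nz), strictly
#'   positive.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, shape) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(shape) == 3L)
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  if (any(spacing <= 0)) stop("grid spacing must be strictly positive")
  if (any(shape <= 0L)) stop("grid shape must be strictly positive")
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel-centre coordinates along each axis
#'
#' @param grid a [voxel_grid()].
#' @return List with numeric vectors `x`, `y`, `z` of voxel-centre
#'   positions in mm.
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}

#' Do two grids describe the same geometry?
#'
#' @param a,b [voxel_grid()] objects.
#' @param tol absolute tolerance in mm.
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

.check_same_grid <- function(a, b, what = "objects") {
  if (!grids_equal(a$grid, b$grid))
    stop(sprintf("%s are defined on different grids", what))
  invisible(TRUE)
}

#' Scalar voxel volume (HU, RED or Gy)
#'
#' @param values numeric 3-D array with `dim == grid$shape`.
#' @param grid a [voxel_grid()].
#' @param unit one of `"HU"`, `"RED"`, `"Gy"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid, unit = c("HU", "RED", "Gy")) {
  unit <- match.arg(unit)
  stopifnot(inherits(grid, "voxel_grid"))
  values <- array(as.numeric(values), dim = grid$shape)
  if (any(!is.finite(values))) stop("volume values must be finite")
  if (unit == "HU" && any(values < -1024))
    stop("HU values below -1024 are not physical")
  if (unit != "HU" && any(values < 0))
    stop(sprintf("%s values must be non-negative", unit))
  structure(list(grid = grid, values = values, unit = unit),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume:%s> range [%.4g, %.4g]\n",
              x$unit, min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Binary voxel mask
#'
#' @param member logical 3-D array with `dim == grid$shape`.
#' @param grid a [voxel_grid()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(member, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  member <- array(as.logical(member), dim = grid$shape)
  if (any(is.na(member))) stop("mask membership must be TRUE/FALSE")
  structure(list(grid = grid, member = member), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d member voxels (%.3f cc)\n",
              sum(x$member), mask_volume_cc(x)))
  invisible(x)
}

# Even-odd point-in-polygon for a matrix of points, vectorised over points.
# Half-open edge convention (lower vertex inclusive) via the strict/non-strict
# crossing test, so a ray through a vertex is counted once.
.points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py[crosses] - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      idx <- which(crosses)
      flip <- px[idx] < xint
      inside[idx[flip]] <- !inside[idx[flip]]
    }
    j <- i
  }
  inside
}

#' Rasterize a planar-contour structure onto a voxel grid
#'
#' Voxel-centre inclusion under the even-odd rule: a voxel belongs to the
#' mask iff its centre lies inside an odd number of the structure's
#' polygons on that slice. Multiple polygons on one slice are combined by
#' even-odd parity (so nested contours cut holes, disjoint pockets union).
#'
#' @param structure list of contours; each contour a numeric matrix with
#'   columns (x, y, z) in mm, at least 3 vertices, planar with constant z.
#'   An empty list yields an all-`FALSE` mask.
#' @param grid target [voxel_grid()].
#' @return A [binary_mask()].
#' @export
rasterize_structure <- function(structure, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  member <- array(FALSE, dim = grid$shape)
  if (length(structure) == 0L)
    return(binary_mask(member, grid))
  ax <- grid_axes(grid)
  for (contour in structure) {
    contour <- as.matrix(contour)
    if (nrow(contour) < 3L) stop("each contour needs at least 3 vertices")
    zs <- contour[, 3]
    if (diff(range(zs)) > 1e-6)
      stop("contour is not planar in z")
    z <- zs[1]
    k <- round((z - grid$origin[3]) / grid$spacing[3]) + 1
    if (k < 1 || k > grid$shape[3] ||
        abs(z - ax$z[max(1L, min(grid$shape[3], k))]) > grid$spacing[3] / 2 + 1e-9)
      stop(sprintf("contour plane z = %.3f mm does not align with any slice", z))
    # drop duplicated closing vertex if present
    vx <- contour[, 1]; vy <- contour[, 2]
    if (vx[1] == vx[length(vx)] && vy[1] == vy[length(vy)]) {
      vx <- vx[-length(vx)]; vy <- vy[-length(vy)]
    }
    # restrict the point test to the polygon bounding box
    ix <- which(ax$x >= min(vx) - grid$spacing[1] & ax$x <= max(vx) + grid$spacing[1])
    iy <- which(ax$y >= min(vy) - grid$spacing[2] & ax$y <= max(vy) + grid$spacing[2])
    if (!length(ix) || !length(iy)) next
    pts <- expand.grid(x = ax$x[ix], y = ax$y[iy])
    inside <- .points_in_polygon(pts$x, pts$y, vx, vy)
    sub <- member[ix, iy, k]
    member[ix, iy, k] <- xor(sub, array(inside, dim = c(length(ix), length(iy))))
  }
  binary_mask(member, grid)
}

#' Mask intersection
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return A [binary_mask()] whose members belong to both inputs.
#' @export
mask_intersection <- function(a, b) {
  .check_same_grid(a, b, "masks")
  binary_mask(a$member & b$member, a$grid)
}

#' Mask union
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return A [binary_mask()] whose members belong to either input.
#' @export
mask_union <- function(a, b) {
  .check_same_grid(a, b, "masks")
  binary_mask(a$member | b$member, a$grid)
}

#' Mask volume in cc
#'
#' @param mask a [binary_mask()].
#' @return Volume in cubic centimetres (member count times voxel volume).
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$member) * prod(mask$grid$spacing) / 1000
}

#' Mask centroid
#'
#' Arithmetic mean of the member voxel centres.
#'
#' @param mask a non-empty [binary_mask()].
#' @return Numeric length-3 position (x, y, z) in mm.
#' @export
mask_centroid <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$member, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty structure")
  centres <- sweep(sweep(idx - 1, 2, mask$grid$spacing, `*`),
                   2, mask$grid$origin, `+`)
  unname(colMeans(centres))
}
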