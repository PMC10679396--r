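# Radiotherapy DICOM I/O on top of the minimal codec in dicom.R.
# Writers emit single-frame-of-reference, axial, axis-aligned files so that
# fixtures remain readable by third-party viewers; readers accept any
# explicit-VR-little-endian file with the attributes used here.

.UID_CT <- "1.2.840.10008.5.1.4.1.1.2"
.UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
.UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"

.el <- function(vr, value) list(vr = vr, value = value)

.common_dataset <- function(uids, modality) {
  ds <- list()
  ds[[.tag_key(0x0008, 0x0016)]] <- .el("UI", uids$sop_class)
  ds[[.tag_key(0x0008, 0x0018)]] <- .el("UI", uids$sop_instance)
  ds[[.tag_key(0x0008, 0x0060)]] <- .el("CS", modality)
  ds[[.tag_key(0x0010, 0x0010)]] <- .el("PN", "SYNTHETIC^PHANTOM")
  ds[[.tag_key(0x0010, 0x0020)]] <- .el("LO", "GASDOSE")
  ds[[.tag_key(0x0020, 0x000D)]] <- .el("UI", uids$study)
  ds[[.tag_key(0x0020, 0x000E)]] <- .el("UI", uids$series)
  ds[[.tag_key(0x0020, 0x0052)]] <- .el("UI", uids$frame)
  ds
}

#' Write a CT series as one DICOM file per slice
#'
#' @param ct a `scalar_volume` in HU.
#' @param directory output directory (created if missing).
#' @param rescale_slope,rescale_intercept linear mapping from stored pixel
#'   values to HU; stored values are quantized to integers.
#' @return Invisibly, a list with the generated series and
#'   frame-of-reference UIDs.
#' @export
write_ct_series <- function(ct, directory, rescale_slope = 1,
                            rescale_intercept = -1024) {
  stopifnot(inherits(ct, "scalar_volume"), ct$unit == "HU")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  g <- ct$grid
  uids <- list(study = dcm_new_uid(), series = dcm_new_uid(),
               frame = dcm_new_uid(), sop_class = .UID_CT)
  for (k in seq_len(g$shape[3])) {
    uids$sop_instance <- dcm_new_uid()
    ds <- .common_dataset(uids, "CT")
    z <- g$origin[3] + (k - 1) * g$spacing[3]
    ds[[.tag_key(0x0020, 0x0032)]] <- .el("DS", c(g$origin[1], g$origin[2], z))
    ds[[.tag_key(0x0020, 0x0037)]] <- .el("DS", c(1, 0, 0, 0, 1, 0))
    ds[[.tag_key(0x0020, 0x0013)]] <- .el("IS", k)
    ds[[.tag_key(0x0028, 0x0002)]] <- .el("US", 1L)
    ds[[.tag_key(0x0028, 0x0004)]] <- .el("CS", "MONOCHROME2")
    ds[[.tag_key(0x0028, 0x0010)]] <- .el("US", g$shape[2])  # rows (y)
    ds[[.tag_key(0x0028, 0x0011)]] <- .el("US", g$shape[1])  # columns (x)
    ds[[.tag_key(0x0028, 0x0030)]] <- .el("DS", c(g$spacing[2], g$spacing[1]))
    ds[[.tag_key(0x0018, 0x0050)]] <- .el("DS", g$spacing[3])
    ds[[.tag_key(0x0028, 0x0100)]] <- .el("US", 16L)
    ds[[.tag_key(0x0028, 0x0101)]] <- .el("US", 16L)
    ds[[.tag_key(0x0028, 0x0102)]] <- .el("US", 15L)
    ds[[.tag_key(0x0028, 0x0103)]] <- .el("US", 0L)
    ds[[.tag_key(0x0028, 0x1052)]] <- .el("DS", rescale_intercept)
    ds[[.tag_key(0x0028, 0x1053)]] <- .el("DS", rescale_slope)
    stored <- round((as.vector(ct$values[, , k]) - rescale_intercept) / rescale_slope)
    if (any(stored < 0 | stored > 65535))
      stop("stored pixel values out of unsigned 16-bit range; adjust rescale")
    ds[[.tag_key(0x7FE0, 0x0010)]] <- .el("OW", .pack_uint16(stored))
    dcm_write_file(file.path(directory, sprintf("ct_%04d.dcm", k)),
                   ds, .UID_CT, uids$sop_instance)
  }
  invisible(uids)
}

#' Read a single-series axial CT from a directory of DICOM files
#'
#' Slices are sorted by z position regardless of file order; stored values
#' are mapped to HU through each file's rescale slope and intercept; slice
#' spacing must be uniform within 1%.
#'
#' @param directory directory containing exactly one CT series.
#' @return A `scalar_volume` in HU.
#' @export
read_ct_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop(sprintf("no DICOM files in %s", directory))
  slices <- lapply(files, function(f) dcm_read_file(f)$dataset)
  series <- vapply(slices, function(ds) dcm_get(ds, 0x0020, 0x000E), character(1))
  if (length(unique(series)) != 1L)
    stop("directory contains a mixed series (multiple SeriesInstanceUIDs)")
  zs <- vapply(slices, function(ds) dcm_numbers(ds, 0x0020, 0x0032)[3], numeric(1))
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  first <- slices[[1]]
  rows <- dcm_get(first, 0x0028, 0x0010)
  cols <- dcm_get(first, 0x0028, 0x0011)
  ps <- dcm_numbers(first, 0x0028, 0x0030)  # (row spacing = dy, col spacing = dx)
  ipp <- dcm_numbers(first, 0x0020, 0x0032)
  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(zs)
    if (any(dz <= 0)) stop("duplicate slice positions in series")
    if ((max(dz) - min(dz)) / mean(dz) > 0.01)
      stop(sprintf("non-uniform slice spacing: steps range %.4g to %.4g mm",
                   min(dz), max(dz)))
    dz <- mean(dz)
  } else {
    dz <- dcm_numbers(first, 0x0018, 0x0050)
    if (is.null(dz)) dz <- 1
  }
  grid <- voxel_grid(origin = c(ipp[1], ipp[2], zs[1]),
                     spacing = c(ps[2], ps[1], dz),
                     shape = c(cols, rows, nz))
  values <- array(0, dim = grid$shape)
  for (k in seq_len(nz)) {
    ds <- slices[[k]]
    slope <- as.numeric(dcm_get(ds, 0x0028, 0x1053, "1"))
    intercept <- as.numeric(dcm_get(ds, 0x0028, 0x1052, "0"))
    stored <- .unpack_uint16(dcm_get(ds, 0x7FE0, 0x0010))
    values[, , k] <- array(stored * slope + intercept, dim = c(cols, rows))
  }
  scalar_volume(values, grid, unit = "HU")
}

#' Write a structure set as DICOM RTSTRUCT
#'
#' @param structures named list; each entry a list of contour matrices with
#'   columns (x, y, z) in mm.
#' @param file output path.
#' @param frame_of_reference_uid frame of reference shared with the CT.
#' @return Invisibly, `file`.
#' @export
write_rtstruct <- function(structures, file,
                           frame_of_reference_uid = dcm_new_uid()) {
  stopifnot(is.list(structures))
  if (length(structures) && is.null(names(structures)))
    stop("structures must be a named list")
  uids <- list(study = dcm_new_uid(), series = dcm_new_uid(),
               frame = frame_of_reference_uid, sop_class = .UID_RTSTRUCT,
               sop_instance = dcm_new_uid())
  ds <- .common_dataset(uids, "RTSTRUCT")
  ds[[.tag_key(0x3006, 0x0002)]] <- .el("SH", "GASDOSE")
  roi_seq <- list()
  contour_seq <- list()
  for (i in seq_along(structures)) {
    roi <- list()
    roi[[.tag_key(0x3006, 0x0022)]] <- .el("IS", i)
    roi[[.tag_key(0x3006, 0x0024)]] <- .el("UI", frame_of_reference_uid)
    roi[[.tag_key(0x3006, 0x0026)]] <- .el("LO", names(structures)[i])
    roi_seq[[i]] <- roi
    citems <- lapply(structures[[i]], function(contour) {
      contour <- as.matrix(contour)
      item <- list()
      item[[.tag_key(0x3006, 0x0042)]] <- .el("CS", "CLOSED_PLANAR")
      item[[.tag_key(0x3006, 0x0046)]] <- .el("IS", nrow(contour))
      item[[.tag_key(0x3006, 0x0050)]] <- .el("DS", as.vector(t(contour)))
      item
    })
    rc <- list()
    rc[[.tag_key(0x3006, 0x0040)]] <- .el("SQ", citems)
    rc[[.tag_key(0x3006, 0x0084)]] <- .el("IS", i)
    contour_seq[[i]] <- rc
  }
  ds[[.tag_key(0x3006, 0x0020)]] <- .el("SQ", roi_seq)
  ds[[.tag_key(0x3006, 0x0039)]] <- .el("SQ", contour_seq)
  dcm_write_file(file, ds, .UID_RTSTRUCT, uids$sop_instance)
  invisible(file)
}

#' Read a DICOM RTSTRUCT file into a structure set
#'
#' ROIs without contour data are omitted with a warning.
#'
#' @param file RTSTRUCT path.
#' @return Named list of structures; each a list of (n x 3) contour
#'   matrices in mm.
#' @export
read_rtstruct <- function(file) {
  ds <- dcm_read_file(file)$dataset
  rois <- dcm_get(ds, 0x3006, 0x0020, list())
  names_by_number <- list()
  for (roi in rois) {
    num <- as.integer(dcm_get(roi, 0x3006, 0x0022))
    names_by_number[[as.character(num)]] <- dcm_get(roi, 0x3006, 0x0026)
  }
  out <- list()
  seen <- character(0)
  for (rc in dcm_get(ds, 0x3006, 0x0039, list())) {
    num <- as.character(as.integer(dcm_get(rc, 0x3006, 0x0084)))
    nm <- names_by_number[[num]]
    if (is.null(nm)) nm <- paste0("ROI_", num)
    contours <- lapply(dcm_get(rc, 0x3006, 0x0040, list()), function(item) {
      pts <- dcm_numbers(item, 0x3006, 0x0050)
      matrix(pts, ncol = 3, byrow = TRUE,
             dimnames = list(NULL, c("x", "y", "z")))
    })
    contours <- Filter(function(m) !is.null(m) && nrow(m) >= 3, contours)
    if (length(contours)) {
      out[[nm]] <- contours
      seen <- c(seen, num)
    }
  }
  missing <- setdiff(names(names_by_number), seen)
  for (num in missing)
    warning(sprintf("ROI '%s' has no contour data; omitted",
                    names_by_number[[num]]))
  out
}

#' Write a dose volume as DICOM RTDOSE (grid-scaled)
#'
#' @param dose a `scalar_volume` in Gy.
#' @param file output path.
#' @param scaling dose-grid scaling in Gy per stored unit.
#' @param frame_of_reference_uid frame of reference shared with the CT.
#' @return Invisibly, `file`.
#' @export
write_rtdose <- function(dose, file, scaling = 1e-3,
                         frame_of_reference_uid = dcm_new_uid()) {
  stopifnot(inherits(dose, "scalar_volume"), dose$unit == "Gy", scaling > 0)
  g <- dose$grid
  uids <- list(study = dcm_new_uid(), series = dcm_new_uid(),
               frame = frame_of_reference_uid, sop_class = .UID_RTDOSE,
               sop_instance = dcm_new_uid())
  ds <- .common_dataset(uids, "RTDOSE")
  ds[[.tag_key(0x0020, 0x0032)]] <- .el("DS", g$origin)
  ds[[.tag_key(0x0020, 0x0037)]] <- .el("DS", c(1, 0, 0, 0, 1, 0))
  ds[[.tag_key(0x0028, 0x0002)]] <- .el("US", 1L)
  ds[[.tag_key(0x0028, 0x0008)]] <- .el("IS", g$shape[3])
  ds[[.tag_key(0x0028, 0x0010)]] <- .el("US", g$shape[2])
  ds[[.tag_key(0x0028, 0x0011)]] <- .el("US", g$shape[1])
  ds[[.tag_key(0x0028, 0x0030)]] <- .el("DS", c(g$spacing[2], g$spacing[1]))
  ds[[.tag_key(0x0028, 0x0100)]] <- .el("US", 32L)
  ds[[.tag_key(0x0028, 0x0101)]] <- .el("US", 32L)
  ds[[.tag_key(0x0028, 0x0102)]] <- .el("US", 31L)
  ds[[.tag_key(0x0028, 0x0103)]] <- .el("US", 0L)
  ds[[.tag_key(0x3004, 0x0002)]] <- .el("CS", "GY")
  ds[[.tag_key(0x3004, 0x0004)]] <- .el("CS", "PHYSICAL")
  ds[[.tag_key(0x3004, 0x000A)]] <- .el("CS", "PLAN")
  ds[[.tag_key(0x3004, 0x000C)]] <- .el("DS", (seq_len(g$shape[3]) - 1) * g$spacing[3])
  ds[[.tag_key(0x3004, 0x000E)]] <- .el("DS", scaling)
  stored <- round(as.vector(dose$values) / scaling)
  if (any(stored >= 2^32)) stop("dose exceeds 32-bit stored range at this scaling")
  ds[[.tag_key(0x7FE0, 0x0010)]] <- .el("OW", .pack_uint32(stored))
  dcm_write_file(file, ds, .UID_RTDOSE, uids$sop_instance)
  invisible(file)
}

#' Read a DICOM RTDOSE file
#'
#' Stored integers are multiplied by the dose-grid scaling to give Gy.
#'
#' @param file RTDOSE path.
#' @return A `scalar_volume` in Gy.
#' @export
read_rtdose <- function(file) {
  ds <- dcm_read_file(file)$dataset
  scaling <- dcm_get(ds, 0x3004, 0x000E)
  if (is.null(scaling)) stop("RTDOSE file has no DoseGridScaling")
  scaling <- as.numeric(scaling)
  rows <- dcm_get(ds, 0x0028, 0x0010)
  cols <- dcm_get(ds, 0x0028, 0x0011)
  nframes <- as.integer(dcm_get(ds, 0x0028, 0x0008, "1"))
  ps <- dcm_numbers(ds, 0x0028, 0x0030)
  ipp <- dcm_numbers(ds, 0x0020, 0x0032)
  offsets <- dcm_numbers(ds, 0x3004, 0x000C)
  dz <- if (length(offsets) > 1) offsets[2] - offsets[1] else 1
  grid <- voxel_grid(origin = ipp, spacing = c(ps[2], ps[1], dz),
                     shape = c(cols, rows, nframes))
  stored <- .unpack_uint32(dcm_get(ds, 0x7FE0, 0x0010))
  scalar_volume(array(stored * scaling, dim = grid$shape), grid, unit = "Gy")
}

#' Read a two-column (HU, RED) calibration table
#'
#' @param file delimited text with two numeric columns, HU then RED;
#'   comma, tab or whitespace separated; lines starting with `#` and an
#'   optional header line are ignored.
#' @return Data frame with columns `hu`, `red`, sorted by HU.
#' @export
read_calibration_table <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parse_line <- function(l) {
    parts <- strsplit(trimws(l), "[,;\t ]+")[[1]]
    suppressWarnings(as.numeric(parts))
  }
  rows <- lapply(lines, parse_line)
  rows <- Filter(function(r) length(r) >= 2 && !any(is.na(r[1:2])), rows)
  if (length(rows) < 2L) stop("calibration table needs at least 2 (HU, RED) points")
  pts <- data.frame(hu = vapply(rows, `[`, numeric(1), 1),
                    red = vapply(rows, `[`, numeric(1), 2))
  if (anyDuplicated(pts$hu)) stop("duplicate HU values in calibration table")
  pts <- pts[order(pts$hu), , drop = FALSE]
  rownames(pts) <- NULL
  if (any(diff(pts$red) < 0))
    warning("calibration RED is not monotone in HU; curve kept as given")
  pts
}

#' Assemble a patient case
#'
#' @param ct `scalar_volume` in HU.
#' @param structures named list of planar-contour structures.
#' @param doses named list of `scalar_volume`s in Gy sharing one grid
#'   (typically `APLAN`, `WPLAN`, `GPLAN`).
#' @param prescription_dose prescription in Gy (> 0).
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(ct, structures = list(), doses = list(),
                         prescription_dose = NA_real_) {
  stopifnot(inherits(ct, "scalar_volume"), ct$unit == "HU")
  if (length(doses)) {
    if (is.null(names(doses))) stop("doses must be a named list")
    g0 <- doses[[1]]$grid
    for (d in doses) {
      stopifnot(inherits(d, "scalar_volume"), d$unit == "Gy")
      if (!grids_equal(d$grid, g0)) stop("all dose volumes must share one grid")
    }
    if (!is.na(prescription_dose) && prescription_dose <= 0)
      stop("prescription_dose must be > 0")
  }
  structure(list(ct = ct, structures = structures, doses = doses,
                 prescription_dose = prescription_dose),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %d structures [%s], %d dose volumes [%s], Rx %.4g Gy\n",
              length(x$structures), paste(names(x$structures), collapse = ", "),
              length(x$doses), paste(names(x$doses), collapse = ", "),
              x$prescription_dose))
  invisible(x)
}

#' Save / load a patient case bundle
#'
#' Single-file compressed container for fast round trips; DICOM remains
#' the interchange format.
#'
#' @param case a `patient_case`.
#' @param file bundle path (`.rds`).
#' @return `save_case` returns `file` invisibly; `load_case` the case.
#' @export
save_case <- function(case, file) {
  stopifnot(inherits(case, "patient_case"))
  saveRDS(case, file)
  invisible(file)
}

#' @rdname save_case
#' @export
load_case <- function(file) {
  case <- readRDS(file)
  stopifnot(inherits(case, "patient_case"))
  case
}

#' Resample a scalar volume onto another grid by trilinear interpolation
#'
#' Points outside the source extent take the nearest-edge value.
#'
#' @param vol source `scalar_volume`.
#' @param grid target [voxel_grid()].
#' @return A `scalar_volume` on `grid`.
#' @export
resample_to_grid <- function(vol, grid) {
  stopifnot(inherits(vol, "scalar_volume"), inherits(grid, "voxel_grid"))
  if (grids_equal(vol$grid, grid)) return(scalar_volume(vol$values, grid, vol$unit))
  sg <- vol$grid
  # fractional source indices (0-based) of every target voxel centre, clamped
  fi <- function(axis) {
    t <- (grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis] -
            sg$origin[axis]) / sg$spacing[axis]
    pmin(pmax(t, 0), sg$shape[axis] - 1)
  }
  tx <- fi(1); ty <- fi(2); tz <- fi(3)
  x0 <- pmin(floor(tx), sg$shape[1] - 2); fx <- tx - x0
  y0 <- pmin(floor(ty), sg$shape[2] - 2); fy <- ty - y0
  z0 <- pmin(floor(tz), sg$shape[3] - 2); fz <- tz - z0
  if (sg$shape[1] == 1) { x0 <- rep(0, length(tx)); fx <- rep(0, length(tx)) }
  if (sg$shape[2] == 1) { y0 <- rep(0, length(ty)); fy <- rep(0, length(ty)) }
  if (sg$shape[3] == 1) { z0 <- rep(0, length(tz)); fz <- rep(0, length(tz)) }
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  X0 <- array(rep(x0, times = ny * nz), dim = grid$shape)
  FX <- array(rep(fx, times = ny * nz), dim = grid$shape)
  Y0 <- array(rep(rep(y0, each = nx), times = nz), dim = grid$shape)
  FY <- array(rep(rep(fy, each = nx), times = nz), dim = grid$shape)
  Z0 <- array(rep(z0, each = nx * ny), dim = grid$shape)
  FZ <- array(rep(fz, each = nx * ny), dim = grid$shape)
  v <- vol$values
  at <- function(dx, dy, dz) {
    idx <- (X0 + dx) + (Y0 + dy) * sg$shape[1] + (Z0 + dz) * sg$shape[1] * sg$shape[2] + 1
    array(v[idx], dim = grid$shape)
  }
  out <- at(0, 0, 0) * (1 - FX) * (1 - FY) * (1 - FZ) +
    at(1, 0, 0) * FX * (1 - FY) * (1 - FZ) +
    at(0, 1, 0) * (1 - FX) * FY * (1 - FZ) +
    at(0, 0, 1) * (1 - FX) * (1 - FY) * FZ +
    at(1, 1, 0) * FX * FY * (1 - FZ) +
    at(1, 0, 1) * FX * (1 - FY) * FZ +
    at(0, 1, 1) * (1 - FX) * FY * FZ +
    at(1, 1, 1) * FX * FY * FZ
  scalar_volume(out, grid, vol$unit)
}
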