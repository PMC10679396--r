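make_ct <- function(seed = 1, shape = c(9, 8, 4), spacing = c(2, 2, 2.5)) {
  g <- voxel_grid(c(-8, -7, 0), spacing, shape)
  set.seed(seed)
  scalar_volume(array(sample(-1000:2000, prod(shape), TRUE), dim = shape),
                g, "HU")
}

test_that("CT series round-trips through DICOM, in any file order", {
  ct <- make_ct()
  dir <- withr::local_tempdir()
  write_ct_series(ct, dir)
  back <- read_ct_series(dir)
  expect_equal(back$values, ct$values)
  expect_true(grids_equal(back$grid, ct$grid))
  # shuffle file names: reader must sort by slice position, not name
  files <- list.files(dir, full.names = TRUE)
  set.seed(3)
  shuffled <- file.path(dir, sprintf("s_%s.dcm", sample(letters, length(files))))
  file.rename(files, shuffled)
  expect_equal(read_ct_series(dir)$values, ct$values)
})

test_that("a CT series with a missing slice is rejected mentioning spacing", {
  ct <- make_ct(shape = c(6, 6, 5))
  dir <- withr::local_tempdir()
  write_ct_series(ct, dir)
  file.remove(file.path(dir, "ct_0003.dcm"))
  expect_error(read_ct_series(dir), "spacing")
})

test_that("mixing two series in one directory is rejected", {
  dir <- withr::local_tempdir()
  write_ct_series(make_ct(seed = 1, shape = c(6, 6, 2)), dir)
  sub <- withr::local_tempdir()
  write_ct_series(make_ct(seed = 2, shape = c(6, 6, 2)), sub)
  file.copy(file.path(sub, "ct_0001.dcm"), file.path(dir, "ct_0009.dcm"))
  expect_error(read_ct_series(dir), "mixed series")
})

test_that("RTSTRUCT round-trips polygons to within 1e-3 mm", {
  cube <- lapply(c(0, 2.5), function(z)
    cbind(x = c(-5, 5, 5, -5), y = c(-5, -5, 5, 5), z = z))
  two_pockets <- list(
    cbind(x = c(0, 3, 3, 0), y = c(0, 0, 3, 3), z = 0),
    cbind(x = c(-8, -5, -5, -8), y = c(0, 0, 3, 3), z = 0))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(list(CUBE = cube, GAS = two_pockets), f)
  back <- read_rtstruct(f)
  expect_named(back, c("CUBE", "GAS"))
  expect_length(back$GAS, 2)  # both pockets on the same slice retained
  for (k in 1:2) {
    expect_lt(max(abs(back$CUBE[[k]] - cube[[k]])), 1e-3)
    expect_lt(max(abs(back$GAS[[k]] - two_pockets[[k]])), 1e-3)
  }
})

test_that("an empty structure set round-trips and contourless ROIs warn", {
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(list(), f)
  expect_length(read_rtstruct(f), 0)
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(list(EMPTY = list(),
                      OK = list(cbind(x = c(0, 1, 1), y = c(0, 0, 1), z = 0))),
                 f2)
  expect_warning(back <- read_rtstruct(f2), "EMPTY")
  expect_named(back, "OK")
})

test_that("RTDOSE round-trips within the quantization bound", {
  g <- voxel_grid(c(0, 0, 0), c(2, 2, 3), c(7, 6, 5))
  set.seed(2)
  dose <- scalar_volume(array(runif(prod(g$shape)) * 45, dim = g$shape), g, "Gy")
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(dose, f, scaling = 1e-3)
  back <- read_rtdose(f)
  expect_true(grids_equal(back$grid, g))
  expect_lte(max(abs(back$values - dose$values)), 0.5e-3)
  # all-zero and uniform fixtures are exact
  zero <- scalar_volume(array(0, dim = g$shape), g, "Gy")
  write_rtdose(zero, f)
  expect_true(all(read_rtdose(f)$values == 0))
  ten <- scalar_volume(array(10, dim = g$shape), g, "Gy")
  write_rtdose(ten, f, scaling = 1e-3)
  expect_true(all(read_rtdose(f)$values == 10))
})

test_that("DICOM files written here are readable by an independent reader", {
  ct <- make_ct(seed = 5, shape = c(5, 4, 2))
  dir <- withr::local_tempdir()
  write_ct_series(ct, dir)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, glob, json",
    "import pydicom",
    "vals = []",
    "for f in sorted(glob.glob(sys.argv[1] + '/*.dcm')):",
    "    ds = pydicom.dcmread(f)",
    "    arr = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)",
    "    vals.append({'z': float(ds.ImagePositionPatient[2]),",
    "                 'rows': int(ds.Rows), 'cols': int(ds.Columns),",
    "                 'spacing': [float(x) for x in ds.PixelSpacing],",
    "                 'sum': float(arr.sum()), 'first': float(arr[0, 0])})",
    "print(json.dumps(vals))"), script)
  out <- system2("python", c(script, dir), stdout = TRUE)
  info <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(nrow(info), 2)
  expect_equal(info$rows, c(4, 4))         # DICOM rows = y extent
  expect_equal(info$cols, c(5, 5))
  expect_equal(info$z, c(0, 2.5))
  expect_equal(info$sum, c(sum(ct$values[, , 1]), sum(ct$values[, , 2])))
  expect_equal(info$first, c(ct$values[1, 1, 1], ct$values[1, 1, 2]))
})

test_that("calibration tables are parsed, sorted and validated", {
  f <- withr::local_tempfile(lines = c("# HU,RED", "0, 1.0", "-1000, 0.0"))
  pts <- read_calibration_table(f)
  expect_equal(pts$hu, c(-1000, 0))
  expect_equal(pts$red, c(0, 1))
  f2 <- withr::local_tempfile(lines = c("-1000,0", "-500,0.5", "-500,0.6"))
  expect_error(read_calibration_table(f2), "duplicate HU")
  f3 <- withr::local_tempfile(lines = "-1000,0")
  expect_error(read_calibration_table(f3), "at least 2")
  f4 <- withr::local_tempfile(lines = c("-1000,0", "-500,0.8", "0,0.7"))
  expect_warning(read_calibration_table(f4), "monotone")
})

test_that("a patient case survives the bundle round trip", {
  ct <- make_ct(seed = 7, shape = c(6, 6, 3))
  dose <- scalar_volume(array(1, dim = ct$grid$shape), ct$grid, "Gy")
  case <- patient_case(ct, structures = list(GTV = list(
    cbind(x = c(-2, 2, 2, -2), y = c(-2, -2, 2, 2), z = 2.5))),
    doses = list(APLAN = dose), prescription_dose = 38)
  f <- withr::local_tempfile(fileext = ".rds")
  save_case(case, f)
  expect_equal(load_case(f), case)
})

test_that("trilinear resampling is exact for affine fields", {
  g1 <- voxel_grid(c(0, 0, 0), c(2, 2, 2), c(10, 10, 6))
  ax <- grid_axes(g1)
  affine <- outer(outer(2 * ax$x, 3 * ax$y, `+`), 0.5 * ax$z, `+`) + 7
  vol <- scalar_volume(affine, g1, "Gy")
  g2 <- voxel_grid(c(1, 1, 1), c(1.5, 1.5, 1.5), c(8, 8, 5))
  ax2 <- grid_axes(g2)
  expected <- outer(outer(2 * ax2$x, 3 * ax2$y, `+`), 0.5 * ax2$z, `+`) + 7
  expect_equal(resample_to_grid(vol, g2)$values, expected, tolerance = 1e-12)
})
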