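test_that("gamma of a distribution against itself passes everywhere", {
  ref <- dose_blob_field(20, 1)
  g <- gamma_2d(ref, ref, c(1, 1))
  expect_equal(g$gpr, 100)
  expect_equal(max(g$gamma, na.rm = TRUE), 0)
})

test_that("a global 0.5% dose offset passes a 1% dose tolerance", {
  ref <- dose_blob_field(20, 2)
  g <- gamma_2d(ref, ref * 1.005, c(1, 1))
  expect_equal(g$gpr, 100)
})

test_that("optimized gamma matches the exhaustive oracle", {
  # GPR at the default criteria over random smooth pairs
  for (s in 1:10) {
    p <- dose_blob_pair(20, s)
    g <- gamma_2d(p$ref, p$ev, c(1, 1))
    o <- gamma_oracle(p$ref, p$ev, c(1, 1))
    expect_lte(abs(g$gpr - oracle_gpr(o)), 0.5)
  }
  # per-pixel agreement at matched fine search resolution
  p <- dose_blob_pair(14, 99)
  fine <- gamma_criteria(step_factor = 0.01, search_radius_factor = 5)
  g <- gamma_2d(p$ref, p$ev, c(1, 1), fine)
  o <- gamma_oracle(p$ref, p$ev, c(1, 1), step = 0.01, radius = 5)
  ok <- !is.na(o)
  expect_lte(max(g$gamma[ok] - o[ok]), 0.02)
})

test_that("GPR is monotone when criteria are loosened, and scale invariant", {
  p <- dose_blob_pair(20, 7)
  base <- gamma_2d(p$ref, p$ev, c(1, 1), gamma_criteria(1, 1))$gpr
  expect_gte(gamma_2d(p$ref, p$ev, c(1, 1), gamma_criteria(2, 1))$gpr, base)
  expect_gte(gamma_2d(p$ref, p$ev, c(1, 1), gamma_criteria(1, 2))$gpr, base)
  expect_gte(gamma_2d(p$ref, p$ev, c(1, 1), gamma_criteria(3, 3))$gpr, base)
  # doubling both doses changes nothing under global normalization
  doubled <- gamma_2d(2 * p$ref, 2 * p$ev, c(1, 1))
  expect_equal(doubled$gpr, gamma_2d(p$ref, p$ev, c(1, 1))$gpr)
})

test_that("gamma is asymmetric in the choice of reference", {
  p <- dose_blob_pair(20, 12)
  ab <- gamma_2d(p$ref, p$ev, c(1, 1))
  ba <- gamma_2d(p$ev, p$ref, c(1, 1))
  expect_false(isTRUE(all.equal(ab$gamma, ba$gamma)))
})

test_that("degenerate gamma inputs are rejected", {
  ref <- dose_blob_field(10, 3)
  expect_error(gamma_2d(ref, ref[, 1:5], c(1, 1)), "shape")
  expect_error(gamma_2d(matrix(1, 5, 5), matrix(1, 5, 5),
                        c(1, 1), gamma_criteria(low_dose_threshold = 200)),
               "no pixels above dose threshold")
})

test_that("orthogonal plane extraction is nearest-slice indexing", {
  g <- voxel_grid(c(0, 0, 0), c(2, 2, 2.5), c(8, 9, 6))
  uni <- scalar_volume(array(5, dim = g$shape), g, "Gy")
  pl <- extract_orthogonal_planes(uni, c(7, 7, 7))
  for (p in pl) expect_true(all(p$values == 5))
  set.seed(5)
  vol <- scalar_volume(array(runif(prod(g$shape)), dim = g$shape), g, "Gy")
  # point exactly at a voxel centre returns the stored slices
  pt <- c(2 * 3, 2 * 4, 2.5 * 2)
  pl <- extract_orthogonal_planes(vol, pt)
  expect_identical(pl$axial$values, vol$values[, , 3])
  expect_identical(pl$sagittal$values, vol$values[4, , ])
  expect_identical(pl$coronal$values, vol$values[, 5, ])
  expect_equal(pl$axial$spacing, c(2, 2))
  expect_equal(pl$sagittal$spacing, c(2, 2.5))
  # nearest-slice rule for an off-centre point
  pl2 <- extract_orthogonal_planes(vol, pt + c(0.9, -0.9, 1.2))
  expect_identical(pl2$axial$values, vol$values[, , 3])
  expect_identical(pl2$sagittal$values, vol$values[4, , ])
  expect_error(extract_orthogonal_planes(vol, c(100, 0, 0)), "outside")
})

test_that("plan comparison averages the three orthogonal-plane GPRs", {
  g <- voxel_grid(c(0, 0, 0), c(2, 2, 2), c(10, 10, 5))
  ct <- scalar_volume(array(0, dim = g$shape), g, "HU")
  gtv <- list(cbind(x = c(-0.9, 0.9, 0.9, -0.9),
                    y = c(-0.9, -0.9, 0.9, 0.9), z = 4))
  ref <- array(10, dim = g$shape)
  ev <- ref
  # disturb 50 of the 100 axial-plane pixels on the GTV slice, avoiding the
  # sagittal (i = 1) and coronal (j = 1) planes through the centroid
  mod <- as.matrix(expand.grid(i = 2:10, j = 2:10))[1:50, ]
  ev[cbind(mod, 3)] <- 5
  case <- patient_case(ct, structures = list(GTV = gtv),
                       doses = list(
                         REF = scalar_volume(ref, g, "Gy"),
                         EVAL = scalar_volume(ev, g, "Gy")),
                       prescription_dose = 10)
  ident <- compare_plans(case, "REF", "REF")
  expect_equal(ident$mean_gpr, 100)
  res <- compare_plans(case, "REF", "EVAL")
  expect_equal(unname(res$gpr["axial"]), 50)
  expect_equal(unname(res$gpr["sagittal"]), 100)
  expect_equal(unname(res$gpr["coronal"]), 100)
  expect_equal(res$mean_gpr, (100 + 100 + 50) / 3)
  expect_error(compare_plans(case, "REF", "NOPE"), "missing")
})
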