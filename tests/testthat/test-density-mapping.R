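test_that("structure HU statistics match hand arithmetic", {
  g <- unit_grid(shape = c(4, 4, 1))
  hu <- array(-620, dim = g$shape)
  all_m <- binary_mask(array(TRUE, g$shape), g)
  s <- structure_hu_stats(scalar_volume(hu, g, "HU"), all_m)
  expect_equal(s$mean, -620)
  expect_equal(s$sd, 0)
  hu2 <- array(0, dim = g$shape)
  hu2[1:2] <- c(-600, -640)
  two <- array(FALSE, g$shape); two[1:2] <- TRUE
  s2 <- structure_hu_stats(scalar_volume(hu2, g, "HU"), binary_mask(two, g))
  expect_equal(s2$mean, -620)
  expect_equal(s2$sd, sqrt(800))  # sample SD, n-1 denominator
  expect_equal(s2$n, 2)
  expect_error(structure_hu_stats(scalar_volume(hu, g, "HU"),
                                  binary_mask(array(FALSE, g$shape), g)),
               "empty structure")
})

test_that("a 1e5-voxel gas pocket recovers its generator mean within 1 HU", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(50, 50, 40))
  n <- prod(g$shape)
  set.seed(620)
  hu <- pmax(rnorm(n, -620, 90), -1000)
  s <- structure_hu_stats(scalar_volume(array(hu, g$shape), g, "HU"),
                          binary_mask(array(TRUE, g$shape), g))
  expect_gte(s$n, 1e5)
  expect_lt(abs(s$mean - (-620)), 1)
})

test_that("KS normality calls behave under null and bimodal alternatives", {
  null_p <- vapply(1:200, function(s) {
    set.seed(s); ks_normality(rnorm(21))$p_value
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.95)
  alt_p <- vapply(1:200, function(s) {
    set.seed(s)
    x <- rnorm(21, mean = sample(c(-5, 5), 21, TRUE), sd = 0.1)
    ks_normality(x)$p_value
  }, numeric(1))
  expect_gte(mean(alt_p < 0.05), 0.95)
  set.seed(10); x <- rnorm(21)
  expect_identical(ks_normality(x)$p_value, ks_normality(x)$p_value)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 3")
})

test_that("Mann-Whitney: exact enumeration, symmetry and null behaviour", {
  expect_equal(mann_whitney_unpaired(c(1, 2, 3), c(1, 2, 3)), 1.0)
  # U = 0; two-sided exact p = 2 * 1/choose(6,3) = 0.1
  expect_equal(mann_whitney_unpaired(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_error(mann_whitney_unpaired(numeric(0), 1), "empty sample")
  # under the null (equal distributions) p-values are ~ Uniform(0,1)
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    mann_whitney_unpaired(rnorm(21, -610, 80), rnorm(21, -610, 80))
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)  # rejection at ~ alpha
})

test_that("calibration fitting is OLS on the in-domain segment", {
  two <- fit_calibration_segment(data.frame(hu = c(-1000, 0), red = c(0, 1)))
  expect_equal(two$slope, 0.001)
  expect_equal(two$intercept, 1)
  # collinear points: zero residuals
  hu <- c(-1000, -750, -500, -250, 0)
  col <- fit_calibration_segment(data.frame(hu = hu, red = 1 + hu / 1000))
  expect_equal(col$slope * hu + col$intercept, 1 + hu / 1000, tolerance = 1e-12)
  # noisy points vs the closed-form normal-equations oracle
  set.seed(4)
  hu <- runif(15, -1000, 0)
  red <- 1 + hu / 1000 + rnorm(15, 0, 0.02)
  fit <- fit_calibration_segment(data.frame(hu = hu, red = red))
  sxx <- sum((hu - mean(hu))^2)
  slope_oracle <- sum((hu - mean(hu)) * (red - mean(red))) / sxx
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(red) - slope_oracle * mean(hu),
               tolerance = 1e-12)
  # out-of-domain points are ignored; too few in-domain points error
  with_out <- fit_calibration_segment(
    data.frame(hu = c(-1000, 0, 500, 1500), red = c(0, 1, 1.3, 1.9)))
  expect_equal(with_out$slope, 0.001)
  expect_error(fit_calibration_segment(data.frame(hu = c(100, 500), red = c(1, 2))),
               "at least 2")
})

test_that("the default calibration maps -620 HU to a GIGED of exactly 0.38", {
  curve <- default_calibration()
  expect_equal(giged(curve, -620), 0.38)
  expect_equal(hu_to_red(curve, 0), 1.0)
  expect_equal(hu_to_red(curve, -1000), 0.0)
  expect_warning(hu_to_red(curve, 200), "extrapolating")
})

test_that("RED override replaces only the masked voxels and copies the input", {
  g <- unit_grid(shape = c(6, 6, 3))
  set.seed(8)
  red <- scalar_volume(array(runif(prod(g$shape), 0.9, 1.1), g$shape), g, "RED")
  m <- random_mask(g, 0.3, seed = 11)
  empty <- binary_mask(array(FALSE, g$shape), g)
  expect_equal(override_red(red, empty, 0.5)$values, red$values)
  before <- red$values
  a <- override_red(red, m, 0.0012)
  w <- override_red(red, m, 1.000)
  expect_identical(red$values, before)  # input untouched
  differs <- a$values != w$values
  expect_identical(differs, m$member)   # the two overrides differ exactly on the mask
  expect_true(all(a$values[m$member] == 0.0012))
  expect_equal(a$values[!m$member], red$values[!m$member])
})

test_that("the cohort gas report partitions GAS consistently", {
  specs <- lapply(1:3, function(s)
    phantom_spec(spacing = c(5, 5, 5), n_pockets = 3, seed = 100 + s))
  cases <- lapply(specs, generate_patient)
  rpt <- gas_hu_report(cases)
  tab <- rpt$structures
  gas <- tab[tab$structure == "GAS", ]
  parts <- tab[tab$structure != "GAS", ]
  # voxel counts and HU sums add up over the partitions
  expect_equal(sum(parts$n_voxels), gas$n_voxels)
  expect_equal(sum(parts$mean_hu * parts$n_voxels, na.rm = TRUE) /
                 gas$n_voxels, gas$mean_hu)
  expect_named(rpt$pairwise_p, c("STGvsLBG", "STGvsSBG", "SBGvsLBG"))
  expect_true(all(rpt$pairwise_p >= 0 & rpt$pairwise_p <= 1, na.rm = TRUE))
  expect_gt(rpt$giged, 0)
  expect_lt(rpt$giged, 1)
})
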