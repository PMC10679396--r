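small_spec <- function(seed, ...) {
  phantom_spec(spacing = c(5, 5, 5), seed = seed, ...)
}

test_that("phantom generation is seed-deterministic, bit for bit", {
  a <- generate_patient(small_spec(21))
  b <- generate_patient(small_spec(21))
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$structures, b$structures)
  c2 <- generate_patient(small_spec(22))
  expect_false(identical(a$ct$values, c2$ct$values))
})

test_that("a phantom without pockets has empty GAS and a collapsed plan triplet", {
  case <- generate_patient(small_spec(31, n_pockets = 0))
  gas <- rasterize_structure(case$structures$GAS, case$ct$grid)
  expect_equal(mask_volume_cc(gas), 0)
  trip <- build_plan_triplet(case)
  expect_equal(trip$doses$WPLAN$values, trip$doses$APLAN$values)
  expect_equal(trip$doses$GPLAN$values, trip$doses$APLAN$values)
  expect_equal(compare_plans(trip, "WPLAN", "APLAN")$mean_gpr, 100)
  expect_equal(compute_agv(gas, trip$doses$APLAN, trip$prescription_dose), 0)
})

test_that("pocket HU sampling recovers the specified mean on a large-pocket phantom", {
  spec <- phantom_spec(body_semiaxes = c(120, 100, 80), spacing = c(2, 2, 2),
                       n_pockets = 3, pocket_semiaxes_range = c(24, 30),
                       seed = 77)
  case <- generate_patient(spec)
  gas <- rasterize_structure(case$structures$GAS, case$ct$grid)
  s <- structure_hu_stats(case$ct, gas)
  expect_gt(s$n, 2e4)
  expect_lt(abs(s$mean - spec$pocket_hu_mean), 3)
})

test_that("the toy engine gives symmetric, monotone depth dose in water", {
  g <- voxel_grid(c(-72.5, 1.5, -72.5), c(5, 3, 5), c(30, 60, 30))
  red <- scalar_volume(array(1, g$shape), g, "RED")
  beams <- beam_set(angles = 270, isocenter = c(0, 90, 0),
                    field_halfwidth = 40, field_halfheight = 40)
  dose <- toy_dose_engine(red, beams, engine_params(ere_gain = 0))
  # deterministic
  dose2 <- toy_dose_engine(red, beams, engine_params(ere_gain = 0))
  expect_identical(dose$values, dose2$values)
  # left-right symmetry about the beam axis
  expect_equal(dose$values, dose$values[rev(seq_len(30)), , ], tolerance = 1e-12)
  # strictly decreasing central-axis dose with depth (no buildup modelled)
  iso_i <- round((0 - g$origin[1]) / 5) + 1
  cax <- dose$values[iso_i, , iso_i]
  expect_true(all(diff(cax) < 0))
})

test_that("doubling the RED halves the isodose depth along a single beam", {
  g <- voxel_grid(c(-72.5, 1, -72.5), c(5, 2, 5), c(30, 100, 30))
  beams <- beam_set(angles = 270, isocenter = c(0, 100, 0),
                    field_halfwidth = 40, field_halfheight = 40)
  depth_at_level <- function(red_value, level) {
    red <- scalar_volume(array(red_value, g$shape), g, "RED")
    cax <- toy_dose_engine(red, beams, engine_params(ere_gain = 0))$values[15, , 15]
    cax <- cax / cax[1]
    ax <- grid_axes(g)$y
    i <- max(which(cax >= level))
    ax[i] + (cax[i] - level) / (cax[i] - cax[i + 1]) * 2 - ax[1]
  }
  d_half <- depth_at_level(0.5, 0.7)
  d_full <- depth_at_level(1.0, 0.7)
  expect_equal(d_full / d_half, 0.5, tolerance = 0.03)
})

test_that("plan-triplet differences stay localized to beam paths through the gas", {
  case <- generate_patient(small_spec(55, n_pockets = 1,
                                      pocket_semiaxes_range = c(12, 16)))
  trip <- build_plan_triplet(case)
  gas <- rasterize_structure(trip$structures$GAS, trip$ct$grid)
  pc <- mask_centroid(gas)
  idx <- which(gas$member, arr.ind = TRUE)
  g <- trip$ct$grid
  pos <- sweep(sweep(idx - 1, 2, g$spacing, `*`), 2, g$origin, `+`)
  rp <- max(sqrt(colSums((t(pos) - pc)^2)))
  dd <- abs(trip$doses$WPLAN$values - trip$doses$APLAN$values)
  aff <- which(dd > 0.02 * max(trip$doses$APLAN$values), arr.ind = TRUE)
  expect_gt(nrow(aff), 0)
  apos <- sweep(sweep(aff - 1, 2, g$spacing, `*`), 2, g$origin, `+`)
  angles <- beam_set()$angles * pi / 180
  # distance from each affected voxel to the nearest beam line through the
  # pocket centre; everything must sit inside a pocket-wide beam corridor
  mind <- rep(Inf, nrow(apos))
  for (a in angles) {
    d3 <- c(cos(a), sin(a), 0)
    w <- sweep(apos, 2, pc, `-`)
    proj <- w %*% d3
    perp2 <- rowSums(w^2) - proj^2
    mind <- pmin(mind, sqrt(pmax(perp2, 0)))
  }
  expect_lt(max(mind), rp + 15)
})

test_that("a large gas pocket reproduces the clinical GPR ordering of the comparisons", {
  spec <- small_spec(42, n_pockets = 3, pocket_semiaxes_range = c(18, 30))
  trip <- build_plan_triplet(generate_patient(spec))
  wa <- compare_plans(trip, "WPLAN", "APLAN")$mean_gpr
  wg <- compare_plans(trip, "WPLAN", "GPLAN")$mean_gpr
  ga <- compare_plans(trip, "GPLAN", "APLAN")$mean_gpr
  expect_gt(wg, ga)  # GIGED is dosimetrically closer to water ...
  expect_gt(wg, wa)  # ... and air is the outlier
  expect_gt(ga, wa)
  # PTV DVH deltas for water-vs-air stay within the clinically observed band
  ptv <- rasterize_structure(trip$structures$PTV, trip$ct$grid)
  mw <- dvh_metrics(trip$doses$WPLAN, ptv, trip$prescription_dose, structure = "PTV")
  ma <- dvh_metrics(trip$doses$APLAN, ptv, trip$prescription_dose, structure = "PTV")
  delta <- dvh_delta(mw, ma)[c("d98", "d50", "d2", "dmin", "dmean", "dmax")]
  expect_true(all(delta >= -4.13 & delta <= 0.50))
})

test_that("AGV grows with pocket volume for fixed geometry", {
  small <- build_plan_triplet(generate_patient(
    small_spec(66, n_pockets = 2, pocket_semiaxes_range = c(8, 12))))
  big <- build_plan_triplet(generate_patient(
    small_spec(66, n_pockets = 2, pocket_semiaxes_range = c(16, 24))))
  agv_of <- function(trip) {
    gas <- rasterize_structure(trip$structures$GAS, trip$ct$grid)
    compute_agv(gas, trip$doses$APLAN, trip$prescription_dose)
  }
  expect_gt(agv_of(big), agv_of(small))
})

test_that("the slab interface experiment reproduces the qualitative interface physics", {
  sl <- slab_experiment(gap_red_values = c(0.0012, 0.1, 0.3, 0.5, 1.0))
  gpr <- sl$table$gpr
  expect_equal(gpr[1], 100)                 # air vs air: identity
  expect_true(all(diff(gpr) <= 0))          # more water-like, less air-like
  # the interface distortion fades by half water density: the depth-dose
  # beyond RED 0.5 differs from water by no more than pure attenuation
  pdd <- sl$pdd
  atten_bound <- function(red) exp(0.05 / 10 * (1 - red) * 30) - 1
  gap_05 <- max(abs(pdd$red_0.5 - pdd$red_1))
  gap_01 <- max(abs(pdd$red_0.1 - pdd$red_1))
  expect_lt(gap_05, atten_bound(0.5))
  expect_gt(gap_01, gap_05)                 # distortion shrinks with RED
})

test_that("small simulated cohorts run end to end and round-trip as CSV", {
  rec <- simulate_cohort(n_patients = 5, seed = 19)
  expect_equal(nrow(rec), 5)
  expect_true(all(rec$gprWA >= 0 & rec$gprWA <= 100))
  expect_true(all(rec$agv_cc >= 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_agv_records(rec, f)
  back <- read_agv_records(f)
  expect_equal(back$agv_cc, rec$agv_cc)
  expect_equal(back$gprWG, rec$gprWG, tolerance = 1e-12)
})
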