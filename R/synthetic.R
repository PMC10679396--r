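# Synthetic abdominal phantoms, the declared toy dose engine, plan
# triplets via gas RED override, the slab interface experiment, and
# end-to-end cohort simulation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic abdominal phantom specification
#'
#' Defines a reproducible phantom: an ellipsoidal soft-tissue body with
#' mild Gaussian HU texture, three gastrointestinal organ volumes (ST, SB,
#' LB), ellipsoidal gas pockets with Hounsfield values drawn from the
#' gas-pocket distribution (mean -620 HU, SD 90 HU), a spherical GTV and
#' its 3 mm isotropic PTV expansion.
#'
#' @param body_semiaxes body ellipsoid semi-axes (x, y, z) in mm.
#' @param spacing grid voxel pitch in mm.
#' @param gtv_radius GTV radius in mm.
#' @param ptv_margin isotropic GTV-to-PTV margin in mm.
#' @param n_pockets number of gas pockets.
#' @param pocket_semiaxes_range range (min, max) of pocket semi-axes in mm.
#' @param pocket_hu_mean,pocket_hu_sd gas-pocket HU distribution; draws
#'   are clipped below at -1000 HU.
#' @param body_hu_sd SD of the soft-tissue HU texture around 0 HU.
#' @param seed mandatory RNG seed; generation is fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_semiaxes = c(100, 80, 60),
                         spacing = c(2.5, 2.5, 2.5),
                         gtv_radius = 18, ptv_margin = 3,
                         n_pockets = 4,
                         pocket_semiaxes_range = c(6, 18),
                         pocket_hu_mean = -620, pocket_hu_sd = 90,
                         body_hu_sd = 10, seed) {
  if (missing(seed) || is.null(seed)) stop("phantom_spec requires a seed")
  stopifnot(length(body_semiaxes) == 3, all(body_semiaxes > 0),
            length(spacing) == 3, all(spacing > 0),
            gtv_radius > 0, ptv_margin >= 0, n_pockets >= 0,
            pocket_semiaxes_range[1] > 0,
            pocket_semiaxes_range[2] >= pocket_semiaxes_range[1])
  structure(list(body_semiaxes = body_semiaxes, spacing = spacing,
                 gtv_radius = gtv_radius, ptv_margin = ptv_margin,
                 n_pockets = n_pockets,
                 pocket_semiaxes_range = pocket_semiaxes_range,
                 pocket_hu_mean = pocket_hu_mean, pocket_hu_sd = pocket_hu_sd,
                 body_hu_sd = body_hu_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# polygonal contour stack (32-gon per slice) of an axis-aligned ellipsoid
.ellipsoid_contours <- function(center, semiaxes, grid, n_vertices = 32) {
  ax <- grid_axes(grid)
  zs <- ax$z[abs(ax$z - center[3]) < semiaxes[3]]
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  lapply(zs, function(z) {
    s <- sqrt(pmax(0, 1 - ((z - center[3]) / semiaxes[3])^2))
    cbind(x = center[1] + semiaxes[1] * s * cos(theta),
          y = center[2] + semiaxes[2] * s * sin(theta),
          z = z)
  })
}

.inside_ellipsoid <- function(center, semiaxes, grid) {
  ax <- grid_axes(grid)
  X <- ((ax$x - center[1]) / semiaxes[1])^2
  Y <- ((ax$y - center[2]) / semiaxes[2])^2
  Z <- ((ax$z - center[3]) / semiaxes[3])^2
  outer(outer(X, Y, `+`), Z, `+`) <= 1
}

#' Generate a synthetic patient case (CT + structures, no doses)
#'
#' Pockets are placed inside the organ volumes (cycling through ST, SB,
#' LB so the per-organ gas partitions are non-trivial) by rejection
#' sampling against mutual overlap; placement failing 1000 attempts is an
#' error. The CT gas voxels are filled through the same rasterization used
#' for analysis, so contoured GAS and imaged gas coincide voxel-wise.
#'
#' @param spec a [phantom_spec()].
#' @return A `patient_case` with structures GTV, PTV, ST, SB, LB, GAS.
#' @export
generate_patient <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    pad <- 6
    shape <- ceiling(2 * (spec$body_semiaxes + pad) / spec$spacing)
    grid <- voxel_grid(origin = -(shape - 1) / 2 * spec$spacing,
                       spacing = spec$spacing, shape = shape)
    b <- spec$body_semiaxes
    organs <- list(
      ST = list(center = c(-0.40 * b[1], -0.30 * b[2], 0.25 * b[3]),
                semiaxes = c(0.32 * b[1], 0.30 * b[2], 0.38 * b[3])),
      SB = list(center = c(0.38 * b[1], 0.25 * b[2], -0.20 * b[3]),
                semiaxes = c(0.33 * b[1], 0.34 * b[2], 0.40 * b[3])),
      LB = list(center = c(-0.28 * b[1], 0.42 * b[2], -0.22 * b[3]),
                semiaxes = c(0.30 * b[1], 0.32 * b[2], 0.38 * b[3])))
    gtv_center <- c(0.12 * b[1], -0.12 * b[2], 0)

    # pocket placement by rejection sampling inside the host organ;
    # voxel-level overlap test (analytic ellipsoids, 1 mm inflation)
    pockets <- list()
    if (spec$n_pockets > 0) {
      body_vox <- .inside_ellipsoid(c(0, 0, 0), spec$body_semiaxes, grid)
      blocked <- .inside_ellipsoid(gtv_center,
                                   rep(spec$gtv_radius + spec$ptv_margin + 1, 3),
                                   grid) | !body_vox
      for (p in seq_len(spec$n_pockets)) {
        organ <- organs[[((p - 1) %% 3) + 1]]
        placed <- FALSE
        for (attempt in seq_len(1000)) {
          semi <- stats::runif(3, spec$pocket_semiaxes_range[1],
                               spec$pocket_semiaxes_range[2])
          # crowded organs: progressively concede size rather than fail
          semi <- pmax(semi * (1 - attempt / 1200), spec$pocket_semiaxes_range[1] / 2)
          semi <- pmin(semi, 0.8 * organ$semiaxes)
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
          center <- organ$center + u * pmax(organ$semiaxes - semi, 0)
          cand <- .inside_ellipsoid(center, semi + 1, grid)
          if (!any(cand & blocked)) {
            pockets[[p]] <- list(center = center, semiaxes = semi,
                                 organ = names(organs)[((p - 1) %% 3) + 1])
            blocked <- blocked | cand
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("could not place gas pockets without overlap after 1000 attempts")
      }
    }

    structures <- list(
      GTV = .ellipsoid_contours(gtv_center, rep(spec$gtv_radius, 3), grid),
      PTV = .ellipsoid_contours(gtv_center,
                                rep(spec$gtv_radius + spec$ptv_margin, 3), grid),
      ST = .ellipsoid_contours(organs$ST$center, organs$ST$semiaxes, grid),
      SB = .ellipsoid_contours(organs$SB$center, organs$SB$semiaxes, grid),
      LB = .ellipsoid_contours(organs$LB$center, organs$LB$semiaxes, grid),
      GAS = if (length(pockets))
        do.call(c, lapply(pockets, function(p)
          .ellipsoid_contours(p$center, p$semiaxes, grid)))
      else list())

    body <- .inside_ellipsoid(c(0, 0, 0), spec$body_semiaxes, grid)
    hu <- array(-1000, dim = grid$shape)
    hu[body] <- pmax(stats::rnorm(sum(body), 0, spec$body_hu_sd), -1000)
    for (p in pockets) {
      m <- rasterize_structure(.ellipsoid_contours(p$center, p$semiaxes, grid),
                               grid)
      n <- sum(m$member)
      if (n) hu[m$member] <- pmax(stats::rnorm(n, spec$pocket_hu_mean,
                                               spec$pocket_hu_sd), -1000)
    }
    patient_case(scalar_volume(hu, grid, unit = "HU"), structures)
  })
}

#' Beam arrangement for the toy engine
#'
#' Beams are spread uniformly over the gantry circle except inside two
#' blocked sectors (couch-edge avoidance), mirroring the 24-beam template
#' with ~20-degree blocks centred at 120 and 240 degrees.
#'
#' @param n_beams number of beams.
#' @param blocked_centers,blocked_width centres and width (degrees) of the
#'   blocked sectors.
#' @param prescription prescription dose in Gy (prescribed at the 80%
#'   isodose in the clinical template; 35-40 Gy typical).
#' @param angles explicit beam angles in degrees (overrides the spread).
#' @param isocenter length-3 position in mm (defaults to the GTV centroid
#'   when the plan triplet is built).
#' @param field_halfwidth,field_halfheight field half-aperture in mm
#'   (in-plane lateral, and along z); defaults cover the PTV.
#' @return An object of class `beam_set`.
#' @export
beam_set <- function(n_beams = 24, blocked_centers = c(120, 240),
                     blocked_width = 20, prescription = 38,
                     angles = NULL, isocenter = NULL,
                     field_halfwidth = NULL, field_halfheight = NULL) {
  stopifnot(prescription > 0)
  if (is.null(angles)) {
    lo <- (blocked_centers - blocked_width / 2) %% 360
    hi <- (blocked_centers + blocked_width / 2) %% 360
    blocked_len <- length(blocked_centers) * blocked_width
    allowed <- 360 - blocked_len
    t <- (seq_len(n_beams) - 0.5) * allowed / n_beams
    # map arc-length parameter to angle, skipping blocked sectors
    angles <- vapply(t, function(ti) {
      a <- ti
      for (s in seq_along(lo)) if (a >= lo[s]) a <- a + blocked_width
      a %% 360
    }, numeric(1))
  }
  structure(list(n_beams = length(angles), angles = angles,
                 blocked_centers = blocked_centers,
                 blocked_width = blocked_width,
                 prescription = prescription, isocenter = isocenter,
                 field_halfwidth = field_halfwidth,
                 field_halfheight = field_halfheight),
            class = "beam_set")
}

#' Toy dose engine parameters
#'
#' A declared stand-in for a Monte Carlo dose engine: per beam the dose
#' follows `exp(-mu * radiological depth)` with a Gaussian-penumbra flat
#' field, plus an interface perturbation emulating the electron return
#' effect at tissue-gas boundaries: dose is lowered inside the cavity
#' (recovering over a rebuild length that grows as the cavity density
#' falls) and raised on the proximal tissue side. The perturbation
#' amplitude is `ere_gain * max(0, 1 - RED/red_sat)`: proportional to
#' `(1 - RED)` near air and vanishing at half water density, where the
#' interface effect is observed to disappear.
#'
#' @param mu_per_cm effective attenuation per unit radiological path
#'   (1/cm).
#' @param sigma_mm lateral penumbra sigma in mm.
#' @param ere_gain dimensionless perturbation gain; 0 disables it.
#' @param ere_range_mm rebuild/backscatter range in mm at unit density.
#' @param red_sat RED at and above which the interface perturbation
#'   vanishes.
#' @param step_mm ray-marching step in mm.
#' @return An object of class `engine_params`.
#' @export
engine_params <- function(mu_per_cm = 0.05, sigma_mm = 3, ere_gain = 0.3,
                          ere_range_mm = 10, red_sat = 0.5, step_mm = 2) {
  stopifnot(mu_per_cm >= 0, sigma_mm >= 0, ere_gain >= 0, ere_range_mm >= 0,
            red_sat > 0, step_mm > 0)
  structure(list(mu_per_cm = mu_per_cm, sigma_mm = sigma_mm,
                 ere_gain = ere_gain, ere_range_mm = ere_range_mm,
                 red_sat = red_sat, step_mm = step_mm),
            class = "engine_params")
}

#' Run the toy dose engine
#'
#' Deterministic: identical inputs give identical dose. The output is in
#' engine units; plan builders rescale it to the prescription.
#'
#' @param red `scalar_volume` in RED (not identically zero).
#' @param beams a [beam_set()] with `isocenter`, `field_halfwidth` and
#'   `field_halfheight` set.
#' @param params an [engine_params()].
#' @return A `scalar_volume` in Gy (engine units before normalization).
#' @export
toy_dose_engine <- function(red, beams, params = engine_params()) {
  stopifnot(inherits(red, "scalar_volume"), red$unit == "RED",
            inherits(beams, "beam_set"), inherits(params, "engine_params"))
  if (max(red$values) <= 0) stop("RED volume is zero everywhere")
  if (is.null(beams$isocenter) || is.null(beams$field_halfwidth) ||
      is.null(beams$field_halfheight))
    stop("beam_set needs isocenter and field apertures; see build_plan_triplet")
  g <- red$grid
  d <- engine_dose_cpp(as.numeric(red$values), g$shape, g$spacing, g$origin,
                       beams$angles, beams$isocenter,
                       beams$field_halfwidth, beams$field_halfheight,
                       params$mu_per_cm / 10, params$sigma_mm,
                       params$ere_gain, params$ere_range_mm, params$red_sat,
                       params$step_mm, 0.8, 50)
  scalar_volume(array(d, dim = g$shape), g, unit = "Gy")
}

#' Build the APLAN / WPLAN / GPLAN density-override plan triplet
#'
#' Converts the CT to relative electron density through the calibration
#' curve, overrides the GAS volume RED with air (0.0012), water (1.000)
#' and GIGED respectively, and recomputes dose with the same beams for all
#' three plans -- no re-optimization. One common scale factor, chosen on
#' the air-override plan so that the near-minimum PTV dose (D98) equals
#' the prescription, is applied to the whole triplet.
#'
#' @param case a `patient_case` with GAS (and ideally GTV/PTV) structures.
#' @param calibration a `calibration_curve`.
#' @param engine an [engine_params()].
#' @param beams a [beam_set()]; isocenter and apertures default to the GTV
#'   centroid and the PTV extent.
#' @param giged_red RED used for the GPLAN override (default: GIGED from
#'   the calibration at -620 HU, i.e. 0.38 on the default curve).
#' @return The case with doses `APLAN`, `WPLAN`, `GPLAN` and
#'   `prescription_dose` set.
#' @export
build_plan_triplet <- function(case, calibration = default_calibration(),
                               engine = engine_params(), beams = beam_set(),
                               giged_red = NULL) {
  stopifnot(inherits(case, "patient_case"))
  if (is.null(case$structures$GAS)) stop("case has no GAS structure")
  g <- case$ct$grid
  gas <- rasterize_structure(case$structures$GAS, g)
  red0 <- .ct_to_red_volume(calibration, case$ct)
  giged_red <- giged_red %||% giged(calibration, -620)

  if (is.null(beams$isocenter) || is.null(beams$field_halfwidth) ||
      is.null(beams$field_halfheight)) {
    tgt <- if (!is.null(case$structures$PTV)) "PTV" else "GTV"
    if (is.null(case$structures[[tgt]]))
      stop("case needs a GTV/PTV structure to aim the beams")
    ptv <- rasterize_structure(case$structures[[tgt]], g)
    ctr <- mask_centroid(ptv)
    idx <- which(ptv$member, arr.ind = TRUE)
    pos <- sweep(sweep(idx - 1, 2, g$spacing, `*`), 2, g$origin, `+`)
    lat <- max(sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2))
    vert <- max(abs(pos[, 3] - ctr[3]))
    beams$isocenter <- beams$isocenter %||% ctr
    beams$field_halfwidth <- beams$field_halfwidth %||% (lat + 3)
    beams$field_halfheight <- beams$field_halfheight %||% (vert + 3)
  }

  overrides <- c(APLAN = 0.0012, WPLAN = 1.000, GPLAN = giged_red)
  doses <- lapply(overrides, function(v)
    toy_dose_engine(override_red(red0, gas, v), beams, engine))

  ptv_mask <- if (!is.null(case$structures$PTV))
    rasterize_structure(case$structures$PTV, g) else NULL
  raw_ap <- doses$APLAN
  scale <- if (!is.null(ptv_mask) && any(ptv_mask$member)) {
    beams$prescription / dose_at_volume(cumulative_dvh(raw_ap, ptv_mask,
                                                       bin_width = 0.001), 98)
  } else {
    beams$prescription / (0.8 * max(raw_ap$values))
  }
  doses <- lapply(doses, function(d)
    scalar_volume(d$values * scale, g, unit = "Gy"))
  patient_case(case$ct, case$structures, doses,
               prescription_dose = beams$prescription)
}

#' Slab-phantom interface experiment
#'
#' A solid-water cube with a full-width density gap, irradiated by a
#' single fixed field from the top; the gap RED is varied and each dose
#' distribution is compared, on the axial plane through the isocentre,
#' against the air-RED reference by 2-D gamma analysis (1%/1 mm by
#' default). Central-axis depth-dose curves are also returned.
#'
#' @param gap_red_values RED values for the gap.
#' @param engine an [engine_params()].
#' @param side slab side length in mm.
#' @param spacing grid spacing in mm (x, depth, z).
#' @param gap_top,gap_thickness gap position below the entry surface, and
#'   thickness, in mm.
#' @param field field side in mm (square field).
#' @param rx dose at the isocentre in Gy.
#' @param reference_red the reference gap RED (air).
#' @param criteria [gamma_criteria()] for the comparison.
#' @return List with `table` (data frame `red`, `gpr`), `pdd` (data frame:
#'   `depth_mm` plus one normalized column per RED, including the
#'   reference), and the geometry used.
#' @export
slab_experiment <- function(gap_red_values = seq(0.1, 1.0, by = 0.1),
                            engine = engine_params(),
                            side = 300, spacing = c(5, 2.5, 5),
                            gap_top = 75, gap_thickness = 30,
                            field = 100, rx = 10,
                            reference_red = 0.0012,
                            criteria = gamma_criteria()) {
  stopifnot(length(gap_red_values) >= 1)
  shape <- round(side / spacing)
  grid <- voxel_grid(origin = c(-(shape[1] - 1) / 2 * spacing[1],
                                spacing[2] / 2,
                                -(shape[3] - 1) / 2 * spacing[3]),
                     spacing = spacing, shape = shape)
  ax <- grid_axes(grid)
  gap_slices <- which(ax$y >= gap_top & ax$y < gap_top + gap_thickness)
  iso <- c(0, side / 2, 0)
  beams <- beam_set(angles = 270, prescription = rx, isocenter = iso,
                    field_halfwidth = field / 2, field_halfheight = field / 2)
  run <- function(red_gap) {
    red <- array(1, dim = grid$shape)
    red[, gap_slices, ] <- red_gap
    d <- toy_dose_engine(scalar_volume(red, grid, unit = "RED"), beams, engine)
    ii <- round((iso - grid$origin) / grid$spacing) + 1
    scalar_volume(d$values * rx / d$values[ii[1], ii[2], ii[3]], grid, "Gy")
  }
  ref_dose <- run(reference_red)
  iso_k <- round((iso[3] - grid$origin[3]) / grid$spacing[3]) + 1
  iso_i <- round((iso[1] - grid$origin[1]) / grid$spacing[1]) + 1
  pdd <- data.frame(depth_mm = ax$y)
  cax <- ref_dose$values[iso_i, , iso_k]
  pdd[[sprintf("red_%g", reference_red)]] <- cax / max(cax)
  gpr <- numeric(length(gap_red_values))
  for (m in seq_along(gap_red_values)) {
    d <- run(gap_red_values[m])
    gpr[m] <- gamma_2d(ref_dose$values[, , iso_k], d$values[, , iso_k],
                       grid$spacing[1:2], criteria)$gpr
    cax <- d$values[iso_i, , iso_k]
    pdd[[sprintf("red_%g", gap_red_values[m])]] <- cax / max(cax)
  }
  list(table = data.frame(red = gap_red_values, gpr = gpr),
       pdd = pdd, reference_red = reference_red,
       grid = grid, gap_slices = gap_slices)
}

#' Simulate a cohort through the full pipeline
#'
#' Per patient: generate a phantom with randomized pocket count and size,
#' build the density-override plan triplet, run the three plan
#' comparisons, and compute the AGV on the air-override (APLAN) dose.
#'
#' @param n_patients cohort size (>= 5).
#' @param seed master seed; per-patient phantoms derive their own seeds
#'   from it.
#' @param spec_template a [phantom_spec()] providing the common geometry
#'   (its seed and pocket fields are re-drawn per patient).
#' @param n_pockets_range,pocket_scale_range per-patient ranges for pocket
#'   count and for the scale factor applied to the template's pocket
#'   semi-axes range.
#' @param calibration,engine,beams,criteria pipeline settings.
#' @return AGV records data frame (`patient`, `gprWA`, `gprWG`, `gprGA`,
#'   `agv_cc`).
#' @export
simulate_cohort <- function(n_patients = 21, seed,
                            spec_template = phantom_spec(spacing = c(5, 5, 5),
                                                         seed = 1),
                            n_pockets_range = c(1, 6),
                            pocket_scale_range = c(0.5, 1.5),
                            calibration = default_calibration(),
                            engine = engine_params(), beams = beam_set(),
                            criteria = gamma_criteria()) {
  stopifnot(n_patients >= 5)
  if (missing(seed)) stop("simulate_cohort requires a seed")
  draws <- .with_seed(seed, data.frame(
    n_pockets = sample(n_pockets_range[1]:n_pockets_range[2], n_patients,
                       replace = TRUE),
    scale = stats::runif(n_patients, pocket_scale_range[1],
                         pocket_scale_range[2]),
    sub_seed = sample.int(2^30, n_patients)))
  records <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    spec <- spec_template
    spec$n_pockets <- draws$n_pockets[i]
    spec$pocket_semiaxes_range <- pmin(spec$pocket_semiaxes_range *
                                         draws$scale[i], 35)
    spec$seed <- draws$sub_seed[i]
    case <- generate_patient(spec)
    case <- build_plan_triplet(case, calibration, engine, beams)
    gas <- rasterize_structure(case$structures$GAS, case$ct$grid)
    records[[i]] <- data.frame(
      patient = sprintf("Sim %d", i),
      gprWA = compare_plans(case, "WPLAN", "APLAN", criteria)$mean_gpr,
      gprWG = compare_plans(case, "WPLAN", "GPLAN", criteria)$mean_gpr,
      gprGA = compare_plans(case, "GPLAN", "APLAN", criteria)$mean_gpr,
      agv_cc = compute_agv(gas, case$doses$APLAN, case$prescription_dose))
  }
  do.call(rbind, records)
}
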