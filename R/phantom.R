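#' Parameters of the paired-course CT phantom
#'
#' The phantom emulates the structure of a two-course adaptive
#' radiotherapy case: an elliptical soft-tissue body cylinder (about
#' 0 HU) on an air background (-1000 HU), a visible lesion whose CTV is
#' the lesion plus a fixed margin, and two bone-surrogate rods (+700 HU)
#' that give the registration gradient structure. The second course is
#' the same scene observed through an unknown rigid offset plus a smooth
#' deformation, with the lesion regrown/regressed by a per-case scale,
#' its conspicuity faded, and independent voxel noise.
#'
#' @param grid_shape Voxel triple of the rendered grids.
#' @param spacing_mm Voxel spacing in mm.
#' @param body_radius_frac Body cylinder radius as a fraction of the
#'   lateral physical extent.
#' @param target_radii_mm Semi-axes (mm) of the target ellipsoid.
#' @param rigid_offset_mm Inter-course translation (mm); also the per-axis
#'   draw range for cohorts.
#' @param rigid_rotation_deg Inter-course rotation about x/y/z (degrees);
#'   also the per-axis cohort draw range.
#' @param deform_amplitude_mm Maximum displacement of the smooth warp.
#' @param deform_scale_mm Correlation length of the warp; the amplitude
#'   must stay below half this value so the map remains invertible.
#' @param ctv_margin_mm Fixed margin added to the visible lesion
#'   semi-axes to form the CTV (margins are rule-based, so they do not
#'   scale with lesion regression — the component of CTV change that
#'   intensity-driven registration propagates incorrectly).
#' @param target_scale2 Multiplier on the target semi-axes at course 2,
#'   emulating tumor regression/growth between courses — the component of
#'   CTV change that intensity-driven registration tracks only partially.
#' @param target_fade2 Multiplier on the lesion's intensity contrast at
#'   course 2 (post-treatment changes reduce tumor conspicuity), so the
#'   second-course image alone under-determines the target boundary.
#' @param decoy_scale Relative size of a decoy structure with the same
#'   contrast as the lesion on the opposite side of the body (a
#'   neighbouring organ that is not part of the CTV). It makes the
#'   second-course image ambiguous without prior-course guidance; 0
#'   disables it.
#' @param lesion_side +1 or -1: which side of the body hosts the lesion
#'   (the decoy sits on the opposite side). Cohorts draw it at random per
#'   case, so the second-course image alone cannot tell target from
#'   decoy.
#' @param target_scale2_range Per-case draw range of `target_scale2` used
#'   by [generate_cohort()].
#' @param noise_sd_hu Standard deviation of the additive intensity noise.
#' @param organ_contrast_hu Named HU values for `air`, `body`, `target`
#'   (contrast added on top of body), and `bone`.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(64, 64, 48),
                           spacing_mm = c(2.5, 2.5, 2.5),
                           body_radius_frac = 0.40,
                           target_radii_mm = c(18, 14, 18),
                           rigid_offset_mm = c(6, 3, 2),
                           rigid_rotation_deg = c(0, 0, 3),
                           deform_amplitude_mm = 8,
                           deform_scale_mm = 40,
                           ctv_margin_mm = 10,
                           target_scale2 = 1,
                           target_scale2_range = c(0.7, 1.3),
                           target_fade2 = 0.75,
                           decoy_scale = 0.9,
                           lesion_side = 1,
                           noise_sd_hu = 20,
                           organ_contrast_hu = c(air = -1000, body = 0,
                                                 target = 60, bone = 700)) {
  p <- list(grid_shape = as.integer(grid_shape),
            spacing_mm = as.numeric(spacing_mm),
            body_radius_frac = body_radius_frac,
            target_radii_mm = as.numeric(target_radii_mm),
            rigid_offset_mm = as.numeric(rigid_offset_mm),
            rigid_rotation_deg = as.numeric(rigid_rotation_deg),
            deform_amplitude_mm = deform_amplitude_mm,
            deform_scale_mm = deform_scale_mm,
            ctv_margin_mm = ctv_margin_mm,
            target_scale2 = target_scale2,
            target_fade2 = target_fade2,
            decoy_scale = decoy_scale,
            lesion_side = sign(lesion_side),
            target_scale2_range = as.numeric(target_scale2_range),
            noise_sd_hu = noise_sd_hu,
            organ_contrast_hu = organ_contrast_hu)
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  if (any(p$target_radii_mm <= 0) || p$deform_scale_mm <= 0 ||
      p$body_radius_frac <= 0 || any(p$spacing_mm <= 0))
    stop("all radii and scales must be strictly positive")
  if (p$deform_amplitude_mm < 0)
    stop("deform_amplitude_mm must be nonnegative")
  if (p$deform_amplitude_mm > 0 &&
      p$deform_amplitude_mm >= p$deform_scale_mm / 2)
    stop("deform_amplitude_mm must stay below deform_scale_mm / 2 ",
         "to keep the warp invertible")
  body_r <- 0.8 * p$body_radius_frac *
    min(p$grid_shape[1:2] * p$spacing_mm[1:2])  # minor semi-axis
  smax <- max(1, p$target_scale2,
              if (!is.null(p$target_scale2_range)) p$target_scale2_range)
  if (smax * max(p$target_radii_mm[1:2]) + p$ctv_margin_mm +
      p$deform_amplitude_mm + max(abs(p$rigid_offset_mm[1:2])) >= body_r)
    stop("target ellipsoid does not fit inside the body cylinder at both ",
         "courses")
  invisible(p)
}

phantom_center_mm <- function(p) (p$grid_shape - 1) * p$spacing_mm / 2

# Analytic scene evaluation: HU value and target membership at arbitrary
# physical points (mm) in the course-1 frame.
phantom_scene <- function(pts, p, target_scale = 1, target_fade = 1) {
  ctr <- phantom_center_mm(p)
  body_r <- p$body_radius_frac * min(p$grid_shape[1:2] * p$spacing_mm[1:2])
  hu <- rep(p$organ_contrast_hu[["air"]], nrow(pts))
  # elliptical body cross-section (pelvis-like); the azimuthal asymmetry
  # makes rotations observable to intensity-based registration
  r2 <- ((pts[, 1] - ctr[1]) / 1.15)^2 + ((pts[, 2] - ctr[2]) / 0.8)^2
  in_body <- r2 <= body_r^2
  hu[in_body] <- p$organ_contrast_hu[["body"]]
  # bone-surrogate rods, parallel to the axial direction
  rod_r <- 0.12 * body_r + 3
  for (sgn in c(-1, 1)) {
    rod_c <- ctr[1:2] + c(sgn * 0.55 * body_r, 0)
    in_rod <- ((pts[, 1] - rod_c[1])^2 + (pts[, 2] - rod_c[2])^2) <=
      rod_r^2
    hu[in_rod & in_body] <- p$organ_contrast_hu[["bone"]]
  }
  # decoy organ: same contrast as the lesion, opposite side, stable
  # across courses, not part of the CTV
  if (p$decoy_scale > 0) {
    dc <- ctr + c(0, -p$lesion_side * 0.24 * body_r, 0)
    radd <- p$target_radii_mm * p$decoy_scale
    ed <- ((pts[, 1] - dc[1]) / radd[1])^2 +
      ((pts[, 2] - dc[2]) / radd[2])^2 +
      ((pts[, 3] - dc[3]) / radd[3])^2
    hu[ed <= 1] <- p$organ_contrast_hu[["body"]] +
      p$organ_contrast_hu[["target"]]
  }
  # target ellipsoid, offset from centre to break symmetry
  tc <- ctr + c(0, p$lesion_side * 0.24 * body_r, 0)
  rad <- p$target_radii_mm * target_scale
  e <- ((pts[, 1] - tc[1]) / rad[1])^2 +
    ((pts[, 2] - tc[2]) / rad[2])^2 +
    ((pts[, 3] - tc[3]) / rad[3])^2
  in_lesion <- e <= 1
  hu[in_lesion] <- p$organ_contrast_hu[["body"]] +
    target_fade * p$organ_contrast_hu[["target"]]
  # CTV = visible lesion + fixed (unscaled) margin
  radm <- rad + p$ctv_margin_mm
  em <- ((pts[, 1] - tc[1]) / radm[1])^2 +
    ((pts[, 2] - tc[2]) / radm[2])^2 +
    ((pts[, 3] - tc[3]) / radm[3])^2
  list(hu = hu, target = as.integer(em <= 1))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic paired-course case
#'
#' Renders the analytic phantom on the course-1 grid, composes the
#' requested rigid offset with a smooth random warp, and re-renders the
#' scene in warped coordinates for course 2 (so the ground-truth
#' inter-course transform is exact, not a raster warp). Fully reproducible
#' from `seed`.
#'
#' @param params A [phantom_params()].
#' @param seed Integer seed controlling warp and noise.
#' @param case_id Identifier stored with the case.
#' @return A list of class `rg_case` with elements `ct1`, `ctv1`, `ct2`,
#'   `ctv2`, `true_transform` (dense DVF mapping course-2 points into the
#'   course-1 frame), `case_id`, and `seed`.
#' @export
generate_case <- function(params, seed = 0L, case_id = sprintf("case%04d",
                                                               seed)) {
  validate_phantom_params(params)
  p <- params
  dims <- p$grid_shape
  sp <- p$spacing_mm
  hu_lim <- c(-1000, 1500)
  with_seed(seed, {
    pts <- voxel_centers_mm(dims, sp)
    s1 <- phantom_scene(pts, p)
    ct1 <- s1$hu + rnorm(nrow(pts), 0, p$noise_sd_hu)
    ct1 <- pmin(pmax(ct1, hu_lim[1]), hu_lim[2])
    ctv1 <- array(s1$target, dims)
    if (sum(ctv1) == 0) stop("course-1 target is empty on this grid")

    u <- random_smooth_warp(dims, sp, p$deform_scale_mm,
                            p$deform_amplitude_mm)
    rig <- rigid_transform(p$rigid_rotation_deg, p$rigid_offset_mm,
                           phantom_center_mm(p))
    mapped <- transform_points(rig, pts) + matrix(u, nrow(pts), 3)
    s2 <- phantom_scene(mapped, p, target_scale = p$target_scale2,
                        target_fade = p$target_fade2)
    ct2 <- s2$hu + rnorm(nrow(pts), 0, p$noise_sd_hu)
    ct2 <- pmin(pmax(ct2, hu_lim[1]), hu_lim[2])
    ctv2 <- array(s2$target, dims)
    if (sum(ctv2) == 0)
      stop("target leaves the grid under the requested transform ",
           "(course-2 target empty); reduce the offset/warp")
    edge <- ctv2
    edge[2:(dims[1] - 1), 2:(dims[2] - 1), 2:(dims[3] - 1)] <- 0L
    if (sum(edge) > 0)
      stop("target leaves the grid under the requested transform ",
           "(course-2 target touches the grid boundary)")

    dvf <- array(mapped - pts, c(dims, 3))
    tt <- dvf_transform(dvf, sp, c(0, 0, 0),
                        meta = list(rigid_rotation_deg =
                                      p$rigid_rotation_deg,
                                    rigid_offset_mm = p$rigid_offset_mm,
                                    deform_amplitude_mm =
                                      p$deform_amplitude_mm,
                                    seed = seed))
    structure(list(case_id = case_id,
                   ct1 = rg_volume(array(ct1, dims), sp),
                   ctv1 = rg_mask(ctv1, sp),
                   ct2 = rg_volume(array(ct2, dims), sp),
                   ctv2 = rg_mask(ctv2, sp),
                   true_transform = tt,
                   seed = seed, params = p),
              class = "rg_case")
  })
}

derive_case_seed <- function(cohort_seed, i) {
  as.integer((as.numeric(cohort_seed) * 1000 + 2 * i) %%
               .Machine$integer.max)
}

#' Generate a cohort of paired-course cases
#'
#' Per-case seeds are derived from the cohort seed by a counter scheme and
#' per-case transform parameters are drawn from the ranges in `params`
#' (translation and rotation uniform over +/- the stated component, warp
#' amplitude uniform over 50-100% of the stated maximum), so cases differ
#' while remaining reproducible.
#'
#' @param n_cases Number of cases (>= 1).
#' @inheritParams generate_case
#' @return A list of `rg_case` objects.
#' @export
generate_cohort <- function(n_cases, params = phantom_params(), seed = 0L) {
  stopifnot(n_cases >= 1)
  lapply(seq_len(n_cases), function(i) {
    cs <- derive_case_seed(seed, i)
    pi <- with_seed(cs, {
      p <- params
      p$rigid_offset_mm <- runif(3, -1, 1) * params$rigid_offset_mm
      p$rigid_rotation_deg <- runif(3, -1, 1) * params$rigid_rotation_deg
      if (params$deform_amplitude_mm > 0)
        p$deform_amplitude_mm <- runif(1, 0.5, 1) *
          params$deform_amplitude_mm
      p$target_scale2 <- runif(1, params$target_scale2_range[1],
                               params$target_scale2_range[2])
      p$lesion_side <- sample(c(-1, 1), 1)
      p
    })
    generate_case(pi, cs + 1L, case_id = sprintf("case%04d", i))
  })
}

#' Write a phantom case to disk as NIfTI plus a JSON sidecar
#'
#' @param case An `rg_case`.
#' @param dir Output directory (created if missing).
#' @return The sidecar path, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- case$case_id
  write_volume(case$ct1, file.path(dir, paste0(id, "_ct1.nii.gz")))
  write_volume(case$ctv1, file.path(dir, paste0(id, "_ctv1.nii.gz")))
  write_volume(case$ct2, file.path(dir, paste0(id, "_ct2.nii.gz")))
  write_volume(case$ctv2, file.path(dir, paste0(id, "_ctv2.nii.gz")))
  write_transform(case$true_transform,
                  file.path(dir, paste0(id, "_true_transform")))
  side <- list(case_id = id, seed = case$seed,
               rigid_rotation_deg = case$true_transform$meta$rigid_rotation_deg,
               rigid_offset_mm = case$true_transform$meta$rigid_offset_mm)
  jp <- file.path(dir, paste0(id, ".json"))
  jsonlite::write_json(side, jp, auto_unbox = TRUE, digits = NA)
  invisible(jp)
}
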