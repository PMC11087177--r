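#' Preprocessing configuration
#'
#' Settings of the preprocessing chain applied before training: axial slab
#' extraction (48 slices containing the whole target), cropping to the
#' union of the two body contours, resampling to a fixed training grid
#' (192 x 160 x 48 by default), and HU truncation to (-1000, 1500) with
#' linear normalization to (0, 1).
#'
#' @param slab_slices Number of contiguous axial slices to extract.
#' @param target_shape Voxel triple of the training grid; its axial extent
#'   must equal `slab_slices`.
#' @param hu_window HU truncation window (lower, upper).
#' @param body_threshold_hu Threshold for body-contour extraction.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(slab_slices = 48,
                              target_shape = c(192, 160, 48),
                              hu_window = c(-1000, 1500),
                              body_threshold_hu = -300) {
  if (target_shape[3] != slab_slices)
    stop("target_shape axial extent must equal slab_slices")
  if (hu_window[1] >= hu_window[2])
    stop("hu_window lower bound must be below the upper bound")
  structure(list(slab_slices = as.integer(slab_slices),
                 target_shape = as.integer(target_shape),
                 hu_window = as.numeric(hu_window),
                 body_threshold_hu = body_threshold_hu),
            class = "preprocess_config")
}

crop_volume <- function(vol, xr, yr, zr = NULL) {
  d <- vol_dims(vol)
  if (is.null(zr)) zr <- c(1L, d[3])
  a <- vol$data[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2], drop = FALSE]
  origin <- vol$origin + (c(xr[1], yr[1], zr[1]) - 1) * vol$spacing
  if (is_mask(vol)) rg_mask(a, vol$spacing, origin)
  else rg_volume(a, vol$spacing, origin)
}

#' Extract the axial slab containing the target
#'
#' Returns exactly `slab_slices` contiguous axial slices whose range
#' contains every mask-positive slice, centred on the mask's axial
#' midpoint when there is slack (clamped to the volume).
#'
#' @param ct An [rg_volume].
#' @param mask A nonempty [rg_mask] on the same lattice.
#' @param cfg A [preprocess_config()].
#' @return A list with the cropped `ct`, `mask`, and the 1-based slice
#'   range `slab`.
#' @export
extract_slab <- function(ct, mask, cfg = preprocess_config()) {
  stop_if_lattice_mismatch(ct, mask)
  d <- vol_dims(ct)
  ns <- cfg$slab_slices
  if (d[3] < ns)
    stop("volume has ", d[3], " axial slices; cannot extract a ", ns,
         "-slice slab")
  zpos <- which(apply(mask$data, 3, sum) > 0)
  if (length(zpos) == 0) stop("mask is empty")
  z0 <- min(zpos)
  z1 <- max(zpos)
  if (z1 - z0 + 1L > ns)
    stop("mask spans ", z1 - z0 + 1L, " axial slices; cannot be contained ",
         "in a ", ns, "-slice slab")
  mid <- floor((z0 + z1) / 2)
  start <- mid - ns %/% 2 + 1L
  start <- max(1L, min(start, d[3] - ns + 1L))
  start <- min(start, z0)            # keep the mask inside the slab
  start <- max(start, z1 - ns + 1L)
  zr <- c(start, start + ns - 1L)
  list(ct = crop_volume(ct, c(1L, d[1]), c(1L, d[2]), zr),
       mask = crop_volume(mask, c(1L, d[1]), c(1L, d[2]), zr),
       slab = zr)
}

#' Body mask from a CT volume
#'
#' Thresholds the HU volume, keeps the largest 3D connected component,
#' applies a one-voxel morphological closing, and fills internal holes —
#' the standard CT body-contour construction.
#'
#' @param ct An HU-valued [rg_volume].
#' @param cfg A [preprocess_config()]; `body_threshold_hu` is the cut.
#' @return An [rg_mask].
#' @export
body_mask <- function(ct, cfg = preprocess_config()) {
  d <- vol_dims(ct)
  fg <- array(as.integer(ct$data >= cfg$body_threshold_hu), d)
  if (sum(fg) == 0)
    stop("no voxels above the body threshold (", cfg$body_threshold_hu,
         " HU)")
  lab <- array(cpp_label3d(as.integer(fg), as.integer(d)), d)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  m <- array(as.integer(lab == keep), d)
  # one-voxel closing in voxel metric
  dil <- cpp_edt_sq(as.integer(m), as.integer(d), c(1, 1, 1)) <= 1.001
  ero <- cpp_edt_sq(as.integer(!dil), as.integer(d), c(1, 1, 1)) > 1.001
  m <- array(as.integer(ero), d)
  # fill holes: background components not touching the grid boundary
  bg <- array(as.integer(m == 0L), d)
  blab <- array(cpp_label3d(as.integer(bg), as.integer(d)), d)
  border <- unique(c(blab[1, , ], blab[d[1], , ], blab[, 1, ],
                     blab[, d[2], ], blab[, , 1], blab[, , d[3]]))
  border <- border[border > 0]
  hole <- blab > 0 & !(blab %in% border)
  m[hole] <- 1L
  rg_mask(m, ct$spacing, ct$origin)
}

#' Crop volumes to the union of the two body contours
#'
#' The crop box is the lateral bounding box of the union of the body
#' masks of `ct2` and the aligned `act1`; the identical box is applied to
#' every input (axial extent untouched — that is the slab's job).
#'
#' @param ct2 Second-course CT ([rg_volume]).
#' @param act1 Aligned first-course CT on the same lattice.
#' @param masks List of [rg_mask] objects to crop with the same box.
#' @param cfg A [preprocess_config()].
#' @return A list with cropped `ct2`, `act1`, `masks`, and the `box`
#'   (`xr`, `yr`).
#' @export
crop_to_union <- function(ct2, act1, masks = list(),
                          cfg = preprocess_config()) {
  stop_if_lattice_mismatch(ct2, act1)
  u <- body_mask(ct2, cfg)$data | body_mask(act1, cfg)$data
  xs <- which(apply(u, 1, any))
  ys <- which(apply(u, 2, any))
  xr <- range(xs)
  yr <- range(ys)
  list(ct2 = crop_volume(ct2, xr, yr),
       act1 = crop_volume(act1, xr, yr),
       masks = lapply(masks, crop_volume, xr = xr, yr = yr),
       box = list(xr = xr, yr = yr))
}

#' Resample a volume and mask to the fixed training grid
#'
#' Linear interpolation for the image, nearest neighbour for the mask;
#' the physical extent is preserved, so the output spacing is
#' `extent / target_shape`.
#'
#' @param vol An [rg_volume] (may be `NULL`).
#' @param mask An [rg_mask] on the same lattice (may be `NULL`).
#' @param cfg A [preprocess_config()].
#' @return A list with resampled `vol` and `mask`.
#' @export
resample_to_grid <- function(vol, mask = NULL, cfg = preprocess_config()) {
  template <- vol %||% mask
  d <- vol_dims(template)
  td <- cfg$target_shape
  new_spacing <- d * template$spacing / td
  edge <- template$origin - template$spacing / 2
  pts <- voxel_centers_mm(td, new_spacing, edge + new_spacing / 2)
  # clamp to the source extent so edge voxels interpolate, not background
  for (ax in 1:3) {
    lo <- template$origin[ax]
    hi <- template$origin[ax] + (d[ax] - 1) * template$spacing[ax]
    pts[, ax] <- pmin(pmax(pts[, ax], lo), hi)
  }
  out_vol <- NULL
  out_mask <- NULL
  new_origin <- edge + new_spacing / 2
  if (!is.null(vol)) {
    vals <- cpp_sample_volume(vol$data, d, vol$spacing, vol$origin, pts,
                              0L, -1000)
    out_vol <- rg_volume(array(vals, td), new_spacing, new_origin)
  }
  if (!is.null(mask)) {
    vals <- cpp_sample_volume(mask$data, vol_dims(mask), mask$spacing,
                              mask$origin, pts, 1L, 0)
    out_mask <- rg_mask(array(as.integer(vals), td), new_spacing,
                        new_origin)
  }
  list(vol = out_vol, mask = out_mask)
}

#' Truncate and normalize HU intensities
#'
#' Clips to the HU window and maps it affinely to `[0, 1]`. Input whose
#' values already lie in `[0, 1]` is treated as normalized and returned
#' unchanged, which makes the preprocessing chain idempotent.
#'
#' @param vol An HU-valued [rg_volume].
#' @param cfg A [preprocess_config()].
#' @return An [rg_volume] with values in `[0, 1]`.
#' @export
normalize_hu <- function(vol, cfg = preprocess_config()) {
  rng <- range(vol$data)
  if (rng[1] >= 0 && rng[2] <= 1) return(vol)
  w <- cfg$hu_window
  a <- pmin(pmax(vol$data, w[1]), w[2])
  a <- (a - w[1]) / (w[2] - w[1])
  rg_volume(array(a, vol_dims(vol)), vol$spacing, vol$origin)
}
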