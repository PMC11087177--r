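#' Registration configuration
#'
#' Settings shared by the rigid and B-spline stages: Mattes mutual
#' information as the rigid similarity metric, a regular-step gradient
#' descent with initial step 8 that terminates after `max_iterations`
#' candidate evaluations or when the step falls below `min_step`, a
#' four-level multiresolution pyramid, and a B-spline control-point
#' spacing of 16 voxels at the finest level.
#'
#' @param metric Similarity metric of the rigid stage.
#' @param optimizer_initial_step Initial step (mm / degrees).
#' @param max_iterations Iteration budget per pyramid level.
#' @param min_step Termination step size.
#' @param pyramid_levels Number of multiresolution levels (>= 1).
#' @param grid_spacing_voxels B-spline control-point spacing at the finest
#'   level, in voxels (>= 2).
#' @param mi_bins Histogram bins of the mutual-information metric.
#' @param max_samples Intensity samples per metric evaluation.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(metric = "mutual_information",
                                optimizer_initial_step = 8,
                                max_iterations = 500,
                                min_step = 0.001,
                                pyramid_levels = 4,
                                grid_spacing_voxels = 16,
                                mi_bins = 32,
                                max_samples = 262144) {
  if (pyramid_levels < 1) stop("pyramid_levels must be >= 1")
  if (grid_spacing_voxels < 2) stop("grid_spacing_voxels must be >= 2")
  structure(list(metric = metric,
                 optimizer_initial_step = optimizer_initial_step,
                 max_iterations = max_iterations, min_step = min_step,
                 pyramid_levels = pyramid_levels,
                 grid_spacing_voxels = grid_spacing_voxels,
                 mi_bins = mi_bins, max_samples = max_samples),
            class = "registration_config")
}

#' Rigid (6-DOF) spatial transform
#'
#' Maps a fixed-image physical point x to the moving-image frame as
#' `R (x - c) + c + t`, with `R = Rz Ry Rx` from the given Euler angles.
#'
#' @param rotation_deg Rotations about x, y, z in degrees.
#' @param translation_mm Translation in mm.
#' @param center_mm Centre of rotation in mm.
#' @param meta Optional metadata list.
#' @return An `rg_transform` of kind `"rigid"`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0), meta = list()) {
  structure(list(kind = "rigid", rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm),
                 center_mm = as.numeric(center_mm), meta = meta),
            class = "rg_transform")
}

#' Dense deformation-vector-field transform
#'
#' Maps a fixed-grid point x to `x + u(x)`, with the displacement u (mm)
#' stored per fixed voxel and interpolated trilinearly in between.
#'
#' @param dvf 4D array `[X, Y, Z, 3]` of displacements in mm.
#' @param spacing,origin Lattice of the fixed grid the field lives on.
#' @param meta Optional metadata list.
#' @return An `rg_transform` of kind `"dvf"`.
#' @export
dvf_transform <- function(dvf, spacing, origin = c(0, 0, 0), meta = list()) {
  stopifnot(length(dim(dvf)) == 4L, dim(dvf)[4] == 3L)
  if (any(!is.finite(dvf))) stop("dvf must be finite everywhere")
  structure(list(kind = "dvf", dvf = dvf, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), meta = meta),
            class = "rg_transform")
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a spatial transform to physical points
#'
#' @param t An `rg_transform`.
#' @param pts N x 3 matrix of physical coordinates (mm).
#' @return N x 3 matrix of mapped coordinates.
#' @export
transform_points <- function(t, pts) {
  if (t$kind == "rigid") {
    R <- rotation_matrix(t$rotation_deg)
    ctr <- matrix(t$center_mm, nrow(pts), 3, byrow = TRUE)
    sweep((pts - ctr) %*% t(R) + ctr, 2, -t$translation_mm)
  } else {
    d <- dim(t$dvf)[1:3]
    u <- matrix(0, nrow(pts), 3)
    for (c in 1:3) {
      u[, c] <- cpp_sample_volume(t$dvf[, , , c], d, t$spacing, t$origin,
                                  pts, 0L, 0)
    }
    pts + u
  }
}

#' Grid descriptor of a volume
#'
#' @param vol An [rg_volume].
#' @return A list with `dims`, `spacing`, `origin` usable as a
#'   `target_grid` in [propagate()].
#' @export
grid_of <- function(vol) {
  list(dims = vol_dims(vol), spacing = vol$spacing, origin = vol$origin)
}

#' Propagate an image or mask through a spatial transform
#'
#' Resamples the input onto `target_grid` through `t` (which maps target
#' points into the input's frame): linear interpolation for images,
#' nearest neighbour for masks (output strictly binary). Points mapping
#' outside the input are filled with -1000 HU for images and 0 for masks.
#'
#' @param input An [rg_volume] or [rg_mask].
#' @param t An `rg_transform` defined over the target grid.
#' @param target_grid A grid descriptor (`list(dims, spacing, origin)`) or
#'   a template [rg_volume]; defaults to the input's own grid.
#' @return A resampled [rg_volume] or [rg_mask] on the target grid.
#' @export
propagate <- function(input, t, target_grid = NULL) {
  if (is.null(target_grid)) target_grid <- grid_of(input)
  if (inherits(target_grid, "rg_volume")) target_grid <- grid_of(target_grid)
  pts <- voxel_centers_mm(target_grid$dims, target_grid$spacing,
                          target_grid$origin)
  mapped <- transform_points(t, pts)
  if (is_mask(input)) {
    vals <- cpp_sample_volume(input$data, vol_dims(input), input$spacing,
                              input$origin, mapped, 1L, 0)
    rg_mask(array(as.integer(vals), target_grid$dims),
            target_grid$spacing, target_grid$origin)
  } else {
    vals <- cpp_sample_volume(input$data, vol_dims(input), input$spacing,
                              input$origin, mapped, 0L, -1000)
    rg_volume(array(vals, target_grid$dims), target_grid$spacing,
              target_grid$origin)
  }
}

# Block-mean downsampling by an integer factor per axis (pyramid levels).
downsample_volume <- function(vol, factor) {
  factor <- rep(as.integer(factor), length.out = 3)
  if (all(factor == 1L)) return(vol)
  d <- vol_dims(vol)
  nd <- d %/% factor
  a <- vol$data[seq_len(nd[1] * factor[1]), seq_len(nd[2] * factor[2]),
                seq_len(nd[3] * factor[3]), drop = FALSE]
  dim(a) <- c(factor[1], nd[1], factor[2], nd[2], factor[3], nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  a <- array(colMeans(matrix(a, prod(factor), prod(nd))), nd)
  rg_volume(a, vol$spacing * factor,
            vol$origin + (factor - 1) * vol$spacing / 2)
}

# One-voxel box smoothing (edge-replicated). Applied to both images
# before metric sampling so intensities vary slowly relative to the grid;
# without it the mutual information develops spurious maxima at exact
# integer-voxel alignments of the two grids.
box_smooth3 <- function(vol) {
  a <- vol$data
  d <- dim(a)
  out <- array(0, d)
  xs0 <- seq_len(d[1]); ys0 <- seq_len(d[2]); zs0 <- seq_len(d[3])
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    out <- out + a[pmin(pmax(xs0 + dx, 1L), d[1]),
                   pmin(pmax(ys0 + dy, 1L), d[2]),
                   pmin(pmax(zs0 + dz, 1L), d[3])]
  }
  rg_volume(out / 27, vol$spacing, vol$origin)
}

check_registration_inputs <- function(fixed, moving) {
  for (v in list(fixed, moving)) {
    if (diff(range(v$data)) <= 0)
      stop("registration did not converge: constant-intensity image")
  }
  invisible(NULL)
}

# Deterministic sample positions for metric evaluation: a voxel subsample
# with a fixed sub-voxel jitter, so the fixed image is interpolated like
# the moving one. On-grid sampling of piecewise-constant images inflates
# the mutual information of slightly misaligned poses (the interpolation
# artifact); off-grid sampling restores the maximum at true alignment.
metric_samples <- function(vol, max_samples) {
  d <- vol_dims(vol)
  n <- prod(d)
  stride <- max(1L, floor(n / max_samples))
  idx <- seq(1L, n, by = stride)
  pts <- voxel_centers_mm(d, vol$spacing, vol$origin)[idx, , drop = FALSE]
  jit <- with_seed(12345L,
                   matrix(runif(3L * length(idx), -0.5, 0.5), ncol = 3))
  pts <- pts + sweep(jit, 2, vol$spacing, "*")
  vals <- cpp_sample_volume(vol$data, d, vol$spacing, vol$origin, pts, 0L,
                            NA_real_)
  keep <- is.finite(vals)
  list(values = vals[keep], pts = pts[keep, , drop = FALSE])
}

neg_mi_rigid <- function(par, center, samp, moving, nbins) {
  t <- rigid_transform(par[1:3], par[4:6], center)
  mapped <- transform_points(t, samp$pts)
  mvals <- cpp_sample_volume(moving$data, vol_dims(moving), moving$spacing,
                             moving$origin, mapped, 0L, NA_real_)
  -cpp_mi_linear(samp$values, mvals, nbins)
}

# Regular-step gradient descent: normalized finite-difference gradient,
# step halved whenever the trial point fails to improve the metric. The
# gradient is re-evaluated only after an accepted move.
rsgd <- function(f, p0, step0, min_step, max_iter, delta) {
  p <- p0
  fcur <- f(p)
  step <- step0
  iter <- 0L
  np <- length(p)
  g <- NULL
  while (step >= min_step && iter < max_iter) {
    if (is.null(g)) {
      g <- numeric(np)
      for (j in seq_len(np)) {
        pj <- p
        pj[j] <- pj[j] + delta
        g[j] <- (f(pj) - fcur) / delta
      }
      gn <- sqrt(sum(g^2))
      if (gn < 1e-14) break
      g <- g / gn
    }
    cand <- p - step * g
    fc <- f(cand)
    iter <- iter + 1L
    if (fc < fcur) {
      p <- cand
      fcur <- fc
      g <- NULL
    } else {
      step <- step / 2
    }
  }
  list(par = p, value = fcur, iterations = iter,
       converged = step < min_step)
}

#' Rigid-body registration with Mattes mutual information
#'
#' Aligns `moving` to `fixed` with a 6-DOF transform by maximizing the
#' Mattes mutual information (linearly binned joint histogram) under a
#' regular-step gradient descent over a multiresolution pyramid.
#'
#' @param fixed,moving [rg_volume] objects with valid spacing and
#'   overlapping fields of view.
#' @param cfg A [registration_config()].
#' @return An `rg_transform` of kind `"rigid"`; its `meta` records the
#'   final metric value, iteration counts, and the configuration echo.
#' @export
register_rigid <- function(fixed, moving, cfg = registration_config()) {
  check_registration_inputs(fixed, moving)
  center <- fixed$origin + (vol_dims(fixed) - 1) * fixed$spacing / 2
  L <- cfg$pyramid_levels
  par <- rep(0, 6)
  iters <- integer(0)
  value <- NA_real_
  for (l in seq_len(L)) {
    f0 <- 2^(L - l)
    cap <- max(1L, min(vol_dims(fixed)) %/% 8L)
    f0 <- min(f0, cap)
    fx <- box_smooth3(downsample_volume(fixed, f0))
    mv <- box_smooth3(downsample_volume(moving, f0))
    samp <- metric_samples(fx, cfg$max_samples)
    obj <- function(p) neg_mi_rigid(p, center, samp, mv, cfg$mi_bins)
    step0 <- cfg$optimizer_initial_step / 2^(l - 1)
    delta <- if (l == L) 0.1 else 0.25 * max(f0, 1)
    res <- rsgd(obj, par, step0, cfg$min_step, cfg$max_iterations, delta)
    par <- res$par
    iters <- c(iters, res$iterations)
    value <- res$value
  }
  rigid_transform(par[1:3], par[4:6], center,
                  meta = list(metric = cfg$metric, metric_value = -value,
                              iterations = iters,
                              pyramid_levels = cfg$pyramid_levels,
                              converged = TRUE))
}

#' B-spline deformable registration
#'
#' Free-form deformation on a cubic B-spline control lattice (spacing
#' `grid_spacing_voxels` voxels at the finest level), optimized over a
#' multiresolution pyramid by gradient descent on the mean squared
#' intensity difference with an analytic gradient; a rigid
#' mutual-information stage initializes the alignment. The composite map
#' is materialized as a dense voxelized deformation vector field (DVF) on
#' the fixed grid.
#'
#' @inheritParams register_rigid
#' @param init_rigid Optional precomputed rigid initialization.
#' @return An `rg_transform` of kind `"dvf"`; `meta` echoes the pyramid
#'   depth and control-grid spacing.
#' @export
register_bspline <- function(fixed, moving, cfg = registration_config(),
                             init_rigid = NULL) {
  check_registration_inputs(fixed, moving)
  rigid <- init_rigid %||% register_rigid(fixed, moving, cfg)
  L <- cfg$pyramid_levels
  coefs <- NULL
  prev_grid <- NULL
  final_loss <- NA_real_
  for (l in seq_len(L)) {
    f0 <- min(2^(L - l), max(1L, min(vol_dims(fixed)) %/% 8L))
    fx <- downsample_volume(fixed, f0)
    d <- vol_dims(fx)
    # moving resampled through the rigid stage onto this level's grid,
    # from the equally smoothed pyramid level of the moving image;
    # edge-clamped so boundary voxels do not masquerade as mismatch
    mvs <- downsample_volume(moving, f0)
    ptsl <- voxel_centers_mm(vol_dims(fx), fx$spacing, fx$origin)
    mvl <- rg_volume(array(cpp_sample_volume(mvs$data, vol_dims(mvs),
                                             mvs$spacing, mvs$origin,
                                             transform_points(rigid, ptsl),
                                             2L, 0),
                           vol_dims(fx)), fx$spacing, fx$origin)
    grad <- intensity_gradient(mvl)
    sp_vox <- cfg$grid_spacing_voxels
    Bx <- bspline_basis_1d(d[1], sp_vox)
    By <- bspline_basis_1d(d[2], sp_vox)
    Bz <- bspline_basis_1d(d[3], sp_vox)
    nc <- c(ncol(Bx), ncol(By), ncol(Bz))
    new_coefs <- array(0, c(nc, 3))
    if (!is.null(coefs)) {
      # initialize from the previous level's dense field, sampled at the
      # new control-point physical positions
      cp <- control_points_mm(nc, sp_vox, fx)
      for (comp in 1:3) {
        prev_field <- bspline_evaluate(coefs[, , , comp], prev_grid$Bx,
                                       prev_grid$By, prev_grid$Bz)
        new_coefs[, , , comp] <-
          array(cpp_sample_volume(prev_field, prev_grid$dims,
                                  prev_grid$spacing, prev_grid$origin,
                                  cp, 0L, 0), nc)
      }
    }
    coefs <- ffd_optimize(fx, mvl, grad, new_coefs, Bx, By, Bz,
                          max_iter = ceiling(cfg$max_iterations / L),
                          min_step = cfg$min_step)
    final_loss <- attr(coefs, "loss")
    prev_grid <- list(Bx = Bx, By = By, Bz = Bz, dims = d,
                      spacing = fx$spacing, origin = fx$origin)
  }
  # materialize the composite map on the full fixed grid
  d <- vol_dims(fixed)
  u <- array(0, c(d, 3))
  pts <- voxel_centers_mm(d, fixed$spacing, fixed$origin)
  for (comp in 1:3) {
    field <- bspline_evaluate(coefs[, , , comp], prev_grid$Bx,
                              prev_grid$By, prev_grid$Bz)
    u[, , , comp] <- array(cpp_sample_volume(field, prev_grid$dims,
                                             prev_grid$spacing,
                                             prev_grid$origin, pts, 0L, 0),
                           d)
  }
  mapped <- transform_points(rigid, pts + matrix(u, nrow(pts), 3))
  dvf <- array(mapped - pts, c(d, 3))
  dvf_transform(dvf, fixed$spacing, fixed$origin,
                meta = list(pyramid_levels = cfg$pyramid_levels,
                            grid_spacing_voxels = cfg$grid_spacing_voxels,
                            rigid_init = list(rotation_deg =
                                                rigid$rotation_deg,
                                              translation_mm =
                                                rigid$translation_mm),
                            final_ssd = final_loss))
}

control_points_mm <- function(nc, sp_vox, vol) {
  xs <- vol$origin[1] + ((seq_len(nc[1]) - 2) * sp_vox) * vol$spacing[1]
  ys <- vol$origin[2] + ((seq_len(nc[2]) - 2) * sp_vox) * vol$spacing[2]
  zs <- vol$origin[3] + ((seq_len(nc[3]) - 2) * sp_vox) * vol$spacing[3]
  cbind(rep(xs, times = nc[2] * nc[3]),
        rep(rep(ys, each = nc[1]), times = nc[3]),
        rep(zs, each = nc[1] * nc[2]))
}

# Central-difference spatial gradient of a volume, mm^-1 units, one
# rg_volume per component.
intensity_gradient <- function(vol) {
  a <- vol$data
  d <- dim(a)
  g <- vector("list", 3)
  for (ax in 1:3) {
    hi <- a
    lo <- a
    n <- d[ax]
    idx <- lapply(d, seq_len)
    ih <- idx; ih[[ax]] <- pmin(seq_len(n) + 1L, n)
    il <- idx; il[[ax]] <- pmax(seq_len(n) - 1L, 1L)
    hi <- a[ih[[1]], ih[[2]], ih[[3]], drop = FALSE]
    lo <- a[il[[1]], il[[2]], il[[3]], drop = FALSE]
    step <- pmin(seq_len(n) + 1L, n) - pmax(seq_len(n) - 1L, 1L)
    denom <- array(1, d)
    if (ax == 1) denom <- array(rep(step, times = prod(d[2:3])), d)
    if (ax == 2) denom <- aperm(array(rep(step, times = prod(d[c(1, 3)])),
                                      d[c(2, 1, 3)]), c(2, 1, 3))
    if (ax == 3) denom <- aperm(array(rep(step, times = prod(d[1:2])),
                                      d[c(3, 1, 2)]), c(2, 3, 1))
    g[[ax]] <- rg_volume((hi - lo) / (denom * vol$spacing[ax]),
                         vol$spacing, vol$origin)
  }
  g
}

# Gradient-descent FFD optimization of SSD at one pyramid level.
ffd_optimize <- function(fixed, moving, grad, coefs, Bx, By, Bz,
                         max_iter, min_step) {
  d <- vol_dims(fixed)
  pts <- voxel_centers_mm(d, fixed$spacing, fixed$origin)
  fvals <- as.numeric(fixed$data)
  nvox <- length(fvals)
  eval_loss <- function(cf) {
    u <- vapply(1:3, function(comp)
      as.numeric(bspline_evaluate(cf[, , , comp], Bx, By, Bz)),
      numeric(nvox))
    warped <- cpp_sample_volume(moving$data, d, moving$spacing,
                                moving$origin, pts + u, 2L, 0)
    r <- warped - fvals
    list(loss = mean(r^2), resid = r, pts_w = pts + u)
  }
  cur <- eval_loss(coefs)
  step <- max(fixed$spacing)  # initial displacement step, mm
  it <- 0L
  # below this SSD the residual is interpolation noise, not misalignment
  floor_loss <- 1e-6 * stats::var(fvals)
  while (it < max_iter && step >= min_step && cur$loss > floor_loss) {
    # analytic gradient: 2 r * grad(moving) at the warped points,
    # pulled back to the coefficient lattice
    gcoef <- array(0, dim(coefs))
    for (comp in 1:3) {
      gm <- cpp_sample_volume(grad[[comp]]$data, d, moving$spacing,
                              moving$origin, cur$pts_w, 2L, 0)
      gv <- array(2 * cur$resid * gm / nvox, d)
      gcoef[, , , comp] <- bspline_adjoint(gv, Bx, By, Bz)
    }
    gmax <- max(abs(gcoef))
    if (gmax < 1e-14) break
    cand <- coefs - step * gcoef / gmax
    new <- eval_loss(cand)
    it <- it + 1L
    if (new$loss < cur$loss * (1 - 1e-4)) {
      coefs <- cand
      cur <- new
      step <- min(step * 1.2, 4 * max(fixed$spacing))
    } else {
      step <- step / 2
    }
  }
  attr(coefs, "loss") <- cur$loss
  coefs
}
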