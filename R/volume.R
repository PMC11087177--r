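#' 3D scalar volume with physical voxel spacing
#'
#' A minimal container for a 3D image: a numeric array plus voxel spacing
#' (mm) and the physical position of the first voxel centre (mm). Voxel
#' `(i, j, k)` (1-based) sits at `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric array.
#' @param spacing Positive numeric triple, voxel spacing in mm.
#' @param origin Numeric triple, physical coordinate of the first voxel
#'   centre in mm. Defaults to `c(0, 0, 0)`.
#' @return An object of class `rg_volume`.
#' @export
rg_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)),
         " dimensions")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be a positive finite triple")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite triple")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "rg_volume")
}

#' Binary label mask on a volume lattice
#'
#' @param data 3D array coercible to 0/1 integers.
#' @inheritParams rg_volume
#' @return An object of class `c("rg_mask", "rg_volume")`.
#' @export
rg_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(data)
  data <- as.integer(round(data))
  if (!all(data %in% c(0L, 1L)))
    stop("mask values must be binary (0/1)")
  dim(data) <- d
  v <- rg_volume(data, spacing, origin)
  class(v) <- c("rg_mask", "rg_volume")
  v
}

is_mask <- function(x) inherits(x, "rg_mask")

vol_dims <- function(v) dim(v$data)

#' @export
print.rg_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, range [%g, %g]\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

same_lattice <- function(a, b, tol = 1e-6) {
  identical(vol_dims(a), vol_dims(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_lattice_mismatch <- function(a, b) {
  if (!same_lattice(a, b))
    stop("inputs are not on the same lattice (dims/spacing/origin differ)")
  invisible(NULL)
}

# Physical coordinates (mm) of every voxel centre, in array order
# (first index fastest). Returns an N x 3 matrix.
voxel_centers_mm <- function(dims, spacing, origin = c(0, 0, 0)) {
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  cbind(rep(xs, times = dims[2] * dims[3]),
        rep(rep(ys, each = dims[1]), times = dims[3]),
        rep(zs, each = dims[1] * dims[2]))
}

# One-hot encoding of a binary mask over K = 2 classes (background first).
one_hot <- function(mask_data, n_classes = 2L) {
  d <- dim(mask_data)
  y <- array(0, c(d, n_classes))
  y[, , , 1] <- 1 - mask_data
  y[, , , 2] <- mask_data
  y
}
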