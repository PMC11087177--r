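# Cubic B-spline lattice machinery shared by the phantom's smooth warp and
# the free-form deformable registration: a dense basis matrix per axis plus
# tensor-product application and its adjoint.

# Basis matrix mapping nc control coefficients (control j sits at voxel
# position (j - 2) * spacing_vox, 1-based j) to n voxel samples.
bspline_basis_1d <- function(n, spacing_vox) {
  stopifnot(spacing_vox > 0)
  nc <- floor((n - 1) / spacing_vox) + 4L
  B <- matrix(0, n, nc)
  s <- (seq_len(n) - 1) / spacing_vox
  l <- floor(s)
  u <- s - l
  w <- cbind((1 - u)^3 / 6,
             (3 * u^3 - 6 * u^2 + 4) / 6,
             (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
             u^3 / 6)
  for (m in 0:3) {
    col <- l + m + 1L
    B[cbind(seq_len(n), col)] <- w[, m + 1L]
  }
  B
}

# Apply a matrix along one axis of a 3D array.
apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  out <- M %*% matrix(a, da[1], da[2] * da[3])
  out <- array(out, c(nrow(M), da[2], da[3]))
  inv <- order(perm)
  aperm(out, inv)
}

# Dense field from a coefficient lattice: tensor product of the per-axis
# basis matrices.
bspline_evaluate <- function(coefs, Bx, By, Bz) {
  apply_axis(apply_axis(apply_axis(coefs, Bx, 1), By, 2), Bz, 3)
}

# Adjoint: accumulate a dense voxel field back onto the coefficient lattice.
bspline_adjoint <- function(field, Bx, By, Bz) {
  apply_axis(apply_axis(apply_axis(field, t(Bx), 1), t(By), 2), t(Bz), 3)
}

# Smooth random 3-component displacement field (mm) on a voxel grid:
# i.i.d. normal coefficients on a coarse lattice with physical correlation
# length scale_mm, upsampled by cubic B-splines, then rescaled so the
# maximum displacement magnitude equals amplitude_mm.
random_smooth_warp <- function(dims, spacing, scale_mm, amplitude_mm) {
  if (amplitude_mm <= 0) return(array(0, c(dims, 3)))
  sp_vox <- pmax(2, round(scale_mm / spacing))
  Bx <- bspline_basis_1d(dims[1], sp_vox[1])
  By <- bspline_basis_1d(dims[2], sp_vox[2])
  Bz <- bspline_basis_1d(dims[3], sp_vox[3])
  nc <- c(ncol(Bx), ncol(By), ncol(Bz))
  u <- array(0, c(dims, 3))
  for (comp in 1:3) {
    coefs <- array(rnorm(prod(nc)), nc)
    u[, , , comp] <- bspline_evaluate(coefs, Bx, By, Bz)
  }
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  mmax <- max(mag)
  if (mmax > 0) u <- u * (amplitude_mm / mmax)
  u
}
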