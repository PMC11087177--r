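# Shared test fixtures and independent oracles.

# Small, fast phantom configurations.
tiny_phantom <- function(...) {
  args <- list(grid_shape = c(40, 40, 24), spacing_mm = c(3.5, 3.5, 3.5),
               target_radii_mm = c(14, 11, 8), ctv_margin_mm = 8,
               rigid_offset_mm = c(4, 2, 1),
               rigid_rotation_deg = c(0, 0, 2),
               deform_amplitude_mm = 5, deform_scale_mm = 40)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_params, args)
}

still_phantom <- function(...) {
  # no inter-course change, no noise
  args <- list(rigid_offset_mm = c(0, 0, 0),
               rigid_rotation_deg = c(0, 0, 0),
               deform_amplitude_mm = 0, target_scale2 = 1,
               target_fade2 = 1, noise_sd_hu = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(tiny_phantom, args)
}

tiny_model <- function(variant = "mcmp", ...) {
  model_config(variant, base_filters = 2, n_levels = 2, ca_reduction = 2,
               ...)
}

random_mask <- function(dims, p = 0.3) {
  array(as.integer(runif(prod(dims)) < p), dims)
}

# Independent surface-distance oracle: O(n^2) all-pairs distances between
# surface voxel centres, with surface voxels found by explicit neighbour
# loops (no shared code with the package implementation).
oracle_surface <- function(m) {
  d <- dim(m)
  idx <- which(m == 1L, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    surf <- FALSE
    for (ax in 1:3) for (dd in c(-1L, 1L)) {
      n <- v
      n[ax] <- n[ax] + dd
      if (n[ax] < 1L || n[ax] > d[ax] || m[n[1], n[2], n[3]] == 0L) {
        surf <- TRUE
      }
    }
    keep[r] <- surf
  }
  idx[keep, , drop = FALSE]
}

oracle_surface_distances <- function(a, b, spacing) {
  sa <- oracle_surface(a)
  sb <- oracle_surface(b)
  pa <- sweep(sa - 1, 2, spacing, "*")
  pb <- sweep(sb - 1, 2, spacing, "*")
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2 +
    outer(pa[, 3], pb[, 3], "-")^2
  list(a_to_b = sqrt(apply(d2, 1, min)), b_to_a = sqrt(apply(d2, 2, min)))
}

oracle_dsc <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a == 1L & b == 1L) / (sum(a) + sum(b))
}
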