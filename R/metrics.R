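#' Dice similarity coefficient
#'
#' Spatial overlap `2|A intersect B| / (|A| + |B|)` between two binary
#' masks on the same lattice. Two empty masks are defined to agree
#' perfectly (DSC 1).
#'
#' @param a,b [rg_mask] objects (or plain binary 3D arrays) on one lattice.
#' @return A number in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  am <- mask_data(a)
  bm <- mask_data(b)
  if (!identical(dim(am), dim(bm)))
    stop("masks are on different lattices")
  if (inherits(a, "rg_volume") && inherits(b, "rg_volume"))
    stop_if_lattice_mismatch(a, b)
  sa <- sum(am)
  sb <- sum(bm)
  if (sa + sb == 0) return(1.0)
  2 * sum(am & bm) / (sa + sb)
}

mask_data <- function(m) {
  if (inherits(m, "rg_volume")) m$data else m
}

# Surface voxels: mask voxels with at least one face-adjacent background
# neighbour; voxels on the grid boundary count their missing neighbours as
# background.
surface_voxels <- function(m) {
  d <- dim(m)
  interior <- array(TRUE, d)
  nb <- array(0L, d)
  shift_min <- function(a, ax, by) {
    # neighbour value with zero fill outside the grid
    out <- array(0L, dim(a))
    idx_src <- lapply(dim(a), seq_len)
    idx_dst <- idx_src
    n <- dim(a)[ax]
    if (by == 1L) {
      idx_src[[ax]] <- seq_len(n - 1L)
      idx_dst[[ax]] <- 2:n
    } else {
      idx_src[[ax]] <- 2:n
      idx_dst[[ax]] <- seq_len(n - 1L)
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  all_nb_fg <- array(TRUE, d)
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    all_nb_fg <- all_nb_fg & (shift_min(m, ax, by) == 1L)
  }
  (m == 1L) & !all_nb_fg
}

#' Symmetric surface distances between two masks
#'
#' Extracts the surface voxels of each mask (mask voxels with a
#' face-adjacent background neighbour), then measures, for every surface
#' voxel of one mask, the Euclidean distance in physical mm to the nearest
#' surface voxel of the other. Voxel centres are the point model.
#'
#' @param a,b Nonempty [rg_mask] objects on one lattice.
#' @param spacing Voxel spacing in mm; taken from `a` when omitted.
#' @return A list with numeric vectors `a_to_b` and `b_to_a` (mm).
#' @export
surface_distances <- function(a, b, spacing = NULL) {
  am <- mask_data(a)
  bm <- mask_data(b)
  if (!identical(dim(am), dim(bm)))
    stop("masks are on different lattices")
  if (is.null(spacing))
    spacing <- if (inherits(a, "rg_volume")) a$spacing else c(1, 1, 1)
  if (sum(am) == 0 || sum(bm) == 0)
    stop("surface distances are undefined for an empty mask")
  sa <- surface_voxels(am)
  sb <- surface_voxels(bm)
  d <- dim(am)
  dt_b <- sqrt(cpp_edt_sq(as.integer(sb), as.integer(d), as.numeric(spacing)))
  dt_a <- sqrt(cpp_edt_sq(as.integer(sa), as.integer(d), as.numeric(spacing)))
  list(a_to_b = dt_b[which(sa)], b_to_a = dt_a[which(sb)])
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The 95th percentile of the pooled symmetric surface-distance multiset,
#' with linear interpolation between order statistics.
#'
#' @inheritParams surface_distances
#' @return Distance in mm.
#' @export
hd95 <- function(a, b, spacing = NULL) {
  sd <- surface_distances(a, b, spacing)
  unname(quantile(c(sd$a_to_b, sd$b_to_a), 0.95, type = 7))
}

#' Average symmetric surface distance (mm)
#'
#' Mean of the pooled symmetric surface-distance multiset.
#'
#' @inheritParams surface_distances
#' @return Distance in mm.
#' @export
asd <- function(a, b, spacing = NULL) {
  sd <- surface_distances(a, b, spacing)
  mean(c(sd$a_to_b, sd$b_to_a))
}

#' All three segmentation metrics for one mask pair
#'
#' @inheritParams surface_distances
#' @return A one-row data frame with columns `dsc`, `hd95_mm`, `asd_mm`.
#' @export
segmentation_metrics <- function(a, b, spacing = NULL) {
  sdd <- surface_distances(a, b, spacing)
  pooled <- c(sdd$a_to_b, sdd$b_to_a)
  data.frame(dsc = dsc(mask_data(a), mask_data(b)),
             hd95_mm = unname(quantile(pooled, 0.95, type = 7)),
             asd_mm = mean(pooled))
}
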