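#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into an [rg_volume] (or [rg_mask] when
#' `mask = TRUE`). Spacing is taken from the pixdim header; the origin from
#' the stored xform translation.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param mask Logical; read as a binary label mask.
#' @return An [rg_volume] or [rg_mask].
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D NIfTI payload, got ", length(d), "D: ", path)
  aff <- RNifti::xform(img)
  if (any(!is.finite(aff))) stop("non-finite affine in ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- abs(aff[1:3, 4]) * sign(diag(aff[1:3, 1:3]))
  origin[!is.finite(origin)] <- 0
  arr <- array(as.numeric(img), d)
  if (mask) rg_mask(arr, spacing, origin) else rg_volume(arr, spacing, origin)
}

#' Write a volume or mask as NIfTI
#'
#' Images are stored as 32-bit float, masks as unsigned 8-bit. Spacing and
#' origin are preserved through the qform.
#'
#' @param vol An [rg_volume] or [rg_mask].
#' @param path Output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "rg_volume"))
  arr <- vol$data
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  dtype <- if (is_mask(vol)) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Write a spatial transform to disk
#'
#' Rigid transforms become a JSON sidecar; deformable transforms a dense
#' DVF NIfTI-like array (one file per component) plus JSON metadata.
#'
#' @param t An `rg_transform`.
#' @param stem Output path stem (no extension).
#' @return The JSON path, invisibly.
#' @export
write_transform <- function(t, stem) {
  stopifnot(inherits(t, "rg_transform"))
  meta <- list(kind = t$kind, meta = t$meta)
  if (t$kind == "rigid") {
    meta$rotation_deg <- t$rotation_deg
    meta$translation_mm <- t$translation_mm
    meta$center_mm <- t$center_mm
  } else {
    meta$spacing <- t$spacing
    meta$origin <- t$origin
    meta$dims <- dim(t$dvf)[1:3]
    for (c in 1:3) {
      comp <- rg_volume(t$dvf[, , , c], t$spacing, t$origin)
      write_volume(comp, paste0(stem, "_dvf", c, ".nii.gz"))
    }
  }
  jpath <- paste0(stem, ".json")
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA)
  invisible(jpath)
}

#' Read a spatial transform written by [write_transform()]
#' @param stem Path stem used when writing.
#' @return An `rg_transform`.
#' @export
read_transform <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (meta$kind == "rigid") {
    rigid_transform(meta$rotation_deg, meta$translation_mm, meta$center_mm,
                    meta = meta$meta)
  } else {
    dims <- meta$dims
    dvf <- array(0, c(dims, 3))
    for (c in 1:3) {
      comp <- read_volume(paste0(stem, "_dvf", c, ".nii.gz"))
      dvf[, , , c] <- comp$data
    }
    dvf_transform(dvf, meta$spacing, meta$origin, meta = meta$meta)
  }
}
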