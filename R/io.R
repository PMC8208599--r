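#' Read and write acquisition geometry as JSON
#'
#' The JSON carries exactly the constructor fields of
#' [cone_beam_geometry()].
#'
#' @param geometry A [cone_beam_geometry()].
#' @param path Output/input file path.
#' @return \code{read_geometry_json} returns a [cone_beam_geometry()].
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(unclass(geometry), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cone_beam_geometry, g)
}

#' Read and write projection stacks (raw float32 + JSON sidecar)
#'
#' Line-integral stacks are stored as little-endian 32-bit floats in R
#' array order (row fastest, then column, then view) next to a JSON sidecar
#' \code{<path>.json} holding the dimensions and the acquisition geometry.
#'
#' @param stack A [projection_stack()] or array (then supply
#'   \code{geometry}).
#' @param path Path of the raw file (the sidecar gets \code{.json}
#'   appended).
#' @param geometry Geometry when a bare array is given.
#' @return \code{read_projection_stack} returns a [projection_stack()].
#' @export
write_projection_stack <- function(stack, path, geometry = NULL) {
  data <- stack_data(stack)
  if (is.null(geometry) && inherits(stack, "projection_stack"))
    geometry <- stack$geometry
  stopifnot(!is.null(geometry))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(dim = dim(data), dtype = "float32", order = "row,col,view",
         geometry = unclass(geometry)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_projection_stack
#' @export
read_projection_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  data <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  dim(data) <- meta$dim
  projection_stack(data, do.call(cone_beam_geometry, meta$geometry))
}

#' Write a mask stack as multi-page 8-bit TIFF
#'
#' @param masks A [mask_stack()] (its AEC masks are written; the low-dose
#'   masks are their complement) or a binary array.
#' @param path Output TIFF path.
#' @export
write_mask_tiff <- function(masks, path) {
  arr <- if (inherits(masks, "mask_stack")) masks$aec_mask else masks
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] + 0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @return \code{read_mask_tiff} returns a binary (0/1) integer array.
#' @export
read_mask_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- (pages[[k]] > 0.5) + 0L
  arr
}

#' Read and write volumes as NIfTI
#'
#' Voxel spacing is stored in the NIfTI header.
#'
#' @param vol 3D array.
#' @param grid The [volume_grid()] the volume lives on.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @export
write_volume_nifti <- function(vol, grid, path) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @return \code{read_volume_nifti} returns a plain 3D array with a
#'   \code{spacing} attribute.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "spacing") <- RNifti::pixdim(img)
  out
}

#' Read and write marker sets as JSON (world mm)
#'
#' @param markers A \code{marker_set} or n x 3 matrix.
#' @param path File path.
#' @export
write_markers_json <- function(markers, path) {
  pos <- if (inherits(markers, "marker_set")) markers$positions
         else as.matrix(markers)
  jsonlite::write_json(
    list(positions = unname(apply(pos, 1, as.numeric, simplify = FALSE)),
         units = "mm"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_markers_json
#' @export
read_markers_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- j$positions
  pos <- if (is.matrix(pos)) pos else do.call(rbind, lapply(pos, as.numeric))
  dimnames(pos) <- NULL
  structure(list(positions = pos, sizes = rep(NA_real_, nrow(pos))),
            class = "marker_set")
}
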