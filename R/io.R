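#' Write a 3-D map as NIfTI-1
#'
#' @param map 3-D numeric array (e.g. an accuracy or t map); `NA` is written
#'   as 0.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_size_mm = 2) {
  if (is.list(map)) map <- map$map
  arr <- map
  arr[is.na(arr)] <- 0
  img <- RNifti::asNifti(arr, pixdim = rep(voxel_size_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D map from NIfTI-1
#'
#' @param path File path.
#' @return 3-D numeric array.
#' @export
read_map_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim(arr))
}
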