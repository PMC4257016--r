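# Thin NIfTI-1 read/write helpers.

#' Write a numeric array as NIfTI-1
#' @param vol 3-D or 4-D array.
#' @param path output path (.nii or .nii.gz).
#' @param voxel_size mm triple.
#' @param tr frame spacing in s for 4-D series (optional).
#' @return The path, invisibly.
#' @export
write_nifti_vol <- function(vol, path, voxel_size = c(1, 1, 1), tr = NULL) {
  pd <- if (length(dim(vol)) == 4L && !is.null(tr))
    c(voxel_size, tr) else voxel_size
  attr(vol, "pixdim") <- pd
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "float"), path)
  invisible(path)
}

#' Read a NIfTI file as a plain array
#' @param path NIfTI path.
#' @return list with `data` (array) and `voxel_size` (mm).
#' @export
read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = as.array(img), voxel_size = pd[1:3])
}
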