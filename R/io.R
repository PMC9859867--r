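# NIfTI + JSON-sidecar input/output.
#
# Volumes travel as NIfTI (.nii.gz); per-frame acquisition times cannot live
# in a NIfTI header, so they sit in a JSON sidecar next to the image,
# together with voxel size, ROI definitions and (for phantoms) ground truth.
# Voxel indices in sidecars are 1-based (`index_base: 1`).

#' Write a CTP series to NIfTI with a JSON sidecar
#'
#' @param series A `ctp_series`.
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param sidecar Output JSON path; defaults to `path` with a `.json`
#'   extension.
#' @param extra Named list merged into the sidecar (e.g. ground truth).
#' @return `path`, invisibly.
#' @export
write_ctp_series <- function(series, path, sidecar = sidecar_path(path),
                             extra = list()) {
  stopifnot(inherits(series, "ctp_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size_mm,
                           diff(series$times_s[1:2]))
  RNifti::writeNifti(img, path)
  meta <- c(list(times_s = series$times_s,
                 voxel_size_mm = series$voxel_size_mm,
                 index_base = 1L), extra)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a CTP series from NIfTI plus its JSON sidecar
#'
#' @param path NIfTI path holding a 4D volume.
#' @param sidecar JSON sidecar path with `times_s` (one per frame) and
#'   `voxel_size_mm`.
#' @return A `ctp_series`.
#' @export
read_ctp_series <- function(path, sidecar = sidecar_path(path)) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  if (length(dim(data)) != 4L)
    abort("expected a 4D NIfTI volume.", class = "collateraltime_format_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  times <- as.numeric(meta$times_s)
  if (length(times) != dim(data)[4])
    abort(sprintf("sidecar has %d timestamps but the image has %d frames.",
                  length(times), dim(data)[4]),
          class = "collateraltime_format_error")
  vox <- as.numeric(meta$voxel_size_mm %||% RNifti::pixdim(img)[1:3])
  new_ctp_series(data, times, vox)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a region specification as NIfTI masks plus JSON
#'
#' Masks are written as uint8 NIfTI volumes
#' (`<prefix>_mca_occluded.nii.gz`, `<prefix>_mca_contralateral.nii.gz`);
#' ROI centers (1-based voxel indices), radii and the occlusion side go to
#' `<prefix>_regions.json`.
#'
#' @param regions A [region_spec()].
#' @param prefix Output path prefix.
#' @return The JSON path, invisibly.
#' @export
write_region_spec <- function(regions, prefix) {
  stopifnot(inherits(regions, "region_spec"))
  wmask <- function(mask, suffix) {
    img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
    RNifti::writeNifti(img, paste0(prefix, suffix), datatype = "uint8")
  }
  wmask(regions$mca_occluded_mask, "_mca_occluded.nii.gz")
  wmask(regions$mca_contralateral_mask, "_mca_contralateral.nii.gz")
  js <- paste0(prefix, "_regions.json")
  jsonlite::write_json(
    list(arterial_roi = regions$arterial_roi, venous_roi = regions$venous_roi,
         occlusion_side = regions$occlusion_side, index_base = 1L),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(js)
}

#' Read a region specification written by [write_region_spec()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [region_spec()].
#' @export
read_region_spec <- function(prefix) {
  rmask <- function(suffix) {
    img <- RNifti::readNifti(paste0(prefix, suffix))
    array(as.numeric(img) > 0, dim(img))
  }
  meta <- jsonlite::read_json(paste0(prefix, "_regions.json"),
                              simplifyVector = TRUE)
  region_spec(
    mca_occluded_mask = rmask("_mca_occluded.nii.gz"),
    mca_contralateral_mask = rmask("_mca_contralateral.nii.gz"),
    arterial_roi = list(center = as.integer(meta$arterial_roi$center),
                        radius_mm = meta$arterial_roi$radius_mm),
    venous_roi = list(center = as.integer(meta$venous_roi$center),
                      radius_mm = meta$venous_roi$radius_mm),
    occlusion_side = meta$occlusion_side)
}
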