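#' Segmentation parameters for enhanced-vessel extraction
#'
#' The vessel segmentation used here is a deliberate, loudly documented
#' stand-in for a learned vessel segmentation model: a voxel is a vessel
#' voxel iff it lies in the region of interest and its enhancement over the
#' unenhanced baseline volume is at least `enhancement_threshold_hu`. The
#' step is pluggable: anything producing a binary vessel mask per frame can
#' replace [segment_vessels()] without touching the rest of the pipeline.
#'
#' @param enhancement_threshold_hu Enhancement over baseline (HU) at which a
#'   voxel counts as vessel; comparison is inclusive (`>=`).
#' @param baseline_frames Which frames define the unenhanced reference; the
#'   baseline volume is their voxelwise mean (default: first two frames).
#' @param cr_cap Optional upper clamp for the collateral ratio, in percent.
#'   `NULL` (default) leaves the CR unclamped; set 150 to reproduce a
#'   bounded 0-150 scoring range.
#' @return A list of class `"segmentation_params"`.
#' @export
segmentation_params <- function(enhancement_threshold_hu = 50,
                                baseline_frames = 1:2,
                                cr_cap = NULL) {
  if (enhancement_threshold_hu <= 0)
    abort("`enhancement_threshold_hu` must be positive.",
          class = "collateraltime_parameter_error")
  structure(list(enhancement_threshold_hu = enhancement_threshold_hu,
                 baseline_frames = baseline_frames, cr_cap = cr_cap),
            class = "segmentation_params")
}

#' Segment contrast-enhanced vessels in one frame
#'
#' Subtraction-threshold segmentation: a voxel is selected iff it lies inside
#' `region` and `frame - baseline >= enhancement_threshold_hu`.
#'
#' @param frame,baseline 3D HU arrays on the same grid.
#' @param params A [segmentation_params()].
#' @param region 3D logical mask restricting the search region (e.g. an MCA
#'   mask); `NULL` searches the whole grid.
#' @return 3D logical vessel mask.
#' @export
segment_vessels <- function(frame, baseline, params = segmentation_params(),
                            region = NULL) {
  if (!identical(dim(frame), dim(baseline)))
    abort("`frame` and `baseline` must share a grid.",
          class = "collateraltime_shape_error")
  mask <- (frame - baseline) >= params$enhancement_threshold_hu
  if (!is.null(region)) {
    if (!identical(dim(region), dim(frame)))
      abort("`region` must share the frame grid.",
            class = "collateraltime_shape_error")
    mask <- mask & region
  }
  mask
}

#' Enhanced vessel volume of a binary mask
#'
#' @param mask 3D logical array.
#' @param voxel_size_mm Per-axis voxel size in mm.
#' @return Volume in mL (1 mL = 1000 mm^3).
#' @export
enhanced_vessel_volume <- function(mask, voxel_size_mm) {
  sum(mask) * prod(voxel_size_mm) / 1000
}

#' Collateral ratio
#'
#' The collateral ratio (CR) is the enhanced vessel volume in the MCA region
#' of the occluded side divided by the enhanced vessel volume on the healthy
#' (contralateral) side, expressed in percent. A zero contralateral volume
#' makes the ratio undefined; such frames carry `NA` and are skipped by curve
#' consumers rather than being coerced to 0 or infinity.
#'
#' @param vol_occluded,vol_contralateral Volumes in mL; vectorized.
#' @param params A [segmentation_params()]; `cr_cap`, if set, clamps the CR
#'   from above.
#' @return CR in percent (`NA` where the contralateral volume is 0).
#' @examples
#' collateral_ratio(50, 50)  # 100
#' collateral_ratio(90, 50, segmentation_params(cr_cap = 150))  # 150
#' @export
collateral_ratio <- function(vol_occluded, vol_contralateral,
                             params = segmentation_params()) {
  cr <- ifelse(vol_contralateral > 0, 100 * vol_occluded / vol_contralateral,
               NA_real_)
  if (!is.null(params$cr_cap)) cr <- pmin(cr, params$cr_cap)
  cr
}
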