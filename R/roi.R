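# Regions of interest: total tissue (TT), vascular (VS), perivascular (PVS).
# All physical dilations threshold the Euclidean distance transform at the
# radius (rotation-consistent "enlarge" semantics); equivalence with
# iterated dilation is exercised by the distance-profile oracle tests.

#' Total-tissue ROI
#'
#' TT is the DAPI-positive region (minus any exclusion) dilated by
#' `dilation_um` (default 10 um, excluding luminal and acellular surfaces),
#' with the exclusion subtracted again after dilation so no excluded pixel
#' ever contributes downstream.
#'
#' @param dapi_mask DAPI [binary_mask()] (or logical matrix).
#' @param exclusion optional operator-supplied exclusion mask on the same
#'   grid.
#' @param resolution pixel size in um (taken from the mask if available).
#' @param dilation_um dilation radius in um.
#' @return A [binary_mask()] labelled `"TT"`.
#' @export
build_tt <- function(dapi_mask, exclusion = NULL, resolution = NULL,
                     dilation_um = 10) {
  res <- mask_res(dapi_mask, resolution)
  px <- mask_px(dapi_mask)
  if (!is.null(exclusion)) {
    check_same_grid(dapi_mask, exclusion, "DAPI and exclusion masks")
    px <- px & !mask_px(exclusion)
  }
  tt <- dilate_um(px, dilation_um, res)
  if (!is.null(exclusion)) tt <- tt & !mask_px(exclusion)
  binary_mask(tt, res, marker = "TT",
              provenance = list(dilation_um = dilation_um))
}

#' Vascular ROI
#'
#' VS is the CD31-positive area minus the exclusion, size-filtered.
#'
#' @param cd31_mask segmented CD31 [binary_mask()].
#' @param exclusion optional exclusion mask.
#' @param min_object_area_um2 drop vessel fragments below this area.
#' @inheritParams build_tt
#' @return A [binary_mask()] labelled `"VS"`.
#' @export
build_vs <- function(cd31_mask, exclusion = NULL, min_object_area_um2 = 0,
                     resolution = NULL) {
  res <- mask_res(cd31_mask, resolution)
  px <- mask_px(cd31_mask)
  if (!is.null(exclusion)) {
    check_same_grid(cd31_mask, exclusion, "CD31 and exclusion masks")
    px <- px & !mask_px(exclusion)
  }
  px <- filter_small_objects(px, min_object_area_um2, res)
  binary_mask(px, res, marker = "VS",
              provenance = list(min_object_area_um2 = min_object_area_um2))
}

#' Perivascular ROI
#'
#' PVS is the `shell_um` (default 5 um) band lining VS: the Euclidean
#' dilation of VS minus VS itself, so PVS and VS are always disjoint.
#'
#' @param vs the VS [binary_mask()].
#' @param shell_um shell thickness in um (> 0).
#' @inheritParams build_tt
#' @return A [binary_mask()] labelled `"PVS"`.
#' @export
build_pvs <- function(vs, shell_um = 5, resolution = NULL) {
  if (!is.numeric(shell_um) || shell_um <= 0)
    stopf("`shell_um` must be > 0")
  res <- mask_res(vs, resolution)
  px <- mask_px(vs)
  pvs <- dilate_um(px, shell_um, res) & !px
  binary_mask(pvs, res, marker = "PVS",
              provenance = list(shell_um = shell_um))
}

#' Build the full ROI set for one image
#'
#' @param dapi_mask,cd31_mask segmented DAPI and CD31 masks.
#' @param exclusion optional exclusion mask applied to every region.
#' @param resolution pixel size in um.
#' @param tt_dilation_um,pvs_shell_um region parameters.
#' @param vs_min_area_um2 size filter for vessel fragments.
#' @return Object of class `roi_set` with `tt`, `vs`, `pvs`, `exclusion`,
#'   `resolution_um_per_px`.
#' @export
roi_set <- function(dapi_mask, cd31_mask, exclusion = NULL,
                    resolution = NULL, tt_dilation_um = 10,
                    pvs_shell_um = 5, vs_min_area_um2 = 0) {
  res <- mask_res(dapi_mask, resolution)
  check_same_grid(dapi_mask, cd31_mask, "DAPI and CD31 masks")
  tt <- build_tt(dapi_mask, exclusion, res, tt_dilation_um)
  vs <- build_vs(cd31_mask, exclusion, vs_min_area_um2, res)
  pvs <- build_pvs(vs, pvs_shell_um, res)
  if (!is.null(exclusion)) {
    pvs$px <- pvs$px & !mask_px(exclusion)
  }
  structure(list(tt = tt, vs = vs, pvs = pvs, exclusion = exclusion,
                 resolution_um_per_px = res),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  res <- x$resolution_um_per_px
  cat(sprintf(
    "<roi_set> TT %.0f um^2 | VS %.0f um^2 | PVS %.0f um^2 @ %.4g um/px\n",
    mask_area_um2(x$tt), mask_area_um2(x$vs), mask_area_um2(x$pvs), res))
  invisible(x)
}
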