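# Surface-based marker indices and the object-based covered-vessel
# frequency.  Surface values are staining areas (um^2) divided by the area
# of the reference region; they are dimensionless and can exceed 1 only
# when the numerator region is not contained in the denominator region
# (the perivascular indices, by definition).

#' Surface-based index
#'
#' `area(marker ∩ numerator_region) / area(denominator_region)`.  A zero
#' denominator is an explicit error, never a silent 0.  Values above 1 are
#' possible only when the numerator region is not a subset of the
#' denominator region; such results carry an `exceeds_denominator`
#' attribute.
#'
#' @param marker marker [binary_mask()] (or logical matrix).
#' @param numerator_region region the marker is intersected with.
#' @param denominator_region region whose area divides.
#' @return Numeric fraction.
#' @export
surface_index <- function(marker, numerator_region, denominator_region) {
  check_same_grid(marker, numerator_region, "marker and numerator region")
  check_same_grid(marker, denominator_region, "marker and denominator region")
  den <- sum(mask_px(denominator_region))
  if (den == 0)
    stopf("surface index undefined: denominator region is empty")
  num <- sum(mask_px(marker) & mask_px(numerator_region))
  out <- num / den
  if (out > 1) attr(out, "exceeds_denominator") <- TRUE
  out
}

#' Endothelial-specific index
#'
#' Marker surface inside VS divided by the VS surface (used for TUNEL and
#' ZO-1 on the endothelium).
#'
#' @param marker marker mask.
#' @param vs the vascular ROI.
#' @return Numeric fraction in `[0, 1]`.
#' @export
endothelial_index <- function(marker, vs) {
  surface_index(marker, vs, vs)
}

#' Perivascular index
#'
#' Marker surface inside the PVS shell divided by the VS surface (not the
#' PVS surface), so a fully stained shell around a disk vessel of radius r
#' with a 5-um shell evaluates to ((r+5)^2 - r^2) / r^2.
#'
#' @param marker marker mask (SMA or desmin).
#' @param pvs,vs the perivascular and vascular ROIs (from one [roi_set()]).
#' @return Numeric value >= 0 (bounded by area(PVS)/area(VS)).
#' @export
perivascular_index <- function(marker, pvs, vs) {
  surface_index(marker, pvs, vs)
}

#' Per-vessel perivascular shells
#'
#' Assigns every PVS pixel to its nearest vessel object (by Euclidean
#' distance-transform feature), so adjacent vessels never share shell
#' pixels and per-object coverage is well defined.
#'
#' @param vessel_labels integer label matrix from [label_vessels()].
#' @param pvs the PVS [binary_mask()].
#' @return Integer matrix: vessel label owning each PVS pixel, 0 elsewhere.
#' @export
vessel_shells <- function(vessel_labels, pvs) {
  lab <- if (inherits(vessel_labels, "vessel_objects"))
    vessel_labels$labels else vessel_labels
  pv <- mask_px(pvs)
  if (!identical(dim(lab), dim(pv)))
    stopf("vessel labels and PVS are on different grids")
  e <- cpp_edt(lab > 0)
  shells <- matrix(0L, nrow(lab), ncol(lab))
  sel <- which(pv & e$frow > 0)
  shells[sel] <- lab[cbind(e$frow[sel], e$fcol[sel])]
  shells
}

#' Covered-vessel frequency
#'
#' A vessel counts as covered when the desmin+/SMA+ double-positive area
#' within its own perivascular shell reaches `coverage_threshold` of that
#' shell.  Returns the percentage of covered vessels.  The threshold is a
#' free parameter (the source methodology never defines "covered"); it is
#' recorded in the result's attributes.
#'
#' @param vessel_labels a [label_vessels()] result or integer label matrix.
#' @param desmin,sma segmented pericyte-marker masks.
#' @param pvs the PVS mask.
#' @param coverage_threshold fraction of a vessel's own shell that must be
#'   double-positive.
#' @return Percent of vessels covered (0..100), with attributes `n_vessels`
#'   and `coverage_threshold`.
#' @export
covered_vessel_frequency <- function(vessel_labels, desmin, sma, pvs,
                                     coverage_threshold = 0.10) {
  check_scalar(coverage_threshold, "coverage_threshold", lower = 0, upper = 1)
  lab <- if (inherits(vessel_labels, "vessel_objects"))
    vessel_labels$labels else vessel_labels
  n <- max(lab)
  if (n == 0) stopf("no vessel objects")
  shells <- vessel_shells(lab, pvs)
  dp <- mask_px(desmin) & mask_px(sma)
  shell_px <- tabulate(shells[shells > 0L], nbins = n)
  pos_px <- tabulate(shells[shells > 0L & dp], nbins = n)
  frac <- ifelse(shell_px > 0, pos_px / shell_px, 0)
  out <- 100 * mean(frac >= coverage_threshold & shell_px > 0)
  attr(out, "n_vessels") <- n
  attr(out, "coverage_threshold") <- coverage_threshold
  out
}
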