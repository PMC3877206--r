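#' Segmentation parameters
#'
#' The segmentation rule marks a pixel positive when its intensity is at
#' least `ratio_k` times the local background *and* at least the
#' negative-control floor; connected components smaller than
#' `min_object_area_um2` are then discarded as artifacts.  The local
#' background is a median over a disk of `background_radius_um`, robust to
#' bright foreground.  The source methodology states the ratio rule but not
#' its numeric values, so all parameters here are explicit configuration,
#' not reproductions.
#'
#' @param background_radius_um neighbourhood scale of the local background
#'   estimate (default 50 um).
#' @param ratio_k minimum foreground/background intensity ratio (> 1).
#' @param negcontrol_floor absolute intensity floor, typically derived from
#'   a negative-control image via [negcontrol_floor_from()].
#' @param min_object_area_um2 artifact size filter.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(background_radius_um = 50, ratio_k = 2,
                                negcontrol_floor = 0,
                                min_object_area_um2 = 10) {
  check_scalar(background_radius_um, "background_radius_um", lower = 1e-9)
  if (!is.numeric(ratio_k) || ratio_k <= 1)
    stopf("`ratio_k` must be > 1")
  check_scalar(negcontrol_floor, "negcontrol_floor", lower = 0)
  check_scalar(min_object_area_um2, "min_object_area_um2", lower = 0)
  structure(list(background_radius_um = background_radius_um,
                 ratio_k = ratio_k, negcontrol_floor = negcontrol_floor,
                 min_object_area_um2 = min_object_area_um2),
            class = "segmentation_params")
}

#' Local background estimate
#'
#' Median filter over a disk of `radius_um`, clamped below at 1 so
#' foreground/background ratios are always defined.
#'
#' @param channel numeric matrix of intensities (single channel).
#' @param radius_um disk radius in um (must map to at least 1 px).
#' @param resolution pixel size in um.
#' @return Numeric matrix of per-pixel background levels (>= 1).
#' @export
estimate_background <- function(channel, radius_um, resolution) {
  if (!is.matrix(channel) || length(channel) == 0)
    stopf("`channel` must be a non-empty matrix")
  check_scalar(resolution, "resolution", lower = 1e-9)
  r_px <- max(1L, as.integer(round(radius_um / resolution)))
  m <- matrix(as.integer(round(pmin(65535, pmax(0, channel)))),
              nrow(channel))
  bg <- cpp_median_disk(m, r_px)
  pmax(bg, 1)
}

#' Segment one marker channel
#'
#' @param channel numeric intensity matrix, or a [calibrated_image()]
#'   together with `marker`.
#' @param params a [segmentation_params()].
#' @param resolution pixel size in um (taken from the image if one is
#'   given).
#' @param marker marker/channel name (required when `channel` is an image).
#' @return A [binary_mask()] with the parameters recorded in its
#'   provenance.
#' @export
segment_channel <- function(channel, params, resolution = NULL,
                            marker = NA_character_) {
  if (inherits(channel, "calibrated_image")) {
    resolution <- channel$resolution_um_per_px
    channel <- get_channel(channel, marker)  # errors if absent
  }
  stopifnot(inherits(params, "segmentation_params"))
  check_scalar(resolution, "resolution", lower = 1e-9)
  bg <- estimate_background(channel, params$background_radius_um, resolution)
  pos <- channel >= params$ratio_k * bg & channel >= params$negcontrol_floor
  pos <- filter_small_objects(pos, params$min_object_area_um2, resolution)
  binary_mask(pos, resolution, marker = marker,
              provenance = c(unclass(params),
                             list(resolution_um_per_px = resolution)))
}

#' Negative-control intensity floor
#'
#' The q-th percentile of a negative-control channel (antibody-competed or
#' secondary-only staining).  The default 99.9th percentile keeps
#' essentially all control pixels below the floor.
#'
#' @param channel numeric matrix of the negative-control image.
#' @param q percentile in (0, 1).
#' @return Scalar intensity floor.
#' @export
negcontrol_floor_from <- function(channel, q = 0.999) {
  check_scalar(q, "q", lower = 0, upper = 1)
  as.numeric(quantile(channel, q, names = FALSE))
}
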