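#' Binary mask on a calibrated pixel grid
#'
#' A `binary_mask` couples a logical `[row, col]` raster with the marker name
#' it represents, the pixel size, and the provenance (parameters) of the
#' operation that produced it.
#'
#' @param px logical matrix (TRUE = positive).
#' @param resolution_um_per_px pixel size in um (isotropic in-plane).
#' @param marker marker name, e.g. `"CD31"`.
#' @param provenance named list describing how the mask was obtained.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(px, resolution_um_per_px, marker = NA_character_,
                        provenance = list()) {
  if (!is.matrix(px)) stopf("`px` must be a matrix")
  if (!is.logical(px)) {
    storage.mode(px) <- "logical"
  }
  px[is.na(px)] <- FALSE
  check_scalar(resolution_um_per_px, "resolution_um_per_px", lower = 1e-9)
  structure(list(px = px, marker = marker,
                 resolution_um_per_px = resolution_um_per_px,
                 provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s  %dx%d px @ %.4g um/px, %d positive (%.2f%%)\n",
              x$marker, nrow(x$px), ncol(x$px), x$resolution_um_per_px,
              sum(x$px), 100 * mean(x$px)))
  invisible(x)
}

# Accept a binary_mask or a plain logical matrix; return the logical matrix.
mask_px <- function(m) {
  if (inherits(m, "binary_mask")) m$px
  else if (is.matrix(m)) { storage.mode(m) <- "logical"; m }
  else stopf("expected a binary_mask or logical matrix")
}

mask_res <- function(m, resolution = NULL) {
  if (!is.null(resolution)) return(resolution)
  if (inherits(m, "binary_mask")) return(m$resolution_um_per_px)
  stopf("pixel resolution (um/px) missing: pass `resolution` or a binary_mask")
}

#' Physical area of a mask
#'
#' @param m a `binary_mask` or logical matrix.
#' @param resolution pixel size in um, required when `m` is a bare matrix.
#' @return Area in um^2 (pixel count times `res^2`).
#' @export
mask_area_um2 <- function(m, resolution = NULL) {
  res <- mask_res(m, resolution)
  sum(mask_px(m)) * res^2
}

check_same_grid <- function(a, b, what = "masks") {
  pa <- mask_px(a); pb <- mask_px(b)
  if (!identical(dim(pa), dim(pb)))
    stopf("%s are on different grids (%dx%d vs %dx%d)", what,
          nrow(pa), ncol(pa), nrow(pb), ncol(pb))
  invisible(TRUE)
}

#' Euclidean distance transform in physical units
#'
#' Per-pixel Euclidean distance (um) from each pixel center to the nearest
#' TRUE pixel center of the mask; 0 inside the mask, `Inf` when the mask is
#' empty.
#'
#' @inheritParams mask_area_um2
#' @param feature if TRUE, also return the nearest-pixel index maps.
#' @return A numeric matrix of distances (um), or when `feature = TRUE` a
#'   list with `dist`, `frow`, `fcol` (1-based indices of the nearest TRUE
#'   pixel, 0 when none exists).
#' @export
distance_transform_um <- function(m, resolution = NULL, feature = FALSE) {
  res <- mask_res(m, resolution)
  e <- cpp_edt(mask_px(m))
  e$dist <- e$dist * res
  if (feature) e else e$dist
}

#' Euclidean dilation / erosion by a physical radius
#'
#' Dilation thresholds the Euclidean distance transform at `radius_um`
#' (rotation-consistent, matching "enlarge" semantics), rather than iterating
#' discrete structuring elements.
#'
#' @inheritParams mask_area_um2
#' @param radius_um dilation radius in um (must be > 0 for `dilate_um`).
#' @return Logical matrix.
#' @export
dilate_um <- function(m, radius_um, resolution = NULL) {
  res <- mask_res(m, resolution)
  check_scalar(radius_um, "radius_um", lower = 0)
  px <- mask_px(m)
  if (radius_um == 0 || !any(px)) return(px)
  cpp_edt(px)$dist * res <= radius_um
}

#' @rdname dilate_um
#' @export
erode_um <- function(m, radius_um, resolution = NULL) {
  res <- mask_res(m, resolution)
  px <- mask_px(m)
  if (radius_um == 0) return(px)
  !(cpp_edt(!px)$dist * res <= radius_um) & px
}

# Remove connected components smaller than `min_area_um2` (8-connectivity).
filter_small_objects <- function(px, min_area_um2, resolution) {
  if (min_area_um2 <= 0 || !any(px)) return(px)
  lab <- cpp_label(px, 8L)
  n <- attr(lab, "n")
  if (n == 0L) return(px)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- sizes * resolution^2 >= min_area_um2
  out <- px
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Calibrated multi-channel image
#'
#' @param pixels numeric or integer array `[row, col, channel]` (a matrix is
#'   treated as one channel); intensities must lie in the unsigned 16-bit
#'   range 0..65535.
#' @param channels character vector of marker names, one per channel.
#' @param resolution_um_per_px pixel size in um.
#' @param z_step_um optional slice spacing (thin stacks only).
#' @return Object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, channels, resolution_um_per_px,
                             z_step_um = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stopf("`pixels` must be a [row, col, channel] array")
  if (length(channels) != dim(pixels)[3L])
    stopf("channel-name count (%d) does not match channel count (%d)",
          length(channels), dim(pixels)[3L])
  check_scalar(resolution_um_per_px, "resolution_um_per_px", lower = 1e-9)
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 65535)
    stopf("intensities must be within the unsigned 16-bit range 0..65535")
  structure(list(pixels = pixels, channels = as.character(channels),
                 resolution_um_per_px = resolution_um_per_px,
                 z_step_um = z_step_um),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %dx%d px, %d channels (%s) @ %.4g um/px\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", "),
              x$resolution_um_per_px))
  invisible(x)
}

#' Extract one channel of a calibrated image as a matrix
#'
#' @param img a `calibrated_image`.
#' @param channel channel name (must exist in `img$channels`).
#' @return Numeric matrix of intensities.
#' @export
get_channel <- function(img, channel) {
  stopifnot(inherits(img, "calibrated_image"))
  k <- match(channel, img$channels)
  if (is.na(k)) stopf("channel '%s' not present (have: %s)", channel,
                      paste(img$channels, collapse = ", "))
  img$pixels[, , k]
}
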