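# Calibrated image / mask / ground-truth / results I/O.
#
# Images travel as multi-page uncompressed 16-bit grayscale TIFFs (one page
# per channel, channel-first) with a JSON sidecar carrying the um/px
# calibration and the channel-name map.  No R TIFF reader is assumed: the
# package ships a minimal baseline codec for exactly this dialect
# (little-endian, uncompressed, single strip per page) and refuses anything
# else rather than guessing.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a calibrated image as multi-page 16-bit TIFF plus JSON sidecar
#'
#' @param img a [calibrated_image()].
#' @param path output TIFF path; the calibration sidecar is written next to
#'   it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "calibrated_image"))
  pages <- lapply(seq_along(img$channels), function(k) img$pixels[, , k])
  write_tiff16(pages, path)
  meta <- list(resolution_um_per_px = img$resolution_um_per_px,
               channels = as.list(img$channels))
  if (!is.null(img$z_step_um)) meta$z_step_um <- img$z_step_um
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibrated image written by [write_image()]
#'
#' Calibration must be present in the sidecar (or supplied via `meta`);
#' a missing or zero resolution is an error, never a silent default.
#'
#' @param path TIFF path.
#' @param meta optional explicit sidecar path, or a list with
#'   `resolution_um_per_px` and `channels`.
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, meta = NULL) {
  if (!file.exists(path)) stopf("image file does not exist: %s", path)
  pages <- read_tiff16(path)
  if (is.null(meta)) meta <- sidecar_path(path)
  if (is.character(meta)) {
    if (!file.exists(meta))
      stopf("missing calibration: no sidecar at %s", meta)
    meta <- jsonlite::read_json(meta, simplifyVector = TRUE)
  }
  res <- meta$resolution_um_per_px
  if (is.null(res) || !is.numeric(res) || length(res) != 1 || res <= 0)
    stopf("missing or invalid resolution_um_per_px in calibration metadata")
  channels <- unlist(meta$channels)
  if (length(channels) != length(pages))
    stopf("channel-name count (%d) does not match page count (%d)",
          length(channels), length(pages))
  px <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) px[, , k] <- pages[[k]]
  calibrated_image(px, channels, res, z_step_um = meta$z_step_um)
}

#' Write / read a binary mask as a single-page TIFF
#'
#' Masks are stored as 16-bit 0/1 rasters with the same sidecar convention.
#'
#' @param mask a [binary_mask()].
#' @param path TIFF path.
#' @return `path` invisibly / a [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_tiff16(list(matrix(as.integer(mask$px), nrow(mask$px))), path)
  jsonlite::write_json(
    list(resolution_um_per_px = mask$resolution_um_per_px,
         marker = mask$marker, provenance = mask$provenance),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("mask file does not exist: %s", path)
  pages <- read_tiff16(path)
  if (length(pages) != 1) stopf("mask TIFF must have exactly one page")
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stopf("missing calibration: no sidecar at %s", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  prov <- meta$provenance
  binary_mask(pages[[1]] > 0, meta$resolution_um_per_px,
              marker = meta$marker %||% NA_character_,
              provenance = if (is.null(prov)) list() else as.list(prov))
}

# ---- minimal baseline TIFF codec (16-bit grayscale, uncompressed) --------

write_tiff16 <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w16(42)
  n <- length(pages)
  # layout: header (8) | page data blocks | IFDs
  offsets <- integer(n)
  pos <- 8
  for (k in seq_len(n)) {
    offsets[k] <- pos
    pos <- pos + 2L * length(pages[[k]])
  }
  ifd_offsets <- pos + (0:(n - 1)) * (2 + 9 * 12 + 4)
  w32(ifd_offsets[1])
  for (k in seq_len(n)) {
    m <- pages[[k]]
    v <- as.integer(t(m))  # row-major pixel order
    if (any(v < 0 | v > 65535)) stopf("pixel values outside 16-bit range")
    writeBin(v, con, size = 2, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count); w32(value)
  }
  for (k in seq_len(n)) {
    m <- pages[[k]]
    w16(9)  # entry count
    entry(256, 3, 1, ncol(m))             # ImageWidth
    entry(257, 3, 1, nrow(m))             # ImageLength
    entry(258, 3, 1, 16)                  # BitsPerSample
    entry(259, 3, 1, 1)                   # Compression: none
    entry(262, 3, 1, 1)                   # Photometric: BlackIsZero
    entry(273, 4, 1, offsets[k])          # StripOffsets
    entry(277, 3, 1, 1)                   # SamplesPerPixel
    entry(278, 3, 1, nrow(m))             # RowsPerStrip
    entry(279, 4, 1, 2L * length(m))      # StripByteCounts
    w32(if (k < n) ifd_offsets[k + 1] else 0)
  }
  invisible(path)
}

read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stopf("not a TIFF file: %s", path)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II")
    stopf("unsupported TIFF byte order (only little-endian 'II' handled)")
  if (u16(2) != 42) stopf("not a TIFF file: %s", path)
  pages <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    nent <- u16(ifd)
    tags <- list()
    for (e in seq_len(nent)) {
      off <- ifd + 2 + (e - 1) * 12
      tags[[as.character(u16(off))]] <-
        list(type = u16(off + 2), count = u32(off + 4), value = u32(off + 8))
    }
    need <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) {
        if (is.null(default)) stopf("TIFF tag %d missing", tag)
        return(default)
      }
      # SHORT values sit in the low bytes of the value word
      if (t$type == 3) t$value %% 65536 else t$value
    }
    if (need(258, 16) != 16 || need(259, 1) != 1 || need(277, 1) != 1)
      stopf("unsupported TIFF variant (need uncompressed 16-bit grayscale)")
    wd <- need(256); ht <- need(257)
    strip_off <- need(273); nbytes <- need(279, 2 * wd * ht)
    if (nbytes != 2 * wd * ht)
      stopf("unsupported TIFF strip layout (need one full-image strip)")
    vals <- readBin(raw[(strip_off + 1):(strip_off + nbytes)], "integer",
                    n = wd * ht, size = 2, endian = "little", signed = FALSE)
    pages[[length(pages) + 1]] <- matrix(vals, nrow = ht, ncol = wd,
                                         byrow = TRUE)
    ifd <- u32(ifd + 2 + nent * 12)
  }
  if (length(pages) == 0) stopf("TIFF contains no pages: %s", path)
  pages
}

# ---- scene spec & ground truth ------------------------------------------

#' Read/write a scene specification as JSON
#'
#' @param spec a [scene_spec()].
#' @param path JSON file path.
#' @return `path` invisibly / a `scene_spec`.
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  vals <- unclass(spec)
  # named vectors must serialize as JSON objects, not bare arrays
  vals$marker_fractions <- as.list(vals$marker_fractions)
  vals$puncta_per_mm2_lumen <- as.list(vals$puncta_per_mm2_lumen)
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("marker_fractions", "puncta_per_mm2_lumen"))
    if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
  do.call(scene_spec, vals)
}

#' Serialize ground truth to JSON plus a clean-mask TIFF
#'
#' Writes `<prefix>.json` (trees, nuclei, true metrics, spec) and
#' `<prefix>_masks.tif` (+ sidecar) with the noise-free channel masks.
#'
#' @param gt a `ground_truth`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_ground_truth <- function(gt, prefix) {
  stopifnot(inherits(gt, "ground_truth"))
  trees <- lapply(gt$trees, function(t) {
    list(id = t$id, radius_um = t$radius_um, perfused = t$perfused,
         covered = t$covered, zo1 = t$zo1, n_junctions = t$n_junctions,
         length_um = t$length_um,
         segments = unname(apply(t$segments, 1, as.numeric, simplify = FALSE)))
  })
  spec_vals <- unclass(gt$spec)
  spec_vals$marker_fractions <- as.list(spec_vals$marker_fractions)
  spec_vals$puncta_per_mm2_lumen <- as.list(spec_vals$puncta_per_mm2_lumen)
  jsonlite::write_json(
    list(trees = trees, nuclei = gt$nuclei,
         resolution_um_per_px = gt$resolution_um_per_px,
         spec = spec_vals, true_metrics = gt$true_metrics),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  masks <- lapply(gt$clean_masks, function(m)
    matrix(as.integer(m), nrow(m)))
  write_tiff16(masks, paste0(prefix, "_masks.tif"))
  jsonlite::write_json(
    list(resolution_um_per_px = gt$resolution_um_per_px,
         channels = as.list(names(gt$clean_masks))),
    sidecar_path(paste0(prefix, "_masks.tif")),
    auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(prefix) {
  j <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  trees <- lapply(seq_len(nrow(j$trees)), function(k) {
    t <- j$trees[k, ]
    seg_raw <- t$segments[[1]]
    segs <- if (is.matrix(seg_raw)) seg_raw else do.call(rbind, seg_raw)
    list(id = t$id, radius_um = t$radius_um, perfused = t$perfused,
         covered = t$covered, zo1 = t$zo1,
         segments = segs, n_junctions = as.integer(t$n_junctions),
         length_um = t$length_um)
  })
  pages <- read_tiff16(paste0(prefix, "_masks.tif"))
  meta <- jsonlite::read_json(sidecar_path(paste0(prefix, "_masks.tif")),
                              simplifyVector = TRUE)
  clean <- lapply(pages, function(p) p > 0)
  names(clean) <- unlist(meta$channels)
  spec_vals <- as.list(j$spec)
  for (f in c("marker_fractions", "puncta_per_mm2_lumen"))
    if (!is.null(spec_vals[[f]])) spec_vals[[f]] <- unlist(spec_vals[[f]])
  spec <- do.call(scene_spec, spec_vals)
  gt <- structure(list(trees = trees, nuclei = j$nuclei,
                       clean_masks = clean, spec = spec,
                       resolution_um_per_px = j$resolution_um_per_px),
                  class = "ground_truth")
  gt$true_metrics <- true_metrics(gt, spec)
  gt
}

# ---- result tables -------------------------------------------------------

#' Write result tables as CSV
#'
#' One file per table: an index table (one row per image), optional group
#' summaries and comparisons.  Column order is fixed and rows are sorted so
#' re-running the same analysis yields byte-identical files.
#'
#' @param tables named list of data frames (e.g. `index`, `summary`,
#'   `comparisons`).
#' @param out_dir output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stopf("cannot create '%s'", out_dir)
  }
  if (length(tables) == 0) stopf("no tables to write")
  paths <- character(0)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    if (!is.data.frame(df)) next
    if (nrow(df) == 0)
      warning(sprintf("table '%s' is empty; writing header only", nm),
              call. = FALSE)
    ord <- do.call(order, c(unname(as.list(df[, intersect(
      c("group", "image_id", "metric", "group_a", "group_b"),
      names(df)), drop = FALSE])), list(method = "radix")))
    if (length(ord) == nrow(df) && nrow(df) > 0) df <- df[ord, , drop = FALSE]
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  invisible(paths)
}
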