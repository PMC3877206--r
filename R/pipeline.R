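# Config-driven orchestration: generate or ingest calibrated images, run
# segmentation -> ROIs -> indices / distance profile / network metrics per
# image, aggregate per group (mean +/- sem), and run the rank-based group
# statistics.  Per-image analyses are independent; processing order never
# affects results.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (scenes generated from `base_spec`) or
#'   `"images"` (TIFFs + sidecars read from `input_dir`).
#' @param base_spec a [scene_spec()] (synthetic mode).
#' @param groups synthetic mode: named list, one entry per group label, each
#'   a list with `n_scenes` and optional `overrides` (scene-spec fields
#'   varied for that group, e.g. `perfused_fraction`).  Image mode: named
#'   list mapping group label to character vectors of image paths.
#' @param channels named channel map: which image channel plays each role;
#'   defaults match the generator (`dapi = "DAPI"`, `cd31 = "CD31"`, ...).
#' @param seg named list of [segmentation_params()], one per channel name,
#'   plus an optional `default` used for unlisted channels.  Every analyzed
#'   channel must be covered.
#' @param negcontrol `"auto"` (synthetic mode: floor simulated from the
#'   background/noise model) or a numeric floor applied to all channels.
#' @param tt_dilation_um,pvs_shell_um,gap_um,hypoxic_cutoff_um ROI and
#'   distance-profile constants (10, 5, 5 and 100 um defaults).
#' @param coverage_threshold covered-vessel shell threshold.
#' @param vs_min_area_um2 vessel size filter.
#' @param prune_um skeleton spur-pruning threshold.
#' @param seed global seed; every scene derives its own seed from it.
#' @param out_dir optional output directory for [write_results()].
#' @return Validated object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "images"), base_spec = NULL,
                       groups = list(), channels = NULL, seg = NULL,
                       negcontrol = "auto", tt_dilation_um = 10,
                       pvs_shell_um = 5, gap_um = 5,
                       hypoxic_cutoff_um = 100, coverage_threshold = 0.10,
                       vs_min_area_um2 = 10, prune_um = 10, seed = 1L,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  channels <- utils::modifyList(
    list(dapi = "DAPI", cd31 = "CD31", ki67 = "Ki67", tunel = "TUNEL",
         ef5 = "EF5", sma = "SMA", desmin = "desmin", zo1 = "ZO1",
         hoechst = "Hoechst", dex10k = "dex10k", dex2m = "dex2M"),
    as.list(channels %||% list()))
  if (is.null(seg)) seg <- list(default = segmentation_params())
  cfg <- structure(list(mode = mode, base_spec = base_spec, groups = groups,
                        channels = channels, seg = seg,
                        negcontrol = negcontrol,
                        tt_dilation_um = tt_dilation_um,
                        pvs_shell_um = pvs_shell_um, gap_um = gap_um,
                        hypoxic_cutoff_um = hypoxic_cutoff_um,
                        coverage_threshold = coverage_threshold,
                        vs_min_area_um2 = vs_min_area_um2,
                        prune_um = prune_um, seed = as.integer(seed),
                        out_dir = out_dir),
                   class = "run_config")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (length(cfg$groups) == 0 || is.null(names(cfg$groups)) ||
      any(names(cfg$groups) == ""))
    stopf("`groups` must be a non-empty named list (group labels)")
  if (cfg$mode == "synthetic") {
    if (is.null(cfg$base_spec)) cfg$base_spec <- scene_spec()
    stopifnot(inherits(cfg$base_spec, "scene_spec"))
    for (g in names(cfg$groups))
      if (is.null(cfg$groups[[g]]$n_scenes) || cfg$groups[[g]]$n_scenes < 1)
        stopf("group '%s' needs `n_scenes` >= 1", g)
  }
  # every analyzed channel must have segmentation parameters
  if (is.null(cfg$seg$default)) {
    for (ch in unlist(cfg$channels, use.names = FALSE))
      if (is.null(cfg$seg[[ch]]))
        stopf("no segmentation parameters for channel '%s' and no default",
              ch)
  }
  for (p in cfg$seg)
    if (!inherits(p, "segmentation_params"))
      stopf("`seg` entries must be segmentation_params objects")
  check_scalar(cfg$hypoxic_cutoff_um, "hypoxic_cutoff_um", lower = 0)
  cfg
}

seg_params_for <- function(cfg, channel, floor = NULL) {
  p <- cfg$seg[[channel]] %||% cfg$seg$default
  if (is.null(p)) stopf("no segmentation parameters for channel '%s'", channel)
  if (!is.null(floor)) p$negcontrol_floor <- max(p$negcontrol_floor, floor)
  p
}

# Simulated negative-control floor for the background/noise model of a
# scene spec (the rendered background is flat at background_level with
# additive Gaussian noise).
auto_negcontrol_floor <- function(spec, seed) {
  with_seed(seed, {
    blank <- spec$background_level + rnorm(256 * 256, 0, spec$noise_sd)
    negcontrol_floor_from(matrix(pmin(65535, pmax(0, blank)), 256), 0.999)
  })
}

#' Analyze one calibrated image
#'
#' Runs segmentation, ROI construction, all surface/object indices, the
#' distance profile and the network metrics for a single image.
#'
#' @param img a [calibrated_image()].
#' @param cfg a [run_config()].
#' @param image_id identifier recorded in the output row.
#' @param group group/time label.
#' @param exclusion optional exclusion [binary_mask()].
#' @param floor negative-control floor (numeric, or NULL for the configured
#'   behaviour).
#' @return List: `row` (one-row data.frame of the index table), `profile`
#'   (a `distance_profile` or NULL), `masks` (named list of segmented
#'   masks), `rois`, `network`.
#' @export
analyze_image <- function(img, cfg, image_id = "img", group = NA_character_,
                          exclusion = NULL, floor = NULL) {
  stopifnot(inherits(img, "calibrated_image"))
  ch <- cfg$channels
  if (is.null(floor) && is.numeric(cfg$negcontrol)) floor <- cfg$negcontrol
  seg_one <- function(role) {
    name <- ch[[role]]
    if (is.null(name) || !(name %in% img$channels)) return(NULL)
    segment_channel(img, seg_params_for(cfg, name, floor), marker = name)
  }
  masks <- list(dapi = seg_one("dapi"), cd31 = seg_one("cd31"),
                ki67 = seg_one("ki67"), tunel = seg_one("tunel"),
                ef5 = seg_one("ef5"), sma = seg_one("sma"),
                desmin = seg_one("desmin"), zo1 = seg_one("zo1"),
                hoechst = seg_one("hoechst"), dex10k = seg_one("dex10k"),
                dex2m = seg_one("dex2m"))
  if (is.null(masks$dapi) || is.null(masks$cd31))
    stopf("image must provide DAPI and CD31 channels (have: %s)",
          paste(img$channels, collapse = ", "))
  rois <- roi_set(masks$dapi, masks$cd31, exclusion = exclusion,
                  tt_dilation_um = cfg$tt_dilation_um,
                  pvs_shell_um = cfg$pvs_shell_um,
                  vs_min_area_um2 = cfg$vs_min_area_um2)
  res <- rois$resolution_um_per_px
  tt <- rois$tt; vs <- rois$vs; pvs <- rois$pvs
  tt_mm2 <- mask_area_um2(tt) / 1e6
  has_vs <- any(mask_px(vs))

  sidx <- function(m) if (is.null(m)) NA_real_ else
    as.numeric(surface_index(m, tt, tt))
  eidx <- function(m) if (is.null(m) || !has_vs) NA_real_ else
    as.numeric(endothelial_index(m, vs))
  pidx <- function(m) if (is.null(m) || !has_vs) NA_real_ else
    as.numeric(perivascular_index(m, pvs, vs))

  objects <- label_vessels(vs, cfg$vs_min_area_um2, res)
  covered <- if (objects$n > 0 && !is.null(masks$desmin) &&
                 !is.null(masks$sma))
    as.numeric(covered_vessel_frequency(objects, masks$desmin, masks$sma,
                                        pvs, cfg$coverage_threshold))
  else NA_real_

  profile <- NULL; pct_beyond <- NA_real_
  if (has_vs) {
    dmap <- vessel_distance_map(vs, res)
    profile <- distance_profile(masks$dapi, tt, dmap, cfg$gap_um)
    pct_beyond <- sum(profile$percent_per_bin[
      profile$bin_lower_um >= cfg$hypoxic_cutoff_um])
  }

  net <- NULL
  net_row <- list(branch_per_mm = NA_real_, mean_diameter_um = NA_real_,
                  skeleton_length_mm = NA_real_, tortuosity = NA_real_,
                  n_junctions = NA_integer_)
  if (has_vs) {
    skel <- skeletonize_vs(vs, res, prune_um = cfg$prune_um)
    if (skel$length_um > 0) {
      net <- network_metrics(skel, vs, objects, tt_mm2)
      net_row <- list(branch_per_mm = net$branch_per_mm,
                      mean_diameter_um = net$mean_diameter_um,
                      skeleton_length_mm = net$skeleton_length_mm,
                      tortuosity = net$tortuosity,
                      n_junctions = net$n_junctions)
    }
  }

  row <- data.frame(
    image_id = image_id, group = group,
    ki67_index = sidx(masks$ki67), tunel_index = sidx(masks$tunel),
    ef5_index = sidx(masks$ef5), hoechst_surface = sidx(masks$hoechst),
    dextran10k_surface = sidx(masks$dex10k),
    dextran2M_surface = sidx(masks$dex2m),
    zo1_endothelial_index = eidx(masks$zo1),
    tunel_endothelial_index = eidx(masks$tunel),
    sma_perivascular_index = pidx(masks$sma),
    desmin_perivascular_index = pidx(masks$desmin),
    covered_vessel_frequency = covered,
    mvd_per_mm2 = if (tt_mm2 > 0) microvessel_density(objects, tt_mm2)
                  else NA_real_,
    n_vessels = objects$n, tt_area_mm2 = tt_mm2,
    vs_area_um2 = mask_area_um2(vs),
    pct_cells_beyond_100um = pct_beyond,
    branch_per_mm = net_row$branch_per_mm,
    mean_diameter_um = net_row$mean_diameter_um,
    skeleton_length_mm = net_row$skeleton_length_mm,
    tortuosity = net_row$tortuosity,
    n_junctions = net_row$n_junctions,
    stringsAsFactors = FALSE)
  list(row = row, profile = profile, masks = masks, rois = rois,
       network = net)
}

scene_seed <- function(cfg_seed, g_index, k) {
  as.integer((as.numeric(cfg_seed) * 131 + g_index * 7919 + k * 104729) %%
             2147483629)
}

#' Run a full experiment
#'
#' Synthetic mode: generates `n_scenes` scenes per group (group overrides
#' applied to the base scene spec, per-scene seeds derived from the global
#' seed), analyzes each, and aggregates.  Image mode: reads each listed
#' TIFF (with its sidecar) and analyzes it.  A failing image is reported in
#' `logs$failures` and skipped.
#'
#' @param cfg a [run_config()].
#' @return Result bundle: `index` (per-image table), `summary` (per group x
#'   metric mean, sem, n), `comparisons` (pairwise tests), `kruskal`
#'   (omnibus rows when >= 3 groups), `profiles`, `truth` (synthetic mode:
#'   per-scene true metrics), `logs`.
#' @export
run_experiment <- function(cfg) {
  cfg <- validate_run_config(cfg)
  rows <- list(); profiles <- list(); truth <- list(); failures <- list()
  g_labels <- names(cfg$groups)
  for (gi in seq_along(g_labels)) {
    g <- g_labels[gi]
    if (cfg$mode == "synthetic") {
      n <- cfg$groups[[g]]$n_scenes
      overrides <- cfg$groups[[g]]$overrides %||% list()
      for (k in seq_len(n)) {
        id <- sprintf("%s_scene%02d", g, k)
        sp <- utils::modifyList(cfg$base_spec, overrides)
        sp$seed <- scene_seed(cfg$seed, gi, k)
        sp <- validate_scene_spec(structure(sp, class = "scene_spec"))
        out <- tryCatch({
          scn <- generate_scene(sp)
          floor <- if (identical(cfg$negcontrol, "auto"))
            auto_negcontrol_floor(sp, sp$seed + 7L) else NULL
          a <- analyze_image(scn$image, cfg, image_id = id, group = g,
                             floor = floor)
          truth[[id]] <- scn$gt$true_metrics
          a
        }, error = function(e) e)
        if (inherits(out, "error")) {
          failures[[id]] <- conditionMessage(out)
        } else {
          rows[[id]] <- out$row
          profiles[[id]] <- out$profile
        }
      }
    } else {
      paths <- cfg$groups[[g]]
      for (p in paths) {
        id <- tools::file_path_sans_ext(basename(p))
        out <- tryCatch(
          analyze_image(read_image(p), cfg, image_id = id, group = g),
          error = function(e) e)
        if (inherits(out, "error")) {
          failures[[id]] <- conditionMessage(out)
        } else {
          rows[[id]] <- out$row
          profiles[[id]] <- out$profile
        }
      }
    }
  }
  if (length(rows) == 0) stopf("no image analyzed successfully")
  index <- do.call(rbind, unname(rows))
  metrics <- setdiff(names(index)[vapply(index, is.numeric, logical(1))],
                     c("n_vessels"))
  summary <- group_summary(index, metrics)
  stats <- group_statistics(index, metrics)
  logs <- list(seed = cfg$seed, n_images = nrow(index),
               failures = failures,
               package_version = as.character(utils::packageVersion("vascquant")),
               timestamp_free = TRUE)
  bundle <- list(index = index, summary = summary,
                 comparisons = stats$comparisons, kruskal = stats$kruskal,
                 profiles = profiles, truth = truth, logs = logs)
  if (!is.null(cfg$out_dir))
    write_results(list(index = index, summary = summary,
                       comparisons = stats$comparisons), cfg$out_dir)
  bundle
}

group_summary <- function(index, metrics) {
  gs <- split(index, index$group)
  out <- list()
  for (g in names(gs)) {
    for (m in metrics) {
      v <- gs[[g]][[m]]
      v <- v[!is.na(v)]
      out[[length(out) + 1]] <- data.frame(
        group = g, metric = m, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

group_statistics <- function(index, metrics) {
  groups <- unique(index$group)
  comparisons <- list(); kruskal <- list()
  if (length(groups) < 2)
    return(list(comparisons = data.frame(), kruskal = data.frame()))
  for (m in metrics) {
    vals <- lapply(groups, function(g) {
      v <- index[[m]][index$group == g]
      v[!is.na(v)]
    })
    names(vals) <- groups
    if (any(vapply(vals, length, integer(1)) == 0)) next
    if (length(groups) == 2) {
      comparisons[[m]] <- mann_whitney(vals[[1]], vals[[2]], metric = m,
                                       labels = groups)
    } else {
      kd <- kruskal_dunn(vals, metric = m)
      comparisons[[m]] <- kd$pairwise
      kruskal[[m]] <- data.frame(metric = m, H = kd$H, df = kd$df,
                                 p_value = kd$p_value,
                                 stringsAsFactors = FALSE)
    }
  }
  list(comparisons = if (length(comparisons))
         do.call(rbind, unname(comparisons)) else data.frame(),
       kruskal = if (length(kruskal))
         do.call(rbind, unname(kruskal)) else data.frame())
}
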