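#' Synthetic-scene specification
#'
#' Parameters of the synthetic microscopy scene generator.  Defaults emulate
#' an orthotopic prostate-tumor field: microvessel density around 50
#' vessels/mm^2 (a normal-prostate-like field would use `n_stems` near 166
#' per mm^2), mean vessel diameter 9.5 um, hypoxia marking beyond 100 um
#' from the nearest perfused vessel, and 16-bit rendering with a Gaussian
#' point-spread function and additive Gaussian sensor noise at a
#' signal-to-noise ratio of about 10.
#'
#' @param field_width_um,field_height_um physical field extent (um).
#' @param resolution_um_per_px pixel size (um/px).
#' @param n_stems number of vessel root segments (trees) in the field.
#' @param branch_prob probability of a branch per centerline step; with the
#'   default 5-um step, 0.045 yields about 9 branch points per mm of
#'   centerline.
#' @param step_um centerline step length of the persistent random walk.
#' @param angle_sd_rad angular perturbation (sd, radians) per step.
#' @param max_tree_length_um path-length budget from root to any leaf.
#' @param mean_diameter_um,diameter_sd_um lognormal vessel-diameter
#'   parameters (mean and sd of the diameter itself).
#' @param perfused_fraction fraction of vessels flagged perfused.
#' @param covered_fraction fraction of vessels given a desmin+/SMA+ pericyte
#'   shell.
#' @param zo1_fraction fraction of vessels expressing junctional ZO-1.
#' @param pericyte_shell_um thickness of the pericyte shell (default 3 um,
#'   deliberately below the 5-um perivascular ROI so the perivascular index
#'   is exercised below saturation).
#' @param zo1_band_um width of the intra-endothelial ZO-1 band.
#' @param hoechst_halo_um diffusion halo of the small perfusion marker
#'   around perfused lumens.
#' @param nuclei_density_per_mm2 nucleus density.
#' @param nucleus_radius_um nucleus disk radius.
#' @param marker_fractions named fractions of nuclei positive per marker
#'   (`ki67`, `tunel`).
#' @param hypoxia_distance_um distance from the nearest perfused vessel
#'   surface beyond which a nucleus is marked hypoxic (EF5+).
#' @param puncta_radius_um radius of perfusion-marker (dextran) puncta.
#' @param puncta_per_mm2_lumen named puncta densities per mm^2 of perfused
#'   lumen (`dex10k`, `dex2m`); the source study gives no generative value,
#'   so these are free parameters.
#' @param psf_sigma_um Gaussian PSF sigma of the rendering.
#' @param noise_sd additive Gaussian noise sd (16-bit counts).
#' @param background_level,foreground_level rendered intensity levels.
#' @param allow_overlap if FALSE, trees are rejection-sampled so their tubes
#'   do not touch (making object counts and junction counts exactly
#'   recoverable).
#' @param seed integer RNG seed; every random draw of the generator derives
#'   from it.
#' @return A validated object of class `scene_spec`.
#' @export
scene_spec <- function(field_width_um = 1000, field_height_um = 1000,
                       resolution_um_per_px = 1,
                       n_stems = 50, branch_prob = 0.045, step_um = 5,
                       angle_sd_rad = 0.15, max_tree_length_um = 75,
                       mean_diameter_um = 9.5, diameter_sd_um = 2,
                       perfused_fraction = 0.7, covered_fraction = 0.2,
                       zo1_fraction = 0.5,
                       pericyte_shell_um = 3, zo1_band_um = 1,
                       hoechst_halo_um = 2,
                       nuclei_density_per_mm2 = 3000, nucleus_radius_um = 3,
                       marker_fractions = c(ki67 = 0.30, tunel = 0.05),
                       hypoxia_distance_um = 100,
                       puncta_radius_um = 1.5,
                       puncta_per_mm2_lumen = c(dex10k = 60000, dex2m = 30000),
                       psf_sigma_um = 0.5, noise_sd = 950,
                       background_level = 500, foreground_level = 10000,
                       allow_overlap = TRUE, seed = 1L) {
  spec <- structure(as.list(environment()), class = "scene_spec")
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  check_scalar(spec$field_width_um, "field_width_um", lower = 1e-9)
  check_scalar(spec$field_height_um, "field_height_um", lower = 1e-9)
  check_scalar(spec$resolution_um_per_px, "resolution_um_per_px", lower = 1e-9)
  check_scalar(spec$mean_diameter_um, "mean_diameter_um", lower = 1e-9)
  check_scalar(spec$diameter_sd_um, "diameter_sd_um", lower = 0)
  check_scalar(spec$hypoxia_distance_um, "hypoxia_distance_um", lower = 0)
  check_scalar(spec$n_stems, "n_stems", lower = 0)
  check_scalar(spec$step_um, "step_um", lower = 1e-9)
  check_scalar(spec$noise_sd, "noise_sd", lower = 0)
  for (f in c("branch_prob", "perfused_fraction", "covered_fraction",
              "zo1_fraction"))
    check_scalar(spec[[f]], f, lower = 0, upper = 1)
  if (any(spec$marker_fractions < 0 | spec$marker_fractions > 1))
    stopf("marker_fractions must lie in [0, 1]")
  if (spec$foreground_level < spec$background_level)
    stopf("foreground_level must be >= background_level")
  if (spec$background_level < 0 || spec$foreground_level > 65535)
    stopf("intensity levels must lie in the 16-bit range")
  spec
}

scene_dims <- function(spec) {
  c(max(1L, round(spec$field_height_um / spec$resolution_um_per_px)),
    max(1L, round(spec$field_width_um / spec$resolution_um_per_px)))
}

# Segment table (x0, y0, x1, y1, r) of one tree, for the capsule rasterizer.
tree_segments <- function(tree) {
  cbind(tree$segments, r = rep(tree$radius_um, nrow(tree$segments)))
}

#' Rasterize one vessel tree to a binary tube mask
#'
#' @param tree one element of the list returned by
#'   [generate_vessel_network()].
#' @param spec the `scene_spec` the tree was grown under.
#' @return Logical matrix on the scene grid.
#' @export
tree_mask <- function(tree, spec) {
  d <- scene_dims(spec)
  cpp_rasterize_tubes(tree_segments(tree), d[1], d[2],
                      spec$resolution_um_per_px)
}

# Persistent-random-walk growth of one tree; returns segments and the count
# of realized junctions (branch events where both parent and child continued).
grow_tree <- function(spec, root, dir0, radius_um) {
  grow_tree_tip(spec, root[1], root[2], dir0, spec$max_tree_length_um,
                radius_um)
}

# One tip: advance by step_um with angular diffusion, branching recursively.
# Two constraints keep the branch-point ground truth anatomically
# resolvable on the raster: a branch is realized only when the child
# subtree extends beyond max(5 * radius, 3 * step) from the branch point
# (a stub buried inside the parent tube is not a branch), and branch events
# on one tip are separated by a refractory period of 3 steps (two branch
# points inside one tube-diameter would fuse into a single medial-axis
# junction).  A realized branch event becomes a junction only when the
# parent also appends at least one more segment afterwards.
grow_tree_tip <- function(spec, x, y, dir, remaining, radius_um,
                          refractory = 3L) {
  W <- spec$field_width_um; H <- spec$field_height_um
  min_extent <- max(5 * radius_um, 3 * spec$step_um)
  segs <- matrix(numeric(0), ncol = 4)
  n_junctions <- 0L
  resumes <- integer(0)
  cooldown <- refractory
  repeat {
    if (remaining <= 0) break
    dir <- dir + rnorm(1, 0, spec$angle_sd_rad)
    nx <- x + spec$step_um * cos(dir)
    ny <- y + spec$step_um * sin(dir)
    if (nx < 0 || nx > W || ny < 0 || ny > H) break
    segs <- rbind(segs, c(x, y, nx, ny))
    x <- nx; y <- ny
    remaining <- remaining - spec$step_um
    cooldown <- cooldown - 1L
    if (spec$branch_prob > 0 && cooldown <= 0 &&
        runif(1) < spec$branch_prob && remaining > 0) {
      child_dir <- dir + sample(c(-1, 1), 1) * runif(1, pi / 3, pi / 2)
      child <- grow_tree_tip(spec, x, y, child_dir, remaining, radius_um,
                             refractory)
      if (nrow(child$segments) > 0) {
        extent <- max(sqrt((child$segments[, 3] - x)^2 +
                           (child$segments[, 4] - y)^2))
        if (extent >= min_extent) {
          segs <- rbind(segs, child$segments)
          resumes <- c(resumes, nrow(segs))
          n_junctions <- n_junctions + child$n_junctions
          cooldown <- refractory
        }
      }
    }
  }
  if (length(resumes) > 0)
    n_junctions <- n_junctions + sum(resumes < nrow(segs))
  list(segments = segs, n_junctions = n_junctions)
}

# TRUE when no two distant-in-tree centerline segments come closer than
# 2 * radius + clear_um (tubes would merge away from a branch point,
# making component / junction counts ill-posed).  Flat segment order is
# depth-first, so small index gaps correspond to path-adjacent segments,
# which are allowed to touch.
tree_self_clear <- function(segs, radius_um, clear_um) {
  n <- nrow(segs)
  if (n < 8) return(TRUE)
  thr <- 2 * radius_um + clear_um
  mx <- (segs[, 1] + segs[, 3]) / 2
  my <- (segs[, 2] + segs[, 4]) / 2
  for (i in seq_len(n - 7)) {
    js <- (i + 7):n
    d2 <- (mx[js] - mx[i])^2 + (my[js] - my[i])^2
    if (any(d2 < thr^2)) return(FALSE)
  }
  TRUE
}

#' Generate a synthetic vessel network
#'
#' Grows `n_stems` vessel trees by a persistent random walk (small angular
#' perturbation per step) with Bernoulli branching per step, assigns each
#' tree a lognormal diameter and perfused / covered / ZO-1 flags at the
#' stated fractions.  Deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return List of vessel trees; each tree is a list with `id`,
#'   `radius_um`, `perfused`, `covered`, `zo1`, `segments` (matrix of
#'   centerline steps `x0, y0, x1, y1` in um), `n_junctions`, `length_um`.
#' @export
generate_vessel_network <- function(spec) {
  spec <- validate_scene_spec(spec)
  d <- scene_dims(spec)
  with_seed(spec$seed, {
    m <- spec$mean_diameter_um; s <- spec$diameter_sd_um
    sdlog <- sqrt(log(1 + (s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    occupancy <- NULL
    if (!spec$allow_overlap)
      occupancy <- matrix(FALSE, d[1], d[2])
    trees <- vector("list", spec$n_stems)
    i <- 1L
    while (i <= spec$n_stems) {
      diam <- if (s > 0) stats::rlnorm(1, meanlog, sdlog) else m
      radius <- max(diam / 2, spec$resolution_um_per_px)
      attempts <- 0L
      repeat {
        attempts <- attempts + 1L
        root <- c(runif(1, 0, spec$field_width_um),
                  runif(1, 0, spec$field_height_um))
        g <- grow_tree(spec, root, runif(1, 0, 2 * pi), radius)
        if (nrow(g$segments) == 0) next
        if (is.null(occupancy)) break
        # require clear separation so components map 1:1 to trees
        margin <- 2 * spec$resolution_um_per_px
        if (!tree_self_clear(g$segments, radius, margin)) {
          if (attempts > 500L)
            stopf("could not place %d non-overlapping trees", spec$n_stems)
          next
        }
        probe <- cpp_rasterize_tubes(
          cbind(g$segments, r = radius + margin),
          d[1], d[2], spec$resolution_um_per_px)
        if (!any(probe & occupancy)) {
          occupancy <- occupancy | probe
          break
        }
        if (attempts > 500L)
          stopf("could not place %d non-overlapping trees", spec$n_stems)
      }
      seg_len <- sqrt((g$segments[, 3] - g$segments[, 1])^2 +
                      (g$segments[, 4] - g$segments[, 2])^2)
      trees[[i]] <- list(
        id = i, radius_um = radius,
        perfused = runif(1) < spec$perfused_fraction,
        covered = runif(1) < spec$covered_fraction,
        zo1 = runif(1) < spec$zo1_fraction,
        segments = g$segments, n_junctions = g$n_junctions,
        length_um = sum(seg_len))
      i <- i + 1L
    }
    trees
  })
}

# Dart-throwing nucleus placement with a minimum center distance of
# 1.5 x radius, using a uniform grid hash for the neighbourhood test.
place_nuclei <- function(spec) {
  area_mm2 <- spec$field_width_um * spec$field_height_um / 1e6
  n <- round(spec$nuclei_density_per_mm2 * area_mm2)
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  mind <- 1.5 * spec$nucleus_radius_um
  cell <- mind
  ngx <- max(1L, ceiling(spec$field_width_um / cell))
  ngy <- max(1L, ceiling(spec$field_height_um / cell))
  grid <- vector("list", ngx * ngy)
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L; tries <- 0L; max_tries <- 60L * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    x <- runif(1, 0, spec$field_width_um)
    y <- runif(1, 0, spec$field_height_um)
    gx <- min(ngx, 1L + floor(x / cell)); gy <- min(ngy, 1L + floor(y / cell))
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) {
      cx <- gx + dx; cy <- gy + dy
      if (cx < 1 || cx > ngx || cy < 1 || cy > ngy) next
      for (k in grid[[(cx - 1L) * ngy + cy]]) {
        if ((xs[k] - x)^2 + (ys[k] - y)^2 < mind^2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
    idx <- (gx - 1L) * ngy + gy
    grid[[idx]] <- c(grid[[idx]], placed)
  }
  cbind(x = xs[seq_len(placed)], y = ys[seq_len(placed)])
}

#' Rasterize a synthetic scene
#'
#' Renders the vessel trees and a nucleus field into a calibrated
#' multi-channel 16-bit image plus its exact ground truth.  Channel
#' semantics: `CD31` = union of vessel tubes; `SMA`/`desmin` = pericyte
#' shell around covered vessels; `DAPI` = all nucleus disks;
#' `Ki67`/`TUNEL` = disks of drawn-positive nuclei; `EF5` = disks of nuclei
#' farther than `hypoxia_distance_um` from the nearest perfused vessel
#' surface; `ZO1` = junctional band inside ZO-1+ vessels; `Hoechst` =
#' perfused lumens with a diffusion halo; `dex10k`/`dex2M` = puncta inside
#' perfused lumens.  Clean (noise-free) masks are stored before rendering;
#' rendered channels are the clean masks scaled between `background_level`
#' and `foreground_level`, convolved with the Gaussian PSF, with additive
#' Gaussian noise, clamped to 0..65535 and rounded.
#'
#' @param trees result of [generate_vessel_network()].
#' @param spec the same `scene_spec`.
#' @return List with `image` (a [calibrated_image()]) and `gt` (a
#'   `ground_truth`: `trees`, `nuclei` data frame, `clean_masks`,
#'   `true_metrics`, `spec`).
#' @export
rasterize_scene <- function(trees, spec) {
  spec <- validate_scene_spec(spec)
  d <- scene_dims(spec); nr <- d[1]; nc <- d[2]
  res <- spec$resolution_um_per_px
  if (spec$field_width_um < 2 * spec$nucleus_radius_um ||
      spec$field_height_um < 2 * spec$nucleus_radius_um)
    stopf("field too small to contain one nucleus (radius %g um)",
          spec$nucleus_radius_um)

  all_segs <- do.call(rbind, lapply(trees, tree_segments))
  empty <- matrix(FALSE, nr, nc)
  rast <- function(sub) {
    if (is.null(sub) || nrow(sub) == 0) empty
    else cpp_rasterize_tubes(sub, nr, nc, res)
  }
  cd31 <- rast(all_segs)
  perf <- rast(do.call(rbind, lapply(Filter(function(t) t$perfused, trees),
                                     tree_segments)))
  covd <- rast(do.call(rbind, lapply(Filter(function(t) t$covered, trees),
                                     tree_segments)))
  zo1t <- rast(do.call(rbind, lapply(Filter(function(t) t$zo1, trees),
                                     tree_segments)))

  shell <- if (any(covd))
    dilate_um(covd, spec$pericyte_shell_um, res) & !cd31 else empty
  zo1 <- if (any(zo1t)) {
    inner <- cpp_edt(!cd31)$dist * res  # distance to the vessel boundary
    zo1t & inner <= spec$zo1_band_um
  } else empty
  hoechst <- if (any(perf)) dilate_um(perf, spec$hoechst_halo_um, res)
             else empty

  d_perf <- if (any(perf)) cpp_edt(perf)$dist * res else
    matrix(Inf, nr, nc)

  second_seed <- (spec$seed + 500009L) %% .Machine$integer.max
  gt_nuclei <- NULL; clean <- NULL
  with_seed(second_seed, {
    pts <- place_nuclei(spec)
    nnuc <- nrow(pts)
    mf <- spec$marker_fractions
    ki67 <- runif(nnuc) < (mf[["ki67"]] %||% 0)
    tunel <- runif(nnuc) < (mf[["tunel"]] %||% 0)
    # nucleus center pixel -> distance to the nearest perfused vessel surface
    ii <- pmin(nr, pmax(1L, ceiling(pts[, "y"] / res)))
    jj <- pmin(nc, pmax(1L, ceiling(pts[, "x"] / res)))
    dvals <- d_perf[cbind(ii, jj)]
    ef5 <- dvals > spec$hypoxia_distance_um
    disks <- function(keep) {
      if (!any(keep)) return(empty)
      cpp_rasterize_disks(cbind(pts[keep, "x"], pts[keep, "y"],
                                spec$nucleus_radius_um), nr, nc, res)
    }
    dapi <- disks(rep(TRUE, nnuc))
    puncta <- function(density) {
      lum <- which(perf)
      if (length(lum) == 0 || density <= 0) return(empty)
      lumen_mm2 <- length(lum) * res^2 / 1e6
      np <- round(density * lumen_mm2)
      if (np == 0) return(empty)
      sel <- sample(lum, np, replace = TRUE)
      cx <- ((sel - 1) %/% nr + 0.5) * res
      cy <- ((sel - 1) %% nr + 0.5) * res
      cpp_rasterize_disks(cbind(cx, cy, spec$puncta_radius_um), nr, nc, res)
    }
    clean <- list(
      DAPI = dapi, CD31 = cd31, Ki67 = disks(ki67), TUNEL = disks(tunel),
      EF5 = disks(ef5), SMA = shell, desmin = shell, ZO1 = zo1,
      Hoechst = hoechst,
      dex10k = puncta(spec$puncta_per_mm2_lumen[["dex10k"]] %||% 0),
      dex2M = puncta(spec$puncta_per_mm2_lumen[["dex2m"]] %||% 0))
    gt_nuclei <- data.frame(x_um = pts[, "x"], y_um = pts[, "y"],
                             ki67 = ki67, tunel = tunel, ef5 = ef5,
                             dist_perfused_um = dvals)
    # render under the same derived seed, after all placement draws
    px <- array(0L, c(nr, nc, length(clean)))
    bg <- spec$background_level; fg <- spec$foreground_level
    for (k in seq_along(clean)) {
      ch <- bg + (fg - bg) * clean[[k]]
      if (spec$psf_sigma_um > 0)
        ch <- cpp_gauss_blur(ch, spec$psf_sigma_um / res)
      if (spec$noise_sd > 0)
        ch <- ch + rnorm(length(ch), 0, spec$noise_sd)
      px[, , k] <- as.integer(round(pmin(65535, pmax(0, ch))))
    }
    img <- calibrated_image(px, names(clean), res)
  })
  gt <- structure(list(trees = trees, nuclei = gt_nuclei,
                       clean_masks = clean, spec = spec,
                       resolution_um_per_px = res),
                  class = "ground_truth")
  gt$true_metrics <- true_metrics(gt, spec)
  list(image = img, gt = gt)
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper: [generate_vessel_network()] followed by
#' [rasterize_scene()].
#'
#' @inheritParams generate_vessel_network
#' @return See [rasterize_scene()].
#' @export
generate_scene <- function(spec) {
  rasterize_scene(generate_vessel_network(spec), spec)
}

#' Exact metrics of a synthetic scene
#'
#' Computes every recovery target from the clean masks and the vessel graph
#' (never from rendered pixels): microvessel density over the true total
#' tissue region, covered-vessel frequency from the flags, per-marker area
#' fractions, junction count and total centerline length, plus the true
#' EF5+ nucleus fraction.
#'
#' @param gt a `ground_truth` from [rasterize_scene()].
#' @param spec the `scene_spec` (defaults to the one stored in `gt`).
#' @return List with `index` (named true index values) and `network`
#'   (junction count, centerline length, length-weighted mean diameter,
#'   component count).
#' @export
true_metrics <- function(gt, spec = gt$spec) {
  res <- gt$resolution_um_per_px
  cm <- gt$clean_masks
  tt <- dilate_um(cm$DAPI, 10, res)
  tt_area <- sum(tt) * res^2
  if (tt_area == 0) stopf("ground truth has no tissue (empty DAPI mask)")
  lab <- cpp_label(cm$CD31, 8L)
  ncomp <- attr(lab, "n")
  vs_area <- sum(cm$CD31) * res^2
  pvs <- dilate_um(cm$CD31, 5, res) & !cm$CD31
  frac_tt <- function(m) sum(m & tt) / sum(tt)
  covered <- vapply(gt$trees, function(t) t$covered, logical(1))
  lens <- vapply(gt$trees, function(t) t$length_um, numeric(1))
  diams <- vapply(gt$trees, function(t) 2 * t$radius_um, numeric(1))
  idx <- list(
    ki67_index = frac_tt(cm$Ki67),
    tunel_index = frac_tt(cm$TUNEL),
    ef5_index = frac_tt(cm$EF5),
    hoechst_surface = frac_tt(cm$Hoechst),
    dextran10k_surface = frac_tt(cm$dex10k),
    dextran2M_surface = frac_tt(cm$dex2M),
    zo1_endothelial_index = if (vs_area > 0)
      sum(cm$ZO1 & cm$CD31) / sum(cm$CD31) else NA_real_,
    sma_perivascular_index = if (vs_area > 0)
      sum(cm$SMA & pvs) / sum(cm$CD31) else NA_real_,
    desmin_perivascular_index = if (vs_area > 0)
      sum(cm$desmin & pvs) / sum(cm$CD31) else NA_real_,
    covered_vessel_frequency = 100 * mean(covered),
    mvd_per_mm2 = ncomp / (tt_area / 1e6),
    ef5_nucleus_fraction = mean(gt$nuclei$ef5),
    tt_area_mm2 = tt_area / 1e6)
  net <- list(
    n_components = ncomp,
    junction_count = sum(vapply(gt$trees, function(t) t$n_junctions,
                                integer(1))),
    total_centerline_um = sum(lens),
    mean_diameter_um = if (sum(lens) > 0)
      sum(lens * diams) / sum(lens) else NA_real_)
  list(index = idx, network = net)
}
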