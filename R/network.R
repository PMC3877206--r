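# Object-based vessel metrics: connected-component labelling, microvessel
# density, medial-axis skeletonization with a branch graph, and intensity
# cross-sections.  Thick stacks are reduced by maximum-intensity projection
# before segmentation; all skeleton analysis here is 2D.

#' Label vessel objects
#'
#' Connected components of VS under 8-connectivity, size-filtered.
#'
#' @param vs the vascular [binary_mask()].
#' @param min_object_area_um2 drop components below this area.
#' @param resolution pixel size in um.
#' @return Object of class `vessel_objects`: `labels` (integer matrix,
#'   labels dense 1..N), `table` (per-object area um^2, equivalent diameter
#'   um, centroid px).
#' @export
label_vessels <- function(vs, min_object_area_um2 = 0, resolution = NULL) {
  res <- mask_res(vs, resolution)
  px <- filter_small_objects(mask_px(vs), min_object_area_um2, res)
  lab <- cpp_label(px, 8L)
  n <- attr(lab, "n")
  # relabel densely after the size filter
  if (n > 0) {
    ids <- sort(unique(lab[lab > 0L]))
    lab[lab > 0L] <- match(lab[lab > 0L], ids)
    n <- length(ids)
  }
  tab <- if (n > 0) {
    areas <- tabulate(lab[lab > 0L], nbins = n) * res^2
    rows <- row(lab)[lab > 0L]; cols <- col(lab)[lab > 0L]
    labs <- lab[lab > 0L]
    data.frame(
      label = seq_len(n),
      area_um2 = areas,
      equiv_diameter_um = 2 * sqrt(areas / pi),
      centroid_row = as.numeric(tapply(rows, labs, mean)),
      centroid_col = as.numeric(tapply(cols, labs, mean)))
  } else {
    data.frame(label = integer(0), area_um2 = numeric(0),
               equiv_diameter_um = numeric(0), centroid_row = numeric(0),
               centroid_col = numeric(0))
  }
  structure(list(labels = lab, table = tab, n = n,
                 resolution_um_per_px = res),
            class = "vessel_objects")
}

#' Microvessel density
#'
#' Number of vessel objects per mm^2 of tissue (TT area).
#'
#' @param objects a [label_vessels()] result (or an object count).
#' @param tissue_area_mm2 TT area in mm^2 (> 0).
#' @return Vessels per mm^2.
#' @export
microvessel_density <- function(objects, tissue_area_mm2) {
  n <- if (inherits(objects, "vessel_objects")) objects$n else objects
  check_scalar(tissue_area_mm2, "tissue_area_mm2", lower = 1e-12)
  n / tissue_area_mm2
}

#' Skeletonize the vascular ROI and build its branch graph
#'
#' Topology-preserving thinning to the medial axis, followed by graph
#' construction: nodes are junction-pixel clusters (>= 3 skeleton
#' neighbours) and endpoints (1 neighbour); edges are the degree-2 chains
#' between them, with path lengths from voxel-step geometry (1 or sqrt(2)
#' pixel steps, in um).  Spur branches (junction-to-endpoint) shorter than
#' `prune_um` are removed and the graph rebuilt, since thinning a rasterized
#' tube sheds sub-diameter spurs that are not anatomy; junction clusters
#' connected by chains shorter than `merge_um` are counted as one junction
#' (thinning occasionally splits one anatomical branch point in two).
#'
#' @param vs the vascular [binary_mask()] (2D; thick stacks should be
#'   projected first, see [segment_channel()] on a projected image).
#' @param resolution pixel size in um.
#' @param prune_um spur-pruning threshold; default 10 um, of the order of
#'   one vessel diameter.
#' @param merge_um junction-merging threshold; default 3 px.
#' @return Object of class `vessel_skeleton`: `skeleton` (logical matrix),
#'   `edges` (data frame: from, to, length_um, chord_um, kind), `nodes`
#'   (data frame: id, type, row, col), `n_junctions`, `n_endpoints`,
#'   `length_um` (total skeleton length).
#' @export
skeletonize_vs <- function(vs, resolution = NULL, prune_um = 10,
                           merge_um = NULL) {
  res <- mask_res(vs, resolution)
  if (is.null(merge_um)) merge_um <- 3 * res
  px <- mask_px(vs)
  sk <- cpp_thin(px)
  g <- skeleton_graph(sk, res, merge_um)
  # prune spurs, then rebuild (up to a few passes: removing a spur can turn
  # a junction into a plain path and merge its two other branches)
  for (pass in 1:4) {
    if (nrow(g$edges) == 0) break
    spur <- g$edges$kind == "spur" & g$edges$length_um < prune_um
    if (!any(spur)) break
    drop_px <- unlist(g$edge_pixels[spur])
    sk[drop_px] <- FALSE
    g <- skeleton_graph(sk, res, merge_um)
  }
  structure(list(skeleton = sk, edges = g$edges, nodes = g$nodes,
                 n_junctions = g$n_junctions, n_endpoints = g$n_endpoints,
                 length_um = g$length_um, resolution_um_per_px = res),
            class = "vessel_skeleton")
}

# Build the branch graph of a 1-px skeleton.  Chains are the connected
# components of non-junction skeleton pixels; each chain is walked from one
# of its tips to order the pixels and measure its path length.
skeleton_graph <- function(sk, res, merge_um) {
  nr <- nrow(sk); nc <- ncol(sk)
  empty_nodes <- data.frame(id = integer(0), type = character(0),
                            row = numeric(0), col = numeric(0))
  empty_edges <- data.frame(from = integer(0), to = integer(0),
                            length_um = numeric(0), chord_um = numeric(0),
                            kind = character(0))
  if (!any(sk))
    return(list(nodes = empty_nodes, edges = empty_edges, n_junctions = 0L,
                n_endpoints = 0L, length_um = 0, edge_pixels = list()))
  nb <- cpp_neighbor_count(sk)
  junc <- sk & nb >= 3L
  jlab <- cpp_label(junc, 8L)
  njc <- attr(jlab, "n")
  chains <- cpp_label(sk & !junc, 8L)
  nch <- attr(chains, "n")

  # total skeleton length: sum over adjacent skeleton-pixel pairs
  total_len <- skeleton_length_px(sk) * res

  # chain bookkeeping
  idx <- which(chains > 0L)
  ch_of <- chains[idx]
  ords <- split(idx, ch_of)

  offs <- c(-1 - nr, -1, -1 + nr, -nr, nr, nr - 1, 1, 1 + nr)
  neighbors8 <- function(i) {
    r <- (i - 1L) %% nr + 1L; cl <- (i - 1L) %/% nr + 1L
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- cl + dc
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc)
        out <- c(out, rr + (cc - 1L) * nr)
    }
    out
  }
  step_len <- function(a, b) {
    ra <- (a - 1L) %% nr; ca <- (a - 1L) %/% nr
    rb <- (b - 1L) %% nr; cb <- (b - 1L) %/% nr
    if (ra != rb && ca != cb) sqrt(2) else 1
  }

  edges <- list(); edge_px <- list()
  for (ci in seq_along(ords)) {
    pix <- ords[[ci]]
    # order the chain by walking from a tip (pixel with <= 1 chain neighbour)
    if (length(pix) == 1L) {
      path <- pix
    } else {
      inset <- logical(nr * nc); inset[pix] <- TRUE
      deg <- vapply(pix, function(i) sum(inset[neighbors8(i)]), integer(1))
      start <- pix[which(deg <= 1L)[1]]
      if (is.na(start)) start <- pix[1]  # pure cycle
      path <- integer(length(pix)); path[1] <- start
      visited <- logical(nr * nc); visited[start] <- TRUE
      for (k in seq_len(length(pix) - 1L)) {
        nbrs <- neighbors8(path[k])
        nxt <- nbrs[inset[nbrs] & !visited[nbrs]]
        if (length(nxt) == 0L) { path <- path[1:k]; break }
        # prefer 4-connected continuation for a stable walk
        nxt <- nxt[order(vapply(nxt, function(b) step_len(path[k], b),
                                numeric(1)))][1]
        path[k + 1L] <- nxt
        visited[nxt] <- TRUE
      }
    }
    plen <- 0
    if (length(path) > 1L)
      for (k in seq_len(length(path) - 1L))
        plen <- plen + step_len(path[k], path[k + 1L])
    # junction clusters adjacent to either end of the chain
    ends <- c(path[1], path[length(path)])
    jends <- lapply(ends, function(e) {
      nbrs <- neighbors8(e)
      unique(jlab[nbrs][jlab[nbrs] > 0L])
    })
    # attach: each end connects to at most one junction cluster step
    att <- integer(0); extra <- 0
    for (side in 1:2) {
      js <- jends[[side]]
      if (length(js) > 0) {
        att <- c(att, js[1])
        extra <- extra + 1  # one connecting step (approximate as 1 px)
      }
    }
    from <- if (length(att) >= 1) att[1] else NA_integer_
    to <- if (length(att) >= 2) att[2] else NA_integer_
    kind <- if (length(att) == 2) "branch"
            else if (length(att) == 1) "spur" else "free"
    # chord between the two ends of the full branch
    e1 <- ends[1]; e2 <- ends[2]
    chord <- sqrt(((e1 - 1) %% nr - (e2 - 1) %% nr)^2 +
                  ((e1 - 1) %/% nr - (e2 - 1) %/% nr)^2)
    edges[[length(edges) + 1]] <- data.frame(
      from = from, to = to, length_um = (plen + extra) * res,
      chord_um = chord * res, kind = kind)
    edge_px[[length(edge_px) + 1]] <- path
  }
  edges <- if (length(edges)) do.call(rbind, edges) else empty_edges

  # junction merging: clusters connected by a short branch count once
  n_junctions <- njc
  if (njc > 0 && nrow(edges) > 0) {
    parent <- seq_len(njc)
    findp <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    short <- which(edges$kind == "branch" & edges$length_um < merge_um &
                   edges$from != edges$to)
    for (e in short) {
      ra <- findp(edges$from[e]); rb <- findp(edges$to[e])
      if (ra != rb) parent[ra] <- rb
    }
    n_junctions <- length(unique(vapply(seq_len(njc), findp, integer(1))))
  }

  endpoints <- sk & nb == 1L
  nodes <- data.frame(id = seq_len(njc), type = rep("junction", njc),
                      row = as.numeric(tapply(row(jlab)[jlab > 0],
                                              jlab[jlab > 0], mean))[seq_len(njc)] %||% numeric(0),
                      col = as.numeric(tapply(col(jlab)[jlab > 0],
                                              jlab[jlab > 0], mean))[seq_len(njc)] %||% numeric(0))
  list(nodes = nodes, edges = edges, n_junctions = n_junctions,
       n_endpoints = sum(endpoints), length_um = total_len,
       edge_pixels = edge_px)
}

# Skeleton length in pixel units: each adjacent pair of skeleton pixels
# contributes one step of 1 (4-neighbour) or sqrt(2) (diagonal), except
# that diagonal steps shortcutting an existing 4-connected path are not
# counted twice; the standard estimator sums unique adjacencies.
skeleton_length_px <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  horiz <- sum(sk & shift(sk, 0, 1))
  vert <- sum(sk & shift(sk, 1, 0))
  d1 <- sk & shift(sk, 1, 1)
  d2 <- sk & shift(sk, 1, -1)
  # drop diagonal adjacencies that parallel an axial 2-step path
  diag_cnt <- sum(d1) + sum(d2)
  horiz + vert + sqrt(2) * diag_cnt
}

#' Vessel network metrics
#'
#' * `branch_per_mm`: junction count divided by total skeleton length (mm).
#'   The denominator choice is intrinsic to the network; a per-mm^2-tissue
#'   variant is available via `per_tissue = TRUE`.
#' * `mean_diameter_um`: mean over skeleton pixels of twice the distance to
#'   the VS boundary (medial-axis width).
#' * `tortuosity`: mean over junction-to-junction/endpoint branches of path
#'   length over chord length (optional; reported but excluded from
#'   recovery guarantees).
#'
#' @param skel a [skeletonize_vs()] result.
#' @param vs the VS mask the skeleton came from.
#' @param objects optional [label_vessels()] result (for MVD).
#' @param tissue_area_mm2 optional TT area (for MVD).
#' @param per_tissue if TRUE, `branch_per_mm` uses mm^2 of tissue as the
#'   denominator instead of skeleton length.
#' @return Object of class `network_metrics`: `mvd_per_mm2` (NA unless
#'   `objects` and `tissue_area_mm2` given), `branch_per_mm`,
#'   `skeleton_length_mm`, `mean_diameter_um`, `tortuosity`,
#'   `n_junctions`, `n_endpoints`.
#' @export
network_metrics <- function(skel, vs, objects = NULL,
                            tissue_area_mm2 = NULL, per_tissue = FALSE) {
  stopifnot(inherits(skel, "vessel_skeleton"))
  res <- skel$resolution_um_per_px
  if (skel$length_um <= 0) stopf("zero skeleton length")
  px <- mask_px(vs)
  inner <- cpp_edt(!px)$dist * res
  diam <- 2 * mean(inner[skel$skeleton])
  denom <- if (per_tissue) {
    check_scalar(tissue_area_mm2, "tissue_area_mm2", lower = 1e-12)
    tissue_area_mm2
  } else skel$length_um / 1000
  branches <- skel$edges[skel$edges$kind %in% c("branch", "free") &
                         skel$edges$chord_um > 0, , drop = FALSE]
  tort <- if (nrow(branches) > 0)
    mean(branches$length_um / branches$chord_um) else NA_real_
  mvd <- if (!is.null(objects) && !is.null(tissue_area_mm2))
    microvessel_density(objects, tissue_area_mm2) else NA_real_
  structure(list(mvd_per_mm2 = mvd,
                 branch_per_mm = skel$n_junctions / denom,
                 skeleton_length_mm = skel$length_um / 1000,
                 mean_diameter_um = diam, tortuosity = tort,
                 n_junctions = skel$n_junctions,
                 n_endpoints = skel$n_endpoints),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<network_metrics> MVD %.1f /mm^2 | %.2f branch/mm | skeleton %.2f mm",
    " | diameter %.1f um | tortuosity %.2f\n"),
    x$mvd_per_mm2, x$branch_per_mm, x$skeleton_length_mm,
    x$mean_diameter_um, x$tortuosity))
  invisible(x)
}

#' Intensity profile along a cross-section
#'
#' Samples the named channels along the segment from `p0` to `p1` (um
#' coordinates) at 1-px spacing with bilinear interpolation.  With
#' `eight_bit = TRUE` each channel is min-max rescaled to 0..255,
#' reproducing the display convention of pseudocolor histogram panels;
#' such values are explicitly non-quantitative.
#'
#' @param image a [calibrated_image()].
#' @param p0,p1 numeric `c(x, y)` endpoints in um; must lie inside the
#'   field.
#' @param channels channel names to sample (default: all).
#' @param eight_bit rescale each channel to 8-bit for display.
#' @return Data frame: `distance_um` plus one column per channel.
#' @export
cross_section_profile <- function(image, p0, p1, channels = NULL,
                                  eight_bit = FALSE) {
  stopifnot(inherits(image, "calibrated_image"))
  res <- image$resolution_um_per_px
  d <- dim(image$pixels)
  W <- d[2] * res; H <- d[1] * res
  for (p in list(p0, p1))
    if (p[1] < 0 || p[1] > W || p[2] < 0 || p[2] > H)
      stopf("cross-section endpoint (%g, %g) outside the %g x %g um field",
            p[1], p[2], W, H)
  channels <- channels %||% image$channels
  len_px <- sqrt(sum((p1 - p0)^2)) / res
  n <- max(2L, ceiling(len_px) + 1L)
  t <- seq(0, 1, length.out = n)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  # continuous pixel coordinates (pixel centers at (k - 0.5) * res)
  cx <- xs / res + 0.5; cy <- ys / res + 0.5
  out <- data.frame(distance_um = t * sqrt(sum((p1 - p0)^2)))
  for (ch in channels) {
    m <- get_channel(image, ch)
    x0 <- pmin(pmax(floor(cx - 1), 0), d[2] - 1)
    y0 <- pmin(pmax(floor(cy - 1), 0), d[1] - 1)
    fx <- pmin(pmax(cx - 1 - x0, 0), 1)
    fy <- pmin(pmax(cy - 1 - y0, 0), 1)
    x1 <- pmin(x0 + 1, d[2] - 1)
    y1 <- pmin(y0 + 1, d[1] - 1)
    v <- (1 - fx) * (1 - fy) * m[cbind(y0 + 1, x0 + 1)] +
         fx * (1 - fy) * m[cbind(y0 + 1, x1 + 1)] +
         (1 - fx) * fy * m[cbind(y1 + 1, x0 + 1)] +
         fx * fy * m[cbind(y1 + 1, x1 + 1)]
    if (eight_bit) {
      rng <- range(m)
      v <- if (rng[2] > rng[1])
        round(255 * (v - rng[1]) / (rng[2] - rng[1])) else rep(0, length(v))
    }
    out[[ch]] <- v
  }
  out
}

#' Maximum-intensity projection of a thin stack
#'
#' Reduces a list of per-slice matrices (or a 3D array) to one 2D matrix.
#' True 3D skeletonization is out of scope; thick-stack analyses run on
#' the projection, which is adequate for thin (<= ~100 um, flattened)
#' sections.
#'
#' @param slices list of matrices or a 3D array `[row, col, z]`.
#' @return Numeric matrix.
#' @export
max_project <- function(slices) {
  if (is.array(slices) && length(dim(slices)) == 3)
    slices <- lapply(seq_len(dim(slices)[3]), function(k) slices[, , k])
  Reduce(pmax, slices)
}
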