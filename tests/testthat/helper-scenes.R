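# Shared fixtures, built in code at test time.

# A small, fast scene spec; noise-free by default so segmentation is exact.
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(field_width_um = 300, field_height_um = 300, n_stems = 5,
         nuclei_density_per_mm2 = 2000, noise_sd = 0, psf_sigma_um = 0,
         seed = seed),
    list(...))
  do.call(scene_spec, args)
}

# Disk mask of radius r_um centered at (cx, cy) um on an n x n grid.
disk_mask <- function(n, cx, cy, r_um, res = 1, marker = "disk") {
  px <- vascquant:::cpp_rasterize_disks(cbind(cx, cy, r_um), n, n, res)
  binary_mask(px, res, marker = marker)
}

# Rectangular block mask on an n x n grid (1-based pixel index ranges).
rect_mask <- function(n, rows, cols, res = 1, marker = "rect") {
  px <- matrix(FALSE, n, n)
  px[rows, cols] <- TRUE
  binary_mask(px, res, marker = marker)
}

# Horizontal tube (capsule) mask.
tube_mask <- function(nr, nc, x0, y0, x1, y1, r_um, res = 1, marker = "tube") {
  px <- vascquant:::cpp_rasterize_tubes(matrix(c(x0, y0, x1, y1, r_um), 1),
                                        nr, nc, res)
  binary_mask(px, res, marker = marker)
}

dice_coef <- function(a, b) {
  pa <- if (inherits(a, "binary_mask")) a$px else a
  pb <- if (inherits(b, "binary_mask")) b$px else b
  2 * sum(pa & pb) / (sum(pa) + sum(pb))
}
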