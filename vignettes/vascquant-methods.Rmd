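---
title: "Quantifying tumor vasculature: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor vasculature: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vascquant` quantifies the tumor vascular microenvironment from calibrated
multi-channel immunofluorescence images. This vignette is the package's
account of its science: the measurement model, the parameters that matter,
what the synthetic-scene generator does and does not emulate, the numerical
choices, and the known limitations. It states no empirical result that the
test suite does not itself compute.

## 1. Measurement model

### Conventions

All rasters are `[row, col]` matrices; the pixel in row *i*, column *j*
has its center at `((j − 0.5)·res, (i − 0.5)·res)` µm, where `res` is the
isotropic in-plane pixel size. Areas are pixel counts × `res²`; every
physical quantity in the API is in µm, µm² or mm² as named — pixel units
never escape to output tables. Physical dilations threshold the exact
Euclidean distance transform (EDT) at the radius, which is
rotation-consistent and matches the "enlarge selection" semantics of
interactive ROI tools, rather than iterating discrete structuring
elements.

### Segmentation

A pixel of a marker channel is positive when

* intensity ≥ `ratio_k` × local background, **and**
* intensity ≥ `negcontrol_floor`,

and its connected component (8-connectivity) has area ≥
`min_object_area_um2`. The local background is the median over a disk of
`background_radius_um` (default 50 µm) — robust to bright foreground and
clamped at 1 so ratios are always defined. The floor is the 99.9th
percentile of a negative-control channel (`negcontrol_floor_from()`);
with Gaussian sensor noise this keeps ~0.1 % of control pixels above the
floor, and those survive only as sub-`min_object_area` specks. The
original methodology states the ratio-to-background-and-control rule but
none of its numeric values, so `ratio_k = 2`, 50 µm, and 10 µm² are
explicit configuration defaults of this package, not reproductions; the
mask provenance records the values used. Raising `ratio_k` or the floor
can only shrink a mask (tested as a set-inclusion property).

### Regions of interest

* `TT` (total tissue): DAPI⁺ pixels (minus any operator-supplied exclusion
  mask) dilated by 10 µm, minus the exclusion again — so luminal/acellular
  space is excluded and no excluded pixel ever contributes to any index.
* `VS` (vascular): the segmented CD31⁺ area, size-filtered.
* `PVS` (perivascular): the 5 µm band lining VS (`dilate(VS, 5) \ VS`);
  disjoint from VS by construction.

Manual cropping of non-tumor structures is supported only as an exclusion
mask prepared externally; the package never auto-detects tissue type,
because that step was manual in the original workflow.

### Indices

Surface indices divide a marker's area inside a region by a region area:
Ki-67, TUNEL, EF5 and the perfusion markers over `TT`; endothelial ZO-1
and TUNEL over `VS`; perivascular SMA and desmin use
`area(marker ∩ PVS) / area(VS)` — the denominator is deliberately the
vessel area, not the shell area, so a fully stained shell around a disk
vessel of radius 10 µm evaluates to (15² − 10²)/10² = 1.25. A zero
denominator is an explicit error, never a silent zero.

The covered-vessel frequency is object-based: vessels are the
8-connected components of VS; each PVS pixel is assigned to its *nearest*
vessel via the EDT feature transform (adjacent vessels never share shell
pixels); a vessel is covered when the desmin⁺∩SMA⁺ fraction of its own
shell reaches `coverage_threshold`. The original study never defines
"covered", so the threshold (default 0.10) is a free, recorded parameter.

### Distance profile

Distances are measured from the VS region itself (border-inclusive);
pixels inside VS — endothelial nuclei — land in bin 0. Bins are
`(k·gap, (k+1)·gap]` with `gap = 5` µm, bin 0 additionally holding
distance 0; this matches the iterative-enlargement construction in which
each enlarged selection includes its boundary. The profile mass is DAPI⁺
*surface* inside TT (not nucleus count); raw bins sum to exactly 100 %.
The summary scalar is the mass at ≥ 100 µm, the conventional threshold
for the chronically hypoxic zone. Smoothing (3-bin centered moving
average) exists for display only; raw bins feed all summaries. The
profile is truncated at 300 µm with one overflow bin.

### Vessel network

The VS mask is thinned to its medial axis with the Guo-Hall
two-subiteration algorithm. Zhang-Suen was evaluated first and rejected:
it leaves 2-px diagonal staircases in which a third of skeleton pixels
classify as junctions, which destroys branch counting. The skeleton graph
takes junction-pixel clusters (≥ 3 neighbours) and endpoints (1
neighbour) as nodes and degree-2 chains as edges, with path lengths from
voxel-step geometry (1 or √2 px). Two cleanups reflect raster reality:
spur branches shorter than `prune_um` (default 10 µm, one vessel
diameter; thinning a rasterized tube sheds sub-diameter spurs that are
not anatomy) are removed and the graph rebuilt; junction clusters joined
by chains shorter than 3 px are counted as one junction (thinning
occasionally splits one anatomical branch point).

Metrics: `branch_per_mm` = junctions / skeleton length (mm) — the
denominator of the conventional "branch/mm" is ambiguous, and skeleton
length was chosen because it is intrinsic to the network (a per-mm² of
tissue variant is a flag); `mean_diameter_um` = mean over skeleton pixels
of 2 × EDT to the VS boundary (medial-axis width; exact for even-width
tubes, up to +1 px for odd widths — within the ±2·resolution recovery
tolerance); `tortuosity` = mean branch path/chord ratio, reported but
excluded from recovery guarantees because no reference method exists for
it. Thick stacks are reduced by maximum-intensity projection before
segmentation; true 3D thinning is out of scope (thin, flattened sections
are the intended input).

### Statistics

Two-group comparisons use the two-tailed Mann-Whitney test — exact when
n_A + n_B ≤ 20 without ties (delegated to `stats::wilcox.test`; an
independent enumeration oracle `mw_exact_p()` is part of the package and
its tests), asymptotic with midranks and continuity correction otherwise.
When every value is identical the test is degenerate and p = 1 by
convention. Three or more groups: tie-corrected Kruskal-Wallis followed
by pairwise Dunn z-tests on the pooled midranks with Bonferroni
family-wise adjustment — the classical "Dunn's post test" as implemented
by common statistics software, whose exact multiplicity rule the source
methodology does not state. Stars: \*, \*\*, \*\*\* at 0.05, 0.01, 0.001.

Note on calibration: the exact test is discrete. At n = 7 per group its
attainable size at α = 0.05 is exactly 0.0379 (rejection region U ≤ 8),
so simulated null rejection rates settle near 0.038, not 0.05 — the test
suite asserts agreement with the analytic size.

## 2. The synthetic-scene generator

The generator is a forward model of the stained section, not of tumor
biology. Defaults state a tumor-like world:

| parameter | default | meaning |
|---|---|---|
| `n_stems` | 50 per (1 mm)² field | microvessel density ≈ 50/mm² (tumor-like; normal prostate-like fields would use ≈ 166) |
| `mean_diameter_um`, `diameter_sd_um` | 9.5, 2 | lognormal vessel diameter |
| `branch_prob`, `step_um` | 0.045, 5 | ≈ 9 branch points per mm of centerline |
| `max_tree_length_um` | 75 | root-to-leaf budget; keeps CD31 area fraction at a tumor-plausible few % |
| `perfused_fraction` | 0.7 | not all tumor vessels are perfused |
| `covered_fraction` | 0.2 | untreated-like pericyte coverage (≈ 20 %) |
| `hypoxia_distance_um` | 100 | EF5⁺ beyond this distance from a perfused vessel surface |
| `nuclei_density_per_mm2`, `nucleus_radius_um` | 3000, 3 | nucleus field, dart-thrown with min spacing 1.5 × radius |
| `marker_fractions` | ki67 0.30, tunel 0.05 | per-nucleus Bernoulli labels |
| `pericyte_shell_um` | 3 | below the 5 µm PVS so the perivascular index is exercised under saturation |
| `psf_sigma_um`, `noise_sd` | 0.5, 950 | Gaussian PSF; additive noise at SNR ≈ 10 for the 9500-count signal |
| `puncta_per_mm2_lumen` | dex10k 60000, dex2m 30000 | free parameters — no generative value exists in the source |

Vessels grow as persistent random walks (angular sd 0.15 rad per 5 µm
step) and branch at 60–90° to the parent. Three growth constraints exist
so that the *ground truth is well-posed on a raster*, decided before the
recovery tests were run: (i) a child branch is realized only if it
extends beyond max(5 × radius, 3 steps) from the branch point — a stub
buried inside the parent tube is not a resolvable branch; (ii) branch
events on one tip are at least 3 steps apart — two branch points within
one tube diameter fuse into a single medial-axis junction; (iii) in
`allow_overlap = FALSE` mode, a tree is rejected when any two
distant-in-tree centerline points come within 2 × radius + margin of each
other, and whole trees are rejected when their tubes would touch another
tree's — making component counts and junction counts exactly recoverable.
With overlap allowed (the default, realistic case), tree crossings create
genuine raster junctions and merged components; the ground truth then
reports the component count of the rasterized union, so density recovery
remains well-posed while junction counts are only meaningful per
isolated network.

Hypoxia is a hard distance threshold (no oxygen-diffusion PDE, by
design): a nucleus is EF5⁺ iff its center is farther than
`hypoxia_distance_um` from the nearest perfused vessel pixel. Rendering:
clean mask → scaled to `background_level`/`foreground_level` → Gaussian
PSF → additive Gaussian noise → clamp to 16 bits. Every random draw
derives from `spec$seed`; identical spec + seed gives bit-identical
scenes.

**What a green test establishes — and what it does not.** The generator
emulates the *statistical structure the analysis assumes*: tubular
CD31 geometry, disk nuclei, flat background, stationary Gaussian noise.
Real sections add uneven illumination, autofluorescence, staining
gradients, touching nuclei, partial-volume effects and genuine 3D
structure. Recovery of generator parameters therefore validates the
measurement code, not the biology; parameters tuned on synthetic scenes
(especially `ratio_k` and the negative-control percentile) must be
re-examined on real control slides.

## 3. Numerical choices

* **EDT**: exact two-pass lower-envelope algorithm, with the
  nearest-feature map used for per-vessel shell assignment. An
  independent brute-force nearest-neighbour engine exists solely as its
  test oracle.
* **Iterative-enlargement oracle**: the successive 5 µm selections are
  iterated as *continuous* regions (the radius grows by `gap` each step)
  and each selection is rasterized with the brute-force engine. Iterating
  *rasterized* dilations instead would re-measure from pixel centers of
  the previous raster each step; the sub-pixel deficit accumulates across
  ~60 enlargements into bin shifts of up to a percentage point, so exact
  dual-route agreement is only available — and is demanded by the tests —
  under the continuous-selection reading, which is also how interactive
  ROI tools behave.
* **Background median**: Huang sliding-histogram disk median on the
  16-bit range, with edge replication; O(r) per pixel.
* **Degenerate inputs**: empty VS → distance profile and network metrics
  are errors/NA, never silent zeros; empty denominator regions are
  errors; empty masks round-trip through I/O unchanged.
* **Determinism**: per-scene seeds derive arithmetically from the global
  seed (kept below 2³¹); per-image analyses are independent, so
  processing order can never affect results.

## 4. Known limitations

* 2D analysis only; thick stacks are max-projected, which overestimates
  apparent vessel area and can merge crossing vessels.
* The TIFF codec reads exactly the package's own dialect (little-endian,
  uncompressed, 16-bit grayscale, one strip per page) and refuses
  anything else; microscope-native formats must be converted upstream.
* `branch_per_mm` on noisy masks is an upper bound: boundary roughness
  survives spur pruning occasionally.
* Tortuosity has no recovery guarantee.
* Configs are JSON (YAML is not supported in this build).
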