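# vascquant

Quantification of the tumor vascular microenvironment in calibrated
multi-channel immunofluorescence images, with a synthetic-scene generator
that provides exact ground truth for validation.

## The scientific problem

Solid-tumor vasculature is structurally abnormal — sparse microvessels,
missing pericyte coverage, immature endothelial junctions — and the
resulting hypoxia is a major radioresistance factor. Studies of vascular
remodeling under treatment quantify this from stained tissue sections:
endothelium (CD31), proliferation (Ki-67), cell death (TUNEL), severe
hypoxia (EF5), perfusion (Hoechst 33342 and fluorescent dextrans),
junctional maturity (ZO-1) and mural cells (α-SMA, desmin). `vascquant`
implements that image-analysis layer as tested, reusable code:

* **Segmentation** — a pixel is positive when its intensity is at least
  `ratio_k` times the local background (disk-median over
  `background_radius_um`) *and* above a negative-control floor; components
  below `min_object_area_um2` are discarded.
* **Regions of interest** — total tissue `TT` (DAPI⁺ dilated 10 µm),
  vascular `VS` (CD31⁺ area), perivascular `PVS` (the 5 µm shell lining
  VS). Dilations threshold the Euclidean distance transform.
* **Indices** — surface indices `area(marker ∩ TT) / area(TT)` (Ki-67,
  TUNEL, EF5, perfusion markers), endothelial indices
  `area(marker ∩ VS) / area(VS)` (ZO-1, TUNEL), perivascular indices
  `area(marker ∩ PVS) / area(VS)` (SMA, desmin), and the object-based
  covered-vessel frequency (percent of vessels whose own shell is
  desmin⁺/SMA⁺ above a coverage threshold).
* **Distance profile** — percent of DAPI⁺ surface per successive 5 µm
  annulus of distance to the nearest vessel; the mass beyond 100 µm
  proxies chronically hypoxic tissue.
* **Network metrics** — microvessel density (objects per mm² of TT),
  skeleton-based branch density (junctions per mm of medial-axis length),
  mean vessel diameter (2 × distance-to-boundary along the skeleton),
  optional tortuosity.
* **Statistics** — two-tailed Mann-Whitney (exact for small tie-free
  samples, with an in-repo enumeration oracle), Kruskal-Wallis with Dunn
  post tests (Bonferroni family-wise adjustment), significance stars at
  0.05 / 0.01 / 0.001.
* **Synthetic scenes** — tubular vessel trees grown by a persistent random
  walk at tumor-like density (~50/mm², mean diameter 9.5 µm), nuclei
  fields, pericyte shells on a configurable fraction of vessels, EF5
  positivity beyond a 100 µm diffusion distance from perfused vessels,
  perfusion puncta, Gaussian PSF and sensor noise — plus the exact ground
  truth (vessel graph, per-nucleus labels, clean masks) for every scene.

## Worked example

```r
library(vascquant)

spec <- scene_spec(field_width_um = 512, field_height_um = 512,
                   n_stems = 13, seed = 7)       # ~50 vessels/mm^2
scn  <- generate_scene(spec)
scn$image
#> <calibrated_image> 512x512 px, 11 channels (DAPI, CD31, Ki67, TUNEL,
#>   EF5, SMA, desmin, ZO1, Hoechst, dex10k, dex2M) @ 1 um/px

cfg   <- run_config(groups = list(demo = list(n_scenes = 1)))
floor <- vascquant:::auto_negcontrol_floor(spec, 14)
a     <- analyze_image(scn$image, cfg, image_id = "demo", floor = floor)
a$row[c("mvd_per_mm2", "ef5_index", "sma_perivascular_index",
        "covered_vessel_frequency", "mean_diameter_um",
        "pct_cells_beyond_100um")]
#>   mvd_per_mm2 ef5_index sma_perivascular_index covered_vessel_frequency
#>          38.0    0.0395                 0.0728                     12.5
#>   mean_diameter_um pct_cells_beyond_100um
#>               11.2                   27.8
```

Read against the ground truth (`scn$gt$true_metrics`: MVD 38.1/mm²,
EF5 index 0.0386, covered frequency 15.4 %): the pipeline recovers vessel
density and the hypoxia index from the rendered noisy image to within a
few percent; 27.8 % of the DAPI⁺ surface lies farther than 100 µm from the
nearest vessel, i.e. in the theoretically hypoxic zone.

A full two-group experiment (generate → segment → ROIs → indices →
profiles → network → statistics) is one call:

```r
cfg <- run_config(
  base_spec = scene_spec(field_width_um = 512, field_height_um = 512,
                         n_stems = 13),
  groups = list(
    t0  = list(n_scenes = 6, overrides = list(perfused_fraction = 0.5,
                                              covered_fraction = 0)),
    t14 = list(n_scenes = 6, overrides = list(perfused_fraction = 0.95,
                                              covered_fraction = 0.6))),
  seed = 42)
bundle <- run_experiment(cfg)   # index, summary (mean ± sem), comparisons
```

The same pipeline runs from the command line
(`inst/scripts/vascquant.R`): subcommands `simulate`, `analyze`, `stats`,
`all` with `--config`, `--out`, `--seed`, `--log-level`.

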