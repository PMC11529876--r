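# emmosaic

Electron microscopy resolves nanometre detail at the cost of context: at
30,000× magnification 1 µm of specimen spans 3 cm of display, the field
of view shrinks to a few micrometres, and the surrounding "reference
space" — the cell or tissue a structure sits in — disappears from the
image. The remedy is to record a grid of overlapping tile images
(typically ~30% overlap), assemble them into one gigapixel mosaic, and
publish that mosaic as a zoomable web atlas so readers can move between
overview and full resolution the way they would in a digital map.

`emmosaic` implements that pipeline end to end for 2-D grayscale EM
montages, for microscopists and imaging-facility staff who want a
scriptable, dependency-light route from a folder of tiles to a static
HTML atlas:

1. **Flat-field correction** of each tile — smooth per-tile gradients
   from a misaligned beam or uncalibrated detector turn into repetitive
   patterns after assembly. Three classic corrections are built in:
   rolling-ball background subtraction (grayscale opening with a disk),
   polynomial shading correction (least-squares 2-D surface of total
   degree ≤ 4), and frequency-domain Gaussian high-pass
   (H(f) = 1 − exp(−f²/2c²)).
2. **Stitching** under a translation-only model. For each grid
   adjacency the offset maximizing the normalized cross-correlation
   (NCC) of the overlap strips is found via windowed phase correlation
   plus a local NCC hill climb, with quadratic sub-pixel refinement;
   low-score or ambiguous pairs fall back to the nominal grid offset.
   Global positions solve the weighted least-squares system
   `pos(b) − pos(a) = d_ab` over all pairs, anchored at tile (0,0).
3. **Torn-seam compositing.** Straight tile borders leave visible lines
   and brightness steps; the old darkroom trick of *tearing* prints
   instead of cutting them is emulated with a seeded bounded random-walk
   seam through every overlap, a linear alpha ramp over ±`feather_px`
   of signed distance to the seam, and exact renormalization so weights
   sum to 1 at every covered pixel.
4. **Deep Zoom pyramid.** The mosaic is cut into a dzi tile pyramid
   (`NAME.dzi` XML descriptor + `NAME_files/<level>/<col>_<row>.png`),
   level L−1 being the 2× downsample of level L (Gaussian anti-alias
   pre-blur, σ = 0.5, then 2×2 area mean), down to a 1×1 level 0.
5. **Atlas pages.** Deterministic static HTML with one viewer container
   per configuration, a floating scalebar calibrated by the integer
   `PixelsPerMeter = round(1e9 / pixel_size_nm)`, side-by-side
   comparison layouts, and switchable transparent overlay pyramids.
   Pages work from `file://`.

A deterministic synthetic-montage generator (`make_phantom()`,
`slice_tiles()`) produces EM-like phantoms with known crop origins,
injected shading fields and noise, so the whole pipeline is testable
without a single real micrograph. Grayscale PNG and baseline TIFF
codecs are built in (the package has no image-I/O dependency).

## Worked example

```r
library(emmosaic)

# synthetic ground-truth montage: 3x3 grid, 256 px tiles, 30% overlap,
# +-8 px stage jitter, 20% shading, brightness jitter, noise sigma 5
phantom <- make_phantom(phantom_spec(720, 720, n_blobs = 16, seed = 1))
montage <- slice_tiles(phantom, slice_spec(
  rows = 3, cols = 3, tile_px = 256, overlap_fraction = 0.3,
  jitter_px = 8, shading_amplitude = 0.2, brightness_jitter = 0.05,
  noise_sigma = 5, seed = 2))
write_tiles(montage, "tiles")

result <- stitch(read_tiles("tiles")$tiles,
                 flatfield = flatfield_params("polynomial", degree = 2))
#> [info] pair r0_c0->r0_c1 [right]: dx=170.06 dy=2.03 score=0.899 accepted
#> [info] pair r0_c0->r1_c0 [below]: dx=-7.00 dy=185.97 score=0.823 accepted
#> ... one log line per grid adjacency ...
result$layout
#> <mosaic_layout: 9 tiles, canvas 624x630>

err <- layout_error(result$layout, montage$truth)
sprintf("position error: mean %.3f px, max %.3f px", err$mean, err$max)
#> "position error: mean 0.023 px, max 0.037 px"
```

Each log line reports the measured offset of the right/bottom neighbour
relative to its tile (x rightward, y downward), the NCC score in
`[0, 1]`, and whether the pair was accepted; the position error compares
the solved layout with the generator's recorded crop origins, so 0.037
px means every tile landed within a twenty-fifth of a pixel of the
truth. Continuing to a published atlas:

```r
seams  <- montage_seams(result$layout, seam_spec(feather_px = 20, seed = 1))
masks  <- feather_masks(result$layout, seams, feather_px = 20)
mosaic <- crop_mosaic(composite(result$tiles, result$layout, masks),
                      result$layout)
desc   <- dzi_descriptor(ncol(mosaic), nrow(mosaic))
dzi_build(mosaic, desc, "site/dzi", name = "demo")
write_site(list(viewer_config("viewer1", "dzi/demo.dzi",
                              pixel_size_nm = 2.5)),
           "site", title = "Demo atlas")
```

## Command line

The installed script `exec/emma` wires the stages together:

```sh
emma all      --config config.json --out site     # stitch -> composite -> pyramid -> page
emma stitch   --config config.json --out out      # layout only
emma selftest --seed 1                            # synthetic end-to-end check, exits nonzero on failure
```

Configuration is JSON; unknown keys are rejected by name. Exit codes:
0 ok, 2 configuration, 3 stitching, 4 pyramid, 5 site.

```json
{
  "input_dir": "tiles",
  "grid": {"rows": 3, "cols": 3, "order": "row-major"},
  "overlap_fraction": 0.3,
  "pixel_size_nm": 2.5,
  "flatfield": {"method": "polynomial", "degree": 2},
  "seam": {"roughness_px": 10, "step_px": 4, "feather_px": 20},
  "pyramid": {"tile_size": 256, "overlap": 1, "format": "png"},
  "name": "demo",
  "seed": 1
}
```

Tile files are `tile_r{row}_c{col}.tif` (or `.png`) in `input_dir`.

The generated `openseadragon/` directory contains clearly labelled
placeholder scripts: before publishing, replace them with the real
OpenSeadragon and scalebar plug-in downloads — the pages only *configure*
the viewer and work unchanged once the real scripts are in place. Upload
the site directory to any static host (e.g. GitHub Pages) to put the
atlas online; no server-side code is needed.

## Scope

Translation-only registration (elastic/affine deformation correction is
delegated to specialist tools); single-channel 2-D mosaics; png
pyramids. Web hosting/deployment, in-browser viewer internals, and
quantitative analysis on the mosaic are out of scope — measure on the
raw data, not on blended pixels.
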