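---
title: "Montage assembly and atlas generation: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Montage assembly and atlas generation: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emmosaic)
```

## The problem

A transmission-EM image at useful magnification covers a few
micrometres. To keep a structure of interest embedded in its reference
space, one records a rectangular grid of tile images with roughly 30%
overlap and assembles them into a single mosaic, then publishes the
mosaic as a multi-resolution tile pyramid behind a web viewer. Two
artifact classes dominate assembled EM montages and drive the design of
this package: smooth per-tile intensity gradients that become
repetitive patterns after assembly (the *illumination issue*), and
visible lines or brightness steps where tiles meet (the *projection
issue*).

## Image model and conventions

Images are matrices indexed `[y, x]`, y downward, x rightward, 0-based
pixel positions in all public coordinates, integer grey levels at 8 or
16 bit. All processing is floating point internally; quantization back
to the grey-level grid happens at composite output and on write. A tile
carries its grid indices, nominal overlap fraction and physical pixel
size in nm/px.

## Flat-field correction

Each tile is corrected *before* registration: a shading gradient is a
low-frequency signal that biases correlation toward zero lag, so
correction first measurably improves pairwise offsets. Three standard
remedies are provided, selected by `flatfield_params()`:

* **Rolling ball** (`rolling_ball()`): background = grayscale opening
  with a flat disk of radius `radius_px` (default tile width / 8),
  subtracted from the image. The opening is computed by chord
  decomposition with van Herk running minima, O(N·r) rather than
  O(N·r²). The classic light-background variant (opening of the
  inverted image) is behind `light_background`. The correction is
  idempotent up to quantization and exactly shift-equivariant more than
  2r away from borders.
* **Polynomial** (`polynomial_flatfield()`): least-squares fit of a 2-D
  polynomial surface of total degree ≤ 4 (default 2) on normalized
  `[-1, 1]²` coordinates. Because fitting is linear, an additively
  injected polynomial field is recovered exactly on top of whatever the
  image content projects onto the basis.
* **High-pass** (`highpass()`): Fourier-domain transfer function
  `H(f) = 1 − exp(−f²/(2c²))` with `c = cutoff_fraction` in cycles per
  pixel (default 0.02, i.e. a ~5-cycle-per-256-px-tile shading band is
  attenuated to a few percent while frequencies above 0.1 c/px pass
  essentially unchanged).

`preserve_mean` (default `TRUE`) restores the original mean after every
method so that tiles keep a common grey scale — blending compares
absolute intensities, and a montage whose tiles were re-centred
independently would reintroduce steps at the seams.

## Pairwise registration

The model is translation-only. Elastic deformation of sections is real
but out of scope here; it needs landmark- or block-matching machinery,
and a translation model keeps the solver linear and the ground truth
exact. This is a documented limitation, not an oversight.

For each grid adjacency the nominal overlap strips are extracted
(nominal offset = `round(tile · (1 − overlap))`), mean-subtracted and
Hann-windowed (the window suppresses the periodic-boundary artifact of
the FFT), and phase-correlated. The whitened correlation surface is
reordered into shift space `±search_px` and smoothed with a σ = 0.8
Gaussian: under noise the phase peak splits across neighbouring integer
shifts, and without smoothing the peak-ratio test misfires. The
contract is that the reported offset *maximizes the NCC* and phase
correlation is the way to find it, so the strongest smoothed phase
peaks (up to five, plus the nominal offset) serve as starts for a local
hill climb on the true Pearson NCC of the overlapping pixels; the best
basin wins, ties broken toward the smallest displacement from nominal.
Sub-pixel refinement fits a 1-D parabola through the NCC values around
the integer peak in each axis, which on the fixture worlds lands within
a few hundredths of a pixel.

Rejection: a pair is rejected when the NCC score at the peak falls
below `score_threshold` (default 0.3) or the smoothed phase surface's
peak-to-runner-up ratio outside a 5×5 exclusion zone falls below
`min_peak_ratio` (default 1.5, the classic ambiguity test that fails on
periodic patterns). Rejected and featureless pairs contribute their
nominal offset at a small epsilon weight, so a montage with a blank
tile still solves. The measured integer peak is kept on rejected
records (`peak_dx_px`/`peak_dy_px`) so that the oracle-equivalence
property — phase-correlation peak equals exhaustive NCC argmax — can be
asserted independently of the rejection policy.

Global layout: weighted linear least squares over per-tile positions,
one equation per pair, weights = scores, gauge fixed by anchoring tile
(0,0), positions then translated to a (0,0) minimum. On a consistent
offset set the residual is zero; a single perturbed edge in a 2×2
square distributes its inconsistency equally over the 4-cycle (0.25 px
per edge for a 1 px perturbation — verified against the hand-solved
normal equations in the tests).

Recovered and true layouts are compared after removing the mean
translation of each (registration determines relative placement only).

## Torn seams and feathering

Each pairwise overlap gets a seam: a seeded random walk along the band
midline, lateral steps ±1 px every `step_px`, reflected at
±`roughness_px`. Reflection makes the excursion bound exact and keeps
the long-run mean at zero; roughness 0 degenerates to the straight
midline, as does a band too narrow for the requested roughness (with a
warning). Each tile's alpha mask is the product of linear ramps
`clip(0.5 + d/(2·feather_px), 0, 1)` over the signed Euclidean distance
`d` to each of its seams (positive on the tile's own side), then all
masks are renormalized to sum to exactly 1 at every covered pixel.

The product-then-renormalize construction is a deliberate deviation
from a precedence rule ("vertical seams win, horizontal seams terminate
on them"): products resolve 4-tile corners symmetrically without
special cases, and renormalization restores the partition of unity
exactly, which the tests assert to 1e-6 at ten thousand random pixels.
A linear ramp was chosen over a cosine because its value at a known
distance is exactly predictable in tests; the compositor quantizes once
at output so identical-content overlaps reproduce their input
bit-exactly.

`hard_composite()` keeps the naive projection — every pixel from the
nearest tile, straight borders, no gradients — as the measurable
baseline. `seam_step_metric()` scans finite differences across seam
samples; on two constant tiles differing by ΔI it reads exactly ΔI for
the hard composite and at most `ΔI/(2·feather) + 1` grey levels for the
feathered one. On textured montages the metric includes genuine image
gradients, so quantitative seam comparisons are made on the
constant-tile world where the artifact is the only signal.

## Deep Zoom pyramid

Geometry is fixed by the dzi conventions: `max_level =
ceil(log2(max(w, h)))`, level dims by repeated ceiling halving down to
1×1, `ceil(dim / tile_size)` tiles per level, adjacent tiles sharing
`overlap` border pixels (default 1; none added on left/top edges).
Tiles are written as png — lossless, so re-assembling the top level
reproduces the mosaic bit-exactly; jpg is accepted when *reading*
third-party descriptors but the built-in codec does not encode it.

Downsampling is a Gaussian anti-alias pre-blur at σ = 0.5 per halving
step followed by a 2×2 area mean (edge blocks average the available
pixels). The area mean itself contributes box smoothing, so the
combined kernel is close to the standard pyramid generating kernel
while each level stays within a fraction of a grey level of an
independent plain box downsample — the oracle the tests compare
against. A σ as large as 1.0 before the area mean measurably
over-smooths (1–2 grey levels mean deviation from the box oracle on the
phantom fixture) and was rejected for exactly that reason; plain box
mode remains available behind `box = TRUE`.

## Atlas pages

Page generation is pure text assembly — it never touches pixel data,
so build time is independent of mosaic size. The output is well-formed
XML (asserted with a strict parser in the tests), byte-deterministic
for fixed inputs, and works from `file://`. The scalebar is driven by
the integer `PixelsPerMeter = round(1e9 / pixel_size_nm)`; the display
arithmetic helper `projected_length()` converts feature length ×
magnification into display units (1 µm at 30,000× → 3 cm). Overlay
pyramids are RGBA with the overlay colour at alpha 0.35 by default on
labeled pixels and full transparency elsewhere, sharing the base
pyramid's geometry so viewers can stack them. The viewer and scalebar
scripts themselves are external vendored assets; the package writes
labelled placeholder stubs so that path checks are meaningful, and the
README instructs replacing them with the upstream downloads. A QR-code
helper was considered and dropped: no encoder is available in the
supported environment and it is cosmetic.

## The synthetic world

`make_phantom()` builds an EM-like phantom: band-limited texture (white
noise blurred at σ = 2, rescaled to `texture_sigma` grey levels),
`n_blobs` darker soft-edged disks placed without overlap (so the blob
mask has exactly `n_blobs` connected components — a flood-fill oracle
checks this), and curvilinear membrane-like random walks. The blob mask
and raw texture layer ride along as attributes for tests.

`slice_tiles()` emulates acquisition: integer stage jitter uniform on
`[-j, +j]` per tile (sub-pixel mode resamples bilinearly), per-tile
quadratic shading normalized to `shading_amplitude` × dynamic range
peak-to-peak, per-tile constant brightness offsets, additive Gaussian
noise, quantization. Defaults for the acceptance world follow the
stated conditions: 3×3 grid, 256 px tiles, 30% overlap, jitter ≤ 8 px,
shading 0.2, noise σ = 5 at 8 bit. Stage-jitter magnitude for real
microscopes is not characterized here; the integer default was chosen
because it keeps the recovery oracle exact.

What the generator does *not* emulate: electron-optical distortion,
beam damage, charging, focus gradients, elastic section deformation,
detector fixed-pattern noise. A green test therefore establishes that
the algorithms recover the stated corruption classes exactly or within
stated bounds — not that any particular microscope will achieve 0.04 px
registration error.

## Numerical choices and degenerate inputs

* Seeded determinism everywhere: every stochastic step runs under a
  saved-and-restored RNG state, so equal seeds give bit-identical
  phantoms, seams and pages.
* Featureless (zero-variance) overlaps are rejections, never errors; a
  disconnected adjacency graph (only possible with missing pairs) is a
  configuration error.
* Correlation ties break toward the smallest displacement from the
  nominal offset.
* `feather_px = 0` produces binary masks via the sign of the distance
  (value 0.5 exactly on the seam).
* 16-bit inputs are processed in floating point and re-quantized only
  on write.
* Oversized rolling-ball radii degrade to global-minimum subtraction
  with a warning; 1×1 "grids" flow through the whole pipeline as a
  degenerate single-tile atlas.

## Known limitations

Translation-only registration; no exposure harmonization beyond
feathering (a global gain gradient across the montage survives); png
only on the write path; the seam walk is a convention, not a model of
manually torn prints — only the stated goal (no straight lines, no
steps above the feather bound) is encoded as a metric and tested.
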