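---
title: "Methods: digital phenotyping of wheat spikes with spikescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital phenotyping of wheat spikes with spikescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikescan)
```

# Scope and model

`spikescan` measures wheat spikes from single-spike photographs taken in the
"on a clip" protocol: the spike held vertically against a saturated blue
paper backdrop, optionally with a reference colour chart in frame. The
pipeline has five stages — segmentation, calibration, morphometry,
colorimetry/texture, certificate assembly — plus a synthetic phantom
generator that provides exact ground truth for all of them, and a relational
datastore for collections.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic tests do and do not
establish.

# The phantom generator: a stated world

A phantom is defined by `phantom_spec()`: body length and maximal width in
mm, the relative axis position of the widest point, a body profile, flat
body/awn/background colours, awn count/length/thickness, an optional chart,
the scale (mm/px), in-plane rotation, Gaussian pixel noise, and a seed.
Rendering is a pure function of (spec, seed); noise is added after
labelling, so the truth mask is exact.

Two body profiles are provided:

* **kite** — the filled quadrangle itself; its area is analytically
  `L·W/2`, which makes it the natural oracle for the quadrangle model.
* **smooth_lanceolate** — width profile `w(t) = W·sin(π·t^γ)` with
  `γ = log(1/2)/log(p)` so the maximum sits exactly at the requested
  relative position `p`. A one-parameter smooth family whose quadrangle fit
  is still analytically predictable.

Defaults describe a realistic bread-wheat spike: 90 mm long, 16 mm wide,
widest at 35 % of the axis from the base, straw-coloured
(RGB 181, 160, 108), 12 awns of 30 mm, imaged at 0.2 mm/px — dimensions in
the range a field scientist would report for awned bread wheat. When the awn
colour is not given it defaults to 0.82× the body colour: awns share the
spike's pigmentation, slightly darker. This coupling is deliberate — cohorts
that differ "only in body colour" then shift body *and* awn colour features
together, which is how pigmentation differences behave between accessions.

Rasterization detail: a pixel belongs to the body when its centre lies
within the width band, with a half-pixel floor on the band so the sub-pixel
slivers at the sharp base/tip are still rendered; without the floor a kite
loses its analytically stated length to discretization.

Two deliberate non-realisms: the body is flat-coloured (plus optional i.i.d.
noise), so texture features on phantoms measure noise texture, not glume
relief; and awns are straight strokes, not curved bristles. Green tests
therefore establish correctness of the *measurement* operators, not
robustness to real-photograph nuisance (shadows, specularity, overlapping
awns, non-uniform backdrop).

# Segmentation

The reference pipeline this package stands in for segments with a trained
neural network; `spikescan` substitutes a classical method so that the whole
artifact is self-contained, and `load_mask()` accepts masks from any
external segmenter instead.

1. **Background**: pixels within half of `background_hue_window` (default
   40°, i.e. ±20°) of the modal hue of saturated pixels, requiring
   saturation ≥ 0.15 so grey/white chart patches are never "blue".
2. **Chart**: clusters of ≥ 6 small rectangular foreground components
   (fill ≥ 0.85, aspect within 2:1). Blue-ish chart patches can be swallowed
   by the background window — calibration tolerates missing patches.
3. **Body vs awns**: morphological opening with a disk of
   `body_opening_radius_px` (default 5 px at ~0.2 mm/px) erases structures
   thinner than ~2 r; the largest surviving component is the body. Residue
   components are awns when they are thin (erosion by
   `⌈(awn_max_thickness_px+1)/2⌉` empties them), elongated (bounding-box
   diagonal ≥ 4× the thickness cap) and reach beyond the body's 3 px fringe;
   compact residue hugging the body (the fringe and the sharp tips the
   opening shaved off, up to `2·r` away) is reattached to the body; detached
   specks stay background.

**Known limitation.** Any thickness-based separation truncates the body
where it is thinner than the awn-thickness threshold. On the analytically
sharp kite tip this costs up to ~10 % of axis length through the segmenter;
real spike tips are blunter, but the bias direction (shorter) persists.
Consequently the parameter-recovery guarantees (2 % on `q_L`, `q_W`; ±0.05
on `q_pW`) are stated — and tested — against ground-truth masks; the
segmenter has its own accuracy contract (body Jaccard ≥ 0.95, awn area
within 30 % on 2 px awns).

# Calibration

With a chart: `mm_per_px = patch_size_mm / median observed patch side`, and
the colour transform is the least-squares affine map (3×4: gain matrix plus
offset) from observed patch mean RGB to reference RGB. Patch-to-reference
correspondence uses predicted patch centres when the grid position is known
(phantom sidecars record it) and a pitch-grid fit otherwise; ≥ 6 matched
patches are required. Without a chart the user supplies the scale explicitly
and the transform is the identity — the imaging protocol does not specify
how chartless images were scaled, so an explicit parameter is the only
honest fallback.

Colour features are computed **after** applying the transform, and the
transform is stored with the calibration, so either convention can be
reconstructed.

# Morphometry

Conventions: 8-connected foreground, Moore boundary tracing, convex hull on
boundary pixel centres (`grDevices::chull`). The perimeter is the length of
the polygon through every 4th boundary pixel — raw 8-connected chain length
overestimates smooth outlines by ~5 %, which would push a disk's
circularity to ~0.91; chord subsampling keeps disks within 0.5 % and is
exact on straight edges. The convex hull area gets half a boundary layer
(`+ P_hull/2`) added, because pixels extend half a pixel beyond their
centres; this keeps solidity of convex digitized shapes ≤ 1. Axis length
adds one pixel for the two half-pixel footprints at the ends.

The spike axis is the first principal direction of body pixel coordinates;
the base is the lower image end by protocol (spikes are clipped base-down),
with an override for other orientations.

The seven outline descriptors use the standard ImageJ-style definitions
(circularity `4πA/P²`, roundness `4A/(πL²)` with `L` the axis length,
solidity `A/A_hull`, rugosity `P/P_hull`); the upstream literature names
them without formulas, and these are the definitions consistent with values
bounded by 1.

**Quadrangle model.** The width profile is measured in 64 axis bins (binning
damps awn-adjacent noise; per-row widths would be noisier), each half-width
gets the half-pixel footprint back, and the profile maximum is refined by
parabolic interpolation over the three bins around the argmax. The 11
reported parameters are the redundant kite parameterization
`(q_L, q_W, q_pW)` + 8 analytic derivatives. The upstream feature list for
the quadrangle model is not public; a symmetrized quadrangle with two
vertices on the axis *is* a kite, so this parameterization is declared —
and isolated in one function (`kite_parameters()`) so an alternative can be
swapped in. A profile whose maximum sits on an end bin is clamped to
`q_pW ∈ [0.02, 0.98]` and flagged.

# Colour

Means are taken per region over colour-corrected pixels in four spaces: RGB
(0–255); CIELAB via `grDevices::convertColor` (sRGB primaries, D65, L in
0–100); HSV with H in degrees and V = max/255; YCbCr with the
standard-definition luma coefficients (0.299/0.587/0.114, chroma offset
128). Hue is averaged **circularly** — arithmetic averaging is wrong at the
0/360 wrap (the mean of pure red and pure blue is 300°, not 120°).

Dominant colours are the k = 3 k-means centroids of region RGB triples:
seeded k-means++ initialisation, 10 restarts, Lloyd iterations, clusters
ordered by pixel count. Fewer than k distinct colours is handled by
degenerate clusters (duplicated centroids, zero proportion, `merged` flag).
Because centroids are cluster means over a full partition, the
proportion-weighted centroid mean reconstructs the region mean exactly — a
tested invariant.

Empty regions (awnless spikes) yield **missing** colour features, never
zeros: zero is a valid black. Missingness propagates through certificates
and group tests.

# Texture

Luminance is the YCbCr Y component, quantized uniformly over the region's
min–max range into `gray_levels` (default 32 — at typical body sizes of
~10⁴ px, finer quantization makes the co-occurrence matrix too sparse,
coarser loses contrast). Quantization is computed on integer
milli-luminance, so adding a constant to every pixel leaves the levels
bit-identical (a tested invariance). Pairs/runs pool the four standard
directions (0°, 45°, 90°, 135°) at distance 1, symmetrized; pairs crossing
a non-body pixel are dropped and runs truncate at region boundaries.

The ten GLCM and six GLRM features are the common Haralick/Galloway
selections matching the required counts (the upstream lists are not
recoverable); their identities are fixed in two registries
(`GLCM_FEATURE_NAMES`, `GLRM_FEATURE_NAMES`) so the sets can be re-mapped.
Conventions: entropy uses the natural log with `0·log 0 = 0`; correlation of
a constant region is 0 by convention (flagged); run percentage divides by
pixels × directions so it is ≤ 1; LGRE counts grey levels from 1 to avoid
division by zero. Implementations are verified against brute-force pair/run
enumerators on random patches.

# Certificates and statistics

A certificate holds two blocks: frontal (mean of frontal + back views) and
lateral (mean of the two sides), each 24 features = 11 quadrangle + 7
outline + body R,G,B + awn R,G,B. The awn area `c_Sa` is carried alongside
each block rather than inside the 24: the source material is contradictory
about whether it is one of the "7 outline features" (its methods list
excludes it; its results report it among certificate indices), so both are
exposed. A single-view spike yields a one-block certificate.

Group comparison is per-feature Welch's t-test by default (Mann–Whitney U
optional) with Benjamini–Hochberg correction across the 25 features — the
upstream analysis names neither test nor correction, so the defaults are
declared, not inferred. Features with zero variance in both groups and
equal means get p = 1. The test-calibration suite checks the *uncorrected*
per-feature rejection rate on matched null cohorts against the binomial
band [0.01, 0.12]: under BH an FDR-controlled full-null rate in that band
would be impossible by construction.

Model rendering follows the established presentation: thin blue kite
outlines per spike, a thick red mean-parameter polygon filled with the
group's mean body colour, and the width axis magnified 5× relative to
length. The mean polygon is the polygon of mean parameters, not the mean of
vertex coordinates — the latter is not a kite.

# Datastore

A single JSON file holds the 11-table schema: five uploaded tables
(Collection → Plant → Spike → Image, plus Environment keyed to Plant) and
six extracted tables keyed by Image (SpikeData 8, QuadrangleModel 11,
MeanColor 12 per region, DominantColor 3×4, GLCMTexture 10, GLRMTexture 6).
Plant carries exactly 20 fields; beyond the documented ones (year, accession
number, sowing id, reproduction number, Q-gene allele, parents, taxonomy,
origin) the remainder are implementation-chosen and include a free-text
annex that preserves unrecognized manifest columns verbatim. Foreign keys
are enforced on insert; batch import validates per row (missing files,
duplicate spike/view), rejects rows individually with reasons, and commits
accepted rows together. Doubles are serialized with 17 significant digits so
feature round-trips are bit-exact. A server-grade SQL deployment is out of
scope; the schema is deliberately dialect-neutral.

# Numerical and testing notes

* Budgets: statistical acceptance tests run cohorts at a coarse 0.6 mm/px
  scale (≈ 150×60 px images) so 100-replicate suites finish in minutes on
  one CPU; geometry oracles use finer scales where discretization matters.
* Tolerances in tests come from the contracts above: 2 % for truth-mask
  parameter recovery, 3 % for 15° rotation invariance (discretization), 1 %
  for polygon area/perimeter oracles, machine precision for the analytic
  kite identities.
* File formats are portable anymaps (PPM/PGM) rather than PNG: the package
  avoids compiled image codecs entirely; PNM is lossless, self-describing
  and universally convertible.
* Degenerate inputs: 1-px bodies raise geometry errors; constant-luminance
  regions flag `constant` and fix correlation at 0; bodies under 64 px
  refuse texture analysis; `n < 3` per group refuses testing.
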