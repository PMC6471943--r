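---
title: "Methods: smart acquisition, quality control and cyst morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smart acquisition, quality control and cyst morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

kidneyscreen implements a complete high-content screening workflow for
glomerular cyst formation in the zebrafish pronephros, the embryonic kidney
visualised here as a GFP-labelled bilateral structure in dorsally mounted
embryos in 96-well plates. The workflow has five stages -- feedback ("smart")
acquisition, z-stack preprocessing, image quality control, heuristic
phenotype classification, and cyst-area quantification -- and ships a
ground-truthed synthetic plate generator so that every stage can be validated
quantitatively without instrument data. This vignette explains the models and
the numerical decisions; the README shows a worked end-to-end example.

## The two-pass acquisition model

Screening microscopes trade resolution for field of view. The workflow
therefore images each well twice. A 4x pre-scan (NA 0.13, one z-plane, GFP
channel) covers the whole well; the pronephros is found in it by automatic
thresholding (Li's minimum cross-entropy method by default) followed by the
intensity-weighted centre of mass of the foreground. The pixel coordinates
are mapped to stage micrometres by an affine calibration -- pixel (0,0) is
the centre of the top-left pixel, x rightward, y downward, with configurable
axis sign flips -- and a short job script is emitted:

```
GOTO <X> <Y>
AUTOFOCUS GFP470 700.0
SET_CHANNEL BF 60 10
STACK 30 4.0
SET_CHANNEL GFP470 100 20
STACK 30 4.0
```

The defaults encode the acquisition protocol the package models: a software
autofocus search volume of 700 um, bright-field at 60% LED / 10 ms, GFP470
at 100% LED / 20 ms, and a 30-slice z-stack at dZ = 4 um per channel on a
2048 x 2048 sCMOS camera. The job grammar is a documented functional
stand-in for vendor scripting interfaces (one uppercase verb per line,
micrometre arguments at one decimal); an adapter for a real instrument
replaces `mock_microscope_execute()` and the filename parser, nothing else.

Detection deliberately returns a blank signal rather than an error for empty
wells. Two guards exist: a minimum foreground area (50 px) and a minimum
foreground/background mean contrast (5x). The contrast guard matters
because an automatic threshold always splits a noise-only image somewhere;
area alone cannot tell a dim well from an empty one.

Pixel calibrations default to 1.625 um/px at 4x and 0.65 um/px at 10x,
i.e. a 6.5 um camera pitch. These must be set explicitly for real optics;
every pixel-denominated threshold below is tied to the 10x figure.

## Synthetic scenes and what they do (and do not) emulate

The generator models the pronephros as an elongated soft-edged bar: full
length ~N(280, 15) um, full width ~N(60, 5) um, near-horizontal orientation
(uniform +/- 8 degrees, reflecting the standardised dorsal mounting), with a
dim midline seam so the bilateral tubules read as two bright stripes. The
cystic phenotype inserts a zero-intensity lumen strip of 20-80 um across the
glomerular (central) region -- the dark gap every downstream heuristic keys
on. Blank wells render background only; "blurred" wells add 10 um of
Gaussian defocus, the scale of a failed autofocus (at NA 0.3 a focus error
of ~50 um blurs by roughly this much), while the spec of each blur is a
per-well dial.

Optics are analytic: each edge profile is the exact 1-D Gaussian blur of the
underlying indicator (a pair of normal CDFs) with width
sqrt(0.8^2 + (0.2 * dz_offset)^2) um, growing linearly away from the
best-focus plane. Noise follows a standard widefield camera model applied
after the optics: Poisson shot noise on the expected photoelectrons (gain 2
counts/e-), Gaussian read noise (sd 2 counts) and a small uniform pedestal
(4 counts), rounded and clamped to 16 bits. A fixed seed reproduces every
frame bit for bit, and peak signal (20000 counts, lognormal 8% well-to-well
variation) leaves 16-bit headroom.

Ground truth is the un-blurred geometric footprint evaluated at pixel
centres, so the truth areas are exact pixel counts of the rendered geometry,
and the lumen truth equals the rendered gap footprint by construction.

What the generator does not emulate: uneven illumination, autofluorescence,
yolk glare, partially mounted or doubled embryos, and the halo of
out-of-focus light that real widefield optics spread far beyond a Gaussian.
Passing validation here therefore demonstrates the pipeline's logic and
numerics, not robustness to every artefact of real screens; the QC
calibration step below is the designed hook for porting to real data.

## Preprocessing

Each rescan GFP stack is reduced in a fixed chain, each step recording
itself with parameters in a provenance list: best-focus slice (argmax of the
variance of the 3x3 Laplacian; plain intensity variance is the config
alternative; ties break to the lowest index), a 7-slice sub-stack around it
(clamped at stack ends so exactly 7 slices always result), per-plane 3x3
median denoising, maximum projection, a centred 512 x 512 crop, and a
glomerular recrop that keeps full width but reduces height by 1.6
(round(512/1.6) = 320 rows, banker's rounding fixed so shapes are
bit-exact). The recrop is finally auto-thresholded with Li's method.

Li's threshold is computed by exhaustive minimisation of the cross entropy
over all integer thresholds (on values + 1, so zero-valued backgrounds are
well defined); the test suite cross-checks it against the independent
iterative fixed-point formulation. Deconvolution is deliberately absent from
the chain: the heuristics below only require a near-zero background and
contrast, which the median filter and background subtraction provide; a
deblurring adapter can be slotted in before denoising if needed.

## Quality control

Two variance statistics on the cropped projection decide the well label,
blank first (so empty wells are never reported as merely blurred), then
blur:

* blur: population variance of the rolling-ball background-subtracted image
  (disc opening, radius 50 px at 0.65 um/px); "blurred" strictly below the
  threshold, published default 400;
* blank: population variance of the 3x3 Laplacian response; the published
  rule removes wells strictly above 124.

Both absolute thresholds are instrument-specific (bit depth, gain,
denoising), so `calibrate_qc()` sweeps candidate thresholds over a labelled
image set and the pipeline self-calibrates on a synthetic set derived from
its own seed. Two calibration findings are deliberate design notes. First,
on denoised data the blank rule works in the opposite direction from the
published one: structure raises the Laplacian variance, noise-only blanks
sit orders of magnitude lower. The comparison direction is therefore a
config option (`blank_above`, default: the published direction) and the
calibration selects it from data rather than silently overriding the
published rule. Second, the rolling-ball radius is as data-dependent as the
threshold: blur detection works because the ball strips a sharp structure
completely from the background estimate (radius larger than the sharp
structure's half-width) while absorbing much of a defocus-spread one
(radius smaller than the blurred width). With realistic structure-width
variability a fixed radius can land inside the sharp-width range, and wide
sharp wells then leak into the background and mimic blur. The calibration
therefore sweeps a short radius grid at and above the configured value
jointly with the threshold (ties broken by the separation margin between
the classes) and returns both. The radius is specified in pixels, so
ports to other pixel sizes should also scale the configured centre of the
grid.

The blur statistic is monotone non-increasing under growing Gaussian blur,
which the suite asserts on rendered wells.

## Phenotype classification

Two independent heuristics vote on every QC-passing well and must agree;
disagreement yields "ambiguous", which is reported, excluded from
quantification by default, and includable via config. Auditability was the
reason for agreement-or-ambiguous over any silent precedence rule.

The primary vote inspects the horizontal mean-intensity profile of a
bounding-box ROI around the segmented pronephros (Gaussian blur sigma 2 px,
Li threshold, union bounding box expanded 15% per side; fully-foreground
masks are inverted first). The profile is taken on the denoised,
background-subtracted grayscale image. A well votes cystic when the profile
contains a run of at least 3 columns at or below epsilon = 2 counts that is
flanked on both sides by tissue-level signal (5% of the profile maximum).
Three numerical choices deserve note. The published test looks for exact
zeros; without deconvolution, one to two counts of residual noise survive
background subtraction even inside a true lumen, so a small positive epsilon
is the faithful translation (the operation's own default remains 0, and with
epsilon 0 the vote is exactly invariant to intensity scaling). The minimum
run length suppresses single-column flickers. The tissue-flank requirement
exists because the expanded ROI contains background columns at its margins;
a lumen is a dark gap *between* bright humps, and requiring bright flanks
encodes exactly that.

The confirmatory vote fits an ellipse to every 8-connected mask particle:
centroid plus second central moments (with the 1/12 single-pixel variance
term), axes rescaled so the ellipse area equals the particle pixel area --
the standard particle-analysis ellipse, verified against a brute-force
double-loop to 1e-9. The particle with the largest major axis (ties: larger
area, then lower raster id) decides: strictly greater than 299 px at
0.65 um/px means an intact elongated wild-type structure (~194 um); a cyst
splits the mask into shorter particles. The threshold is config-exposed and
should be scaled as 299 x (0.65 / pixel_size) for other optics.

Sensitivity limit: a 20 um lumen is ~31 px; after the soft optical edge,
projection bleed from defocused planes in deep stacks can close the
zero-run at strong tilts. On single-plane or shallow stacks the balanced
288-well study classifies perfectly; expect the profile vote to be the
first to degrade on narrow lumens in deep, undeconvolved stacks.

## Quantification

Pronephric area sums mask particles passing position/size/morphology
filters (defaults: area >= 50 px^2, centroid within the central 80% band of
the image width, circularity bounds [0, 1] -- i.e. permissive, as the
published filter values are not stated and real screens should calibrate
them). Cystic area inverts the mask inside the convex hull of all
foreground pixels: the hull boundary is what separates the cystic lumen
from the general background (the lumen is open at its ends, so without the
hull restriction it would be connected to the outer background and never
enclosed). Enclosed background particles are numbered and kept when their
number is at most 10 and their Feret diameter (maximum pairwise distance
between convex-hull vertices of the pixel corners; a single pixel measures
sqrt(2)) is at least 70 px.

Particle numbering is area-descending by default rather than raster order.
On realistic masks the hull/mask boundary produces on the order of a hundred
tiny slivers; under raster numbering the lumen's index routinely exceeds 10
and the index filter would discard every true cyst. Area-descending
numbering gives large enclosed particles the low numbers the published
count-of-10 rule intends to keep, and the Feret cut removes the slivers
regardless; raster numbering remains available (`particle_order =
"raster"`).

Total kidney area allocates pronephric area to wild-type wells and the sum
of pronephric and cystic areas to cystic wells, in px^2 and um^2 (via the
squared pixel size), aggregated into an 8 x 12 plate matrix with missing
(QC-failed, undetected or ambiguous) wells marked, as CSV and heatmap.

The convex hull is a monotone-chain implementation preceded by a per-column
extreme-point reduction; it is checked exactly against an O(n^3) brute-force
enumeration. Connected components use a 4-connected labelling pass plus a
vectorised diagonal merge for the 8-connectivity default.

## Validation studies and problem sizes

`benchmark_closed_loop()`, `benchmark_qc()`, `benchmark_phenotype()` and
`benchmark_cyst_recovery()` are the package's validation harnesses; the
acceptance script reruns them from scratch. Sizes were chosen once so each
study completes in about a minute on one core while keeping every pixel
threshold meaningful: closed-loop and phenotype studies use 512 px frames at
the instrument calibration (the full structure and the 299/70 px thresholds
apply unchanged); the closed-loop study uses 5-plane GFP-only stacks since
the centring score does not depend on stack depth; phenotype and
cyst-recovery studies use single best-focus planes (classification operates
on the projection, and a single in-focus plane is its fast equivalent); the
QC study uses 256 px frames at 1.3 um/px with the rolling ball scaled to
the same physical size; the structural full-plate study (5760 planes to 96
processed wells) uses 64 px frames because it checks counts and shapes, not
photometry. Typical results: sub-micrometre closed-loop centring error
(tolerance ~17 um), perfect QC class separation after calibration, >= 0.95
phenotype accuracy with ambiguous counted as error, and ~2-5% median cyst
area error dominated by the narrowest lumens, where the soft edge bias
(about one pixel per side of the gap) is proportionally largest.

## Known limitations

* The two classifiers share the Li-masked segmentation; a systematic
  segmentation failure (e.g. saturated wells) degrades both votes together.
* Absolute QC thresholds do not transfer across instruments; always run
  `calibrate_qc()` on labelled data first.
* The Feret and axis thresholds are pixel-denominated at 0.65 um/px.
* The folder watch is polling-based with a size-stability handshake; files
  appearing non-atomically slower than one poll interval per write are
  still dispatched only after stabilising, but no checksum is kept.
* Severity grading beyond the binary phenotype, hit-calling statistics
  across compound plates, and multi-embryo wells are out of scope; the
  measurement CSV is the hook for plate-level statistics.
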