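---
title: "Annotating flower color from specimen images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating flower color from specimen images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petalhue)
```

## The problem

Community biodiversity repositories hold large numbers of flower
photographs whose color is described in free text. Text search for a color
word like "blue" retrieves images whose actual petal hues span a broad arc
of the color wheel, because describers apply the same word to anything from
cyan-leaning blues to magenta-leaning purples. Turning those photographs
into comparable, machine-readable color phenotypes requires (i) collapsing
an image's petal region to a single representative color, (ii) reducing
that color to the perceptual dimension describers actually disagree about —
hue — and (iii) mapping hue onto a small controlled vocabulary with stable
ontology identifiers, so annotations can be stored, searched and aggregated.
`petalhue` implements that pipeline end to end, together with a synthetic
generator that provides ground truth for every stage.

## The color model

An 8-bit sRGB triple $(R, G, B) \in \{0, \dots, 255\}^3$ (the scale used by
common photo editors) is converted to hue/saturation/value by the standard
hexcone formulas: $V = \max/255$, $S = (\max-\min)/\max$, and $H$ by the
piecewise 60°-sector rule, with $H \in [0^\circ, 360^\circ)$. When
$S = 0$ (gray, white, black) hue is mathematically undefined; `rgbToHsv()`
returns a *tagged* `NA` rather than a silent 0, and every classifier
branches on that tag. This matters in practice: petals containing
complementary colors average to gray, and a numeric pseudo-hue of 0 would
silently count such flowers as red.

Saturation and value are computed transiently and then discarded by the
survey pipeline. Brightness depends on display and exposure conditions, and
saturation mixes in the white/black content of the pigment; hue is the
component on which color-word disagreement concentrates.

### The bipolar hue scale

Because the survey of interest concentrates between blue (240°) and magenta
(300°), hue is linearized by cutting the circle at red and mapping

$$H_{\mathrm{bipolar}} = \frac{100}{360}\,H_{\mathrm{degree}} - 60,$$

so the scale runs from $-60$ (red, at 0°) through $-26.67$ (green),
$-10$ (cyan), $6.67$ (blue) and $23.33$ (magenta) up to $40$ at the
360° wrap; one bipolar unit is 3.6°. The transform is affine and strictly
increasing, `bipolarToHue()` is its exact inverse, and exact red — which
sits at both ends of the cut — is flagged (`redWrap()`) so display code can
render the conventional dual label `40/-60` while the transform itself
remains a function: 0° maps to $-60$, and 360° is accepted as the closed
upper wrap mapping to $40$.

```{r}
bipolarLabel(hueToBipolar(c(0, 60, 120, 180, 240, 300, 360)))
```

Historical tables print two of these values with coarser rounding (magenta
as 20, green as $-30$); the vocabulary registry stores those display
strings verbatim for fidelity, but all numeric logic derives from degrees.

## The color vocabulary

`colorVocabulary()` holds fourteen terms. Eight *principal* colors (red,
magenta, purple, blue, cyan, green, yellow, orange) are anchored at exact
RGB/HSV definitions and PATO URIs. Six *intermediate* terms
(greenish-yellow, yellowish-orange, orangish-red, reddish-purple,
purplish-blue, bluish-green) name hue ranges with PATO or EOL URIs. Three
design points were genuinely open and were resolved as follows:

* **Half-open ranges.** The published range endpoints are printed as bare
  pairs; we adopt $[lo, hi)$ so that the six ranges partition
  $[0^\circ, 360^\circ)$ with no gap or overlap (a class validity
  invariant, exhaustively tested). A hue exactly at 240° is therefore
  purplish-blue, not bluish-green. The bluish-green range
  $[120^\circ, 240^\circ)$ is kept exactly as published even though it is
  twice as wide as the others.
* **Purple vs magenta.** Both terms are kept in the registry for URI
  fidelity (purple is the half-value form of the 300° hue), but hue-level
  classification treats them as synonymous: `principalTermForHue()` never
  returns purple.
* **Nearest-anchor labelling.** No published rule assigns a principal name
  to a non-anchor hue, so `principalTermForHue()` uses circular
  nearest-anchor distance with ties broken toward the lower anchor hue
  (270°, equidistant from blue and magenta, resolves to blue). This rule is
  this package's choice and is documented as such.

`annotateColor()` bundles the full derivation — HSV, bipolar value, both
terms, both URIs, achromatic flag — into one serializable record.

## Region averaging

`averageRegionColor()` reproduces, as a plain per-channel arithmetic mean,
the photo-editor workflow of copying a petal selection and resizing it to a
single pixel. Two deliberate simplifications: the mean is unweighted and
kernel-free (resize filters add proprietary interpolation weights whose
effect is confined to region edges), and averaging happens directly on the
stored 8-bit sRGB values without linear-light conversion, which is what a
default sRGB-document resize does and what the recorded RGB numbers
represent. Channels are rounded half away from zero to integers.
`averageMultiRegion()` combines several petal samples either with equal
region weights (default; the behaviour when equal-sized samples are pasted
in a row) or pooled by pixel count (faithful when sample areas differ);
which of the two a historical measurement used is unknowable, so both are
exposed. Masks are supplied externally as single-channel PNGs or run-length
text files; no interactive selection tool is provided.

## The survey pipeline

Records (`image_id`, `species`, `locality`, `cultivated`, `r`, `g`, `b`)
are read from tab-delimited files with strict validation: missing RGB rows
are dropped with their line numbers reported; malformed or out-of-range
channels are errors naming the line.

**Sampling.** `selectSample()` keeps up to 10 images per species (the
survey convention), prioritizing breadth over localities: localities are
ordered wild-before-cultivated, stably by first appearance; one image is
taken per locality in that order, then a second per locality, round-robin,
until the cap. Which image is a locality's "first" is drawn from a seeded
generator, since record order carries no meaning; the seed is a required
argument. A locality counts as cultivated only if all its records are
(unknown status defaults to wild).

**Statistics.** Medians are *linear* on hue degrees, not circular: the
analysis deliberately flattens hue onto the bipolar axis, where white/gray
and wrap-adjacent flowers are visible as outliers rather than absorbed by a
circular statistic. Achromatic records are excluded from every hue
statistic but counted and reported separately. The overall median is
per-image, not per-species. Bipolar medians are derived from the unrounded
degree median; printed renderings use nearest-degree and two-decimal
precision. `hueHistogram()` bins species medians into left-closed bins of 5
bipolar units (18°) by default — the bin width of the survey figure is not
on record, so it is configurable — with the last bin closed so the 360°
wrap is countable.

## The synthetic generator

`generateSurvey()` emulates the statistical structure the analysis assumes:
species hue centers drawn from a normal distribution on degrees (default
mean 270°, sd 25°, concentrating records between blue and magenta, the
regime the survey analysis addresses), within-species noise (default sd
10°, a realistic between-photograph spread for one species) added and
wrapped to $[0^\circ, 360^\circ)$, full saturation and value so that hue is
the only informative channel, a small achromatic fraction (default 5%)
of equal-channel gray records emulating white flowers, and round-robin
locality metadata with a 30% cultivated fraction. Wrapped-normal noise is
used instead of von Mises for simplicity; at these small standard
deviations the difference is negligible. `groundTruth()` replays the same
seed and returns the exact centers and the realized medians *before* 8-bit
RGB quantization; the pipeline run on the written file matches those
realized medians up to the quantization bound (below 0.3° at full
saturation and value, verified exhaustively for integer hues).
`renderFlower()` draws stylized radial-ellipse flowers with a known petal
HSV color, seeded Gaussian channel noise, and a mask covering exactly the
petal pixels.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real photographs: illumination and exposure
variation, camera color profiles and post-processing, partially
desaturated petals, multi-colored petals, segmentation error in the petal
mask, and species imbalance in image counts. Results on real survey data
inherit all of those error sources on top of the pipeline's arithmetic.

## Numerical choices and test scale

* Display rounding is half-away-from-zero at the precision of the table
  being reproduced; internal computation is full precision throughout.
* Degenerate inputs fail loudly: empty masks, mismatched dimensions,
  channels outside $[0, 255]$, hues outside $[0^\circ, 360^\circ]$, an
  undefined hue with positive saturation, and classification of an
  achromatic color are all explicit errors.
* The test suite verifies RGB→HSV against an independently coded hexcone
  oracle on a 4096-triple grid, round-trips a dense hue grid, scans all
  integer hues for the range partition and the quantization bound, and runs
  parameter recovery on surveys of 100 species × 10 images (500 species for
  the overall-median check, where the median's sampling error must be well
  inside 1°). These sizes make every property check sharp while keeping the
  whole suite fast.

## Limitations

The package annotates *hue only*; lightness- and saturation-qualified terms
("light blue", "saturated blue") are out of scope, as are wavelength-based
color definitions, ICC/Exif color management, automatic petal segmentation,
and any querying of remote trait repositories. Linear medians are
appropriate for surveys concentrated away from the red cut; a survey
centered near 0°/360° would need the cut moved or circular statistics.
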