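---
title: "Semi-automated molding-plate design for unilateral cleft lip and palate: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated molding-plate design for unilateral cleft lip and palate: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namplate)
```

## The clinical problem

Nasoalveolar molding (NAM) shapes the alveolar segments of a newborn with
a unilateral cleft lip and palate before surgical lip closure.  A passive
intraoral plate is worn from the first days of life; as the maxilla
grows, the plate guides the greater and smaller alveolar segments toward
a harmonic arch and narrows the cleft.  Classically each plate requires
a fresh impression.  A virtual workflow instead digitizes a single
plaster cast and derives the whole series of plates from it: the
alveolar crest is detected automatically, the dental arch is summarized
by a fitted ellipse, the cleft is bridged virtually along that ellipse,
and successive plates apply a monthly relative growth factor with a
progressive virtual closure of the cleft channel.

`namplate` implements this pipeline end to end, together with the
landmark-based morphometrics (ten stored landmarks, seven inter-landmark
distances, seven-column cohort summaries, exact Wilcoxon tests) used to
evaluate molding therapy on pre/post casts.

## Synthetic anatomy: what it emulates

No patient casts ship with the package.  The generator
(`generateCleftMaxilla()`) builds a parametric neonatal cleft maxilla as
a watertight height-field solid on a structured polar grid:

* the **arch** is an alveolar ridge of Gaussian cross-section
  (`ridgeHeight`, default 6 mm; `ridgeHalfwidth`, 3 mm) swept along a
  planar ellipse arc with semi-axes `ellipseA` = 20.7 mm
  (anterior-posterior) and `ellipseB` = 18.3 mm (transversal) over
  ±110° of arc;
* the **cleft** interrupts the ridge over an angular span whose chord
  equals `cleftWidth` (default 10.8 mm) centered at `cleftAngle`
  (default 25° to the patient's left);
* the **palatal vault** depresses the interior by `palateDepth` (4 mm);
  a flat base closes the solid, mimicking the trimmed underside of a
  plaster cast;
* `noiseSigma` adds Gaussian vertex jitter emulating scanner roughness
  without changing topology; `segmentShift` can displace the smaller
  segment.

The defaults were chosen once so that the seven ground-truth landmark
distances fall at the median of published neonatal unilateral-cleft
reference dimensions (arch length A–MT ≈ 27.8 mm, tuberal width
T–T′ ≈ 34.4 mm, transversal L–L′ ≈ 31.7 mm, anterior cleft
SA–SA′ ≈ 10.8 mm, posterior cleft SD–SD′ ≈ 21.8 mm); the `archSpan` of
110° and the axis lengths follow algebraically from the first three of
these.  Landmarks are placed by construction (A at the anterior crest of
the greater segment, SA/SA′ at the cleft margins on the crest, L/L′ at
±60° of arc, T/T′ at the arch ends, P on the midline behind A, SD/SD′
flanking the posterior hard-palate cleft at 0.62 of the arch radius,
`sdWidening` = 11 mm wider than the anterior cleft).

What the generator does **not** emulate: real mucosal texture,
scan-merge artifacts, bilateral clefts, out-of-plane arch warp beyond a
rigid smaller-segment shift, and the anatomical (rather than geometric)
definition of the sulcus lateralis.  Passing tests therefore demonstrate
correctness of the geometry pipeline and its statistics on idealized
casts, not clinical accuracy on scanned patients.

`generateCohort()` draws per-subject parameters from truncated normal
distributions and emulates the paired two-impression design: impression
1 at therapy start, impression 2 after a per-subject multiplicative arch
growth and a configured cleft-width reduction.

## Crest detection and ellipse fitting

`detectRidge()` composes three steps.

1. **Occlusal frame** (`computeOcclusalFrame()`): the occlusal normal is
   the least-variance principal direction of the vertex cloud, refined
   and sign-fixed by the cast's planar cut base — the dominant coplanar
   cluster of face normals is oriented downward.  This keeps the crest
   above the palatal vault and makes the frame equivariant under rigid
   motion of the cast.
2. **Crest extraction** (`extractCrest()`): vertices above a height
   threshold (10th percentile + `heightFrac` = 0.55 of the P10–P98
   vertical extent) are binned by angle about their in-plane centroid
   (`nBins` = 180); each bin's crest point is the highest candidate in
   the radial band, ties broken by smaller radius then lower vertex
   index, so detection is deterministic.  Bins whose best point sits
   well below the typical crest height (median − max(0.5 mm, 6 MAD))
   are discarded: this trims the tapered arch ends and cleft-margin
   ramps.  Runs of ≥ `minGapBins` (3) empty bins split the crest into
   segments; shorter runs are treated as sampling noise, which matters
   when the angular bins are finer than the mesh edge length.  The
   posterior opening of the horseshoe is always the widest empty run;
   the cleft is the second one.
3. **Ellipse fit** (`fitEllipse()`): a direct least-squares conic fit
   constrained to ellipses (the numerically stable partitioned
   formulation), on centered/scaled coordinates — the fit is exactly
   equivariant under similarity transforms, so conditioning costs no
   accuracy.  The residual is geometric: true point-to-ellipse
   distances by per-point Newton iteration on the stationarity
   condition, started from a 90-point parametric scan.

The detection result serializes to editable JSON
(`writeDetection()`/`readDetection()`): the "confirm and correct" step
of an interactive workflow becomes edit-and-rerun, which is scriptable
and testable.  The crest detector is a self-contained design honoring
the observable contract (crest polylines, fitted ellipse, user
correction point); it is not a port of any published detector.

## Plate construction

* **Bridging** (`bridgeGap()`): vertices in the gap channel are raised
  along the occlusal normal to a loft whose spine follows the ellipse
  arc — the "guiding track" for alveolar growth.  The target height
  interpolates the near-margin crest heights (median of the five crest
  points adjacent to each margin, robust against the margin ramps).
  Topology is untouched: watertightness is preserved and vertices
  outside the channel stay bit-identical.  A `targetGap` > 0 leaves a
  central channel of that chordal width open.
* **Shell** (`buildPlate()` / `offsetShell()`): the intaglio is the
  anatomical surface region itself — upward-facing faces inside the
  arch footprint plus the vestibular skirt down to `trimHeight` (4 mm)
  below the crest — so intaglio fidelity is exact by construction.  The
  outer surface offsets each vertex by `thickness` (2 mm) along its
  area-weighted normal; walls close each boundary loop.  Where creases
  sharper than the thickness would fold the outer sheet, the offset
  direction field is smoothed over the neighborhood, and as a last
  resort blended toward the mean region normal (a constant-direction
  offset is a translation and cannot fold); if more than 20 % of faces
  fold at the first attempt the thickness is judged incompatible with
  the geometry scale and the build errors out.  The offset magnitude is
  never reduced, so the wall measured along the offset direction always
  equals the nominal thickness.
* **Ventilation hole** (`addVentilationHole()`): exact surgery on the
  structured shell — matching intaglio/outer face pairs inside the hole
  radius are removed and the rims stitched.  Genus increases by exactly
  one and the removed volume is the prism between the surfaces.
* **Retention pin** (`addRetentionPin()`): a capped cylinder anchored on
  the outward-facing skin at the pin arc position, tilted anteriorly
  45° from the occlusal plane, embedded just deep enough that its
  lowest rim stays inside the shell wall, then united with the plate by
  the boolean engine.  A fully embedded pin returns the plate unchanged;
  a detached pin is a placement error.
* **Boolean engine** (`booleanMesh()`): voxel-backed — signed z-distance
  fields sampled per solid by column ray casting on a shared grid
  (origin offset by an irrational pitch fraction so flat faces never
  coincide with grid planes), combined by min/max, and contoured by
  marching tetrahedra, which cannot produce the ambiguous cases of
  marching cubes and therefore always yields a watertight surface.
  Iso-vertices are kept strictly off grid nodes so welding never
  creates degenerate faces.  Accuracy is sub-pitch vertically and about
  one pitch (default 0.2 mm) laterally.  The hole deliberately does not
  use this engine: the exact surgery gives exact volume and genus.
* **Smoothing** (`smoothPlate()`): Taubin λ/μ fairing (λ = 0.5,
  μ = −0.53).  Intaglio vertices are clamped to ≤ 0.05 mm so the fit is
  preserved; all other vertices carry a 0.2 mm displacement budget so
  fairing removes roughness without eroding the plate form — this is
  what keeps the volume change well under 1 % even at many iterations.

The pipeline order is bridge → shell → hole → pin → smooth: the hole
needs the structured shell, while the pin union remeshes the plate.

Thickness, pin and hole dimensions (2.0 / 1.5 × 10 / 1.0 mm) are
clinical placeholders, set in `plateSpec()`, not anatomically derived
values.

## Growth model and plate series

`planSeries()` targets, for plate *k* of `nPlates` (default 6, the
customary stock of devices planned from one impression), the detected
ellipse scaled by $(1+g)^{k\,\Delta w / 4.345}$ where `g` is the
monthly relative growth fraction, $\Delta w$ the plate interval in
weeks, and 4.345 = 365.25/12/7 weeks per month.  The default
`g` = 0.02/month is an explicit placeholder: the underlying
longitudinal growth value belongs to anatomical reference data not
shipped here, and every test uses a known synthetic `g` instead of
trusting the default.  Both semi-axes are scaled equally
(anisotropic growth is not modeled; the choice is configurable in the
sense that the warp accepts any target factor).  The linear closure
schedule leaves $(n-k)/(n-1)$ of the initial gap at plate *k*, reaching
zero at the last plate.

`generateSeries()` realizes each target by a radial warp of the cast
about the ellipse center — no displacement at the palatal center,
blending to full scaling at and beyond the crest — which implements
passive growth guidance without rotating the segments, then re-detects,
bridges to the target residual gap and runs the plate pipeline.
Segment-orientation and axis-monotonicity checks are evaluated on the
warped casts before bridging, because once the channel is bridged the
crest becomes continuous and per-segment measures are no longer
defined.

## Morphometrics and statistics

`computeDistances()` evaluates the seven distances A–MT, L–L′, SA–SA′,
T–T′, SD–SD′, A–P and SA–SD, with MT always derived as the midpoint of
T–T′ and never stored.  `summarizeDistances()` produces the
seven-column cohort row (min, 1st quartile, median, mean, 3rd quartile,
max, SD) with type-7 quartiles (linear interpolation of order
statistics) and the n−1 sample SD; values stay at full precision and
`formatSummaryRow()` applies the one-decimal presentation rounding.
Because the quartile convention of the published tables is not stated,
quartile cells are not used as numerical targets anywhere.

`wilcoxonSignedRank()` excludes zero differences by default (classical
Wilcoxon; Pratt's ranking is available and recorded in the output) and
uses midranks for ties.  The exact two-sided p-value is
$P(|W - E[W]| \ge |w_{obs} - E[W]|)$ under the null of all $2^n$ sign
assignments of the ranked absolute differences; it is computed by
generating-function convolution over doubled midranks, which is
algebraically identical to the full enumeration (the test suite checks
this against a literal enumeration up to n = 10), with n ≤ 25 enforced.
The asymptotic mode uses the normal approximation with tie-corrected
variance and continuity correction.  `wilcoxonRankSumExact()` provides
the exact two-group counterpart (all $\binom{N}{n_1}$ rank
assignments, N ≤ 20) because "exact Wilcoxon test" can denote either
variant in clinical reports.  `boxplotStats()` emits the box (1st–3rd
quartile), median bar, 1.5-IQR whiskers and outliers as plot-ready
numbers.

## Numerical choices and degenerate inputs

* Vertex merge tolerance 1e-6 mm: below scanner resolution, above
  float32 noise; binary STL stores float32, so round trips are exact to
  1e-5 mm.
* `cleftWidth = 0` produces a continuous arch: SA and SA′ coincide,
  detection reports one crest and an empty gap, and bridging is the
  identity.
* All-zero paired differences, empty landmark files, meshes with
  repeated vertex indices, truncated STL files and holes placed off the
  plate raise typed errors rather than propagating nonsense.
* Crest ties are broken deterministically (height, then radius, then
  vertex index); every stochastic path is seeded, and the generator
  restores the caller's RNG state.

## Problem sizes used in the checks

The shipped tests and the acceptance script run on meshes of 0.5–0.9 mm
edge length (roughly 8k–30k faces), a 20-subject recovery cohort, a
100-subject distribution check at coarse resolution, a 6-plate series
without the pin stage (the pin union is exercised separately on one
plate), and 100 null replicates for the type-I check.  These sizes were
chosen as the smallest at which the geometric tolerances of interest
(0.05 mm intaglio fidelity, 0.5 mm closure scheduling, 5 % axis
recovery) are comfortably resolved.

## Known limitations

* The crest detector assumes a cast-like solid with a dominant planar
  underside for frame orientation; headless fragments or unclosed scans
  may need a manually edited detection JSON.
* The vertex-normal offset is not a true Minkowski offset: in grooves
  narrower than twice the thickness the outer sheet bridges over and
  the local wall, measured perpendicular to the steep groove walls, can
  be thinner than nominal.
* The boolean engine remeshes at voxel resolution; volumes and
  watertightness are accurate, but the pin union output is much denser
  than the structured shell.
* Clinical parameters (growth rate, pin/hole dimensions, trim line) are
  configuration values, not measurements.
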