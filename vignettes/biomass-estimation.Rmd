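---
title: "Estimating biovolume and biomass of small invertebrates from silhouettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biovolume and biomass of small invertebrates from silhouettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invermass)
```

## The problem

Individual body mass of small invertebrates (body lengths from tens of
micrometres to a few centimetres — mites, copepods, trematodes,
acanthocephalans, small annelids) is a basic currency of community and
ecosystem ecology, yet specimens are usually too light to weigh singly and
weighing is destructive. The practical route is indirect: estimate body
*volume* from images or linear measurements, then convert to mass with a
measured tissue density $\rho$ (g ml$^{-1}$):

$$ m\,[\mathrm{mg}] = V\,[\mu\mathrm{m}^3] \times \rho \times 10^{-9}. $$

`invermass` implements a family of volume estimators spanning the
morphologies such organisms present, the calibration steps they require,
and the statistics used to compare estimators against a directly weighed
benchmark.

## The estimators

**Flat-section method** (dorso-ventrally flattened bodies, e.g. a
trematode). Volume is ventral-view area times mean dorso-ventral thickness,
$V = A \,\bar t$, with `area_um2()` counting object pixels in a binary
silhouette and `thickness_profile()` averaging thicknesses measured at
anatomical landmarks. Salient organs such as a ventral sucker are added as
their own $A \times t$ term (`add_structure_volume()`).

**Solid-of-revolution method** (subcircular cross-sections, e.g. an
acanthocephalan trunk). The silhouette is rotated so its long axis lies
along the image columns; each one-pixel-wide column with $d$ object pixels
is treated as a circular slice of volume $\pi (d/2)^2 \cdot 1\,$px, and

$$ V_{\mathrm{px}^3} = \sum_x \pi \left(\frac{d_x}{2}\right)^2, \qquad
   V_{\mu\mathrm{m}^3} = V_{\mathrm{px}^3} \times r^3 $$

for a scale of $r$ µm px$^{-1}$ (`revolve_volume()`). The slice model
assumes rotational symmetry about the horizontal axis, so the method suits
straight, symmetrical, convex bodies; `revolve_volume()` warns when hull
solidity drops below 0.9.

**Composite method** (complex morphologies, e.g. a caligid copepod). The
body is partitioned by the user into flat parts (body regions of similar
thickness, appendages — with a multiplicity of 2 for the measured member of
a bilateral pair) and revolution parts (egg strings); `composite_volume()`
sums `part_volume()` over the declared `body_part()`s. Partitioning is
declared, not inferred: automatic anatomical segmentation is out of scope.

**Clay-model scaling.** An enlarged clay replica of the specimen displaces
a measurable water volume $V_m$; isometry gives the specimen volume
$V_s = V_m (L_s/L_m)^3$ (`clay_scaled_volume()`), with a warning if the
"model" is smaller than the specimen.

**Geometric approximations.** The classical proxies: an ellipsoid
$V = \frac{\pi}{6} BL \cdot BW \cdot BD$ and a cylinder
$V = \frac{\pi}{4} BW^2 BL$ from maximum body length and width
(`ellipsoid_volume()`, `cylinder_volume()`). Field protocols usually set
the unmeasured depth $BD = BW$; for a flattened animal of true depth $D$
this inflates the ellipsoid by exactly $BW/D$, and the cylinder by a
further factor 1.5 — the mechanism behind the several-fold overestimation
these proxies produce.

## Calibration

`calibrate_focus()` turns a fine-focus drive into a depth gauge: focusing
on both faces of a reference slide (100 µm by default, overridable) and
averaging the knob-division counts over repeats gives µm per division;
`thickness_from_divisions()` then converts specimen readings.
`density_from_trials()` averages mass/displaced-volume quotients over
trials; the quoted error is the **half-range** of the quotients — a spread
measure chosen because trials are few (often two), flagged as such rather
than a standard error. `pooled_mean_mass()` implements the set-level mean
$(\sum_k w_k/n_k)/K$ for specimens weighed in pooled sets, generalized to
any number of sets; note it equals the individual-weighted mean only for
equal set sizes.

## Alignment: which axis to revolve about

The formal alignment rule in image-analysis workflows is "rotate until the
Feret (maximum caliper) diameter is horizontal", and `feret_angle()` /
`align_to_feret()` implement it exactly, by brute force over convex-hull
vertex pairs (silhouettes are desk-scale, so the exact search is cheap;
ties go to the smallest absolute angle). However, the maximum caliper of a
low-aspect shape is its *diagonal*: for a 200 × 100 rectangle the Feret
direction lies 26.6° off the symmetry axis, and revolving about it biases
the volume by about +2%. The package therefore defaults to the
**principal axis** of the object pixels (`principal_angle()`,
`orientation = "principal"`) as the revolution axis. The two rules coincide
for elongated convex bodies — the organisms the method targets — while the
principal axis remains unbiased for compact shapes;
`orientation = "feret"` restores the literal rule.

## Numerical choices

- **Rasterization** (synthetic shapes): a pixel is object iff its center
  lies inside the ideal shape, which keeps pixel-count area unbiased as
  resolution grows.
- **Rotation**: nearest-neighbour lookup on pixel centers about the object
  centroid, re-binarized — no gray halos, object-pixel count conserved to
  well under 1% for shapes of ≥ 10³ pixels.
- **Slice diameter**: the *count* of object pixels per column (default),
  robust to the interior holes segmentation can introduce; the
  top-to-bottom *extent* is available (`diameter_mode = "extent"`) and is
  by construction insensitive to interior holes.
- **Thresholding**: Otsu's between-class variance criterion computed on
  the histogram of observed integer intensities, which makes the automatic
  split deterministic and exactly invariant under adding a constant to all
  intensities; a fixed level reproduces a manually chosen ImageJ threshold.
  A constant image is a degenerate-threshold error, never a guess.
- **Connectivity**: components are 8-connected, matching common blob
  analysis defaults; size ties break to the topmost-leftmost component.
- **Mixed model p-values** use a residual-df approximation
  ($N - p - q + 1$) and are labelled approximate; estimates, standard
  errors and t-values are the quantities to interpret. The balanced-design
  identity (fixed effects = differences of method means) is kept as an
  independent oracle in the test suite rather than as the implementation.

## What the synthetic generator emulates — and what it does not

`make_population()` produces specimens with *analytically known* volumes so
every estimator can be validated without external data:

- **flatworm** — a trematode-like body modelled as a triaxial ellipsoid
  (axes $BL \times BW \times D$), $BL$ log-normal around 6 mm (4–8 mm),
  $BW = BL/4$, true depth $D = BW/4$, imaged at 10 µm px$^{-1}$, tissue
  density 1.06 g ml$^{-1}$. Landmark thicknesses are drawn around the true
  mean dorso-ventral depth of an ellipsoid ($\tfrac{2}{3}D$, 2% CV),
  emulating landmarks chosen to be representative of mean thickness.
- **worm** — an acanthocephalan-like prolate spheroid, $BL$ log-normal
  around 50 mm, aspect 10:1, at 25 µm px$^{-1}$, density 1.05 g ml$^{-1}$.
- **copepod** — a partitioned body: cephalothorax, fourth pedigerous
  somite and genital–abdominal complex as flat areas, eight appendage
  pairs (multiplicity 2), and two egg-string cylinders, at 5 µm px$^{-1}$,
  density 1.15 g ml$^{-1}$, all scaled by a common log-normal size factor.

Each specimen also carries a simulated clay-model record whose displaced
volume is rounded to a graduated-cylinder reading (0.05 or 0.5 ml), so the
cube-law path is exercised with realistic read-off error.

The generator emulates geometry and measurement resolution, **not**
photographic reality: there is no uneven illumination, no out-of-focus
blur, no segmentation ambiguity, no body curvature, and the direct
benchmark is the exact analytic mass rather than a balance reading.
Passing tests therefore demonstrate correctness of the estimators and the
size of their discretization errors, not robustness to image-acquisition
artefacts. `perturb()` (boundary jitter, interior holes) probes the first
step beyond ideal silhouettes.

## Validation at a glance

The test suite and `scripts/acceptance.R` recompute, from scratch, at the
sizes noted:

- disk r = 100 and r = 200 px revolve to the sphere volume within 0.03%
  (tolerances 1.5% / 0.8%);
- a 200 × 100 px rectangle reproduces the analytic cylinder exactly and
  matches `cylinder_volume()`;
- a 150 × 60 px ellipse matches the prolate spheroid within 0.2% (2%);
- pre-rotating any of these by 10–80° and re-aligning changes the volume
  by < 1% (3%);
- on a 20-specimen flatworm population the flat-section and clay methods
  track the true mean mass within 0.1%, while the BD = BW ellipsoid
  overestimates by the designed factor 4 (and the cylinder by 6); the
  Bonferroni-corrected one-sample t-tests flag exactly the two geometric
  methods;
- a 20-specimen worm population is recovered by the revolution method
  within 0.2%, and a 20-specimen copepod population by the composite
  method to rounding;
- mixed-model estimates on balanced tables equal column-mean differences
  to 10⁻⁸, and a seeded 4-method × 20-individual simulation recovers its
  offsets well within 3 standard errors.

## Known limitations

Curved ("bent") bodies are not straightened before revolution, so strongly
curved specimens overestimate; appendage-rich silhouettes should use the
composite route rather than a single revolution; optical depth through
mounting media is taken at face value (no refractive-index correction);
and the half-range density error is a coarse uncertainty for $\ge 3$
trials. Whether to double per-pair appendage volumes is left to the
`multiplicity` argument (default 2 when declared as a pair member) since
measurement conventions differ between studies.
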