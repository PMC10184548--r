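---
title: "Methods: endocast volumetrics and sensory inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endocast volumetrics and sensory inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoneuro)
```

`paleoneuro` computes the standard derived quantities of comparative
palaeoneurology from per-specimen measurements and surface meshes. This
vignette is the package's account of those methods: the models and their
assumptions, the parameters that matter, the numerical conventions, and what
the validation machinery does and does not establish.

## Endocast volumetrics

A reptilian endocast is the cast of everything inside the braincase — brain,
dura, venous sinuses — so its volume is an upper bound on, not a measurement
of, brain volume. `mesh_volume()` treats the segmented surface as ground
truth and computes the enclosed volume by the divergence theorem, summing the
signed tetrahedra `det(v0, v1, v2)/6` spanned by each face and the origin.
This is exact for any closed, consistently oriented triangle surface,
invariant under rigid motion (the tests require 1e-9 relative agreement under
random rotation and translation), and additive over disjoint closed
components — a segmentation split across braincase fragments can simply be
concatenated.

Conventions:

* **Units.** Vertices are millimetres; volumes are reported in cm³, the unit
  of the comparative tables. The single mm³→cm³ division happens at output.
* **Watertightness.** Strict mode (default) refuses a mesh with boundary
  edges, reporting how many. Permissive mode (`strict = FALSE`) computes the
  signed sum anyway, warns, and flags the result — real fossil segmentations
  often carry small holes, and a flagged approximation is more useful than a
  refusal, but the flag keeps it out of silent downstream use.
* **Orientation.** Surface formats, STL especially, guarantee nothing about
  winding consistency. Before refusing a mesh, face orientation is propagated
  deterministically outward from the first face of each connected component;
  only genuinely non-orientable input errors out. A globally inverted mesh is
  harmless since the absolute value is taken.
* **Welding.** STL stores vertices per facet; duplicates are welded at
  1e-6 mm by coordinate quantisation, which is deterministic and far below
  any CT voxel size (tens of micrometres at best).
* **Neurovascular exclusion.** Comparative endocast volumes conventionally
  exclude neurovascular features. That is a segmentation-time decision; the
  package documents it but cannot enforce it on a finished mesh.

`linear_distance()` and `polyline_length()` are the calliper primitives for
straight and curved measurements (e.g. duct lengths along a centreline). A
100-point discretised quarter circle recovers its arc length to 0.001%.

## Body mass and encephalisation

Body mass comes from the minimum femoral circumference `FC` (mm) under the
developmental-mass allometry for bipeds:

$$M_{Bd} = 10^{\,2.749\,\log_{10}(\sqrt{2}\,FC)\; -\; 1.104}\ \text{g}.$$

The √2 factor maps the femoral circumference onto the combined stylopodial
circumference scale of the underlying quadrupedal regression; dropping it
changes a 350 mm femur from ~2011 kg to ~776 kg, so the factor is load-bearing
and is pinned by a test. The function is a pure power law (exponent 2.749),
which the suite checks to 1e-9 relative, along with its analytic inverse.

The reptile encephalisation quotient is observed brain mass over the mass
expected for a non-avian reptile of the same body mass:

$$REQ = \frac{M_{Br}}{0.0155\,M_{Bd}^{0.553}},$$

masses in grams, brain mass excluding the olfactory tract and bulbs. Because
non-maniraptoriform dinosaur brains did not fill the endocranial cavity,
brain mass is taken as a *fill fraction* of endocast volume at a brain-tissue
density of 1 g/cm³ (density near unity makes volume and mass
interchangeable). The two conventional fractions, 37% and 50%, are defaults
in `pipeline_config()`, not constants: they are assumptions, and bracketing
with both is the honest presentation. REQ is linear in the fill fraction, so
intermediate assumptions interpolate exactly.

## Hearing

Cochlear duct length tracks hearing sensitivity and range across living
reptiles and birds. The proxy is the endosseous cochlear duct length scaled
to basicranial length and log-transformed, `x = log10(ECD/BCL)`, with two
linear calibrations:

* best hearing range: `y = 6104.3 x + 6975` Hz,
* mean best frequency: `y = 3311.3 x + 4000.8` Hz.

The log base is not stated in the calibration's usual citation trail; base 10
is forced here because it alone reproduces the published comparative values
(e.g. 2538/1594 Hz for the *Baryonyx* inputs 19.6/104.5 mm), and that
reproduction is pinned by tests. BCL — the anteroposterior distance from the
anterior basisphenoid limit (excluding the cultriform process) to the
posterior occipital-condyle margin — is accepted as a measured input, never
computed from meshes. Records lacking BCL are carried as literature values
flagged non-recomputable; nothing is imputed.

Most rows of the packaged auditory table rederive exactly from their printed
1-decimal inputs. Three literature rows differ by 1 Hz (their sources
evidently used unrounded measurements); they are flagged `recomputable =
FALSE` and the suite asserts only that they rederive within 2 Hz.

## Olfaction and midbrain elongation

The olfactory ratio is the longest olfactory-bulb diameter (any orientation)
as a percentage of the longest cerebral-hemisphere diameter. Raw ratios scale
with body size, so `log_olfactory_point()` returns `log10(ratio %)` and
`log10(body mass g)` for placement against a reference regression. The
published theropod regression's coefficients are not reprinted anywhere this
package could verify, so `plot_olfactory_space()` accepts a user-supplied
slope and intercept rather than hard-coding one, and the package deliberately
does not compute "predicted ratio for a theropod of this size".

A specimen without postcrania cannot have its mass estimated; the report
builder lets one specimen borrow another's mass estimate
(`borrow_mass_from`), recording the provenance in the report — the standard
size-proxy convention for closely comparable taxa.

The midbrain elongation index is midbrain length (anterior floccular-lobe
border to dorsal-expansion peak) over "medulla" length (foramen magnum to
trigeminal trunk). The quotation marks are deliberate: the dural envelope
obscures the real medulla, and the denominator approximates the
rhombencephalon.

## Packaged reference tables

Five comparative tables ship as UTF-8 CSV under `inst/extdata/`, one row per
printed row, with a `source` column, ranges stored as min/max pairs (never
midpoints), thousands separators stripped, and `NA` for missing cells.
Flexure angles are stored-only: there is no reproducible protocol for
measuring them, so the package will not pretend to recompute them.

Each derived-value row carries a `recomputable` flag, set `TRUE` only where
this package's operations reproduce *every* printed derived value from the
printed inputs at the printed precision. `audit_reference_tables()` performs
that rederivation en masse and is run in the test suite; "at printed
precision" means within half an ulp of the printed value, because different
source papers round decimal ties in different directions (one table prints
half of 150.5 as 75.3; another prints 37% of 95 as 35.1). Rows that fail —
a misreported pair of volume columns acknowledged in the source, a truncated
value, ranges with unstated pairings, rows with no printed inputs — are
stored as printed, flagged `FALSE`, with the reason in a `note` column.

## Reporting and rounding

`specimen_report()` computes everything derivable from what a specimen has,
and reports the rest as "not computable" with the missing inputs named —
silence is never a result. Stored values keep full precision; rounding is
presentation-only and centralised in one profile (`rounding_profile()`:
frequencies to the nearest Hz, REQ to 1 decimal, ratios to 2, percentages to
1). Ties round half away from zero, matching the dominant convention of the
comparative tables. Report serialisation is deterministic: identical inputs
give byte-identical JSON.

## The synthetic-data generator

Every stage is testable without scan data:

* `make_ellipsoid_mesh(a, b, c, subdivisions)` builds a geodesic sphere — an
  icosahedron refined by `subdivisions` 4-to-1 passes with new vertices
  projected to the sphere — scaled to the semi-axes, and returns the analytic
  volume 4/3·π·abc alongside. As an inscribed polyhedron its mesh volume is
  strictly below the smooth volume and converges monotonically: 0.86% low at
  three passes, 0.22% at the default four (5120 faces), which is what the
  0.5%-agreement tests rely on.
* `make_tube_mesh(path, radius, segments)` sweeps an inscribed regular
  polygon along a polyline with parallel-transport frames and flat end caps,
  watertight by construction. For a straight path the enclosed volume is
  exactly the prism volume, a factor `sin(x)/x` (x = 2π/segments) below
  π·r²·L — 0.64% at the default 32 segments, inside the 1% cylinder-agreement
  test. A heuristic warns when the radius exceeds the local turning radius of
  a path corner (mitre self-intersection).
* `make_specimen_cohort(n, seed, ranges)` draws measurement sets log-uniformly
  within ranges spanning the packaged comparative tables, and stores
  ground-truth derived values computed *inline from the closed forms* —
  deliberately not by calling the pipeline — so generator and pipeline check
  each other to 1e-9 relative on cohorts of 100+.

Two generator choices are worth justifying. Log-uniform sampling is the
scale-free choice for quantities spanning orders of magnitude (body masses
here cover ~kg to tonnes). And the cochlear pair is sampled as BCL times a
log-uniform ECD:BCL ratio over the empirically observed span (0.156–0.43),
with rejection until ECD also lands in its range — independent draws of the
two lengths would produce anatomically impossible ducts longer than the
basicranium; tying the ratio makes the monotone frequency bounds real (all
generated best ranges fall in roughly 2050–4740 Hz, inside the observed
2000–4800 Hz band of the comparative table).

What the generator does **not** emulate: CT artefacts, plastic deformation,
disarticulation, segmentation noise, or realistic endocast shape. Passing the
synthetic suite therefore demonstrates that the arithmetic chain is correct
and self-consistent, not that measurements taken from a damaged fossil are
accurate — the dominant error source in practice is upstream of this package,
in segmentation and measurement-landmark choices.

## Problem sizes and determinism

The whole validation suite is desk-scale by design: the published quantities
it reproduces are closed-form evaluations of printed measurements, so the
tests and the acceptance script run in seconds. Mesh property tests use
2–4 refinement passes (80–5120 faces) and cohorts of 100–200 specimens, sizes
at which the discretisation bounds above already bind. All randomness
(rotations, cohort draws) flows through explicit seeds; `withr` scopes them
so nothing leaks into the user's session.

## Known limitations

* An endocast volume is not a brain volume; the fill fractions are
  assumptions bracketing an unknown, and REQ inherits body-mass error
  (typically from damaged or incomplete femora) with no uncertainty
  propagation — the comparative convention this package follows reports point
  values.
* The hearing calibrations have known critiques; no alternative estimator is
  implemented, so results should be read as "under the standard
  calibration".
* Mesh repair is limited to orientation propagation; hole filling and
  self-intersection removal belong in dedicated mesh software.
* The olfactory reference regression is user-supplied; without it the package
  only positions points, it does not classify acuity.
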