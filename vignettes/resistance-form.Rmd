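---
title: "Methods: frustum geometry, groove augmentation and the half-arcsine resistance limit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frustum geometry, groove augmentation and the half-arcsine resistance limit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistform)
```

## The preparation model

The simulated tooth preparation is a rectangular-based frustum: a block of
mesiodistal width $W$ and buccolingual length $L$ whose four axial walls
(mesial, distal, buccal, lingual) are inclined from the path of insertion by
per-wall taper angles $\theta_M, \theta_D, \theta_B, \theta_{Li}$, leaving a
flat occlusal table at height $H$. The default footprint, $W = 5$ mm by
$L = 8$ mm with $H \in \{3, 4, 5\}$ mm and uniform tapers of
$\{2, 6, 12, 18\}^\circ$, is the premolar-sized study design returned by
`premolar_grid()`. The model deliberately has no anatomic features: no
finish-line geometry, rounded line angles, cement layer, friction or
elasticity. Every result is purely geometric.

Angles are accepted in degrees everywhere (the convention of the clinical
literature) and converted to radians internally. Tapers must lie in
$[0^\circ, 45^\circ)$ and a preparation whose occlusal table would close up
(`top_md` or `top_bl` $\le 0$) is rejected as *over-truncated* rather than
clamped.

## Surface area

Each wall is a planar trapezoid. For the mesial wall, say, the parallel
edges are the base edge of length $L$ and the top edge of length
$L - H(\tan\theta_B + \tan\theta_{Li})$, and the in-plane distance between
them is the slant height $H / \cos\theta_M$; the four walls meet at shared
slant edges with no corner rounding, and the occlusal table is the top
rectangle. This is the exact surface of the frustum, not an approximation:
`surface_area()` reports the per-wall breakdown, the occlusal area and the
total, which components sum to within $10^{-9}$ mm². At zero taper the
total reduces to the block closed form $2WH + 2LH + WL$, which gives the
desk-checkable 118.0, 144.0 and 170.0 mm² for the three study heights.

## Groove augmentation

Supplemental grooves are cut into the mesial and distal walls at the
buccolingual midpoint with a tapered fissure bur, idealised as a cone
frustum of tip radius $r_0$ (default 0.59 mm) and side half-angle $\varphi$
(default $3^\circ$), so the local radius at height $h$ above the tip is
$r(h) = r_0 + h\tan\varphi$.

The bur axis follows the path of insertion (vertical), tip level with the
cervical margin, and is seated so that it is embedded to exactly one radius
at the *occlusal* edge of the wall. This seating was a genuinely open design
choice, and it matters. Seating the bur to one radius at the *base* instead
makes the channel independent of the wall taper and makes the net gain
*fall* slightly as taper rises, which contradicts the qualitative behaviour
the analysis is meant to capture (gain growing with taper and height,
maximal for the tallest, most tapered wall). With occlusal-edge seating the
inclined wall advances toward the bur axis on the way down, so the axis lies
$e(h) = (H - h)\tan\theta_{wall}$ inside the tooth at height $h$: the
channel deepens toward the margin, and on tall strongly tapered walls the
bur is fully buried near the base. Per groove,

* channel surface $= \int_0^H 2\,\alpha_0(h)\, r(h) \sec\varphi \, dh$ with
  $\alpha_0 = \arccos(-e/r)$ clamped to $[\pi/2, \pi]$ (a half-cone exactly
  when the wall is vertical, a full buried circle when $e \ge r$);
* wall strip removed $= \int_0^H 2\sqrt{\max(r^2 - e^2, 0)} \sec\theta_{wall}\, dh$;
* occlusal half-disc removed $= \pi r(H)^2 / 2$ (at the table $e = 0$).

The integrands are exact and evaluated with `stats::integrate()` at a
relative tolerance of $10^{-10}$; the groove's new resisting wall sits
$L/2 - r_0$ from the lingual axis (3.41 mm for the defaults). Grooves wider
than the wall's top width are rejected. Two grooves are exactly twice one,
since the mesial and distal channels cannot overlap.

The printed reference magnitudes for groove areas rest on derivations
published elsewhere and not recoverable here; the replication report
therefore records deviations for them without pass/fail, while this model
reproduces their sign and every monotone trend.

## The half-arcsine resistance limit

Rotation is modelled about a horizontal axis along the lingual cervical
margin, which makes the problem planar in the buccolingual section. The
restoration point seated at the opposing wall's base, a distance $B$ from
the axis, traces the circle of radius $B$; it re-crosses the plane of a
wall tapered at $\theta$ at height $y^* = B\sin 2\theta$. The wall blocks
rotation iff it reaches that height, $y^* < H$, giving the limiting taper

$$\theta_{max} = \tfrac{1}{2}\arcsin(H / B).$$

For $H \ge B$ the re-entry height can never exceed $B \le H$, so every
taper below $45^\circ$ resists; `max_resistance_angle()` reports
`theta_max = 45` with `capped = TRUE` rather than an error, which makes the
groove case well defined for 4 and 5 mm walls on the 3.41 mm base — the
published account applies its formula there only implicitly, and the capped
interpretation is this package's documented reading. At the boundary the
predicate is strict (`taper == theta_max` does not resist); reported angles
are rounded to one decimal only in reports, full precision elsewhere.

## Numeric oracles

Two independent brute-force routes guard every closed form:

* `mesh_surface_area()` rebuilds the (optionally grooved) prepared surface
  as parametric patches in 3-D, triangulates each on an $n \times n$ grid
  and sums raw triangle areas. Planar faces are exact at any refinement;
  curved groove patches converge quadratically. Refinement 16 already puts
  random-spec disagreement below 0.01 mm²; the grooved study cells are
  checked at refinement 96.
* `sweep_resists()` samples the rotation arc at an `angular_step` of
  0.001° (so classifications are reliable except within ~0.02° of the
  analytic boundary) up to the angle where the arc passes the wall top,
  with a penetration tolerance of $10^{-6}$ mm against floating-point
  grazing. The sweep cap `max_rotation` defaults to 90°: re-entry happens
  at a rotation of $2\theta$, so any smaller cap would blind the oracle to
  legitimately resisting geometries.

The test suite checks closed form against oracle on 200 seeded random
(taper, height, base) triples and 100 seeded random preparations, sizes
chosen to exercise the full parameter ranges while keeping the default
suite in seconds.

## Synthetic parameter grids

`random_prep_grid()` draws heights in 1–8 mm, widths 3–8 mm, lengths
5–12 mm and independent per-wall tapers 0–25° — generous envelopes around
clinically reported crown dimensions and convergence angles — and rejects
over-truncated draws rather than clamping, so accepted parameters keep
their simple uniform distribution. Generation is seed-deterministic and
restores the caller's RNG state. The generator emulates valid *parameter
sets* only: it makes no claim of anatomical realism (no correlation between
tooth size and height, no distribution of real convergence angles), so
passing tests demonstrate correctness of the geometry over the stated
ranges, not clinical prevalence of any configuration.

## Replication report

`replicate_study()` recomputes every printed cell of the three bundled
reference tables, including the zero-taper block rows, and compares:
formula-anchored quantities (per-height limits, base lengths, groove-wall
values) must match within 0.05° for angles and 0.005 mm for lengths;
area quantities carry recorded deviations with `within_tol = NA`, honesty
being preferable to reverse-engineering an unavailable derivation. The
fixture's header also flags a known internal inconsistency in the source
(one area cell printed as 160.0 in its table and 160.7 in its text; the
table value is stored).

## Known limitations

* The rotation axis is fixed at the lingual margin, level with the
  resisting wall base; finite-element work locating the axis below the
  margin in the root is out of scope.
* No cement shear strength, friction, load magnitude or tooth flexure: the
  resistance verdict is a purely geometric interference test.
* The groove model idealises the bur cut as the swept cone intersected with
  the frustum under the stated seating; real grooves have rounded shoulders
  and operator variation.
* Tapered-cell reference areas are matched in trend, not magnitude, for the
  reasons above.
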