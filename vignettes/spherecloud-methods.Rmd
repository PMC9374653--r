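---
title: "Sphere-cloud stimuli: model, generation methods and design choices"
author: "spherecloud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sphere-cloud stimuli: model, generation methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherecloud)
```

## The stimulus model

A stimulus is an ordered list of spheres, each described by seven numbers:
scene coordinates `x`, `y`, `z` (dimensionless; `y` is the depth axis in
the default display), a radius `size` in scene units, and an HSV color
(`hue`, `sat`, `val`). Two hard constraints define the legal parameter
space:

* `size >= 0.01`. Below this floor spheres are barely visible at typical
  display scales; any operation that proposes a smaller radius stores
  exactly 0.01 instead.
* `hue` lives on a circle of period 1, with red at both 0 and 1; `sat` and
  `val` are confined to `[0, 1]`.

Sphere order is meaningful: morphing and deviation measures pair spheres
by index, and the renderer uses a stable sort so equal depths preserve the
stored order.

`validate_stimulus()` reports violations rather than raising, so it can be
used as a post-hoc audit on imported or hand-edited stimulus files. The
JSON dialect written by `save_stimulus()`/`save_category()` serializes
numbers at 17 significant digits, which makes the load/save roundtrip
bit-identical for IEEE doubles — important when a category must be
regenerated years later for a replication.

## Random base stimuli

`make_base(n, seed)` samples every parameter independently and uniformly.
The sampling windows are package defaults, chosen for display usefulness
rather than dictated by the method itself:

| parameter | default window | why |
|---|---|---|
| x, y, z | [-1, 1] | symmetric scene box, renderer-friendly |
| size | [0.05, 0.25] | visible but rarely overlapping at 8 spheres |
| hue | [0, 1) | the full chromatic circle |
| sat, val | [0.6, 1.0] | avoids colorless, pale or near-black spheres |

Saturation/value floors matter: desaturated or dark spheres lose exactly
the color information a hue manipulation is supposed to carry. The window
can be overridden per call via `base_ranges()`.

## Deriving category members

Members are derived from the base per sphere and per parameter,
independently — no cross-sphere or cross-parameter coupling. Two modes:

* **uniform**: magnitude `m ~ U[lo, hi]`, then a fair random sign. The
  symmetric sign is deliberate: a one-sided perturbation would shift the
  category centroid off the prototype and make the "prototype = central
  tendency" assumption of prototype-based training false.
* **gauss**: `Normal(base, sigma)` draws.

Positions are special-cased. The x–z pair moves together in polar
coordinates: an angle `theta ~ U[0, 2*pi)` and a distance `d`, converted
back to Cartesian offsets, so the Euclidean x–z displacement equals the
drawn distance exactly. Depth `y` is perturbed independently like a scalar
parameter, because the default display projects the scene along x–z and
`y` only affects occlusion order; coupling it to the planar shift would
add invisible variation.

In Gaussian mode the shift distance uses the half-normal
`|Normal(0, sigma)|` (mean `sigma * sqrt(2/pi)`): a distance is
nonnegative by construction, and the half-normal is the minimal
modification of a Gaussian draw that respects that. This is a documented
package choice; a uniform-range distance is available in uniform mode.

**Clamping.** Bounds are enforced *after* sampling: sizes are floored,
`sat`/`val` clamped, hue wrapped modulo 1. Resampling-until-valid was
rejected because it would silently distort the stated distributions near
the bounds; instead a clamp event is recorded in the member's `lineage`
string (`;clamped=k`), so a generated set can be audited for boundary
artifacts. Hue wrapping is not a clamp — the circle has no boundary — and
is the only treatment consistent with red sitting at both ends of the hue
scale.

**Reproducibility.** Every generator is a pure function of its inputs and
a seed. Categories fan out one child seed per member by seeding R's RNG
with the master seed and drawing `n` integers, so member `i` is
reproducible in isolation and members are mutually independent. All
internal RNG use is scoped (via `withr::with_seed` and private RNG streams
in the schedulers) and never perturbs the caller's RNG state.

`preview_exemplars()` visualizes the extremes of a spec: uniform mode at
deviation `hi` on both sides; Gaussian mode at the two-sided 5 % tail
quantiles of `Normal(base, sigma)`, i.e. the 2.5th and 97.5th percentiles.
"5 % tails" could also be read as 5 % per tail; the tail mass is therefore
an argument (`tail_mass`, default 0.05 two-sided — pass 0.10 for the
per-tail reading).

## Morph continua

`morph_pair(p1, p2, k)` requires equal sphere counts and pairs spheres by
index. Step `j` of `k` in-between stimuli takes every scalar parameter to
`p1 + j/(k+1) * (p2 - p1)`. Linear interpolation is chosen because it is
the only rule that gives *equal physical spacing* between adjacent steps,
which is precisely what a categorical-perception experiment needs: a sharp
behavioral boundary must be attributable to perception, not to uneven
stimulus spacing. Hue travels along the shortest circular arc; exact
antipodes (circular distance 0.5) tie-break toward increasing hue, the one
configuration where morph symmetry (`morph(p2, p1)` reversing
`morph(p1, p2)`) cannot hold. Endpoints are the parent objects themselves,
not recomputed interpolants, so endpoint fidelity is exact by
construction. Interpolated sizes are floored at 0.01 like all other sizes.

## Category exceptions

Exceptions are stimuli assigned to a category whose parameters lie outside
its parametric extent. Route one (`exceptions_from_limits`) first computes
the per-sphere, per-parameter min/max over the members
(`category_limits`), then pushes past them: per parameter a side is chosen
by a fair coin and a magnitude `~ U[lo, hi]` is added above the upper or
subtracted below the lower limit. With zero ranges the exception sits
exactly on the extremes — still typically far from the prototype. Route
two (`exceptions_from_base`) derives exceptions from a dedicated exception
base with the uniform machinery, which permits a different sphere count
than the category's.

Two open choices and how they were resolved:

* limits are computed **per sphere index** by default (pooled across
  spheres behind `per_sphere = FALSE`): per-sphere limits keep exceptions
  structurally comparable to members, while pooling makes the exception
  depend on the category's global extremes;
* hue limits are computed on deviations **unwrapped around the base hue**
  (smallest signed circular difference) and re-wrapped afterwards — a raw
  min/max on circular values is meaningless when a category straddles red.

Exceptions are parametric outliers only; nothing here guarantees they are
*perceptual* outliers.

## Parametric deviation ("similarity")

`stimulus_deviation()` reports, per sphere: Euclidean distance in the
display plane (`xz_distance`) and in 3D (`xyz_distance`) — both are given
because whether depth should count toward "distance" depends on whether
the display is 2D —, absolute size difference, circular hue distance
(`min(|dh|, 1-|dh|)`, at most 0.5), and absolute `sat`/`val` differences,
plus mean and max aggregates. Deliberately, no single scalar similarity is
produced: numeric deviations need not track perceived similarity (a large
positional change may be invisible while a small size change transforms
the gestalt), so downstream analyses should model the parameters
separately, e.g. in a GLM on performance data. The schedulers that need a
scalar ordering key use the sum of the mean aggregates, documented as an
ordering device only.

## Rendering

`render()` is a deterministic rasterizer: rotate the scene by azimuth
(about the vertical axis) and elevation (about the horizontal axis),
project orthographically (x right, z up), sort spheres by projected depth,
and paint them back to front as discs with radius proportional to sphere
size. Orthographic projection is a modeling decision, not a shortcut: the
stimuli are designed for a 2D display in which depth affects only
occlusion order, and a perspective camera would make `y` change apparent
size. The disc shading (a fixed highlight offset toward the upper left
with a fixed intensity ramp) is constant-parameter, so identical inputs
give byte-identical PNG output — renders are part of the reproducibility
contract, which is also why rotation uses `cospi`/`sinpi` (a 360° turn is
bit-exact, not within float error). Larger `y` is closer by default
(`near_positive_y = FALSE` inverts). PNG output is lossless at 8-bit
depth; JPEG is provided for convenience and is not byte-stable across
library builds.

## Training protocols

All three schedulers are stateful objects with `next_trial()` /
`record(response)` and are pure functions of (config seed, response
sequence).

**Prototype-based.** Block 1 presents only the two prototypes. When
rolling accuracy over the last `window` trials (default 20) is at or above
the criterion (default 0.80), the per-category set size multiplies by
`growth_factor` (default 2). Two estimator details are package decisions,
since "performance at criterion" does not pin down an estimator: the
window must be completely filled *since the last advancement* before the
rule is evaluated (otherwise a single lucky trial right after an
advancement would immediately trigger the next one and the doubling ladder
1, 2, 4, 8 … would collapse), and the comparison is `>=`, so exactly 80 %
advances and 79.9 % does not. Pool stimuli join the active set in order of
increasing parametric deviation from their prototype — later blocks are
both larger and less prototype-like; pass `similarity_order = FALSE` for
pool order.

**Exemplar-based.** Every trial draws uniformly from the full pool from
trial 1; the category bases are excluded (removed with a warning if
found), since the defining feature of this regime is that the learner
never sees the prototype itself.

**Continuum.** Trials draw uniformly from a morph continuum's steps; the
true category is the side of a boundary index, and `set_boundary()`
relabels subsequent trials without touching the stimuli — the
boundary-relearning manipulation.

**Simulated observer.** `simulated_observer()` classifies by parametric
deviation to each category's prototype (or to the nearest stored exemplar)
through a softmax with temperature `noise`; zero noise is deterministic,
infinite noise is chance. It exists to make sessions testable end to end
and to check the qualitative prediction that prototype-protocol learning
curves start steeper than exemplar-protocol curves for a matched observer.
That ordering is only measurable when members stray far enough from their
prototype that pool trials are genuinely harder than prototype trials; the
test suite uses broad uniform specs (planar shifts up to 0.9 scene units,
hue deviations up to 0.25) for exactly that reason. It is a property of
this observer model, not evidence about any particular species' learning.

## Numerical notes and test scale

* Hue wrap is `x %% 1`. Bit-exact return after increments summing to 1
  holds for binary-representable increments (0.5, 0.25, …); general
  increments return within 1e-12. Degenerate inputs: `delta_range(0, 0)`
  and `gauss_spec(0)` are exact identities; `k = 0` morphs return just the
  parents.
* Statistical tests in the suite run at desk scale: distribution recovery
  at n = 2,000 (3 standard errors), scheduler uniformity at 4,000–5,000
  trials (chi-squared, alpha = 0.01), learning-curve ordering over 5
  sessions of 100 trials per protocol. These sizes keep the full suite
  under a minute while leaving comfortable statistical margins.
* The fixture suite (`make_fixtures()`) regenerates all example artifacts
  from seeds at run time; nothing binary ships with the package.

## What the generator does and does not emulate

The synthetic worlds used in the tests reproduce the *parametric*
structure of real stimulus sets: constant sphere count within a category,
uniform vs Gaussian feature spread, controlled within-category deviation
bands. They do not model perceptual salience, display calibration,
species-specific color vision, or inter-subject variability — passing
tests show the generation machinery is correct, not that any particular
category set is learnable by a given subject. Known limitations: morphing
requires equal sphere counts and index-paired spheres (nearest-position
pairing is out of scope), exceptions are parametric rather than perceptual
outliers, and the renderer implements flat shaded discs rather than a
physical lighting model.
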