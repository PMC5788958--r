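---
title: "View matching on tree trunks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{View matching on tree trunks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Nocturnal bull ants that forage on trees must, at the end of a foraging
trip, descend a vertical trunk and leave it on the side facing the nest.
The working hypothesis this package implements is that they do so by
*panoramic view matching*: the ant stores one or more views from the base
of the tree on its habitual (nest-facing) side and, while descending,
compares its current panorama with the stored views. Two families of read-out
are implemented:

* a **gradient of familiarity** — move so that the mismatch between the
  current and stored views decreases, with no heading extraction;
* a **visual compass** — find the image rotation that best aligns the
  current view with the stored view and turn so as to null it.

Everything is tested against synthetic scenes, because the study system's
raw data (angular positions of descending foragers, field panoramas) are
not available as machine-readable data. The synthetic world is therefore a
first-class, tested module, and the package's claims are about what view
matching *can* reproduce in such a world, not about new field data.

## Panoramas and the rotational image difference function

Panoramas are equirectangular grids of 8-bit intensities, 360 columns
(1 deg of azimuth per column) by 117 rows. Rows span elevations +66 deg
(top row) down to -50 deg, placing the horizon about 50 rows above the
bottom edge; this fixes the "roughly 50 below / 67 above" convention as an
exact constant, with row centres on integer degrees. Column `c` is centred
on azimuth `c - 0.5` deg clockwise from the *nest direction* — panoramas
are world-aligned rather than heading-aligned, which removes all heading
bookkeeping because the mismatch scan below explores every rotation anyway.

For a reference view `R` and test view `T`, the rotational image
difference function (rotIDF) is

    mismatch(r) = sum_{x,y} | R(x, y) - rot_r(T)(x, y) | ,   r = 0, ..., 359

where `rot_r` rotates the test image `r` degrees clockwise (an exact
circular column shift; no sub-degree interpolation). This
sum-of-absolute-differences (SAD) form is the default; a root-mean-square
(RMS) variant is provided because the study's figure captions describe the
curves that way while its methods text says "sum of the absolute
difference". Both are reported with a metric tag and share the same argmin
on noise-free shifted copies; intensities are kept as integers 0-255 so the
SAD oracle in the test-suite can demand exact equality.

Conventions pinned by tests:

* `rotate(p, r)` column `c` equals `p` column `(c + r) mod 360`;
  consequently `rotidf(ref, rotate(test, k))` is the base curve shifted by
  `k`, and `rotidf(a, b)(r) = rotidf(b, a)((-r) mod 360)`.
* `best_rotation` is the argmin; ties break toward the smallest absolute
  signed rotation, then clockwise, so "no turn" is favoured.
* `valley_depth = 1 - min/mean` in [0, 1]; an all-zero curve has depth 0.
* A curve has a **clear minimum** when `valley_depth >= 0.15` *and* every
  rotation within 5% of the valley depth of the minimum lies within +/-5 deg
  of the argmin. The depth threshold is a package constant exposed in the
  API (`has_clear_minimum(theta = 0.15, plateau = 5)`), not a claim about
  the biology: the source study never quantified "clear", so the criterion
  is operationalised once and reported alongside every curve. The 5%
  near-minimum rule means both broad plateaus and multimodal troughs count
  as "no clear minimum" — both are useless to a compass user.

## The synthetic world

Scenes are deliberately minimal geometric worlds: vertical cylindrical
trunks on a flat ground plane, spherical canopies, an optional square
screen (four opaque walls, by default 1.5 m x 1.5 m, 0.05-2.0 m high,
around the nest tree — the landmark-blocking manipulation), a bright
uniform sky (255) and dark terrestrial surfaces, emulating blue-channel
imaging in which the skyline carries the dominant contrast. One ray is cast
per pixel; the nearest intersected primitive wins, which automatically
produces occlusion — including self-occlusion by the trunk the viewer
clings to, a dark band roughly 126 deg wide at the default 2 cm eye offset.

Texture is *world-anchored*: each surface cell (1 deg cells on trunks and
canopies, 10 cm cells on the ground, 1 cm on the screen) carries an
additive pseudo-random offset derived by hashing the cell coordinates with
the scene seed. Texture is therefore stable across viewpoints and renders
— the same bark patch always looks the same — which is what makes view
matching informative at all. Two amplitudes exist: `amplitude` (default 40
in the default scene) for ground, canopy and screen, and `bark_amplitude`
(default 70) for trunk surfaces. Early versions used a single small
amplitude (10) and produced a cartoon world whose failure was instructive:
with visually flat bark, the viewer's own trunk band matches the reference
band *perfectly* at trunk-aligned rotations, so views from the far side of
the tree acquired deep spurious rotIDF valleys that no real image shows.
Strongly mottled bark (as in real eucalypts) makes band-on-band overlap pay
a texture-decorrelation cost and removes the artefact; the moderate global
amplitude similarly prices in the fine structure of ground and foliage.

The default scene places the nest 10 cm from the nest tree, the foraging
tree 3 m from the nest (the nest direction from the foraging tree is world
azimuth 0), and eight distractor trees of two kinds:

* six **near saplings** (0.9-2.0 m away, bearings 65-115 deg) — tall thin
  trunks whose images are full-height vertical stripes. Because they are
  taller than the rendered field of view from any on-trunk position, their
  appearance is invariant to viewer *height*; but moving *around* the trunk
  shifts each stripe's azimuth by a different parallax, so no single
  rotation re-aligns them. They are what makes same-side/different-height
  views matchable while different-side views are not — the geometric heart
  of the reproduced pattern. They sit in a single flank thicket because two
  clusters on opposite sides would be mapped onto each other by a 180 deg
  rotation, recreating the spurious valley.
* two **mid-distance canopy trees** (crowns between ~30 and ~60 deg of
  elevation) plus the nest tree's crown, giving an azimuthally varied
  skyline. Per-tree bark and crown tones differ, so misrotated panoramas
  cannot cheaply match one tree's silhouette to another's.

What the generator does *not* emulate: leaf-level canopy structure, real
luminance distributions, twilight spectra, clouds, wind motion, and any
non-vertical trunk geometry. Passing tests therefore show that the
algorithms behave correctly and that the study's qualitative pattern is
*achievable* by view matching in a world with realistic parallax structure;
they do not show that real foraging habitats have these statistics.

The one field quantity the imaging protocol needed but the study never
stated — the camera position for the base reference image — is exposed as
the `offset` argument of `trunk_viewpoint()` rather than hard-coded; all
shipped analyses use the same 2 cm bark offset for reference and test
views.

## Circular statistics

Angular positions on the trunk are analysed with standard circular
statistics, implemented directly (no circular-statistics package is
assumed) and validated against simulation oracles rather than against any
particular commercial implementation:

* mean direction and resultant length: `mu = atan2(mean sin, mean cos)`,
  `R` the length of the mean unit vector; `mu` is flagged undefined when
  `R` is numerically zero.
* Rayleigh test of uniformity: `Z = n R^2` with the standard series
  approximation for `p`, clipped to [0, 1]. Its measured type-I error at
  `n = 15` is checked to lie in [0.04, 0.06]. Comparison against
  100 000-replicate exact nulls showed the series drifting beyond three
  Monte-Carlo standard errors below `n = 10`, so the default (`"auto"`)
  method switches to a 20 000-replicate simulated null there.
* V-test toward an a-priori direction (`mu0 = 0`, the nest):
  `V = R cos(mu - mu0)`, `u = V sqrt(2n)`, one-tailed normal upper-tail
  `p`. The same null comparison put the normal approximation's validity at
  about `n >= 15`; below that the default method is the uniform-null
  permutation p (20 000 replicates). Both simulated-p paths draw from the
  current RNG stream; the experiment driver seeds them so reports
  reproduce exactly.
* 95% confidence interval for `mu` by the circular-dispersion method:
  half-width `asin(z * sqrt(delta / n))` with
  `delta = (1 - rho2) / (2 R^2)`. When the asin argument exceeds 1 (data
  too dispersed) the interval is reported as explicitly undefined — never
  silently wrapped; the source study contains one table row whose printed
  interval appears inconsistent with its near-uniform data, and that case
  maps onto this undefined branch. Membership of a direction in the CI is
  decided on the wrapped arc from lower bound through `mu` to upper bound,
  because intervals routinely straddle 0/360.
* Alpha is fixed at 0.05 and no multiple-testing correction is applied,
  mirroring the original analysis protocol; the report tables carry raw
  p-values so readers can adjust if desired.
* von Mises samples come from the Best-Fisher rejection sampler;
  `kappa = 0` reduces to the circular uniform.

When a simulated (or real) forager abandons a descent and climbs back up,
only the *final descent* — the path suffix from the last local maximum of
height, ties allowed — enters analysis, matching the study's filtering
rule. Crossings of analysis heights (1 m, ground; 1.4 m in blocked runs)
are linearly interpolated between bracketing steps on the unwrapped
azimuth track.

## The descent agents

Both agent strategies share a skeleton: at each step the agent makes one
bounded lateral decision, then descends `step_down = 0.10` m (the study
marked paths every 10 cm). Azimuth changes per step are clamped to
`lateral_step = 20` deg — about 5 cm of arc on the default trunk — chosen
so that an agent released opposite the nest can reach the nest side within
a 2 m descent. Motor noise is a von Mises deviate (default
`kappa = 50`, circular s.d. roughly 8 deg) added to the lateral component
before clamping; `kappa = Inf` disables it in tests.

* **gradient**: probe familiarity (minimum best-mismatch over stored
  views) at `scan_offsets = c(-20, -10, 10, 20)` deg at the current
  height — a minimal model of the horizontal scanning the ants perform —
  and move `min(lateral_step, |best offset|)` toward the best probe;
  symmetric ties mean no lateral move. Probe azimuths are rounded to whole
  degrees (the rendering resolution, matching the ~1 pixel/degree visual
  acuity the imaging emulates), which also lets runs memoise rendered
  view-matches.
* **compass**: compute `best_rotation` of the current view against memory
  and side-step `min(lateral_step, |r|)` in the direction that shrinks the
  wrapped rotation. On a trunk this works because the dominant image
  feature — the viewer's own dark band — sits at a rotation offset roughly
  equal to the trunk azimuth.

Neither rule is claimed to be the ants' mechanism; they are the two
minimal read-outs named by the hypotheses above, and both must reproduce
the qualitative field pattern.

**Landmark blocking.** Memory is always acquired in the scene *without*
the screen (views are learned before the manipulation). A no-signal
threshold is precomputed per blocked run as 0.9 times the mean familiarity
of inside-screen views at the four cardinal azimuths at release height:
when every probe is worse than this, the agent has no usable gradient and
side-steps uniformly at random within `lateral_step`. A fraction
`p_escape = 0.5` of the cohort escapes above the screen on first hitting
no-signal — half the observed foragers climbed above the blocked height,
and the fraction is treated as a property of the population (which ants
escape is randomised) rather than an independent coin per ant, because the
blocked condition's signature uniformity arises from the cancellation of
the escaper cluster (near the nest side) against the non-escaper cluster
(near the release side) and is a statement about that balanced mixture. An
escaping agent ascends to 0.2 m above the screen top, performs a full
panoramic familiarity scan there — escaped foragers were observed to scan
repeatedly — moves to the scanned best azimuth, and then commits to a
final descent (one escape per agent). The scan-based reorientation
replaced a purely local gradient rule after the local rule was found to
strand escapers in a secondary familiarity dip; a full scan at a single
height is both closer to the observed behaviour and free of that trap.
Below the screen the descent is again no-signal random wandering, so
escapers spread around their reorientation azimuth while non-escapers
spread around the release side — jointly reproducing the observed
uniformity of blocked positions at 1.4, 1 and 0 m.

The memory-free control (`memory = list()`) replaces every lateral
decision with the uniform random rule, which is how the tests show that
nest-ward orientation comes from view matching and not from the scene or
path geometry. Because lateral steps are bounded, a single-release cohort
of memory-free agents stays clustered near its release azimuth (a bounded
random walk cannot mix around the circle in a 2 m descent); the control is
therefore run with releases spread uniformly around the trunk, where
memory-free ground positions stay uniform while view-matching agents from
the same releases converge on the nest side.

## Problem sizes and numerical choices

The shipped analyses use the study's own sample sizes: 15 agents per
unblocked condition, 20 in the blocked condition, releases at 0/90/180/270
deg and 2 m (1.5 m blocked). Test-suite oracles use 100 000-replicate
simulated nulls for p-value agreement (tolerance: three Monte-Carlo
standard errors), 10 000 replicates for type-I error, and 2 000 for CI
coverage. Rendering is exact ray casting (no sampling noise); the only
stochastic components are texture hashing (seeded per scene), behavioural
sampling, and agent motor noise, all of which flow from named integer
seeds, so every run is bit-reproducible.

Degenerate inputs are defined, not patched: an all-zero rotIDF curve has
valley depth 0; a zero-resultant sample has an undefined mean direction
and an undefined CI; rotation by non-whole degrees is rejected rather than
interpolated; a viewpoint inside a solid is an error.

## Known limitations

* The renderer's two-tone-plus-texture world has no gradual lighting; the
  blue-channel emulation is a contrast structure, not a spectral model.
* Canopies are spheres and the screen is four rectangles; fine occlusion
  structure (branches, leaves) is absent, so absolute mismatch values are
  not comparable to field imagery — only orderings and valley structure
  are used.
* The agent motor model is a 10 cm grid walker with bounded lateral steps;
  it cannot express the full loops and pauses of real foragers, and the
  escape rule is a stand-in for an unmodelled information-seeking
  behaviour.
* The dispersion-method CI is a large-sample interval; its measured
  coverage at `n = 15`, `kappa = 2` sits at the lower edge of nominal
  (about 93%), a known mild undercoverage of this estimator for small
  samples.
* Celestial cues and path integration are deliberately outside scope; the
  cue-conflict observation is reflected only in that these agents ignore
  any home vector by construction.
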