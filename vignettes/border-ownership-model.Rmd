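---
title: "Figure-ground segregation by border-ownership functional minimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Figure-ground segregation by border-ownership functional minimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Deciding which side of every image boundary belongs to an object —
figure-ground segregation — is under-determined: a white square on black can
equally be a white object or a square hole in a black sheet, and the human
visual system can even perceive boundaries where the image has no intensity
gradient at all (illusory contours, as in Kanizsa figures). `bomap`
implements a model in which every candidate assignment of boundaries is
scored by a cost functional and perceived interpretations correspond to
*local minima* of that functional, ranked by cost. Illusory contours are not
constructed by any special junction detector; they fall out of the same
minimization that detects real boundaries.

The state variable is a **border-ownership map** `b[x, y, l]`: a signed
strength, at every pixel, for each of `L = 12` discrete directions
`alpha_l = 2*pi*l/L`. A large `|b[x, y, l]|` means "a boundary passes
through `(x, y)` perpendicular to direction `l`, and the object that owns it
lies on the side `l` points to". Sign carries no meaning — the map enters
the functional only through its square — which spares the optimizer from
fencing the values to stay positive.

Before any component is evaluated, the raw map is smoothed circularly over
the direction index (width `sigma_SA`, in direction steps) and spatially
(width `sigma_SX`, zero-padded: there is no ownership outside the canvas).
All six components consume this smoothed field `bS`:

* **Edge alignment** `F_A = -(1/T) * sum(A^2 * bS^2)`, where `A` is the
  response of a bank of oriented odd filters (Gaussian times the sign of the
  projection on `u_l`, with a dead zone `|x| <= 0.001`) and
  `T = width * height * L` normalizes all components per site. Edge
  responses enter squared, so ownership is rewarded equally on both sides of
  an edge; choosing a side is the job of the other components.
* **Strength limiting** `F_R = (1/T) * sum(bS^4)`: quartic, so it always
  overtakes the quadratic reward at high strength.
* **Suppression off edges** `F_V = (1/T) * sum(eps_V / (A^2 + eps_V) *
  bS^2)`: a tax on ownership where the image has no gradient. Illusory
  contours must pay this tax and are only kept when the grouping terms repay
  it.
* **One-sidedness** `F_N`: squared ownership is spatially blurred and
  products between nearly opposite directions (deviations `|m| < L/4` from
  `l + L/2`, weighted `cos^2(2*pi*m/L)`, normalized by their sum) are
  penalized — an object lies on one side of a boundary, not both.
* **Continuity** `F_C`: for every site, channel and travel sense along the
  boundary tangent, the *ending* mass (an oriented half-lobe grouping of
  `bS^2` behind the site) should not exceed the best *originating* mass
  (the maximal grouping over all continuations turning at most 90°,
  including perpendicular occluders). The excess passes through a
  Gaussian-smoothed ramp.
* **Bending** `F_E`: products of incoming and outgoing lobe mass over all
  tangent turns up to 90°, weighted `(dtheta/pi)^2` and multiplied by
  `kappa > 1` when the turn is concave (away from the owned side). This is
  what makes a white square read as an object rather than a hole: the
  object reading has four convex corners, the hole reading four concave
  ones.

Every component is averaged over `n_scales` spatial-filter scales
(filters widened by `mu^n`), which decouples the cost from the pixel grid.

### Design choices where the formulation was open

The continuity and bending components are implemented as concrete
reconstructions satisfying their behavioral contracts (zero on unbroken
straight boundaries; positive on dangling endings; relief when a crossing
boundary occludes an ending; straight continuation free; convex 90° cheaper
than concave 90°). Three choices deserve explanation:

* **Non-negativity of `F_C`.** The smoothed ramp `rho` is positive at 0, so
  the naive `sum(rho(Ee - E))` carries a large constant background that the
  optimizer can *reduce* by planting spurious originating mass anywhere —
  an exploitable negative tail. The implemented per-site term is
  `S(Ee) * (rho(Ee - E) - rho(-E))` with the soft ending gate
  `S(x) = x^2 / (x^2 + eps_C^2)`. The bracket is provably non-negative
  (the ramp is increasing and `Ee >= 0`), vanishes when nothing ends, and
  approaches `Ee` for an unanswered ending; the gate removes the residual
  small-mass slope that would otherwise tax all ownership like a second
  `F_V`.
* **Ownership-consistent continuations.** A continuation candidate only
  counts at full strength when it keeps the ownership side relative to the
  travel direction; opposite-side candidates can only belong to a
  different, occluding boundary and are discounted by `gamma_occ = 0.8`.
  Without this distinction a boundary whose ownership flips polarity
  mid-course satisfies continuity for free, and patchwork-polarity minima
  proliferate.
* **The canvas border is not an ending.** The off-canvas fraction of a
  candidate lobe counts as continuation at the ending's own strength: a
  boundary that runs out of the picture is cut by the view, not by the
  world. Without this, every full-canvas boundary pays a large spurious
  dangling penalty at the image border.

A related subtlety: because smoothing is linear and precedes squaring, the
functional is invariant under a global sign flip of the map but *not* under
flipping a single entry — the smoothed field mixes neighbors.

## Finding interpretations

Minimization is a parabolic-step line search along Polak–Ribière conjugate
directions (restarted to the raw gradient whenever conjugacy stops paying),
with an analytic gradient for every component. The functional is first
minimized under heavy smoothing and then progressively de-smoothed
(graduated relaxation): the scale parameter starts at `s0 = 1` and shrinks
by `sR = 0.4` per pass until `sM = 0.15`, after which one final pass runs
the plain functional so that reported minima are stationary points of the
exact cost that ranks them. At scale `s` the border-ownership smoothing
width is multiplied by `1 + s`, all spatial filters inside the components
by `1 + 3*s`, and the ramp width by `1 + s`. The strong filter multiplier
is deliberate: at the coarsest scale the edge filters of nearby contour
fragments overlap across small gaps, which is precisely what lets an
illusory-contour minimum be discovered at high support ratios and not at
low ones.

Multiple minima are enumerated with repulsive particles: relax from a
random start (uniform in `[0.01, 0.02]` — the zero map is a stationary
point, so the start must break it) to the first minimum; add an
inverse-distance repulsion centered there; restart from the *same* random
start; then re-relax the displaced result with the repulsion removed (only
the final scales — the coarse passes would pull it straight back into the
first basin). A new minimum is accepted when its distance to every known
one exceeds `dT`; otherwise the repulsion is escalated by `tau` until
`tau_max`, keeping auxiliary particles at rejected end points.

Both the repulsion and the accept/reject distance operate on the
*smoothed* maps. The raw map has flat directions (the null space of the
smoothing operator), so raw-map distances separate maps that are physically
identical; a raw-distance repulsion is escaped along those flat directions
without changing the interpretation at all.

## Shape extraction and the illusory flag

The top-most object is recovered by a level-set balloon: a small disk is
seeded three pixels inside the owned side of the strongest ownership vector
(deep enough to clear the few-pixel ownership wall), and the front grows
with outward speed `(v - k_weight * k) * g`, where `k` is the front
curvature and the friction `g` collapses to zero where strong smoothed
ownership points against the front (`q` sums `bS^2` weighted by a Gaussian
in the angle to the inward normal; `h = 1 / (1 + q R^2)`; `g = h` above
the threshold `g_T`, else 0). The final mask is grown by one pixel, since
the front freezes just short of the wall that carries the boundary.

An interpretation is flagged *illusory* when more than 5% of its extracted
mask's boundary runs through pixels with essentially no image gradient
(no edge response above 10% of the image maximum anywhere in the
8-neighborhood). Real objects score 0 on this measure; a Kanizsa
interpretation that bridges the inducer gaps scores well above it.

## The stimulus set

The generators reproduce the study conditions: a 20×20 two-region step
edge; an 8×8 white square centered on a 20×20 black canvas; a C-shape
(12×12 square with a 4×6 mouth on a 24×24 canvas); and Kanizsa pacman
figures. For the Kanizsa series the published description fixes only the
*support ratio* `r/h` (pacman radius over half the illusory-square side),
not pixel sizes; the package uses a 36×36 canvas with `h = 9` and
`r ∈ {4.8, 5.1, 6.0}`, giving support ratios 0.53, 0.57 and 0.67 — the
smallest canvas on which the three ratios are cleanly rasterized and the
inducers stay well inside the border. All stimuli are binary, rasterized
without anti-aliasing (a pixel is black iff its center falls inside an
inducer disk and outside its mouth quadrant).

What the generator deliberately does not emulate: gray-level texture,
lines, anti-aliased or noisy edges, or natural-image clutter. Passing tests
therefore demonstrate the mechanism on solid-region synthetic images only
— nothing here speaks to robustness on photographs.

## Parameters

The package ships one frozen configuration (`inst/extdata/defaults.yaml`),
used unchanged for every stimulus and every test. The weights were tuned
once, by hand, on the step edge, the square and the Kanizsa series at
support ratios 0.67 and 0.53, then frozen. The qualitative behavior the
tuning targeted: boundaries must be profitable at all (`alpha_A = 6`
against the taxes), ownership must be one-sided (`alpha_N = 10`; lower
values leave both-sided edges cheaper than choosing a side), and the
bending penalty must prefer objects over holes without overwhelming the
edge terms (`alpha_E = 0.5`, `kappa = 3`). Filter widths are ~1 px at the
finest scale (`sigma_A = sigma_N = 1`, `sigma_SX = 0.75`,
`sigma_SA = 0.6` direction steps); the ramp width `sigma_RP = 0.01` is
small against typical lobe masses (~0.1) so the continuity ramp resolves
endings sharply; `eps_C = 0.005` gates continuity below noise mass;
`lambda_C = 3` px sets the grouping reach (about seven pixels of effective
reach at the finest scale — enough to bridge the 6-px gaps of the 0.67
Kanizsa figure but not the 8.4-px gaps at 0.53).

Numerical choices: spatial Gaussians are truncated at `ceiling(3*sigma)`
and renormalized; lobe kernels are cones of angular half-width
`2.5 * sigma_phi` truncated at `2 * lambda` and capped at 12 px radius
(only the heavily smoothed coarse scales would exceed the cap); descent
stops after three consecutive relative improvements below `1e-6`, at most
150 iterations per smoothed pass and 500 on the final plain pass;
continuity ties in the originating maximum resolve to the first candidate
in a fixed enumeration order; the level-set front uses Godunov upwind
differences, CFL step `0.4 / max|speed|`, and exact signed-distance
reinitialization every 20 steps.

Problem sizes throughout (canvases of 20–36 px, `L = 12`) are the study
conditions themselves; a full interpretation search takes a few minutes
per stimulus on one CPU.

## Known limitations

* The multiple-minima search is heuristic: it enumerates the minima it can
  reach from one random start under escalating repulsion, with no
  global-optimality or completeness guarantee.
* The enumeration order (not the final ranking) depends on the seed.
* At support ratio 0.57 the illusory reading exists as a stable minimum —
  seeding the optimizer near it confirms it is even the deepest one — but
  the repulsive-particle search started from the uniform random map does
  not reach it: the coarse-scale funnel leads to the four-pacman basin and
  the repulsion cannot kick the search across.  At 0.67 the coarse edge
  filters bridge the shorter gaps and the illusory reading is found first;
  at 0.53 the illusory configuration is not even a minimum (the bridges
  decay).  The observable detection threshold of the search is therefore
  at 0.67, one step above the threshold of the functional itself.
* Costs are comparable across canvas sizes only through the per-site
  normalization; no claim is made about absolute cost values, which depend
  on the (unpublished) weight choices.
* The level-set extractor recovers the top-most object only; occluded
  (second-depth) objects would need alternative seeds.
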