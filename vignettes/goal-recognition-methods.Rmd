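---
title: "Goal recognition from partial motion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal recognition from partial motion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goalrec)
```

## The problem

An agent moves in the plane from a start point $S$ toward one of a known set
of goals $G$. An observer sees an incrementally growing prefix $O$ of the
motion and must infer the intended goal, as early and as reliably as
possible. `goalrec` implements two classic answers and a hybrid:

* *rationality-based* recognizers assume the agent is cost-efficient and
  need no prior knowledge of plans;
* *plan-library* recognizers assume the observer has a repertoire of known
  plans and match the observation against it;
* LRGR combines the two, matching against known plans where possible and
  scoring the match by its rationality, with a pure-rationality fallback.

All costs are Euclidean arclengths in an obstacle-free plane, so the optimal
plan between two points is the straight segment and its cost is the
distance. Coordinates are dimensionless continuous reals; there is no grid.

## Recognizers

Let $C(g) = \lVert S - g\rVert$ be the optimal cost to goal $g$, and
$C(g, O) = \mathrm{len}(O) + \lVert N - g \rVert$ the cost of the cheapest
plan constrained to pass through the observations, where $N$ is the last
observed point and $\mathrm{len}$ the arclength. The implemented posteriors,
each normalized over goals, are:

| name | score for goal $g$ |
|------|--------------------|
| `rg` | $\exp(-(C(g,O) - C(g,\bar O)))$ |
| `mirroring` | $C(g) / C(g,O)$ |
| `ms` | $\sigma(C(g,S) - C(g,N))$, a sigmoid of the last point's cost advance |
| `dragan` | $\exp(-(\mathrm{len}(O) + \lVert N-g\rVert - C(g)))$ |
| `ideal` | $1/\lvert K\rvert$ for goals $K$ with a matching library plan, else 0 |
| `lrgr` | $\max_{t \in T_g} M(t)$, see below |

Two conventions deserve comment.

**The non-matching plan cost $C(g,\bar O)$.** In a discrete planning domain
one can compute the cheapest plan *not* containing the observations; in an
obstacle-free continuous plane this has no canonical analogue (any plan can
be perturbed infinitesimally off the observations). The package declares a
convention rather than inferring one: when $O$ is not a prefix of the
straight plan to $g$, the optimal plan already fails to match, so
$C(g,\bar O) = C(g)$; when $O$ *is* such a prefix, the cheapest non-matching
plan is charged a minimal detour of twice the match tolerance. This
preserves the sign behavior of the original discrete formulation and is an
approximation of it.

**Masters–Sardina normalization.** The per-goal sigmoids do not sum to one
across goals. They are kept raw in the `"raw"` attribute and additionally
normalized in the returned posterior so that all algorithms plot on a common
probability axis.

The Dragan posterior doubles as the integrand of the *legibility* of a full
trajectory toward its true goal $g^*$:
$\mathrm{legibility} = \int_0^T P(g^*\,|\,O_{[0,\tau]})\, f(\tau)\, d\tau
\big/ \int_0^T f(\tau)\, d\tau$ with early-weighting $f(\tau) = T - \tau$.
The integral is approximated by a midpoint rule on `n_steps` equal-arclength
cells. The midpoint rule was chosen over a one-sided Riemann sum because the
integrand is smooth and the quadrature should be resolution-stable: at 50
cells the midpoint score sits within $3\times10^{-5}$ of a 5000-cell
evaluation, whereas a left sum differs by $4\times10^{-3}$. Decision-curve
analyses use the per-prefix posterior, not the integrated score: convergence
is a property of the unfolding posterior, and the integrated legibility of a
fixed trajectory has no time axis to converge on.

## LRGR

For every library trajectory $t \in T_g$, the matching score is

$$
M(t) = \begin{cases}
1 & O \text{ is a spatial prefix of } t\\[2pt]
\dfrac{C(g)}{\mathrm{len}(O) + \lVert N - w\rVert + \lVert w - g\rVert} &
w = \mathrm{closest}(N, t) \text{ otherwise,}
\end{cases}
$$

the rationality of the hypothesized plan follow-the-observation, detour to
the closest point $w$ on the known plan, continue optimally. When no close
plan exists — $T_g$ empty, or every point of $t$ beyond the `cutoff` — the
closest plan is taken to be the observation itself ($w = N$, zero approach
cost), and the score reduces to the mirroring ratio. A goal's score is
$\max_{t\in T_g} M(t)$; the posterior is the scores normalized by
$\eta = 1/\sum_g \mathrm{score}(g)$. By the triangle inequality $M(t)\le 1$
always, so a direct match dominates and an observation lying on plans to $k$
goals caps each matched goal's posterior at $1/k$ — shared prefixes are
*confusing*, exactly the behavior that distinguishes library-aware
recognition from pure rationality.

Design choices that were genuinely open:

* When $T_g$ is nonempty, only actual library plans are scored; the optimal
  plan is *not* added as an implicit candidate (the literal reading of the
  algorithm's loop: optimal plans need not be in the library, and they enter
  only as the numerator $C(g)$). Setting `include_optimal = TRUE` adds the
  straight plan as a virtual library member for sensitivity analysis.
* The closest-point cutoff defaults to unbounded; it may be set to force the
  fallback at large detours.
* Ties among trajectories for the maximum are immaterial, since only the
  maximum value enters the posterior.

## Spatial prefix matching

`prefix_match(o, t, tol)` is the predicate everything library-based rests
on. It requires every point of `o` to lie within `tol` of the polyline `t`
*and* the points of `o` to project onto `t` at non-decreasing arclength
positions starting from `t`'s start. Mere proximity is not enough: a curled
observation that doubles back over a straight plan is near it everywhere
but is not a prefix of it, and the monotone-progression requirement rejects
it. The default tolerance is $10^{-6}$ times the scenario diameter — tight
enough that only exactly shared segments match, loose enough to absorb
floating-point interpolation error. Exponents in all recognizers are clipped
to $\pm 500$ before exponentiation as an overflow guard.

## The scenario generator

`make_berkovitz_scenario()` reproduces the layout of Berkovitz's human
goal-recognition experiment, in which subjects watched a robot arm move
toward one of two goals along trajectories of varying curvature: one start
at the origin, two goals equidistant from it (defaults $(-3, 10)$ and
$(3, 10)$, i.e. `span = 6`, `depth = 10`), and seven trajectories per goal
ranging from the straight optimal plan to strongly curved, inefficient
plans. The defaults were chosen so that the straight plans to the two goals
diverge slowly, making early prefixes genuinely ambiguous, as in the human
study.

Curved trajectories are quadratic Bézier arcs whose control points bow
progressively to the left in steps of `curvature_scale`; each is discretized
at 200 points (configurable, minimum 100). Trajectories are indexed per goal
by sorting on mean distance from the *distractor* (other) goal, index 1
closest and 7 farthest. Because all bows go to one side, each goal has
exactly one straight trajectory, and it lands at index 1 for the left goal
and index 7 for the right goal — for one goal the optimal plan is also the
most distinctive one, for the other it is the most confusable, an asymmetry
central to the study design.

The original layout has a further feature the recognizers are sensitive to:
some trajectories to different goals *coincide* over an initial stretch.
Two distinct quadratic Béziers cannot coincide on an arc (they are analytic
curves), so the generator engineers one overlap explicitly: one strongly
curved trajectory to the right goal is rebuilt to copy the exact initial
segment (20% by arclength, configurable) of a moderately curved trajectory
to the left goal, then continue to its own goal along a tangent-continuous
Bézier arc. Curvature indices are assigned after this splice, so the strict
ordering by distance-from-distractor always holds.

The generator reproduces the *ordinal* structure of the original
trajectories — curvature ranking, one optimal plan per goal at opposite
index ends, an early cross-goal overlap. No claim is made that its
coordinates match the original apparatus, whose trajectories exist only as
figures; consequently the package does not attempt to reproduce numeric
correlations against the original human response times, and the evaluation
harness asserts ordinal patterns only.

## Evaluation harness

Observations are trajectory prefixes at arclength fractions
$k\cdot\mathrm{step}$ (default step 0.02, i.e. 50 prefixes; the sampling
density of the original decision curves is not documented, so it is a
parameter rather than an inference). The *decision convergence point* of a
posterior series is the earliest grid fraction at which the correct goal's
probability exceeds 0.5 and never falls back to 0.5 or below at a later
grid point; a probability of exactly 0.5 never counts as decided, and the
idealized recognizer's all-zero no-match output is likewise "not yet
decided". Series that never commit are recorded as missing and excluded
from regressions with a logged count.

`leave_one_out()` holds each trajectory out in turn (library = the other
13); `library_size_sweep()` additionally subsamples the library to a given
size uniformly at random, rejection-sampling until both goals are
represented, 20 repeats per held-out trajectory by default — 280 problems
per size for the 14-trajectory scenario, as in the robustness experiments
with sizes 13/10/6/3. Each draw's seed is a deterministic offset of the base
seed and is recorded in the output, so entire sweeps are bit-for-bit
reproducible; all random draws save and restore the global RNG state.

On the default scenario two qualitative findings of the original study are
reproduced and asserted in the test suite:

* the three goal-posterior RGR algorithms (`rg`, `mirroring`, `ms`) have
  *identical* convergence points on all 14 trajectories, despite different
  posterior values — with equidistant goals all three commit exactly when
  the last observed point becomes nearer to the true goal;
* LRGR with the full library cannot commit while the observation still
  matches plans to both goals, so the overlapping pair converges strictly
  later than every non-overlapping trajectory, and per goal the index-7
  trajectory (farthest from the distractor) is the quickest — including the
  strongly curved, far-from-rational one, matching the human pattern that
  distinctiveness, not optimality, drives fast recognition. One nuance: on
  the strongly curved *goal-2* overlap trajectory the RGR methods themselves
  converge very late (the motion initially heads toward goal 1), so LRGR is
  at-or-later than RGR only on the overlap trajectory that RGR commits to
  immediately.

Response times for exercising the regression stage are synthesized as
$rt_i = a + b\,\mathrm{conv}_i + \mathcal N(0, \sigma^2)$; the loader treats
real response-time tables as pre-normalized and accepts them wherever a
numeric vector is expected. `linear_fit_r2()` is ordinary least squares with
the standard F-test for $R^2$ on $(1, n-2)$ degrees of freedom; a constant
response is reported as $R^2 = 0$, $p = 1$ (no explainable variance) rather
than the indeterminate $0/0$.

## What the synthetic conditions do and do not show

The generator emulates the geometry and ambiguity structure of the original
experiment, not its physics: no velocity profile, no 3D arm kinematics, no
perceptual noise, and trajectories that are parametric stand-ins rather than
motion capture. Passing tests therefore demonstrate the algorithms'
definitional and ordinal properties under controlled geometry — not
quantitative agreement with human data, which would require the original
coordinates and response-time tables. Problem sizes used by the test suite
are the study's own: 14 trajectories, 50-prefix series, 280-problem sweeps
per library size (sizes 10/6/3, 20 repeats).

## Known limitations

* Goals and plans are flat; hierarchical goal/plan schemas are out of scope.
* The plan library is matched geometrically; there is no probabilistic
  ranking over partially matching libraries.
* `prefix_match` assumes trajectories do not revisit near-coincident
  regions at grossly different arclength positions within one tolerance
  tube; the greedy monotone assignment could in principle be fooled by
  pathological self-overlapping curves, which do not arise in this domain.
* Costs are arclengths: kinematics, acceleration limits and obstacle
  avoidance are not modeled.
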