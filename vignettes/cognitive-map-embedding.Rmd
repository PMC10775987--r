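---
title: "Euclidean embedding of labeled place graphs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Euclidean embedding of labeled place graphs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazembed)
```

## The two models

Spatial long-term memory can be formalized in two ways. A **non-metric
labeled graph** stores places as vertices, traversable corridors as edges,
and attaches to every ordered triplet of neighboring places $(i, j, k)$ the
locally measured leg distances $d_{ij}, d_{jk}$ and the turn $\alpha_{ijk}$
performed at $j$. The labels are independent of one another: nothing forces
them to satisfy the triangle inequality or to close loops, so the structure
can represent environments that have no planar layout at all. Shortcuts are
derived by *vector addition*: summing distances and turns along the
shortest path.

A **Euclidean map** instead assigns coordinates to places, and shortcuts
are straight lines. The embedded-graph model studied here is the bridge:
given the (possibly inconsistent) labels, find planar coordinates
$X = (x_1, \dots, x_n)$ that reproduce them as well as possible. When the
environment is an ordinary planar maze the two models coincide; when the
labels are non-Euclidean — as in a maze with *wormholes*, seamless
teleports with rotation — they must disagree somewhere, and behavioral data
can arbitrate.

## The stress function

For a triplet $(i, j, k)$ write $u = x_j - x_i$ for the displacement into
$j$ and $w = x_k - x_j$ for the displacement out of it. If the coordinates
realize the labels, then

$$u \cdot w = d_{ij} d_{jk} \cos \alpha_{ijk}, \qquad
  u \otimes w = d_{ij} d_{jk} \sin \alpha_{ijk},$$

where $u \otimes w = u_1 w_2 - u_2 w_1$ is the scalar cross product, twice
the signed area of the triangle. The embedding minimizes

$$f(X) = \sum_{(i,j,k) \in T}
  \lambda_1 \left[ u \cdot w - d_{ij} d_{jk} \cos \alpha_{ijk} \right]^2 +
  \lambda_2 \left[ u \otimes w - d_{ij} d_{jk} \sin \alpha_{ijk} \right]^2 ,$$

with $\lambda_1 = \lambda_2 = 1$ by default. The triplet set $T$ contains,
for every vertex $j$, every ordered pair of incident edges, plus one
backtrack triplet $(i, j, i)$ per incident edge with $\alpha_{iji} =
180^\circ$ — which the sign convention above satisfies identically, since
$w = -u$ gives $u \cdot w = -\lvert u \rvert^2$ and $u \otimes w = 0$.
(A variant of this objective is sometimes written with both constraint
vectors pointing *into* $j$; that form flips the sign of the turn and is
inconsistent with the $180^\circ$ backtrack label, so the heading-change
convention is used throughout: $\alpha$ is the change of heading at $j$,
counterclockwise positive, normalized to $(-180^\circ, 180^\circ]$.)

Three properties matter downstream, and the test suite asserts each:

* $f$ is invariant under global rotations and translations of $X$ (gauge
  freedom), but **not** under reflection — the signed-area term fixes
  chirality.
* For labels measured in any planar maze, the ground-truth coordinates are
  a global minimum with $f = 0$, and the minimizer recovers them up to a
  rigid motion.
* For labels measured through wormholes no configuration reaches zero:
  residual stress is a structural signature of non-Euclidean experience.

## Optimization

The stress is minimized by quasi-Newton BFGS (analytic gradient) from
uniform random initial coordinates $X \sim U(0, 20)^2$, restarted
`n_restarts` times. BFGS alone stalls with gradient norms around $10^{-6}$
at nonzero-stress minima (the objective is quartic in the coordinates, and
at a large-residual minimum the Gauss–Newton approximation is poor), so
runs that miss the gradient target of $10^{-8} (1 + f)$ are polished with
damped Newton steps using the exact analytic Hessian — cheap here because
$u \cdot w$ and $u \otimes w$ are bilinear, making their second derivatives
constant scatter patterns. The Hessian's three-dimensional null space
(translation and rotation gauge) is absorbed by a small ridge.

Runs are deduplicated into distinct local minima when their stress agrees
within a relative $10^{-6}$ and their configurations superpose (reflection
allowed) to within $10^{-4}$ of the mean edge length. Minima are reported
sorted by stress, with the number of restarts that reached each — a useful
diagnostic of basin size. Which minimum the embedded model should use for
prediction is an empirical question (on the wormhole replica two minima
exist, and data may prefer either); `run_analysis(minimum = )` selects one
while the report always lists all.

Per restart the optimizer budget is 5000 iterations; in practice BFGS
converges in a few hundred. Reproducibility is by a single seed that draws
all initial configurations up front.

## Shortcut predictions and the local reference frame

The non-metric model predicts a shortcut $a \to b$ by Dijkstra's algorithm
on the distance labels (lexicographic tie-breaking), then dead-reckoning
along the path: advance each leg's labeled distance, rotate by each labeled
turn. The resultant's direction — seeded with the ground-truth orientation
of the first path arm — is the prediction. The embedded model simply takes
the straight line between embedded positions; the ground-truth model the
straight line between true positions.

Because an embedding's global orientation is arbitrary, all comparisons are
made as *local angles*: the signed difference between a direction and the
orientation of the maze arm the walker starts on, which is invariant to any
common rotation. All three models are referred to the same physical arm
(the first edge of the shortest path), the ground-truth arm orientation for
measured estimates and the non-metric model, and the embedded direction of
that same arm for the embedded model. Objects located mid-corridor are
snapped to the nearest vertex by default; `add_object_vertices()` instead
splits segments so objects become vertices before graph construction.

## Statistics

Circular machinery is implemented from the standard formulas (no circular
statistics package ships with base R):

* mean direction $\mu$ and mean resultant length $R$ from the mean unit
  vector; angular deviation $AD = \sqrt{2(1 - R)}$, reported in degrees;
* Rayleigh test $z = n R^2$ with the usual series p-value approximation;
* Watson–Williams F-test with the $1 + 3/(8\hat\kappa)$ concentration
  correction, $\hat\kappa$ from the three-branch inverse of
  $I_1/I_0$ (a warning is raised when $\hat\kappa < 1$, outside the test's
  comfort zone); its p-value is checked against a label-permutation oracle
  and its type-I error is calibrated by simulation in the test suite;
* circular Cohen's $d$: shortest angular difference of means over the
  pooled angular deviation;
* von Mises fits ($\mu$ = circular mean, $\kappa$ by inverse-$A$
  approximation, capped at $10^4$) and exact log-likelihoods via
  exponentially scaled Bessel functions.

Group structure follows the designs' printed degrees of freedom: each
subject's trial errors are reduced to a circular mean; Rayleigh and
Watson–Williams act on those per-subject means (two models with 10 subjects
each give $F(1, 18)$, with 11 subjects $F(1, 20)$); the *within-subject*
AD is each subject's own spread, averaged across subjects. Model
likelihoods use a per-model von Mises noise fit over all trial errors with
$n$ = the number of measurements; BIC $= k \ln n - 2\,\mathrm{loglik}$.
Parameter counts: the embedded model needs $2\lvert V \rvert + 2$ numbers
(coordinates plus noise $\mu, \kappa$); the non-metric model one distance
per edge and one angle per ordered through-triplet plus noise, by default —
how independent angle labels "should" be counted is a modeling convention,
so `count_parameters()` also offers unordered and per-triplet conventions.
The conclusions do not hinge on it: on the replica the gap between 82 and
any convention's label count dwarfs the likelihood differences.

## The synthetic data generator

`make_wormhole_replica()` is a **schematic** stand-in for the original
wormhole maze, whose exact coordinates were never published: 42 unit-grid
corners, of which two (ids 12 and 35) exist only in the wormhole-free
control layout, leaving 40 navigation vertices — the count implied by the
embedded model's 82 parameters. Two wormholes with $\pm 90^\circ$ rotation
splice distant corridors; each shortens its corridor's experienced length
to 2 grid units (shortened but not zero) and its rotation is absorbed into
the adjacent turn labels. Eleven named objects support the two measurement
designs: *route-finding* (10 subjects × 4 pairs × 2 directions = 80
measurements; the default roster includes two wormhole-spanning pairs) and
*rips-and-folds* (11 subjects × 8 starts × 3 targets = 264).

`generate_estimates()` draws each measurement as the generative model's
predicted direction plus von Mises noise with concentration
$\kappa_{within}$ (default 4, i.e. an angular SD of roughly 30°, the
within-subject spread typical of human shortcut estimates), optionally
offset per subject by a von Mises bias with concentration
$\kappa_{between}$ (off by default). The generator emulates the *structure*
of the human data — design cardinalities, circular noise around one model,
subject nesting — but not its content: real estimates mix both models'
failures with memory and motor noise, contain per-pair idiosyncrasies, and
their noise need not be von Mises. Passing pipeline tests on synthetic data
therefore validates the machinery and its statistical calibration, not any
claim about which model fits humans better.

`make_euclidean_maze()` grows random rectilinear corridor trees (plus
optional loop edges) on a unit grid; these are the consistent-label
controls on which all three models must agree.

## Numerical choices and degenerate inputs

* Angles are degrees counterclockwise from east; turns in
  $(-180^\circ, 180^\circ]$, absolute directions in $[0, 360)$.
* $R$ is snapped to 1 within machine precision so $AD = 0$ holds exactly
  for coincident angles; $R = 0$ leaves the mean direction flagged
  undefined rather than silently zero.
* Zero-length segments, dangling references and disconnected layouts are
  validation errors; shortcut prediction between coincident start and goal
  is an error (direction undefined), as is a zero resultant vector.
* Equal-cost shortest paths break ties toward the lexicographically
  smallest vertex sequence; triplet enumeration is lexicographic — results
  are bit-reproducible given seeds.
* Non-finite noise concentrations mean "noiseless" in the generator, and
  the von Mises $\kappa$ estimate is capped at $10^4$.

## Problem sizes

The shipped tests embed mazes of 10–40 vertices with 15–200 restarts,
calibrate the Watson–Williams test on 2000 two-group simulations, and run
the full pipeline on the 264-measurement design; this keeps the whole suite
under a minute while exercising every claim at meaningful scale. Larger
mazes and restart counts change nothing structurally — cost grows linearly
in triplets and restarts.

## Limitations

* The replica maze is schematic; its corridor lengths and wormhole
  positions are design choices, not measurements, so quantities that
  depend on the exact geometry (stress values, specific prediction angles)
  are not comparable to any particular experiment — only the structural
  phenomena (residual stress, multiple minima, wormhole-ward distortion)
  are.
* The embedding assigns coordinates only to vertices; non-vertex places
  must be snapped or promoted to vertices first.
* Only 2D embeddings are implemented, and only initial shortcut directions
  are predicted — no trajectories, no learning dynamics, no hierarchical
  or region-based map structure.
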