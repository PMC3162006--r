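---
title: "Phase-plane hysteresis as a guide to model reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-plane hysteresis as a guide to model reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseloop)
```

## The idea

Reducing a kinetic model means deciding which species equilibrate so fast,
relative to the dynamics of interest, that their differential (or implicit
algebraic) equations can be replaced by explicit steady-state relations.
`phaseloop` makes that decision graphically. Drive the system with a single
transient input — on for a window, then off — starting from the resting
steady state. Each species traces a concentration timecourse that rises and
then relaxes back; plot one species against another and the on and off
branches form a closed loop. If the pair equilibrates quickly, both
branches hug the same steady-state curve and the loop is thin; if one
species lags the other, the branches separate and the loop encloses area.
After normalizing each trace to $[0,1]$ via
$x_\mathrm{norm}(t) = (x(t) - x_\min)/(x_\max - x_\min)$, the enclosed area
is a dimensionless hysteresis measure between 0 (no timescale separation)
and 1 (complete separation), comparable across pairs whose concentrations
differ by orders of magnitude.

The area of the closed polygonal loop through the points $(X_i, Y_i)$ is
computed with the midpoint rule on the ordinates,

$$ A \;=\; \Bigl|\sum_i \tfrac12\,(Y_{i+1} + Y_i)\,(X_{i+1} - X_i)\Bigr|, $$

wrapping the last segment back to the first point. This is the shoelace
line integral $|\oint y\,\mathrm{d}x|$: exact for polygons, indifferent to
nonuniform spacing in $X$, $Y$ or time, and well behaved when the loop
switches concavity. For self-intersecting (figure-eight) loops the signed
lobes cancel under this definition; `loop_area(..., method = "split")`
instead detects segment crossings, splits the loop and sums absolute
sub-areas. The signed definition is the default because it is the literal
line integral; the split mode is available for systems with adaptive
responses whose loops pinch into two lobes.

## From areas to a reduced model

Computing the area for every pair of non-constant states gives a symmetric
**area matrix**. In networks with genuinely separated kinetics its
histogram is trimodal, and pairs are classified **fast** (area $\le 0.05$),
**medium** ($0.05 <$ area $\le 0.5$) or **slow** ($> 0.5$). The bin at
exactly 0.05 closes downward (fast); both thresholds are arguments of
`speed_thresholds()`. Only **direct** pairs — where one state's rate or
algebraic expression references the other, detected mechanically from the
expression trees by `direct_pairs()` — are meaningful for reduction;
indirect pairs inherit separation through intermediates.

For each fast direct pair the downstream state is re-expressed as an
explicit function of its parent. The function comes from a **concentration
clamp**: the parent is frozen at a value (its equation removed, the value
held constant), the rest of the system is run to steady state with the
stimulus input held at its "on" value, the downstream steady state is
recorded, and the sweep is repeated across the parent's range. By default
the sweep is 25 linearly spaced points from 0 to 1.5 times the parent's
maximum over the reference transient — wide enough that later evaluation
rarely extrapolates (extrapolation is flagged when it happens, and
log-spacing is available for ranges spanning decades). Each candidate form

* Hill $y = y_\max x^h/(K^h + x^h)$ (baseline 0, $K>0$, $h>0$),
* linear $y = a x + b$,
* exponential $y = a e^{rx} + c$,
* power $y = a x^b$,

is fitted by Levenberg–Marquardt least squares (Hill starts: $y_\max$ at
the maximum response, $K$ at the half-maximum abscissa, $h$ multi-started
over $\{0.5, 1, 2, 4\}$; the exponential is seeded by a log-linear
regression against both plausible offsets) and the least-RMSE form wins,
with near-ties resolved toward the simpler form so that exactly linear
data are reported as linear rather than as a power law with unit exponent.
A specific form can always be forced per pair. In the assembled reduced
model the fitted expressions clamp their abscissa at zero
(`pmax(parent, 0)`), because a stiff solver may round a concentration to
$-10^{-12}$ µM and a fractional power of a negative number is undefined.

Reductions that encode conservation or abundance arguments — eliminating a
state via a conservation total, approximating a free concentration by its
total, setting a pool to zero or equal to another — carry model-specific
knowledge and are therefore supplied by the user as explicit
`reduction_action()`s rather than proposed automatically. `apply_plan()`
rewrites the model (reduced species remain predicted, as explicit
algebraic variables), refuses cyclic reductions, and prunes parameters no
longer referenced by any remaining expression. That pruning is what makes
a reduced model *structurally insensitive* to perturbations of mechanisms
it eliminated — the perturbation suite reports such cases instead of
pretending a response.

Accuracy is scored per species as the time-averaged absolute difference
between reduced and original trajectories divided by the original state's
dynamic range over the protocol, times 100 — the same range normalization
used for the loops. A pointwise relative metric is available behind
`metric = "relative"`. Species fixed under the protocol have no range and
are excluded automatically; the overall error is the arithmetic mean over
included species.

## Numerical choices

Simulation integrates the stimulus and washout segments separately with
the input parameter switched between them, avoiding a discontinuous
right-hand side. Pure-ODE systems use `lsoda` (relative tolerance
$10^{-8}$, absolute $10^{-10}$ µM); systems with implicit algebraic states
are treated as semi-explicit index-1 DAEs via `daspk`, after a Newton
solve makes the algebraic states consistent at the initial time, and the
residuals are re-verified at every output time. The default output grid is
2000 uniform samples over the combined on+off window; on the built-in
three-species pathway, doubling the grid changes any loop area by less
than $10^{-3}$, which is the grid-convergence criterion that stands in for
an output-density prescription.

Steady states satisfy the scale-free criterion
$\max_i |\dot x_i| / \max(|x_i|, 1\,\mu M) < 10^{-8}\,s^{-1}$. The solver
tries a damped Newton polish first and falls back to integration over
doubling horizons (then polishes) when Newton fails or lands on a negative
concentration; divergence beyond $10^{12}$ µM and exhausted horizons are
reported as errors, and non-convergent clamp sweep points are flagged
rather than dropped. Constant traces cannot be normalized; a state whose
range is below $10^{-8}$ of its magnitude is flagged static and excluded
from phase analysis instead of being divided by zero.

The Jacobian of the stacked system (ode derivatives plus algebraic
residuals, ordered by state) is computed by central differences with per
component steps $\varepsilon^{1/3}\max(|x_j|,1)$. Modal analysis
eigen-decomposes $J = M\Lambda M^{-1}$ and reports timescales
$\tau_i = -1/\mathrm{Re}(\lambda_i)$ sorted slow to fast. Modal rows are
computed as left eigenvectors matched to the eigenvalues — identical (up
to scale) to rows of $M^{-1}$ when $J$ is diagonalizable, and still
meaningful for isolated modes when it is not — normalized to unit
Euclidean length, with a species reported as dominating a mode when its
entry magnitude exceeds 0.09. The state variables are not rescaled before
thresholding; with unit-normalized rows this is the conventional choice,
but dominance calls near the threshold can depend on it. Complex-conjugate
pairs are folded into one reported mode; modes with $\tau \le 1$ ms are
labelled algebraic-relationship modes. A defective or near-defective
eigenvector matrix (condition number above $10^8$) is flagged and the
affected modes marked unreliable — the built-in toy pathway is itself such
a case, since its rate matrix has the repeated eigenvalue $-1$ s$^{-1}$
with a single eigenvector. `compare_methods()` tabulates, per species,
"fast by the Jacobian" (dominates a mode faster than a cut, by default the
geometric mean of the slowest and fastest timescales) against "fast by the
phase planes" (member of a fast direct pair); partial agreement is the
expected outcome, because modes are linear combinations of species at one
steady state while loops measure nonlinear pairwise dynamics.

## The built-in models and the synthetic generator

The toy pathway is the linear irreversible chain source → A → B → C →
sink with $\dot A = k_1 - k_2 A$, $\dot B = k_2 A - k_3 B$,
$\dot C = k_3 B - k_4 C$, $k_2 = 1$, $k_3 = 10$, $k_4 = 1$ s$^{-1}$ and a
zeroth-order source $k_1 = 100$ µM s$^{-1}$ during a 10 s stimulus window
(0 otherwise). During sustained stimulus its steady state is
$A = 100$, $B = 10$, $C = 100$ µM, so B tracks one tenth of A. Under the
default protocol the A–B loop area evaluates to 0.091 and the B–C area to
0.496, so the A–B reduction is exercised at a threshold of 0.1: the
trimodal 0.05/0.5 thresholds describe a 25-variable network's histogram,
and a three-species chain with a single 10-fold rate ratio sits just above
the lower one. With that threshold the proposed plan replaces B by the
clamp-fitted linear relation $B = 0.1\,A$ and keeps A and C as ODEs, and
the resulting 2-ODE model reproduces the full transient with a mean error
of about 0.7% of dynamic range.

`generate_cascade()` builds linear mass-action chains S1 → … → Sn with a
switchable zeroth-order source; the Jacobian is lower bidiagonal with
eigenvalues equal to minus the rate ladder, so every analysis stage has an
analytic oracle. When no ladder is given, rates are drawn log-uniformly
from $[0.1, 100]$ s$^{-1}$ under a caller-supplied seed (isolated from the
session RNG) — a range wide enough that a four-species draw usually
contains fast, medium and slow adjacent pairs, which is what the
soundness checks need. The matching protocol scales its window to eight
times the slowest chain timescale so every species both equilibrates and
relaxes. These cascades emulate the *timescale structure* of signalling
pathways, not their nonlinearity: they contain no saturation, feedback or
conservation cycles, so passing tests demonstrate correct area
computation, clamp fitting and reduction bookkeeping — they do not by
themselves certify behaviour on strongly nonlinear real networks. The
package-level checks therefore exercise problem sizes of a few species
with 600–2000 output samples and a 25-point clamp sweep; the method
itself has no such limits.

The 25-variable cardiac β1-adrenergic signalling model that motivates the
workflow is handled as a *transcription fixture*: its equations are data
(a declarative model file or CellML), not hand-written code, because
transcription fidelity is the dominant risk and a data file can be
reviewed line by line against its source. The published equations and
parameter tables are not bundled with this package, so
`load_bar_model()` signals an explicit fixture-unavailable condition
until a user supplies a transcription (whose structural counts — 25
states, 12 ODEs, 13 implicit algebraic equations for the full variant —
are validated at load). The five stimulus scenarios
(`iso_1uM`, `iso_0p05uM`, `fsk_10uM`, `ibmx_100uM`, `pp1_knockout`) ship
as code. The resting initial conditions of a transcription are computed
by `find_steady_state()` at zero input rather than read from a table, so
a transcription that ships its own initial conditions should be checked
against that resting state.

## Design decisions that were genuinely open

* **Direction of a reduction.** A fast direct pair is reduced by
  rewriting the *downstream* state (the one whose expression references
  the other). Mutually coupled pairs (mass-action binding, where each
  references the other) have no canonical direction; proposing both
  directions would be circular, so the plan proposal rejects the cycle
  and asks for a `prefer_parent` choice instead of guessing.
* **Error metric.** "Mean error" of a reduced trajectory is defined
  against the original state's dynamic range rather than pointwise
  relative error, keeping it consistent with the loop normalization and
  finite for states that pass through zero; the pointwise variant remains
  available as an option.
* **Boundary convention.** An area of exactly 0.05 classifies as fast
  (closed lower bin). The choice matters only for areas landing exactly
  on a threshold and is configurable.
* **Defective Jacobians.** Rather than failing, the modal decomposition
  reports timescales (which remain well defined), flags the defect, and
  marks the affected modes unreliable, since isolated fast modes are
  typically still trustworthy.
* **Exponential vs power for saturating-but-unsaturated clamps.** Both
  forms are always offered and selection is by least RMSE; when two
  forms describe a sweep equally well the reported form is the simpler
  one, and the choice can be overridden per pair.

## Known limitations

Closed loops require a return to the starting steady state; multistable
systems whose off branch relaxes to a different attractor produce
non-closed "loops", and a large gap between a loop and its clamp curve is
the corresponding warning sign here. The clamp procedure assumes the
remaining system reaches a unique steady state at every sweep value;
non-convergent points are flagged but not resolved. Conservation
constraints are monitored, not enforced, and constraints involving a
clamped species are necessarily suspended during its sweep. The CellML
importer covers only the arithmetic single-component subset needed for
plain reaction models and refuses anything else explicitly. Oscillating
systems, which trace closed loops without any external stimulus, are
compatible with the area measure but not with the transient protocol
driver as written.
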