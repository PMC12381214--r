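---
title: "Methods: force-spectroscopy analysis and multi-state catch-bond modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-spectroscopy analysis and multi-state catch-bond modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchbond)
```

## Scope

`catchbond` implements the analysis stack for AFM-based single-molecule
force spectroscopy (SMFS) of a receptor:ligand complex that unbinds
through multiple pathways — the situation encountered for the sperm-egg
adhesion complex Izumo1:Juno, where constant-speed pulling resolves
three unbinding modes (P0 < P1 < P2 by rupture force) and force-clamp
experiments show bond lifetimes that first rise and then fall with
force (a catch-slip signature). The package covers, end to end:

1. polymer elasticity models (freely rotating chain, worm-like chain),
2. a synthetic-data module that generates curves, clamp traces,
   rupture tables and titrations with known ground truth,
3. the curve pipeline (baseline, peak detection, prefilter,
   contour-length transform, fingerprint identification, rupture and
   lifetime extraction),
4. Gaussian-mixture pathway classification,
5. energy-landscape estimation (histogram off-rate transform,
   Dudko-Hummer-Szabo and Bell-Evans fits),
6. a reversible three-state kinetic Monte Carlo simulator with
   random-search fitting of the hidden inter-state barriers,
7. the statistical protocols (Shapiro-Wilk screen, Kruskal-Wallis with
   Dunn or Wilcoxon post hocs, compact letter displays, Hill fits).

Because no raw AFM dataset is distributed, all validation rests on
analytic oracles and parameter recovery from the synthetic generators;
what that does and does not demonstrate about real data is discussed at
the end.

## Polymer models and the contour-length transform

Force-extension data are mapped into contour-length space with the
freely rotating chain (FRC): rigid bonds of length $b$ joined at fixed
angle $\gamma$, with Kuhn length
$a = b(1+\cos\gamma)/((1-\cos\gamma)\cos(\gamma/2))$ and persistence
length $p = b\cos(\gamma/2)/\lvert\ln\cos\gamma\rvert$. The relative
extension is piecewise in the dimensionless force $Fb/k_BT$:
$Fa/3k_BT$ below $b/p$, $1-(4Fp/k_BT)^{-1/2}$ between $b/p$ and $p/b$,
and $1-(cFb/k_BT)^{-1}$ above, with $c = 2$. The FRC is preferred over
the worm-like chain here because measured rupture events span tens to
hundreds of pN, beyond the range where the Marko-Siggia interpolation
is accurate.

Choices a user should know about:

* **FRC defaults** $b = 0.4$ nm, $\gamma = 41^\circ$, $c = 2$: standard
  polypeptide values for this model family. They are configurable; all
  tests use the defaults.
* **Branch boundaries**: the published inequalities are strict on both
  sides, leaving the boundary points unassigned; the package assigns
  exact equality to the middle branch. The piecewise law is not forced
  to be continuous — `frc_branch_diagnostics()` reports the jumps
  instead of hiding them.
* **Noise floor**: inverting $L = x/(x/L)(F)$ amplifies force noise
  hyperbolically as $F \to 0$, so samples below 10 pN (default) are
  returned as flagged `NA`, never as zeros. Above ~50 pN the inversion
  is flat to well under a nanometre at 2 pN force noise.
* **Thermal scale**: $k_B = 0.013807$ pN·nm/K and $T = 298.15$ K by
  default ($k_BT \approx 4.12$ pN·nm), configurable through
  `thermal_context()`.

The worm-like chain (Marko-Siggia interpolation,
$F = (k_BT/p)\,[1/(4(1-x/L)^2) - 1/4 + x/L]$) is used where the
*simulators* need a force from an extension; the cited source for the
simulation protocol names only "a worm-like chain model", so the
interpolation form is this package's documented choice.

## Curve pipeline

The analysis of a retraction curve proceeds: baseline subtraction
(line fit to the post-rupture zero-force tail; a candidate tail with
slope above 0.2 pN/nm is not a credible baseline and the curve is
flagged instead), peak detection (running-median smoothing, candidate
apexes from sign runs of the force differences, screened by topographic
prominence and by the depth of the following drop, both defaulting to
10 pN), and the prefilter that removes curves with a peak within the
first ~100 nm of extension, with no peaks, or with more than 9 peaks —
the signatures of surface adhesion, empty approaches, and multiple
tethers.

Surviving curves are transformed to contour-length space and classified
by their single-molecule fingerprint:

* **Criterion 1** — a terminal rupture below 100 pN at a contour length
  near the pre-unfolding construct (135 nm target), with no
  fingerprint-window peaks.
* **Criterion 2** — four unfolding peaks inside the 50–80 pN window
  whose contour increments sum to 32 nm (two fingerprint domains, two
  events each), followed by rupture near the fully unfolded contour
  (190 nm target).

The quoted lengths carry tildes in their source; the tolerances that
make them operational (±10, ±10, ±15, ±4 nm; the force window is hard)
are explicit arguments of `fingerprint_criteria()`. The loading rate of
a rupture record is the slope of a force-versus-time line fitted from
the last local force minimum before the terminal peak, restricted to
forces above 30% of the rupture force — the extraction window is not
specified by the source protocol, so it is a documented, configurable
rule here. Subtypes are labelled a (criterion 1), b (criterion 2, no
intermediates), c (with intermediates); the a/b/c convention is an
assumption recorded as such, since the original taxonomy is defined
only graphically.

Force-clamp traces are filtered against the signatures of non-specific
clamping: more than three discrete head-height steps (a "step" is a
jump above 5 nm between feedback plateaus — the threshold is ours, the
count rule is the published one), retraction distances outside
40–200 nm, and lifetimes under the 15 ms feedback-regularisation floor.
The realised setpoint is the highest mean force over any sliding ~5 ms
window during the clamp; the lifetime runs from clamp start to the
resumption of retraction.

## Pathway classification

Pooled rupture forces are square-root transformed and z-standardised
(the transform tames the heavy right tail of the strong pathway;
"normalised" in the source protocol is not further specified, so
standardisation is the documented choice, and it is exactly invertible).
Mixtures of 1–4 univariate unequal-variance Gaussians are fitted with
mclust and the component count selected by BIC; mclust's model-based
hierarchical initialisation makes the fit deterministic, which is why no
restart machinery is layered on top. Components are relabelled by
ascending mean, giving the canonical P0 < P1 < P2 order; records are
assigned by maximum responsibility with ties broken toward the
lower-mean component.

When a fourth component is selected it is treated as experimental
variance, not a new pathway: among the components that overlap another
one (Bhattacharyya coefficient above 0.1 — the overlap criterion is
ours), the smallest-weight component is dissolved and its records
reassigned by maximum remaining responsibility. Restricting the
candidate set to *overlapping* components matters: the smallest-weight
component overall is frequently a genuine, well-separated minor pathway.

Per-speed pathway proportions are means across independent experiments
with the SEM across experiments; a single experiment reports `NA`
rather than a fabricated error bar.

## Energy-landscape estimation

Per pathway, rupture forces pooled over all speeds are binned
(10 pN default) and each bin converted to a force-dependent off-rate:

$$k_\mathrm{off}(F_k) = \frac{h_k\, r(F_k)}{\left(h_k/2 +
\sum_{i>k} h_i\right)\Delta F}, \qquad h_k = \frac{C_k}{C_\mathrm{tot}\,\Delta F},$$

with $F_k$ and $r(F_k)$ the in-bin medians of rupture force and loading
rate. Bins with fewer than 3 records are merged into their
larger-population neighbour (the source is silent on sparse bins); the
transform then uses per-bin widths, which reduces to the equal-width
formula when no merging occurs.

The Dudko-Hummer-Szabo model

$$k_\mathrm{off}(F) = k_0\left(1 - \frac{\nu F \Delta x}{\Delta
G^\ddagger}\right)^{1/\nu - 1} \exp\!\left\{\beta\Delta G^\ddagger\left[1 -
\left(1 - \frac{\nu F \Delta x}{\Delta G^\ddagger}\right)^{1/\nu}\right]\right\}$$

is fitted to $\ln k_\mathrm{off}$ versus $F_k$ by Levenberg-Marquardt
(minpack.lm) from starting points drawn uniformly within the search
bounds $k_0 \in [0.001, 20]$ s$^{-1}$, $\Delta x \in [0.001, 2]$ nm,
$\Delta G^\ddagger \in [0.01, 20]$, for both barrier shapes
$\nu = 1/2$ (cusp) and $1/3$ (linear-cubic). Numerical choices:

* $\Delta G^\ddagger$ is carried in $k_BT$ units (the published bounds
  are unit-silent; in these units $\beta\Delta G^\ddagger$ is the plain
  number, which is also what makes the $[0.01, 20]$ range physically
  sensible).
* The SSR is computed on $\ln k_\mathrm{off}$, matching how the
  quantity is plotted and fitted.
* All random starts are first scored by their initial SSR and only the
  best `optimize_top` (default 200) are polished by the optimiser; with
  the default 10,000 starts this is indistinguishable from optimising
  every start and an order of magnitude faster.
* Three independently seeded runs guard against a lucky basin; best
  SSRs differing by more than 1% raise a warning.
* At $\nu = 1$ the shape factor cancels algebraically and the model
  *is* the Bell rate; $\Delta G^\ddagger$ is then unidentifiable and
  reported `NA` rather than a random bound value.
* Outside the physical region $\nu\beta F\Delta x \ge \Delta
  G^\ddagger$ the rate is undefined and reported `NA`.

The companion force-versus-loading-rate curve is the standard
leading-order typical-rupture-force expression
$F(l) = \frac{\Delta G^\ddagger}{\nu\beta\Delta x}\left[1 -
\left(\frac{1}{\Delta G^\ddagger}\ln\frac{k_0 e^{\Delta
G^\ddagger}}{\beta\Delta x\, l}\right)^\nu\right]$ (with $\Delta
G^\ddagger$ in $k_BT$); its bracket vanishes at the critical loading
rate, giving the barrier-disappearance force
$\Delta G^\ddagger/(\nu\beta\Delta x)$. Being an asymptotic expression,
it tracks the numerically computed distribution mode closely at
moderate loading rates and deviates as the critical force is
approached; the tests pin both regimes.

The Bell-Evans route fits the per-speed median rupture force against
the log median loading rate,
$F = (k_BT/\Delta x)\ln[r_f\Delta x/(k_0 k_BT)]$, by unweighted least
squares (weighting across speeds is unspecified in the source;
unweighted is the documented default).

## Kinetic Monte Carlo and hidden-barrier fitting

The bond is a three-state graph: N ruptures through P0, I1 through P1,
I2 through P2; forward transitions N→I1→I2 always exist, reverse
transitions exist iff the model is reversible. Every edge is Bell:
$k(F) = k_0 e^{\beta F\Delta x}$.

**Constant speed.** Force values are generated by the WLC across an
evenly spaced molecular extension axis (0.1 nm default — the source's
"evenly distributed" axis has unstated resolution), head height
$H = X + F/k_c$ adds the cantilever deflection, and time advances by
$\Delta t_i = \Delta H_i / V$. Per interval, each edge leaving the
current state converts its rate into $P = 1 - e^{-k\Delta t}$, the
eligible events are shuffled, and the first whose independent uniform
draw succeeds executes — the literal reading of the published
"randomly shuffled and the first event executed" rule. Rupture records
the current force and pathway; a tether reaching full extension first
is censored.

**Force clamp.** Identical rules at fixed force with a constant
interval (default $10^{-4}$ s) and a 10 s cap mirroring the
experimental maximum clamp time. The published description multiplies
the off-rate by "the total time elapsed" to get a rupture probability;
taken literally that probability exceeds 1 within a second for ordinary
rates, so the per-interval form $1 - e^{-k\Delta t}$ (the constant-speed
rule, which the same description says the clamp follows) is implemented.
Because the force is constant within a state, the waiting time in a
state is geometric in the number of intervals; the implementation
samples it directly and draws the executed event from the exact
shuffle-order distribution enumerated over the ≤3 eligible edges —
distribution-identical to stepping interval by interval, and what makes
$10^{-4}$ s intervals affordable over 10 s clamps. A warning is raised
when $\Delta t \cdot \max k > 0.1$.

The C++ core uses a package-owned xoshiro generator with
per-replicate substreams derived from the master seed, so results are
bitwise reproducible across platforms and replicate order.

**Hidden-barrier fitting.** The inter-state barriers leave no
observable signature in individual curves, so their Bell parameters are
fitted by random search: candidates drawn uniformly within
$k_0 \in [10^{-5}, 100]$, $\Delta x \in [0.01, 10]$ (the published
ranges; uniform sampling in linear space follows the published
procedure), each scored by simulating the constant-speed protocol at
every target speed and summing squared residuals between
probability-normalised 20 pN histograms. Start draws and simulation
substreams are both re-randomised per start; during the local polish of
a start (coordinate-wise multiplicative line search in log space, step
shrinking golden-ratio style — the source says only that candidates
"underwent optimization") its simulation seed is frozen so the local
objective is deterministic. `compare_transition_models()` refuses
unequal budgets, fits both topologies against the same targets, and
prefers the lower total SSR.

**Default catch-bond parameter set.** `default_state_model()` encodes
the landscape ordering that produces catch bonding — $\Delta x$
decreasing P0→P1→P2 (0.8, 0.3, 0.12 nm) with increasing barrier
stability ($k_0$ = 5, 0.5, 0.1 s$^{-1}$), strongly force-promoted
forward transitions and fast low-force reverse transitions. Under
force clamp its mean lifetime rises from milliseconds at low force to
an interior maximum near 50 pN and falls again, the slip-catch-slip
signature; the exact published parameter values live in supplementary
tables that are not part of the package inputs, so this set is the
package's own reference construction satisfying the stated ordering
constraints, chosen once and used as the generator default.

## Synthetic data: what it emulates, what it does not

`generate_constant_speed_curve()` renders: FRC tether elasticity with
total handle contour 130 nm (two ~65 nm elastin-like spacers) plus a
folded-protein offset (default 28 nm, one free parameter — the
decomposition of the ~190 nm final contour into handle and folded
contributions is not knowable from the curves); four fingerprint
unfolding events at thresholds drawn in 50–80 pN, each adding 8 nm
(32 nm total); optionally one intermediate unfolding event (lognormal
increments, median 15 nm, matching the reported ~15–20 nm range) for
P1/P2 ruptures; and a terminal rupture whose force and pathway come
from the kinetic Monte Carlo on the fully extended tether. Gaussian
force noise, linear baseline drift, and non-specific adhesion
artifacts (spurious peaks within the first 100 nm, which the prefilter
must reject) are configurable. The apex sample of each event is
rendered at the event force, so at zero noise the pipeline recovers
every event force, extension and increment exactly — the round-trip
property the test suite leans on. Clamp traces carry a loading ramp,
a jittered plateau (default 1.5 pN jitter; the instrument holds
setpoints to within ~5 pN), injectable head-step and retraction
artifacts, and a truth lifetime from the clamp driver.

Not emulated: thermal cantilever dynamics, hydrodynamic drag,
instrument feedback beyond setpoint jitter, the 0.2 s surface dwell
(curves start at retraction), or multiple simultaneous tethers.
Passing tests therefore demonstrate correctness of the *analysis logic*
under the stated noise model, not robustness to every artifact of real
AFM data — which is why the filters expose all thresholds as arguments
and the pipeline reports flags instead of silently dropping data.

Problem sizes in the tests and acceptance script (500 replicates per
speed for constant-speed checks, 1000 for clamp oracles, 300–400 per
speed for recovery suites, 100 starts × 100 replicates for the model
comparison, DHS searches of a few hundred starts) are the package's
test-scale defaults; the user-facing defaults (10,000 DHS starts,
10,000 search repeats, 500 replicates) match the published protocol.

## Statistics

Lifetimes are binned at 10 pN. Because multi-pathway unbinding mixes
distributions, normality is screened per bin (Shapiro-Wilk, α = 0.05)
and hypothesis testing is nonparametric: Kruskal-Wallis followed by
Dunn's z-tests on pooled mid-ranks with tie-corrected variance and
Šidák adjustment $p' = 1-(1-p)^m$ (m = all pairs within a panel, the
documented default since the source does not define m), or by pairwise
Wilcoxon rank-sum tests where that protocol is called for. Compact
letter displays come from insert-and-absorb over groups ordered by mean
rank: groups share a letter iff their adjusted p exceeds α. All
identical data yield an omnibus p of 1 by convention. Dunn's test is
implemented from the standard formulas because no pre-installed package
provides it; Kruskal-Wallis, Wilcoxon, Shapiro-Wilk and p-value
adjustment are base R.

Titrations are fitted to the Hill isotherm with the coefficient bounded
to [0.5, 4] and initialised over a log grid (whether the original fits
fixed n = 1 is unstated; the bounds make both behaviours reachable),
standard errors from the fit covariance.

## Known limitations

* Pathway-conditioned rupture-force distributions in multi-state ramps
  are biased relative to their generating single-barrier distributions
  whenever a transition competes inside a rupture window
  (differential censoring). The recovery tests use fixtures whose
  transition edges share the source state's $\Delta x$ (proportional
  hazards), where $\Delta x$ remains identifiable; with strongly
  non-proportional competition, per-pathway Bell fits should be read as
  effective parameters.
* The mixture model assumes Gaussian components in sqrt-force space;
  heavily skewed pathway distributions (a soft pathway with a long
  low-force tail below the detection floor) can make BIC prefer
  splitting one skewed mode over separating true modes.
* The DHS force-versus-loading-rate expression is leading-order and
  deviates near the critical force.
* The random-search barrier fit inherits Monte Carlo noise in its
  objective; equal budgets and seed logging make comparisons fair, not
  noiseless.
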