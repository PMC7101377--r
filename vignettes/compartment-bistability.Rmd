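---
title: "Compartment-induced bistability: models, detection, and robustness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-induced bistability: models, detection, and robustness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compswitch)
```

## The system

A single phosphorylation–dephosphorylation cycle — substrate $S$
phosphorylated to $S^*$ by a kinase $E$ through an intermediate complex $X$,
and dephosphorylated by a phosphatase $F$ through a complex $Y$, all with
mass-action kinetics — is monostable in a well-mixed compartment. Placing one
copy of the cycle in the nucleus and one in the cytosol, and letting $S$,
$S^*$, $E$ and $X$ shuttle between the compartments with first-order rates
$k_\text{in}, k_\text{out}$, creates positive feedback: sequestration of the
kinase by substrate in one compartment propagates, through the transport
reactions and the conservation of total substrate and total kinase, into
activation in the other. For suitable rate constants the stimulus–response
curve (total kinase $E_\text{tot}$ in, nuclear $S^*$ out) becomes
discontinuous and hysteretic — the hallmark of bistability.

`compswitch` implements this model family and the analysis pipeline around
it:

* `build_model()` — the dimensional two-compartment cycle (`FULL_DIM`, 12
  species, 23 control parameters: 12 biochemical rates, 8 shuttling rates,
  3 total concentrations, with $E_\text{tot}$ as the stimulus), its
  dimensionless form (`FULL_NONDIM`, 21 free parameters plus the stimulus
  $c_1 = E_\text{tot}/S_\text{tot}$), and a chain of reductions:
  `MODEL_B` (cytosolic phosphatase removed), `MODEL_C` (nuclear
  dephosphorylation collapsed to a single step), and `MINIMAL` (nuclear
  phosphorylation collapsed to a single step, substrate transport made
  irreversible; 7 species, 2 conservation laws, hence 5 independent
  variables, and 8 dimensionless parameters).
* `sweep_up_down()` / `classify()` — the going-up/coming-down analysis that
  detects hysteresis.
* `lhs_sample()` / `run_sweep()` / `analyze_sweep()` — log-uniform Latin
  hypercube exploration of parameter space with enrichment and influence
  statistics.
* `score_hysteresis()` — width, loop area and branch distances of a bistable
  response.
* `injectivity_analysis()` / `find_feedback_loops()` — the symbolic Jacobian
  injectivity criterion and the positive feedback loops it implicates.

## Nondimensionalization

Concentrations are scaled by the total substrate $S_\text{tot}$ and time by
the nuclear phosphatase catalytic rate $1/k_\text{cat,F}$. Every bimolecular
rate becomes $k\,S_\text{tot}/k_\text{cat,F}$, every unimolecular rate
$k/k_\text{cat,F}$, leaving 11 free biochemical ratios (`b1`–`b11`;
$k_\text{cat,F}$ itself is pinned to 1), 8 scaled shuttling rates
(`s1`–`s8`, ordered out/in for $S$, $S^*$, $E$, $X$), and two concentration
ratios $f_1 = F_\text{tot}/S_\text{tot}$, $f_2 = F^c_\text{tot}/S_\text{tot}$
— 21 free parameters, exactly the count of the dimensionless system. A unit
test verifies that dimensional and rescaled nondimensional trajectories agree
to better than $10^{-6}$ relative error.

The minimal model's time unit is its pseudo-first-order nuclear
dephosphorylation rate (pinned to 1), leaving `b1` (nuclear
phosphorylation), `b2`, `b3`, `b4` (cytosolic binding, unbinding, catalysis)
and `s1`–`s4` ($E$ out/in, $S$ out, $S^{c*}$ in). The published reduced
system's own symbol table is not available, so symbol-level identity with
the reference analysis cannot be guaranteed; all statistics are therefore
also reported by parameter *class* (biochemical vs shuttling), which is
parameterization-independent. We checked empirically that pinning a
different rate as the time unit (cytosolic catalysis, unbinding, or nuclear
phosphorylation) does not change the order of magnitude of any headline
statistic.

```{r counts}
structural_counts(build_model("FULL_DIM"))$parameters_total
structural_counts(build_model("MINIMAL"))[c("independent_variables", "parameters_total")]
```

## The going-up/coming-down sweep

For each stimulus on an ascending log grid the system is relaxed to steady
state; the next stimulus is warm-started from the previous steady state,
multiplied by $1+10^{-4}$ on its nonzero entries and re-projected onto the
conservation laws (the kinase total is moved to the new stimulus by
adding/removing free cytosolic kinase, draining complexes — which return
their substrate — only when the free pools are exhausted). The descending
branch starts from the final ascending state. A discontinuity exists at a
grid point when the response step exceeds five times the previous step and
is larger than $10^{-3}$; one discontinuity per branch labels the pair
bistable (`stim_on` from the ascending branch, `stim_off` from the
descending one), none labels it monostable, and anything else is flagged for
further analysis. Pairs whose response never reaches $10^{-2}$ are excluded
from downstream statistics (recorded as monostable with
`passed_response_floor = FALSE`).

Numerical choices that matter:

* **Integrator.** Relaxations use an L-stable two-stage Rosenbrock method
  implemented in C with the analytic mass-action Jacobian (path tolerances
  `rtol = 1e-4`, `atol = 1e-9`), so a whole up/down sweep is one C call and
  a 5,000-point study runs in minutes on one CPU. `steady_state()` also
  offers `deSolve::lsoda` as an independent backend; the two agree to
  $10^{-5}$ on random parameter sets (tested), and steady states satisfy
  the rate equations to near machine precision after a Newton polish.
* **Convergence is equilibrium-verified.** A state counts as steady only
  when the relative rate of change is below $10^{-6}$ per unit time *and* a
  Newton iteration (with conservation laws substituted) lands on a true
  nearby equilibrium. Without the second condition, trajectories crossing a
  saddle-node ghost — where the flow is slow but no equilibrium exists —
  are recorded as spurious "steady states" that lag behind the true branch;
  ascending and descending passes then lag in opposite directions, and a
  steep but perfectly continuous (ultrasensitive) response acquires an
  artificial hysteresis gap. We found this artifact inflates the bistable
  count several-fold at loose tolerances (see *Known limitations*).
* **Grid density.** Default 10 points per decade (configurable). The label
  and thresholds of verified bistable points are stable under grid doubling
  (tested); density mainly affects how often steep continuous responses
  trigger one-sided (flagged) detections.
* **Stimulus ranges.** $10^{-6}$–$10^{1}$ for the minimal model,
  $10^{-3}$–$10^{3}$ otherwise.

```{r bistable}
m <- build_model("MINIMAL")
p <- c(b1 = 384.5, b2 = 420.3, b3 = 1.98, b4 = 0.175,
       s1 = 1.27e-3, s2 = 1.59e-3, s3 = 1.99e-2, s4 = 424.8)
res <- classify(sweep_up_down(m, p))
res$label; c(res$stim_off, res$stim_on)
```

## Parameter-space exploration

`lhs_sample()` draws seeded Latin hypercube samples, log-uniform per
parameter; stratification is exact (one value per equal-width stratum in
log10 space) and marginals are uniform by Kolmogorov–Smirnov (tested at
$n = 10^4$). The standard minimal-model design samples all 8 parameters on
$[10^{-3}, 10^3]$; the package default of $n = 5000$ points is a desk-scale
version of the reference 30,000-point design, chosen so that the full study
completes in a few minutes while each decade bin still holds several hundred
points (binomial standard error on a bin fraction of a few percent is below
one percentage point).

For every parameter, `analyze_sweep()` bins the sampled values into decade
classes and reports the bistable fraction per class, a hypergeometric
upper-tail enrichment p-value per class (enriched when $p < 10^{-4}$; no
further multiple-testing correction is applied beyond this fixed threshold),
and a Mann–Whitney influence ranking (bistable vs monostable values of the
parameter, two-sided normal approximation with continuity and tie
correction, sorted by $|z|$). Hysteresis metrics are binned on the fixed
logarithmic grids (7 decade classes for width, 9 for area, half-decade
classes for the branch distances) and their influence rankings split the
bistable population at metric value $10^{-1}$, the boundary of the two
highest classes.

## Hysteresis scoring

For a bistable pair: `width` $=$ `stim_on` $-$ `stim_off`; `area` is the
trapezoidal integral of (descending $-$ ascending) response over the
bistable interval on the *linear* stimulus axis, with one-sided branch
limits at the two thresholds (the branches are discontinuous exactly there;
this convention makes the ideal rectangular loop exact on any grid);
`distance_1` is the branch gap at `stim_on`; `distance_2` the descending
output just above `stim_off` minus the ascending output just below
`stim_on`. On synthetic loops with known geometry all four metrics are
recovered to better than 1% at 30 points per decade (tested). Loops so
narrow that quadrature noise makes the area negative are flagged and
excluded, mirroring the exclusion applied in the reference analysis.

## Injectivity criterion and feedback loops

Steady states are the positive roots of the polynomial map obtained by
replacing, for each conservation law, one rate equation by the law itself.
If every monomial of $\det J$ of that map has the same sign, the map is
injective on the positive orthant and multistationarity is impossible; the
minority-sign ("offending") monomials otherwise carry the structural
information. The package expands the determinant exactly (the networks here
yield at most a few thousand permutations), evaluates it against a numeric
determinant oracle (tested), and:

* reports the rate constants occurring in **every** offending monomial —
  necessary conditions for multistationarity (setting any of them to zero
  provably restores monostationarity);
* decomposes each offending permutation into cycles of the species influence
  graph and reports as *relevant* the positive cycles that are the sole
  positive cycle of some offending term — the loop the sign flip is
  attributable to;
* verifies that breaking all relevant loops (removing the reactions behind
  their mass-action edges; conservation-law edges entry-wise) restores a
  sign-uniform determinant.

Two conventions are fixed and documented because determinant sign patterns
depend on them: each conservation law replaces the equation of its free
cytosolic species (the inactive pool), and the phosphatase laws — confined
to one compartment — replace their complex. Under these conventions the
minimal model has exactly one relevant loop (it traverses the cytosolic
kinase–substrate complex and both compartments, and deleting any one of its
edges restores sign-uniformity), `MODEL_C` has 4, `MODEL_B` has 5, and the
full model 7, of which 5 involve translocation. The reference analysis
reports 6 relevant loops (4 with translocation) for the full model: our
criterion additionally implicates the nuclear phosphatase-sequestration
two-cycle ($F \leftrightarrow Y$), the mirror image of the cytosolic one,
and the loop compositions route through conservation-law coupling edges
rather than pictorial reaction paths. An exhaustive scan of the substitution
choices showed no single uniform convention that reproduces all three
published counts at once, so we report the discrepancy rather than adopt
model-specific conventions.

```{r loops}
find_feedback_loops(build_model("MINIMAL"))
```

## Synthetic fixtures

`make_synthetic_loop()` generates branch pairs with known geometry (jump
positions snapped to the grid so the recorded truth is exact), used to
calibrate detection and scoring. `discover_bistable_points()` searches
parameter space and keeps only points whose bistability is confirmed by an
independent check: relaxing from two distinct initial conditions at the
geometric mid-loop stimulus must yield two well-separated equilibria. These
verified points replace externally derived seed sets in the
restrict-then-sample strategy: `derive_restricted_ranges()` widens the
per-parameter envelope of the cache by one decade each way, and a sweep
restricted to those ranges concentrates bistability far above the
unrestricted rate (tested). `lift_minimal_to_full()` embeds a bistable
minimal-model point into the 21-parameter full model by realizing each
reduction step as an explicit limit (fast-through nuclear kinase,
unsaturated nuclear phosphatase, negligible cytosolic phosphatase,
near-irreversible substrate transport), which seeds the full-model search.

## What the synthetic studies do and do not show

The generator and the sampled studies emulate the *structure* of the
reference analysis: mass-action kinetics, two well-mixed compartments,
first-order transport, log-uniform parameter ranges. They do not emulate
features of real signaling data — molecular noise, finite copy numbers,
measurement error, gradients within compartments, or transport machinery
saturation — so passing tests demonstrate correctness of the method on the
model class, not biological validity of any particular parameter regime.

## Known limitations

* **Bistable-fraction magnitudes.** With equilibrium-verified convergence,
  the n = 5000 minimal-model study classifies ~0.2–0.3% of parameter space
  as bistable, with per-(parameter, decade-bin) maxima around 1.5–2% (low
  cytosolic catalysis, high nuclear phosphorylation, high cytosolic binding)
  and ~1% at low substrate export — the same parameters, the same
  directions, and the same zero-bistability thresholds for the loop-breaking
  rates as the reference analysis, but magnitudes several-fold below its
  printed maxima (8.5%, 4.9%, 5.1%). Relaxing the convergence criterion (relative-change threshold
  $10^{-3}$, no equilibrium verification) moves the fractions strongly
  toward the printed values by counting lag-induced pseudo-hysteresis on
  ultrasensitive responses; an independent two-initial-condition census
  confirms the lower rate for true multistationarity. The package keeps the
  rigorous criterion as its default and reports the lower numbers.
* **Loop count for the full model.** 7 relevant loops instead of 6, as
  discussed above.
* **Flagged cases.** One-sided detections on steep continuous responses are
  honest outcomes of the literal discontinuity rule; `scan_parameter_set()`
  can optionally re-scan them on a widened stimulus range and report
  one-way switches.
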