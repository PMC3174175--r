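---
title: "Event-transition Markov chains: model, calibration and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-transition Markov chains: model, calibration and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etmc)
```

## The model and its assumptions

`etmc` treats the dynamics of a gene regulatory network at the level of
*events*: a constant slope direction (`+` or `-`) of one gene product
over a time unit. The event transition graph (ETG) records which event
can immediately succeed which; it can be written by hand, loaded from a
TSV edge list, or derived from a qualitative state transition graph with
`etgFromStateGraph()` (an ETG edge per consecutive transition pair of the
state graph — the only construction computable from the state graph
alone; self-successions are kept when the state graph produces them).
Endowing the ETG with a row-stochastic matrix `P` gives the
event-transition Markov chain. Its entries are *population* quantities:
the mean fraction of trajectories (cells) crossing each transition, so a
stationary distribution of the chain — the *permanent regime* — is a
fixed mix of rising/falling transcripts across the population, not a
biological steady state.

The framework assumes the chain is *minimal* (irreducible and aperiodic;
`checkMinimality()`), which excludes intrinsically oscillatory wiring, and
that protein concentrations respond multiplicatively to events — the
standard exponential-kinetics picture for prokaryotes, where transcription
bursts amplify into protein fold-changes. Dead-end events are a hard
error rather than being silently absorbed, because every asymptotic
statement below needs minimality.

A protein `h` couples to the chain through its impact matrix: edges into
`h:+` carry the active production coefficient `s`, edges into `h:-` the
active degradation coefficient `d = 1/s`, all other edges the passive
rate `ρ`. The mean accumulated concentration from an initial event
distribution `v0` is exactly `v0' C^n 1` with `C = P ∘ I`
(`exactMean()`), and asymptotically `a·λ1^n` where `λ1` is the Perron
eigenvalue of `C` and `a = (v0·r)(l·1)` with the dominant eigenvectors
normalized by `sum(r) = 1`, `l·r = 1` (`asymptoticStats()`). Second
moments use the generating matrix `C(2)` with squared impacts; the
variance closed form `b·λ2^n − a²·λ1^(2n)` is reported when nonnegative
and replaced by the exact computation through `C(2)` powers at small `n`
where trailing spectral terms still matter. The relative error of the
asymptotic mean decays like the spectral-gap ratio
`ε = |λ_second|/λ1` to the power `n` (`convergenceError()`).

## Equilibrium calibration of the impact coefficients

The passive rate `ρ` is the model's one free scale. The default 0.95 — a
5 % decay per transition — expresses that a protein untouched by an event
only degrades naturally; it can be overridden per protein. Given `ρ`, the
active coefficient is fixed by an equilibrium principle: *with no
information (uniform transition probabilities), expected concentrations
must stay constant.* Since the mean grows as `a·λ1^n`, constancy is
exactly `λ1 = 1` for the uniform chain. Writing the column weights
`w(d)` (`1/d` on the production event, `d` on the degradation event, `ρ`
elsewhere), the function `d ↦ d·det(I − P·diag(w(d)))` is a degree-two
polynomial in `d` — the production and degradation events are single
columns, so the determinant is affine in `1/d` and in `d` separately —
and the calibration takes its unique root in (0, 1), verifying that the
resulting cost matrix has dominant eigenvalue 1 to 1e-9
(`equilibriumDegradation()`). Degenerate cases are surfaced, not patched:
`ρ = 1` always admits the trivial root `d = 1` (no passive decay to
compensate) and is flagged with a warning; graphs in which every cycle
visits the production and degradation events equally often have a
`d`-independent determinant and no calibration — the error message
reports the roots and discriminant. An explicit `overrides = list(s = …)`
bypasses the solver, e.g. for auxiliary compounds or published scales.

An alternative reading of the equilibrium — balancing the *one-step*
stationary expected factor, `π(h+)·s + π(h−)·d + rest·ρ = 1` — is also a
quadratic in `d` but leaves `λ1` up to a percent away from 1 on small
graphs, so expected concentrations would drift under the uniform chain.
We use the spectral form because constancy of the mean is the property
the rule exists to deliver.

## From time series to growth objectives

Protein series are modeled as successions of exponentials between
user-supplied cutpoints (`fitPiecewiseExponential()`): log-space least
squares per segment, endpoint ratios when a segment has exactly two
points (the sparse-data case), and an optional nonzero basal level via an
iterative fit (the default basal is zero, which keeps the fit linear).
The chain and the clock are linked by the mean transition duration
`δ = halfLife · ln(1/ρ)/ln 2` minutes (`transitionDuration()`): the N-end
rule supplies the shortest amino-acid half-life, and `log(1/2)/log(ρ)`
passive steps make up one half-life. A segment multiplying the
concentration by `r` over `Δt` minutes then pins the per-transition
growth factor `λ = r^(δ/Δt)` (`growthObjective()`), and
`reconstructSeries()` inverts the relation to draw predicted curves. The
carbon-starvation configuration uses `δ = 0.35` min, the value implied by
the case study's correspondence of 20 iterations to 7 minutes. Interval
objectives default to the point estimate (width 0); a relative width can
be supplied where measurement error is to be modeled, as no canonical
width exists.

## Reverse engineering

The inference score is the Euclidean distance between achieved and target
growth rates, where each achieved rate is the Perron eigenvalue of the
candidate's cost matrix (`scoreChain()`). By default only the growth
rates enter the score: sparse series rarely constrain more. When an
observation additionally pins the level of the mean curve — the two-gene
tutorial's two measured points fix both the growth rate and the intercept
of `a·λ^n` — an objective can carry `aTarget`, adding the
permanent-regime constant from the uniform initial distribution to the
residual vector. With two free probabilities and both residuals the
tutorial becomes exactly identifiable, which is why the bundled case
study uses it; phase-spanning problems keep the default.

The free-parameter space has one coordinate per supported edge minus one
per row (the last out-edge carries the residual mass), so volumes and
directions live in a full-dimensional space. `localSearch()` is an ad-hoc
two-phase descent built on numerically evaluated eigenvalues (they have
no explicit form in the probabilities): multi-start — the uniform chain
first, then seeded Dirichlet restarts — with single-coordinate
perturbation sweeps and adaptive step halving, followed by a
derivative-free simplex polish. It is deterministic given the seed,
returns the best point flagged `converged = FALSE` when the budget (20
000 evaluations by default) is exhausted, and keeps every emitted matrix
row-stochastic on the support. Searches restricted to a subset of rows
(`freeRows`) mirror problems whose remaining rows are pinned, like the
tutorial's two-unknown matrix.

Interval problems are explored geometrically: `sourcePoint()` targets the
interval midpoints, `boundaryPoint()` bisects along a ray until an
interval endpoint or a simplex face is active within 1e-6 (the bracket is
tightened three decades further so the reported point is feasible with an
active constraint), and `sampleSolutionSet()` collects boundary points
along uniformly random unit directions. The solution-set volume is
estimated by Monte-Carlo hit ratios inside the bounding box of the stored
points, with feasibility re-checked by direct eigenvalue evaluation — a
deliberate choice over exact polyhedral descriptions, which only scale to
a handful of genes; the estimate carries its own standard error and is
expressed in free-parameter coordinates (no absolute scale is defined).
`predictDistribution()` integrates an unobserved protein's growth rate
over the set by drawing convex combinations of the stored points and
re-checking feasibility (the set need not be convex).

Sensitivity follows the perturbation definition: multiply one transition
probability by 1.01, renormalize its row, and report the score change in
percent of the reference score (`transitionSensitivity()`); at an exact
optimum the reference is ~0 and raw score changes are ranked instead.
Two caveats are inherent to the definition. Within a two-edge row the
upward move on one edge and the downward move on the other trace the same
line, so their derivative magnitudes tie exactly and only curvature
separates the reported values — rankings should be read per tied group.
And sensitivities are local to the evaluation point, not properties of
the whole solution set.

## Fixtures and what the tests do (and do not) show

`twoGeneFixture()` and `carbonStarvationFixture()` reconstruct the two
case-study graphs from their printed structural facts; both published
figures are graphical only, so the exact arrow sets are labeled
synthetic. The two-gene graph is the gene-swap-symmetric wiring with two
out-edges per event on which both proteins calibrate and the tutorial's
hundredfold specification is attainable with two unknowns. The
carbon-starvation graph has 11 events — slope pairs for fis, crp, cya,
gyrAB, topA plus one auxiliary "complex" node — and 22 edges, two of them
existing only without carbon starvation; the starvation signal itself is
modeled as the environmental condition label, matching its role as an
input switched between phases, and transitions into the complex are
passive for every protein since no impact rule is published for it. The
crp and cya events are placed exchangeably (a graph automorphism swaps
them), which is the structural form of the observation that the two
proteins behave identically in prediction: the identity holds in
distribution over the solution set, not for a single inferred matrix.
`fisSeriesFixture()` carries the documented tenfold rise over 80 minutes
and a synthetic decline thereafter.

`randomEtg()` generates the property-test graphs: a random Hamiltonian
cycle (strong connectivity), a chord closing a cycle of coprime length
(aperiodicity), random extra edges, redrawn until every product
calibrates. `syntheticSeries()` emits exponentials with log-normal noise,
matching the asymptotic law of accumulated costs. These generators
emulate the *structure* of the study systems — small minimal graphs,
sparse noisy exponential series — but not promoter-level mechanisms,
measurement bias, or non-exponential kinetics; green tests certify the
numerics and the internal consistency of the framework on such inputs,
not biological validity on real expression data.

Problem sizes in the suite are chosen so each statistical check has the
power it needs and no more: path-enumeration oracles run on graphs of at
most 5 events and horizons of 6 (exact to 1e-12); eigenvalue recovery
uses 20 hidden chains of up to 8 events; Monte-Carlo means use 2 000
trajectories per run so the 3-standard-error band is calibrated; and the
log-normality screen uses 2 000 trajectories of length 300, keeping the
finite-horizon central-limit error (order `1/sqrt(n)`) below the
Kolmogorov–Smirnov resolution (order `1/sqrt(reps)`) — with many more
trajectories the screen would reject any finite horizon, a property of
the test, not of the law.

## Numerical choices

Dominant eigenpairs are computed by dense `eigen()` — the event
abstraction keeps graphs far below the size where iterative methods pay
off — with minimality rejected on tied dominant moduli or complex
dominant pairs. Stationary distributions come from the unit left
eigenvector with a 1e-10 residual check. Row sums are enforced to 1e-9 by
the `TransitionMatrix` validity method; restriction to a new edge set
renormalizes surviving rows and re-spreads rows that lost all mass
equally (a configurable reserve can seed newly added edges instead).
Trajectory simulation uses inverse-CDF sampling on row distributions and
accumulates log-impacts, so results are reproducible across platforms
given the seed. Event ordering is canonicalized (product, then sign,
auxiliaries last) to make every matrix reproducible across runs; files
use event names, never indices.

## Limitations

The approach needs a trustworthy qualitative graph; the bundled
carbon-starvation edges are a documented reconstruction that users can
replace with a curated TSV. Periodic or reducible wiring is out of scope
by assumption, as are additive accumulation rules, time-varying impacts,
and continuous-time chains. Growth objectives identify the growth-rate
vector, not the transition matrix itself — the solution set is the honest
answer, and all predictions should be read through it.
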