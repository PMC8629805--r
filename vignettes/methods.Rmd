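---
title: "Measuring coordination by relative redundancy, and partitioning systems into coordinated components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coordination by relative redundancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redpart)
```

## The measure

Take a system of `n` elements (fish, neurons, agents) with microscopic
random variables `X_1, ..., X_n`. Describing the system element by element
costs at least `Σ H(X_i)` bits; describing it jointly costs at least the
joint entropy `H({X_i})`. Their difference — the total correlation
`I = Σ H(X_i) − H({X_i})` — is the information made redundant by
coordination. `redpart` works with the *relative* redundancy

`r = I / Σ H(X_i) = 1 − s`,

where `s` is the incompressible fraction. `r` is dimensionless, zero for
independent elements, `1 − 1/n` for `n` perfect copies, bounded above by
`1 − max_i H(X_i)/Σ H(X_i)`, and invariant to the overall scale of
individual variability — which makes it comparable across systems of
different sizes, species and measurement units. `total_correlation()` and
`relative_redundancy()` compute the discrete case exactly from a joint
probability table (reported in bits; internal Gaussian computations are in
nats, with `bits_to_nats()`/`nats_to_bits()` for conversion; no log base is
canonical for the measure itself since `r` is a ratio).

A system whose elements are all constant has `Σ H = 0`; we define `r = 0`
there (with a warning): a system of constants is vacuously uncoordinated.

## The Gaussian lower bound

Exact entropies are unobtainable for continuous empirical data, so the
package computes a bound instead (`estimate_gaussian_model()`,
`gaussian_relative_redundancy()`):

1. **Rank-Gaussianization** (`rank_gaussianize()`): each variate is mapped
   to `Φ⁻¹((rank − ½)/T)` (average ranks for ties; constant columns are an
   error, never silently dropped). The result is invariant to any strictly
   increasing per-variate transform — so the bound measures monotone
   dependence and is unaffected by unit changes (pixels vs meters).
2. **Gaussian mutual information**: with sample correlation matrix `P_S`
   of the transformed variates, `I_G = −½ log det(P_S)` lower-bounds the
   total correlation of the original variables.
3. **Quantization offset `α`**: differential entropies can be negative, so
   a per-variate offset `α` (nats) converts them to approximate
   discrete entropies `h_i + k_i α` (for an element with `k_i` variates).
   We apply `α` per variate — the quantization argument applies to each
   continuous variable separately — giving the denominator
   `Σ_i (h_i + k_i α)`. The default is 4 bits ≈ 2.773 nats, which keeps all
   marginal terms positive after rank-Gaussianization for scalar elements
   (`h = ½ ln 2πe ≈ 1.419` nats) and for multivariate elements whose
   variates are not collinear. `α` rescales `r`, so **cross-system
   comparisons require the same `α` on both sides**; it is a recorded field
   of every model.

For elements with several variates (`k_i > 1`, e.g. the two velocity
components of one fish) the subset numerator subtracts the within-element
block terms, `I_G(A) = −½[log det P_A − Σ_{i∈A} log det P_i]`, so that
dependence *inside* an element never counts as coordination and every
singleton subset scores exactly zero (a flag restores the literal
variate-level quantity). The redundancy of the empty set is defined as zero.

**Degenerate inputs.** Numerically singular correlation (sub)matrices are
shrunk toward the identity, `P ← (1−ε)P + εI`, starting at `ε = 1e-8` and
escalating by decades to `1e-4` before raising an error; every escalation is
a logged warning. A non-positive denominator raises an error instructing a
larger `α`.

**Bias.** The plug-in `−½ log det` estimate is biased upward at finite `T`
(more strongly for larger subsets); tests use `T` in the thousands where the
bias is small compared to the effects measured. The estimate converges to
the closed form from below-or-equal on jointly Gaussian data.

## Partitioning into coordinated components

A component is a (possibly soft) subset of elements. Given assignment
probabilities `p(j|i)` (each element's row summing to 1 over the `m`
components; the element prior `p(i)` is uniform, as nothing favors one
element over another), a component induces a Bernoulli product measure over
subsets, `p(A|j) = Π_{i∈A} p(j|i) Π_{i∉A} (1 − p(j|i))`, and its quality is
the expected subset redundancy `E[r(A)|j]`. The objective is the equally
weighted average over components, `E[r(A)] = (1/m) Σ_j E[r(A)|j]` — empty
components count zero, so `m > n` is legal and surplus components simply
end up empty.

The optimizer is an alternating minimization in the Blahut–Arimoto style:
each cycle computes the marginal value `Δd(i,j)` of element `i` to component
`j` — the expected redundancy of the component with `i` included minus with
`i` excluded, scaled by `1/p(i)` — and updates
`p(j|i) ∝ p(j) exp(β Δd(i,j))`, then refreshes the marginals `p(j)`. The
three steps are applied as one synchronous cycle (all rows from the current
marginals, then the marginal refresh); the row maximum of `β Δd` is
subtracted before exponentiation for numerical stability. `β ≥ 0` trades
compression against redundancy: at `β = 0` the assignment decouples from the
data; by `β ≈ 200` assignments are effectively hard, and the achieved
average redundancy is flat across `β ∈ [10, 1000]` on block fixtures. The
achieved rate `I(S; Ŝ)` (bits) is reported with every solution.

`Δd` is computed three ways:

* **exact** — power-set enumeration, capped at `n ≤ 15` elements
  (`delta_d_exact()`; it equals the central finite-difference derivative of
  `E[r(A)|j]` with respect to `p(j|i)` up to the `1/p(i)` factor);
* **Monte Carlo** (`delta_d_monte_carlo()`) — `K` subsets of the other
  elements drawn by independent inclusion with probability `p(j|k)`;
  unbiased, with a reported standard error, exact for hard assignments, and
  bit-reproducible under a fixed seed;
* **hard limit** (`solve_hard()`) — one-hot assignments, where only
  single-element moves matter: elements are visited in seeded random order
  and moved to the component with the largest strict objective gain (ties
  keep the current component; tied gains go to the lowest component index),
  until a full pass makes no move. Subset redundancy is evaluated by
  Cholesky log-determinants of principal submatrices of `P_S`; the inner
  loop is compiled (RcppArmadillo) and uses R's RNG, so results are
  reproducible from `set.seed()`.

Only local optima are guaranteed, so all solvers take random restarts
(rows drawn from a symmetric Dirichlet with concentration 1 for the soft
solver; uniform random labels for the hard solver) and keep the best
solution; 100 restarts is the reference setting, and the package's own
validation uses 50 where a scan over many `m` is involved. Convergence is
declared when the average redundancy changes by less than `1e-9` (soft) or
a greedy pass makes no move (hard), with a 500-iteration / 200-pass safety
cap (non-convergence is logged and the best iterate returned).

## How many components? The Δ scan

`component_scan()` solves the problem for `m = 1..m_max` and forms
`Δ(m) = r̄(m−1) − r̄(m)`. Splitting nearly independent parts changes the
average redundancy little; cutting a strongly coordinated component changes
it a lot. The structure-count heuristic is the first local minimum of the
**magnitude** `|Δ(m)|`. Using the magnitude matters: when independent
groups of unequal sizes are being separated, the unweighted average of
per-group redundancies can slightly exceed the redundancy of the pooled
system, so `Δ` can be slightly negative during the "cheap" splits; the
magnitude treats small changes of either sign as cheap. Minima require
`|Δ(m)| < |Δ(m±1)|` with the left end (`m = 2`) tested one-sidedly and the
right end excluded; ties within `1e-12` are equal and resolved toward
smaller `m`. A monotone `|Δ|` sequence has no minimum and the scan reports
none — the heuristic is exactly that, a heuristic: systems may have no
informative minimum or several.

## The simulators and what they do (and do not) show

**Vicsek model** (`vicsek_simulate()`): constant-speed agents in a periodic
box adopt the angular average heading (direction of the summed unit heading
vectors, including self) of all neighbors within radius `d`, plus uniform
noise on `[−η/2, η/2]`; positions advance by the current velocity and wrap.
Defaults `c = 0.03`, `d = 0.2`, `L = 1`, `n = 50`. The redundancy-vs-noise
sweep (`redundancy_vs_noise_sweep()`) runs 500 burn-in steps and measures
over the following 1000 steps; per noise level it reports redundancy
samples, kernel-density mode estimates (Silverman bandwidth, modes kept at
≥ 20% of the peak density, adjacent-noise modes linked within 0.05), and
the time-averaged polarization with its temporal standard deviation.
Redundancy reproduces the order–disorder transition that polarization
shows: ordered (low `η`) runs score higher than disordered (high `η`) runs
on paired seeds.

*Element variable for the sweep.* The sweep uses one scalar heading per
agent (recentered by the global circular mean so the wrap cut falls where
the heading density is lowest). The velocity-component alternative
(`headings = FALSE`) is degenerate precisely in the coherently ordered
state: both velocity components are then monotone functions of a nearly
constant heading, their rank-transformed within-element correlation block
is exactly singular, and the block entropies become regularization
artifacts. Heading elements avoid this failure mode; for the schooling
simulations below, where headings wander widely, the 2-D velocity elements
are well conditioned and are the default.

**Schooling model** (`school_simulate()`): constant-speed agents in open
space with nested interaction shells — repulsion inside `r_rep = 0.2` (which
overrides everything), heading alignment inside `r_align = 1`, attraction in
the annulus `[r_align, r_att = 2)` with each attracting neighbor weighted by
its relative distance, so edge agents turn back harder. The heading relaxes
toward the social direction at rate `kappa = 5` with weights
`w_align = 1, w_att = 0.5`, timestep `dt = 0.1`, speed 1, and angular noise
of standard deviation `η√dt` per step. Groups start as a compact disk
(radius 0.75) with a roughly common heading (sd 0.2). These defaults were
fixed by behavioral self-checks only — after a 500-step burn-in a single
group of 5–20 agents must stay cohesive (no agent beyond `5 r_att` of the
centroid) and polarized (time-averaged polarization > 0.8) at both study
noise levels `η = 0.15` and `0.2` — and every simulated trajectory carries
its self-check outcome in its metadata, with a warning when a run fails
(borderline `n = 20` runs at `η = 0.2` occasionally sit at polarization
0.78–0.80). The model is a behaviorally validated stand-in for
attraction–alignment–repulsion schooling dynamics, not a replication of any
specific published parameterization.

`independent_groups()` simulates each group separately (own derived seed, no
cross-group interactions) and offsets them in space; the returned group
labels are ground truth for validation only — all downstream analysis uses
velocities alone, never positions or labels.

**What passing these tests shows — and what it does not.** The synthetic
fixtures establish that the measure tracks order, that the optimizers find
exhaustively verified optima at small `n`, and that truly non-interacting
groups are separated from velocity coordination alone. Real trajectory data
differ in ways the generators do not emulate: interactions are
time-varying and leader–follower asymmetric, tracking noise and occlusions
create gaps, group membership changes, and within-group coordination
structure is richer. One concrete consequence observed here: how a large
group subdivides internally (whether near-free spatially assorted halves
exist) is highly model-dependent, so component counts above the number of
groups generalize to other systems only qualitatively.

**Problem sizes.** The package's validation uses groups of 5–20 agents
(up to 40 elements / 80 variates), 500 burn-in + 1000 analysis steps,
scans to `m_max = 10` with 50 restarts, and 10–11 seeded replicates per
scenario; exhaustive-search cross-checks run at `n ≤ 8` and Monte-Carlo
validation at `K = 10^5`. These sizes give stable majorities and
sub-minute runtimes per scenario on one CPU.

## Trajectory pipeline

`read_tracks()` ingests `(frame, id, x, y)` tables (0-based frames,
closed window intervals, y-axis taken as recorded), normalizes ids and
rejects duplicate `(frame, id)` pairs. `savgol_velocities()` estimates
velocities as the smoothed first derivative (3rd-order Savitzky–Golay,
7-frame window, scaled by the frame rate, 30 fps default) — exact for
polynomial tracks up to the filter order; the first and last 3 frames of
each contiguous run are dropped rather than extrapolated, and runs shorter
than the window are dropped with a warning. `window_observations()` takes a
closed `±15 s` window (configurable; `2·15·30 + 1 = 901` samples at 30 fps)
around a time of interest and excludes, with a warning, any individual
missing a frame inside it (no interpolation; exclusion keeps the dependence
estimate honest at the cost of sample size). No claim is made that `±15 s`
is optimal — the window is an exposed parameter.

## Known limitations

* The Gaussian bound is for continuous variables; it is not appropriate for
  discrete or mixed systems (the discrete operations are exact but assume a
  known joint table, with no bias-corrected estimation from samples).
* `r` comparisons depend on a shared `α`; there is no canonical value.
* The partitioning objective has local optima; restarts mitigate but do not
  certify. Exact expectations are capped at `n ≤ 15`; beyond that only the
  Monte-Carlo and hard-limit paths scale.
* The first-|Δ|-minimum rule is a heuristic; plateaus and multiple minima
  are reported (`local_minima`) so users can inspect alternatives.
* Finite-sample upward bias in subset redundancy slightly favors merging
  weakly correlated elements; it shrinks with the window length.
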