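# redpart

Coordination in collective systems — fish schools, bird flocks, neural
populations — is usually measured with system-specific order parameters
(e.g. mean alignment for a school), which makes comparisons across systems
impossible. `redpart` implements a system-independent alternative:
**relative redundancy**, the total correlation of the system's microscopic
variables normalized by their summed marginal entropies,

```
r = I({X_i}) / Σ_i H(X_i) = 1 − H({X_i}) / Σ_i H(X_i),
I({X_i}) = Σ_i H(X_i) − H({X_i}).
```

`r` lies in `[0, 1 − 1/n)`: it is 0 when the `n` elements are independent,
`1 − 1/n` when they are perfect copies, and it is invariant to the overall
magnitude of individual variability. For continuous data the package
computes a practical lower bound: each variate is rank-transformed to
standard-normal quantiles, the Gaussian mutual information
`I_G = −½ log det(P_S)` of the resulting correlation matrix bounds the total
correlation from below, and a fixed per-variate quantization offset `α`
(default 4 bits) converts the differential entropies in the denominator to
approximate discrete entropies. Comparisons are valid whenever the same `α`
is used on both sides.

On top of the measure sits a **redundancy-partitioning algorithm**: a
probabilistic assignment `p(j|i)` of elements to `m` components is optimized
to maximize the equally weighted average expected component redundancy
`E[r(A)] = (1/m) Σ_j Σ_A r(A) p(A|j)`, by a Blahut–Arimoto-style alternating
minimization with inverse temperature `β` (soft assignments), a Monte-Carlo
variant for large systems, and a fast greedy hard-partition limit
(`β → ∞`). Scanning the best average redundancy over `m = 1..m_max` and
locating the first local minimum of the magnitude of its successive changes
("Δ average redundancy") estimates how many coordinated components the
system naturally contains.

The package also ships seeded generators used to validate the method —
the Vicsek alignment model and a zone-based attraction–alignment–repulsion
schooling model, including multi-group non-interacting fixtures — and a
trajectory pipeline for empirical tracks (Savitzky–Golay velocity
estimation, time windowing).

## Worked example

Four variables: a coordinated pair (one is a noisy copy of the other) plus
two independent ones.

```r
library(redpart)
set.seed(1)
z <- matrix(rnorm(600), 200, 3)
x <- cbind(z[, 1], z[, 1] + rnorm(200, sd = 0.1), z[, 2], z[, 3])

model <- estimate_gaussian_model(rank_gaussianize(observation_matrix(x)))
gaussian_relative_redundancy(model, 1:4)
#> [1] 0.1242791

component_scan(model, m_max = 4, restarts = 20, seed = 2)
#> Delta-average-redundancy scan over m = 1..4
#>  m avg_redundancy   delta
#>  1       0.124279      NA
#>  2       0.123959 0.00032
#>  3       0.082639 0.04132
#>  4       0.061980 0.02066
#> Local minima at m = 2 | first: 2
```

The system-wide redundancy bound is about 0.124 — almost all of it carried
by the duplicated pair. Separating the independent variables from the pair
(m = 2) costs almost nothing (Δ = 0.0003), while cutting the coordinated
pair itself (m = 3) costs two orders of magnitude more (Δ = 0.041), so the
scan reports its first local minimum at 2 components: one coordinated unit
plus background.

The same pipeline runs on motion data: `vicsek_simulate()` /
`school_simulate()` / `independent_groups()` produce trajectories;
`trajectory_observations()` (velocities) or `read_tracks()` +
`savgol_velocities()` + `window_observations()` (tracked positions) produce
the observation matrix; `redundancy_partition()` is the one-call fitting
front-end. A thin command-line wrapper with the same operations is installed
at `inst/cli/redpart.R` (subcommands `simulate-vicsek`, `simulate-school`,
`redundancy`, `sweep`, `partition`, `scan`).

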