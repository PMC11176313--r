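---
title: "Evolving reservoir wiring patterns: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving reservoir wiring patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
circuit model and its assumptions, the estimators and their conventions,
the parameters that matter, and the places where the design was genuinely
open and a choice had to be made.

## The circuit model

The reservoir is a 48-unit recurrent network split into three spatially
segregated subtypes of 16 units each: *input* units receive the external
stimulus, *RC-readout* units project to a linear readout, and *hidden*
units form the remainder. No unit both receives input and feeds the
readout, so all information must traverse the recurrent fabric. States
evolve as

$$x_i(t+1) = x_i(t) + \alpha \sum_j W_{ij}\, r_j(t) + \beta u_i(t) + \sigma \xi,$$

with $r = \tanh(x)$, $\xi \sim \mathcal N(0,1)$ drawn fresh per unit and
step, and the readout $z = W^{out} \hat r$ computed from the RC-readout
units' activations.

Two modelling points deserve emphasis:

* **The update has no leak term.** As written, the state is an integrator:
  a unit under sustained nonnegative drive ramps until its $\tanh$
  activation saturates. This shapes everything downstream — input units
  saturate under natural-image clips (which are nonnegative), information
  transfer is carried largely by transients and by units whose net
  recurrent drive is balanced, and a pattern with *no* wiring at all
  produces random-walk readout states whose binned transfer entropy is
  pure estimator bias. We keep the update exactly as printed above and
  treat the consequences as properties of the model; the readout can be
  switched to raw states via `reservoir_params(readout_activation =
  "raw")`.
* **$\hat r$ means bounded activations.** The readout reads $\tanh(x)$
  of the RC-readout units rather than the raw states: the bounded variable
  keeps the readout scale stable and is the same quantity used for every
  information-theoretic measurement.

Initial states are zero. Self-connections are permitted and treated like
any other entry.

### Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `alpha` | 0.1 | gain on the recurrent drive (dimensionless) |
| `beta` | 1.0 | input strength |
| `sigma` | 0.01 | state-noise standard deviation per step |
| `n_units` / `n_per_subtype` | 48 / 16 | three equal subtypes |
| `sparsity` | 0.2 | nonzero fraction of fresh weight matrices |
| `tau` | 0.1 | Hebbian time constant |
| `dt` | 1e-4 | Hebbian Euler step per model timestep |
| `t_tune` | 100 | spontaneous-activity tuning duration (steps) |
| `n_bins`, `k`, `l` | 8, 1, 1 | TE/MI binning and history lengths |

The one default that required measurement to set is the Hebbian Euler step.
The subtractive-normalized rule
$\tau\, \dot w = v\,\mathbf u - v(\mathbf n\cdot\mathbf u)\mathbf n / N$
conserves the *sum* of each unit's incoming weights but not their norm;
combined with the leakless state update it forms a positive feedback loop
(weights grow, activity grows, Hebbian increments grow). Per-step learning
rates `dt/tau` of 1-10 are runaways that saturate every unit and inflate
the weight scale by orders of magnitude within the 100-step tuning window;
at rate 0.001 the tuning phase is a genuine but gentle refinement that
leaves the population at the intended pre-evolution operating point
(mean coupling cost ≈ 235 and density 0.2 after tuning, against ≈ 232
untuned). The default `dt = 1e-4` encodes that stable-refinement regime;
the runaway regimes remain reachable by setting `dt` explicitly. For the
same reason readout training, which runs for thousands of steps, slowly
grows the readout weight norm; nothing feeds back from the readout into
the reservoir, so this affects only the recorded `z` trajectories and is
documented rather than clamped.

### Plasticity conventions

"Activity" in both Hebbian applications means the bounded activations
$r$. Updates are applied online, once per model timestep, with the Euler
factor `dt/tau` — `hebb_delta(v, u)` returns
$(dt/\tau)\,(v\mathbf u - v\,\overline{\mathbf u})$, which sums to zero
exactly. Reservoir tuning updates only connections that already exist
(`mask_preserving = TRUE`), so tuning can never change the density; the
unrestricted variant is available and measurably densifies the matrix.
The tuned matrix is *not* re-normalized to unit spectral radius: spectral
normalization precedes tuning in the per-pattern pipeline, and the small
drift that tuning introduces is part of what selection acts on. Readout
training uses the stimulus series itself as the training signal — there
is no supervised target anywhere in the pipeline.

## Stimuli

The training series emulates saccadic sampling of natural scenes without
any external image database. Surrogate landscapes are Gaussian white-noise
fields whose Fourier amplitudes are shaped to $1/f$ — the canonical
second-order statistic of natural images — then min-max rescaled to
$[0,1]$. From each landscape, square scene windows are cut at random
positions; within each scene a 4x4 clip window performs a random walk
(integer shifts uniform on $\pm$ scene/4 per axis, clamped), and each clip
is linearized row-major into a 16-vector that occupies one timestep. The
clip side of 4 matches the 16 input units one-to-one.

What the surrogates do **not** reproduce: the phase structure of real
scenes (edges, objects, occlusions), their heavy-tailed luminance
statistics, and any temporal correlation between successive scenes. Tests
passing on these stimuli therefore certify the pipeline's behaviour under
natural *second-order* statistics only.

The characterization probe consists of eight 4x4 oriented bars — two
placements each of horizontal, vertical, diagonal-down and diagonal-up,
value 1 on a width-1 line — held for `n_hold` steps with fresh uniform
$[0, 0.1]$ noise per step, separated by equally long blank intervals.
`n_hold = 20` balances per-stimulus sample size (160 labelled embedding
points) against probe length.

## Information estimators

Transfer entropy and mutual information use the simplest reproducible
convention: each series is discretized into 8 equal-width bins over its own
range, joint frequencies are plug-in counts, logs are base 2 (bits), and
histories are one step. A constant series occupies a single bin, making its
TE zero by construction. The estimators are exact: on tiny discrete systems
they match exhaustive-enumeration oracles to 1e-12 (tested), and the
one-step binary relay $y(t+1) = x(t)$ yields 1 bit as the analytic value.

Plug-in estimates are biased upward at finite length — with 8 bins and
histories of 1 the joint space has 512 cells, so series of a few hundred
steps carry a per-pair bias of order 0.01-0.1 bits. Two consequences
matter. First, the pattern-level TE (the evolution objective, by default
the *sum* over the 16 x 16 input-readout pairs) is comparable only between
runs of identical length. Second, an unwired pattern's readout states are
random walks whose bias-TE can exceed the genuine TE of wired patterns;
near-zero TE for absent pathways is therefore asserted on the probe
protocol, where it holds, not as a universal constant. All knobs
(`n_bins`, `k`, `l`, aggregation) are exposed in `info_config()` /
`pattern_te()`.

The separation score is the classic normalized mutual information
$NMI(C, K) = I(C;K)/\sqrt{H(C)H(K)}$ computed directly from label
frequencies; it is label-permutation invariant, so k-means cluster ids
need no matching step.

## Structural metrics

Units live on a 3-layer 4x4 integer grid, one subtype per layer, with
unit distance between neighbouring units. The neighbourhood includes
diagonal neighbours (the 26-neighbourhood), consistent with how square
structural regions are treated throughout the package; shortest distances
come from Floyd-Warshall on that lattice, which makes $D$ the Chebyshev
distance. The empirical anchor for this choice is the pre-evolution
coupling cost: freshly initialized populations average ≈ 232 under
diagonal adjacency versus ≈ 416 under axis-only adjacency, and only the
former matches the pre-evolution operating point of ≈ 250 that the
package's acceptance checks target. The axis-only variant remains
available (`build_layout(neighbourhood = "vonneumann")`).

Coupling cost uses $|W_{ij}| D_{ij}$: absolute strengths keep the cost a
nonnegative penalty that inhibitory connections cannot cancel (the literal
signed sum is available for audit). Density counts all $n^2$ entries,
diagonal included, with an exclusion switch. Modularity is Newman's $Q$
maximized by fast-greedy agglomeration on the symmetrized absolute-weight
graph $|W| + |W|^T$. Clustering and path length are computed on the
*directed* binarized graph (Fagiolo local clustering; mean shortest path
over connected ordered pairs): at directed density 0.2 the directed
statistics sit near 0.2 and 1.9, whereas the undirected union graph would
have density $1-(1-0.2)^2 = 0.36$ and clustering near 0.36 — the directed
reading is the one consistent with the quantities the package's checks
reproduce. An undirected switch exists.

## Evolution

NSGA-II in the standard form: non-dominated sorting (verified against a
brute-force dominance oracle), crowding distance with infinite boundary
scores and zero-range guards, binary tournament parent selection on
(rank, crowding) with a uniform-random alternative, elitist survivor
selection filling fronts and crowding-truncating the last. Objectives are
internally minimized; TE enters negated.

Variation operates on aligned square tiles of the weight matrix
(default 2x2, tiling anchored at the origin): crossover copies each tile
whole from either parent with probability one half; mutation picks one
tile and either zeroes it (probability 0.5) or refills it at the initial
sparsity from Uniform[-0.5, 0.5]. Children are re-normalized to unit
spectral radius; in the measure-zero case of a vanishing spectral radius
the child is replaced by a fresh random pattern. Offspring are produced by
crossover-then-mutation (mutation probability 0.8).

Accounting: the initial population of $P+Q$ patterns counts as the first
cycle and each of the remaining `generations - 1` cycles adds $Q$
offspring, so a run touches `generations * Q + P` patterns
(`pattern_count()`); at the full published scale (100 generations,
$P=Q=250$) this is 25,250. The summary table has `generations + 1` rows:
the initial population, each cycle's survivors, and a final selection.
Reproducibility is strict: all GA randomness flows from one master seed,
and per-pattern evaluation seeds are drawn from that stream at birth, so
identical seeds give byte-identical histories.

The per-pattern evaluation pipeline is: spectral normalization (already
guaranteed by the generating operator), Hebbian tuning under spontaneous
activity, then a single driven pass over the training series during which
the readout learns online and the trajectory is recorded. Transfer entropy
is measured from that same pass — readout weights cannot influence
reservoir states, so a separate measurement pass would differ only in its
noise realization while doubling the cost.

## Characterization

Embeddings standardize each selected unit's series to zero mean and unit
variance (constant units are dropped with a warning) and project onto the
top three principal components. Fractal dimension is the least-squares
slope of $\log N(\varepsilon)$ versus $\log 1/\varepsilon$ over a ladder
of 8 logarithmically spaced box sizes between half and 1/64 of the
bounding-cube edge; for finite trajectories this is a slope fit, not a
limit, and clustered stimulus-locked point sets yield fractional values
below 1. The ladder is an argument: fixtures with few points relative to
the box count need coarser ladders (box counting requires many more points
than occupied boxes), and integer-ratio line directions align cell
crossings with the grid and bias the slope, so dimension fixtures use
irrational directions. Trajectory volume is voxel occupancy times voxel
volume; when entities are compared, all trajectories are counted on a
shared voxel grid (max bounding edge / 50) and divided by the maximum so
the largest volume is 1. k-means uses k = number of distinct stimulus
labels (8 for the probe set) with 10 seeded restarts; blank-interval
timesteps are embedded but excluded from clustering.

## Problem sizes

The package's experiments run at three bundled scales: `"smoke"`
(2 generations, $P=Q=6$, 50-step series) for interface tests, `"desk"`
(10 generations, $P=Q=25$, 2,000-step series from two landscapes) for all
quantitative checks, and `"paper"` (100 generations, $P=Q=250$,
20,000-step series from five landscapes) for full-scale runs. The test
suite and the acceptance script use desk scale, chosen so a complete
condition — evolution plus characterization — runs in well under a minute
on one core.

## Known limitations

* The leakless integrator saturates units under sustained nonnegative
  drive; long-run information transfer is transient-dominated, and
  absolute TE values depend on the series length and binning convention.
* Desk-scale evolution reaches only part of the coupling-cost reduction
  that longer runs achieve: ten generations cut the survivors' mean cost
  by roughly a third, with the decline still steady at the final
  generation.
* Probe-protocol contrasts between the best and worst evolved entities
  (fractal dimension, separation NMI, trajectory volume orderings) are
  seed-sensitive at desk scale; only their reproducibility under a fixed
  seed and their ranges are asserted, not their directions, except for
  the volume ordering which the acceptance suite checks and which desk
  scale does not reliably reproduce.
* Readout weight norms grow without bound under long Hebbian training;
  recorded readout outputs are faithful to the rule but can become large.
* Surrogate stimuli reproduce natural second-order statistics only.
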