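# evowire

Multi-objective evolution of recurrent reservoir wiring patterns.

## The problem

Sensory circuits are wired before any supervised learning takes place, yet
their connectivity is far from arbitrary: it appears tuned to transmit
stimulus information efficiently while keeping the metabolic and material
cost of wiring low. `evowire` frames this as a multi-objective optimization
problem over the internal weight matrix **W** of a small echo-state
reservoir and asks what wiring patterns emerge when evolution, rather than
gradient learning, does the tuning. It is aimed at computational
neuroscientists and reservoir-computing researchers who want a desk-scale,
fully reproducible implementation of the complete pipeline: stimulus
synthesis, circuit dynamics, prenatal-style Hebbian refinement,
information-theoretic scoring, NSGA-II evolution, and structural/dynamical
characterization of the evolved circuits.

## The model

The reservoir has 48 units in three subtypes of 16 (input, hidden,
RC-readout; no unit both receives external input and feeds the readout),
with states updated as

    x_i(t+1) = x_i(t) + alpha * sum_j W_ij r_j(t) + beta * u_i(t) + sigma * xi,

where `r = tanh(x)`, `xi ~ N(0,1)` fresh per unit and step, and defaults
`alpha = 0.1`, `beta = 1`, `sigma = 0.01`. **W** starts sparse (20% nonzero,
entries Uniform[-0.5, 0.5]) and is always rescaled to unit spectral radius.
A linear readout `z = W_out r_hat` reads the RC-readout activations.

Three objectives drive NSGA-II (non-dominated sorting, crowding distance,
binary tournaments; 2x2-block crossover and delete/refill block mutation):

* **Transfer entropy** (maximized): the sum over all 16 x 16 input-readout
  pairs of the binned plug-in estimate of
  `TE(X -> Y) = sum p(y', y, x) log2[ p(y'|y, x) / p(y'|y) ]`
  with 8 equal-width bins and history length 1.
* **Coupling cost** (minimized): `C = sum_ij |W_ij| * D_ij`, where `D` holds
  Floyd-Warshall shortest distances on a 3-layer 4x4 grid (one subtype per
  layer, neighbouring units — including diagonal neighbours — at distance 1).
* **Density** (minimized): the fraction of nonzero entries of **W**.

Before scoring, each pattern is refined by a subtractive-normalized Hebbian
rule (`tau dw/dt = v u - v (n.u) n / N`) under input-free spontaneous
activity, and the readout is Hebbian-trained on the stimulus series.
Evolved circuits are then characterized under eight oriented probe stimuli:
3D PCA embedding of the dynamics, k-means stimulus separation scored by
normalized mutual information, box-counting fractal dimension, and voxel
trajectory volume.

Training stimuli emulate saccadic sampling of natural scenes: synthetic
grayscale landscapes with 1/f spatial spectra are clipped by a randomly
shifting 4x4 window, one linearized clip per timestep.

## Worked example

```r
library(evowire)

# training stimuli: saccadic clips from two synthetic 1/f landscapes
landscapes <- lapply(1:2, generate_surrogate_landscape)
series <- make_saccade_series(landscapes, n_scenes = 25, n_clips = 40,
                              scene_size = 16, clip_size = 4, seed = 1)

# evolve wiring patterns: maximize transfer entropy, minimize coupling cost
fit <- evolve_wiring(series,
                     evolution_config(generations = 10, p_survivors = 25,
                                      q_offspring = 25,
                                      objectives = c("te", "cost")),
                     seed = 1)
fit
#> Wiring-pattern evolution (NSGA-II)
#>   objectives : maximize_te, minimize_cost
#>   generations: 10   P = 25, Q = 25   evaluated: 275
#>   TE    mean : 1.757 -> 2.633 (bits)
#>   cost  mean : 243.2 -> 186.4
#>   dens. mean : 0.201 -> 0.188
```

Across ten generations the surviving population's mean transfer entropy
rises (1.76 to 2.63 bits) while the mean coupling cost falls (243 to 186)
and the density stays near the initial 20% — evolution rewires *where*
connections sit and how strong they are, not how many there are.
`summary(fit)` tabulates every generation; `plot(fit)` draws the
max/min/mean trajectories of all four metrics.

```r
tb <- top_bottom_patterns(fit)           # top / bottom 10% by TE
best <- fit$archive[[tb$top[1]]]
round(c(te = best$te, cost = best$cost, density = best$density,
        modularity = best$modularity), 3)
#>         te       cost    density modularity
#>      4.014    214.192      0.189      0.198

ch <- characterize_pattern(best$pattern, probe = make_probe_series(seed = 1),
                           seed = 1)
round(c(fd = ch$fd, nmi = ch$separation_nmi,
        pc3 = ch$cumulative_contribution[3]), 3)
#>    fd   nmi   pc3
#> 0.756 0.894 0.808
```

The best pattern transfers 4.0 bits (summed over input-readout pairs) at a
below-average wiring cost. Probed with the eight oriented stimuli, its
reservoir trajectory embeds 81% of its variance in three principal
components, separates the stimuli with NMI 0.89 under k-means, and has a
box-counting fractal dimension of 0.76 — a compact, low-complexity,
stimulus-selective representation.

`run_condition(condition_id, scale, seed)` wraps the whole experiment for
the seven objective-set conditions (e.g. condition 1 = TE up + cost down)
at `"smoke"`, `"desk"` or `"paper"` scale, including top/bottom-entity
characterization and consensus-connectivity maps.

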