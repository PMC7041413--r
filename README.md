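# bumpcode

Population codes with broadly or sharply tuned neurons trade off sample
efficiency against final precision when a network has to learn from scalar
feedback alone. `bumpcode` is an R package for studying that trade-off with
a fully specified, gradient-free learning model: two grid populations of
binary neurons connected by probabilistic synapses, where a localized
"bump" of co-active neurons encodes a continuous value (its center the
value, its width the tuning breadth), and an abstract continuous-attractor
mechanism selects the output bump that receives the most stochastic
synaptic input. It is aimed at computational neuroscientists and machine
learners interested in neural coding, synaptic pruning/consolidation, and
sample-efficient zeroth-order learning.

## The model

A population of `n^d` neurons encodes `x ∈ [0,1]^d`; neuron `i` represents
`(i_1/n, …, i_d/n)` and a bump of width `k` centered at `i` is the product
of integer intervals `[i_j − k/2, i_j + k/2]`. Populations `A` and `B` are
fully connected with synaptic probabilities `p_ij` (weights fixed to 1).
Given an input bump `I` and output width `k_B`, each synapse transmits
independently with probability `p_ij`, and the attractor activates the
candidate bump `J` maximizing the received count `s(I, J) = Σ_{I×J} X_ij`
(ties uniform at random). Learning adjusts `P` from the scalar feedback
`L(x, y)` only; the network error is `E[L(x, y)]` under uniform inputs.

Three learner families are implemented:

* **Counter-based (analysis) algorithms** — `static_theory_train()`
  increments/decrements synaptic counters between co-active bumps by
  comparing `L` to a threshold, prunes non-positive counters after
  `M = ⌈c (n/k)^{d_A+d_B} ln n⌉` samples
  (`c = (d_A+d_B+1)(2C)^{d_A}(d_A+d_B)^{d_A+d_B}`), and attains error
  `≤ 3k/n`; `dynamic_theory_train()` halves `k` and the threshold per
  phase, reaching error `ε` in `O(ε^{−d_A} log n)` samples.
* **Simulation algorithms** — `adaptive_train()` adds per-neuron running
  error thresholds (EMA with decay `alpha`), immediate pruning of
  co-active blocks on above-threshold feedback, inactivity pruning
  (`theta_prune`), consolidation (`theta_syn`), and, in the dynamic
  variant, bump widths proportional to each input neuron's live synapse
  count.
* **Reinforcement learning** — `rl_train()` drives a static-width bump
  policy with k-step temporal-difference returns
  `G_t = R_{t+1}+…+R_{t+k}+v(S_{t+k})−v(S_t)` from a tabular value
  function, updating probabilities by the clipped rule that keeps every
  `p_ij ∈ [0.1, 0.9]`.

Benchmark tasks (identity, sinus, rescaled second-order polynomial, ball
throwing, two-joint robotic arm) and environments (continuous mountain
car, cart-pole) are generated from closed forms — no external data.

## Worked example

Learn the 1-D identity map with adaptive tuning width on populations of
200 neurons:

```r
library(bumpcode)
set.seed(7)
grid <- population_grid(d = 1, n = 200)
task <- mapping_tasks()$identity
res <- adaptive_train(task, grid, grid,
                      adaptive_config(ell = 0.02, max_samples = 30000),
                      variant = "dynamic")
res$run
#> <learning_run> adaptive (dynamic): 8656 samples, converged=TRUE, final=0.01876
tail(res$run$curve[, 1:4], 4)
#>    sample      error mean_L_hat mean_live
#> 36   5907 0.02064409 0.02219172    10.815
#> 37   7089 0.02031657 0.02120685     9.875
#> 38   8506 0.01768400 0.02019585     9.185
#> 39   8656 0.01875840 0.01999982     9.085
```

Training stopped when the mean per-neuron error threshold fell below
`ell = 0.02`; the Monte-Carlo error estimate at stopping (0.019) agrees,
and each input neuron has pruned its ~200 initial synapses down to ~9
around its target, i.e. tuning curves sharpened from the initial width
~20 to ~1 while the map was learned. `samples_to_threshold(res$run$curve)`
reports 2794 samples to reach 1.5× the final error — the sample-efficiency
metric used when comparing widths.

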