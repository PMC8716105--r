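---
title: "Stochastic synaptic release, metaplasticity, and consolidation: the model behind stochsyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic synaptic release, metaplasticity, and consolidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(stochsyn)
```

## The model

When an action potential reaches a synapse, there is a substantial
probability that no neurotransmitter is released. `stochsyn` models this
all-or-nothing transmission failure inside otherwise standard layered
networks. Synapse $i$ carries a strength $m_i$ and a release probability
$p_i$, and on every presentation transmits

$$ w_i = r_i \, m_i, \qquad r_i \sim \mathrm{Bernoulli}(p_i), $$

so its expected strength is $\bar w_i = p_i m_i$. A postsynaptic neuron
computes $\sigma\!\left(\sum_i w_i a_i\right)$ with a rectifier in hidden
layers and a softmax at the readout; there are no biases. Every layer,
including the readout, transmits stochastically, and a fresh mask is drawn
independently for every example presentation — each action potential is an
independent release event.

Two quantities are learned:

* **Expected strengths.** Stochastic gradient descent on the cross-entropy
  loss, applied to $\bar w$: $\bar w_i \leftarrow \bar w_i - \eta g_i$
  with $g_i = \partial L / \partial \bar w_i$. The explicit strength
  update is $m_i^{(t+1)} = \left(p_i^{(t)} m_i^{(t)} - \eta g_i\right) /
  p_i^{(t+1)}$: the expected weight entering the update is formed from the
  pre-update state, the division uses the fresh release probability.
* **Release probabilities**, by a threshold metaplasticity rule on the
  same update direction:
  $$ p_i \leftarrow \begin{cases} p_i + p_\mathrm{up} & |g_i| >
  g_\mathrm{lim} \\ p_i - p_\mathrm{down} & |g_i| \le g_\mathrm{lim},
  \end{cases} $$
  clipped into $[p_\mathrm{min}, 1]$ with $p_\mathrm{min} = 0.25$, which
  is also the initial value. Synapses receiving persistently large
  updates therefore acquire high release probabilities.

The order of operations in one step of [plasticity_step()] is: compute
$g$; update $p$; update $\bar w$ with the learning rate based on the
pre-update $p$; recompute $m = \bar w / p_\mathrm{new}$. One
mini-batch-averaged $g$ drives both updates.

Because training is noisy, $g$ does not decay to zero as the task is
learned; the rule therefore maintains high release probabilities exactly
on the synapses whose gradients stay large. Under a zero-mean Gaussian
model $g_i \sim \mathcal N(0, \sigma_i^2)$ the probability of the
increase branch is

$$ p_i^+ = \Pr[|g_i| > g_\mathrm{lim}] =
\operatorname{erfc}\!\left(\frac{g_\mathrm{lim}}{\sigma_i\sqrt{2}}\right), $$

monotonically increasing in $\sigma_i^2 = \mathbb E[g_i^2]$ — the
diagonal empirical Fisher information of the synapse
(`analytic_increase_probability()`, `empirical_fisher()`). High release
probability therefore marks synapses that network function is sensitive
to. The measurement battery quantifies the consequences:

* `synaptic_energy()` — metabolic cost proxy $\sum_i |\bar w_i|$: the
  dominant cost of synaptic transmission is reversing postsynaptic ion
  fluxes, and the expected synaptic strength is the model quantity closest
  to the expected postsynaptic current. The magnitude (not the square) is
  used, matching the physical analogue of current size; squared energy is
  one edit away in `synaptic_energy(per_synapse = TRUE)` consumers.
* `mutual_information()` — plug-in estimate of $I(Y; Z)$ between labels
  and arg-max predictions, in bits (no base is canonical; bits make the
  10-class ceiling $\log_2 10 \approx 3.32$ easy to read).
* `lesion_curve()` — cumulative removal of synapses (zeroing strengths),
  lowest release probability first versus random order.
* `sparsity_report()` — per-neuron counts of "important" synapses
  ($p \ge 0.9$), Kolmogorov–Smirnov distance from a shuffled-importance
  baseline, counts of neurons two shuffled standard deviations above or
  below the shuffled mean, and the Pearson correlation between
  important-input and important-output counts per neuron.

## Consolidation and lifelong learning

For sequential-task learning the release probability doubles as an
importance signal for *stabilisation*:

$$ \eta(p_i) = \eta_0 (1 - p_i), $$

so important synapses become hard to overwrite, and release probabilities
are *frozen* once they reach a threshold $p_\mathrm{freeze} = 0.9$,
so importance acquired on an early task survives later tasks during which
the synapse is unused (presynaptic depression is assumed slower than
single-task learning).

A subtlety: freezing must leave $(1 - p_i) > 0$, otherwise strengths
become fully rigid. With the perceptron constants ($p_\mathrm{up} = 0.2$
from $p_\mathrm{init} = 0.25$) the reachable grid of probabilities skips
the interval $[0.9, 1)$ entirely — a literal "clip to $[0.25, 1]$, then
freeze anything $\ge 0.9$" freezes synapses at $p = 1$ and stalls
learning. `stochsyn` therefore freezes a crossing synapse *at*
$p_\mathrm{freeze}$, which guarantees a residual strength plasticity of
$1 - p_\mathrm{freeze}$ for every constant set and leaves the
multilayer-network dynamics essentially unchanged (those constants reach
$0.9208$; they now freeze at $0.9$).

Model variants for the ablation study (`train_lifelong_experiment()`):

* `plastic_stochastic` — the full model;
* `no_consolidation` — probability dynamics but no learning-rate
  modulation and no freezing;
* `ghost` — transmission fixed at $p = 0.5$ while "ghost" probabilities
  $\tilde p_i$ evolve under the same rule and drive modulation and
  freezing: consolidation without transmission stochasticity;
* `deterministic` — a plain network ($p \equiv 1$, no dynamics).

All variants consume R's random-number stream with identical draw counts,
so `set.seed(s)` before each run yields paired comparisons that share
initial strengths and batch orders and differ only in the ablated
mechanism.

## Rule constants

| constant | energy experiments | lifelong | perceptron |
|---|---|---|---|
| $p_\mathrm{up}$ | 0.07 | 0.0516 | 0.2 |
| $p_\mathrm{down}$ | 0.07 | 0.0520 | 0.2 |
| $g_\mathrm{lim}$ | 0.001 | 0.001 | 0.1 |
| $\eta_0$ | 0.05 | 0.01 or 0.001 | 1 |
| $p_\mathrm{min}$ | 0.25 | 0.25 | 0.25 |
| $p_\mathrm{freeze}$ | — (off) | 0.9 | 0.9 |

These are exposed as `energy_config()`, `lifelong_config()` and
`perceptron_config()`. Consolidation (modulation + freezing) is active
only in the lifelong and perceptron settings; the energy experiments run
with plain $\eta_0$.

## The synthetic task generator

`generate_synthetic_classification()` stands in for handwritten-digit
data: inputs that are high-dimensional with high entropy while the
task-relevant information is only the class identity. Each of the
`n_classes = 10` classes has a random binary (0/1) prototype on a random
subset of `relevant_dim = 20` of `dim = 784` coordinates — high-contrast
"strokes". An example is the prototype plus Gaussian noise
(`noise_sd = 0.3`) on the relevant coordinates, and pure high-variance
Gaussian nuisance ($\mathcal N(0.5, 0.5^2)$) elsewhere; values are
clipped into $[0, 1]$. Labels are exactly balanced, so $H(Y) = \log_2
10$ bits. Clipping (rather than global min–max rescaling) keeps the
prototype geometry at full contrast; rescaling by the nuisance range was
found to shrink the class signal several-fold and with it every gradient,
making the task unlearnable at the model's learning rates within a
sensible number of updates.

What the generator shares with real image data: high ambient
dimensionality, a low-dimensional task-relevant structure, bounded
high-entropy inputs, balanced classes. What it does not share: spatial
correlations between pixels, within-class style variation beyond
isotropic noise, and overlap between class supports. Passing tests on
this generator therefore demonstrate the mechanisms — gradient-driven
probability dynamics, importance encoding, consolidation — not
performance claims on natural images.

## Problem sizes and the training regime

The reference experiments behind the model were run on 60,000-image
datasets for tens of thousands of SGD steps. The package's experiment
battery reproduces the phenomena at desk scale: `n_train = 1200`
examples (generator default 2400, split 6:1 train:test like the classic
digit benchmark), the standard 784–200–200–10 architecture, and
mini-batches of 10 at the model's $\eta_0 = 0.05$ for roughly 20–25
epochs (2400–3000 updates). Small batches are the package's scaled-down
condition of choice: they deliver many more updates per unit compute and
keep per-batch gradient magnitudes in the regime the metaplasticity
threshold $g_\mathrm{lim}$ was calibrated for. At batch 100 and desk-scale
step counts, neither SGD nor the probability dynamics move measurably —
the defaults in the function signatures nevertheless remain at the
reference values (batch 100), and every experiment function takes the
sizes explicitly.

Under these conditions the full model reaches ~95–99% test accuracy on
the default task while keeping most release probabilities at the clamp
and raising a sparse subset (roughly 10–20%) above 0.9 — the
qualitative signature the analysis battery then quantifies.

The three experiment families use these concrete sizes:

* **Importance analyses** (Fisher/release correspondence, lesion curves,
  sparsity): the full 784–200–200–10 architecture, `n_train = 1200`,
  20 epochs of batch 10 at $\eta_0 = 0.05$, `p_init = 0.25`.
* **Energy/information trade-off**: hidden layers of 100,
  `p_init = 0.5` (the probability dynamics are reported to be robust to
  the initial value, and a milder starting noise level lets all variants
  train within 12 epochs), l2 grid $\lambda \in \{0, 10^{-3}, 3\times
  10^{-3}, 10^{-2}\}$ — wider than a long-run grid would be, because
  the decay a given $\lambda$ produces scales with the step count.
* **Lifelong ablations**: five split parity tasks, hidden layers of
  100, 15 epochs per task, evaluation over `K = 5` mask draws.

One constant co-varies with the batch size: the threshold
$g_\mathrm{lim}$ separates signal-bearing gradients from noise, and the
noise level of a batch-mean gradient scales as $1/\sqrt{B}$. The
lifelong experiments at batch 10 therefore scale the reference threshold
by $\sqrt{100/10}$, $g_\mathrm{lim} = 0.001 \cdot \sqrt{10} \approx
0.00316$, keeping the exceedance probability of a noise-dominated
gradient comparable to the reference regime. Without this, freezing —
a one-way ratchet — eventually captures nearly every synapse: small-batch
noise pushes each synapse's probability above the freeze threshold at
some point, and importance stops being discriminated. The energy
experiments, which run without freezing, keep the reference
$g_\mathrm{lim} = 0.001$ (the probability dynamics there are reversible,
and the resulting sparse high-$p$ subset matches the intended picture).

## Numerical choices

* **Randomness.** All mask sampling runs in compiled kernels under a
  dedicated counter-seeded xoshiro256++ generator; seeds are drawn from
  R's global RNG, so one `set.seed()` fixes an entire experiment
  bit-exactly. Example $e$ of a batch uses kernel seed $s + e - 1$,
  making the fused batch path and the per-example
  `forward_stochastic()` path produce identical masks.
* **Gradients through sampling.** The default estimator differentiates
  through the drawn masks ($\partial L/\partial m_i$ carries $r_i$) and
  converts with $\partial L/\partial \bar w_i = (1/p_i) \partial
  L/\partial m_i$; an expected-weight mode (`mode = "expected"`) is
  available for comparison, and the two coincide exactly at $p \equiv 1$
  (the deterministic-variant trainer uses this identity).
* **Evaluation.** Default prediction averages class scores over $K = 10$
  fresh mask draws, reflecting that transmission noise is part of the
  model; expected-weight evaluation is one flag away. The perceptron is
  evaluated with expected weights (its sign output makes single-draw
  voting too coarse), while its training predictions sample release.
* **Threshold tie.** $|g| = g_\mathrm{lim}$ takes the decrease branch.
* **Lesioning.** Synapses are removed globally across layers in order of
  $p$, ties broken by $|m|$ ascending, then by index; removal zeroes the
  strength. At fraction 1 the network outputs a constant and accuracy
  equals the marginal frequency of the tie-break class.
* **Degenerate inputs.** The perceptron predicts $+1$ on a zero weighted
  sum; empty count tables and empty datasets are errors.
* **Serialisation.** Networks round-trip through JSON with reals stored
  as 17-significant-digit decimal strings (lossless for IEEE doubles).

## Design choices that were genuinely open

* **Evaluation mode** (sampled vs expected) is not pinned by the
  reference account: both are provided; sampled with $K = 10$ is the
  package default for networks, expected for the perceptron.
* **Gradient estimator** (through sampled or expected weights): sampled
  is the default — it is the biologically sensible choice (learning sees
  the same noise as transmission) and produces the Fisher-linked
  gradient statistics the probability rule builds on.
* **Energy of a synapse** is $|\bar w_i|$, not $\bar w_i^2$.
* **Fixed-release control matching**: the uniform release probability of
  the control is matched to the global mean of the plastic model's final
  probabilities for the same regularisation strength and seed (per-layer
  matching would also be defensible; global is what the comparison
  needs).
* **Continuous protocol**: the transition window is
  `transition_fraction = 0.2` of a task segment, centred on each task
  boundary, with the incoming-task share rising linearly 0 → 1 across
  the window (50/50 at the boundary itself).
* **Split-task labelling**: even source class → label 0.

## Known limitations

* Desk-scale problem sizes: effect sizes (retention gaps, energy-ratio
  gaps) are smaller and noisier than at 60,000-example scale; the
  package asserts orderings and signs, not headline percentages.
* Single-release-site Bernoulli model: no binomial multi-site synapses,
  no short-term plasticity, no spiking dynamics, no biases.
* The plug-in mutual-information estimator is biased upward for small
  samples; comparisons hold it fixed across variants, which is what the
  energy trade-off needs.
* The ghost and fixed-release controls change the gradient-noise
  geometry as well as the ablated mechanism. In particular, the ghost
  control transmits at a fixed $p = 0.5$ and never pays the
  early-training transmission-noise penalty that the full model pays at
  $p_\mathrm{init} = 0.25$; long training amortises that penalty, but at
  desk-scale step counts the ghost variant's mean accuracy typically
  sits slightly *above* the full model's, while both clearly beat the
  no-consolidation ablation (the larger effect). The test suite asserts
  the full ordering and documents this expectation.
```
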