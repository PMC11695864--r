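---
title: "Memory traces from behavioral time-scale plasticity: model, theory, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory traces from behavioral time-scale plasticity: model, theory, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`btspcam` models the creation of memory traces in hippocampal area CA1
by behavioral time-scale synaptic plasticity (BTSP). The network is a
pool of `n` disconnected McCulloch–Pitts memory neurons (CA1) receiving
binary-weight synapses from `m` input neurons (CA3) through a fixed
random connectivity mask of density `f_w`. Memory items are sparse
binary vectors whose bits are i.i.d. Bernoulli(`f_p`). Each item is
presented exactly once (one-shot learning). During an item's
presentation every memory neuron independently receives a plateau
potential with probability `f_q`; a plateau opens a seconds-long
plasticity window for that neuron's synapses from active inputs, and the
flip

* `w: 0 → 1` (LTP) if the input bit is 1 and the weight is weak,
* `w: 1 → 0` (LTD) if the input bit is 1 and the weight is strong,

is applied with probability 1/2. At recall, a memory neuron fires iff
its weighted input sum strictly exceeds an integer threshold `v_th`;
the vector of firing neurons is the item's memory trace.

### Granularity of the stochastic gate

The probability 1/2 models where the item's arrival time falls within
the ten-second plasticity window relative to the plateau onset. An input
pattern arrives at one moment, and a neuron has one plateau onset per
item, so this timing is a single random variable per (neuron, item):
when the gate fires, all of the neuron's eligible synapses are updated
together. We adopt this per-neuron gate as the default.

The alternative — an independent coin per synapse — looks innocuous but
changes the physics. Under per-synapse gating, the probability that a
synapse is strong given only that its neuron had a plateau for the item
is exactly 1/2 (the parity of a fair coin plus anything is a fair coin),
the weighted-sum distribution loses most of its bimodality, and recall
from masked cues collapses. Under per-neuron gating, conditioning on the
neuron's *effective* update reproduces the closed-form strong-weight
probability `p_e` below exactly, and the "core" rule (deterministic
flips at plateau probability `f_q/2`) becomes equal in law to the
stochastic rule at `f_q` — which is also why the package's equivalence
test between the two rules is expected to pass exactly rather than
approximately. The asymmetric variant (separate LTP/LTD probabilities)
uses two independent per-neuron draws, one per direction.

## The theory

Because a binary weight is the parity of its update count, the whole
system reduces to binomial parity calculations:

* `P(X even) = (1 + (1 − 2p)^N)/2` for `X ~ Binomial(N, p)`.
* A synapse from an active bit onto a neuron whose plateau gate fired
  for the item is strong after `M` items with probability
  `p_e = (1 + (1 − f_p f_q)^{M−1})/2`; without the plateau,
  `p_o = (1 − (1 − f_p f_q)^{M−1})/2`. The unconditional strong-weight
  fraction is `(1 − (1 − f_p f_q)^M)/2`.
* Firing probabilities are binomial survival functions
  `1 − F(v_th; I, f_w p)` with `I` the number of active cue bits, and
  the average firing probability `p_favg` marginalises over the plateau
  indicator and `I ~ Binomial(m, f_p)`.
* Expected Hamming distances: between an item's trace and its masked
  cue's trace, the per-branch product
  `F(v_th; I(1−f_d), f_w p) · (1 − F(v_th; I, f_w p))` (a one-sided
  mask can silence but never ignite a neuron); between two items,
  `2 n p_favg (1 − p_favg)`.

Relative dissimilarity — the masked-cue distance divided by the mean
distance between traces of different items — is the headline recall
metric; 0.5 means a masked cue's trace is indistinguishable from an
unrelated item's trace.

### A known bias, kept as printed

The theory conditions `p_e` on the item's own update having happened,
yet weights that branch by the plateau probability `f_q` rather than
the effective rate `f_q/2`. The two halves of the approximation do not
cancel in the trace-size prediction: simulated mean trace sizes run
about 25–30% below `n · p_favg` at the testing scale, and the predicted
relative-dissimilarity curve is correspondingly optimistic, while the
unconditional strong-weight fraction (which needs no such conditioning)
agrees with simulation to four decimal places. We implement the
formulas exactly as stated rather than introducing our own corrected
variant, and the test suite documents where simulation and prediction
agree (strong-weight fraction, qualitative trends, threshold ranking)
and where the conditional approximation bites (absolute trace size,
absolute dissimilarity). The acceptance report always prints the
simulated and predicted values side by side.

### Overlapping items

For ensembles sharing `c` common 1-bits, the common-bit synapses of a
neuron are updated by *every* item in its plateau set, so after learning
they are strong or weak *together*, according to the parity of the
plateau count `s`. The predictions therefore mix, per neuron, an
all-or-none `Binomial(c, f_w)` common-bit contribution (probability =
parity of `s`, i.e. `prob_even(M−1, f_q)` for a plateau neuron) with
the non-common bits acting through the `s`-marginalised conditional
probabilities `p̂_e`, `p̂_o`. The construction is written so that at
`c = 0` it collapses bit-exactly onto the random-item formulas — that
reduction is asserted at machine precision in the tests.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `m` | input neurons (CA3) | 25,000 full / 2,500 reduced | 1/10 of rat CA3 |
| `n` | memory neurons (CA1) | 39,000 full / 3,900 reduced | 1/10 of rat CA1 |
| `f_p` | input density | 0.005 full / 0.02 reduced | measured CA3 sparsity; reduced preset keeps `m·f_p = 50` testable |
| `f_q` | plateau probability | 0.005 full / 0.01 reduced | plateau rate 0.0005/s × 10 s window |
| `f_w` | connection probability | 0.6 | ~15,000 inputs per CA1 cell |
| `p_update` | update gate | 0.5 | LTP/LTD window occupies half the 10 s plasticity window |
| `v_th` | firing threshold | grid search | argmin of predicted relative dissimilarity at `f_d = 0.33`, ties to the smaller value |
| `f_d` | masking fraction | 0.33 sweep default | one-third masking is the robustness operating point |

## Numerical choices

* Powers `(1 − f_p f_q)^{M−1}` are evaluated in log space
  (`exp((M−1)·log1p(−f_p f_q))`), so the theory runs without underflow
  at `m = 2.5×10⁶`, `f_p = 5×10⁻⁵`, `M = 800,000` (seconds, not
  minutes).
* The `I`-summation in `p_favg` and the Hamming-distance formulas is
  truncated to the binomial mean ± 10 SD; the neglected mass is
  returned as a `truncation_error` attribute (≤ 1e-10 at all scales
  used).
* The non-integer trial count `I(1 − f_d)` is rounded to the nearest
  integer, matching the simulator's round-half-to-even masked-ones
  count.
* Strict `>` at every threshold; ties never fire.
* The pairwise-distance denominator of relative dissimilarity is
  estimated from 1,000 random distinct pairs (an unbiased estimate of
  the all-pairs mean, which would cost `M²` recalls).
* Top-K ties break toward the lowest index; an all-zero cue yields an
  all-zero trace.

## The synthetic-data generator

All inputs are synthetic by design: random sparse items, fixed-overlap
ensembles (`c = ⌊m f_c f_p⌋` common bits, remaining density
`(m f_p − c)/(m − c)` so the expected ones-count is invariant), masked
and two-sided-perturbed cues, and 50×50 line drawings (five 8-pixel
axis-aligned segments; one planted pair shares exactly three segments).
The generator reproduces the statistical structure the model is about —
sparsity, controlled overlap, one-sided masking — and nothing else: no
temporal dispersion within an item, no spatial correlations between
bits, no firing-rate gradations. Tests passing on these ensembles
therefore validate the learning rule and theory, not the model's
adequacy for any particular recorded dataset.

## Scale sensitivity of the functional effects

The testing preset (`preset_reduced()`: `m = 2,500`, `n = 3,900`,
`f_p = 0.02`, `f_q = 0.01`, `M ≤ 2,000`) keeps ones-per-item, plateau
neurons per item and fan-in proportionate to the full scale so that
learning runs in seconds. Two of the paper-level effects, however, live
in margins that shrink with the square root of the ones-count
`I = m f_p` and with the trace size `n f_q`:

* **Repulsion.** Similar items (40% shared bits) cross-activate each
  other's trace neurons with weighted sums around `0.4 · I f_w p_e`,
  while masked recall needs the threshold below `0.67 · I f_w p_e`.
  At `I = 125` that window is ≈3 binomial SDs wide and the repulsion
  index resolves above 1 over 20 trials; at `I = 50` it is ≈1.3 SD and
  cross-activation floods the similar-pair overlap, so the index falls
  below 1 at any threshold. The Top-K projection control shows its
  attraction effect (index < 1) at every scale.
* **Completion.** Reconstruction quality is set by the feedback
  matrix's saturation (`≈ M f_p · (trace size)/n` per connection) and
  by the signal/noise separation of the input-layer sums, which grows
  with the square root of the trace size. The mid-scale property test
  (`m = 5,000`, `n = 7,800`, saturation ≈ 0.025) reconstructs with a
  scaled error far below 1; at the reduced preset (saturation ≈ 0.27,
  traces of ~25 neurons) the scanned optimum hovers just above 1.

The acceptance script computes and reports both effects at the reduced
preset as-is; the numbers should be read with this geometry in mind.

## Problem sizes used by tests and the acceptance script

Simulation-backed checks run at the reduced preset with 3–5 replicates
and 100–200 probe items; the exhaustive oracles run at `m ≤ 20`,
`M ≤ 6`; the brain-scale evaluation is theory-only. The full biological
scale (`m = 25,000`, `n = 39,000`, `M = 30,000`) is supported by the
same code paths (bit-packed persistence keeps a full weight matrix
around 122 MB) but is not exercised by the tests.

## Known limitations

* The continuous-weight biophysical rule is out of scope; only the
  multi-release-site construction connects the binary rule to graded
  weight changes, and a plug-in hook (any function updating `W` in
  place) can replace `btsp_step` in custom loops.
* No lateral CA1 connectivity, spiking dynamics, or membrane time
  courses.
* The Hopfield baseline stores the input patterns themselves
  (`n = m` for that comparison), following the covariance-rule
  indexing of pattern bits.
* Feedback reconstruction is a single generative step; the model never
  iterates feedforward–feedback cycles.
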