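# btspcam

Content-addressable memory with binary synapses, built by one-shot
learning with behavioral time-scale synaptic plasticity (BTSP).

## The scientific problem

When the brain stores an episodic memory it must allocate, on the fly, a
set of CA1 neurons that form a trace for the new experience and that can
later be reactivated from a partial cue. Experiments in behaving animals
identified the plasticity rule behind this: BTSP. It differs radically
from Hebbian rules and STDP — it is gated not by postsynaptic firing but
by stochastic plateau potentials arriving from entorhinal cortex, it
works in a single trial, the direction of the weight change (LTP vs LTD)
depends on the current weight, and it acts on a time scale of seconds.

`btspcam` implements a transparent binary-weight model of this rule and
the memory system it creates, for computational neuroscientists and
neuromorphic-hardware researchers who want a CAM that needs only two
weight states and one-shot, online learning.

## The model

A pool of `n` McCulloch-Pitts memory neurons receives binary-weight
synapses from `m` input neurons through a random mask of density `f_w`.
Memory items are sparse binary vectors (density `f_p`). During learning
of item `x`, each memory neuron receives a plateau potential with
probability `f_q`; because the item's arrival time falls in the plastic
part of the seconds-long window with probability 1/2, the flip

```
Δw_i = +1  if x_i = 1 and w_i = 0      (LTP)
Δw_i = −1  if x_i = 1 and w_i = 1      (LTD)
```

is applied to the neuron's eligible synapses with probability 1/2 per
(neuron, item). A neuron fires at recall iff its weighted input sum
exceeds a threshold `v_th` chosen by a theory-driven grid search.

Because a binary weight is its own update parity, the whole system
admits a closed-form theory built on the parity of a binomial count,
`P(X even) = (1 + (1 − 2p)^N)/2`. From this follow the probability that
a synapse stays strong after `M` items
(`p_e = (1 + (1 − f_p f_q)^{M−1})/2`), firing probabilities (binomial
survival functions), expected trace sizes, and expected Hamming
distances between traces of items, masked cues, and overlapping items —
all computable at the scale of the human brain (`m = 2.5e6`,
`M = 800,000`) in well under a minute.

The package also provides the classical comparators (a covariance-rule
Hopfield network, thresholded and Top-K random projections), one-shot
Hebbian feedback connections for true input completion, and the
repulsion-effect protocol in which traces of similar items are pulled
apart.

## Worked example

```r
library(btspcam)

p <- preset_reduced()                 # m=2500, n=3900, f_p=0.02, f_q=0.01
tp <- theory_params(p$m, p$n, p$M, p$f_p, p$f_q, p$f_w)
v_th <- optimize_threshold(tp, f_d = 0.33)   # 13
tp$v_th <- v_th

ens  <- gen_random_patterns(p$M, p$m, p$f_p, seed = 1)
pls  <- draw_plateaus(p$M, p$n, p$f_q, seed = 2)
mask <- build_connectivity(p$m, p$n, p$f_w, seed = 3)
net  <- learn_sequence(ens, pls, mask, v_th = v_th, seed = 4)

strong_weight_fraction(net)           # 0.1661; theory: 0.1649
trace_size(net, ens, 1:200)           # 31.0 memory neurons per trace

rd <- relative_dissimilarity(net, ens, f_d = 0.33, items = 1:200, seed = 5)
rd$ratio                              # 0.245 — well below the 0.5
                                      # indistinguishability level
```

`strong_weight_fraction` lands within a fraction of a percent of the
parity prediction `(1 − (1 − f_p f_q)^M)/2`. The relative dissimilarity
says that after masking a third of a cue's active bits, the recalled
trace is still far closer to the stored trace than traces of unrelated
items are to each other.

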