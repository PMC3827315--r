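# plastevo

Evolving plastic neural networks with developmental encodings, and
measuring whether structural regularity buys general learning ability.

## The problem

A fixed neural network can be evolved to *do* something; a plastic one
can be evolved to *learn* something. `plastevo` implements a complete
experimental system for the second question, built around a simulated
Skinner box: 4 stimulus lights, 4 levers, a positive and a negative
reward line, and the chosen action echoed back into the input layer.
An *association set* assigns one correct lever to each light; there
are `4^4 = 256` of them. A network gets 90 learning episodes to master
one set within its lifetime, driven only by neuromodulated Hebbian
plasticity:

- neuron output: `o_i = phi(sum_j s_ij * w_ij * o_j + b_i)`, with
  `phi(x) = 1 / (1 + exp(-lambda * x))`;
- modulatory neurons contribute to a modulatory sum `m_i` instead of
  driving activation;
- every *plastic* weight (standard source, modulated target) updates as
  `w_ij <- clamp(w_ij + eta * tanh(m_i) * o_i * o_j, 0, w_max)`.

Actions are drawn from a softmax over the 4 outputs
(`p_k ∝ exp(o_k / tau)`). Networks are evolved with NSGA-II over two
objectives — lifetime learning fitness on a small *evolutionary
training set* and behavioral novelty — under three encodings with
different regularity biases: a direct graph encoding, a map-based
developmental encoding (neural maps expanded into identical neurons),
and a minimal HyperNEAT variant (two CPPNs queried over a 3D
substrate). Two measurements close the loop:

- **GLA score** — the fraction of all 256 association sets a champion
  can fully learn: generalization of the learning ability beyond the
  sets evolution saw;
- **regularity** — the exact number of automorphisms of the developed,
  pruned network (vertex-colored by neuron kind and binned synaptic
  weight; counted with BLISS, cross-checked by brute force).

## A worked example

A hand-wired plastic network (`make_fixture("hand_learner")`) solves
the task with exactly the ingredients evolution must discover: reward
lines wired to modulatory gates, gating by the chosen action's
feedback, reinforcement landing on a plastic stimulus-to-output fan.

```r
library(plastevo)

hl <- make_fixture("hand_learner")
hl
#> <plastic_network> 30 neurons (10 in / 16 hidden / 4 out, 8 modulatory), 48 connections (16 plastic)

set.seed(11)
sets <- sample_training_set(enumerate_global_set(4, 4), 40)
ev <- evaluate_fitness(hl, sets)
ev$fitness       # association-level lifetime learning fitness
#> [1] 0.93125
ev$set_fitness   # fraction of sets with all four associations learned
#> [1] 0.75

set.seed(12)
gla_score(hl, n_repeats = 2)
#> <gla_score> set-level 0.6895, association-level 0.9092 (256 sets x 2 repeats)
```

Chance level is 0.25 at association level and `(1/4)^4 ≈ 0.0039` at
set level, so the hand learner generalizes across essentially the
whole task. Regularity of canonical structures:

```r
count_automorphisms(make_fixture("fully_connected", n = 4))  # 4! = 24
count_automorphisms(make_fixture("mlp", layers = c(4, 4)))   # 4!*4! = 576
count_automorphisms(make_fixture("lamprey_cpg"))             # 2*2 = 4
```

A scaled-down evolution run, champion measured on both axes:

```r
set.seed(1)
sets <- sample_training_set(enumerate_global_set(4, 4), 1)
res <- evolve(encoding_map(), sets,
              evolution_config(pop_size = 50, generations = 60, seed = 8))
glance(res)           # one-row run summary
tidy(res)             # per-generation history (a tibble)
autoplot(res)         # fitness trajectory

count_automorphisms(res$champion$network)
set.seed(2)
gla_score(res$champion$network, n_repeats = 1)
```

Full series (`run_series()`) sweep encodings × training-set sizes ×
replicates and aggregate GLA and regularity per cell
(`summarize_series()`, `compare_series()` for Mann–Whitney contrasts,
`autoplot()` for the boxplots). A command-line front end is installed
at `inst/scripts/plastevo` (`evolve`, `evaluate`, `regularity`,
`series`).

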