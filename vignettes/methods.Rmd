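---
title: "Evolving plastic networks: model, encodings and regularity measure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving plastic networks: model, encodings and regularity measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastevo)
```

## The scientific question

When neural networks are evolved for their ability to *learn during a
lifetime* — rather than for a fixed behavior — does the choice of
genetic encoding matter? Developmental (generative) encodings bias
search toward structurally regular networks: repeated modules,
symmetric wiring, neurons treated as interchangeable members of a map.
This package provides the machinery to ask whether that regularity
bias translates into *general* learning ability: the capacity to learn
associations never seen during evolution. Regularity is quantified
exactly, as the number of automorphisms of the developed network, and
generalization as the fraction of all possible stimulus-action
assignments a champion can learn within one lifetime.

## The plastic neuron model

Networks are synchronous, recurrent, and contain two neuron kinds.
*Standard* neurons drive activation: neuron $i$ outputs
$$o_i = \varphi\Big(\sum_{j \in \mathrm{std}(i)} s_{ij} w_{ij} o_j + b_i\Big),
\qquad \varphi(x) = \frac{1}{1 + e^{-\lambda x}},$$
where $s_{ij} \in \{-1, +1\}$ is the connection polarity, $w_{ij} \in
[0, w_{\max}]$ its magnitude, and $b_i$ the bias. *Modulatory* neurons
do not drive activation; their outgoing connections accumulate into a
modulatory sum $m_i = \sum_{j \in \mathrm{mod}(i)} s_{ij} w_{ij} o_j$
at each target. Every *plastic* connection — one whose source is
standard and whose target receives at least one modulatory input — is
updated after each step by the neuromodulated Hebbian rule
$$w_{ij} \leftarrow \mathrm{clamp}\big(w_{ij} + \eta\,
\tanh(m_i)\, o_i\, o_j,\ 0,\ w_{\max}\big).$$

Choices worth stating explicitly:

* $\tanh$ is the modulation transfer: it is odd and vanishes at zero,
  so weights are frozen wherever no modulatory signal arrives, and
  both potentiation and depression are possible. Magnitude-only
  plasticity means an inhibitory connection can weaken to zero but
  never change polarity.
* Defaults: $\lambda = 5$, $\eta = 0.1$, $w \in [0, 2]$, biases in
  $[-2, 2]$. All are configurable; the qualitative behavior (sigmoid
  saturation around $\pm 1$ drive, weight saturation within tens of
  modulated steps) is insensitive to moderate changes.
* Inputs relay their clamped values without a sigmoid, and the clamp
  is written into the state *before* propagation, so a signal crosses
  one connection per step starting at the step its input appears.
  Five steps per phase therefore suffice for the network depths used
  here.
* Plasticity is applied after every step of every phase, not only
  during reward delivery. Nothing in the model prevents adaptation
  while a stimulus is merely being presented; evolved (or hand-built)
  networks must cope with that.
* The modulatory "threshold" of the conceptual model is realized by
  the modulatory neurons' own evolved biases — a modulatory neuron
  with a strongly negative bias is silent until its inputs exceed it —
  rather than by an extra gate parameter.

## The conditioning task

The task is a simulated Skinner box with 4 stimuli and 4 actions. An
*association set* assigns one correct action to each stimulus; there
are $4^4 = 256$ of them (the *global training set*). A lifetime on one
set spans 90 episodes; each episode presents the 4 associations in
fixed stimulus order. A presentation has two 5-step phases: stimulus
only, then stimulus + reward + feedback, with the one-hot feedback
block echoing the softmax-chosen action into the input layer (10 input
lines in all: 4 + 2 + 4). The action is drawn from
$p_k \propto e^{o_k / \tau}$ with $\tau = 0.1$: sharp enough to
exploit learned contrast, soft enough to explore. Plastic weights are
randomized uniformly at the start of each lifetime, so a network never
has to un-learn the previous set.

Fitness is reported at two granularities: the association-level
average (fraction of the last episode's presentations answered
correctly) and the set-level success (all four correct). Evolution
maximizes the association-level value — the finer gradient — while the
General Learning Abilities (GLA) score is the set-level success rate
over all 256 sets, averaged over several seeded lifetimes (5 by
default) to tame softmax sampling noise. Two calibration points pin
the scale: an oracle that always answers correctly scores 1.0 on both,
and an all-zero network scores $1/4$ at association level and
$(1/4)^4 \approx 0.0039$ at set level.

The stimulus stays clamped during the reward phase. The presentation
order within an episode is fixed; because learning never pauses, the
transition between consecutive associations briefly overlaps the old
reward signal with the new stimulus, a crosstalk that any solution
must tolerate (the hand-wired `make_fixture("hand_learner")` does so
with a two-stage relay that delays the new stimulus's presynaptic
drive past the stale gate signal).

## Three encodings

**Direct.** The genotype is the network graph itself. Generation 0 is
a bare input-to-output fan with random weights and polarities (hence
no modulatory neurons and no plasticity — learning machinery must be
discovered). Seven mutation operators act independently in fixed
order: add / delete / re-attach a connection, insert a neuron by
splitting a connection (both halves keep the split weight), delete a
neuron, polynomial mutation of weights (per connection), and intrinsic
parameter mutation (per neuron: bias, kind flip; per connection: sign
flip). There is no crossover. Defaults: structural rates 0.1 / 0.1 /
0.1 / 0.05 / 0.05, per-element rates 0.1, distribution index
$\eta_m = 15$ — typical for this family of graph encodings, and all
configurable.

**Map-based.** The genotype is a small labeled graph whose nodes are
neural *maps* (here all of size 4, matching the 4 stimuli and
actions) or single neurons, and whose edges carry (weight, polarity,
scheme) labels with scheme one-to-one or one-to-all. Every label is a
real gene in $[0,1]$ (booleans threshold at 0.5, reals scale
affinely), mutated by the same polynomial operator. Development
expands each map node into identical neurons and each edge into a
uniform bundle, which is what makes the encoding's networks regular
by construction. The fixed I/O roster mirrors the task: stimulus and
feedback maps, two reward singletons, one output map. A one-to-one
edge between a singleton and a map falls back to one-to-all; since
all maps share one size, no other size mismatch can arise, but the
development error remains defined (and is converted to minimal
fitness) for configurations that allow it. A developed connection is
inhibitory if either its edge or its source node carries the
inhibitory label — the node label makes a whole map inhibitory, the
edge label a single bundle.

**HNN (minimal HyperNEAT).** Neurons sit at fixed 3D coordinates
(inputs at $z=-1$, 5 hidden at $z=0$, outputs at $z=+1$; evenly
spaced in $x$, grouped in $y$ by role). Two CPPNs — feed-forward
graphs of sine / sigmoid / Gaussian / linear nodes, themselves
evolved with the direct encoding — are queried over coordinates: a
connection-centred CPPN returns a link-expression output (connection
created iff LEO $> 0.5$) and a weight (clipped to $[-1,1]$; sign
gives polarity, magnitude scales to $[0, w_{\max}]$), and a
node-centred CPPN returns each neuron's bias and kind (hidden neurons
are modulatory iff the kind output falls below 0.4). A constant bias
input of 1 is provided to both CPPNs, standard practice so they can
express thresholds. Cyclic CPPN genotypes are rejected at evaluation
with minimal fitness rather than repaired. The canonical substrate
here uses 10 inputs, matching the task's input vector, with a 9-input
variant (a single signed reward line) available; the task evaluator
accepts both layouts.

## Evolution

NSGA-II over two maximized objectives: task fitness and behavioral
novelty — the mean Euclidean distance from an individual's behavior
descriptor (the $16 \cdot |E|$ raw outputs recorded on the last
episode) to its $k = 15$ nearest neighbors in the archive plus the
current population. Parents are chosen by binary tournament on (front
rank, crowding distance), ties broken by crowding then uniformly;
variation is mutation-only; survivors by $\mu + \lambda$
non-dominated truncation; one uniformly chosen offspring descriptor
joins the unbounded archive each generation (the simplest policy
consistent with an archive-plus-population neighborhood). Each
individual is evaluated once, with an evaluation seed derived from
(run seed, generation, index), so runs are exactly reproducible and
best-so-far fitness is monotone. Runs stop at the generation cap or
as soon as any individual reaches perfect fitness on the evolutionary
training set; the champion is the fittest individual, novelty
ignored.

A consequence worth knowing: with a single training set and a sharp
softmax, a lucky lifetime can produce perfect fitness without any
learning machinery, and the one-evaluation policy preserves that
score. Such champions show near-zero GLA — the very
training-set-size effect the experiment series is designed to
expose.

## The regularity measure

A developed network is first pruned to the neurons on some
input-to-output path (isolated vestiges would otherwise inflate
symmetry; a network with no I/O anchors is left as is). Neurons
become vertices colored `m` (modulatory) or `n` (anything else);
biases are ignored; each connection is replaced by a path through a
vertex colored by its signed weight's bin — large/small ×
negative/positive, boundary $w_{\max}/2$, zero counting as small
positive — because exact automorphism engines take vertex colors, not
edge labels. The automorphism count of this colored digraph (BLISS,
exact, never approximated) is the regularity score; a brute-force
enumerator over color-respecting permutations serves as an
independent oracle for graphs of up to 10 vertices. Plastic
magnitudes are set to the midpoint $(w_{\min}+w_{\max})/2$ before
binning so the score does not depend on one lifetime's learning
history; a snapshot mode keeps current magnitudes instead. Input and
output vertices carry no role color by default — matching the
labeling convention stated for the measure, at the cost of counting
same-role I/O swaps — and a strict mode adds role colors for users
who want the conservative count.

Canonical anchors: a uniform fully connected digraph on $n$ vertices
counts $n!$; a uniform two-layer 4-4 perceptron counts $4!\,4! =
576$; an 8-neuron CPG-style ladder with left-right mutual inhibition
and symmetric longitudinal coupling counts $2 \times 2 = 4$; a
typical random network counts 1. Map development guarantees counts
divisible by (map size)! whenever a developed hidden map survives
pruning with only one-to-all attachments.

## The experiment series and its synthetic scope

`run_experiment()` is one cell: sample an evolutionary training set of
`n_train` sets, evolve, then measure the champion's GLA over all 256
sets and its automorphism count. `run_series()` runs the grid
encodings × `n_train` × replicates with derived seeds and aggregates
medians, quartiles and the fractions of champions with more than 1,
more than 3, and at least 10 automorphisms. The full-scale preset
(population 400, up to 4000 generations, sizes 1–7) reproduces the
study design and needs cluster-class compute: single cells take hours.
The desk preset (population 100, cap 500, sizes 1–3, 5 replicates)
gives a workstation-scale qualitative echo. The bundled tests and the
acceptance script use still smaller runs — populations of 20–100 for
15–100 generations — chosen so the whole suite completes in minutes;
at that scale the *direction* of encoding differences is logged as
advisory information rather than asserted, because a handful of short
runs cannot establish distributional claims.

All data in this package are generated: there is no external input.
What the generators emulate is the task structure (associations,
rewards, feedback) and the genotype spaces; what they cannot emulate
is the compute regime of the full study, so passing tests demonstrate
correctness of the machinery and calibration of the measures — not
the original effect sizes.

## Numerical choices and degenerate inputs

* Engine duality: lifetime evaluation has a compiled fast path and a
  pure-R reference that consume R's RNG in the same order (one
  uniform per plastic weight at reset, column-major; one per softmax
  draw, inverse-CDF); they agree bitwise under a seed and are tested
  against each other.
* Softmax is computed with max-subtraction; $\tau \le 0$ is an error.
* Polynomial mutation uses the bounded formulation, so mutated genes
  never leave their interval; values at a bound stay mutable inward.
* Degenerate genotypes: a network genotype can lose all its
  connections (it still develops; fitness will be chance-level);
  deleting the last hidden neuron, re-adding an existing edge
  (replacement), and self-loops on hidden/output nodes are all legal.
* Automorphism counts can be astronomically large for sparse networks
  (isolated I/O neurons are mutually swappable); counts are returned
  as doubles, exact for the sizes arising here.
* Novelty with an empty pool is 0; with fewer than $k$ others, the
  mean runs over what exists.

## Known limitations

* Lifetime simulation is synchronous rate-based; no spiking,
  continuous time, weight decay or heterosynaptic competition.
* No NEAT-style speciation or innovation protection for CPPNs — the
  deliberately simplified direct encoding evolves them.
* The archive policy and novelty neighborhood are fixed-parameter
  defaults; no adaptive novelty threshold.
* Statistical comparison between series cells is delegated to
  `stats::wilcox.test()`; the package does not re-implement rank
  tests.
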