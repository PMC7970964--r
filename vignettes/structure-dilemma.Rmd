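---
title: "Methods: sparse network structure, implantation and perturbed training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse network structure, implantation and perturbed training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structnet)
```

## The model

`structnet` treats a trainable neural network and a directed signed graph
as two views of the same object. The graph view is ternary: every
potential connection is activating (+1), inhibiting (−1) or absent (0).
The network view adds real-valued weights on the active connections plus a
trainable additive offset per neuron (the bias, called *neuron offset*
throughout to avoid the statistical sense of "bias"). The package's
experiments all revolve around moving information between the two views:
extracting the ternary structure of a trained dense network, implanting a
structure into an untrained one, and measuring what training changes.

Two architecture families are supported. Feed-forward stacks
(`arch_feed_forward()`) apply relu hidden layers and a softmax output once
per sample. Recurrent networks (`arch_recurrent()`) iterate a single
tanh-activated state layer for a fixed number of steps (default 25) from a
zero initial state, with the input added to the pre-activation of the
input neurons at *every* step — the input is constant over the iteration —
followed by a readout chain applied to the final state. Where the input
dimension does not match the input neurons (all connectome models), a
fixed random encoder with entries U(−0.05, 0.05) maps the 784-dimensional
sample onto the sensory neurons; the encoder is drawn once per experiment
and never trained.

The injection point for the recurrent input (pre-activation, every step)
and the recurrent readout (a dense trainable softmax layer over all state
nodes) were genuinely open choices; both are documented here as the
package's defaults. The dense readout means 10 nodes' worth of output
capacity is counted as "reserved" when free nodes are enumerated (below).

## From connectome to network

The micro-connectome pipeline starts from two non-negative adjacency
matrices: neuron-to-neuron synapse counts and neuron-to-muscle attachment
counts. Synapse-count weights are used only for ordering and thresholding;
trained weights are always re-initialized, because measured synapse counts
span an unusable numeric range and carry no inhibition information.
Inhibition is instead assigned at the *neuron* level: one fraction is
drawn uniformly from 20–30% (the measured mammalian range), that fraction
of neurons is marked inhibitory, and all their out-edges get sign −1. An
edge-level assignment mode exists behind a flag for sensitivity checks.

Two trainable forms are derived. The recurrent form keeps all neurons in
one tanh state layer masked by the neuron adjacency, maps the state onto
tanh muscle nodes masked by the muscle adjacency, and decodes the muscles
densely to 10 softmax outputs. The feed-forward form flattens the graph by
each neuron's minimal directed distance to a muscle: distance-1 neurons
form the deepest hidden layer, distance-2 the next, and neurons at
distance ≥ 3 merge into the layer farthest from the output; neurons that
cannot reach any muscle are dropped; layers left empty by the distance
distribution are dropped too, so the hidden-layer count is an upper bound.
Only edges between consecutive layers are kept — the published description
does not say how skip-layer edges were handled, and discarding them is the
strict feed-forward reading. Encoded inputs are injected at whichever
layer their sensory neuron was binned into.

The macro-connectome pipeline thresholds a symmetric region-by-region
matrix to a target mean degree near 22, discards the weights, and gives
each retained undirected link one uniformly random direction and one
uniformly random sign. The published edge count is ambiguous about whether
it refers to undirected links before or directed edges after the
transformation; the default follows the one-directed-edge-per-link
reading, and the other reading sits behind `edge_convention = "full"`.

## Sparsification and its conventions

`sparsify_to_structure()` keeps the `round(n·c)` globally
largest-magnitude entries across *all* structural blocks, where `n` is the
total node count of the architecture. Global (rather than per-block)
selection, with `n` the total node count, is a deliberate convention: it
is the only reading under which the published connectivity behavior of the
sparsified 784-300-100-10 network is reproduced — at `c = 5` the 5970
survivors all sit in the two deeper blocks (whose glorot limits exceed the
global threshold), leaving exactly 410 of 1194 nodes (34.3%) connected
with zero variance across seeds, while `c = 15` reconnects the input
layer (≈ 99.9%). The acceptance suite recomputes both numbers.

Ties in magnitude at the cutoff break by ascending flat index (blocks in
order, column-major within a block) — deterministic and testable. Asking
for more connections than there are nonzero weights is a degenerate-input
error rather than a silent shortfall; `c ≤ 0` or exceeding capacity is an
invalid-parameter error.

## Initializations

* **glorot** — per-block uniform with limit `sqrt(6/(fan_in + fan_out))`.
* **uniform** — U(−0.05, 0.05), the solver-table default for the
  `uniform` recurrent runs.
* **irnn** — identity recurrent state block plus N(0, 0.001) noise, glorot
  elsewhere; the identity scale and noise level are not published and are
  package choices.
* **lightning** — the strategy of this name is cited but never described
  in the source literature available here; the shipped implementation is a
  documented *surrogate* whose only contract is the published connectivity
  behavior: on top of a glorot base it places one large-magnitude seed
  weight (2.5× the block's glorot limit) out of every row and into every
  column of each block, so sparsification at any mean degree ≥ 5 keeps
  the network almost fully weakly connected.
* **dense / sparse diversity** — per-node in-degrees drawn from the
  two-component normal mixtures (35% round(N(100,10)) / 65% round(N(50,5));
  80% round(N(8,2)) / 20% round(N(25,5))), rounded to nearest and clipped
  to the valid range; that many incoming positions per node get full-scale
  weights, the rest near-zero noise at 1/100 scale.
* **structure implantation** — primary entries `±v` with `v` defaulting to
  each block's glorot limit (the published description fixes only "the
  same value", not its magnitude), then uniform noise U(−v/10, v/10) added
  to *every* entry. Applying the noise to the zero entries as well is
  essential: the secondary connections must exist as live small weights,
  because the experiments rely on pruning being able to keep or discard
  them. Since `0.9·v > 0.1·v`, re-sparsifying an implanted model at the
  same `c` recovers the structure exactly (a tested round-trip identity).
* **winning ticket** — the `round(n·c)` strongest trained weights copied
  verbatim, background noise scaled by the mean copied magnitude.

Offsets always initialize to zero.

## Training, pruning, disturbance

Training is plain SGD with momentum on categorical cross entropy, with
masks re-applied after every optimizer step so masked positions are
exactly zero at all times. Defaults follow the published solver table
(feed-forward: lr 0.05, momentum 0, batch 128; large recurrent: lr 0.03,
momentum 0.01, batch 256; 30 epochs), all overridable. Validation is
evaluated once per epoch after the pruning hook. A non-finite loss aborts
with the epoch index.

Bio pruning defines *strong* connections as the top `round(n·c)` active
weights by magnitude — the published text defines strength only through
the connection budget implied by `c` — and deletes weakest-first among the
remaining active ("weak") connections. Newly created connections are
re-initialized from U(−v/10, v/10) with `v` the block's implantation
magnitude (or glorot limit). Creations and deletions are both Pois(20), so
the active count drifts as a Skellam difference around zero, which the
property suite bounds.

Disturbance adds N(0, σ) to the targeted values (weights XOR offsets)
before every batch's optimization; the noise persists in the values. In
blocked mode the targeted values are excluded from updates and the
untargeted values are never disturbed. The two summary metrics are
implemented as true root-mean-squares — the printed formulas take roots of
sums of *signed* quantities, but both are explicitly named RMS metrics, so
squares are intended: `γ` is the RMS per-value gradient over σ, and `δ`
the RMS total change from the initial state over `√N·σ`. Masked weight
positions are not trainable values and are excluded from both metrics; an
untrained (learning-rate-0) run then accumulates pure noise and has
`δ ≈ 1`, a tested closed-form limit. `σ = 0` makes both metrics undefined
and raises an error rather than returning infinities.

## Graph counting conventions

The number of possible edges `M` sums source×target over structural
blocks only — a recurrent state block counts `n²` including self-loops,
and a dense readout bolted onto a recurrent network does not count. The
isomorphism count multiplies factorials of per-layer *free-node* counts:
for feed-forward networks every hidden node is free; for recurrent
networks the free set is the state layer minus input neurons and minus the
10 readout-reserved nodes. These conventions reproduce the published
mantissas (2.86·10^772 for 300 + 100 free nodes, 8.77·10^2457 for 4×300,
6.40·10^868 for the 400 free nodes of the 1194-node net) and are the only
ones found to do so.

The unique-graph count is printed in the source material as `M!/m!`, yet
its value for the 177-node recurrent network is only consistent with the
falling factorial `M!/(M−m)!`, while the 784-300-100-10 row is consistent
with `M!/m!` at `m = round(n·c)`. Rather than guessing a single intent,
`unique_graphs_log10()` takes `m` and the convention explicitly and
documents both readings. All factorial arithmetic goes through log-gamma;
factorials are never formed.

The degree-sequence isomorphism screen is a necessary condition only: it
compares sorted (in-degree, out-degree) pairs and reports the fraction of
matching positions, declaring "possibly isomorphic" at ≥ 0.9. It has zero
false negatives (exhaustive-permutation-tested on small graphs) but
over-reports possibility for networks with pinned input/output nodes,
which it cannot see.

## The synthetic task

`generate_classification_dataset()` emulates the *interface* of the image
benchmarks — 784-dimensional inputs in [0, 1], ten classes, a training and
a validation split — with a prototype-plus-Gaussian-noise model:
`noise_sd` (default 0.3 in prototype units) sets the difficulty, and a
nearest-prototype oracle provides an independent accuracy reference. The
validation split is one sixth per class, mirroring the 60k/10k convention
of the originals (the source does not state its holdout protocol). What
the generator does *not* emulate: pixel correlation structure, class
overlap asymmetries, and the sheer scale of the real datasets. Passing
tests on the synthetic task therefore demonstrate that the machinery
trains, prunes and perturbs correctly and that qualitative phenomena
(implanted structures learn, disturbance collapses accuracy beyond a noise
scale, offsets decorrelate) appear — they do not certify benchmark
accuracy numbers, which are out of scope. An IDX reader is provided for
locally available benchmark files; nothing is downloaded.

## Problem sizes

The test and acceptance runs use deliberately small instances chosen to
keep the full suite in the minutes range on one CPU core: training
exercises use a 120-dimensional task with 600 training samples, a
160-node recurrent network at mean degree 22 (the published degree, at
roughly 1/7 the node count), and 5 training epochs; the disturbance sweep
uses the grid σ ∈ {0, 10⁻³, 10⁻², 10⁻¹, 1} with two repetitions per cell.
The combinatorial and connectivity acceptance computations run at full
published size (1194-node architectures, ten seeds) since they need no
training.

## Known limitations

* No convolutional architectures, gap junctions/electrical synapses, or
  spatial connectome geometry.
* The feed-forward connectome flattening discards skip-layer edges; an
  alternative would be residual-style pass-through nodes.
* The lightning surrogate satisfies the connectivity contract but is not
  the cited algorithm.
* Recurrent backpropagation stores all 25 step states; very large state
  layers are memory-hungry in plain R.
* The isomorphism screen is one-sided (no false negatives, many false
  positives by design).
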