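# structnet

How much of a neural network's function lives in its *wiring*? Biological
connectomes differ markedly between individuals, yet damaged or grossly
altered brains can recover full function — structure clearly matters, but
no single structure is privileged. `structnet` provides the machinery to
study this "structure dilemma" computationally: it converts biological
connectomes (the *C. elegans* chemical-synapse micro-connectome, thresholded
human macro-connectome matrices) and random graphs (G(n, p), directed
small-world) into trainable sparse neural networks, trains them with masked
SGD under various initializations, pruning schedules and parameter
disturbances, and quantifies how structure, weights and neuron offsets
change — or refuse to change — during learning.

The package is aimed at researchers in computational neuroscience and
sparse-network machine learning who want a fully seeded, desk-scale
laboratory for structure-versus-weights experiments.

## The core operations

**Ternary sparsification.** A dense network is turned into a sparse signed
graph by keeping the `round(n·c)` globally largest-magnitude weights, where
`n` is the total node count and `c` the target mean degree (average
connectivity). Retained positive weights become activating connections
(+1), negative ones inhibiting (−1), everything else is absent (0). The
magnitude threshold is thereby adjusted dynamically so the mean degree
stays exactly `c`.

**Structure implantation vs. winning tickets.** Structure implantation
initializes from the ternary pattern alone — primary connections get fixed
magnitudes `±v`, then low uniform noise `U(−v/10, v/10)` is added to every
position, so "secondary" connections exist as small random weights. A
winning ticket instead copies a pretrained sparse structure *with* its
weight values.

**Pruning.** Iterative pruning re-selects the strongest `round(n·c)`
weights as the active mask after every epoch. Bio pruning mimics biological
turnover: up to `Pois(20)` new connections appear and up to `Pois(20)` weak
connections disappear per epoch, and strong connections (the top
`round(n·c)` by magnitude) are never broken.

**Disturbed and blocked training.** Gaussian noise `ε ∼ N(0, σ)` is added
to the weights or to the neuron offsets before every batch's optimization;
in blocked mode the disturbed values are additionally frozen. Two RMS
metrics summarize the response: `γ = RMS(∂l/∂χ) / σ` (gradient strength
relative to the disturbance) and `δ = RMS(Δχ) / (√N·σ)` (total value
change relative to a pure `N`-step noise random walk).

**Graph counting.** For an architecture with `M` possible edges (sum of
block source×target counts), the number of unique labeled graph forms
`P = M!/m!` and the number of isomorphic variants `I = ∏ f_l!` over the
per-layer free-node counts `f_l` are computed on the log10 scale via
log-gamma.

**Comparison analytics.** Spearman rank correlations of weights and
offsets, odd-edge counts between ternary structures, a degree-sequence
isomorphism possibility screen, one-sided two-sample t-tests on best
accuracy and learn-curve sum with Bonferroni correction, and paired
triangular "toast" comparison matrices over many runs at once.

## Worked example

Implant the structure of a random recurrent graph — with no weight
information — and watch it learn a synthetic 10-class task:

```r
library(structnet)

ds <- generate_classification_dataset(n_per_class = 60, noise_sd = 0.15,
                                      seed = 2, dim = 120)
g  <- generate_gnp(160, 22, seed = 3)
st <- ternary_structure(list(sign(graph_to_adjacency(g))), mean_degree(g), 160)
print(st)
#> <ternary_structure> 1 blocks, 3573 active connections (c = 22.3313, n = 160)

bundle <- connectome_spec_bundle(arch_recurrent(160, input_index = 1:120), st)
model  <- implant_structure(build_model(bundle$architecture), st, seed = 5)
rec    <- train_model(model, ds,
                      solver_config(0.05, 0.01, epochs = 5, batch_size = 64),
                      seed = 20)
round(rec$accuracy, 3)
#> [1] 0.10 0.27 0.36 0.60 0.87
```

The implanted network reaches 87% validation accuracy in five epochs
although only the activating/inhibiting/absent pattern was provided. The
trained weights stay strongly rank-correlated with the implanted state,
and the trained structure is *identical* to the implanted one — the
structure persists through learning:

```r
spearman_weight_similarity(rec$final_model, rec$initial_model)
#> [1] 0.9098904
odd_edge_count(model_structure(rec$final_model, st$target_mean_degree), st)$fraction
#> [1] 0
```

The combinatorial reference quantities for a 784-300-100-10 network at
mean degree 22:

```r
graph_count_report(arch_lenet_300_100(), c = 22)
#> <graph_count_report> M = 266200, m = 26268
#>   unique graphs: 1.71 x 10^1223900
#>   isomorphisms: 2.86 x 10^772
```

`M = 266,200` possible edges admit about `10^1,223,900` distinct sparse
wirings, of which any one has `2.86·10^772` node-permutation-equivalent
(isomorphic) variants from permuting the 300 + 100 free hidden nodes.

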