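# apnn — attention prototypical nearest-neighbour networks

`apnn` is an R package for **few-shot image classification** of visually
similar categories — its motivating use case is fish species recognition,
where most species have only a handful of labelled photographs. Intended
users are researchers who need a classifier that generalises to *new*
classes from N labelled examples each, and who want every stage of the
pipeline (data, embedding, metric, training, evaluation) inspectable in R.

## The method

Classification is episodic. A *K-way N-shot episode* draws K classes, N
support images per class and M query images per class; support and query
sets are disjoint, and train/validation/test splits are **class-disjoint**
so evaluation is always on unseen categories.

- **Embedding** `f_φ`: a truncated ResNet18-style CNN (no final FC/GAP
  layer; last stage at stride 1) with *hybrid attention* after each stage —
  channel attention fusing a 3×3 branch and a dilated-3×3 branch through a
  per-channel two-way softmax (`a_c + b_c = 1`, squeeze width
  `d = max(C/r, L)`), then spatial attention via a sigmoid-gated 7×7
  convolution over L2-normalised pooled maps. An 84×84 image yields
  `m = h×w = 36` local descriptors of dimension 512.
- **Prototypes**: `c_k = (1/n) Σ f_φ(x_i)`, the position-wise mean of the
  class's support feature maps.
- **Image-to-class metric**: `score(x, c_k) = Σ_{i=1..m} Σ_{j=1..k}
  cos(x_i, x̃_ij)` where `x̃_ij` are the k nearest prototype descriptors of
  query descriptor `x_i` (Euclidean and Manhattan variants negate distance
  sums so larger is always closer). A softmax over scores gives class
  probabilities; training minimises episodic cross-entropy with Adam
  (lr 0.001, step decay 0.5, weight decay 5e-4).
- **Evaluation**: mean top-1 episode accuracy over repeated blocks of
  episodes with a 95% confidence half-width `1.96·sd/√N`.

A procedural generator of fish-like synthetic species (elliptical striped
bodies, fins, cluttered water backgrounds, controllable inter-class
similarity) makes the whole pipeline runnable and testable offline.

## Worked example

Thirty synthetic species, class-disjoint 20/5/5 split, small backbone,
5-way 5-shot training for 4 epochs × 180 episodes (a few minutes on one
CPU):

```r
library(apnn)

idx    <- build_dataset(30, 15, "synthetic_fish", seed = 1)
splits <- split_classes(idx, c(20, 5, 5), seed = 1)

model <- apnn_model("reduced", attention = "ha", k = 3, distance = "cosine")
cfg   <- apnn_config(train_epoch = 4, train_episode = 180,
                     ways = 5, shots = 5, queries = 5, seed = 11)
fit   <- apnn(splits$train, splits$val, model = model, config = cfg)
print(fit)
#> Attention prototypical nearest-neighbour model
#>   backbone: reduced (descriptors: 25 x 64, grid 5x5)
#>   attention: ha   metric: k = 3 cosine
#>   parameters: 104,323
#>   trained: 4 epochs, final loss 0.0010, best val acc 0.884 (epoch 2)

evaluate(fit, splits$test, episode_spec(5, 5, 5),
         episodes = 100, repeats = 1, seed = 9)
#> episode accuracy: 89.520% +/- 1.119% (95% CI, 100 episodes)
```

The evaluation line reads: across 100 held-out 5-way 5-shot episodes on
species never seen in training (chance = 20%), the model labels 89.5% of
queries correctly, with the ± value giving the 95% confidence half-width
over episodes. The same fitted object supports `predict()` on an episode,
`pair_similarity()` for two images (bounded in \[0, 1\], higher for
same-species pairs — 0.91 vs 0.82 in this run),
`activation_map()` for a saliency overlay, `plot()` for training curves,
and `summary()`/`coef()` for introspection. The full-scale reference
configuration — `apnn_model("resnet18", "ha")` with
`apnn_config()` defaults (100 epochs × 600 episodes, 600-episode ×
20-repeat testing) — is the same code at larger settings and requires real
data and long training.

A thin command-line front end with `synth`, `split`, `train`, `eval`,
`ablate`, `cam` and `pairsim` subcommands is installed at
`inst/cli/apnn.R`.

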