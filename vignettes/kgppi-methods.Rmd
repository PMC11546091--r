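---
title: "Methods: hybrid link prediction and literature validation for protein interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid link prediction and literature validation for protein interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Associative gene networks built by literature mining are incomplete: many
real protein–protein interactions are described in abstracts that the
extraction rules missed, and many co-mentions are not interactions at all.
`kgppi` implements a three-stage hybrid strategy for expanding such a
network while keeping false discoveries under control:

1. **Topology stage.** A two-layer neighbourhood-aggregation encoder
   (GraphSAGE-style) learns a 64-dimensional embedding $z_u$ for every
   node of the network. A candidate edge $(u, v)$ is scored by the dot
   product $s(u,v) = \sum_i z_{u,i}\, z_{v,i}$, interpreted as a logit.
2. **Fusion stage.** For unconnected pairs, a multilayer perceptron takes
   the 129-vector $[\,z_u \,\|\, z_v \,\|\, 1-p\,]$, where $p$ is the
   literature co-occurrence p-value of the pair, and outputs an
   interaction probability. Probabilities strictly above 0.5 are positive;
   exactly 0.5 is negative.
3. **Context stage.** Every abstract mentioning a predicted-positive pair
   is turned into an instruction prompt (few-shot examples, the document
   context, a question restricted to that context, a required leading
   YES/NO indicator, a confidence level, an explanation) and submitted to
   a generation backend. A pair is confirmed if *any* mentioning document
   yields a YES verdict. The shipped backend is a deterministic rule
   system keyed to an interaction-verb lexicon; a fine-tuned language
   model can be plugged in through the same one-function contract.

The stages form a funnel — candidates, with co-occurrence data,
classified positive, with documents, confirmed — whose counts are audited
and monotonically non-increasing. Evaluation throughout uses the standard
six metrics (sensitivity, specificity, precision, accuracy, F1, and the
Matthews correlation coefficient), with degenerate denominators reported
as 0 and flagged.

## Models and training

**Encoder.** Layer 1 maps node features to a 128-dimensional hidden
representation through separate self and mean-of-neighbours weight
matrices followed by a rectified-linear activation; layer 2 maps to the
final 64 dimensions the same way. Training minimises binary cross-entropy
on the dot-product logits of positive edges versus 1:1 sampled non-edges,
with the decoupled-weight-decay Adam optimiser (AdamW) at learning rate
0.01 and weight decay 0.01. Edges are split 85/10/5 into
train/validation/test; message passing uses training edges only, so a
held-out link never reaches its own aggregation neighbourhood. Early
stopping monitors the validation loss with a patience of 20 epochs and
restores the best-validation weights.

**Classifier.** The MLP is 129 → 256 → 128 → 64 → 1 with rectified-linear
hidden units and a logistic output, trained with binary cross-entropy,
AdamW at learning rate 0.001, mini-batches of 64, and early stopping on
the validation MCC with a patience of 50 epochs. The data split is
80/10/10, stratified by class. The co-occurrence ablation removes the
129th input and retrains from scratch, leaving a 128-input model.

**Verdict convention.** Generated answers must begin with `YES` or `NO`;
the parser strips leading whitespace/punctuation, matches the first token
case-insensitively, extracts a `confidence: high|medium|low` phrase when
present (defaulting to "unstated"), and keeps the remainder as the
explanation. A malformed generation is retried once; a second failure is
recorded as a NO verdict flagged `malformed`, so batch runs always
terminate with one verdict per example.

## Numerical and design choices

Several choices were genuinely open; the reasoning:

* **Node features.** The graph carries no informative node attributes, so
  the default feature matrix is: degree, a one-hot entity type, and 16
  adjacency-spectral positional coordinates (leading eigenvectors of the
  training-edge adjacency, z-scored). Spectral coordinates are the
  classical positional encoding for structure-only graphs — community
  structure concentrates in the leading eigenvectors — and, computed from
  training edges only, they leak nothing about held-out links. A
  trainable one-hot identity channel is available (`identity_features`)
  but off by default: it memorises the training edges quickly, which
  pulls the early-stopping point forward and costs held-out accuracy.
* **Negative sampling.** Validation and test negatives are frozen in the
  link split; training negatives are frozen too rather than resampled
  each epoch. Resampling repeatedly pushes the same positive pairs up
  while spreading the negative gradient over ever-fresh pairs, which
  drifts the score of *every* generic pair upward; with the decision
  threshold fixed at probability 0.5, that inflates apparent performance
  on structureless data. Frozen 1:1 negatives keep generic-pair scores
  centred.
* **Initialisation.** Weights use the seeded uniform fan-in scheme;
  encoder biases start at zero so the initial embedding cloud is centred
  — a shared bias offset would give every dot product the same sign.
* **Chance-level control.** To verify the encoder learns structure rather
  than artefacts, the same pipeline is run on a degree-destroying random
  rewiring of the edge set. One subtlety: on a structure-free graph the
  validation loss never genuinely improves, so "best validation epoch"
  degenerates to the near-initialisation model, whose probabilities all
  sit at 0.5000x and whose F1 then measures only the sign convention. The
  control is therefore fitted to convergence
  (`restore_best = FALSE`, patience = max epochs = 300) and evaluated on
  the held-out links, where it scores at chance.
* **Measurement.** Held-out F1 on a 200-protein world rests on ~260
  held-out links per split, so single-split estimates carry a standard
  error of a few points. The acceptance measurement pools the held-out
  confusion counts of five seeded fits (~1,300 decisions): validation
  pairs are scored with train-only message passing, test pairs with
  train+validation message passing (mirroring standard link-split
  semantics), and one F1 is computed from the pooled counts.
* **Edge semantics.** Undirected edges are canonicalised to `u < v` by
  string comparison; parallel edges of different interaction types are
  kept as typed rows, and the pair-level edge set is their distinct
  `(u, v)` projection. The unipartite projection is the induced subgraph
  (kept-type nodes and the direct edges between them) — the most
  conservative reading; contracting two-hop paths through other entity
  types would inflate density unverifiably.
* **Missing data.** A pair without a co-occurrence entry, or with an
  endpoint that was filtered out before embedding, is skipped and
  reported, never imputed. Objects with no co-occurrence p-value against
  a query term are dropped with a warning. The object filter keeps
  `p <= 0.05`, removing strictly greater values.

## The synthetic world

`make_world()` generates the complete test-bed: a planted-partition graph
of 200 proteins in 4 blocks (within-block edge probability 0.3, between
0.01) plus 40 other typed entities; 20 planted-missing ("held-out")
within-block edges that act as discovery targets; 20 decoy pairs that are
co-mentioned but never interact; co-occurrence p-values drawn from
Beta(1, 19) (mean 0.05) for true and held-out pairs and uniformly for
null pairs and decoys; and one templated abstract per pair — interaction
abstracts link the two names with a verb from the shared lexicon inside
one sentence, decoy abstracts mention the names in separate sentences.
A handful of nodes get 4-character names to exercise the short-name
filter. Everything is reproducible from one seed.

These sizes were chosen so that the whole pipeline — five encoder fits,
one classifier fit, and a full discovery run — completes in well under a
minute on one CPU; smaller worlds (60 proteins) back the unit tests.

What the generator emulates: block-structured association topology,
co-occurrence significance that correlates with interaction truth, and a
corpus whose language is decidable by the rule backend. What it does not
emulate: realistic abstract language, entity-name ambiguity,
multi-document evidence conflicts, the heavy-tailed degree distribution
of real literature networks, or the 11-type/36-relation schema of a
production knowledge base. Passing tests therefore demonstrate that the
machinery is correct and calibrated on its stated statistical structure —
not that the same accuracy would transfer to real literature, where the
context stage in particular depends on the plugged-in language model.

## Known limitations

* The planted-partition world puts a ceiling on achievable held-out link
  F1 (~0.87 under the default densities: within-block non-edges are
  statistically indistinguishable from held-out edges), so measured
  values sit close to the acceptance bound by construction.
* The rule-based backend validates only verb patterns it knows; it is a
  test double with perfect precision on generated corpora, not a model of
  language.
* The discovery orchestration is single-threaded and in-memory; graphs
  beyond ~10^4 nodes would need neighbour sampling (the `encode` path is
  full-neighbourhood) and a real document index behind the store
  contract.
* Interaction-nature tags (regulatory / physical binding /
  co-localization) come from a small keyword map over the validator
  explanation, with "untyped" as an honest fallback.
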