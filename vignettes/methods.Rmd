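---
title: "Joint text + knowledge-graph representation learning at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint text + knowledge-graph representation learning at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Biomedical knowledge accumulates in two complementary forms: structured
triples — `(Sorafenib, directlyDecreases, VEGFR-2)` — assembled into
knowledge graphs (KGs), and the unstructured sentences from which those
triples were extracted. A triple is precise but stripped of context; its
evidence sentence carries context (species, tissue, disease, experimental
setting) but no explicit structure. **kgcross** implements a multimodal
cross encoder that reads both at once: a BERT-style transformer applied to
the concatenation of a tokenized evidence sentence and a sequential
representation of the triple, so that attention spans both modalities and
no entity-linking step is needed. It is benchmarked against a text-only
encoder and a static KG-embedding baseline under shared, deterministic
cross-validation.

## Data model

The atom is the *text-triple pair*: an evidence sentence plus the
`(head, relation, tail)` triple it supports, with optional per-task class
annotations. Pairs live in a TSV with a JSON annotations column
(`readPairs()` / `writePairs()`); the KG is a TSV edge list. Pairs whose
evidence is empty, or whose endpoints are not grounded (absent from the KG
node set or missing a `namespace:id` prefix), are removed by
`filterPairs()` before any training — mirroring the preprocessing of
assembled knowledge bases, where non-grounded nodes and evidence-less
triples are filtered out. `splitCorpus()` then partitions pairs into the
unannotated pre-training corpus and per-task fine-tuning sets.

## Triple sequences

The KG side enters the model as a *sequence*, to match the text side's
shape:

* **Walk mode** (default): a random walk from the head and one from the
  tail, each node replaced by its embedding, concatenated as
  `walk(head) ⊕ [SEP] ⊕ walk(tail) ⊕ [SEP]`. With the full-scale walk
  length of 127 this yields exactly 256 positions — the KG half of the
  512-position combined input. Node embeddings come from
  `trainNodeEmbeddings()`, a skip-gram-with-negative-sampling model over
  uniform second-order random walks (the node2vec family). Walks traverse
  edges as undirected with `p = q = 1`; a dead-end node repeats itself so
  sequences always have the fixed length the combined input requires.
* **TransE mode** (ablation): the triple's three vectors
  `(e_h, e_r, e_t)` from a margin-ranking TransE model
  (`trainTransE()`; margin 1, L2 norm, uniform head-or-tail corruption —
  the standard choices), padded to the KG half length. Because this input
  encodes the relation directly, TransE-input models are excluded from
  relation-type tasks in the benchmark.

One walk is cached per node (`newWalkCache()`), so all examples sharing a
node reuse the identical walk within a run; whether to resample per epoch
is exposed but off by default — resampling adds variance without changing
any qualitative result at this scale.

## The cross encoder

`assembleInput()` builds the combined input: `textLen` tokenized text
positions (`[CLS] … [SEP]`, padded/truncated, truncation keeps the sentence
head since evidence is sentence-level), then `kgLen` triple-sequence
positions. Segment ids are 0/1 for the two halves; position ids run
`0..maxLen-1` in a single ramp (a restart at the KG half would add nothing
the segment embedding does not already provide, and the single ramp matches
the convention the architecture inherits). The full-scale geometry is
512 = 256 + 256 (`bertBaseProfile()`); the desk-scale default is
64 = 32 + 32 with hidden size 64, 2 layers, 4 heads.

Three pre-training heads sit on the encoder:

* **MLM** — masked-language modeling over the text half;
* **MEM** — masked-entity modeling over the KG half, a linear + softmax
  map onto the node vocabulary *including the separator*, so the inserted
  `[SEP]` tokens are reachable labels (separator positions are therefore
  maskable);
* **NSP** — a binary head on the `[CLS]` state deciding whether sentence
  and triple belong together. `makeNspExamples()` *augments* the corpus
  with `round(0.25 · n)` mismatched pairs rather than replacing originals;
  negatives draw evidence and triple from two distinct originals and are
  verified never to reproduce an existing pair. Negative examples also
  contribute to MLM/MEM — the simplest reading of "augment the data", and
  the masked objectives remain well-posed on mismatched pairs.

Masking (`applyMasking()`) follows the classic 15% / 80-10-10 recipe
independently per maskable position; text-half specials
(`[CLS]`, `[SEP]`, `[PAD]`) are excluded, KG-half pads and TransE relation
slots are excluded. A masked KG position is fed the *text-side* `[MASK]`
embedding vector — the masking signal is shared across modalities — and a
randomly-replaced KG position receives a random real node's embedding,
mirroring the random-token rule in entity space.

The total pre-training loss is `L_total = L_MLM + L_MEM + L_NSP`, each
term a mean cross-entropy over its own supervised positions only (the
ignore marker is `NA`); the `no_nsp` ablation drops the last term exactly.
Fine-tuning (`finetune()`) pools the `[CLS]` hidden state through one
linear + softmax head and updates *all* parameters. The static KG baseline
(`fitKgBaseline()`) instead max-pools a triple sequence dimension-wise and
trains only the linear head — its embedding table is bit-identical before
and after fitting, which the test suite asserts.

## Implementation notes

The encoder is the package's core contribution and is implemented in
full here: the transformer stack
(post-layer-norm blocks, GELU feed-forward, multi-head attention with
additive key masking), its full backward pass, and AdamW with 10% linear
warmup, linear learning-rate decay and global-norm gradient clipping at
1.0 — all in base R matrix code (BLAS-backed). The warmup and
clipping are the standard stabilizers of this architecture family; without
them, few-sample fine-tuning occasionally collapses on single folds.
Correctness is guarded by finite-difference gradient checks in the test
suite (relative error below 1e-3 at `eps = 1e-5`) and by an independent
cross-entropy oracle for the loss components. Dropout defaults to 0 so
that every run is bit-reproducible from its seeds; all randomness flows
through `deriveSeed(seed, purpose)`, a polynomial string hash that gives each
pipeline stage an independent stream derived from one master seed.

Numerical choices worth stating: attention masking adds −1e9 to masked
key columns before the softmax; layer norm uses ε = 1e-12; cross-entropy
clamps probabilities at 1e-12; softmax rows are max-shifted; ties in
`max.col` are broken deterministically (`"first"`). Degenerate inputs are
handled explicitly: a loss component with no supervised positions is 0, a
dead-end walk pads by repetition, unknown nodes map to a dedicated
trainable `[UNK]` entry (fine-tuning corpora may contain nodes unseen in
pre-training).

When the node-embedding dimension differs from the hidden size, the
backbone vectors are projected once at initialization by a fixed seeded
linear map; because the node table is trainable by default, a separately
learned projection would be redundant with the table itself. A `freeze`
argument exposes the frozen-table alternative, in which case the
projection is the only trainable KG-input component.

## The synthetic corpus

`generateKG()` / `generatePairs()` / `generateTaskLabels()` emulate the
statistical shape of a large assembled biomedical KG at desk scale — the
features the method's mechanics depend on, not biomedical language:

* grounded node ids (`toy:0001`) distinct from surface names (`BAROLE12`),
  so sentences mention names while the graph holds identifiers;
* typed directed edges from a relation-typed Erdős–Rényi-style sampler
  with block structure: `round(n·d̄/2)` edges, tails within the head's
  block with probability 0.8, isolated nodes repaired, duplicates dropped;
* one template sentence per pair —
  `"<head-name> <verb(relation)> <tail-name> <filler…> <keyword?>"`;
* a minority of pairs annotation-capable: the default 15% is the
  minority-annotated regime scaled up just enough that fivefold CV folds
  of the annotated subset still hold a learnable number of examples per
  class (the real corpus' ~1.6% of 13.6M pairs would leave a desk-scale
  corpus with too few labeled examples to train on at all).

Defaults (800 nodes in 4 blocks, 6 relations, mean total degree 8, 2000
pairs, 60 filler words) are the package's study conditions. The node count
is deliberately large relative to the annotated subset (~0.4 annotated
pairs per node), so that a text-only model cannot cover the entity
inventory by memorizing surface names — the regime in which graph-side
structure has something to add, and the desk-scale analog of a corpus
whose entity inventory dwarfs any task's labeled data. The block count is
small enough that block membership is learnable from walk sequences at
these sample sizes.

Four label mechanisms probe what each modality can and cannot see —
`relation_determined` (label = relation type), `node_determined` (label =
head-node block; no class keyword is written into the sentence, so a
text-only model can reach the label only by memorizing surface names,
never by generalizing),
`text_determined` (label = a keyword appended to the sentence; independent
of node identity, which a mutual-information test against a permutation
null verifies), and `fused` (a gated-copy rule: the label equals the
keyword class when the head block's parity bit is 1 and collapses to
class 0 otherwise). The fused rule is a joint function of both modalities
— keyword alone achieves Bayes accuracy `(n+1)/2n`, the node bit alone the
same, while the joint truth table is deterministic — and, unlike a
modular-sum (XOR) rule, it is linearly expressible over good keyword and
block representations, which keeps it learnable at desk-scale sample
sizes (an XOR variant was tried during development and proved beyond what
a 2-layer, hidden-64 model learns reliably from ~240 examples; both
tested models then collapsed to memorization and the task stopped
distinguishing them). Note that sentences also mention the head's surface
name, so a text-only model can in principle recover node identity by
memorization; the multimodal model's advantage on the fused task comes
from generalizing through the walk-sequence block structure rather than
per-name memorization. The eight benchmark task fixtures reuse
these mechanisms with the canonical class counts 2, 2, 10, 10, 5, 3, 2, 8.

What passing tests on this corpus do **not** show: robustness to real
biomedical language (subword effects, negation, hedging), reader-system
noise, ontology-grounding ambiguity, or class-imbalance profiles of real
curated tasks (the generator exposes a class-probability vector instead of
copying any particular profile).

## Evaluation

`weightedF1()` is the per-class-F1 average weighted by true-class counts,
with 0/0 defined as 0 (this makes the all-predictions-on-an-absent-class
case exactly 0); it is tested to 1e-9 against a confusion-matrix oracle.
`makeCvSplits()` produces deterministic, optionally label-stratified folds
(sizes differ ≤ 1; per-class fold counts differ ≤ 1) that are served
identically to every model of a benchmark; fold scores are computed on the
held-out fold after training on the other k−1, and summaries use the
arithmetic mean over folds. `relativeGain(a, b) = 100·(a−b)/b` reports the
best-variant-over-best-baseline gain in percent.

## Desk-scale study and its calibration

`runDeskScaleStudy()` is the package's end-to-end experiment: pre-train on
the NSP-augmented unannotated corpus, then benchmark three models on a
fused task and a text-determined task under shared fivefold CV. Problem
sizes — 800 nodes, 2000 pairs, 300 annotated, a 64-position combined
input, 600 pre-training steps, 20 fine-tuning epochs (8 for the
early-saturating text task) — were chosen once so that the full study runs
in minutes on a single CPU while still exhibiting the method's qualitative
behavior: pre-training loss decreases; the text-only baseline dominates
the static KG baseline wherever the label is written in the sentence; and
on the fused task, where no modality alone determines the label and
per-name memorization cannot cover the entity inventory, the multimodal
model outperforms both unimodal baselines.

Two training constants deliberately differ from the full-scale profile,
whose fine-tuning settings (5 epochs, batch 16, AdamW at 5e-5 with linear
decay — kept as `trainConfig()`'s defaults) presume a large pre-trained
backbone: at desk scale the backbone is pre-trained for hundreds (not
hundreds of thousands) of steps, so fine-tuning uses a learning rate of
1e-3 and 20 epochs; and the static baseline's head — the only thing that
baseline trains — gets lr 0.05 for 50 epochs, without which it would stay
at its initialization and make every comparison against it vacuous.

## Known limitations

Whitespace tokenization (no subwords) is a deliberate stand-in for a
pre-trained biomedical tokenizer; the pluggable contract (ids, specials,
padding) is what downstream code depends on. The walk mode carries no
relation embeddings — a structural property of walk-based node embeddings;
the TransE input is the in-package alternative. Single-threaded, CPU-only
training bounds the reachable scale; the architecture accepts the
full-scale geometry, but nothing desk-sized approximates the absolute
scores of a multi-week, multi-GPU pre-training on millions of pairs, which
is why the package's claims are structural laws, oracle equivalences and
qualitative orderings rather than absolute benchmark numbers.
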