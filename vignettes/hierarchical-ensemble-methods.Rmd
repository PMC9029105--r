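---
title: "Hierarchical ensembling for imbalanced user-level suicide-risk detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical ensembling for imbalanced user-level suicide-risk detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhesd)
```

## The problem

Suicidal-ideation detection on social media is a user-level classification
problem with two structural difficulties. First, prevalence: users at risk
are a small minority (in the motivating Weibo study population, 1606 of 4521
users), so a classifier trained directly on the raw corpus is rewarded for
predicting "normal" and its accuracy hides a useless recall. Second,
provenance: much of the explicit signal is concentrated in semi-anonymous
venues ("tree holes", e.g. a Depression SuperTopic), and some at-risk users
disclose *only* there. A model whose evidence is dominated by tree-hole posts
fails exactly on the population a screening tool most needs to reach — users
who never post in a tree hole.

`dhesd` implements a deep hierarchical ensemble (DHE-SD) that addresses the
imbalance, and a sentence-level mask mechanism that measures (and stresses)
the provenance dependence.

## The model

The classification unit is the user $u_i$ with posting sequence
$T_i = (t_1, \dots, t_{y_i})$ and binary label (suicidal / non-suicidal).
Base classifiers consume the concatenated document
$d_i = t_1 \,\|\, t_2 \,\|\, \dots \,\|\, t_{y_i}$ (`concat_posts()`, with a
separator token between posts, input order preserved — the source data's
ordering is respected and never re-sorted, since post order on disk is the
posting order).

**Balanced sub-datasets.** The imbalanced training set $D$ is divided into
$n$ balanced sub-datasets $D_1, \dots, D_n$ with $D = D_1 \cup \dots \cup
D_n$: each $D_p$ holds *all* minority users plus an equal-sized majority
sample (`build_partition_plan()`). Two sampling strategies are provided. The
default, `independent_sample`, draws each subset's majority sample
independently; overlap between subsets is then possible and, at the study's
own counts, unavoidable ($3 \times 1284 > 2333$ majority training users), so
disjointness cannot have been a property of the original three-subset design.
The alternative `disjoint_cycle` deals majority users round-robin and
guarantees the coverage reading of $D = \cup_p D_p$ whenever capacity allows
($n \cdot |\text{minority}| \ge |\text{majority}|$).

**Two-level voting.** Each sub-dataset trains $m$ base classifiers
$c_{p1}, \dots, c_{pm}$ (here: TextCNN, FastText, DPCNN). For a test user,
votes $r_{pq} = c_{pq}(d_i)$ fill an $n \times m$ grid; the first level takes
a majority within each subset's row, $r_p = E(r_{p1}, \dots, r_{pm})$, the
second level a majority across subsets, $r = E(r_1, \dots, r_n)$
(`hierarchical_predict()`). The ensemble operation $E$ is implemented as
**hard majority voting** — the reading under which counting "correct
classifiers" is meaningful; probability-averaging is deliberately not the
default and would be a different estimator. Ties cannot occur at the
default odd shape $n = m = 3$; for even configurations the tie rule defaults
to the positive class, favouring recall in a screening context.

The structural advantage over a flat majority across all $n \cdot m$ votes is
combinatorial: with nine classifiers, a flat majority needs five correct
votes, while the hierarchy can be correct with four (two rows carried
2-of-3). `vote_pattern_census()` verifies this by exhaustive enumeration of
all $2^{9}$ correctness patterns, and the test suite checks the reduction
against an independently coded counting oracle on every pattern.

**Sentence-level mask.** `apply_sentence_mask()` deletes every post whose
`source` tag is in the masked set (default: `tree_hole`), producing the
masked condition from the unmasked one ($y_i' \le y_i$). Masking is by
provenance tag only, never by content: the construction of the original
masked dataset removed posts synchronised from the Depression SuperTopic,
and content-based masking would be a different (and label-leaking)
mechanism. Masking is idempotent, never increases a post count, and drops
(and reports) users left with no posts.

## Preprocessing

`clean_corpus()` applies the eight-step pipeline in a fixed order: drop
system-generated posts; strip URLs, @-mentions, emoticon tokens, boilerplate
phrases ("sharing pictures" and similar), administrative-division location
strings, and SuperTopic titles; drop posts whose residue is empty; and drop
users with fewer than `min_posts_per_user` retained posts. A post removed by
an earlier rule is never counted by a later rule, and the per-rule removal
tally is attached to the result (`removal_tally()`).

Two defaults deserve flagging. The regular expressions (URLs, mentions,
bracketed emoticons plus Unicode symbol codepoints, `#...#` SuperTopic
titles) are *replaceable stand-ins*: the exact emoticon inventory,
boilerplate list and division list of a given platform are
deployment-specific, so every pattern is configurable and can be loaded from
YAML. And `min_posts_per_user = 3` makes "too few remaining posts" concrete:
three posts keep the concatenated document non-degenerate while discarding
near-empty users; the original threshold is not stated anywhere, so user
counts of the source datasets cannot be re-derived.

## Base classifiers

No deep-learning framework is assumed: the three architectures are
implemented directly in vectorised R (im2col convolutions over BLAS
matmuls, hand-derived backpropagation, Adam). Correctness rests on
finite-difference gradient checks in the test suite, which compare every
architecture's analytic gradients against central differences at small
sizes.

* **TextCNN** — parallel 1-d convolutions (kernel widths 2/3/4) over the
  embedded document, ReLU, global max-pooling per filter, linear softmax.
* **FastText** — averaged embeddings of unigrams and hashed bigrams,
  linear softmax.
* **DPCNN** — region convolution followed by pyramid blocks
  (stride-2 max-pooling, two same-padded convolutions, residual
  connection), global max-pooling, linear softmax. The halving pooling uses
  window size 2; the pyramid and residual structure are what matter at this
  scale.

Training follows the fixed protocol: batch size 128 for every model,
20 epochs for the CNNs and 50 for FastText, early stopping on validation F1
with best-checkpoint semantics (the reported `validation_f1` is the maximum
of the training log). Word vectors are randomly initialised and learned end
to end; no pretrained embeddings. The tokenizer is pluggable (whitespace by
default; a Chinese segmenter can be dropped in for real Weibo text).

Hyperparameters not fixed by the protocol are desk-scale choices:
embedding width 16, 16 filters per kernel, 3 pyramid blocks, documents
truncated to 256 tokens (head policy), patience 5, learning rates 5e-3
(TextCNN), 8e-3 (DPCNN) and 0.05 (FastText). The learning rates and patience
were set by inspecting training curves on the synthetic generator's default
corpus: at ~256 training documents there are only two minibatches per epoch,
and with smaller steps the models linger in an all-one-class plateau long
enough for early stopping to freeze a degenerate checkpoint. The widths are
deliberately small — the synthetic task's signal is lexical (see below), so
capacity is not the binding constraint, and the full two-condition,
three-seed study stays within a laptop-class CPU budget. All of these are
`train_config()` arguments. A `dummy` architecture (convex bag-of-words
logistic scorer) exists purely as a fast, deterministic test double for the
ensemble machinery and carries no fidelity claim.

## The synthetic corpus generator

Real corpora of this kind cannot be redistributed, so `generate_corpus()`
emulates the statistical structure the method's claims rest on, at 1/10
scale: 160 positive / 290 negative users (vs. 1606/2915); post counts
Poisson + 1 with means 8 vs. 15 (vs. average 83.65/147.20 posts per user);
12-token posts. The vocabulary is a four-block unigram mixture — shared,
positive-signal, tree-hole-signal, negative-signal — because the
separability evidence in real corpora of this kind is lexical
(high-frequency word contrasts such as "die"/"uncomfortable" against
"laugh"/"cute"), so unigram signal suffices to
exercise every pipeline stage while keeping difficulty fully controllable.

Three parameters define the scientific structure:

* `signal_strength` (default 0.5) — mixture weight of class-signal words in
  a signal post;
* `hidden_fraction` (default 0.3) — fraction of positive users whose
  ordinary posts are *distributionally identical* to negative users', with
  their entire signal in tree-hole posts. These users reproduce the
  known failure mode in which a user with clear tree-hole ideation is
  unreachable after masking: with `hidden_fraction = 1`, the masked positive
  and negative classes are indistinguishable by construction (verified by a
  chi-square test on token counts in the suite);
* `treehole_post_rate` (default 0.25) — per-post probability that a positive
  user's post is tree-hole-tagged. The default is calibrated to the observed
  ~25% drop in suicide-group post counts under masking (83.65 to 62.48
  average posts per user).

The generator is a pure function of its config (including the seed), and
`generate_dirty_corpus()` additionally injects URLs, mentions, emoticons,
boilerplate, locations, SuperTopic titles, system posts and URL-only posts
at known rates, recording an injection ledger that the cleaning tally must
reproduce exactly — the oracle for the preprocessing module.

What the generator does *not* emulate: real language (no syntax, no
semantics, no Chinese segmentation ambiguity), bursty posting dynamics,
label noise, or covariate shift between tree-hole and ordinary styles
beyond vocabulary choice. Post-count dispersion is Poisson by declaration;
the real dispersion is unknown (only means are published). Passing tests on
this generator therefore demonstrate that the pipeline's machinery is
correct and that the method's *directional* claims hold under the assumed
lexical-signal model — not that the published accuracy levels transfer to
real data.

## Splits, seeds and determinism

`stratified_split()` shuffles within class and assigns the validation and
test partitions their exact quota rounded half-down, the training partition
taking the remainder; at 8:1:1 this reproduces the reference per-class
partition sizes (1284/161/161 positive, 2333/291/291 negative) exactly.
Every stochastic operation takes an explicit integer seed, and derived seeds
(subset validation views, per-model training seeds) are computed from the
master seed so that a single integer replays an entire experiment;
`run_experiment()` writes a manifest and intermediate files whose bytes
reproduce under the same config.

Numerical corner cases are pinned down deliberately: 0/0 in precision,
recall or F1 reports 0 with a visible `zero_division` flag; prediction
argmax breaks exact logit ties toward the negative class; the vocabulary
orders tokens by (frequency desc, token asc) so builds are reproducible;
the padding embedding row is frozen at zero, so padded positions are true
zero vectors throughout training.

## The scaled-down study

`run_experiment()` executes the full protocol: (clean) → (mask) → split
8:1:1 → balanced partition plan (3 subsets, each with its own balanced
validation view) → train the 3 × 3 grid → hierarchical prediction on the
test set → evaluation against baselines. The `single` baseline trains each
architecture on the full imbalanced training partition and reports the one
with the best validation F1; `oversample`/`undersample` retrain that
architecture on resampled training data (whole users are duplicated or
removed — the classification unit is the user, so duplicating individual
posts would change the document model).

The acceptance script (`scripts/acceptance.R`) runs this study on the
default generator conditions over three seeds, both masked and unmasked, and
reports medians; the test suite asserts the directional claims (the
hierarchical ensemble matches or beats the best single model; masking hurts
the baseline; the ensemble stays at or above the baseline under masking).
Problem sizes — 450 users, 3 seeds, 16-wide models — are the package's
working scale; everything accepts larger values.

## Known limitations

* The ensemble operation is hard voting only; soft voting is an extension
  point, not an option, because the reference behaviour is defined by
  correct/incorrect counting.
* "Three models with the best performance" is interpreted as the three
  architectures at their best checkpoints. A random-search selection layer
  (top-k of a search per architecture) would be a different experiment; the
  hyperparameter search of the original protocol is not reproduced.
* The whitespace tokenizer is a stand-in for real Chinese segmentation; all
  fidelity claims about real Weibo text are out of scope.
* At 45 test users, one flipped user moves F1 by roughly three percentage
  points; directional comparisons are therefore made on medians over seeds,
  and single-seed rankings are noisy.
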