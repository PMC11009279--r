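---
title: "Screening birth narratives for CB-PTSD: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening birth narratives for CB-PTSD: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cbptsdscreen)
```

## The problem and the model

Childbirth-related post-traumatic stress disorder (CB-PTSD) affects a
significant minority of postpartum women, and no standard screening
protocol exists. The method implemented here screens from a single
patient-friendly data source: a free-text narrative of the birth
experience. Ground truth for training is *provisional*, not clinical: the
PCL-5 symptom checklist (20 items, each 0–4) is summed with missing items
coded as 0, and a total of 31 or more defines class 1. The cutoff sits at
the low end of the validated 31–33 range to reduce false negatives, which
is the right trade-off for a screening instrument.

The core statistical difficulty is sample size: a realistic cohort has only
a few hundred cases, far too few to train a text classifier directly. The
pipeline addresses this with **pairwise augmentation**. Instead of learning
`narrative → label`, it learns `pair of narratives → same class?`. With
`n` training narratives per class, the training set grows from `2n` labeled
narratives to `4·C(n,2)` labeled pairs — at `n = 170`, 57,460 examples —
balanced by construction (both within-class sets are *similar*, the
cross-class set is sized to match). Each pair `(u, v)` is represented by
the Hadamard (elementwise) product `z = emb(u) ∘ emb(v)` of the two
narrative embeddings. The Hadamard feature is symmetric in the pair, which
the tests verify, and it preserves the coordinate structure of the
embedding space: coordinates where the two vectors agree in sign push `z`
positive.

The similarity model is a small feedforward network, `d → 400 → 50 → 1`,
ReLU hidden activations and a sigmoid output, trained with binary
cross-entropy. A single narrative is classified at test time by pairing it
with every training reference of each class and comparing the mean
similarity per class.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| PCL-5 cutoff | 31 (unitless total score) | low end of the validated range; favors sensitivity |
| minimum words | 30 | narratives shorter than this carry too little signal |
| train fraction | 17/19 of each class | generalizes the 190-per-class → 170-train design |
| embedding dimension `d` | 1536 | contract of the ada-002 embedder; any `d ≥ 2` works |
| cross-pair count | `2·C(n,2)` | balances the augmented set exactly |
| hidden widths | 400, 50 | stated recipe; no search performed |
| optimizer | Adam, lr 1e-4, batch 32 | stated recipe |
| epochs / patience | ≤ 50 / 3 (on validation loss) | stated recipe; see below |
| validation fraction | 0.2, stratified by pair label | stated recipe |
| repeats | 10 | resampled evaluation, analogous to 10-fold CV |

## Design choices where the design was open

**Early-stopping monitor.** "No loss improvement for 3 consecutive epochs"
does not say which loss. We monitor *validation* loss: that is what the
20% hold-out exists for, and monitoring training loss would make the
hold-out pointless. Any strict decrease counts as improvement
(`min_delta = 0`); weights are those of the stopping epoch (no rollback),
matching the common framework default.

**Cross-pair sampling.** Set 3 is drawn *without* replacement over distinct
cross pairs. At `n = 170` there are 28,900 possible cross pairs and 28,730
are needed, so duplicates would be both wasteful and likely; distinctness
maximizes information and is reproducible.

**Single-narrative decision rule.** The pair classifier does not by itself
classify one narrative. We use mean-similarity reference voting:
`score_c = mean over train references r of class c of sim(test ∘ r)`,
predicting `1` iff `score_1 ≥ score_0`. Ties go to class 1 because a
screening instrument should fail toward sensitivity. Prediction is
invariant to reference order (mean aggregation), which is tested.

**Seed derivation.** All randomness flows through one integer seed. Repeat
`i` of the evaluation uses `(seed mod 1e6)·1000 + i`, not `seed + i`: with
naive addition, the repeat streams of adjacent master seeds coincide.

**Duplicate subject IDs are a hard error** — a silent duplicate could sit
on both sides of a train/test split and leak.

## The synthetic world

The generator emulates the cohort structure the pipeline was designed
around, so that every stage is testable offline:

* 1295 subjects at prevalence 190/1295 ≈ 14.7%, allocated exactly;
* narrative word counts lognormal per class, parameterized from the
  published class means and medians (class 1: mean 194.67 / median 158,
  class 0: mean 155.39 / median 106; `meanlog = log(median)`,
  `sdlog² = 2·log(mean/median)`). The default 5-word floor lets ~7% of
  class-0 narratives fall under 30 words, exercising the length filter;
* PCL-5 totals uniform in [31, 60] (class 1) and [0, 25] (class 0),
  distributed over items capped at 4; missing items (per-subject
  probability 14/1295, 1–3 items) are assigned *before* the total is
  distributed over the remaining items, so missing-as-zero scoring always
  reproduces the intended label;
* embeddings: a hidden unit direction `e` is drawn once; class means are
  `±(δ/2)·e`; each vector is its class mean plus isotropic Gaussian noise
  of expected norm `noise_scale` (default 1), normalized to unit length.
  `δ` (the distance between class mean directions) is the single knob for
  class separation: `δ = 0` makes the classes identical in law, `δ = 2`
  makes a naive centroid classifier nearly perfect.

What a green test does **not** establish: the generator's narratives are
bags of class-tilted tokens, not language; its embedding geometry is a
two-cluster idealization, not anything a real text encoder produces; and
recovery of synthetic labels says nothing about performance on a real
cohort, which is explicitly out of scope (the original data are not
deposited). Green tests establish that the machinery — scoring, filtering,
balancing, augmentation arithmetic, training, metric algebra, seeding — is
correct and deterministic.

## Numerical choices

* Sigmoid logits are clamped to ±30 before exponentiation and predicted
  probabilities to `[1e-12, 1 − 1e-12]` in the loss, so BCE is always
  finite.
* Weights are Glorot-uniform initialized (zero biases), seeded through R's
  RNG; the compiled training kernel draws its epoch shuffles from R's RNG
  too, so a single `set.seed` reproduces training bit-for-bit.
* Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-7 (framework defaults).
* Training loss is logged as the running per-batch average (pre-update);
  validation loss, the early-stopping monitor, is a full pass per epoch.
* Metrics with zero denominators are reported as `NA`, never coerced to 0;
  report tables round half-even to 2 decimals while JSON keeps raw values.
* A label-only classifier's ROC has one interior operating point, so
  `AUC = (sensitivity + specificity)/2`; the implementation is checked
  against a generic trapezoidal ROC oracle on 1000 random confusion tables.
  Note this identity makes a published row with (sens 0.81, spec 0.72,
  AUC 0.80) internally inconsistent — per-fold averaging order can do
  that — which is why reports expose both the mean of per-repeat AUCs and
  the pooled-counts AUC.

## Degenerate inputs

Empty texts, wrong item counts, out-of-range severities, single-class
corpora, over-budget documents (> 16,384 tokens, mirroring the 16k chat
context), missing embedding vectors, and dimension mismatches all raise
validation errors naming the offending slot or subject. Unparseable chat
responses are a reported value (`NA` label plus a counter), not an error:
excluding them silently would bias metrics invisibly.

## Known limitations

* The provisional PCL-5 label is not a clinical diagnosis; nothing here is
  a diagnostic device.
* The real cohort and ada-002 embeddings are unavailable, so published
  real-data performance is not reproduced here, only the machinery.
* The live chat/embedding backends are interface-only; all tests run
  against deterministic mocks.
* The reference-voting inference rule is this package's documented
  stand-in for an unpublished aggregation step.
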