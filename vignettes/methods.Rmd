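---
title: "Distilled masked vision-language pre-training: models, masking and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distilled masked vision-language pre-training: models, masking and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mvldistill` implements pre-training-stage knowledge distillation for
medical vision-language (VL) backbones. This vignette is the package's own
account of the method: the model family, the objectives, the distillation
losses, the attention-guided masking algorithm, and — because several parts
of the recipe are stated only loosely in the literature this family comes
from — the concrete design decisions the implementation makes, with the
reasoning behind each.

## The model family

Each model is a pair of uni-modal transformer encoders with a multi-modal
fusion module on top:

* an **image encoder**: non-overlapping square patches (16 px at full
  scale), linearly embedded, a learnable *summary token* prepended, learned
  position embeddings added, then `image_layers` pre-norm transformer
  blocks;
* a **text encoder**: token + position embeddings over a fixed vocabulary,
  then `text_layers` blocks. The toy tokenizer is whitespace-based over a
  48-token closed vocabulary; a sub-word tokenizer can be plugged in for
  full-scale corpora (an untested hook);
* a **fusion module** of `fusion_layers` *co-attention* layers: two
  parallel streams (image and text), each layer applying self-attention,
  cross-attention into the other stream, and an MLP. This two-stream form
  is what the published per-component parameter counts imply — a fusion
  layer costs `16 d^2` weights per stream (`d = 768`: 9.45 M, so six layers
  are 56.7 M per stream), and the two printed multi-modal columns sum with
  the uni-modal columns to the printed totals. A single stack over the
  concatenated token stream cannot reproduce those counts. The two-stream
  reading also gives a natural `N x N` "text-to-image" attention object:
  the *image-stream self-attention inside the fusion module*, which carries
  text influence through the preceding cross-attention layers;
* **task heads**: an MLM head tied to the token embedding (the RoBERTa
  convention; an untied head would add ~38 M parameters that the published
  totals do not contain), a 2-way matching head on the pooled joint
  representation (the average of the two streams' summary-token outputs),
  and a masked-autoencoder-style **reconstruction decoder** (512-dim, 6
  layers at full scale) that inserts a learnable mask token at masked patch
  positions and predicts raw pixel vectors. The published image-column
  parameter counts exceed a standard ViT stack by a near-constant ~18 M in
  every preset, which is what a decoder of exactly this size costs; we
  attribute the excess to the decoder and obtain preset totals within 0.5%
  of the printed 341.4 / 188.8 / 141.6 M; exact reproduction is not claimed
  since the original breakdown is unpublished.

Presets: `teacher-m3ae` (12/12/6 layers), `student-base` (7/6/2),
`student-small` (5/4/1), all at width 768 with 12 heads on 288-px images;
`toy-teacher` (4/4/2) and `toy-student` (2/2/1) at width 32 with 2 heads on
32-px images. The toy scale is the default profile and the scale of every
test.

## Objectives

* **MLM**: 15% of non-special tokens are selected (`floor(0.15 x
  maskable)`, uniform without replacement); of the selected, 80% are
  replaced by `[MASK]`, 10% by a random vocabulary word, 10% kept. The loss
  is mean cross-entropy over selected positions only. Selected-but-kept
  tokens contribute to the loss (standard practice; the source is silent).
* **MIM**: 75% of patches are masked (`round(0.75 N)`, round-half-up); the
  loss is the mean squared error over the masked patches' raw pixel vectors
  in `[0, 1]`, with no per-patch normalisation. The reconstruction target
  formula is sometimes written with a cross-entropy symbol in this
  literature while the prose specifies MSE; MSE is implemented (the prose
  wins, and it matches masked-autoencoder practice).
* **ITM**: each pair flips to a negative with probability 0.5; a negative
  substitutes the caption or the image (probability 0.5 each) with that of
  a different, uniformly drawn batch member. Mean binary cross-entropy on
  2-way logits.

The three task branches run separate forwards (masked text + full image;
masked image + full text; full pairs). Whether the original implementation
shares one fusion forward is unknown; separate forwards are the
unambiguous reading.

Losses compose without weights: `pretrain = mlm + mim + itm`, `distill =
hid + attn`, `total = pretrain + distill`. The metrics log reproduces these
identities exactly, row by row.

## Distillation

Layer mapping is uniform interval sampling: student layer `i` of `l` maps
to teacher layer `ceil(i L / l)`, so the printed 2:1 / 3:1 / 6:1 ratios are
reproduced whenever `L/l` is integral, the deepest layers always align, and
the non-integral image-encoder cases (12 to 7, 12 to 5) fall back to the
same ceiling spacing — the published ratio table is internally inconsistent
for those depths, and ceiling spacing is the single rule consistent with
every integral case.

Hidden-state distillation sums per-layer MSE between student states and
mapped teacher states (teacher constant, no gradient; equal widths in all
presets, with an optional learned projection hook for unequal widths).
Attention distillation compares *post-softmax* row-stochastic maps (the
formula defines the map as the softmaxed product; the pre-softmax variant
used by some uni-modal distillation work is deliberately not used).
Teacher and student share the head count in every preset; head `i` pairs
with head `i`. Distillation is computed on the masked-text branch — the
branch choice is not specified at the source, and computing it on one
branch keeps the cost of a step bounded.

## Attention-guided progressive masking

Per step, for each sample:

1. one gradient-free forward of teacher and student on the *unmasked* pair;
2. four `N x N` guidance maps are extracted: per model, the head-averaged
   self-attention of the last image-encoder layer (uni-modal) and of the
   last fusion layer's image stream (multi-modal), with the summary-token
   row/column dropped and rows renormalised. The summary token is excluded
   because downstream ranking concerns patches only; whether to aggregate
   one layer or all layers is unspecified at the source — the last layer is
   the conventional choice for salience;
3. the maps are summed and min-max normalised to `[0, 1]`; an (all but
   degenerate) constant sum returns a uniform 0.5 matrix so salience is
   defined everywhere. Positive rescaling of the inputs cannot change the
   output;
4. per-patch salience is the **column mean** of the aggregate — the average
   attention a patch *receives*. The source never states how an `N x N`
   matrix becomes a sortable per-patch score; column means are the
   "attention received" convention;
5. the high-attention group is the `round((1-r) N)` top-salience patches
   (ties broken by lower index; stable), with
   `r = r_start - (r_start - r_end) * step / max_steps`, `r_start = 0.95`,
   `r_end = 0.3`, clamped beyond the horizon;
6. the whole high group is masked; the remaining budget up to the fixed
   total of `round(0.75 N)` is drawn uniformly from the low group.

Step 6 resolves a genuine ambiguity: the source text says a proportion
"75% - r" of the low group is randomly masked, which is negative at
`r = 0.95`. Fixing the *total* budget at 75% of `N` matches the masking
ratio of the MIM objective and both narrated endpoints — at `r = 0.95` the
mask is 5% key patches plus 70% random; at `r = 0.3` it is 70% key plus 5%
random. Likewise the mask is treated as a per-patch vector in `{0,1}^N`
(the `N x N` matrix form in the source is read as a typo: masks act on
patches).

The schedule horizon `max_steps` equals the run's total scheduled optimizer
steps, and the guided mask is recomputed every step (caching per epoch
would be cheaper; recomputation is the default because the maps move with
the student).

## Training loop

AdamW (decoupled weight decay 0.01, betas 0.9/0.999) with linear warm-up
over 10% of steps then linear decay to zero, mirroring the published
schedule. The full-scale learning rate of 1e-5 cannot move a
randomly-initialised toy model measurably within a few hundred steps, so
the toy profile uses 1e-3; both are plain configuration values. Teachers
are resolved once and never updated (their weight digest is asserted
unchanged in the tests). Checkpoints carry the optimizer state and the RNG
state, so a resumed run is bit-identical to an uninterrupted one. Every
step logs a JSONL row with all loss components, the schedule value `r` and
the learning rate.

## The synthetic corpus

The generator emulates the *structure* that the method exploits in real
radiograph-caption corpora, not radiology itself:

* a smooth low-contrast background (a seeded sum of four low-frequency
  sinusoids, amplitudes 0.015-0.04 around a 0.35 base), emulating the low
  tissue contrast the masking strategy is motivated by;
* one bright elliptical "lesion" per image (round / oval / elongated,
  additive gain 0.38-0.62), placed away from the image border and away
  from the quadrant midlines so that its quadrant is unambiguous; the gain
  floor is chosen so that even a "faint" lesion is the image's brightest
  structure — the premise of using it as the ground-truth salient region;
* the set of patches the lesion's interior covers is recorded in the
  manifest (`salient_patches`), giving an exact oracle for
  attention-guided-masking tests;
* a caption from a fixed 20-word template naming the lesion's size, shape,
  intensity and quadrant (`"a large round faint opacity is seen in the
  lower left region of the lung field with smooth margin noted"`). The
  fixed length means every caption has exactly 20 maskable tokens, so the
  15% MLM selection rate is realised exactly (`floor(0.15 x 20) = 3`)
  rather than distorted by floor effects on very short captions.

What the corpus does **not** model: real anatomy and pathology vocabulary,
multi-sentence reports, compound figures, inter-reader variability, or any
correlation structure beyond one lesion and one sentence. Passing tests on
this corpus demonstrate that the mechanisms (masking, objectives,
distillation, scheduling) are implemented correctly and interact as
specified — not that the method reaches any particular downstream accuracy
on real data, which requires full-scale pre-training on real corpora and is
out of scope here.

## Numerical choices

* Round-half-up for all group sizes and budgets (base R's `round()` is
  round-half-even); salience ties break toward lower patch indices, making
  mask generation deterministic given the RNG state.
* Min-max normalisation for the guidance aggregate, with the constant
  guard at `1e-12`.
* Attention rows are exactly stochastic up to floating point (asserted at
  `1e-5` in tests).
* GELU uses the sigmoid approximation `x * sigmoid(1.702 x)`; its error is
  orders of magnitude below optimisation noise, and value and derivative
  are consistent by construction.
* Weight init: truncated normal (sd 0.02, clipped at 2 sd) via inverse-CDF
  sampling so each array consumes a fixed number of RNG draws;
  layer-norm gains start at 1, biases at 0. Initialisation from published
  CLIP/RoBERTa weights is an optional, untested hook at full scale.
* The autodiff engine is verified against central-difference numerical
  gradients for every operation, including both outputs (context and
  attention map) of the attention core.

## Problem sizes used in the tests

The test suite and the acceptance script run entirely at toy scale: 8-40
corpus pairs at 32-96 px, toy models (width 32), a 500-step distillation
run for the end-to-end check, 10,000 sequences / 100,000 selections for
masking statistics, and 1,000 randomised trials for the brute-force
mask-equivalence check. Full-scale presets are exercised at the
configuration level (depths, parameter counts) plus one build of the
teacher preset; full-scale pre-training on real corpora (hundreds of
thousands of pairs, GPU-scale) and downstream fine-tuning are explicitly
out of scope.

## Known limitations

* The published image-encoder parameter counts exceed a standard ViT-B
  stack by ~18 M per preset; attributing the excess to the reconstruction
  decoder reproduces every printed total within 0.5%, but the original
  breakdown is not published, so exact parameter reproduction is not
  claimed.
* Padded-token attention rows are not masked out inside the encoders (toy
  captions are near-fixed-length, so padding is minimal); distillation
  compares full maps.
* The ITM head sees in-batch negatives only; with batch size 8 and a
  finite caption grammar, occasional caption collisions between distinct
  images are possible (labels follow the substitution, not string
  equality).
* One fusion forward per task branch (three per step plus the guidance and
  teacher forwards); sharing activations across branches would be cheaper
  but is deliberately not done, keeping each branch's inputs exactly as its
  objective defines them.
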