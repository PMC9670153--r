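---
title: "Comparing facial-expression databases through action-unit tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing facial-expression databases through action-unit tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Posed facial expressions of the basic emotions are partly universal and
partly culture-specific: the same emotion label can be acted with
different patterns of facial movement in different populations. The
Facial Action Coding System (FACS) decomposes any facial movement into
action units (AUs) — elementary movements driven by specific muscles,
e.g. AU#12, the lip-corner puller of a smile. `auface` implements an
image-analysis framework that makes such differences measurable without
human raters: train image classifiers separately on two
expression-labeled face databases, measure how poorly each classifier
transfers to the other database, probe what each classifier's output
units have learned in AU coordinates, and summarize the cross-database
similarity of that AU tuning.

Because the posed-face photograph collections this kind of analysis is
normally applied to are distributed only on request, the package ships
a parametric synthetic face generator that plays the role of the two
databases and of the AU-manipulated probe stimuli. The generator is a
first-class, tested component: it lets every claim of the framework be
exercised end to end under known ground truth.

## The pipeline

1. **Synthesis** (`generate_database()`): each database is defined by a
   *culture map* — per expression label, a mean intensity for each
   involved AU. Each of the `n_identities` posers is a bounded random
   perturbation of a template face (eye spacing/size, brow height,
   mouth width, oval aspect, skin tone, smooth texture), and each
   (identity, expression) image is rendered after drawing AU
   intensities from a truncated normal around the culture means
   (normal draw clipped to [0, 1]; sd = `noise_sd` = 0.1 by default, a
   moderate posing variability; per-AU sds in the culture map override
   it). The renderer is procedural 2-D: geometric primitives with
   AU-indexed control-point displacements that scale linearly with
   intensity (AU#12 moves mouth corners up/out, AU#4 lowers and
   narrows the brows, AU#26/#27 open the jaw and lower the chin,
   AU#22 thickens and rounds the lips, AU#23 thins them, ...). It is
   deterministic, dependency-free and carries the planted signal; it
   makes no attempt at photorealism, 3-D pose, or color.
2. **Standardization** (`preprocess_image()`): grayscale conversion
   (0.299/0.587/0.114), face crop from the generator's known bounding
   box (a cascade face detector is deliberately out of scope), affine
   histogram adjustment to mean 128 / sd 32 (population sd; statistics
   over the crop, before masking), then an oval mask with a linear
   5%-of-height transition band to background 128. The linear blend
   means masking is exactly idempotent inside the oval and outside the
   band, and only approximately so within the band.
3. **Augmentation** (`make_variants()`): a deterministic grid of
   scales x position offsets x horizontal reflections per image, in
   lexicographic order. The canonical grid is 5 x 5 x 2 = 50 variants
   (scales 0.90–1.10, offsets ±5% of the input size); the desk presets
   use 3 x 3 x 2 = 18.
4. **Classifier** (`build_network()`, `train_run()`): a frozen
   convolutional backbone and a trainable head of three fully
   connected layers ending in 7 units, softmax-read as expression
   probabilities, with inverted dropout (p = 0.1) before FC1 and FC2
   and fan-in-scaled normal ("He") initialization with zero biases.
   The default backbone is three frozen random-filter conv stages
   (5x5x8, 3x3x16, 3x3x32) with 2x2 max pooling after each — mirroring
   the pooling placement of the five-conv-layer reference architecture
   — reducing a 64 px input to 8 x 8 x 32 = 2,048 features. Random
   frozen filters preserve enough spatial structure to carry the
   planted AU signal; true pre-trained conv weights can be plugged in
   from a local file but are never downloaded. Because the backbone is
   frozen, features are extracted once per augmented image and cached;
   training touches only the head.
5. **Training** (`train_run()`, `run_experiment()`): identity-disjoint
   40/8/12-proportioned splits, shuffled mini-batches of 32 with a
   remainder batch (14,000-sample epochs leave a final batch of 16 at
   canonical scale), plain SGD (no momentum or weight decay) on
   cross-entropy, piecewise-constant learning rate stepping down at
   fixed iterations, a hard iteration cap (training halts mid-epoch at
   the cap; the canonical protocol's stated epoch count is
   arithmetically inconsistent with its iteration count, so the cap
   governs), per-epoch validation, and `runs` independent repetitions
   with fresh split/init seeds.
6. **Evaluation** (`confusion_matrix()`, `swap_test_database()`,
   `compare_correct_rates()`): 7 x 7 choice-rate matrices on held-out
   test identities (only the centered un-augmented variant of each
   test image is scored; test-time augmentation is not part of the
   protocol), averaged across runs, for the database-matched and
   database-swapped conditions; Welch's two-sided t test on per-run
   mean correct rates and a two-way ANOVA (condition x expression,
   with interaction) on per-run per-expression rates.
7. **AU probing** (`generate_probe_set()`, `probe_responses()`): 20
   series of 11 images (intensities 0.0, 0.1, ..., 1.0 — the uniform
   reading of "11 steps") on the average-identity face, one AU active
   per series, all others shut off; the intensity-0 "null image" is
   bit-identical across series. Probe images pass through the same
   standardization as training data (the units were trained on that
   distribution), one centered presentation each. Pre-softmax FC3
   responses are recorded, the null response subtracted per unit
   (making the null exactly 0), averaged across runs, then normalized
   (averaging before normalizing; per-unit or whole-group maximum
   absolute value = 1).
8. **Profile statistics** (`per_expression_correlations()`,
   `cross_correlation_matrix()`, `correlate_with_confusion()`,
   `run_pca()`): Spearman rank correlations between flattened 20 x 11
   profiles with the null column excluded (it is identically zero in
   every profile and would only inject ties), giving n = 200 per pair;
   7 same-expression correlations with Bonferroni significance at
   0.05/7; the full 7 x 7 cross-group matrix (an orientation flag
   transposes axes without changing values); its Spearman relation to
   the swapped confusion matrix over the 49 aligned pairs (rows of the
   correlation matrix must be the profiles of the group trained on the
   confusion matrix's test database — the object attributes enforce
   this); and PCA of the 20 x 14 matrix of per-AU signed extrema
   (largest-magnitude response over the 11 intensities, sign kept,
   ties broken toward the higher intensity — the stronger expression
   of the AU), with the 14 (expression, database) columns as
   observations, mean-centered but not variance-scaled (the minimal
   standard choice; scaling is available as an argument).

`run_full_experiment()` executes all of this from one master seed;
every stream of randomness (database geometry, AU draws, splits, FC
initializations, batch orders, dropout) is derived from it through one
documented hash, so reports are bit-reproducible.

```{r}
library(auface)
cfg <- fixture_suite("default-twin", preset = "desk", master_seed = 1)
rep <- run_full_experiment(cfg)
summary(rep)
plot(rep)           # the four confusion matrices
```

## The twin-culture fixtures

The default fixture plants a known answer. Both cultures share happy
(AU#12 = 0.85, AU#6 = 0.5), surprised (AU#1/#2/#5/#26), fearful and
disgusted; they diverge in angry — culture A poses it with AU#4 = 0.5
plus lip funneler AU#22 = 0.85, culture B with AU#4 plus lip tightener
AU#23 = 0.85 — and in sad, where B adds AU#22 = 0.60 to the shared
AU#1 + AU#15 pattern. The divergent AUs carry the larger share of the
angry signature deliberately: the construct under test is that the two
groups of classifiers learn opposite uses of AU#22/#23, so profiles of
happy and surprised units should correlate strongly across groups
while angry and sad should not, matched accuracy should exceed swapped
accuracy, and the correlation-vs-confusion relation should be
positive. Two controls bracket this: `"identical-cultures"` (same map
for both databases — any residual gap is identity sampling noise) and
`"disjoint-cultures"` (a derangement of AU sets across expressions —
the maximal gap).

Intensity means where the construct leaves freedom (e.g. fearful,
disgusted) follow common FACS descriptions of those expressions and
were fixed once when the fixture was designed.

## Scale presets and numerical choices

* `"canonical"` — the full-scale protocol (60 identities, 224 px, 50
  variants, FC 4096/4096/7, 12,000 iterations at 1e-4/1e-5/1e-6
  stepping at 4,000/8,000, 40 runs). It validates structurally via
  `dry_run()`; executing it requires compute and pre-trained conv
  weights outside this package's test scope.
* `"desk"` (default) — 24 identities (16/4/4), 64 px, 18 variants, FC
  128/128/7, 1,500 iterations, 5 runs. About two minutes of CPU while
  preserving every structural element (identity-disjoint split,
  remainder batch, LR breakpoints scaled to 500/1,000).
* `"mini"` — 12 identities (8/2/2), 48 px, FC 64/64/7, 800 iterations,
  3 runs. The multi-seed replication scale (~25 s per master seed),
  used where a claim is asserted over ten master seeds.

Two numerical choices depart from a literal transcription of the
canonical protocol and deserve emphasis. First, desk-scale SGD uses
learning rates 0.3/0.03/0.003: the canonical 1e-4 schedule is tied to
the scale of pre-trained AlexNet activations, and a pilot sweep showed
the random-backbone head under-converges below ~0.1 while gaining
nothing above ~0.3. Second, `train_run()` centers features on the
training-set mean and stores that center in the fitted model: with a
frozen random backbone the shared face-mean component dominates the
class signal and plain SGD stalls without this — it is the
mean-image-subtraction step standard in AlexNet-era pipelines, applied
in feature space.

Other conventions: argmax ties break toward the fixed label order
(neutral first); Welch's unequal-variance t test is used where only
"t test" is specified; the two-way ANOVA is computed on the balanced
run x expression table where the sums-of-squares type is immaterial;
Spearman p values use the t approximation (exact permutation is
available for n ≤ 8); probe baselines are validated to agree across
series to 1e-6 before subtraction; and a degenerate (constant-image)
histogram is an error rather than a silent pass-through.

## What the synthetic data does and does not show

The generator emulates the statistical skeleton of a posed-expression
database: identity-disjoint variation, label-conditional AU patterns
with posing noise, shared-versus-divergent structure across two
sources, and probe stimuli whose ground truth is known. It does not
emulate photographic texture, lighting, 3-D pose, occlusion, or the
correlated AU co-activations of real faces. Green tests therefore
certify that the pipeline — standardization, training, evaluation,
probing, statistics — recovers planted structure correctly and
deterministically; they do not certify accuracy levels on real
photographs, which depend on the databases and pre-trained features
used. The headline numbers of a real-data application (e.g. matched
accuracies near 0.75 and swapped accuracies near 0.4–0.5) are
direction-setting references, not targets the synthetic fixture
reproduces.

## Known limitations

* The frozen random backbone is weaker than pre-trained conv features;
  desk-scale accuracies are correspondingly lower, and the package
  reports directions and orderings rather than absolute rates.
* Single-AU probing measures first-order tuning only; nonlinear AU
  interactions are out of scope by design.
* The renderer's AU geometry is its own documented mapping; it is not
  calibrated against any commercial face-synthesis software.
* With few test identities (mini preset: 2 per run) per-seed accuracy
  estimates are noisy; multi-seed claims are therefore stated as
  proportions over master seeds.
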