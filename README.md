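# auface

Quantifying how the facial features that define posed expressions
differ between face databases, in the coordinate system of FACS action
units (AUs).

## The problem

Whether facial expressions of the basic emotions are universal or
culture-specific is a long-standing question. A concrete, measurable
version of it: given two expression-labeled face databases produced in
different populations, do the *visual features* that characterize each
expression agree between them? `auface` answers this with a
classifier-probing framework:

1. Train expression classifiers (a frozen convolutional backbone with a
   trainable fully connected head, seven softmax outputs) separately on
   each database, over many runs with identity-disjoint
   train/validation/test splits.
2. Measure generalization with 7 × 7 confusion matrices in the
   *database-matched* condition (test images from the training
   database) and the *database-swapped* condition (test images from the
   other database). The accuracy gap measures non-transferability of
   the learned features; Welch *t* tests and a two-way ANOVA
   (condition × expression) quantify it.
3. Probe what each output unit learned: present 20 single-AU image
   series (11 intensities from 0.0 to 1.0, all other AUs off, shared
   "null image" at intensity 0), record pre-softmax responses, subtract
   the null baseline, and average across runs. Each unit's 20 × 11
   **tuning profile** states which facial movements promote (positive)
   or oppose (negative) classification as that expression.
4. Summarize cross-database similarity: Spearman rank correlations
   between same-expression profiles (null responses excluded, n = 200;
   Bonferroni at 0.05/7), the full 7 × 7 cross-group correlation
   matrix, its Spearman relation to the swapped confusion matrix over
   the 49 aligned pairs, and PCA of the 20 × 14 matrix of per-AU signed
   extrema (a compact map in which shared expressions sit close
   together across databases and divergent ones far apart).

Real posed-face databases of this kind are distributed only on request,
so the package ships a parametric synthetic face generator: twin
"culture" databases whose expression-to-AU mappings are partly shared
and partly divergent (planted ground truth), plus the AU probe stimuli.
External grayscale images with a manifest (path, label, identity,
database + a face bounding box) are accepted through the same pipeline.

## Worked example

```r
library(auface)

cfg <- fixture_suite("default-twin", preset = "desk", master_seed = 1)
rep <- run_full_experiment(cfg)   # ~2 min on one CPU
print(rep)
```

```
<au_experiment> desk preset, master seed 1 
  mean correct rates: matched 0.764 / 0.771, swapped 0.550 / 0.614
  per-expression profile correlations (A vs B):
    neutral   rs = +0.88 *
    happy     rs = +0.91 *
    fearful   rs = +0.75 *
    sad       rs = -0.04
    angry     rs = -0.07
    surprised rs = +0.88 *
    disgusted rs = +0.95 *
  correlation vs swapped confusion: rs = 0.53 (A->B), 0.54 (B->A)
```

Reading this: both groups of classifiers perform well above chance
(1/7 ≈ 0.14) on their own database and drop when databases are swapped
— the generalization gap. The planted structure is recovered in the AU
tuning: the two cultures pose *happy* and *surprised* identically and
those units' profiles correlate near +1 across the trained groups,
while *angry* and *sad* — posed with different AUs (lip funneler AU#22
vs. lip tightener AU#23) — decorrelate. The positive
correlation-vs-confusion relation shows that profile similarity
predicts which expressions get confused in the swapped condition.
`summary(rep)` adds the t/ANOVA tables and PCA variance; `plot(rep)`
draws the four confusion matrices.

Lower-level entry points mirror the pipeline: `generate_database()`,
`preprocess_image()`, `make_variants()`, `build_network()`,
`train_run()` (returns an `expr_fit` with `predict`/`plot`/`coef`
methods), `confusion_matrix()`, `swap_test_database()`,
`probe_responses()`, `per_expression_correlations()`, `run_pca()`.
See the vignette in `vignettes/au-tuning-framework.Rmd` for the model,
its assumptions, and all numerical choices.

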