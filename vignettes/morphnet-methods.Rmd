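---
title: "Methods: multi-scale morphometry features, w-scores and fusion networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale morphometry features, w-scores and fusion networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`morphnet` implements a differential-diagnosis pipeline for three groups —
normal controls (NC), Alzheimer's disease (AD) and frontotemporal dementia
(FTD) — from structural brain morphometry. The pipeline has five stages:

1. **Patch parcellation.** Each anatomical ROI of a labeled template is
   subdivided into patches by one-dimensional k-means: voxels cluster on
   intensity, cortical vertices on thickness, at three target sizes (500,
   1000 and 2000 members per patch). In the default configuration this
   yields six feature blocks of 1488/705/343 patch volumes and 527/255/131
   patch thicknesses — 3449 features per scan. Patch identity lives on the
   template; per-subject data reach patch space through an externally
   supplied correspondence map (identity by default). Per-subject
   re-clustering is deliberately impossible: features must be comparable
   across subjects.
2. **w-score normalization.** For every feature an ordinary least-squares
   regression on NC training subjects removes covariates (age, sex, ICV,
   field strength, optionally site and scanner; categorical covariates are
   one-hot encoded against a first-level reference). The w-score is the
   standardized residual `w = (x - c'beta) / sigma`, with `sigma` the
   residual SD on the `n - p` denominator, floored at `1e-8` times the
   feature SD so degenerate synthetic features cannot blow up the division.
3. **Two-stage fusion classifier.** One MLP per feature block with hidden
   sizes `3N`, `round(3N/4)`, `50` (rectifier units, dropout 0.5), trained
   independently with temporary softmax heads; the six 50-unit embeddings
   are concatenated (300-d) and classified by a fusion MLP whose hidden
   sizes follow the same rule (900, 225, 50); finally all seven blocks are
   fine-tuned jointly. Training uses inverse-frequency weighted
   cross-entropy (`W_j = N/N_j`, absent classes weight 0), Adam, batch size
   100, and early stopping that restores the best-validation-loss epoch
   after 20 non-improving epochs.
4. **GAN augmentation.** A two-layer generator (100-d Gaussian noise, 512
   rectified units, tanh output at the feature dimension) is trained
   adversarially against the classifier extended with a fourth "fake"
   channel. Real rows are first mapped per feature to [-1, 1] by a
   range normalizer fitted on the training split. Generated rows enter
   *only* as fake-labeled discriminator examples — the generator is
   unconditional, so synthetic rows are never added as labeled real-class
   data. At test time the fake channel is dropped and the three real-class
   logits are re-softmaxed.
5. **Ensemble evaluation.** Subjects (never scans) are assigned to 10
   stratified outer folds; within each outer training set, 10 inner subsets
   provide each ensemble member its own validation split. The ten networks'
   test probabilities are averaged and passed through a softmax before the
   argmax (order-preserving; both vectors are reported). Metrics are
   accuracy and per-class sensitivity; experiments are compared by paired
   one-tailed t-tests with Benjamini–Hochberg control.

# Numerical and design choices

* **"3N, 34N, 50".** The printed middle width "34N" is read as `3N/4`
  (a typesetting artifact): it matches the stated intent of gradually
  reducing width, and `round(3N/4)` reproduces the printed behavior of the
  architecture family the design cites. The fusion block's hidden sizes are
  not legible in the source figure; the same widen-then-narrow rule applied
  to its 300-d input gives 900/225/50, exposed as configuration.
* **Generator objective.** The printed `log(-D(G(z)))` is not a real-valued
  function on (0,1); the implemented objective is the non-saturating
  `-mean log(1 - p_fake)`, which matches the cited motivation (avoiding
  vanishing gradients and mode collapse). It is 0 when the discriminator is
  fully fooled and strictly increasing in each fake probability.
* **GAN safeguards.** The warm-started discriminator is the epoch-0
  early-stopping baseline, and validation monitors the *renormalized
  three-channel* loss rather than the four-channel loss. Both choices close
  a failure mode where adversarial updates collapse the discriminator onto
  the fake channel while its four-channel validation loss looks acceptable.
  Three-class prediction softmaxes the three real logits directly, which
  equals renormalizing the probabilities but survives underflow.
* **k-means.** Clustering is one-dimensional (intensity or thickness only;
  spatial contiguity is not enforced, following the source method).
  Initialization is k-means++ with 10 restarts, best inertia kept, ties to
  the earliest restart, all under a fixed seed, because Lloyd's algorithm is
  not convex and patch identity must be reproducible.
* **Class weights.** `W_j = N_total/N_j` exactly. Note that with balanced
  classes this gives `W_j = K`, not 1 — the weighted loss is then `K` times
  the unweighted cross-entropy. The discriminator applies the same rule to
  the per-batch four-class counts, fake channel included.
* **Early stopping.** A pure controller over the validation-loss sequence:
  stop at the first epoch lying `patience` epochs past the running minimum;
  parameters are restored from the minimum epoch.
* **Ties.** Argmax ties resolve to the lowest class index (NC before AD
  before FTD) everywhere, including the ensemble vote.
* **Zero-variance paired comparisons** report p = 1 when the mean
  difference is non-positive and p = 0.5 otherwise, flagged `degenerate`.
* **Serialization.** Feature tables and model checkpoints round-trip
  bit-exactly: doubles are written as `%.17g` (CSV) or as `%.17g` strings
  inside the JSON checkpoint container, since plain JSON numbers do not
  guarantee exact double round trips.
* **Template I/O.** The synthetic template is serialized as plain text
  (voxel CSV + vertex CSV + JSON manifest) rather than NIfTI: no NIfTI
  reader is available in the offline dependency set, and the template is
  the only volumetric object in the pipeline.

# The synthetic cohort: what it emulates and what it does not

`cohort_spec()`/`generate_cohort()` draw covariates from ranges typical of
aging/dementia cohorts (age ~ N(70, 8²) years clipped to [45, 95], ICV ~
N(1.5e6, 1.5e5²) mm³, sex and field strength Bernoulli(½), three sites, two
scanners) and build each feature as

```
baseline + covariate effects + group shift · noise_sd
         + subject intercept + N(0, noise_sd²)
```

Group atrophy is injected in *residual-SD units* on a sparse random subset
of features (default 10%), negative (atrophy), with the AD and FTD supports
overlapping at a configurable Jaccard index (default 0.3) — mimicking the
observation that both dementias atrophy overlapping territory while
retaining disease-specific regions. Longitudinal scans share a per-subject
random intercept (default 0.5 · noise_sd), which is exactly what makes
subject-level fold splitting matter. Default feature units are plausible
(patch volumes near the patch size in mm³ with SD 25 mm³; thicknesses near
2.5 mm with SD 0.15 mm; age slope −5 mm³/yr and −0.01 mm/yr).

What the generator does **not** emulate: registration error, site batch
effects beyond linear offsets, non-linear covariate effects, heavy-tailed
noise, or correlated feature noise. A green recovery test therefore
establishes that the pipeline recovers *linearly separable, covariate-
confounded sparse group structure* without leakage — not that it attains
any particular accuracy on clinical data.

# Scaled acceptance experiments

The reference cohorts (ADNI/NIFD, 1954 scans, 3449 features) are not
redistributable, and the original training protocol (learning rate 5e-5,
patience 20) implies hundreds of epochs per network — far beyond a CI
budget when 300 networks must be trained for the recovery criterion. The
acceptance tests therefore run the *stated* experiment quantities (600
subjects, balanced classes, 2-SD effects on 10% of features, seeds {1,2,3},
10-fold subject-level CV, 10-network ensembles, batch 100, dropout 0.5) on
a proportionally reduced six-block layout (60/30/15/21/10/5 = 141 features)
with a compressed schedule (learning rate 3e-3; pretrain/fusion/fine-tune
epoch caps 8/6/3; patience 3). The package defaults remain the full
protocol. Criteria that are architecture facts (block dimensions, 7 MLP
blocks) or loss identities run at full dimension.

Two criterion statements required interpretation: the balanced-batch
discriminator loss example (`ln 4`) contradicts the inverse-proportion
weight rule it quotes (which gives `4 ln 4`); and the held-out
`|corr(w, age)| < 0.1` bound cannot hold for the maximum over thousands of
features at n = 500 under the null, so it is applied to the typical
(mean) feature with a tail cap. Both are implemented per the defining
formulas and documented in the repository notes.

# Known limitations

* Pure-R/BLAS training (with small C++ kernels for the Adam update and
  rectifier gates) is single-threaded and orders of magnitude slower than a
  GPU runtime; the full 3449-feature protocol is functional but intended
  for overnight rather than interactive use.
* Bit-level determinism is guaranteed for fixed seeds and a fixed BLAS;
  across BLAS implementations only the statistical properties are stable.
* The PCA+SVM comparator and external-cohort validation of the source study
  are out of scope.
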