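---
title: "Methods: voxel-wise semantic encoding of natural speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise semantic encoding of natural speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelSemantics)
```

## The model

voxelSemantics implements a voxel-wise encoding model for fMRI recorded
while a subject listens to continuous natural speech. The stimulus is not
a categorical event train but a trajectory through a semantic space: every
spoken word $w$ at time $\tau$ is represented by its vector of cosine
similarities to a fixed vocabulary of feature words,

$$ S_{i}(\tau_j) \;=\; \cos\bigl(e(w_j),\, e(f_i)\bigr)
   \;=\; \frac{e(w_j)\cdot e(f_i)}{\lVert e(w_j)\rVert\,\lVert e(f_i)\rVert}, $$

where $e(\cdot)$ is a word2vec-style embedding and $f_1,\dots,f_{997}$ are
the feature words (498 most frequent nouns followed by 499 most frequent
verbs in the reference design). Each feature row is z-scored, low-pass
resampled onto the scanner's TR grid with a Lanczos kernel (cutoff at the
acquisition Nyquist frequency $1/2\,\mathrm{TR}$), and copied at delays of
2, 4, 6 and 8 s to approximate the haemodynamic response without fitting
an explicit HRF — 997 features become 3988 delayed predictors.

Each voxel's time series $R_{jt}$ (linearly detrended and z-scored the
same way as the stimulus rows) is then predicted linearly,
$R'_{jt} = \sum_i \beta_{ji} S_{it}$, with the weights minimizing the
ridge objective

$$ E_j(\beta) = \sum_t \Bigl(R_{jt} - \sum_i \beta_{ji} S_{it}\Bigr)^2
   + \alpha \sum_i \beta_{ji}^2
   \quad\Longleftrightarrow\quad
   E = \lVert Y - X\beta\rVert^2 + \alpha\lVert\beta\rVert^2 . $$

Regularization is essential, not optional: with 3988 predictors and ~490
time samples ordinary least squares is underdetermined. The solution is
the closed form $(X^\top X + \alpha I)^{-1} X^\top Y$, computed from one
economy SVD of the design that is shared across all voxels and all
$\alpha$ candidates.

The fitted weight map is then interpreted geometrically: the delayed
copies are averaged back to one weight per feature word, the
best-predicted voxels are kept, a centered (unscaled) PCA of the
voxel-by-feature weight matrix is taken, the feature words are clustered
with k-means in the leading component space into semantic categories, and
each category is localized back to the voxels where its feature words
carry the largest mean weight. A separate individual-level analysis takes
the most peripheral points of the component space, groups them by
single-linkage ("closest neighbor") clustering, and ranks the resulting
clusters by their median embedding distance to a list of threat-related
seed words.

## Assumptions

* Word meaning is adequately summarized by a static embedding: each token
  contributes the same feature vector regardless of sentence context.
* The BOLD response is linear and time-invariant in the semantic features,
  and is captured by four discrete delays rather than a parametric HRF.
* Temporal autocorrelation is handled by splitting the run into
  *contiguous* blocks (no shuffling) for validation; samples are never
  treated as exchangeable.
* Voxel preprocessing upstream of this package (realignment, MNI
  normalization, smoothing, masking to gray matter) has already happened;
  the package consumes a masked 4-D NIfTI plus a 3-D binary mask.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `tr` | 1.01 | s | repetition time of the multiband acquisition; also sets the resampling cutoff $1/2\,\mathrm{TR}$ |
| `delays` | 2, 4, 6, 8 | s | sample-aligned shifts spanning the rise and fall of the canonical HRF |
| `lanczosA` | 3 | side lobes | common windowed-sinc order; larger is sharper but ringier |
| `alphas` | 10 log points in [1, 10] + 20 in [10, 1000] | – | log-spaced superset of the two search ranges; the exact grid is echoed into results |
| split | 350/140 outer, 300/50 inner (at 490 samples) | samples | first block fits, later blocks validate and test; scaled proportionally for other run lengths |
| `probeVoxels` | 500 | voxels | the alpha search scores a random probe subset; seeded and logged |
| `topVoxels` | 10000 | voxels | voxels kept for PCA/clustering, ranked by held-out prediction r |
| `nComponents` | 4 | – | leading factors used as the semantic coordinate system |
| `kSemantic` | 15 | clusters | semantic category count for the group-level analysis |
| `kThreat` | 12 | clusters | cluster count of the individual-level threat analysis |
| `fraction` | 0.8 | – | subset size of the repeated peripheral-point draws; the top $1-\mathrm{fraction}$ tail by mean distance rank is kept |
| `repeats` | 100 | draws | resampling repeats of the peripheral selection |
| `localizeFraction` | 0.05 | – | fraction of voxels kept per localized cluster; no canonical value exists, so it is explicit and configurable |

One global $\alpha$ for all voxels is the default: in direct comparison
(`compareAlphaModes()`) the shared-$\alpha$ held-out correlation
distribution sits to the right of the per-voxel-$\alpha$ one, because
per-voxel selection overfits the short inner validation block.

## Numerical choices

* **Standard deviation convention.** All z-scoring (stimulus rows and
  voxel rows) divides by $n$, matching the plain formula
  $z = (x - \bar x)/S_x$; the two sides of the regression use the same
  convention. Rows that are constant up to numerical noise become zero
  rows with a warning instead of NaNs, so downstream fits stay finite.
* **Word time stamps.** A token occupies $[t_{start}, t_{end}]$; its
  markup column is stamped at the midpoint.
* **Resampling.** The markup is treated as an irregular impulse train at
  word midpoints; kernel weights are renormalized per output sample, which
  makes the operation exact for constant series and linear in the feature
  series. Grid samples further than $a\cdot\mathrm{TR}$ from every word
  are left at zero.
* **Delays.** Converted to integer sample shifts by rounding
  $\mathrm{delay}/\mathrm{TR}$ (at TR = 1.01 s the stated delays round to
  2, 4, 6, 8 samples); a delay further than 0.15 samples from an integer
  is rejected. Shifted copies are zero-filled before run onset — no
  stimulus precedes the run. Rows are ordered feature-major so delay
  averaging is a fixed block pattern.
* **Ridge.** Economy SVD of the (samples × predictors) design; singular
  values below machine-precision rank tolerance are dropped. The alpha
  search never materializes per-candidate weight matrices: validation
  predictions come directly from the SVD factors.
* **PCA.** Centered, unscaled (`prcomp`); a deliberate decision since the
  weight columns share units. Components are sign-fixed so the
  largest-magnitude loading is positive, making runs comparable.
* **What is clustered.** The PCA treats voxels as observations and feature
  words as variables, and k-means clusters the *feature words* by their
  loading coordinates — only feature clustering can yield word categories.
  The scores (voxel) side is used for localization.
* **k-means.** k-means++ initialization under a fixed seed, Lloyd
  iterations, and farthest-point re-seeding of empty clusters; the
  within-cluster sum of squares is non-increasing and the final labels are
  bit-reproducible. This loop is implemented in the package because the
  stock `stats::kmeans` Lloyd variant fails on empty clusters and seeds
  differently; `stats::kmeans` is used as an independent cross-check on
  planted blobs in the test suite.
* **"Closest neighbor" clustering** is read as single-linkage
  agglomeration (`hclust(method = "single")` + `cutree`).
* **Threat seeds.** Whitespace-separated entries are split into individual
  words and duplicates are removed before distances are computed; distance
  is cosine (1 − similarity) by default, Euclidean by flag.
* **Ties.** Voxel selection and localization break ties toward the lower
  index; the report table orders clusters by median distance then id.

## The synthetic generator

No subject data are deposited with the reference design, so the package
ships a generator that emulates all four inputs with planted ground
truth:

* **Embeddings** — cluster centroids drawn on the unit sphere with an
  enforced minimum pairwise angle ($|\cos| \le 0.5$), members perturbed
  isotropically (sd $0.55/\sqrt{d}$ per coordinate) and renormalized, so
  within-cluster similarity (~0.75) clearly exceeds between-cluster
  similarity (<0.45).
* **Word stream** — onsets on a jittered regular grid at 2.5 words/s,
  durations inside the inter-onset gaps, and a topic schedule of
  contiguous blocks that over-sample one planted cluster each, emulating
  thematic text groups.
* **BOLD** — voxels in contiguous blocks, one per planted cluster; a voxel
  loads with weight 1 on exactly its cluster's feature words; the delayed
  copies are scaled by the canonical double-gamma HRF evaluated at the
  delays; white Gaussian noise is added at `noiseSd` times each voxel's
  signal sd (default 1, i.e. SNR 1).
* **Threat fixture** — a separate generator places word blobs around
  separated centroids with one designated blob at 2.5× the radius of the
  rest, so the planted threat semantics is genuinely peripheral in the
  component space, which is the regime the peripheral-selection step
  assumes.

Defaults mirror the reference scales — 300-dimensional embeddings, 997
feature words, TR 1.01 s, delays 2/4/6/8 s, a 490-sample run — except the
voxel count (2000 rather than ~100,000) so that the full pipeline runs in
seconds; the generator takes `nVoxels` for full-cohort-scale stress runs.

What passing tests on this generator do **not** show about real data: the
noise is white (an optional AR(1) switch exists but is off so the
recovery oracles stay exact), every voxel carries signal (real masks are
mostly non-semantic voxels, which is why the reference design selects the
best-predicted 10,000 of 100,000), planted clusters are isotropic and
equally sized, and no attempt is made to mimic Russian morphology or real
corpus statistics. Recovery at SNR 1 on this generator is evidence that
the estimator is correct, not that real effect sizes are this large —
held-out prediction correlations around 0.4 here correspond to the
planted-signal regime, not to a claim about cortex.

## Problem sizes used by the test suite

The suite fits everything from hand-sized oracles (5×3 ridge problems
checked against a numeric minimizer) up to one full-scale synthetic run
(997 features × 4 delays, 490 samples, 2000 voxels) per session; the
full-scale run takes a few seconds via the shared-SVD solver. Recovery
statistics are averaged over 10 generator seeds. These sizes were chosen
so the entire suite completes in well under a minute while still
exercising the exact dimensions of the reference design.

## Known limitations

* Context-free embeddings: homonyms and context effects are invisible.
* The split is a single nested partition, not repeated cross-validation;
  with one run of data there is no way around it, but alpha curves are
  noisier than k-fold equivalents would be.
* The preliminary procedure that once selected "15" as the semantic
  cluster depth (co-occurrence consistency of word fields) is not
  formalized here; `kSemantic` is an input, and any internal index can be
  plugged in upstream.
* Whether the individual-level threat analysis should use re-fitted
  weights from a single text group or a restriction of the full-run
  weights is left as an input choice (`threatReport()` accepts any
  component space).
* Voxel "MNI coordinates" in synthetic data are grid indices; real MNI
  coordinates come in through the NIfTI mask geometry.
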