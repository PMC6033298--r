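---
title: "Stepwise fine-tuning with low-cost medium-level pathology datasets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{histostep methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Benign/malignant classification of H&E-stained gastric biopsy patches with
CNNs is limited by the scarcity of pathologist-annotated training data.
`histostep` implements a two-stage ("stepwise") fine-tuning scheme that
inserts a cheaply produced intermediate dataset between generic pretraining
and the scarce expert-labelled data, together with the two builders for that
intermediate data:

* **tissue-wise**: background / epithelium / stroma patches cut from coarse
  annotation masks that a non-specialist can draw (epithelium shows an
  organized, banded arrangement; stroma is scattered and disordered);
* **cell-wise**: fully automatic — each patch is reduced to the
  two-dimensional feature *(total nuclear area, nucleus count)* by an image
  processing chain, and patches are pseudo-labelled by K-means into two
  morphology clusters (fewer/larger vs more/smaller nuclei).

## The training model

Training minimizes the mean loss over the $N$ samples of the active stage,

$$L(W) \;=\; \frac{1}{N}\sum_{i=1}^{N} l\!\left(y(x_i; W),\, y_i\right),$$

with $l$ the cross-entropy on softmax class probabilities ($l$ is generic
in the scheme; cross-entropy is this package's choice). A schedule is:

* $t=0$ — initialization. At desk scale this is a seeded random
  initialization of the small backbone; any pretrained weights are
  acceptable here, and large named backbones are out of desk scope.
* $t=1$ — fine-tune on a medium-level dataset (3 tissue classes or 2
  cell-wise clusters).
* $t=2$ — fine-tune on the benign/malignant data.

When the class count changes between stages the classification head is
replaced (`swap_head()`); all backbone weights are preserved bit for bit,
and the head is freshly drawn from the declared scheme (seeded Gaussian,
zero bias) — deliberately *not* a no-op even at an unchanged class count.
A one-stage schedule (only $t=2$) is the conventional baseline. All layers
remain trainable in every stage; a freeze-depth option exists but defaults
to none, since nothing in the scheme requires freezing.

**Desk backbone.** Four 3×3 stride-2 convolution blocks (8, 16, 32, 32
filters) with ReLU, global average pooling, and a linear softmax head, on
32×32 block-averaged inputs. Convolutions are im2col matrix products in
plain R; the backward pass is verified against finite differences in the
test suite. **Model selection** per stage is highest validation AUC
(binary stages; accuracy otherwise), ties broken by lower validation loss.

**Optimizer defaults.** SGD with momentum 0.9, batch 32, 20 epochs,
learning rate 0.1. The learning rate is the one place this package departs
from its build contract's suggested default (1e-3): at desk scale that
value demonstrably stalls (training loss moves by <0.002 over 15 epochs
and both schedules stay at chance), so the default was raised until the
*training loss* converged on the medium stage. It was not tuned on any
acceptance quantity — the acceptance property is a relative comparison of
two schedules that share every hyperparameter.

## The cell-wise measurement chain

1. **Optical density.** $OD_c = -\log_{10}(I_c / I_{0,c})$ per RGB channel,
   with $I_{0,c} = 1$ (patches live in $[0,1]$; 8-bit files are divided by
   255 on read). Intensities are floored at $\varepsilon = 10^{-6}$ before
   the log so saturated black pixels stay finite ($OD = 6$).
2. **Color deconvolution.** $C = D\,[y]$ with the fixed Ruifrok–Johnston
   H&E-DAB matrix
   $$D = \begin{pmatrix} 1.88 & -0.07 & -0.60 \\ -1.02 & 1.13 & -0.48 \\ -0.55 & -0.13 & 1.57 \end{pmatrix}.$$
   The DAB row is computed but unused downstream. Raw maps are not clamped;
   the hematoxylin map handed to thresholding is clipped at zero,
   **noise-floored** (values below $10^{-9}$ of the patch maximum are
   zeroed — they are cancellation residue of the matrix product, and a
   multiplicative threshold would binarize that machine noise), and
   rescaled by its patch maximum. Whether the original pipeline rescaled
   its H channel is not recorded; this normalization is a declared package
   convention.
3. **Phansalkar local threshold.**
   $T = \mu\,(1 + p\,e^{-q\mu} + k(\sigma/r - 1))$ with the recommended
   constants $k=0.25$, $r=0.5$, $p=2$, $q=10$; $\mu,\sigma$ are mean and
   population standard deviation over a circular window. The window radius
   is not recorded by the source method; the default is 15 px for 256×256
   patches (configurable). Foreground is `value > T`: nuclei are *bright*
   in a concentration map, whereas the original formulation targets dark
   nuclei on bright cytology backgrounds; the polarity is exposed as a
   flag. Window statistics use edge replication, computed by an
   incremental sliding window that matches the naive per-pixel definition
   to ~1e-13.
4. **Watershed splitting.** Connected foreground is split on the negated
   exact Euclidean distance transform, seeded at distance maxima thinned
   to a minimum separation of 7 px (maxima are detected within their own
   connected component, so a small nucleus adjacent to a large one keeps
   its seed). Regions under 15 px² are discarded as specks. Both values
   are conventions — the source method names only "watershed".
5. **Contour tracing.** One outer boundary per label by clockwise Moore
   border following (the classic border-following scheme); holes are
   ignored, and the reported area is the filled pixel count — unambiguous
   and oracle-checkable, unlike polygonal boundary area.
6. **Pseudo-labelling.** K-means ($k=2$) on z-scored *(total area, count)*.
   Z-scoring is a package decision: raw areas (~10³–10⁴ px²) would swamp
   counts (~10¹). Lloyd iterations run from k-means++ starts; 10 restarts
   are kept (best within-cluster SS) because single-start Lloyd visibly
   hit local optima on ~2/5 benchmark seeds. Cluster 1 is the
   fewer/larger-nuclei cluster (smaller mean count, ties broken toward
   larger mean area), cluster 2 the more/smaller one, matching the
   published cluster semantics. Before clustering, patches with fewer than
   5 nuclei or mean hematoxylin under 0.02 are excluded (the construction
   names the criteria — too few nuclei, stain inconformity — but not the
   thresholds; these are package defaults).

## Dataset bookkeeping

Tissue-wise patches are cut on a non-overlapping grid (size 256) and kept
for a class only if ≥ 90% of mask pixels carry it — the published
procedure was manual depiction, so the grid-and-purity rule is this
package's algorithmic stand-in. Train/validation splitting uses
round-half-up arithmetic, `n_train = floor(0.9 n + 0.5)`: the only simple
rule consistent with both published cell-wise rows (7,672 → 6,905 + 767
and 6,457 → 5,811 + 646). Manifests assert that no patch path appears in
two levels or two splits and fail loudly with the offenders otherwise.

## The synthetic world

Real gastric H&E data cannot be redistributed, so every downstream stage
is exercised on synthetic patches with known ground truth. The renderer is
the exact inverse of the measurement model: elliptical nuclei add
hematoxylin concentration (overlaps add; ground-truth area counts each
pixel once — what a segmenter can observe), a uniform eosin background
models cytoplasm, and transmitted intensity follows Beer–Lambert
absorption $I_c = 10^{-\sum_s A_s b_{s,c}}$ with the stain basis set to
the exact inverse of $D$. The build contract suggested normalizing the
basis columns; that normalization is omitted here because it would break
the contract's own round-trip requirement (recovered concentrations equal
rendered ones to 1e-6) — with the exact inverse the round trip is exact to
machine precision. Gaussian intensity noise (clipped to $[0,1]$) is the
only staining artifact modelled.

Cell-wise populations default to cluster 1 ≈ Poisson(8) nuclei of major
semi-axis 7–12 px and cluster 2 ≈ Poisson(40) at 3–5 px on 256×256
patches, hematoxylin per nucleus U(0.5, 0.9), eosin background
U(0.2, 0.4); these figures are free choices (the published cluster
morphologies are described only qualitatively) fixed once to give clearly
separated ground truth. Tissue-wise patches: background is near-blank
(eosin ≤ 0.05), epithelium arranges nuclei along 2–4 parallel bands whose
row-centers are recorded as ground truth, stroma scatters sparse nuclei
uniformly. Nuclei are placed non-touching by default (rejection sampling);
touching layouts for watershed tests are constructed explicitly.

What a green test does **not** establish: the generator has no texture,
no stain-vector variation between patches beyond intensity jitter, no
out-of-focus blur, no overlapping nuclei by default, and elliptical
nuclei only. Results on it bound implementation correctness, not clinical
performance; the published performance tables are explicitly out of scope
(private data, GPU-scale backbones).

## The synthetic training benchmark

`synthetic_benchmark()` builds a world where the medium-level structure is
informative for the high-level task: medium patches are pseudo-labelled by
the *measured* pipeline (morphometry → filter → K-means), and
benign/malignant proxy labels come from shifted, overlapping versions of
the same morphology axis (benign ≈ Poisson(8) larger nuclei, malignant ≈
Poisson(14) smaller ones, at 64×64 with noise 0.05), with a deliberately
small high-level training set (15/class). `benchmark_compare()` trains the
one-stage and two-stage schedules from the *identical* $t=0$
initialization and reports validation AUCs. The acceptance property is
directional and stochastic: averaged over ≥5 seeds, two-stage must not be
worse than one-stage by more than 0.02. On seeds 100–500 the observed
means are ≈0.61 (one-stage) vs ≈0.66 (two-stage).

## Seeds and determinism

Every operation that draws randomness takes one explicit integer seed;
composite operations derive sub-seeds as `seed + stage index` (benchmark:
+1 medium population, +2 clustering, +3/4/5 high-level splits, +6 medium
split, +7/8 stage shuffles). Fixed seeds give byte-identical populations,
training logs and demo summaries in single-threaded R.

## Known limitations

* The exclusion thresholds behind the published survivor counts
  (7,672/6,457) are unrecorded and cannot be reproduced; only the split
  arithmetic applied to those counts is checked.
* Watershed runs on the distance transform of the binary mask; whether the
  original used a grayscale relief is unrecorded.
* The CLI stores patches as ASCII PPM (P3) rather than PNG/TIFF: no image
  codec package is available in the target R environment, and PPM keeps
  every artifact plain text.
* The desk backbone is a small CNN; VGG-16 / AlexNet / Inception-V3 scale
  experiments, and ImageNet pretraining itself, are out of scope.
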