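# histostep

Stepwise fine-tuning and low-cost "medium-level" datasets for
histopathology patch classification.

## The problem

CNN classification of H&E-stained gastric biopsy patches (benign vs
malignant) is bottlenecked by scarce pathologist-annotated training data.
`histostep` implements a two-stage fine-tuning scheme that inserts a cheap
intermediate dataset between generic pretraining and the scarce
well-annotated data, so the network acquires basic pathology structure
before attempting the hard task:

* **t = 0** — pretrained (or seeded random) initialization;
* **t = 1** — fine-tune on a *medium-level* dataset;
* **t = 2** — fine-tune on the benign/malignant data, swapping the
  classification head when the class count changes.

Training minimizes the mean loss `L(W) = (1/N) Σᵢ l(y(xᵢ; W), yᵢ)` with
cross-entropy `l`. Two medium-level builders are included:

* **tissue-wise** — background / epithelium / stroma patches cut from
  coarse annotation masks on a non-overlapping grid (purity ≥ 0.9);
* **cell-wise** — fully automatic: each patch is reduced to the feature
  *(total nuclear area, nucleus count)* via color deconvolution
  (`C = D·[y]` on optical densities `ODc = −log₁₀(Ic/I₀,c)` with the fixed
  Ruifrok–Johnston matrix), Phansalkar local thresholding
  `T = μ(1 + p·e^(−qμ) + k(σ/r − 1))` (k = 0.25, r = 0.5, p = 2, q = 10),
  watershed splitting of touching nuclei, and border-following contour
  tracing; patches are then pseudo-labelled by K-means into two clusters
  (1 = fewer/larger nuclei, 2 = more/smaller).

Clinical H&E data cannot be redistributed, so the package ships a
Beer–Lambert synthetic patch generator (`I_c = 10^(−Σ A_s b_{s,c})`,
elliptical hematoxylin-rich nuclei over an eosin background) whose stain
basis is the exact inverse of the deconvolution matrix — rendering and
unmixing are exactly adjoint, and every stage is testable with ground
truth.

## Worked example

```r
library(histostep)

# synthetic cell-wise patches with ground truth
pop <- generate_cellwise_population(2, noise_sd = 0, seed = 7)
pop[[1]]
#> <synthetic_patch 256x256: 15 nuclei, area 3497 px^2, class=none cluster=1>

# the full measurement chain recovers the morphology exactly on
# noiseless patches
measure_nuclei(pop[[1]]$patch)
#> <nuclei_morphometry: 15 nuclei, total area 3497 px^2, mean H 0.0370>

# the published 90/10 split arithmetic (round half up)
split_train_val(7672)
#>      train validation
#>       6905        767
```

`measure_nuclei()` reports exactly the rendered 15 nuclei and 3,497 px² —
on noiseless fixtures the pipeline's count recovery is exact on 100/100
patches (the acceptance bar is ≥ 95%). `split_train_val(7672)` reproduces
the published cell-wise cluster-1 row (6,905 train / 767 validation).

End-to-end demonstration (generates data, builds both medium-level
datasets with manifests, trains both schedules, evaluates on a held-out
test set; ~20 s):

```r
res <- run_demo(list(seed = 1), "demo_out")
res$summary
#>      scheme val_auc test_auc test_acc test_precision test_recall
#> 1 one_stage  0.6112   0.5216      0.5      0.5000000        1.00
#> 2 two_stage  0.6544   0.6048      0.6      0.6190476        0.52
```

On this seed the two-stage schedule lifts held-out AUC from 0.52 to 0.60
— the medium-level morphology stage transfers to the benign/malignant
proxy task. Averaged over 5 seeds (the acceptance property), two-stage
≈ 0.66 vs one-stage ≈ 0.61 validation AUC. These are desk-scale synthetic
numbers; the source study's clinical tables are out of scope (private
data, GPU-scale backbones).

## Command line

```sh
Rscript inst/cli/histostep.R synth --mode cellwise --n 50 --seed 1 --out pop/
Rscript inst/cli/histostep.R segment-nuclei --in pop/ --out features.tsv
Rscript inst/cli/histostep.R build-medium --mode cell --in pop/ --out manifest.tsv
Rscript inst/cli/histostep.R demo --out demo_out --seed 1
```

Patches are stored as plain-text PPM (P3) with TSV manifests; configs are
JSON validated against `default_config()` (unknown keys rejected).

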