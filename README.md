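# recaplab

Functional homologous-recombination (HR) scoring for patient-derived
tumor organoids (PDTO), built as a tested, reusable pipeline.

Ovarian-cancer organoids can predict a patient's response to platinum and
PARP-inhibitor therapy, but the genomic HR tests used for PARPi
prescription (mutation panels, genomic instability scores) frequently
disagree with tumor behavior. A functional alternative scores the actual
HR machinery: organoid sections are irradiated (5 Gy), stained, and the
radiation-induced RAD51 foci in proliferating (Cyclin A2-positive) nuclei
are counted at 0 h / 2 h / 24 h — HR-proficient (HRP) tumors form foci at
2 h and resolve them by 24 h, HR-deficient (HRD) tumors never induce
them. `recaplab` implements the full computational chain of such a study:

* **Imaging** — organoid and nucleus segmentation (Otsu + watershed),
  Cyclin A2-positive calling (difference-of-Gaussians + geodesic
  reconstruction), RAD51 focus detection (Laplacian-of-Gaussian) and
  per-nucleus counting restricted to proliferating nuclei.
* **Scoring** — per-condition Gaussian smoothing of count histograms and
  the index triplet **DI** = mean(control), **RDI** = mean(2 h) −
  mean(control), **RI** = mean(24 h) − mean(2 h); PCA across models with
  an HRD call at PC1 < −0.5.
* **Drug screening** — plate QC
  (z = 1 − (3·SD(neg) + 3·SD(pos)) / (mean(neg) − mean(pos)),
  exploitable at z ≥ 0.4), 4PL dose-response fits, AUC over log10 dose,
  panel-normalized AUC z-scores and sensitivity calls.
* **HR integration** — genomic instability score banding
  (HRP < 0.23 ≤ HRDmid ≤ 0.73 < HRD), variant filtering (VAF ≥ 5% and
  oncogenic/inactivating), functional-vs-genomic concordance tables, and
  platinum-free-interval comparisons (Kaplan-Meier, log-rank,
  Gehan-Breslow-Wilcoxon, Mann-Whitney).
* **Expression concordance** — NMF of organoid transcriptomes,
  non-negative projection onto paired tumors, paired-sample rank
  selection and top-5% signature genes.
* **Synthetic generators** for every input (multichannel IF images,
  viability plates, paired count matrices, survival cohorts, variant
  tables) with complete recorded ground truth, so the whole chain is
  testable offline.

## Worked example

Simulate a four-model cohort (2 HRD, 2 HRP), quantify every slide and
classify:

```r
library(recaplab)
cfg    <- recap_config()
cohort <- gen_recap_cohort(2, 2, seed = 42, nucleus_count = 60)
foci   <- quantify_cohort(cohort, cfg)
idx    <- recap_indices(foci, cfg)
print(idx, digits = 3)
#>   model    DI    RDI      RI
#> 1   M01 1.083  0.194  0.0278
#> 2   M02 1.000 -0.194  0.1667
#> 3   M03 0.972  3.806 -2.0000
#> 4   M04 0.972  3.278 -1.9444
```

M01/M02 show no radio-induced foci (RDI ≈ 0): functionally deficient.
M03/M04 induce ~3.5 foci per proliferating nucleus at 2 h and resolve
about half by 24 h (negative RI): proficient. PCA classification puts
deficient models on the negative PC1 side:

```r
classify_recap(idx, cutoff = cfg$recap_cutoff)
#>   model    pc1     pc2 status
#> 1   M01 -1.366  0.4992    HRD
#> 2   M02 -1.195 -0.9131    HRD
#> 3   M03  1.603 -0.5915    HRP
#> 4   M04  1.390 -0.6615    HRP
```

All four match the generator's ground-truth labels. The numbered scripts
under `analysis/` run the same flow at study scale — simulation,
quantification, classification, drug screen, genomic/survival
integration, and NMF concordance — writing tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

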