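# motifdecon

Supervised motif deconvolution of multi-allelic MHC immunopeptidomes in R.

Mass-spectrometry immunopeptidome samples mix ligands presented by every
HLA molecule a cell expresses (several class I molecules, or a dozen class
II specificities such as the DRB1 plus DRB3/4/5 molecules of an HLA-DR
haplotype) with peptides that co-immunoprecipitate without being MHC
ligands. motifdecon is for immunopeptidomics analysts who have such a
peptide list plus the sample's HLA typing and want each peptide assigned
to its most likely restricting allele, contaminants set aside, and the
per-allele binding motifs, length distributions and contributions
reported.

## Method

Every peptide *p* and declared allele *a* carries a **percentile rank**

&nbsp;&nbsp;&nbsp;&nbsp;rank(p, a) = 100 · #{random natural peptides scoring ≥ score(p, a)} / n_bg

so 0 is the strongest possible score and 100 the weakest. After length
filtering and deduplication, each peptide is assigned

&nbsp;&nbsp;&nbsp;&nbsp;assign(p) = argmin_a rank(p, a)&nbsp;&nbsp;if min_a rank(p, a) ≤ t,&nbsp;&nbsp;else TRASH

with trash threshold t = 20% by default (t = 101 disables the trash
cluster). Ranks can come from any external predictor via a long-format
TSV, or from the built-in PSSM backend: raw score = max over 9-mer windows
of the summed position log-odds, with empirical rank calibration against
100,000 random natural peptides per allele.

Reporting includes 9×20 binding-core frequency matrices, Kullback–Leibler
logo data (info_i = Σ_a p_ia log2(p_ia/q_a)), per-cluster length
histograms, cluster contributions under both the total and the
allele-assigned denominator, and cross-sample motif consistency as the
Pearson correlation of flattened 180-element frequency vectors.
Benchmarking against known restrictions uses confusion matrices, the
Matthews correlation coefficient MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))
per allele with the median across alleles as the headline statistic, and a
peptide-resampling bootstrap for confidence intervals. A seeded synthetic
generator produces ground-truth labeled benchmarks (mock allele motifs,
class-specific length handling, contaminant injection, scrambled-peptide
nulls, k-mer overlap filtering) so the whole pipeline is testable without
trained predictors or downloads.

## Worked example

Deconvolute a synthetic four-allele class II benchmark (800 peptides per
allele, 320 short contaminants) with the true models:

```r
library(motifdecon)

bench <- build_artificial_benchmark(preset = "classII_benchmark",
                                    contaminant_n = 320, seed = 1)
samp <- peptidome_sample("demo", bench$peptides, bench$alleles, "II")
res <- deconvolute(samp, models = bench$models,
                   config = deconv_config("II", length_min = 9,
                                          length_max = 25),
                   calibration_seed = 101, n_bg = 100000)
res$cluster_counts
#> MOCKDR*01:01 MOCKDR*02:01 MOCKDR*03:01 MOCKDR*04:01        TRASH
#>          783          795          832          802          274

contribution_summary(res)[, c("cluster", "count", "percent_total_display")]
#>        cluster count percent_total_display
#> 1 MOCKDR*01:01   783                    22
#> 2 MOCKDR*02:01   795                    23
#> 3 MOCKDR*03:01   832                    24
#> 4 MOCKDR*04:01   802                    23
#> 5        TRASH   274                     8

truth <- setNames(bench$true_label, bench$peptides)
mcc_scores(confusion_matrix(truth[res$assignments$peptide],
                            res$assignments$assigned))
#> mcc_report: median MCC = 0.9419
#> MOCKDR*01:01 MOCKDR*02:01 MOCKDR*03:01 MOCKDR*04:01
#>       0.9437       0.9504       0.9379       0.9400

round(motif_summary(res, "MOCKDR*01:01")$info, 2)
#> [1] 2.27 0.16 0.15 2.65 0.19 2.73 0.17 0.17 2.21
```

Each cluster holds roughly its 800 generating peptides; the trash cluster
absorbs most of the injected contaminants; per-allele MCC against the
ground truth is about 0.94; and the recovered motif carries its
information at the anchor positions P1/P4/P6/P9, as specified for that
mock allele. `write_assignment_table()` exports the per-peptide
assignments and the full peptide×allele score table as TSVs, and
`inst/scripts/motifdecon` wraps the same pipeline for shell use
(`motifdecon simulate ...` / `motifdecon run ...`).

## The methods vignette

`vignettes/motif-deconvolution.Rmd` documents the assignment rule and its
boundary conventions, the PSSM backend and rank calibration, the
evaluation protocol, what the synthetic generator emulates and what it
deliberately does not, and the package's numerical choices and known
limitations.
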