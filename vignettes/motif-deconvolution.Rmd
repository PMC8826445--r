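---
title: "Supervised motif deconvolution of multi-allelic immunopeptidomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised motif deconvolution of multi-allelic immunopeptidomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A mass-spectrometry immunopeptidome sample mixes ligands eluted from every
MHC molecule a cell expresses — up to six class I and a dozen class II
specificities — together with peptides that co-immunoprecipitate without
being MHC ligands at all. Interpreting such a dataset requires *motif
deconvolution*: assigning each peptide to the HLA molecule that most likely
presented it, and separating out the contaminants.

motifdecon implements the supervised approach: when per-allele binding
predictions are available, each peptide is simply assigned to the declared
allele that scores it best, provided that score clears a contaminant
threshold. Unlike unsupervised mixture-model clustering, this needs no
manual motif-to-allele matching, works for any number of declared alleles,
and resolves low-abundance specificities (the HLA-C problem) as long as the
predictor itself is informative for them.

## Scores, ranks, and the trash cluster

Every peptide–allele pair carries a **percentile rank**: the percentage of
random natural peptides whose prediction score for that allele is at least
as good. Rank 0 is the best possible score; rank 100 the worst. Working on
the rank scale makes scores comparable across alleles with very different
raw-score distributions — the property the best-rank assignment rule relies
on.

The pipeline for one sample is:

1. **Length filter** — keep peptides within the configured length window
   (defaults: 8–14 for class I, 13–21 for class II).
2. **Deduplicate** — unique peptides only; multiplicities are logged.
3. **Predict** — every unique peptide against every declared allele.
4. **Assign** — each peptide goes to the allele with the minimum rank *if*
   that rank is at or below the trash threshold (default 20); otherwise it
   is a presumed co-purified contaminant and goes to the **trash cluster**.

Two boundary conventions are fixed deliberately. A rank exactly equal to
the threshold stays assignable — only strictly worse ranks are trash.
Equal best ranks across alleles are broken by C-locale lexicographic allele
order: ties are measure-zero for any real predictor, but assignment must be
deterministic and independent of input order. Setting the threshold to 101
disables the trash cluster entirely, which is occasionally useful for
diagnosing contamination (an implausible motif and a spike of short
peptides in one cluster are the classic symptom).

For class II samples, an optional **class I prefilter**
(`exclude_class_i_binders()`) removes peptides whose best class I rank is
at or below 2% before deconvolution, since co-purified class I ligands are
the dominant contaminant species in class II immunoprecipitates. The
repertoire-overlap analysis (`repertoire_overlap()`) intentionally uses a
much stricter binder threshold (1%) than the trash rule: overlap is a
question about high-confidence repertoires, contamination removal about
generous inclusion.

## The PSSM backend and rank calibration

motifdecon is predictor-agnostic — an external predictor's output can be
supplied as a long-format table (`read_prediction_table()`). The built-in
backend is a position-specific scoring matrix over the 9-residue binding
core: a peptide's raw score is the maximum over all contiguous 9-mer
windows of the summed per-position log-odds, and the arg-max window is the
reported binding core (ties to the leftmost window). Peptides shorter than
9 residues cannot place a core and are pinned to rank 100; no sub-core
scoring is defined.

Ranks are calibrated empirically (`calibrate_ranks()`): `n_bg` random
peptides (default 100,000) are drawn with residues i.i.d. from a background
composition and lengths pooled uniformly over the active length range, and
the rank of a query score is the fraction of background scores greater
than or equal to it, with ties counted as "at least as good". The default
background is the Swiss-Prot average amino-acid composition (a uniform
1/20 option exists). By construction, the ranks of fresh background
peptides are Uniform(0, 100] — the test suite holds a Kolmogorov–Smirnov
check on this below 0.02 at n = 10,000.

Two simplifications relative to neural predictors are documented rather
than modeled: calibration pools all lengths in one curve (no per-length
normalization), and the PSSM has no length-preference term. One
consequence is worth knowing: because the background pool is dominated by
longer peptides with many scoring windows, a short peptide — with fewer or
only one window — sits systematically deep in the pooled score
distribution for *every* allele at once. That is exactly how short
co-purified class I ligands end up in the trash cluster of a class II run.

## Reporting

Per cluster, the package reports the peptide count, the contribution as a
percentage of two denominators (all assigned peptides including trash, and
allele-assigned peptides only — display values round half-up to integer
percent, full precision is retained), the length histogram over the
configured range, and the motif of the assigned binding cores as a 9×20
positional frequency matrix. Frequencies are raw relative counts: no
pseudocounts, no sequence weighting.

Logo data use per-position Kullback–Leibler information against a
background `q`, `info_i = Σ_a p_ia log2(p_ia / q_a)` with `0·log 0 = 0`,
and letter heights `p_ia × info_i`. This is the non-negative,
frequency-weighted rendering; depleted residues are not drawn below the
axis, but the raw `p` and `q` are exported so any rendering can be layered
on. The default logo background is uniform 1/20 — with the natural
composition as `q`, common residues would be visually penalized at
non-anchor positions, and uniform is the convention that makes a point
mass read as `log2 20 ≈ 4.32` bits.

When one allele is deconvoluted in several samples, motif consistency is
the Pearson correlation between the flattened 9×20 frequency matrices.
Flattening is position-major (P1 A..Y, P2 A..Y, …, 180 elements); any
fixed order preserves the correlation, but the order must be fixed for
files to round-trip. A constant vector has no defined correlation and is
reported missing rather than zero. Both sample-vs-sample and
sample-vs-model comparisons are exposed (`model_frequency_matrix()`
inverts a PSSM back to its implied frequencies); neither is privileged.

## Evaluation protocol

Benchmarking against known restrictions uses a confusion matrix of true
label × assigned cluster (trash column included). For methods returning
anonymous clusters, `map_clusters_to_alleles()` applies majority vote with
a deterministic conflict rule: alleles processed by descending dataset
size, a claimed cluster falls to the next allele's best *unclaimed*
cluster, remaining ties lexicographic.

Per allele X with cluster C_X, the counts are: TP, peptides of X in C_X;
FP, peptides of other origins in C_X (trash is never a mapped cluster, so
trash-assigned peptides are never false positives); FN, peptides of X
anywhere else, trash included; TN, everything remaining. This
operationalization is chosen so the four counts tile the matrix exactly —
TN equals peptides of other origins not assigned to C_X, trash included.
MCC is the standard `(TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
defined as 0 when a denominator factor vanishes, and the median over
alleles is the headline comparison statistic. Significance comes from a
bootstrap: peptides are resampled with replacement (default 100
replicates), the median per-allele MCC recomputed each time, and the
2.5/97.5 percentile interval reported. Resampling peptides and summarizing
by the replicate median is one defensible reading of "bootstrap with
N = 100"; it is a contract of this package, not a community standard.

## The synthetic generator: what it emulates, and what it does not

`mock_allele_spec()` defines a ground-truth motif by anchor positions with
preferred-residue frequency maps; `make_mock_allele()` turns it into a
PSSM via `log2(p/q)` with target frequencies floored at 1e-3 so excluded
residues keep finite weights. `sample_peptidome()` draws 9-mer cores from
the target frequencies and builds full-length peptides: class II cores are
embedded in background flanks at a uniform offset; class I length variants
delete core position 5 (length 8) or insert background residues between
core positions 5 and 6 (central bulge). The bulge convention mirrors how
class I ligands really accommodate extra length — both termini stay
anchored in the groove — and it interacts with window scoring: no single
window of a bulged peptide contains the whole core.

The built-in panels reflect that interaction. Class II mock DR alleles
anchor at P1/P4/P6/P9 with pairwise-disjoint preferred residues, loosely
caricaturing published DR motif chemistry (aromatic vs aliphatic P1,
charged P4/P9), with lengths 13–21 peaked at 15. Class I mock alleles
anchor at P2, an auxiliary P3, and the C-terminal P9: the P3 auxiliary
keeps two of three anchors inside one contiguous window for bulged
variants, so a window-maximizing PSSM retains signal on non-9-mers; the
length profile is 9-dominant (70% 9-mers over 8–14). "C-like" alleles are
flat at P2/P3 but keep a sharp C-terminal anchor — a weak-but-anchored
motif, emulating the less defined HLA-C specificity while remaining
recoverable by a supervised method. Anchor maps are blended with 10%
uniform mass (45% at the flattened C-like positions) so every residue
keeps some probability and score distributions are effectively continuous.

`build_artificial_benchmark()` merges per-allele draws with injected
contaminants, enforcing uniqueness within and across origins (a peptide
generated by two alleles has ambiguous truth and is dropped, with a
logged count). Two presets reproduce the published benchmark designs:
four high-abundance class I alleles at 1000 peptides each plus two
low-abundance weak-motif alleles at 200 each (the 5:1 expression ratio of
HLA-A/B over HLA-C), and four class II alleles at 800 peptides each.

Contaminants deserve their own paragraph. The default class II contaminant
model draws short peptides (lengths 8–11, peaked at 9, natural
composition) — emulating the empirically dominant contaminant species,
co-purified class I ligands. This choice is not cosmetic: a contaminant of
the *same* length range as the ligands has, by construction of the rank,
a Uniform(0, 100] rank for each allele, so with `k` declared alleles and
threshold `t` the probability that the trash rule catches it is at most
about `(1 − t/100)^k` — roughly 41% for four alleles at threshold 20. Only
peptides that are systematically worse than the calibration background for
*every* allele at once — in practice, shorter ones with fewer scoring
windows — can be caught at high rates. Even so, the catch rate for 9–11-mer
contaminants saturates around 85%, not 100%; this ceiling is a property of
rank-threshold trash rules in general, not of this implementation, and is
the package's quantitative restatement of why length filtering (or an
explicit class I prefilter) is the more effective contaminant defense.

The generator does **not** emulate: post-translationally modified or
non-canonical sequences (excluded at validation), MS detectability and
abundance biases, peptide quantities, promiscuous multi-allele binders
(every synthetic peptide has exactly one true origin), or the accuracy
profile of trained neural predictors. A passing recovery test therefore
shows that the assignment machinery is correct given an informative
predictor — not that any particular predictor is accurate on real data.

Scrambled-peptide nulls (`scramble_peptides()`) permute each peptide's
residues (composition preserved), keep the best rank per scramble over the
alleles, and subsample to the original length histogram exactly —
per-length without replacement when possible, with replacement otherwise.
`kmer_overlap_filter()` removes peptides sharing a contiguous k-mer with
an exclusion set (8 for class I, 9 for class II in the published
protocol), the standard hygiene step when benchmark peptides must not
overlap a predictor's training data.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `length_min`–`length_max` | 8–14 (I), 13–21 (II) | retained peptide lengths; 12–21 is a reasonable class II alternative when short-length specificities are of interest |
| `trash_threshold` | 20 (% rank) | best rank strictly above this for all alleles → trash; 101 disables |
| `min_logo_peptides` | 10 | clusters below this report counts but suppress the logo |
| `class_i_prefilter_threshold` | 2 (% rank) | class I binder cutoff for the prefilter |
| `binder_threshold` (overlap) | 1 (% rank) | high-confidence binder cutoff for repertoire overlap |
| `n_bg` | 100,000 | background peptides per calibration curve |
| `n_scrambles` | 100 | scrambles per peptide in the null model |
| `n_boot` | 100 | bootstrap replicates for the median MCC |

## Numerical choices and degenerate inputs

Everything random is seeded and restores the caller's RNG state. Window
ties go to the leftmost offset; rank ties count as "at least as good";
equal best ranks go to the lexicographically first allele (C locale).
Display percentages round half-up; full precision is kept internally.
Zero-denominator percentages are reported as undefined, never as 0, and
zero-variance motif correlations as missing. Frequency vectors must be
strictly positive and sum to 1 within 1e-9; target frequencies are floored
at 1e-3 before logs. Empty inputs after any filtering stage raise explicit
errors rather than returning empty results.

The test suite exercises the full benchmark designs (4,400 class I and
3,520 class II peptides with 100,000-peptide calibration curves), KS
uniformity at 10,000 draws against a 50,000-peptide curve, and
oracle-equivalence sweeps of 10,000 random confusion quadruples and 1,000
random scoring cases; these sizes are the package's chosen trade-off
between statistical resolution and a test suite that runs in well under a
minute.

## Known limitations

* Assignment is unambiguous by design: one allele or trash per peptide.
  Promiscuous binders are assigned to their best-ranked allele only.
* The rank-threshold trash rule cannot catch same-length random
  contaminants at high rates (the `(1 − t/100)^k` ceiling above); length
  filtering and the class I prefilter are the effective defenses.
* The PSSM backend has no length-preference or context terms; its pooled
  calibration penalizes short peptides for every allele alike. This is
  what makes it a useful stand-in, not a replacement, for trained
  predictors.
* Class I peptides of length 8 are unscoreable by a 9-mer window and are
  pinned to rank 100; with the default class I length profile this affects
  about 5% of synthetic peptides.

## A minimal session

```{r example}
library(motifdecon)

bench <- build_artificial_benchmark(preset = "classII_benchmark",
                                    contaminant_n = 320, seed = 1)
samp <- peptidome_sample("demo", bench$peptides, bench$alleles, "II")
res <- deconvolute(samp, models = bench$models,
                   config = deconv_config("II", length_min = 9,
                                          length_max = 25),
                   calibration_seed = 101, n_bg = 100000)
res$cluster_counts
contribution_summary(res)

truth <- setNames(bench$true_label, bench$peptides)
mcc_scores(confusion_matrix(truth[res$assignments$peptide],
                            res$assignments$assigned))
```
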