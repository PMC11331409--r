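---
title: "Models and methods in adarscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in adarscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

adarscope re-implements, as a tested pipeline over synthetic data with
recorded ground truth, the computational analyses used to characterise an
ADAR1-knockout hepatocyte cell line: differential A-to-I editing-site
calling between replicate groups, annotation of edited positions,
polysome-profiling translatome analysis by a negative-binomial interaction
model, membership-odds enrichment, small-RNA class summaries, and
image-based cell-area quantification. This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions taken
where the underlying procedures left choices open.

## The synthetic study

ADAR1 deaminates adenosines in double-stranded RNA to inosine, which
sequencers read as guanosine; knockout cells therefore lose A-to-G
mismatches that are present in wild-type RNA-seq. The synthetic-data
module emulates the quantities this study design produces, not the raw
reads:

* **Annotation** (`gen_gene_models`): genes on one chromosome, each with
  an upstream margin between the database gene start and the first
  transcription start site and a downstream margin after the last
  transcript end, so those two site categories exist. About 70% of genes
  are coding (three exons; 5'UTR, CDS with ATG/stop written into the
  genome sequence, 3'UTR), the rest exon-only; quotas force at least one
  exon-only and one snoRNA-host gene. SINE intervals are placed in a
  configurable fraction of introns and 3'UTRs (the SINE set doubles as
  the Alu set for the editing index; Alu sequence content itself is not
  simulated).
* **Pileups** (`gen_pileups`): per-site, per-sample A/C/G/T counts in
  transcript sense for two groups of three replicates. Coverage is
  Poisson with mean 50. Non-edited adenosines draw G counts from
  Binomial(coverage, 0.001), the per-base error rate; planted wild-type-
  only sites draw wild-type G counts from Binomial(coverage, 0.20), the
  editing frequency reported for edited miRNA nucleotides. A small
  fraction of sites carries artifact flags (read-end, splice vicinity,
  homopolymer) or low base quality so the filter cascade is exercised.
* **Counts** (`gen_count_matrix`): negative-binomial counts with
  log2 mean = baseline + cell-line + fraction + interaction effects and
  planted log-uniform size factors in [0.5, 2]. Baselines are log-normal
  (median 200, log-sd 1.2). The default dispersion is 0.02, typical of
  homogeneous cultured-cell-line triplicates; see "Power and its limits"
  below for why this matters. The interaction effect is added to the
  (knockout, unbound) design cell, so a planted value equals the
  population log2[(unbound/polysomal) knockout over wild type].
* **Images** (`gen_cell_images`): non-overlapping cells on an auto-sized
  canvas; the membrane (green) channel holds filled discs whose rendered
  pixel count is the recorded truth area, the nucleus (blue) channel one
  bright round nucleus per cell plus optional elongated and dim
  distractors. Areas are log-normal around the reported medians of 6406
  (wild type) and 8472 px (knockout), a 32% ratio, with log-sd 0.35.

Every generator draws from a stream derived from a master seed by a
stable hash of the stage name (`derive_seed`), so enabling or disabling
one stage never changes another's data, and identical configuration plus
seed reproduce outputs byte-for-byte.

What the generators deliberately do not emulate: read-level artefacts
(mapping bias, PCR duplicates), genuinely overdispersed editing across
replicates, isoform-level expression, correlated gene-gene structure, and
out-of-focus or overlapping cells. Passing tests therefore demonstrate
correctness of the implemented statistics under their stated models, not
robustness to every failure mode of real data.

## Editing-site calling

Sites first pass a deterministic filter cascade, recording the first
failing reason in the fixed order low coverage (any sample under 5
reads), low mean base quality (under 20), artifact flag, and non-A-to-G
change. Sites without any mismatch are kept with an editing signal of
zero so that null sites remain in the denominator of downstream rates.

The differential statistic (`dm_score`) is a beta-binomial — the
two-category Dirichlet-multinomial — likelihood-ratio between a null
model with one A/G composition shared by all samples and an alternative
with one composition per group. The overdispersion is estimated once by
method of moments from within-group replicate scatter (using
group-specific means, so a real group difference does not inflate it) and
held fixed in both models, leaving a one-degree-of-freedom test. The
score is the log likelihood ratio, so the workflow threshold of 2.00
corresponds to a deviance of 4 and an asymptotic null exceedance of about
4.6%; with error-rate counts the score is strongly discrete and the
realised null pass rate is far below that bound. The original study used
an external variant caller whose statistic is not published; this package
reproduces the thresholding workflow, not that caller's numerics.

The "edited only in wild type" selection keeps passing sites with pooled
wild-type frequency at least 0.005 and pooled knockout frequency at most
0.01. The background ceiling deserves a note: at a pooled background
coverage of ~150x, a single error read gives a frequency of ~0.007, so a
ceiling at the error rate itself (0.001) would reject roughly
`1 - 0.999^150` = 14% of genuinely wild-type-only sites. The default
0.01 stays more than an order of magnitude below the 0.20 signal while
tolerating one stray read; both thresholds are arguments.

The Alu editing index (`compute_aei`) is the coverage-weighted aggregate
G/(A+G) over reference-A positions inside Alu (SINE) intervals, pooled
over the chosen samples. Repeat intervals follow the half-open
convention: a position equal to an interval's end coordinate lies
outside.

## Site annotation

`classify_region` implements the gene-anatomy scheme: upstream between
gene start and the minimum transcript start, downstream between the
maximum transcript end and the gene end (both on genomic coordinates,
matching database attribute semantics), and otherwise a resolution
across transcripts with priority CDS > 5'UTR > 3'UTR > exon > intron.
The priority maximises functional information when transcripts disagree
and is independent of transcript listing order; exon-only transcripts
contribute only exon/intron. `codon_consequence` applies the simplest
decoding rule — inosine read as G — to the codon containing the edited
adenosine, strand-aware, and classifies the change as synonymous,
missense, nonsense, stop-retained, stop-loss, or start-loss. Stop-loss
(e.g. TGA edited at its adenosine to TGG) is included even though the
simplest published schemes sometimes omit it, because collapsing it into
missense would mislabel a qualitatively different event.

## Translatome analysis

The engine fits, per gene, a negative-binomial log-linear model with log
size factors (median-of-ratios over all-nonzero genes, geometric mean 1)
as offsets. Two designs are supported: a two-group comparison on total
RNA, and the 2x2 cell-line x fraction interaction over the unbound and
polysomal samples with wild type and polysomal as reference levels. The
interaction coefficient is
log2[(unbound/polysomal) knockout / (unbound/polysomal) wild type]:
positive values mean unbound enrichment in the knockout (retarded
polysome loading), negative values enhanced loading — the orientation is
asserted by a simulation test, not assumed from factor coding.

Dispersion estimation is the step that decides whether the Wald test is
usable at three replicates per cell:

1. Gene-wise dispersions maximise the Cox-Reid adjusted profile
   likelihood (floor 1e-8).
2. A mean-dispersion trend `a0 + a1/mu` is fitted to the gene-wise
   estimates with one outlier-trimming reiteration.
3. The prior width is the robust (MAD-based) spread of gene-wise
   log-dispersions around the trend in excess of the estimator's own
   sampling spread. That sampling spread is measured by a parametric
   bootstrap — null NB genes simulated at the trend dispersion and
   re-estimated — because the chi-square approximation
   (trigamma of half the residual df) understates it at eight residual
   degrees of freedom and would leave the test conservative. A small
   floor (0.05) guards against a degenerate zero-width prior.
4. Each gene's working dispersion maximises the CR-adjusted likelihood
   plus the log-normal prior.

With moderated dispersions the Wald statistic is referred to a standard
normal, as the dispersion is then effectively known; the unshrunk
gene-wise mode instead uses a t with the residual degrees of freedom,
which holds its size but costs substantial power and exists mainly as a
diagnostic. P-values are BH-adjusted over tested genes after
independent filtering: the base-mean cutoff that maximises discoveries
(smoothed, smallest cutoff within one residual SD of the maximum) sets
`padj = NA` for low-information genes, mirroring the practice of
discarding results with non-applicable adjusted p-values. Genes removed
by the count prefilter (fewer than 4 reads in 3 samples) never enter the
adjustment.

Classification applies the fold-change threshold to the point estimate
(|log2FC| at least log2 1.5) together with adjusted p below 0.05, which
matches a plain "fold change over 1.5" rule rather than a composite
null-hypothesis test on the threshold.

### Power and its limits

For a 2x2 design with r replicates per cell and NB weight
`w = mu / (1 + alpha * mu)`, the interaction standard error is at best
`sqrt(4 / (r * w))`, and `w` saturates at `1/alpha` as counts grow. A
log2 effect of 1.5 therefore cannot yield Wald statistics above roughly
`1.04 * sqrt(3 / (4 * alpha))` no matter how highly a gene is expressed:
about 4.0 at dispersion 0.05, against a BH threshold near 3 — which
caps recall of planted effects near 85% for any NB engine (the
DESeq2 reference implementation scores the same on identical data). At
the package default dispersion of 0.02 the ceiling is ~6.4 and recall of
planted 1.5-log2 interactions is 88-98% across seeds, limited by the
low-expression tail of the baseline distribution. Recall of real effects
in noisier designs is correspondingly lower; the engine reports honest
standard errors either way.

PCA for QC runs on log2(normalised count + 1) with per-gene centering — a
plain log transform standing in for a variance-stabilising transform,
adequate for sample-level structure and used for nothing else.

## Enrichment odds

`odds_membership` fits the single-predictor logistic model
logit P(in group) = b0 + b1 * feature and reports exp(b1) with its Wald
p-value; with all four 2x2 cells positive this equals the cross-product
ratio (asserted to 1e-6 in tests, the closed form serving as the
independent oracle). A zero cell switches to the Haldane-Anscombe 0.5
correction with a normal test on the corrected log-odds, flagged in the
output. The gene universe is whatever result table is supplied —
conventionally the genes surviving the prefilter with applicable
adjusted p-values.

## Small RNA

Class summaries run the same NB engine on class-labelled counts (labels
are an input; no annotation inference) and count significant features per
class at the usual thresholds. The read-length comparison normalises by
library size, reports per-length log2 knockout/wild-type ratios of group
means, and attaches seeded bootstrap percentile intervals over
replicates; with three replicates these intervals are optimistic and are
meant for ranking, not strict coverage.

## Cell-area quantification

Nucleus detection thresholds the DAPI channel (Otsu by default), labels
connected components, and filters on mean intensity and roundness
`4 * pi * area / perimeter^2`. The perimeter is the chain-code length of
the Moore-traced boundary with diagonal steps weighted sqrt(2): a
digitised disc then scores about 0.9 — hence the default minimum
roundness of 0.8 — while a 3x30 bar scores about 0.29 and is rejected.
Perimeter estimators that count exposed pixel edges instead would score
every digital disc near pi^2/16 = 0.62 and reject all nuclei at this
threshold, which is why the chain-code estimator was chosen.

Region growing advances all accepted seeds simultaneously over
4-connected pixels whose membrane intensity reaches the stop threshold;
a pixel contested within a step goes to the seed with the nearer
centroid, ties to the lower seed index (the underlying study is silent
on touching cells; this rule is deterministic and symmetric). Seed
pixels are kept even below the threshold, so a seed on background keeps
exactly its own pixels. Population comparison reports medians, quartiles
and the percent difference of medians.

## Reproducibility and problem sizes

The test suite and the acceptance script regenerate all inputs at run
time; no data files ship with the package. Simulation sizes were chosen
so the full suite runs in minutes on one CPU: 2000-plus-250 sites for
editing calibration and power, 2000-gene matrices (pooled over three
where a rate is estimated) for test size, 1000 high-count genes for
effect recovery, 80 planted interaction genes for classification, and
populations of 500 sampled areas with a 20-cell rendered field for the
imaging chain. Each quantity's expected behaviour under these conditions
is asserted in `tests/testthat/test-acceptance.R`.
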