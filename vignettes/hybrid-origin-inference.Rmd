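---
title: "Inferring the backcross origin of an interspecific hybrid from diagnostic SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the backcross origin of an interspecific hybrid from diagnostic SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyborigin)
```

## The problem

A perennial question with putative interspecific hybrids — wild plants,
escaped crops, natural hybrid zones — is not just *whether* an individual
is a hybrid but *what kind*: an F1, or the product of one or more
backcrosses to one of the parental species? hyborigin implements a
count-based answer that needs only a multi-sample VCF: a small
resequencing panel of each candidate parent species (two or three diploid
individuals each is enough) plus the focal individual, all called against
one reference.

The method rests on **species-diagnostic SNPs**: biallelic sites at which
every sampled individual of species A is homozygous for one allele and
every sampled individual of species B is homozygous for the other. At such
a site the focal genotype directly reads out ancestry dosage — homozygous
A-allele (`AA`), heterozygous (`Aa`), or homozygous B-allele (`aa`).

## Genotype classes under backcross pedigrees

Write `g` for the number of backcrosses to the recurrent parent (species
A) after the initial interspecific cross: `g = 0` is the F1, `g = 1` a
single backcross (BC1F1), and so on. At an unlinked diagnostic site the
focal individual always inherits an A allele from the recurrent side;
the other haplotype carries a B allele with probability `2^-g`. With an
error probability `p_error` absorbing genotyping error and mis-ascribed
fixed differences (the `aa` class is impossible under the pedigree, so
its observed mass defines the natural plug-in estimate), the expected
class frequencies are

    q_AA = (1 - p_error) (1 - 2^-g)
    q_Aa = (1 - p_error) 2^-g
    q_aa = p_error

`expected_frequencies()` implements this for any `g >= 0`; `g = 1` and
`g = 2` give the familiar `((1-p)/2, (1-p)/2, p)` and
`(3(1-p)/4, (1-p)/4, p)` rows. Note that under `g = 0` the `AA` class is
impossible, so any observed `AA` count makes the F1 model log-likelihood
`-Inf`; this is deliberate and handled as a value, not an error.

Observed counts `(N_AA, N_Aa, N_aa)` are scored with the full multinomial
log-likelihood, including the multinomial coefficient, with all factorials
computed exactly through `lgamma` — no Stirling approximation. The
coefficient is constant across models, so rankings do not depend on it,
but reported absolute values include it.

`compare_models()` ranks the requested generations and reports the
log-likelihood gap of the top two, the statistic `2 * delta`, and two
p-values: a chi-square reference with one degree of freedom, explicitly
labelled *heuristic* (the generation models are non-nested point
hypotheses, so the chi-square reference has no asymptotic justification),
and a parametric-bootstrap p-value (`bootstrap_pvalue()`), which is the
recommended inferential statement: counts are re-simulated under the null
model and the observed statistic is ranked against the simulated ones.

### p_error: estimate or fix

`compare_models()` defaults to the unrounded observed `aa` fraction
(`estimate_error_rate()`). Passing `p_error = 0.02` fixes it, which is the
convention to use when reproducing analyses whose published
log-likelihoods were computed with a rounded error rate; the two choices
give visibly different absolute log-likelihoods, so the value used is
always echoed in the output.

## The pipeline around the likelihood

`run_hybrid_pipeline()` chains the stages on a VCF:

1. **Filtering** (`filter_biallelic_complete`): only biallelic
   single-nucleotide sites with no missing genotype across both panels and
   the focal sample. Multiallelic records are excluded, never split;
   indels are excluded by the allele-length rule. Genotypes are treated as
   unphased throughout — no stage uses phase.
2. **Diagnostic sites** (`find_discriminatory_sites`): fixation is judged
   on genotype calls (every panel sample homozygous), the natural rule for
   panels of two or three individuals. For larger panels a frequency
   threshold mode (`min_freq`, e.g. 0.95) is available but off by default.
3. **Classification** (`classify_focal_genotypes`): per-site classes in
   site order (painting needs the order), aggregated per chromosome, for
   unanchored contigs, and genome-wide. A focal genotype carrying an
   allele that is neither diagnostic allele is counted in a separate
   `other` bucket rather than forced into a class, because silently
   misclassifying it would bias the likelihood stage.
4. **Model comparison** as above.
5. **Painting** (`paint_chromosomes`, `smooth_track`, `count_segments`):
   see below.
6. **Population-genetic summaries** and the IUPAC alignment export.

Coordinates follow each format's standard: VCF positions are 1-based
inclusive; exported BED segments are 0-based half-open.

## Ancestry painting and smoothing

The ordered class sequence along a chromosome is the "graphical
genotype". `smooth_track()` replaces each site's class by the majority
class in a centred window of `window` sites (default 101), breaks ties
toward the site's own class (deterministic and conservative), merges runs
into segments, and absorbs segments below `min_sites` sites (default 10)
into the larger neighbour. Windows are counted in sites, not base pairs,
which makes the procedure robust to marker-density variation. `aa` sites
(mostly error under a backcross pedigree) are smoothed like any other
class by default so the error structure stays visible; `mask_aa = TRUE`
removes them first.

Numerical notes:

* window edges use truncated windows rather than padding;
* smoothing is idempotent when `min_sites >= (window + 1) / 2` — every
  retained segment then holds a strict majority of any window centred in
  it; with smaller `min_sites` a short retained segment can still be
  out-voted on a second pass;
* segment boundaries always lie on observed site positions, and segment
  site counts add up to the classified site count per chromosome.

## Nucleotide diversity and FST

`nucleotide_diversity()` computes, over the `n = 2 x individuals`
chromosomes of one panel,

    theta_pi = (1 / L_bar) * (n / (n - 1)) * sum_{i<j} k_ij / (n (n-1) / 2)

where `k_ij` counts nucleotide differences between haplotype sequences i
and j. Per biallelic site the pairwise sum equals `c (n - c)` for allele
count `c`, so the estimator is phase-free and identical to explicit
haplotype enumeration (the test suite checks this against a brute-force
all-pairs oracle to 1e-12). `L_bar`, the average number of mapped
(callable) sites per sample, depends on upstream coverage masks that a
SNP-only VCF cannot supply, so it is always an explicit argument and never
inferred or defaulted.

`pairwise_fst()` uses the per-site `F_ST = (H_T - H_S) / H_T` with
equal-weight panels and plain allele-count frequencies (no small-sample
correction), skips monomorphic sites, and averages per-site ratios
arithmetically across the genome. The literature is divided between this
"mean of ratios" and the "ratio of means"; both are implemented
(`average = "ratio_of_means"`) because the choice can move genome-wide
values appreciably, and which convention a published figure used is often
unstated.

## The simulator: what it emulates and what it does not

`simulate_hybrid_dataset()` generates the full data regime the analysis
assumes, with ground truth for every stage:

* **Two diverged species.** Each site is fixed-opposite between species
  (probability `fixed_diff_fraction`, default 0.6), polymorphic within
  one species with frequency uniform(0.1, 0.9) (`within_pop_het_fraction`,
  default 0.3), or monomorphic. The defaults put the diagnostic fraction
  of sites in the majority, emulating a strongly diverged species pair —
  the regime in which this analysis is appropriate at all.
* **Ascertained panels.** Panel haplotypes at within-species polymorphic
  sites are drawn conditioned on the panel actually carrying both alleles,
  the usual ascertainment of a SNP panel. This makes the generator's truth
  labels exact: at error rate 0 the diagnostic-site finder returns
  exactly the simulated fixed-difference list, which the tests assert.
* **Meiosis.** Haldane model: crossovers per chromosome Poisson with mean
  `map_length` Morgans (default 1, a typical plant chromosome),
  breakpoints uniform on the genetic map, no interference, no
  recombination-rate variation along the chromosome.
* **Pedigree.** The F1's mother is the donor species by default (so the
  organelle label, inherited maternally, is the donor's), and each
  backcross uses a freshly drawn recurrent-species father, as wild pollen
  donors would differ across years.
* **Genotype error.** Default mechanism: with probability `error_rate`
  (default 0.02) the focal call is replaced by a uniformly random
  genotype among the three the site's alleles allow. This maps simulator
  rate `e` onto the model's `p_error` as about `e/3` (exactly `e/3` in
  expectation for BC1F1). The alternative `aa_flip` mode sets the call to
  homozygous-donor with probability `e`, realizing `p_error = e` exactly,
  which is convenient for clean unit tests. The two mechanisms bracket
  how real error loads the impossible class.
* **Determinism.** All randomness flows from `sim_config(seed=)`; the
  seed is recorded in the VCF header and truth sidecar, and identical
  configs give byte-identical output files.

What the simulator does *not* model: coalescent mutation/drift dynamics,
selection, sex chromosomes, and recombination-map heterogeneity. Passing
tests on simulated data therefore demonstrate the pipeline's internal
correctness under its own assumptions, not robustness to, for example,
reference bias or depth-dependent genotyping error in real resequencing
data.

## A limitation worth stating plainly: linkage and generation inference

The multinomial likelihood treats diagnostic sites as independent. They
are not: on a 1-Morgan chromosome the focal individual's non-recurrent
haplotype consists of roughly two ancestry blocks, so the genome-wide
heterozygous fraction fluctuates at the level of *blocks*, not sites.
Analytically, the donor fraction of a single F1 gamete on a 1-Morgan
chromosome has variance about 0.14; over 10 chromosomes the genome-wide
heterozygous fraction of a BC1F1 individual has a standard deviation near
0.12 — independent of how many sites are typed.

Consequences, which the test suite documents numerically:

* With multinomial (independent-site) counts of 10,000 sites, model
  selection among adjacent generations is essentially certain (100/100
  across seeds).
* With fully simulated genomes of 10 chromosomes at 1 Morgan each,
  selection among generations 1–3 is right only roughly 65–85% of the
  time, however many sites are typed, because adjacent generations'
  expected heterozygosities differ by less than two block-level standard
  deviations.

The practical reading: a count-based generation call from a 10-chromosome
genome is trustworthy when the observed heterozygous fraction falls close
to one model's expectation and far from its neighbours' (as when 50.3%
observed sits on BC1F1's 50% against BC2F1's 25%), and the reported
site-level p-values overstate certainty in all cases. A
linkage-aware extension (segment-count likelihoods or an HMM over sites)
is the natural next step and is intentionally out of scope here.

## Problem sizes used by the test suite

The packaged tests run the estimator oracles on panels of 2–10 diploids
by up to 1,000 sites, painting consistency on 200 simulated BC1F1
chromosomes, and generation-recovery sweeps of 100 genomes (10
chromosomes by 2,000 diagnostic sites) per generation — sizes chosen so
the whole suite exercises every stage end-to-end in a few minutes on one
core while keeping Monte-Carlo bands (3 standard errors) tight enough to
be informative.

## Reproducing a published-scale analysis from counts alone

Because the likelihood stage needs only the three class counts, a
published analysis can be reproduced without any variant data:

```{r}
cmp <- compare_models(c(434253, 460070, 20760),
                      generations = c(1, 2), p_error = 0.02)
cmp$table
```

yields `lnL(BC1F1) = -547.19` and `lnL(BC2F1) = -143368.97`, with the
single-backcross model decisively best.
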