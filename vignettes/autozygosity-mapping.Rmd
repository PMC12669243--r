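---
title: "Autozygosity mapping with rohscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping with rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The scientific problem

In small, historically isolated populations, individuals frequently inherit
the same haplotype from both parents. The visible trace of such
autozygosity is a *run of homozygosity* (ROH): an uninterrupted stretch of
homozygous genotype calls. Two complementary statistics turn ROH into
analysable quantities:

* **Genome-wide autozygosity** `F_ROH`: the fraction of the genome covered
  by an individual's ROH, a per-sample inbreeding estimate that can be
  correlated with quantitative traits.
* **Regional autozygosity**: a per-SNP, per-sample binary indicator (1 when
  the SNP lies inside one of the sample's ROH). Regressing a trait on this
  indicator, SNP by SNP, maps *where* autozygosity matters — a design that
  is sensitive to recessive architectures that additive genome-wide
  association scans miss.

`rohscan` implements this whole chain — genotype IO, cohort QC, population
structure, the sliding-window ROH caller, `F_ROH` statistics and trait
correlations, and the per-SNP regional association under a linear mixed
model (LMM) — together with a synthetic-cohort generator so the pipeline
can be exercised and validated end to end without access to any restricted
cohort.

## The ROH caller

The caller is the classic sliding-window genotype scan. For each sample
and chromosome a window of `window_snp = 50` consecutive SNPs slides one
SNP at a time; a window *passes* when it contains at most
`window_het_max = 1` heterozygous and `window_missing_max = 5` missing
calls. Each SNP's *hit fraction* is the proportion of windows containing
it (only windows fully inside the chromosome) that pass; the SNP is
*eligible* when that fraction is at least `window_threshold = 0.05`
(inclusive). Maximal runs of eligible SNPs are split wherever two adjacent
SNPs are more than `max_gap_kb = 1000` apart, and a run is emitted as a
segment when it has at least `min_snp = 100` SNPs, spans at least
`min_kb = 1000` kb (length defined as last − first position + 1) and has a
density of at most `max_density_kb_per_snp = 50`. These defaults are the
widely used defaults of the PLINK v1.9 `--homozyg` family; they are all
frozen in `roh_params()` so the dialect is explicit and overridable.

Two behaviors are worth calling out because they surprise users:

* There is **no cap on heterozygotes inside a final segment** — only the
  per-window cap applies. A long segment can therefore contain isolated
  heterozygous calls (e.g. genotyping errors) without being broken.
* Chromosome-edge SNPs are judged on the (fewer) windows that contain
  them, and a chromosome shorter than one window is judged by a single
  truncated window.

The implementation uses cumulative sums; a deliberately naive enumerating
scanner lives in the test suite and the two are required to agree exactly
on hundreds of random instances.

`F_ROH` is total ROH length divided by `genome_length_bp` (default
`3e9`, the human autosomal genome). For synthetic cohorts the pipeline
substitutes the span actually covered by the simulated map, which keeps
the estimate comparable with the generator's planted truth.

Segment summaries are reported twice — for all segments and for the long
class alone (`long_cutoff_kb = 1600`) — because a 1.6 Mb cutoff is the
conventional boundary above which segments are attributed to recent
parental relatedness rather than ancient LD; samples are classified as
{no ROH, only short segments, any long segment}.

For enriched-region tables, contiguous SNP runs whose ROH frequency
reaches a threshold (0.20 and 0.15 are both reported) are merged into
regions. A sample counts as a **carrier of a region when its ROH covers at
least one SNP of the region**. This matches the per-SNP matrix semantics;
the stricter all-SNPs rule can only reduce carrier counts, and the test
suite covers that inequality explicitly.

## Quality control

`apply_qc()` runs, in order: variant missingness (> 0.02 dropped), sample
missingness (> 0.1), the exact Hardy–Weinberg test (p ≤ 5e-8 dropped),
per-sample heterozygosity (outside mean ± 3 SD), and minor allele
frequency (< 0.05). The order follows the conventional listing of these
filters; since tools differ in ordering, the report records removals per
step so the order is auditable. The heterozygosity statistic is computed
once per invocation, on the variants current at that step — it is not
iterated until stability, so a second `apply_qc()` call can in principle
remove further heterozygosity outliers (the test suite demonstrates every
other step is idempotent).

The Hardy–Weinberg test is the two-sided exact conditional test: with the
minor-allele count fixed, `P(n_het) ∝ N! / (n1! n_het! n2!) · 2^n_het`,
and the p-value sums all heterozygote counts whose probability does not
exceed the observed one. No mid-p correction is applied, matching the
default behavior of the standard tools. Computation is in log space with
a normalized maximum, so it is stable for large counts; the suite checks
it against a plain-factorial enumerator for every genotype triple with
N ≤ 25.

## Population structure

* **LD pruning** follows the `--indep-pairwise 50 5 0.2` recipe: 50-SNP
  windows advanced by 5 SNPs; within a window, while any pair of retained
  variants has squared Pearson dosage correlation above 0.2, the worst
  pair loses its lower-MAF member (the later variant in map order on an
  exact tie). The reference tools do not document their internal
  tie-breaking, so exact concordance with them is a non-goal; what matters
  here is that the rule is deterministic and sample-order invariant.
* **PCA** standardizes each variant to mean 0 and variance `2p(1−p)`
  (missing calls mean-imputed), and returns the top eigenvectors of the
  sample covariance; variance fractions are eigenvalues over the trace.
* **GRM**: the VanRaden form `Z Z' / Σ 2 p_j (1 − p_j)` with `Z` the
  column-centered dosage matrix. Monomorphic variants are excluded.

## The regional association model

For the trait *y* the null model is

    y = X b + g + e,   g ~ N(0, var_g K),   e ~ N(0, var_e I)

with `X` = intercept, the top two genotype PCs, sex (0 = female,
1 = male) and age, and `K` the GRM. `fit_null_lmm()` estimates the
variance components by REML: the GRM is eigendecomposed once, the data are
rotated onto the eigenbasis, and the restricted likelihood is profiled
over the variance ratio `var_g / var_e`, optimized on the log scale after
a 25-point grid bracket (search range e^±12; an optimum on the lower
bound is reported as `var_g = 0`).

Each SNP's ROH-inclusion status is then tested by generalized least
squares with the null fit's variance *ratio* held fixed — the standard
efficient two-stage scheme — while the overall residual scale is
re-estimated per SNP, giving a t-test with `n − k − 1` degrees of
freedom. Two consequences: when the GRM is the identity the test is
*exactly* the OLS t-test, and for the bulk of SNPs the p-values agree
with exact per-SNP REML refits to well within a few percent. The residual
disagreement is concentrated in SNPs that are themselves strongly
associated, where a refit would also shift the variance components; the
test suite quantifies this (median relative error below 3%, 95% of SNPs
within 10%).

Before testing, samples without any ROH are removed first and then SNP
columns with regional frequency below 1% (computed on the remaining
samples) — the order matters and is fixed here as samples-first. The
significance threshold is Bonferroni `alpha / m` with `m` the number of
SNP columns actually tested — computed at run time, never hard-coded,
and logged together with `m`. Independent signals are reported by greedy
LD clumping (`p1 = 1e-4`, `p2 = 0.01`, `r² > 0.5`, 250 kb — the reference
tool's documented defaults, all config-exposed), and each clump index SNP
is re-tested on its actual genotypes under additive and recessive
encodings (OLS with the same covariates) as the validation route.

Trait values are used as given: no rank transformation is applied, and
complete-case analysis is used for trait and covariates (counts logged).

## The F_ROH trait scan

Spearman's rank correlation (Pearson correlation of average ranks) with a
two-sided t-approximation p-value on `n − 2` degrees of freedom; an exact
permutation oracle exists in the tests and agrees with the approximation
at small n. Benjamini–Hochberg adjustment is applied across the whole
trait family passed to one `froh_trait_scan()` call — family membership
is therefore explicit in the call, and the output records the `n` used
per trait after pairwise-complete dropping.

## What the synthetic generator emulates — and what it does not

`sim_config()` describes a desk-scale model of an isolated cohort. The
defaults are: 200 samples; 20 chromosomes × 1000 SNPs at 10 kb mean
exponential spacing (a 200 Mb genome); allele frequencies uniform on
[0.05, 0.5] (the analysis operates on common variants); on average 3
planted autozygous segments per genome with lengths 1.6 Mb + Exp(1.4 Mb).
The segment geometry matches the autozygosity landscape reported for
heavily autozygous isolates, scaled to the simulated genome: roughly 4–5%
of the genome in long ROH, segment mean length ~3 Mb, everything above
the 1.6 Mb long-segment cutoff.
Genotyping error is modeled as spurious heterozygosity inside planted
segments at rate 0.002 — the one error mode that breaks ROH calling —
and calls are set missing at rate 0.01.

Autozygosity is planted directly by drawing one haplotype per site from
the allele frequency and duplicating it. This reproduces the statistical
structure the caller and the association tests rely on, at a fraction of
the complexity of pedigree or coalescent simulation. What it deliberately
does **not** reproduce:

* **LD structure.** Sites are independent given the allele frequencies,
  so LD-pruning and clumping see far less correlation than real data.
* **Shared segments between samples.** Background relatedness enters only
  through the GRM-structured polygenic trait component, not through
  genotype sharing; planted segments are independent across samples
  (except the deliberate causal region under the regional trait model).
* **Demography.** No drift, selection or admixture.

Passing tests on these cohorts therefore validate the *algorithmic and
statistical* behavior of the pipeline — caller correctness, estimator
calibration, power under planted effects — not its behavior under
realistic LD or pedigree structure.

Trait models: `null` (covariates + polygenic + noise), `froh_linear`
(effect proportional to the true autozygous fraction), `regional` (effect
on the regional autozygosity status of a fixed causal region on
chromosome 1: samples whose true autozygous segments cover the region's
midpoint — the region is planted deliberately in a 0.25 share of samples,
and background segments that happen to span it also carry the effect),
and `recessive` (effect on homozygotes of a
designated causal variant). The recessive demo variant's allele frequency
defaults to 0.5 so the homozygote class is as large as possible (a
quarter of the cohort) — the configuration in which the additive/
recessive contrast is properly posed, and consistent with the common
variants that motivate recessive modeling in isolates. Ages are uniform
on [18, 80] years (`beta_age = 0.01` per year), sexes Bernoulli(0.5)
(`beta_sex = 0.2`), polygenic and noise variances both 1 by default. The
whole cohort is a deterministic, byte-identical function of the config,
including its seed.

## Numerical choices and degenerate inputs

* `.bed` decoding uses a 256 × 4 lookup table; the payload length must be
  exactly `M · ceil(N/4)` bytes or a truncation error is raised. Writing
  refuses unsorted variant maps (the container class enforces sortedness
  anyway). By default `read_bed()` preserves file allele order so that
  write-then-read is bit-exact; `orient_minor = TRUE` re-orients the
  counted allele to the minor allele (recorded via the returned allele
  columns) and is what the pipeline uses, so effect signs are
  well-defined.
* Multiallelic VCF records are skipped (with a logged count), not
  decomposed; non-autosomal records are dropped by all readers.
* The HWE p-value comparison `p_i ≤ p_obs` uses a `1 + 1e-9` relative
  tolerance on the observed probability, the usual guard against ties
  lost to floating point.
* Eligibility threshold comparisons in the ROH caller are inclusive
  (fraction ≥ threshold).
* `fit_null_lmm()` clamps tiny negative GRM eigenvalues to zero and
  errors when the matrix is materially non-PSD; constant status columns
  and constant genotype regressors are flagged (`NA` results with a
  note), never silently tested.
* Clumping sorts by p-value with variant id as tie-break, making
  assignments independent of input row order.

## Problem sizes used in validation

The test and acceptance studies run at deliberately desk-scale sizes,
chosen so each study still has the statistical resolution its claim
needs: caller-vs-oracle equivalence on 200 random instances of up to 500
SNPs; exact-HWE equivalence on all genotype triples with N ≤ 25; planted-
truth recovery on an error-free 200-sample, 20k-SNP cohort (bp-Jaccard
and F_ROH correlation); LMM calibration on 10,000 null tests — 5 cohorts
of N = 300 with 2000 independent trait replicates each, one status column
tested per replicate, so the tests are independent draws and a binomial
error band applies; power on 20 cohorts of N = 500 with a regional effect
explaining 8% of trait variance; and the additive/recessive contrast on
50 cohorts of N = 500 with a 0.5 SD purely recessive effect. The
`scripts/acceptance.R` script recomputes all of these from scratch.

## Known limitations

* Chromosome X, phased haplotypes, dosages and BGEN/PGEN are out of
  scope; ROH classing beyond the single 1.6 Mb cutoff is not implemented.
* The regional LMM assumes a quantitative trait; binary traits would need
  a logistic mixed model.
* The heterozygosity QC window is single-pass by design (see above).
* The generator's independence assumptions above mean LD-dependent steps
  are only lightly exercised by synthetic data.
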