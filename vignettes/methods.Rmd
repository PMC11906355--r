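---
title: "Methods: pQTL mapping and peptide-level artefact elimination in pediatric plasma proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pQTL mapping and peptide-level artefact elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedpqtl)
```

## The problem

Plasma protein levels in children are shaped by genetic variants, age, sex
and adiposity. Mapping protein quantitative trait loci (pQTLs) from
mass-spectrometry proteomes has a specific failure mode: a protein-altering
variant can change the *detectability* of a tryptic peptide rather than the
abundance of the protein. Because the search database contains only the
reference sequence, peptides carrying the variant residue go undetected in
carriers, the reference peptide appears depleted in proportion to
alternate-allele dosage, and the protein-level quantification inherits an
artificial association. `pedpqtl` implements the full analysis chain —
preprocessing, demographic association, genotype QC, association scans,
clumping, conditional analysis, peptide-level artefact elimination with
confidence tiers, variance decomposition, effect sizes, prediction,
Mendelian randomization, colocalization, replication and novelty — together
with a synthetic-cohort generator that plants every structure the chain must
detect, so each stage is testable without access-restricted cohort data.

## Preprocessing model

Protein (and peptide) matrices are log2 intensities with missing values.
The pipeline applies, in order:

1. **Completeness filter.** Features quantified in at least 60% of samples
   are kept (boundary inclusive). Filtering precedes imputation.
2. **Downshifted-normal imputation.** Missing values for sample $s$ are
   drawn from $\mathcal{N}(\mu_s - 1.8\,\sigma_s,\ (0.3\,\sigma_s)^2)$,
   where $\mu_s, \sigma_s$ are that sample's observed mean and SD across
   features. The moments are per sample row, modelling values missing
   because they fall below the detection limit.
3. **Rank-based inverse normal transformation (INT).** Each feature maps
   through $\Phi^{-1}\!\big((r_i - c)/(N - 2c + 1)\big)$ with the Blom
   offset $c = 3/8$. Ties receive average ranks before transformation —
   the transform is then deterministic and rank-preserving.
4. **Residualization.** INT levels are regressed on age, sex (female = 1),
   BMI-SDS, obesity (clinic group = 1), obesity × BMI-SDS, pubertal status,
   plasma storage time and PC1; the residuals are INT-transformed again.
   The resulting standard-normal residuals are the association phenotype
   for proteins and peptides alike.

## Association and pQTL definition

Association is ordinary least squares of the standardized phenotype on
alternate-allele dosage, with two-sided t tests on $n-2$ degrees of freedom.
The synthetic cohorts are unrelated and population-homogeneous by
construction, so the kinship term of a mixed model is null and OLS is exact;
calibration is monitored per protein with the genomic inflation factor
$\lambda_{GC}$ (median association $\chi^2_1$ over 0.4549).

Genotype QC applies, in order: variant call rate ≥ 95%, minor allele
frequency ≥ 0.05 (a variant at exactly the threshold is kept), Hardy–
Weinberg equilibrium $P \ge 10^{-6}$ (1-df chi-square), sample call rate
≥ 95%, and sample heterozygosity within 3 SD of the cohort mean.

A **primary pQTL** is the lead of a greedy LD clump: the smallest-$P$
variant below $5 \times 10^{-8}$ seeds a clump and absorbs every unassigned
variant with $r^2 > 0.2$ within ±1 Mb; ties on $P$ break toward the smaller
genomic position. The clump window and the cis window are both anchored at
the transcription start site (TSS) of the protein-coding gene; **cis** means
the lead lies within ±1 Mb of the TSS on the same chromosome (boundary
inclusive), anything else is **trans**. Anchoring at the TSS (rather than
gene boundaries) follows the convention of plotting pQTLs against TSS
position; the window source is configurable. Conditionally independent
signals come from exact forward selection on individual-level data: selected
leads enter the design as covariates and scanning repeats while the best
conditional $P$ stays below the genome-wide threshold. The study-wide
threshold divides $5\times10^{-8}$ by the number of proteins tested.

## Peptide-level artefact elimination and confidence tiers

Every protein-group-specific peptide of a pQTL's protein is tested against
the lead variant after preprocessing identical to the proteins. A peptide
*supports* the pQTL when its $P$ falls below $2.4\times10^{-5}$ (the printed
peptide-level threshold; its exact divisor is not derivable from the printed
numbers, so it is a parameter defaulting to the printed value). The decision
tree is:

- **Tier 1** — at least two supporting peptides, all with the same direction
  of effect.
- For exactly one supporting peptide: if the variant is non-synonymous,
  inside the protein-coding gene, and the supporting peptide spans the
  substituted residue (±1 flanking residue, capturing cleavage-site
  effects), the record is **excluded as artefactual** — this is the
  FLT4/LYZ-type case, and exclusion applies regardless of how many peptides
  were testable, since the spanning peptide *is* the evidence of artefact.
- Otherwise single-peptide support requires at most three testable peptides:
  **Tier 2** (non-synonymous, outside the gene), **Tier 3** (non-synonymous,
  inside the gene, peptide avoids the residue), **Tier 4** (synonymous).
- Everything else — discordant multi-peptide support, one significant of
  more than three testable peptides, non-coding single-peptide cases — is
  **unclassified** and reported, never silently dropped.

The flank margin of 1 residue and the ordering of the artefact check ahead
of the ≤3-peptide constraint are this package's design choices where the
published rules are silent; both are parameters.

## Variance decomposition, effect sizes, prediction

Variance decomposition adds predictor blocks in a fixed order —
conditionally independent pQTL dosages, sex, age, obesity, BMI-SDS,
BMI-SDS × obesity — and attributes to each block its increment in explained
sum of squares over the total (sequential/type-I decomposition, well-defined
because the order is fixed). Increments are clipped at zero against
floating-point cancellation and always total the full-model $R^2$ within
1e-10. Age-group stability re-runs the decomposition in 5–9, 10–14 and
15–20-year strata and correlates per-protein genetic fractions between
strata.

Allelic fold change is computed on untransformed (linear-scale) abundances:
group means of heterozygotes and homozygous-alternate carriers relative to
homozygous reference, with $\log_2$ of the homozygote ratio as the headline
effect size. Empty genotype groups yield flagged missing ratios.

Age and BMI prediction uses a 70/30 train/test split, an inner 70/30
train/validation split, feature ranking by absolute Pearson correlation on
the inner training set only, OLS models with the top $k$ features for
$k = 1..200$, and the smallest $k$ whose validation MSE is within 1% of the
curve minimum — a parsimony-preserving reading of "incremental decrease in
MSE"; the raw curve is emitted so any other rule can be re-applied. The
final model is refit on the full training set (the held-out test set is
evaluated exactly once). Neither ranking nor selection ever sees a test
sample, which the test suite verifies by poisoning test labels.

## Mendelian randomization and colocalization

Causal support for a (protein, trait) pair combines a Wald-ratio MR test at
the top cis instrument — $\hat\theta = \beta_{out}/\beta_{exp}$ with
first-order SE $se_{out}/|\beta_{exp}|$, significance at
$0.05/20{,}000 = 2.5\times10^{-6}$ (the Methods value; a Results passage
prints 2.3e-6, and the threshold is a parameter) — with two-trait
approximate-Bayes-factor colocalization under a single-causal-variant model:
per-variant Wakefield log-ABFs with effect prior SD 0.15, per-variant causal
priors $p_1 = p_2 = 10^{-4}$, shared prior $p_{12} = 10^{-5}$, posteriors
PP0–PP4 by log-sum-exp. Colocalization requires PP4 ≥ 0.7 and a regional
association probability $1 - PP0 - PP3 \ge 0.6$. Alleles are harmonized by
(effect, other) pairs with sign flips for swaps; palindromic variants are
dropped with a logged count. Because the exposure phenotype is standardized,
Wald estimates are per SD of protein level.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
mass-spectrometry physics:

- **Covariates.** Age ~ Uniform(5, 20) years; sex balanced; 55% of children
  from the obesity clinic with BMI-SDS ~ Normal(2.8, 0.75) against
  Normal(0, 1) otherwise; puberty a logistic function of age centered at 11
  years (free parameter); storage time ~ Uniform(0, 10) years.
- **Genotypes.** Per-variant MAF uniform in [0.05, 0.5] (overridable with
  `maf_fixed` so replication/outcome cohorts share population frequencies);
  two haplotypes per child under Hardy–Weinberg; LD as a first-order copy
  chain — enough to exercise $r^2$-based clumping, deliberately not a
  coalescent. Ref/alt pairs are never palindromic, as array QC removes
  strand-ambiguous SNPs upstream of any real analysis.
- **Proteome.** Log2 protein = baseline ~ N(20, 2) + planted genetic effects
  × dosage + covariate effects + N(0, 1) noise; peptides track their parent
  protein with fixed offsets and N(0, 0.5) noise. **Artefact peptides** are
  attenuated on the linear scale by $(2 - d)/2$ for dosage $d$:
  heterozygotes retain half the reference peptide, homozygous-alternate
  carriers lose it entirely — exactly the dose-dependent mechanism the tier
  framework must catch. The protein itself carries no effect (the artefact
  is peptide-only).
- **Missingness.** Logistic in log2 intensity with negative slope (MNAR);
  defaults give roughly 90% completeness, matching deep plasma DIA studies.
- **Determinism.** All randomness flows from one root seed through named
  substreams (`substream_seed`), so stages rerun in isolation reproduce
  bit-identically and every output is stamped with a configuration hash.

What the generator does *not* emulate — ion statistics, interference,
batch structure, relatedness, population stratification, linkage beyond the
first-order chain — bounds what passing tests show: they validate the
statistical machinery and its decision rules, not robustness to those
real-data phenomena.

## Numerical choices and problem sizes

All OLS fits run through a shared QR-based multi-response solver; underflow
in extreme $P$ values is guarded at the smallest representable double.
Monomorphic variants are skipped, rank-deficient designs fail loudly with
the collinear columns named, and log-scale colocalization sums use
log-sum-exp. The verification suites use cohorts of 250–2,000 samples,
20–500 variants and 2–200 proteins with 20–200 replicates per property —
sizes at which every planted effect is comfortably powered and the whole
suite completes in minutes on one core. The tier fixture disables background
MNAR dropout so that all planted peptides are testable and the fixture
isolates the tier logic; variance-decomposition recovery is asserted on the
mean over 20 simulated cohorts, since single-cohort sequential sums of
squares carry sampling error of about ±0.01 at n = 2,000.

## Known limitations

- OLS in place of a mixed model is only exact for unrelated,
  population-homogeneous cohorts such as the simulated ones.
- Pairwise two-trait colocalization stands in for multi-trait clustering;
  traits are analysed one pair at a time.
- The conditional analysis uses individual-level forward selection and is
  not a summary-statistics approximation.
- Batch correction, genotype imputation, ancestry analysis and variant
  consequence annotation are consumed as inputs, not implemented.
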