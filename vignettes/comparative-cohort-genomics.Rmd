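---
title: "Methods: comparative cohort genomics with oncocohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative cohort genomics with oncocohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncocohort)
```

`oncocohort` implements the statistical core of a comparative whole-exome
analysis: a small query tumor cohort is contrasted against a large
reference cohort at three levels — germline susceptibility variants,
somatic mutational signatures, and candidate driver genes — with supporting
burden and per-gene frequency comparisons. This vignette explains each
model, its assumptions, the tunable parameters, and the design choices
made where several reasonable options existed.

## Germline prioritization

Variants arrive already annotated (clinical significance, population
allele frequencies, CADD/PolyPhen/SIFT predictions); the package does not
re-derive ACMG classifications and performs no variant calling. The
cascade retains a variant when all of the following hold, checked in a
fixed order so every exclusion carries the *first* failing criterion as a
machine-readable reason code:

1. significance is Pathogenic or Likely pathogenic (`retained_PLP`), or
   Uncertain significance entering the rescue path below;
2. the **maximum** allele frequency over all reported populations is
   strictly below `af_threshold` (default 0.05). The maximum is the
   conservative reading of "rare in every population"; a variant absent
   from every frequency database is treated as rare. The bound is strict:
   a frequency of exactly 0.05 fails;
3. the gene is on the supplied cancer susceptibility list;
4. the variant passed review (`review_pass`), a boolean surrogate for
   manual inspection of the alignments — the package performs no visual
   review itself.

A variant of Uncertain significance is rescued (`retained_VUS`) when,
additionally, at least two of three in-silico criteria hold: CADD phred
> 20, PolyPhen "Probably damaging" or "Possibly damaging", SIFT
"Deleterious". A missing prediction never counts as met, so missingness
can only make the rule harder to satisfy. Relaxing `af_threshold` can only
grow the retained set (a tested monotonicity property).

A patient is a *carrier* iff at least one of their variants is retained;
carrier rates between cohorts are compared with the shared Fisher exact
routine described below.

## The shared Fisher exact test

Carrier rates, signature presence, and per-gene frequencies all reduce to
a 2×2 table. One routine serves all three (a single source of truth,
asserted by tests): conditioning on both margins, the count in cohort 1 is
hypergeometric, and the two-sided p-value is the probability-mass rule —
the total probability of all tables with the observed margins whose
probability does not exceed the observed table's, with a relative
tolerance of 1e-7 absorbing floating-point ties. This is the convention of
mainstream exact-test implementations, and the suite verifies the routine
against exhaustive enumeration (all tables with total ≤ 40, to 1e-12) and
against an independent reference implementation.

## SBS-96 catalogs and signature refitting

Each somatic SNV is classified by its substituted base and the immediate
5′ and 3′ flanking bases. Substitutions reported on the purine strand are
reverse-complemented so all 96 channels are pyrimidine-referenced; the two
strand representations of one event are therefore indistinguishable
downstream (an exactly-tested invariance). Contexts travel with each
mutation record (`context3`), so no reference genome is needed; indels and
records with ambiguous bases are excluded, and each catalog row sum equals
the patient's valid SNV count.

Exposures are refit per patient by non-negative least squares,
min‖m − S·e‖₂ subject to e ≥ 0, solved by the Lawson–Hanson active-set
algorithm. This deliberately omits the forward-selection sparsity
heuristics of published assignment tools: plain NNLS is deterministic,
transparent, and sufficient for cohort-level contrasts; the active-set
solution returns exact zeros for unused signatures, which is why the
default presence threshold `presence_epsilon = 0` is meaningful (it is
configurable for users who want a positive floor). The divergence from
heuristic assignment tools is intentional and should be kept in mind when
comparing attribution tables tool-to-tool.

Cohorts are summarized by the **mean of per-patient proportions** rather
than summed attributed counts, so a single hypermutated patient cannot
dominate the cohort profile; patients with zero SNVs have undefined
proportions and are excluded from the mean. Per-signature cross-cohort
contrasts use the two-sided Wilcoxon–Mann–Whitney test on per-patient
proportions — exact enumeration when the combined sample size is ≤ 20 and
tie-free, otherwise the normal approximation with tie and continuity
corrections; when every value is identical the tie-corrected variance
vanishes and the p-value is defined as 1. Bonferroni correction
(min(1, m·p)) defaults to the number of signatures contrasted.

## Driver-gene consensus

External selection tools (e.g. dN/dS-style, covariate-corrected
significance, functional-impact bias methods) are consumed as ranking
tables — `tool, gene, score, rank` with ranks validated as a permutation.
The consensus procedure:

- **Top decile**: the best ⌈fraction·G⌉ genes (default fraction 0.10).
  Ceiling is used because the decile of, say, 25 genes should not be
  empty-biased; ties at the cutoff break by lexicographically smaller
  symbol, making every set deterministic.
- **Joint detection**: genes in the deciles of ≥ `min_tools` tools
  (default 2 of 3).
- **Coincidence null**: B resamples draw, for each tool, a uniform random
  gene set of the same size from the universe and recompute the joint-set
  size. The universe is the set of genes scored by at least `min_tools`
  tools, since a gene scored by fewer could never enter the joint set. The
  literal "random gene sets" null is intentionally correlation-free;
  correlation-preserving nulls are out of scope. The joint-set *size* is
  the coincidence statistic — the simplest quantity that captures
  "the tools agree more than chance".
- **Cross-cohort overlap null**: random subsets of the sizes of the two
  joint sets, drawn from a shared universe; the analytic expectation
  |A|·|B|/|U| is reported alongside.
- **Empirical p**: (1 + #{null ≥ observed})/(B + 1). The add-one
  convention never reports 0; with B = 50,000 and no exceedance the
  smallest reportable value is 1/50,001, matching how resampling bounds
  like "p < 2 × 10⁻⁵" arise.

The **subsample bias test** asks how much of a small cohort's top-decile
novelty is a sample-size artifact: draw m patients (default 25) from the
reference cohort, re-rank with a pluggable ranker, take the decile, and
record the intersection with a reference driver list and the fraction
outside it. The default ranker scores each gene by the upper-tail Poisson
probability of its non-synonymous mutation count under a neutral,
length-proportional expectation — transparent, fast, and adequate as a
stand-in for the external tools whose internals are explicitly not
re-implemented here.

## Burden and frequency comparisons

TMB counts splice-site, missense, nonsense and nonstop mutations per
patient and divides by the capture size in Mb (default 37.5, a common
exome library), so TMB is exactly linear in the qualifying mutation list;
the cohort median uses the standard midpoint definition. Gene frequencies
count each patient once per gene (idempotent under re-collapsing), exclude
silent mutations by default, and are compared per gene with the shared
Fisher routine; Bonferroni over the genes tested is the default, with
`correction = "none"` available to reproduce single-gene quoted p-values.

## The synthetic-data generator

Every downstream stage is validated against cohorts with planted ground
truth. The generator emulates the statistical structure the pipeline
assumes — not reads, alignments, or haplotypes:

- per-patient mutation counts are Poisson with configurable mean (the
  per-patient load distribution of real cohorts is not pinned down, so it
  is configuration, not doctrine). The default 900 mutations/patient, with
  an 8% indel fraction, yields cohort totals around 22,000 SNVs per 25
  patients — the scale of a small whole-exome study;
- each SNV's channel is drawn from the patient's own Dirichlet mixture of
  catalog signature profiles (concentration `rep(1, K)` by default; a zero
  concentration is the degenerate limit pinning that exposure to exactly
  0). Roughly half of all records are emitted on the purine strand so
  catalog construction must canonicalize;
- planted drivers multiply selected genes' length-proportional mutation
  rates (default ×10), and coordinates are synthetic (sequential within
  per-gene footprints) since nothing downstream consumes genomic position;
- carriers (default rate 0.32) receive exactly one qualifying germline
  variant in a susceptibility gene; half of the non-carriers receive a
  decoy that fails *exactly one* cascade criterion, so every branch and
  reason code is exercised and perfect recovery is a sharp test;
- metadata mirrors a realistic small cohort: smoking
  ever/never/unknown = 0.40/0.28/0.32 (the "unknown" level reflects
  incomplete clinical records), stage IV 64%, P(female) = 0.56, age
  ~ N(58.8, 14.5) truncated to 30–90;
- three ranking tables mix a shared latent driver score with
  tool-specific noise, `score_t = √c·latent + √(1−c)·noise_t`, so
  concordance c interpolates between identical orders (c = 1) and
  independent random orders (c = 0); planted drivers get a configurable
  latent boost.

All randomness flows from one master seed through deterministically
derived stage seeds (recorded in the run report), so cohorts are
reproducible byte for byte and stages can be varied independently.

What passing tests do **not** show: real mutational processes are not
Dirichlet mixtures of well-separated profiles (real COSMIC signatures are
far more collinear, so refit error on real data will be larger than on
these synthetics); real tool rankings are correlated through shared
covariates, not through a single latent score; and real germline decoys
fail filters in correlated ways. The synthetic results validate the
machinery, not the biology.

## Numerical choices and degenerate inputs

- Fisher: probability-mass rule with 1e-7 relative tolerance; degenerate
  empty-margin tables are errors, all-zero or all-one columns give p = 1.
- NNLS: Lawson–Hanson; all-zero catalog rows yield zero exposures and
  NA proportions, flagged and excluded from cohort summaries.
- Wilcoxon: exact iff combined n ≤ 20 and tie-free; all-tied data give
  p = 1.
- Tie-breaking is lexicographic everywhere a deterministic order is
  needed (ranking construction, decile cutoffs, Poisson-score ties).
- The subsample test requires m strictly below the reference cohort size;
  m equal to the cohort size would make every resample identical, and the
  package rejects it rather than returning a zero-variance distribution.
- Empirical p-values are bounded in [1/(B+1), 1] by construction.

## Validation problem sizes

The test suite validates at desk scale, chosen to finish in minutes while
leaving no statistical claim untested: exhaustive Fisher enumeration over
all 2×2 tables with total ≤ 40; 10,000-SNV strand-invariance checks;
signature recovery on 25 patients × 3,000 SNVs from a 5-signature mixture
over 20 seeds (mean L1 error < 0.05; an unused catalog signature stays
below 0.02 in ≥ 90% of patients); coincidence-p calibration against
uniformity over 200 replicate datasets at B = 2,000 (KS test, α = 0.01);
overlap nulls checked against exhaustive subset-pair enumeration at
|U| = 10 and against the analytic mean at |A| = |B| = 63, |U| = 630; the
subsample size effect on a 250-patient reference with 25 planted drivers
at m = 25 vs m = 100 over 20 seeds; and byte-identical end-to-end pipeline
reports for a 25-query / 250-reference configuration at B = 2,000.

## Known limitations

- Only SBS-96 single-base-substitution signatures; no doublet or indel
  signatures, and no de-novo signature extraction (NMF) — refitting
  requires a user-supplied catalog.
- The bundled catalog is synthetic and clearly labeled (`SynSig*`); COSMIC
  catalogs are not redistributed and must be supplied by the user in the
  standard text format.
- The recurrence ranker is a stand-in: it models neutral mutation rate as
  uniform per base, with no trinucleotide, expression or replication-time
  covariates. It is adequate for subsample bias quantification, not for
  novel driver discovery.
- Reference cohorts enter as explicit counts or simulated tables; the
  package does not fetch or bundle any external cohort data.
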