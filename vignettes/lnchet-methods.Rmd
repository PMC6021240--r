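---
title: "Methods: lncRNA heterogeneity screens and guilt-by-association scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA heterogeneity screens and guilt-by-association scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnchet)
```

`lnchet` implements a pipeline for relating long noncoding RNA (lncRNA)
expression to the clinical and molecular heterogeneity of a tumor
cohort, and for predicting lncRNA function from co-expression. This
vignette is the package's account of the underlying statistics: the
models and their assumptions, the tunable parameters, the synthetic data
the tests rely on, and the design decisions taken where the procedure
left room for choice.

## Differential screens

For a binary tumor feature (mismatch-repair status, CIMP, CIN, a
mutation, tumor location), the screen works per lncRNA on the log2
scale. With feature-positive mean $\bar x_+$ and feature-negative mean
$\bar x_-$, the fold change is $\mathrm{FC} = 2^{\bar x_+ - \bar x_-}$.
Significance comes from a two-sided Wilcoxon rank-sum test by default;
q-values are Benjamini–Hochberg within the screened lncRNA family (one
family per feature, matching per-screen FDR reporting). A gene is called
only when both gates pass: $\mathrm{FC} \ge 1.5$ or
$\mathrm{FC} \le 0.67$, and $q < 0.05$. Missing feature labels exclude a
sample from that comparison only; nothing is imputed.

The choice of test deserves a note. The procedure this package follows
describes rank-sum testing after Shapiro normality and Bartlett
homoscedasticity checks, while per-figure analyses elsewhere describe
t-tests; the two are not identical on real data. Rather than guess,
`test_differential()` exposes all three (`wilcoxon`, `ttest`, and the
gated `auto`), defaults to `wilcoxon`, and records the branch taken in
an attribute; the pipeline log stores the configured method. A
degenerate corner: with zero variance in *both* groups the t-branch
returns p = 1 with a warning — no within-group variability gives a
two-sample test no basis for inference.

The subtype screen compares, for subtype $s$ out of $K$, the focal mean
against the unweighted **mean of the per-subtype means** of the others:
$\mathrm{FC}_s = 2^{\bar x_s - \frac{1}{K-1}\sum_{t \ne s} \bar x_t}$.
This is deliberately not the pooled-sample mean: subtypes of different
sizes contribute equally to the reference. The p-value, however, is a
sample-level test of the focal subtype against the pooled remaining
samples, because a "mean of means" has no per-sample test; this pairing
(unweighted FC, pooled test) is a design decision recorded here.
Subtypes with fewer than three samples are excluded with a warning.

## Survival screen

Each lncRNA enters a Cox proportional-hazards model standardized
(z-scored), so the single pair of hazard-ratio gates (1.5 / 0.67) means
the same thing for every gene: a per-SD effect. Two models are fitted
per gene — univariate, and multivariate with KRAS status, MMR status and
ordinal-numeric disease stage — using the Efron tie approximation. The
proportional-hazards assumption is checked on the expression term of the
univariate fit via the Schoenfeld-residual test; genes rejected at
$p < 0.01$ are flagged and excluded from direction calls. A call
requires *both* models to pass $\mathrm{HR} \ge 1.5$ or $\le 0.67$ with
$p \le 0.05$; protective genes (HR < 1) are labeled RFS-positive. The
full follow-up is used with no time-window truncation. Expression is
continuous throughout the screen; the median split in
`km_median_split()` exists only for Kaplan–Meier display export.

## Guilt-by-association

The cohort is split into two halves whose subtype composition matches:
within each subtype stratum (missing labels form their own stratum),
samples are shuffled and dealt alternately, each stratum starting in the
currently smaller half, so per-stratum and total counts differ by at
most one (566 samples give 283 + 283). In each half, each selected
lncRNA is Pearson-correlated with every mRNA and the mRNAs are ranked by
the coefficient, descending, ties broken by gene id for determinism.

The enrichment score of a gene set in such a ranked list is the classic
running-sum statistic: walking the list, a member at rank $i$ adds
$|r_i|^p / \sum_{\text{members}} |r_j|^p$, a non-member subtracts
$1/(N - N_h)$; the ES is the signed maximum deviation from zero. The
exponent defaults to $p = 1$ (the weighted form GSEA software applies);
$p = 0$ is available and is what the brute-force oracle tests use
alongside $p = 1$. Two numerical conventions: an exact tie between the
positive and negative extremum (to within $10^{-12}$, since different
summation orders disagree in the last bits) resolves to the positive
one, and a gene set equal to the whole ranked universe is an error (the
miss decrement is undefined). If all member weights are zero under
$p = 1$ (all correlations exactly zero), the hit increments fall back to
equal weights rather than dividing by zero.

Significance uses **gene-set permutation**: for each tested set, `nperm`
random same-size sets are drawn from the ranked universe, independently
per set. NES normalizes ES by the mean |null ES| of matching sign
(sets with no same-sign null draws get a guarded denominator of
$10^{-6}$ with a warning). The FWER p-value of a set is the fraction of
permutations whose maximum |null NES| across *all* tested sets reaches
the observed |NES| — the max-statistic construction. Nulls are drawn
independently per set even when sets share a size; sharing draws would
understate the maximum and make the FWER anti-conservative.

A pair (lncRNA, gene set) enters the consensus profile only if its FWER
passes the 0.05 gate in **both** halves; its consensus score is the mean
of the two ES values. Pairs significant in both halves with *opposite*
ES signs are dropped with a logged message: averaging them would
fabricate a near-zero score that still passed the gate.

Before any of this, redundant gene sets are merged: overlap distance
$d(A,B) = 1 - |A \cap B| / \min(|A|,|B|)$, complete-linkage clustering,
tree cut at 0.5, union within clusters, names concatenated. Sets are
sorted by name first, which makes the merge invariant to input order.

### A caution on correlated gene sets

Gene-set permutation draws *incoherent* random sets, so a set whose
members are mutually correlated in the data (as co-functional sets are)
can reach large |ES| for lncRNAs with no real association — the members
move up or down the ranking together. The both-halves gate suppresses
only the half-specific part of this. The synthetic cohorts make the
effect visible: wiring one lncRNA to a set at $\rho = 0.6$ necessarily
makes the set internally coherent, and null lncRNAs then occasionally
pass the consensus gate for that set. This is faithful to the method;
it is also exactly why the metascore's null pool (below) must consist of
lncRNAs that went through the same selection, so the random-group null
absorbs the coherence-induced ES distribution.

## Enrichment Metascore

For an lncRNA group $G$ with weights $w_i \in \{-1, +1\}$ ($-1$ for
members down-regulated with respect to the group's defining feature),
the metascore for gene set $S$ is $\mathrm{EM} = \sum_{i \in G} w_i
\mathrm{ES}_i(S)$, a member without a consensus entry contributing zero.
The null is built from random groups of the same size drawn without
replacement from the pool of **all lncRNAs analyzed by the
guilt-by-association stage** (carried on the consensus profile as an
attribute), not merely those with a surviving consensus pair — the
narrower reading can degenerate to a pool equal to the group. Each
sampled lncRNA keeps its own direction weight when one is known, +1
otherwise. One collection of random groups is drawn per observed group
and scored against every gene set, mirroring a single batch of random
groups; p-values are therefore dependent across sets within a group,
which BH tolerates. The p-value is the literal one-sided proportion
(no pseudo-count); p = 0 means below the $1/\text{nperm}$ resolution
floor. BH is applied across gene sets within each group; the
multiplicity family is a design decision recorded in the run log.

One subtlety: the reported p-value takes the side of the *observed*
metascore's sign. Under that convention a null metascore's p-value is
the smaller of its two tail probabilities, distributed Uniform(0, ½) —
not Uniform(0, 1). Calibration checks of null uniformity therefore
evaluate random groups at a *fixed* direction (`metascore_pvalue(...,
"positive")`), which is the statement that is actually true and is what
the test suite and the acceptance script verify by Kolmogorov–Smirnov.

## Reannotation rules

Expression-array probes are assigned to lncRNA genes by a rule chain:

1. keep alignments covering $\ge 80\%$ of the probe with concordant
   biotype between the lncRNA database and the reference annotation;
2. group duplicate transcripts — the shorter sharing $\ge 95\%$ of its
   sequence with the longer — and close the relation into connected
   components (the pairwise relation is not transitive; components make
   grouping order-free and deterministic);
3. drop probes with multiple targets unless all targets sit in one
   duplicate group (this is applied literally at transcript level, so a
   probe hitting two isoforms of one locus is also dropped);
4. merge alternative transcripts of a locus into a gene spanning their
   union; a multi-locus duplicate group becomes one gene at its largest
   member locus, named `multi-` + the lexicographically smallest member
   name;
5. where several probes remain for one gene, keep the one with maximal
   sample variance, exact ties going to the smallest probe id.

Coordinates are 0-based half-open throughout; BED conventions on disk.
The companion interval rules: a two-color-array probe maps to a
transcript when, strand-specifically, it overlaps an exon padded by 5 bp
on each side by at least 58 bp (coverage is probe-relative for the rule
chain above, raw genomic overlap here — each follows its own
definition). CpG sites are promoter if within −2 kb/+1 kb of the TSS
*in transcription orientation* (the windows flip on the minus strand;
offsets alone are strand-ambiguous, and TSS-relative windows are
conventionally transcription-oriented), gene-body anywhere else between
TSS and TTS, and a site may be labeled by several genes.

## Differential methylation

β-values are logit2-transformed, $M = \log_2 \beta/(1-\beta)$, tested
with a per-site two-sided t-test between groups, and gated by
$|\Delta\beta| > 0.2$ where $\Delta\beta$ is the difference of group
*median* β. Both conditions are required; raw p-values are used by
default (the conjunctive magnitude gate is the multiplicity control in
this rule; BH is available as an option). Probe filtering removes sites
failing detection p ≤ 0.05 — per probe when any sample fails, with a
per-value masking option — cross-reactive and SNP-containing sites from
supplied blacklists, and sex-chromosome sites.

## The synthetic cohort

`generate_cohort()` emulates the statistical structure every stage
assumes, not the raw technology. Expression is baseline (uniform on
4–10 log2 units) plus planted group shifts plus homoscedastic Gaussian
noise (SD 0.5 log2 units by default) — the homoscedastic choice keeps
fold changes exactly interpretable and resembles array data after
variance-stabilizing normalization. Clinical features are independent
Bernoulli draws at configurable prevalences (defaults: distal 0.55,
dMMR 0.16, CIMP+ 0.21, CIN-high 0.55, BRAF 0.10, KRAS 0.40, TP53 0.50 —
values a colorectal cohort of this kind plausibly shows); subtypes
default to uniform over C1–C6 (the reference cohort's exact distribution
is not printed anywhere usable, so it is a parameter).

Correlation plants use latent factors: a wired gene set's members load
on a shared factor at $\sqrt{\rho}$ and a wired lncRNA at
$w\rho/\sqrt{\rho}$, so lncRNA–member correlation is $w\rho$ in
expectation while every gene keeps unit total variance. Survival plants
share one latent prognostic factor per |log-HR| magnitude: the factor
drives the hazard $h(t) = h_0 \exp(\beta f)$ and planted genes load on
it at 0.95 (sign per gene). This correlated-module construction is
deliberate: twenty genes with *independent* effects of that size in one
cohort would attenuate each gene's marginal hazard ratio far below its
planted value, making per-gene recovery statements meaningless; a
co-expressed prognostic module is also the biologically typical way many
genes share prognostic signal. The residual attenuation from the 0.95
loading is about 0.05 on the log-HR scale. Censoring is uniform
administrative over 0–10 years with baseline hazard 0.18/year, giving
roughly half the cohort an event — a plausible relapse profile for a
mixed-stage cohort over that follow-up. Methylation is Beta-distributed
with common precision 30; a planted site shifts one group's mean by the
target Δβ, which moves the medians by approximately the same amount in
the mid-range.

What the generator does **not** emulate: probe-level measurement error,
spatial artifacts, batch structure, heteroscedasticity,
mean–variance coupling, realistic lncRNA expression sparsity,
copy-number-driven correlation, or informative censoring. Passing the
recovery tests therefore shows the statistics are implemented correctly
and calibrated under their own assumptions — not that the pipeline is
robust to everything real cohorts do.

## Determinism and problem sizes

One global integer seed lives in the configuration; every stochastic
stage derives a child seed from (seed, stage label) via a polynomial
hash, so stages are reproducible in isolation and inserting a stage does
not shift the streams of the others. Identical configuration and seed
reproduce byte-identical output tables.

The test suite and acceptance script run: oracle equivalence of the
enrichment score on all 2-subsets of 20-gene lists (both exponents) and
of BH on 1000 grid lists of length ≤ 8; null calibration on cohorts of
300 samples × 500 lncRNAs across several seeds; shift recovery at
100 vs 100 samples; hazard-ratio recovery at 500 samples with 20 planted
genes among 480 nulls; and the full guilt-by-association + metascore
chain on 566-sample cohorts (50 lncRNAs, 2000 mRNAs, 20 sets of 30,
GSEA nperm 200, metascore nperm 2000) across five seeds. These sizes
were chosen as the smallest at which each property is statistically
sharp; all scale up through the same parameters.

## Known limitations

* Gene-set permutation ignores inter-gene correlation (see the caution
  above); a sample-permutation GSEA mode is out of scope.
* The Wilcoxon/t ambiguity is exposed, not resolved.
* The multi-target probe rule at transcript level is strict with
  isoform-spanning probes.
* Groups for the metascore inherit their weights from screen direction
  labels; lncRNAs selected by several features keep per-feature weights,
  and the pipeline scores each feature's group separately rather than
  defining a global label per lncRNA.
* `fit_cox()` requires events; it warns below 10 events rather than
  refusing, since the screen's gates make such fits inconsequential.
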