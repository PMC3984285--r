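---
title: "Methods: ancestry-stratified profiling of germline cancer-gene variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry-stratified profiling of germline cancer-gene variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

germvar analyses germline variation in a panel of cancer-associated genes
across an ancestrally diverse cohort: it filters genotypes for
reliability, annotates predicted protein consequences from transcript
models, assigns subjects to ancestry-based subpopulations by supervised
admixture estimation, compares allele frequencies between those
subpopulations, and summarises variant load per individual and per gene.
This vignette documents the models, the tunable parameters, the
synthetic-cohort generator that stands in for protected genotype data,
and the numerical and design choices behind the implementation.

## Genotype reliability filtering

Two fixed filters are applied, in order. The **position filter** removes
every site with a cohort call rate below 80% or an average fractional
allele depth at or below 0.295. The **genotype filter** then masks any
remaining call whose minimum carried-allele depth is 11 reads or fewer
(both alleles for a heterozygote, the single carried allele for a
homozygote); masked calls are treated as no-calls in every downstream
count. The thresholds are published constants from a decision-tree model
trained against orthogonally validated genotypes; this package applies
them, it does not re-train them. `estimate_error_rates()` reproduces the
evaluation protocol — stratified 10-fold cross-validation of the fixed
filter against a labeled call set — and reports false-negative and
false-positive rates with Clopper–Pearson intervals.

Two definitions in this stage are reconstructions, because the source
material does not spell them out, and both are configurable:

* *Average fractional allele depth* is computed as the mean, over called
  genotypes with positive depth, of the depth of the least-supported
  carried allele divided by total depth. For a homozygote this is the
  carried allele's fraction; defining it over both alleles of the site
  instead would drive the statistic to ~0 at any site with homozygous
  calls and make the 0.295 bound meaningless.
* *Minimum allele depth* is taken over the alleles actually carried in
  the genotype. Taking it over both site alleles would mask every
  homozygous call (the uncarried allele has depth ~0), which is not a
  reading under which any data survive the filter.

The position filter is evaluated on raw calls before genotype masking,
matching the order in which the two filters are described.

## Consequence annotation

For each variant and transcript, the reference coding sequence is the
concatenation of exonic bases within the CDS bounds (reverse-complemented
for minus-strand transcripts); the alternate coding sequence is the same
construction after applying the allele substitution. Both are translated
with the standard genetic code and compared:

* length change not a multiple of 3 → frameshift;
* a stop codon upstream of the expected stop position → nonsense (for an
  in-frame indel the expected stop shifts by `ld/3` codons, so a merely
  shifted stop is not "new");
* in-frame length change → in-frame indel;
* amino-acid substitution → missense; identical protein → synonymous.

Variants outside the CDS that intersect the first or last **2** intronic
bases of an intron (the canonical donor/acceptor dinucleotides;
configurable, since the source never states its window) are splice-site;
other intronic/UTR positions are noncoding. A variant's gene-level
category is the most severe per-transcript category, in the order
frameshift > nonsense > splice-site > missense > in-frame indel >
synonymous. Start-loss and stop-loss changes are reported as missense
(first differing residue), a deliberate folding of two rare categories
into the "other nonsynonymous" class.

Variants are assigned three nonexclusive reporting classes over the
nonsynonymous set: *deleterious* (frameshift, nonsense, splice-site),
*HGMD-listed* (membership in a supplied disease-annotation table), and
*VUS* (nonsynonymous variants in neither class); a *novel* flag marks
absence from a supplied known-variant table. Synonymous variants carry
no class flags at all. PolyPhen-style scores bin at >0.85 (probably
damaging), 0.15–0.85 inclusive (possibly damaging; the boundary values
are read into the middle bin because the bin is described as the scores
*between* the two cutoffs), and <0.15 (benign).

## Supervised admixture and subpopulation clustering

Each subject's ancestry is modelled as a vector *q* of six non-negative
coefficients summing to 1 over African, European, Native American, East
Asian, Central Asian and Oceanic ancestral populations. With panel
marker frequencies *f* fixed, the dosage likelihood
`sum_l [x_l log(q'f_l) + (2 - x_l) log(q'(1 - f_l))]` is maximised per
subject by EM from a uniform start. The likelihood is monotone
non-decreasing (asserted in tests); iteration stops when the mean
per-subject log-likelihood gain falls below `tol` (default 1e-3) or at
`max_iter` (default 300). Frequencies of exactly 0/1 are clipped to
`[1e-6, 1 - 1e-6]` to keep the likelihood finite, and subjects need at
least 100 called panel markers. Only this supervised projection is
implemented; unsupervised frequency estimation is out of scope.

Subpopulations are then formed by an explicit threshold rule rather than
a generic clustering algorithm, because the reported cluster boundaries
are threshold-like breakpoints in the admixture coefficients: dominant
ancestry at ≥0.78 (African), ≥0.79 (East/Central Asian), ≥0.83
(European); a two-way African/European admixture rule (African +
European ≥ 0.95 with African in [0.13, 0.75]); and a Hispanic rule
(Native American component ≥ 0.05 with a European component and ≤ 0.50
African — the Native American floor is our reconstruction of "nonzero").
Unassigned subjects and clusters under 20 members merge into "Other",
which is excluded from all allele-frequency statistics. All thresholds
are configurable through `cluster_thresholds()`.

## Ancestry-stratified frequency statistics

Allele counts per subpopulation use two alleles per called diploid
subject; on chromosome X outside the pseudo-autosomal regions males
contribute one. MAF classes: rare < 1%, common > 5%. Between-group
differences use the Pearson chi-squared test (no continuity correction)
when every expected cell exceeds 1, otherwise Fisher's exact test with
Monte-Carlo p-values: 10,000 tables drawn with fixed margins
(`r2dtable`), `p = (1 + #{P(table) <= P(observed)}) / (n_sim + 1)`, the
add-one correction keeping p > 0. Log-probability comparisons use a
1e-7 slack for floating-point ties. No multiple-testing correction is
applied by default (raw p < 0.05), matching the source analysis.

A **major/minor allele flip** requires the minimum group frequency below
0.5 and the maximum above 0.5, a one-sided Fisher test on the
min-vs-max 2×2 allele table, and each extreme differing from 0.5. The
"difference from 0.5" test is implemented as a one-sided exact binomial
test directed at the observed side — a one-sample question has no
standard two-sample Fisher construction; a Fisher variant against an
equal-sized pseudo-sample at 0.5 gives closely similar decisions and the
binomial reading is the sharper null. Pairwise significance is computed
on allele counts (not carrier counts), the more direct reading of an
allele-frequency comparison.

Group-specific common variants are those with frequency >5% in at least
one group and alt alleles observed in exactly one; reference-minor
positions are those with frequency >0.5 in every group.

## Variant-load profiling

A carried variant site counts once per individual whether heterozygous
or homozygous — per-site counting, chosen because the reported
per-person totals are described as variants, not alleles; an
allele-counting mode would be a one-line change in
`individual_profile()`. Per-gene load uses the gene's coding length:
the union across transcripts of exonic bases within CDS bounds. The
variants-per-kb rate is the OLS slope of per-gene variant count on
coding length (intercept included), and group contrasts use one-way
fixed-effects ANOVA on untransformed counts (no transform is specified
in the source); the gene-type contrast is the partial F-test of gene
type in `n_variants ~ coding_length + gene_type`.

## The synthetic cohort generator

Genotype-level data for the original cohort are not public, so
`generate_cohort()` builds a cohort with the statistical structure the
analysis assumes, plus complete truth tables. Defaults are the study
conditions: 681 subjects in seven subpopulations (43 African, 46
African-European, 50 Central Asian, 62 East Asian, 331 European, 118
Hispanic, 31 Other), 158 genes, 2,688 variant sites, per-gene coverage
centred on 58x within 21–84x, and a 2,000-marker ancestral panel (a
computational scale-down of the 16,443-marker panel; admixture recovery
is tested at exactly this size).

Sites fall into strata:

* **Rare stratum** — 65% singletons and 10% doubletons, planted by
  direct allele-count assignment (one or two random heterozygous
  carriers), because the calibration targets are empirical proportions,
  not a coalescent model.
* **Planted contrasts** — 21 allele flips (extreme-group frequencies
  drawn from [0.13, 0.28] and [0.62, 0.80]; the separation is chosen so
  the significance component has high power even when the smallest
  group carries the extreme), 14 reference-minor sites (all groups in
  [0.70, 0.95], high enough that sampling noise cannot pull a group
  below 0.5), and 58 group-specific sites weighted 49/2/6/1 toward the
  African/Central Asian/East Asian/European groups. These strata are
  parameterised directly at the subpopulation level so the planted
  contrasts are recoverable where the analysis measures them.
* **Background stratum** — the remaining sites get an ancestral mean
  frequency `m ~ 0.01 + 0.49 * Beta(0.8, 17.5)` with per-population
  log-normal tilts (sd 0.4), mixed through each subject's Dirichlet
  admixture vector; genotypes are binomial in the subject-level
  frequency, so within-group Hardy–Weinberg holds up to the (small)
  within-cluster admixture spread. The Beta scale is the one calibrated
  quantity: it was fixed, once, so that the expected post-filter load is
  ~68 carried sites per person under all the other defaults.

Quality fields emulate the platform's failure modes: Poisson total
depths at the gene's coverage, binomial allele splits (0.5%
cross-contamination reads), 0.5% baseline no-calls, 25 extra
low-call-rate sites (70% call rate), 15 extra systematically skewed
sites (heterozygote minor fraction 0.10, homozygote carried fraction
0.30 — failing the 0.295 position bound by construction), and a 0.2%
rate of low-depth (Poisson mean 5) genotypes planted on homozygous
reference calls, where they are recoverable by the depth filter without
disturbing carrier counts. Consequence truth is realised in sequence:
each variant's alleles are designed inside toy transcripts (2–5 exons,
plus strand) so that re-annotating the emitted VCF against the emitted
transcripts reproduces the per-variant category truth; in-frame
deletions remove a whole codon so no novel stop codon can form.
Deleterious categories (22 nonsense, 42 frameshift, 16 splice-site) and
in-frame indels sit mostly in the rare stratum, but a few nonsense and
splice-site sites are handed the largest background frequencies, and 12
of the 326 HGMD-like flags go to the very common planted sites — the
reported per-person class means (~2 deleterious, ~14 HGMD) are only
attainable when both classes contain some common alleles.

What the generator does **not** emulate: linkage disequilibrium, real
gene sequences or mutational signatures, X-linked sites (the hemizygote
counting rule is exercised by constructed fixtures and the published
chrX table row instead), minus-strand transcripts (exercised by
constructed mirrored fixtures), multi-allelic sites, and relatedness.
Passing tests therefore demonstrate correctness of the statistical
machinery under idealised sampling, not robustness to real-data
artefacts such as alignment bias or batch effects.

All randomness flows from one mandatory seed through fixed per-stage
sub-seeds, so any stage can be regenerated in isolation and
regeneration is byte-identical.

## Problem sizes and runtime choices

Unit tests run on reduced cohorts (≈400 sites, 40 genes, 300 panel
markers) chosen to keep the full suite under a few minutes while leaving
every code path exercised; the cohort-level validation runs the
full-scale defaults across 20 seeds, and the admixture-recovery,
translation-oracle (1,000 variants), Monte-Carlo-Fisher and flip null
(1,000 replicates) properties at their stated sizes. EM admixture on a
full 681-subject cohort converges in well under a minute; a complete
pipeline run on default synthetic data takes a few seconds per stage.

## Known limitations

* The flip criterion's "significantly different from 0.5" component is a
  reconstruction (see above); with counts rebuilt from rounded published
  frequencies, 19 of the 21 published flip rows pass the full criterion
  and all 21 pass the frequency component — exact printed p-values are
  not reproducible from rounded frequencies.
* Gene-level PolyPhen scores are taken per annotation-table row; the
  handling of conflicting transcript-level predictions in the source is
  unknown.
* The error-rate cross-validation evaluates fixed thresholds; it cannot
  reproduce the original attribute selection or tree induction.
* `min_carried_depth()` assumes diploid genotypes; hemizygous male X
  calls are handled in allele counting but not given a special depth
  rule.
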