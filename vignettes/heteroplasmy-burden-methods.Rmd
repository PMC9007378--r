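---
title: "Methods: mtDNA heteroplasmy burden analysis with mtburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA heteroplasmy burden analysis with mtburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtburden)
library(dplyr)
```

## The problem

Every human cell carries hundreds to thousands of mitochondrial DNA (mtDNA)
copies. A variant present on essentially every copy is a *homoplasmy*; a
variant carried by only a fraction of copies is a *heteroplasmy*, quantified
by its heteroplasmic fraction (HF) — the proportion of sequencing reads
supporting the alternative allele. Deep sequencing (around 1000-fold) makes
heteroplasmies quantifiable down to a few percent, but at that sensitivity
the call set is contaminated by sequencing and alignment artifacts,
homopolymer slippage, and nuclear-embedded mitochondrial segments (NUMTs)
that co-amplify and masquerade as low-level heteroplasmies. `mtburden`
implements the full analysis chain used in cohort studies of heteroplasmy
burden and disease: quality control of per-sample variant calls against the
rCRS reference, heteroplasmy classification and per-individual burden
aggregation, negative binomial disease-association regression, SKAT-O-style
region burden tests, and strand/replication-arc-resolved trinucleotide
mutational signatures — together with a synthetic cohort generator whose
truth labels make every stage testable without access to individual-level
study data.

## Reference model

Coordinates are 1-based rCRS positions ("m." convention) throughout; BED
interchange converts to 0-based half-open at the I/O boundary. The locus map
is the standard 37-gene annotation (13 protein-coding, 22 tRNA, 2 rRNA) plus
the D-loop, which wraps the origin (16024–16569 joined to 1–576). The 89
positions falling between annotations form a 39th region set, the intergenic
aggregate. Protein consequences use the vertebrate mitochondrial genetic
code; the nine genes read from the heavy strand (MT-ND6 and eight tRNAs) are
reverse-complemented before translation, and incomplete terminal codons are
completed with A, as polyadenylation does in vivo. A variant overlapping two
genes (MT-ATP8/MT-ATP6, MT-ND4L/MT-ND4) is counted non-synonymous if it is
non-synonymous in *any* frame — the conservative choice for burden counting.
The replication arcs are delimited by OriH at m.191 and OriL at m.5799;
since the delimiters themselves do not decide inclusivity, the package fixes
position 191 as minor-arc and 5799 as major-arc, so the two arcs partition
all 16,569 positions.

The packaged reference sequence (`inst/extdata/synthetic_rcrs.fasta`) is a
**synthetic stand-in**, not the real NC_012920.1: it reproduces the length,
the L-strand base composition, the N placeholder at position 3107 and the
D-loop poly-C tracts, but base identities elsewhere are random (built
deterministically by `synthetic_mt_sequence()`). All sequence-dependent
machinery — codon translation, trinucleotide contexts, homopolymer masking —
is exercised against this stand-in and validated by independent oracles in
the test suite; analyses of real data should load the genuine rCRS FASTA via
`mt_genome(path)`. Structural properties that do not depend on base
identities (locus boundaries, the 89-position intergenic aggregate, arc
geometry, codon-position arithmetic) are exactly those of the rCRS.

Homopolymer masking flags every run of five or more identical bases
(`min_run = 5`), plus any explicitly configured regions; the exact tract
list used by published pipelines is not standardised, so the mask is
configurable and the default is documented rather than inferred.

## Quality-control cascade

The filters run in pipeline order, each stage a pure subset of its input:

1. **Sample coverage** — samples retained only if more than 95% of the
   mtDNA has at least one read (strict inequality).
2. **Per-call read support** — depth ≥ 500×, ≥ 25 alternative reads in
   total *and* at least one on each strand, HF ≥ 5%.
3. **Homopolymer mask** — calls at masked positions removed.
4. **Cohort prevalence** — for each variant allele and study group, if more
   than 2% of the group's individuals carry it heteroplasmically
   (0.05 ≤ HF ≤ 0.95), the heteroplasmic calls at that site are removed
   within that group (cohort-wide removal available by switch); homoplasmic
   calls always survive this stage.
5. **Panel concordance** — homoplasmic variants (HF > 0.95) are removed
   when the cohort allele frequency differs by more than 0.9 from either of
   two reference panels (alleles absent from a panel count as frequency 0).
   Requiring discordance in *either* panel is the conservative reading.
6. **CV screen for NUMTs** (optional, off by default) — NUMT
   co-amplification produces pseudo-heteroplasmies with nearly identical HF
   in every carrier. The coefficient of variation of HF across
   heteroplasmic carriers is computed per site; sites in the bottom 25th
   percentile of the CV distribution are removed entirely. A carrier floor
   (default ≥ 3) keeps singleton sites out of the distribution — a
   percentile rule over all sites would otherwise remove a fixed quarter of
   everything. This screen is a robustness re-analysis, hence disabled
   unless requested.

On default synthetic cohorts the cascade removes essentially all injected
artifact calls (strand-biased calls fail stage 2, homopolymer calls stage 3)
while retaining over 95% of injected somatic variants, and the CV screen
removes all injected NUMT sites; these recovery rates are asserted in the
test suite against the generator's truth labels.

## Heteroplasmy classes and burden

Classes follow the conventional HF partition: low-level (5–10%),
intermediate (10–95%), homoplasmy (>95%). The interval endpoints are
resolved half-open upward — HF exactly 0.10 is intermediate and exactly
0.95 is homoplasmy — which keeps the three classes a partition and agrees
with the use of HF ≥ 95% for haplogroup-defining homoplasmies. Burden
tables count variants per sample by class and functional category
(non-synonymous, synonymous, tRNA, rRNA, D-loop, intergenic), zero-filling
samples without calls. The sharing spectrum classifies variant alleles as
singletons, shared by 2–10, or by more than 10 individuals (boundaries per
the stated classes: 10 carriers is "2–10"). Per-locus frequencies count
*distinct variant alleles* of each class per region set, divided by region
length; occurrences-per-call would conflate recurrence with carrier counts,
so distinct sites is the documented choice.

## Association models

Burden counts are modelled by negative binomial regression (NB2,
variance = mu + mu²/theta, log link), fitted by iteratively reweighted least
squares alternating with one-dimensional maximum likelihood for theta —
`MASS::glm.nb` is exactly this algorithm and serves as the engine; the test
suite cross-checks it against an independent full-likelihood optimiser.
When the data are equi- or under-dispersed the theta estimate diverges; the
fit then falls back to a Poisson GLM and is flagged rather than reported
silently. Covariates are age, sex, mean read depth and mitochondrial
ancestry, with treatment contrasts and documented reference levels
(control, female, European); models with optional covariates (blood
pressures, smoking) are complete-case. Each family of tests carries a
Bonferroni threshold alpha/m — echoed to one significant figure in
human-readable output (0.05/6 prints as 0.008; machine output keeps full
precision).

The accompanying comparison statistics are the field's standard ones:
Spearman rank correlation for cohort-vs-panel frequency concordance,
two-sample two-sided Kolmogorov–Smirnov tests of HF distributions against
the D-loop reference, Mann–Whitney U for conservation scores, and a two-way
fixed-effects ANOVA (group + heteroplasmy class, main effects) for
pathogenicity scores. Degenerate inputs (constant scores, single groups,
empty samples) raise explicit errors.

## Region burden tests

Regions are either the 39 annotated sets or sliding tiles (100 bp windows
every 10 bp, `bedtools makewindows` semantics, giving 1,657 tiles and a
Bonferroni echo of 3e-5; the 39 sets echo 0.001). Variants are coded as 0/1
heteroplasmy carriers — the analysis counts presence, not dosage (dosage
coding is available by flag) — weighted by Beta(1, 25) density on carrier
frequency, the de facto rare-variant default in the absence of a stated
scheme.

The region statistic is the optimal SKAT/burden combination:
`Q_rho = (1 - rho) Q_SKAT + rho Q_burden` over the grid
rho in {0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1}, with a logistic null
model absorbing covariates. Each `Q_rho` is referred to its weighted
chi-square mixture via modified moment matching (Liu-type), and the
combined p-value applies the standard one-dimensional integration over the
shared chi-square(1) component to the minimum grid p-value. Exact
eigenvalue (Davies) p-values are out of scope by design; instead the
approximation error is *bounded by test* against an in-package permutation
oracle that re-derives the whole statistic family from permuted null
residuals.

Two finite-sample points matter. First, with a binary phenotype the normal
approximation of the score vector is poor when variants have few carriers;
the test therefore rescales each mixture reference to the *exact* mean and
variance of `Q_rho` under residual permutation (closed-form moments of a
permuted quadratic form; the formulas are verified against exhaustive
enumeration in the tests). With this correction the moment-matching p
tracks the 100,000-permutation oracle to within 0.02 on instances with
roughly ten or more expected carriers per variant, and the null type-I
error at nominal 0.05 sits inside [0.03, 0.07] (n = 300, five variants,
1,000 null replicates). Second, in deep-null instances the min-p
combination can saturate at p = 1 while the discrete permutation estimate
tops out slightly below 1; the difference has no inferential consequence
and the oracle-agreement tests therefore probe the decision-relevant range.
Regions with no qualifying variants are reported as untested, never as
p = 1.

## Mutational signatures

Substitutions are reported under the pyrimidine convention: changes with a
pyrimidine reference on the deposited L strand stay as written; purine
reference changes are complemented and attributed to the heavy strand. Each
heteroplasmic call (HF window configurable: 5–95% overall, 5–10% for the
somatic stratum) contributes one count to its (substitution, 5' flank, 3'
flank, strand, arc) cell; contexts are read 5'-to-3' on the attributing
strand, so heavy-strand contexts are reverse complements of the L-strand
triplet, and contexts wrap the circular origin. Calls whose triplet touches
the position-3107 placeholder are excluded and counted in an attribute.

Replication-strand asymmetry is tested per substitution and strand with a
one-tail two-proportions Z test (pooled standard error), alternative
"greater in the major arc" — the direction predicted by strand-asymmetric
replication, in which the major arc spends longest single-stranded. The
multiplicity denominator for the reported threshold is the number of tests
actually run (12 by default: 6 substitutions × 2 strands), since no
canonical family size exists for this analysis.

## The synthetic cohort generator

The generator is first-class, tested code: it emulates the data structure
the pipeline consumes, with truth labels (`inherited`, `somatic`, `numt`,
`artifact`) on every call. Its defaults are the study conditions the
package is calibrated around:

* **Cohort** — cases and controls (default 1000/1000; the
  hypertension-style preset uses 700/360), ages uniform on 30–90 years,
  sex balanced, mitochondrial ancestry 94% European / 3% African / 3%
  Asian, per-sample mean depth Normal(1088, 90), 2% of samples with
  breadth of coverage below the QC threshold.
* **Inherited homoplasmies** — a pool of 60 haplotypes over 150 polymorphic
  sites; 5 near-universal backbone sites (every sample differs from the
  reference at them, as real cohorts do at a handful of rCRS-specific
  positions) plus a heavy-tailed number of lineage sites (negative
  binomial, dispersion 0.5), giving a per-individual mean of 9 homoplasmies
  with SD near 6. HF is drawn from 0.95 + 0.05·Beta(8, 1).
* **Somatic heteroplasmies** — per-sample Poisson counts with log-linear
  rates: the low-level (5–10%) rate carries the age slope 0.02 per year;
  the intermediate (10–95%) rate carries the case-control effect 0.27
  (log scale), with the non-synonymous component at 0.28 realised by a
  small placement bias of case variants toward non-synonymous sites.
  Intercepts are calibrated analytically so the pooled per-individual
  means are 0.3 (low) and 1.3 (intermediate) after accounting for the
  expected NUMT and artifact contributions and the case mix — so the
  marginal means are invariant to the configured cohort composition. HF
  shapes are Beta draws rescaled to the class windows: Beta(2, 2) on
  (0.05, 0.10), and Beta(1.6, 1.1) on (0.10, 0.95), placing the mean
  heteroplasmic HF near 0.6; the class boundaries and means are the
  constrained quantities, the shapes a documented choice.
* **Signature structure** — 99.8% of heteroplasmic variants are
  transitions. Among somatic transitions, 80% are the replication-
  asymmetric pair (C>T on the heavy strand / T>C on the light strand),
  drawn with a major-arc odds multiplier of 4; the remaining transitions
  split between the mirror types, placed by reference-base availability.
  The odds multiplier was chosen so the documented asymmetry is detectable
  at the 0.003 threshold with power above 0.8 at the cohort sizes the
  package targets (≥ 500 somatic heteroplasmic calls), emulating the
  pronounced asymmetry seen in blood mtDNA; position draws are uniform
  within (reference base × arc) strata — the simplest mechanism consistent
  with a context-level spectrum.
* **NUMT pseudo-heteroplasmies** — 8 fixed sites, carrier probability
  0.005 per sample, site-level shared HF uniform on (0.10, 0.30) with
  per-carrier jitter SD 0.005. Contamination is kept small deliberately:
  a case-independent additive NUMT baseline attenuates the fitted
  case-control coefficient below the preset value, and the defaults keep
  the analytically expected attenuation (to about 0.26 from 0.27) inside
  the recovery tolerance the package asserts. Placing the shared HF above
  0.10 keeps the low-level class free of NUMT contamination, so the age
  slope is recovered essentially unattenuated.
* **Artifacts** — 0.05 expected calls per sample: 60% in homopolymer
  tracts, 40% strand-biased (all alternative reads on one strand), HF
  uniform on (0.05, 0.15). Both kinds are removed by the cascade's
  per-call stages, which is what the truth-conditioned recovery tests
  assert.
* **Panels and scores** — two panel tables track cohort homoplasmy
  frequencies with Normal(0, 0.03) noise, except a configured 1% of
  polymorphic sites displaced by more than 0.9 to exercise the concordance
  filter. Conservation scores are Beta(3, 1.5) for coding and Beta(1.2, 3)
  for D-loop sites; pathogenicity scores mark 25% of non-synonymous
  variants as high-pathogenic (≥ 0.7), preferentially at lower HF
  (weight (1 − HF)²), emulating purifying selection.

One seed governs everything through a single root generator
(`withr::with_seed`), so a cohort is byte-identical across runs.

What the generator does *not* emulate: read-level errors (generation starts
at the variant-call level), haplogroup phylogenetic structure (sites are
exchangeable within a haplotype; there is no tree), linkage between somatic
variants, position-specific mutational hotspots beyond the base/arc strata,
and depth heterogeneity along the molecule. Passing tests therefore
demonstrate that the *machinery* recovers known effects under the stated
statistical structure — not that real blood mtDNA satisfies that structure.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately modest sizes
chosen as representative desk-scale versions of the analysis: recovery runs
use 20 replicate cohorts of 1,060 (case-control preset) or 2,000 samples;
calibration checks use single cohorts of 2,000; null calibration of the
region test uses 1,000 simulations at n = 300; oracle comparisons use
100,000 permutations on instances of n = 150–300. Recovery assertions use
±2 empirical standard errors of the replicate mean — the natural sampling
band for a 20-replicate mean. Ties in rank statistics use average ranks;
KS and Mann–Whitney p-values are asymptotic with tie correction; quantiles
use R's default type 7. Eigenvalues below 1e-10 of the largest are treated
as null space; SKAT-O integration runs over (0, 40) with the combined p
floored at the Bonferroni-combined minimum of the grid.

## Known limitations

* The packaged reference is a labelled synthetic stand-in; real-data runs
  must supply the genuine rCRS FASTA (and should supply a curated
  homopolymer exclusion list if one is mandated by the study protocol).
* The region test's moment approximation is accurate down to roughly ten
  expected carriers per variant; below that, use the permutation oracle
  directly.
* The CV-based NUMT screen presumes several heteroplasmic carriers per
  site; in small cohorts most sites fall below the carrier floor and the
  screen is conservative (it removes nothing it cannot assess).
* Mixed models, per-site association, indels and non-rCRS references are
  out of scope.

## A worked run

```{r pipeline, eval = FALSE}
cohort <- generate_cohort(simulation_config(n_cases = 700, n_controls = 360), seed = 1)
report <- run_pipeline(cohort, run_regions = TRUE)
report$associations
ggplot2::autoplot(report$signature)
```
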