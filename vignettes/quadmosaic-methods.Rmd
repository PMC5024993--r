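---
title: "Methods: mosaic and de novo mutation analysis in quad families"
author: "quadmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mosaic and de novo mutation analysis in quad families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadmosaic)
```

# Overview

`quadmosaic` analyses de novo variation in quad families (father, mother,
affected proband, unaffected sibling) with explicit attention to
post-zygotic — *mosaic* — mutation. This vignette documents the models and
procedures, the parameters that matter and why their defaults were chosen,
what the synthetic-data generator does and does not emulate, and the
numerical and design decisions taken where the problem was genuinely open.

# Trio de novo calling

A de novo call for a (site, child) pair requires, jointly:

* the most-likely genotype of each parent excludes the alternate allele
  while the child's includes it;
* total depth ≥ `min_trio_depth` (default 20 reads) in child, father and
  mother;
* child alternate-supporting reads ≥ `min_child_alt_reads` (default 3);
* phred-scaled confidence ≥ `min_child_presence_phred` (default 20) for
  presence in the child and ≥ `min_parent_absence_phred` (default 20) for
  absence in each parent;
* at most `max_carriers_in_cohort` (default 2) individuals — parents and
  children across all families — genotyped with the allele, suppressing
  recurrent artifacts and undercalled inherited variation.

**Likelihood-gap reading of "phred-scaled confidence".** Callers export
per-genotype phred-scaled likelihoods (PL) but the confidence that a tool
derives from them is rarely specified. We operationalise presence in the
child as `PL(hom-ref) − min(PL over allele-carrying genotypes)` and absence
in a parent as `min(PL over allele-carrying genotypes) − PL(hom-ref)`, each
compared to its threshold. This is the natural likelihood-ratio reading; it
reduces to the genotype-quality field in the common case where the best
genotype has PL 0.

Families in which any child exceeds `family_exclusion_threshold` (default
10) de novo calls are removed wholesale — both children — since such an
excess almost always reflects sample swaps, contamination or poor joint
genotyping rather than biology.

Multi-allelic sites are expected to be decomposed into per-allele records
upstream; all internal logic is biallelic.

# Mosaic classification

For a call with alternate depth $k$ of total depth $n$, the mosaic evidence
is the exact lower binomial tail
$p = P(X \le k \mid n, p_0)$ with $p_0 =$ `expected_fraction` (default 0.5,
the diploid heterozygous expectation). P-values are adjusted with the
Benjamini–Hochberg step-up procedure **jointly across the whole callset**
(probands and siblings together; no stratification is applied because none
is justified a priori), and a call is labelled mosaic iff

* `q < fdr` (default 0.05), and
* AARF `< aarf_max` (default 0.34).

The AARF gate exists because capture and alignment favour the reference
allele: at high depth, a genuinely germline heterozygote with AARF ~0.40
can reach arbitrarily small binomial p-values and masquerade as weak
mosaicism. Bounding mosaic calls below 34% AARF trades sensitivity for
high-cell-fraction mosaics against precision, which read-backed phasing
shows to be the right trade (restricting to low AARF raises mosaic
classification precision — the package's acceptance tests reproduce this
pattern on synthetic data).

Ties in p-values are handled by the standard cumulative-minimum step-up
with no randomisation. The same depth convention is applied to SNVs and
indels: the binomial test always uses the call's reported alternate and
total depths.

An optional confirmation step (`intersect_confirmation()`, or the
`confirmed` argument of `classify_mosaic()`) mirrors the requirement that a
mosaic call also appear in an independent callset: unconfirmed mosaic
candidates are dropped from the final callset, while germline-labelled
calls are not subjected to the filter (a `strict-all` usage is possible by
passing every call through `intersect_confirmation()` first).

# Read-backed phasing

Reads spanning a de novo site and a linked inherited heterozygous variant
within ±500 bp are tabulated into four configurations (inherited allele ×
de novo allele). Let X be the inherited allele observed together with the
de novo allele at ≥ `min_support` reads:

* **mosaic** iff the (X, de-novo-absent) configuration also reaches
  `min_support` — three distinct parental haplotypes are then observed;
* **germline** iff the de novo allele co-segregates perfectly with X;
* **uninformative** when the de novo allele rides on both inherited
  backgrounds at support (inconsistent phasing, e.g. through an
  alignment artifact) or no configuration reaches support.

`min_support` defaults to 2 reads: a single read is compatible with a
sequencing or alignment error, so two is the minimal defensible reading of
"multiple reads per haplotype"; it is an exposed parameter. Reads with base
quality below Q20 at either site are dropped before counting — the
procedure's accuracy rests entirely on individual base calls, so a
conventional quality floor is applied; this too is exposed.

The estimated fraction of cells carrying the variant is
`(X ∧ alt) / ((X ∧ alt) + (X ∧ ref))` — the fraction of mutant-haplotype
reads carrying the variant, interpreted under heterozygous mosaicism in a
diploid region (no copy-number correction). Parental origin is the parent
contributing haplotype X, resolvable only when the linked het is present in
exactly one parent; hets carried by both parents are skipped as
origin-ambiguous by `select_informative_het()`, which returns the nearest
eligible candidate (ties break to the upstream site).

# Validation bookkeeping

Two precisions are distinguished. **Detection precision** — the fraction of
assay-successful validations confirming the variant present — measures
whether called variants are real. **Classification precision** — among
informative validations, the fraction confirming the predicted
mosaic/germline label — measures whether real variants are correctly
classed. `summarize_validation()` reproduces the standard table layout
(chosen / success / present / detection precision / label-confirmed /
classification precision) from per-variant outcomes;
`expand_validation_cells()` inverts a table's integer cells into an outcome
list so published ratios can be re-derived exactly. Ratios are kept at full
precision and rounded only for display.

# Mutation rates

Rates are measured only where a de novo call was possible: inside the
four-way intersection of child, father and mother ≥ 40x coverage regions
with the capture target (`joint_region()`), then extrapolated linearly,
`count × capture_length / joint_length`, to the full capture
(`mutation_rate()`). Children with an empty joint region are excluded with
a warning. Interval arithmetic uses 0-based half-open coordinates (the BED
convention) through GenomicRanges; variant records are 1-based (the VCF
convention).

The proband/sibling comparison uses group means with normal-approximation
95% confidence intervals and a one-sided label-permutation test on
per-child extrapolated counts (10,000 permutations under a fixed seed,
exhaustive enumeration when the assignment count is small). The choice of a
permutation test is a documented stand-in — the comparison test behind
published p-values of this kind is typically unstated — so printed
p-values from other studies are not comparison targets for this package.

# The contribution model

Observed classified rates mix the two true classes. Writing $\varepsilon_c$
for the error rate of classified class $c$ — the fraction of class-$c$
calls that are truly the other class, measured by phasing validation
separately per cohort — the true sibling (baseline) rates are

$$B_m = O^s_m(1-\varepsilon^s_m) + O^s_g\,\varepsilon^s_g,\qquad
  B_g = O^s_g(1-\varepsilon^s_g) + O^s_m\,\varepsilon^s_m,$$

and the proband true totals $T_m, T_g$ are the same combinations of
proband observations and proband error rates. The contributory rate of
class $x$ is $C_x = T_x - B_x$; $100\,C_x$ is reported as the percentage of
cases attributed to that class (the expected-count reading; a Poisson
$100(1-e^{-C})$ variant is available and agrees to first order at small
$C$), and $C_x/T_x$ is the contributory fraction. The model is exactly
invertible — re-substituting the solution through the forward
misclassification map reproduces the inputs to machine precision, which the
test suite asserts — and negative point estimates, possible under sampling
noise, are reported as-is with a warning rather than clipped, leaving the
credible interval to communicate uncertainty.

For the stacked decomposition of each *classified* class's proband excess
into correctly and incorrectly classified parts, the baseline is mapped
forward through the proband error rates (a 2×2 linear solve with
determinant $1-\varepsilon^p_m-\varepsilon^p_g$) and the excess over it is
split by $\varepsilon^p$.

**Credible intervals.** Each error rate gets a Beta posterior from its
validation counts — Beta(k+1, n−k+1) under the default uniform prior; a
Jeffreys option (k+0.5, n−k+0.5) is exposed since the prior behind
published beta-binomial treatments is usually unstated and the choice
matters at small n. 10,000 draws re-solve the model; the 2.5th/97.5th
percentiles form the interval. Only the error rates are resampled; the
observed rates are held fixed, matching the published procedure this
mirrors. A bootstrap over children would be a natural extension but is
deliberately not the default, to keep the interval's meaning aligned with
the procedure it reproduces.

Per-cohort validation counts are accepted as inputs
(`classification_errors()`) rather than hard-coded: aggregate published
tables do not split probands from siblings, and any real application will
have its own phasing results.

# Gene-length null models

Under the null, each mutation lands in a gene with probability proportional
to its capture-targeted length (`targeted_gene_lengths()` merges
overlapping coding intervals and intersects them with the capture BED).
`recurrence_test()` draws the observed number of mutations with replacement
10,000 times and counts genes hit ≥ 2; its p-value uses add-one smoothing,
$(1 + \#\{\text{sim} \ge \text{obs}\})/(1 + n_{sim})$, so a simulation
p-value is never exactly zero. `gene_set_enrichment()` compares the
observed number of set genes harbouring mutation against the
length-implied expectation with a two-sided exact binomial test
(minimum-likelihood two-sidedness, the convention of `binom.test`);
gene-level counting is the default, with a mutation-level flag, the two
differing only when one set gene is hit repeatedly.
`conservation_compare()` is a Wilcoxon rank-sum test with a
Hodges–Lehmann location-shift estimate, applied to any per-variant
annotation (base-level conservation scores, 0–31 taxonomic conservation
levels, constraint probabilities); annotation acquisition is out of scope
and annotations are consumed as tables.

# In-silico read mixing

`mix_and_subsample()` implements the mixing contract used for sensitivity
evaluation: per region, the source-A read count is binomial at the
specified fraction (or a uniform random fraction per region), totals hit
the target depth, and sampling is without replacement within each source.
Read pairs are sampled as units by default — both mates kept or dropped,
the conservative choice for downstream realignment — so realized depth may
exceed the target by at most one read per source; single-read sampling is a
flag. Realized per-region depths and fractions are reported alongside the
reads, and `evaluate_sensitivity()` bins caller output by simulated allele
fraction. No external variant caller is bundled; tests exercise the
contract with a simple threshold caller on pileup tables.

# The synthetic cohort generator

The generator (`generate_cohort()`) emulates the *read-count structure* of
a large family whole-exome study:

* **Depth**: negative binomial with mean `depth_mean` = 94.6 reads — the
  mean coverage at de novo sites in the study setting this package
  addresses — and size `depth_dispersion` = 10, giving the overdispersion
  real capture data shows (a coefficient of variation ~0.33 at this mean);
  only the mean is dictated by the emulated setting, the dispersion is the
  package's own realism choice.
* **Rates**: `germline_denovo_rate` = 1.0 and `mosaic_rate` = 0.06 per
  child exome, matching roughly one coding de novo mutation per exome of
  which ~5–6% are detectably mosaic; proband excesses
  `contributory_mosaic_rate` = 0.051 and `contributory_germline_rate` =
  0.056 plant the contributory variation the model estimates.
* **Cell fractions**: uniform on (0.1, 0.7) by default. The emulated
  setting reports no cell-fraction distribution; this default spans
  undetectably low to AARF-gate-straddling high fractions so that
  classification error is realistically present on both sides.
* **Reference bias**: alternate reads are drawn at
  `(cell_fraction/2)(1 − reference_bias)` with `reference_bias` = 0.05.
  The direction is well documented (capture and alignment under-represent
  non-reference alleles) but unquantified in the emulated setting; 0.05 is
  a tunable guess of the right order.
* **Genotype likelihoods**: a symmetric per-read error model with
  ε = 0.001 — per-read alternate probabilities (ε, 0.5, 1−ε) for the three
  diploid genotypes, binomial kernel, rescaled so the best genotype is 0.
  Non-carrier alternate reads are drawn at the same ε. The likelihood
  model deliberately assumes the diploid heterozygous expectation even
  though mosaic carriers violate it: that mismatch is exactly what makes
  low-fraction mosaics hard for germline callers, and the generator
  reproduces it.
* **Phasing reads** (`generate_phasing_reads()`): each read draws a
  parental haplotype fairly; on the mutant haplotype the de novo allele
  appears with probability equal to the cell fraction; reported alleles
  flip with ε; base qualities are high (Q25–40). At least one linked
  inherited het is planted within ±500 bp of every de novo variant
  (`inherited_het_density` controls how many).
* **Coverage tracks** (`generate_coverage_tracks()`): piecewise-constant
  negative-binomial depth over segments tiling the capture region, in the
  BedGraph idiom.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: alignment and mapping artifacts (the dominant
source of real false positives), GC- and target-level capture effects,
correlated errors between family members, multi-allelic sites, indel
realignment ambiguity, tissue-specific mosaicism (not detectable at exome
depth in the emulated setting), and joint-genotyping batch effects. Tests
against the generator establish that the *statistical logic* is correct
under the stated read model, not that the pipeline is robust to every
artifact class of a production callset.

Determinism: every generator function is a pure function of its
configuration's seed (phasing read sets and coverage tracks derive
per-object seeds from the cohort seed, position and family index), so
identical configurations reproduce byte-identical outputs; the pipeline
derives stage seeds from the single run seed by fixed offsets.

# Numerical and degenerate-input choices

* Exact binomial tails come from `pbinom`; BH from `p.adjust` — both are
  cross-checked in the test suite against direct-summation and from-scratch
  step-up oracles at 1e-12.
* Genotype-likelihood ties (possible at depth 0) resolve to the lower
  alternate dosage, i.e. in favour of the reference.
* `abhet()` and the precision functions refuse zero denominators rather
  than returning NaN.
* All-zero phasing observations are uninformative, never errors.
* Empty joint regions exclude the child with a warning rather than
  propagating division by zero.
* Permutation p-values use ≥-with-tolerance (1e-12) comparisons so
  floating-point ties count as exceedances, the conservative direction.

# Problem sizes in the test suite

The suite exercises cohorts of 20–1,200 families depending on what the
property needs: oracle-equality checks run at 40–60 families, the
Poisson-consistency and null-calibration checks at 1,000–1,200, rate-level
contribution recovery and interval-coverage studies at 2,000 families × 60
and 200 replicates, and the end-to-end pipeline demo at 200 families.
These sizes were chosen so each check's Monte-Carlo error is small relative
to the tolerance it asserts. The acceptance script runs the full pipeline
at 1,000 families with 10,000 credible-interval draws.

# Known limitations

* Detection sensitivity for mosaics falls steeply below ~20% cell fraction
  at exome depth under a diploid genotyping model; cohort-level mosaic
  rates are therefore rates of *detectable* mosaicism. Contributory
  *fractions* are insensitive to uniform detection loss (it cancels in
  C/T), but contributory *rates* are not.
* The contribution model treats classification error rates as the only
  resampled uncertainty; observed-rate sampling noise widens the true
  error beyond the credible interval at small cohort sizes.
* The phasing verdict assumes a diploid region; copy-number variation at
  the site invalidates both the verdict and the cell-fraction estimate.
* Gene-level enrichment counts distinct genes but tests against a
  per-mutation binomial, a slight mismatch when one gene is hit many
  times; the mutation-level flag removes the mismatch at the cost of the
  less natural "genes harbouring mutation" reading.
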