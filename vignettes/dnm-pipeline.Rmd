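---
title: "Calling, calibrating and phasing de novo mutations in families"
author: "dnmtrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling, calibrating and phasing de novo mutations in families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmtrio)
```

## The problem

A de novo mutation (DNM) is a variant carried by an individual but by
neither parent's germline.  In deep short-read data, candidate DNMs are
rare (on the order of dozens per genome) while genotyping artifacts that
mimic them — allele-balance-skewed miscalls, 8-oxoguanine (oxoG) damage,
mapping noise — are plentiful, so naive trio subtraction has an
unacceptable false-positive rate.  This package implements a
family-based strategy: extract candidates from trios with strict
read-level filters, then *calibrate* the calls with an orthogonal,
genome-wide biological assay — the transmission of the candidate allele
from the proband to two or more of the proband's own offspring in
three-generation families.  A true germline DNM sits on one of the
proband's haplotypes, so exactly the offspring inheriting that haplotype
must carry it; artifacts segregate with neither haplotype.  The
resulting consistent/inconsistent labels train a classifier that scores
*every* candidate, including those outside three-generation families.
High-quality DNMs are finally assigned a parent of origin by haplotype
sharing and by read-pair tracing to phased markers, and validated by
monozygotic-twin concordance.

## Candidate extraction

Allelic balance (AB) is the fraction of alternative-allele reads out of
ref+alt reads.  A trio candidate (proband mean coverage strictly over
20x) must satisfy all of: proband carries the alt allele (hom-alt calls
tolerate at most one reference read); proband depth at least 12 and
AB at least 0.15; each parent with depth at least 12 (6 for the father
at X sites of male probands, where he is hemizygous), at most one
alt-supporting read and AB at most 0.05; at most 10 *possible* and 3
*likely* carriers beyond the descendants of the parent pair; and a mean
soft-clipped fraction of at most 10% over reads covering the site.
Probands with more than 10% genome-wide average soft clipping, more
than 1.5% average N fraction, or more than 300 candidates are dropped
entirely.

Two wordings are deliberately preserved from the procedure this
implements: candidate depth bounds are *inclusive* ("minimum depth of
12"), while the likely-carrier definition is *strict* (depth over 12,
AB deviation from 0.5 below 0.25, genotype quality over 20).  The
inequality directions are applied exactly as documented; boundary
values are covered by table-driven tests.

"Descendants of the parent pair" means individuals descending from
*both* members of the couple — the couple's children and their
descendants — not half-siblings through one member.  The purpose of the
exclusion is to excuse relatives who could legitimately inherit the
DNM; the couple-descendant set is the conservative, simply-defined
choice, and a brute-force transitive-closure oracle checks the
implementation on randomized pedigrees.

## The transmission assay

For candidates in probands with two or more sequenced offspring, each
offspring is assigned the proband haplotype it inherited at the site
(paternal- or maternal-of-proband, an input derived from IBD sharing).
Offspring calls are treated as missing below 10 reads of depth, and
alt-supporting calls additionally require at least 2 alt reads with AB
of at least 0.1, so low-quality offspring genotypes cannot create
spurious inconsistency.  A candidate is *evaluable* when at least two
non-missing offspring cover both proband haplotypes; it is *consistent*
when one haplotype exactly two-colors the carriers.  On the X
chromosome a male offspring carrying the allele without being
homozygous-alt is biologically impossible for a germline variant and
forces inconsistency.  The implementation's set logic is tested against
an exhaustive enumeration over both haplotype assignments for all
family configurations with up to six offspring.

## The classifier

The labels feed a binomial generalized additive model (logit link):

Y ~ s(proband AB) + s(FoxoG) + s(Trio-NPOSS) + GATK-filter

with penalized cubic regression splines (10 basis functions per smooth,
smoothing selected by generalized cross-validation; the fit is
delegated to mgcv).  FoxoG quantifies oxoG strand bias: it is 0 for
substitutions other than C>A, and for C>A the fraction of alt
read pairs in the artifact-prone F2R1 orientation; G>T sites are
treated as reverse-complement C>A with the orientations swapped, a
documented interpretation of the "non-C>A" convention.  Trio-NPOSS is
the count of *possible* carriers beyond the couple's descendants — the
covariate is defined through possible (not likely) carriers and enters
untransformed.  Candidates without an evaluable label are excluded from
training only; the fitted model then scores every candidate, training
ones included.  A candidate is high quality when its response is
*strictly* greater than 0.8.

Two numerical guards matter in small cohorts: a smooth's basis is
reduced when its covariate has fewer unique values than the basis
requires (Trio-NPOSS is small-integer-valued), and covariates with
fewer than four unique values enter linearly.  Tests assert
classification behaviour (held-out AUC, separation of the response
histogram, leakage past the cutoff), never spline coefficients, which
are legitimately implementation-dependent.

## Parent-of-origin phasing

Two independent methods are reconciled:

* **Three-generation haplotype sharing.**  An offspring carrying the
  DNM on the proband's paternal haplotype votes paternal; a non-carrier
  on the paternal haplotype votes maternal (and symmetrically).  Votes
  count only when the shared segment covering the site spans at least
  0.8 cM and 200 consecutive panel markers; carrier status reuses the
  transmission-assay missingness rules.  Unanimity gives the origin,
  any conflict gives unphased.
* **Read-pair tracing.**  Read pairs physically joining the DNM *alt*
  allele to phased marker alleles of known parental origin assign the
  DNM to a parental chromosome.  Only alt-bearing pairs vote:
  ref-allele pairings, pairs supporting three or more haplotypes and
  markers of unresolved origin contribute nothing.  A DNM is phased
  only with single-sided support — at least one supporting pair
  (configurable) on one side and strictly zero on the other, a literal
  reading of "read support for only one parent of origin" rather than
  a ratio test.
  Markers within 5,000 bp of the DNM are eligible by default.  The
  neighborhood is an artifact choice: it matches the span over which
  the simulator generates physical linkage, and on real data it should
  be set to the sequencing fragment length.

The consensus keeps agreeing calls, takes the single phased method when
only one fires, and *discards but counts* contradictions.  The summary
obeys the exact set identity consensus = three-gen + read-pair − both −
discordant, which the tests assert on arbitrary inputs.

## Validation reports

Monozygotic-twin concordance treats twin calls as missing below depth
10 (het calls additionally need 2 alt reads and AB ≥ 0.1); a DNM is
discordant when the twin call is verifiable and lacks the allele.
Hom-alt twin calls count as concordant carriers: the check verifies
presence or absence of the allele, not the exact genotype.  Discordance
is reported both pooled over verifiable DNMs (count-weighted) and as
the mean of per-twin fractions, since either convention is defensible.
Variant summary tables stratify by SNP/indel and biallelic status with
GATK-pass, phase-score and imputation-information columns, and the
phasing comparison reports the both-phased discrepancy fraction.

Sample-level QC applies nine lane-metric rules (mean base quality below
25; percent duplicates above 50; mean N per read above 30; percent
MAPQ<20 above 11; any of four unmapped-percentage categories above 40;
chip-concordance mismatch rate above 2%), a contamination surrogate
(fraction of heterozygous marker pairs with two or more read pairs
supporting a third haplotype, excluded above 0.1%), and parent-child
confirmation by haplotype sharing.  The confirmation threshold, 0.45 of
the autosomal map on one haplotype, is an artifact decision: true
parent-child pairs sit near 1.0 and second-degree relatives well below,
so the exact value is uncritical; it is configurable.  The imputation
information measure is the ratio of the variance of imputed expected
allele counts to p(1−p), computed per haplotype with the population
variance (divide by n) — the large-sample estimator; it is 1 for
perfect dosages, 0 for frequency-only dosages, and a² for dosages
attenuated toward the frequency by a factor a.

## The simulator

`simulate_dataset()` generates every input the pipeline consumes, with
truth: a toy genome of two 10 Mb autosomes, uniform 1 cM/Mb, phased
markers every 2 kb; three-generation families (founder couple, proband,
unrelated spouse, 2–3 offspring) with optional MZ co-twins; gametes by
Haldane recombination (Poisson crossover count, uniform positions, no
interference); germline DNMs per gamete at Poisson rate 4 (default),
paternal fraction 0.75 — a simulator default for exercising phasing,
*not* an asserted biological value; artifact sites with Beta(2,8)
allelic balance (mean 0.2), half of them oxoG-type C>A/G>T with 95:5
orientation skew; read depth Poisson(34); genotype calls and qualities
derived from the simulated read counts by maximum-likelihood genotyping
at 1% error; read-pair linkage counts with a 0.5% tracing error; and a
3% post-twinning (somatic) DNM fraction.  Planted QC failures (bad
lanes, contaminated samples, excess-soft-clip probands, parent-child
sample swaps) are off by default and switched on per test.

What the simulator does **not** emulate: realistic mutation spectra and
rates (the toy genome is ~1% of a human genome, so per-proband counts
are set for statistical power, not realism), indels (all planted sites
are SNVs), the X chromosome (X-specific filter and transmission rules
are exercised by constructed fixtures instead), linkage disequilibrium
or population structure in the marker panel, and imputation-panel
construction.  Passing tests therefore demonstrate the correctness of
the decision rules and the recoverability of planted signal under the
assumed noise model — not performance on real cohort data.

## Problem sizes and determinism

The test-suite and acceptance computations use a 120-family cohort
(about 780 individuals, roughly 1,000 planted DNMs and 2,200 planted
artifacts yielding over 2,000 post-filter candidates), a 40-family
error-free phasing control, and a 50-twin-pair cohort — sizes chosen so
every stochastic check has comfortable statistical margin while a full
run stays in the minutes range on one core.  All randomness flows from
a single seed in `sim_config()`; the pipeline itself is deterministic,
and re-running with the same seed reproduces every output file byte for
byte.

## Degenerate inputs and edge policies

Zero informative reads make AB undefined: such candidates are skipped
and counted, never called.  A parent with no evidence row renders the
trio unevaluable at that site (logged), rather than silently passing.
An empty variant set flows through the whole pipeline and yields valid
empty outputs.  A training set with a single transmission class aborts
the GAM stage with the stage name — scoring without contrast would be
meaningless.  Response exactly at the cutoff is *not* high quality.
Twin checks with nothing verifiable report `NA` discordance, and the
phase comparison reports an undefined discrepancy when no DNM was
phased by both methods.
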