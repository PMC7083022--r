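---
title: "Methods: candidate-SNP case-control association with genassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-SNP case-control association with genassoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genassoc)
```

## Scope and model

`genassoc` analyses a small panel of biallelic candidate SNPs in a
case-control cohort. Every association statistic in the package reduces to
a 2x2 contingency table whose orientation is fixed throughout: group 1
(cases, or the first-listed clinical class) in the first row, the tested
genotype category ("exposed") in the first column, the reference category
in the second. Under this convention the odds ratio reads as the odds of
carrying the tested category among cases relative to controls, and all
published two-group genotype tables we have re-analysed reproduce without
sign flips.

### Inheritance models

Genotype counts (reference homozygote, heterozygote, alternate homozygote)
collapse into contrasts in five ways: codominant (heterozygote vs
reference homozygote, and alternate homozygote vs reference homozygote,
each reported with its own p-value rather than a pooled 2-df test),
dominant, recessive, overdominant, and allelic, in which each subject
contributes two alleles to a per-allele 2x2. The allelic contrast is the
package's rendering of an "additive" test on counts; a Cochran-Armitage
trend test (`trend_test()`) is available as a genuinely score-based
additive alternative, but it is an extra — the tabulated analyses use the
allele-count contrast.

### Odds ratios: Woolf and Gart

The Woolf interval is computed on the log scale with standard error
`sqrt(1/a + 1/b + 1/c + 1/d)` and the exact 97.5% normal quantile
(1.9599640), not the rounded 1.96; at two-decimal display precision the
difference is visible in extreme intervals (upper bounds in the hundreds).
When any cell is zero the Gart-adjusted logit interval adds 0.5 to **all
four** cells — not only the zero ones — for both the point estimate and
the interval. A table with an entire zero row or column has no defined
odds ratio and is rejected; in the pipeline, contrasts whose tested or
reference category is empty in both groups are dropped rather than forced
through the adjustment.

Tests of independence use the uncorrected Pearson chi-square; no Yates
correction is applied anywhere, because the tabulated p-values we
reproduce (e.g. 0.049 and 0.0465 in the bundled example) are recovered
only without it. Fisher's exact test and the pooled-variance Student
t-test (for descriptive variables) delegate to `stats::fisher.test()` and
`stats::t.test()`; both are cross-checked in the test suite against
explicit enumeration and hand-computed closed forms.

### Hardy-Weinberg testing

`hwe_test()` reports both the classical 1-df chi-square against expected
counts `(np², 2npq, nq²)` and the exact conditional test on the
heterozygote count given the allele counts (summing the probabilities of
all configurations no more probable than the one observed). Both are
reported because published candidate-gene papers rarely state which was
used, and the two can disagree noticeably: the exact test is conservative
and converges slowly, so at cohort sizes in the hundreds, p-values from
the two tests routinely differ by more than 0.02 even under equilibrium.
In the bundled example the case-group value for rs1801133 matches both
tests (p ≈ 0.47) while the near-monomorphic rs1799782 matches only the
exact test (p = 1.00 vs chi-square ≈ 0.76); several of the published
control-group values, in fact, coincide with the exact test. By
convention, equilibrium is assessed for both groups but only the
control-group result should gate marker inclusion. Monomorphic markers
return p = 1 with a warning instead of an error so that marker loops
continue.

### Two-locus haplotypes and LD

For two biallelic loci, only the double heterozygote is phase-ambiguous,
so `em_two_snp()` implements the standard EM: unambiguous cells are
resolved into gametes once, and each E-step splits the double
heterozygotes between the cis and trans configurations in proportion to
their current expected frequencies. Initialisation is at linkage
equilibrium (products of observed allele frequencies), convergence is
declared when the largest frequency change falls below `tol = 1e-10`
(`max_iter = 1000`), and the log-likelihood is asserted non-decreasing at
every step. The all-double-heterozygote sample is a known saddle case: at
50/50 allele frequencies the equilibrium initialisation is exactly the
uniform fixed point and the EM remains there, which is the honest answer
given that the data carry no phase information at all.

`ld_from_haps()` computes `D = p11 - pA*pB`, normalises by the attainable
bound to give |D'| (with the sign of D carried separately, matching the
convention of the common web calculators), and `r² = D²/(pA qA pB qB)`.
Monomorphic margins make D' and r² undefined and they are returned as
`NA`, not 0.

Haplotype case-control contrasts use the most common haplotype in the
pooled sample as reference, with ties broken lexicographically on the
label so the choice is deterministic. Haplotype counts can be supplied
verbatim (the path used for the bundled published tables, whose counts
come from an external phasing of a reference panel) or estimated from
cohort genotypes via the EM.

## Pipeline behaviour

`run_snp_association()` analyses complete cases per marker, attaches both
Hardy-Weinberg tests for both groups, and flags nominal (p <= alpha) and
family-corrected (p < alpha/m) significance. The Bonferroni threshold is
reported at 4 significant digits with round-half-even, so 0.05/18 is
0.002778 (truncating it to 0.0027, as sometimes seen in print, is not
imitated). The default family size is the number of markers analysed.

Case-only subgroup association (`run_subgroup_association()`) replaces
case/control status with a binarised clinical variable (Ki67 at 30%
boundary-inclusive, age at diagnosis at 40, WHO BMI classes, sporadic vs
familial disease, or any two-level variable) and always uses the Gart path
on zero cells, since subgroup tables are small. Covariate screening
follows the unadjusted convention: a covariate is only retained if a
logistic pre-fit shows it matters, and the package's tabulated analyses
are unadjusted, matching the example study's choice (its covariate checks
found no significant effect of age or BMI).

Gene-environment interaction is the multiplicative term of a logistic
model `status ~ genotype + exposure + genotype:exposure`, fitted by IRLS
(`stats::glm`, convergence 1e-8, at most 50 iterations) with a Wald test
on the interaction coefficient. Genotype coding defaults to dominant
(carrier yes/no); dosage and recessive codings are available. The
published analysis this mirrors reported its interaction results only
qualitatively, so the codings here are the package's own documented
defaults. Complete or quasi-complete separation (fitted probabilities
within 1e-6 of 0 or 1 together with a diverging coefficient) is flagged
and no p-value is reported.

### Virtual gel reading

`call_genotype()` matches an observed fragment-length multiset against the
three per-genotype signatures of a marker. Fragments at or below
`min_resolvable_fragment_bp` (default 25 bp) are optional — small control
fragments can run off a 3% gel — while every larger signature fragment is
required with its multiplicity, and no observed fragment may be
unexplained. The default threshold keeps all nine single-assay signatures
of the bundled panel pairwise distinct after dropping optional fragments,
which the constructor enforces for any user-defined marker. Ambiguity
between two compatible signatures is an error naming the candidates, never
a guess; an unmatched pattern is a missing call with a warning. The
two-codon multiplex splitter assigns each fragment to the unique marker
whose signatures contain its length, errors on lengths diagnostic for more
than one marker, and tolerates stray sub-resolution fragments.

## What the synthetic generator emulates

`simulate_case_control()` draws population genotypes in HWE at configured
allele frequencies, assigns disease by a logistic model (baseline odds
0.1 by default, chosen so that case sampling is feasible at desk scale
with a disease prevalence near 9%), and fills the case and control quotas
by rejection from the population stream — simple and exact, at the cost of
drawing more subjects than are kept (a hard cap of 1e7 draws turns
pathological configurations into errors). Default group sizes, 135 cases
and 112 controls, mirror the bundled example study. Two-locus data come
from independent haplotype pairs drawn from a configured four-frequency
vector, with the true phased counts returned for oracle use, and the
generator can emit RFLP fragment multisets (with sub-resolution dropout)
to exercise the virtual gel caller end-to-end.

The generator deliberately omits population structure, relatedness,
genotyping error beyond fragment dropout, missingness mechanisms and
covariate confounding. Passing calibration tests therefore show that the
statistics behave correctly under clean sampling assumptions — not that
real cohorts satisfy those assumptions.

## Calibration results and problem sizes

The acceptance layer recomputes, at fixed seeds, the quantities a reader
would check: the full published five-SNP table (26 odds-ratio/interval
triplets), the haplotype and subgroup tables, and three stochastic
calibrations whose problem sizes were chosen to estimate each rate to
about three decimal places while keeping the suite quick: the empirical
size of the dominant-model chi-square over 5000 null cohorts of 250+250
(observed ≈ 0.054-0.057 across seeds; direct binomial simulation confirms
the true size of the uncorrected test at this design is ≈ 0.054), Woolf
interval coverage over 2000 cohorts of 500+500 at a dominant odds ratio
of 1.5 (observed ≈ 0.945-0.952), and EM recovery of the haplotype
frequencies (0.4, 0.3, 0.2, 0.1) at 10,000 subjects (maximum absolute
error well below 0.01). Fisher's exact p-value is verified against full
hypergeometric enumeration for every 2x2 table with total count up to 40.

## Known data quirks and limitations

Three aspects of the bundled published tables deserve a note. First, two
zero-cell subgroup estimates are printed truncated rather than rounded
(10.92 where the Gart computation gives 10.9259; 0.09 where it gives
0.0961), and one interval bound differs in the last digit (232.80
computed, 232.81 printed); the tests allow exactly this one-unit slack
and no more. Second, the allelic row of rs1801131 prints a control allele
count (A = 168) inconsistent with its own genotype counts (which give
161), so that row cannot be reproduced from the genotype table; the
package reproduces its interval from the printed allele counts and
reports the genotype-derived value (OR 1.13) in its own scan. Third, the
published two-locus haplotype counts total 247 chromosomes in both groups
— fewer than the 270/224 the cohort implies — so they are treated as
given input, not re-derived.

The package handles autosomal biallelic markers only: no X-linked
inheritance, no multi-allelic loci, no haplotypes beyond two loci, no
covariate-adjusted odds ratios in the main path, and no genome-wide
scanning. These are scope decisions, not roadmap gaps: the package is a
faithful, testable implementation of the candidate-gene workflow.
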