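---
title: "Methods: trans-modifier association analysis for ABCA4/Stargardt disease"
author: "transmodR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trans-modifier association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transmodR)
```

# The scientific problem

ABCA4/Stargardt disease is the most common Mendelian macular dystrophy.
Its clinical spectrum — from severe early-onset retinal degeneration to
very late-onset maculopathy — is wider than the allelic series in *ABCA4*
alone explains, and several alleles (notably the hypomorphic p.Asn1868Ile)
are incompletely penetrant. One candidate explanation is *trans*-modifiers:
variants in unlinked genes whose products share the photoreceptor outer
segment with ABCA4 and whose dysfunction phenocopies the disease
(*CDHR1*, *CHM*, *CRX*, *ELOVL4*, *PROM1*, *PRPH2*, *ROM1*).

transmodR implements the corresponding association pipeline for a
bi-allelic case cohort against internal and external control cohorts:

1. **Qualifying-variant collapsing** — per-gene carrier enrichment of rare,
   predicted-deleterious variants (MAF and CADD filters), cases vs
   sequenced controls, with a ladder of MAF thresholds.
2. **Ethnicity-matched external controls** — population reference allele
   frequencies mixed in the exact ethnic proportions of the case cohort,
   then materialised as integer allele/genotype counts.
3. **Haplotype analysis** — EM estimation of the 3-SNP haplotype spectrum
   at the 3' end of *PRPH2* from unphased genotypes, and association of
   the haplotype-tagging SNP (c.1013A, p.Asp338) across genetically
   defined case subgroups.
4. **Subgroup stratification** — classification of cases into a "pure"
   hypomorph group (p.Asn1868Ile, optionally c.4253+43G>A, with no
   pathogenic variant in cis), a p.Gly1961Glu group, and all remaining
   bi-allelic cases.

The raw study cohorts are not public. The package therefore has two entry
modes sharing one statistics code path: *replay* mode ingests the
published summary tables bundled under `inst/extdata/` (carrier counts,
genotype percentages, haplotype counts) and recomputes every headline
statistic from them; *full* mode runs the same functions on genotype-level
data, exercised end to end on synthetic cohorts.

# Statistical conventions

**Association tests.** `fisherExactTwoSided()` implements the two-sided
Fisher exact test under the minimum-likelihood convention (sum of point
hypergeometric probabilities not exceeding the observed one, with a 1e-7
relative guard against floating-point ties); it is property-tested against
brute-force enumeration over all margin-compatible tables.
`chisqTwoSided()` is the uncorrected Pearson chi-square (two-proportion z)
companion. The bundled reference tables' printed p-values agree with the
uncorrected chi-square test to printed precision at every decisive entry
(e.g. 0.000241 for the *ROM1* carrier table, 0.1302 for the gene set at
MAF<0.005, 0.00057 for the extended-hypomorph allele contrast), while the
exact test gives 0.0026, 0.137 and 0.0004 on the same counts. Reporting
functions therefore default to `method = "chisq"` so that replayed tables
reproduce the reference values, and accept `method = "fisher"`
throughout. The two degenerate ladder rows print as 1 under either test at
printed precision.

**Odds ratios.** `oddsRatioWoolf()` returns the cross-product estimate
with the Woolf logit interval
$\exp(\log \mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$; this reproduces
every bracketed interval in the reference tables (no zero cells occur
there). Zero cells trigger the Haldane–Anscombe 0.5 correction to all four
cells, always flagged in the output.

**Multiple testing.** Bonferroni only, with k explicit per run (7 for
per-gene collapsing, 5 for the MAF ladder, 4 and 3 for the discovery and
replication/combined tag-SNP contrasts) — never inferred from table
shape.

**Rounding.** Printed values use half-away-from-zero rounding
(`roundHalfAway()`), matching the 1-dp percentages and 2-dp odds ratios of
the reference tables, and unlike base R's round-half-even.

**Genotype-count reconstruction.** The reference tag-SNP table prints
genotype *percentages* to 1 dp. `reconstructGenotypeCounts()` inverts them
to integer triples summing to the group size, choosing among feasible
triples the one minimising the maximum deviation from the un-rounded
targets (lexicographic tie-break, multiplicity flagged). One published row
(the n = 469 complement group, 4.7/38/57.3) admits *no* integer triple:
the minor-hom and het percentages force counts whose remainder rounds to
57.4. The strict mode raises an error listing the nearest candidate;
replay uses `nearest = TRUE`, which accepts a triple off by one rounding
step in one class and flags it. The corresponding contrast (p printed
0.1184; recomputed 0.1184) is insensitive to the ±1 ambiguity.

# Minor-allele orientation

Public databases report ALT-allele frequencies against the reference
genome; at the three linked *PRPH2* sites (c.910, c.929, c.1013) the
reference carries the *minor* nucleotide, so the "variant" allele is in
fact the major allele at ~0.8 frequency. `orientMinor()` flips such sites
(`minorIsAlt = FALSE`, `minorAF = min(af, 1-af)`) and flags sites with
frequency exactly 0.5 or missing as ambiguous without flipping (kept
ALT-minor — deterministic and visible, no silent choice). Missing global
frequencies are not hidden: the qualifying filter has an explicit
absent-in-panel category (below).

# Qualifying filter and collapsing

A site qualifies at threshold $t$ when minor AF $< t$ (strict) and CADD
$> 25$ (strict). Sites absent from the reference panel are rarer than any
threshold, so they qualify under every numeric $t$; the "nd" sentinel
selects exactly those sites. This makes the carrier sets *nested* down the
ladder (0.005, 0.001, 1e-4, 1e-5, nd), an invariant asserted at run time
and property-tested. Sites without a CADD annotation are excluded with a
message.

Collapsing is individual-level and dichotomous: a sample carries a gene
when it has minor-allele dosage ≥ 1 at ≥ 1 qualifying site in it — a
homozygous qualifying genotype still counts once, and a sample missing
genotypes at all qualifying sites of a gene stays in the denominator as a
non-carrier (the reference design reports fixed denominators). Coverage
QC precedes collapsing: samples need ≥ 90% of CCDS regions covered at
10X (the covered fraction arrives with the sample sheet), and sites with
an absolute case/control difference in coverage-passing fraction ≥ 11%
are dropped. The per-genotype `coverageOK` flag matrix is the desk-scale
stand-in for read-depth data; the synthetic generator emits it.

# Matched external controls

`caseEthnicityWeights()` averages the per-case admixture weight vectors
(hard labels count as weight one; samples under the 0.95 single-population
cutoff are labelled Admixed but keep their weights).
`matchedAF()` forms $\sum_e w_e\,\mathrm{af}_e$ and errors on any
ethnicity missing from the population table. `materializeControls()`
converts the mixed frequency into integer allele counts
($\mathrm{round}(2n\,\mathrm{af})$) and Hardy–Weinberg genotype counts
($nq^2, 2npq, np^2$, largest-remainder rounded to sum to $n$), flagged as
HWE-derived. At the matched frequency 0.2105 and $n = 43{,}029$ this gives
4.4/33.2/62.3% — within one rounding step of the reference 4.5/33.1/62.4,
whose exact integer counts are not published; the residual ±1
non-uniqueness is an accepted tolerance source.

# EM haplotype estimation

Phase is not observed; the spectrum over all $2^3$ haplotypes is estimated
by maximum likelihood via EM (`emHaplotypes()`): the E-step distributes
each sample over its phase-compatible ordered haplotype pairs in
proportion to current frequency products, the M-step re-estimates
frequencies from expected allele counts. Numerical choices: uniform
initialisation over all haplotypes (fully deterministic, no seed),
convergence when the maximum absolute frequency change drops below 1e-8,
cap of 1,000 iterations, observed-data log-likelihood asserted
non-decreasing at every step. Samples with any missing site are excluded
and counted; samples with at most one heterozygous site have unambiguous
phase, for which EM provably reduces to direct counting (tested against a
direct-phasing oracle). The two haplotypes never observed in the reference
spectra (G-G-G, C-G-G) simply receive frequency 0. Read-backed phasing is
out of scope. Pairwise LD (`ldStats()`) is derived from two-site EM
frequencies as $D$, $D'$ and $r^2$, with monomorphic sites returning
flagged missing values.

Haplotypes are labelled by nucleotide at cDNA positions 910-929-1013
(e.g. G-A-G for the major haplotype, amino acids EKG), with cDNA
numbering from the A of the ATG initiation codon; no transcript-coordinate
mapping is implemented — cDNA labels are annotation metadata.

# Subgroup classification

`classifyCase()` sees the ABCA4 diplotype as two per-allele label sets
(phase arrives annotated). The hypomorph group is deliberately "pure":
a hypomorphic label in cis with a pathogenic variant does *not* define
group membership — such cases stay in the remainder, controlling for known
cis-modifiers. The reference design does not state how a compound
heterozygote with a pure hypomorph on one allele and p.Gly1961Glu on the
other is binned; the package defaults to hypomorph-first precedence and
exposes `precedence` to flip it (the synthetic generator produces no such
cases by default, so the choice does not affect the shipped analyses).
c.4253+43G>A is a second hypomorph label that widens the discovery group
from 83 to 97; replication data lack that annotation, so the extended
grouping is discovery-only (`hypomorphLabels` controls it).

# The synthetic cohort generator

`generateCohort()` emulates the discovery design so every stage is
testable without any external data. Its defaults *are* the study
conditions: 622 cases / 10,865 controls; ethnicity mixture 79% European
with the remainder spread over African (5%), Latino (6%), East Asian
(3%), South Asian (2%), Middle Eastern (2%) and Admixed (3%) — the
published design fixes only the 79% European share, the split of the
remainder is a single realistic choice; subgroups 83/153/386 with 14
extended-hypomorph and 20 cis-hypomorph cases inside the third group;
per-gene carrier probabilities equal to the published carrier fractions
(e.g. 8/622 vs 37/10,865 for *ROM1*); subgroup haplotype spectra equal to
the published discovery spectra (the third group's spectrum is the
all-patients spectrum minus the two subgroups); three-site panel minor
frequencies per ethnicity mixing to ≈0.20/0.10/0.21; coverage dropout
2% per genotype.

Mechanics: haplotype pairs are drawn per subgroup with Hardy–Weinberg
random pairing (the hypomorph group's absence of minor-allele homozygotes
is reproduced *by frequency* — expected ≈ 2 homozygotes at $q = 0.16$,
so absence is plausible — not by constraint); control haplotype-region
genotypes are drawn per site from the control's own population frequency
(no LD in controls, which only feed single-site contrasts); carriers are
Bernoulli per gene and placed as a heterozygote at one random qualifying
site. One seed drives named sub-streams (ethnicity, sites, carriers,
haplotypes, coverage) so extending one stage does not shift the draws of
another; equal seeds give byte-identical file sets.

What it does *not* emulate — and hence what green tests do not show about
real data: LD beyond the three-site region, realistic genome-wide site
counts, relatedness and population substructure (kinship filtering and
ancestry-model correction are out of scope; ethnicity arrives as
labels/weights), X-chromosome hemizygosity (*CHM* is treated as diploid),
sequencing error, and read-level evidence.

# Problem sizes and runtime

The shipped analyses run at the published scale: replay statistics are
instantaneous; the simulation-based checks use 100 EM replicates at
n = 622, 200 replicates of the full 622/10,865 enrichment design
(single-gene cohorts), and 1,000 null cohorts at 400/800 with a 5%
carrier probability per gene — sizes chosen so the whole suite completes
in a few minutes while keeping every binomial check well-powered. The
null-cohort type-I check runs on the default (chi-square) reporting path;
the exact test is conservative at rare-variant counts due to discreteness,
which is expected behaviour, not an error.

# Known limitations

* Three published homozygote-absence p-values (0.00038, 0.0015, 0.00066)
  could not be reproduced by either test on any plausible construction of
  the underlying counts (one quoted denominator, 372, also disagrees with
  the stated subgroup sizes). `homozygoteContrast()` implements the plain
  exact test on (minor-hom, rest) counts and reports raw counts alongside
  p; the discrepancy is documented rather than forced.
* The published combined-cohort all-patients row prints p = 4.00e-05 and
  OR 1.24 where the reconstructed counts give 4.64e-05 and 1.234; the
  underlying integer counts are not published and the reconstruction is
  exact for the printed percentages, so the recomputed values are
  reported as-is.
* Replay depends on printed 1-dp percentages; one group's percentages are
  internally inconsistent (see reconstruction section) and carry a ±1
  count ambiguity.
* The collapsing analysis is unweighted carrier collapsing by design; no
  weighted burden tests, variant-level association or covariate-adjusted
  models are provided.
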