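# transmodR

Trans-modifier association analysis for ABCA4/Stargardt disease.

ABCA4/Stargardt disease, the most prevalent Mendelian eye disorder, shows
clinical heterogeneity and incomplete penetrance that the *ABCA4* allelic
series alone does not explain. One proposed source is *trans*-modifiers:
variants in unlinked macular-dystrophy genes (*CDHR1*, *CHM*, *CRX*,
*ELOVL4*, *PROM1*, *PRPH2*, *ROM1*) whose products share the photoreceptor
outer segment with ABCA4. transmodR is a Bioconductor-style R package for
statistical geneticists running (or re-examining) that analysis: it
implements the full pipeline from genotypes to publication-shaped tables,
and a replay mode that recomputes every headline statistic from bundled
summary counts, since the original cohorts are not public.

## What it computes

* **Qualifying-variant collapsing.** A variant qualifies at MAF threshold
  *t* when its minor allele frequency in the reference panel is < *t*
  (absent-in-panel sites qualify at every *t*) and CADD > 25. A sample
  carries a gene if it has minor-allele dosage ≥ 1 at ≥ 1 qualifying site.
  Carrier counts are compared case vs control per gene and for the 7-gene
  set down a MAF ladder (0.005, 0.001, 1e-4, 1e-5, absent), with coverage
  QC (samples ≥ 90% CCDS at 10X; sites with ≥ 11% case/control coverage
  difference dropped) and explicit Bonferroni k per family.
* **Two-by-two statistics.** Minimum-likelihood two-sided Fisher exact
  test (enumeration-tested), uncorrected Pearson chi-square (the test that
  reproduces the reference tables' printed p-values, and the reporting
  default), and Woolf odds-ratio intervals
  exp(log OR ± 1.96·√(1/a+1/b+1/c+1/d)).
* **Ethnicity-matched external controls.** Population reference allele
  frequencies mixed in the exact case ethnic proportions
  (Σ<sub>e</sub> w<sub>e</sub>·af<sub>e</sub>), materialised as integer
  allele and Hardy–Weinberg genotype counts.
* **Haplotype analysis.** Deterministic EM estimation of the 2³ haplotype
  spectrum over the three linked *PRPH2* 3'-end SNPs (c.910, c.929,
  c.1013) from unphased genotypes; tag-SNP (c.1013A, p.Asp338) allele and
  homozygote contrasts across genetically defined case subgroups; D, D',
  r² from two-site EM frequencies.
* **Subgroup stratification.** "Pure" hypomorph cases (p.Asn1868Ile,
  optionally c.4253+43G>A, with no pathogenic variant in cis),
  p.Gly1961Glu cases, and the remainder — with cis-configured hypomorphs
  deliberately kept in the remainder.
* **Synthetic cohorts.** A seeded generator reproducing the discovery
  design (622 cases / 10,865 controls, 79% European mixture, subgroups
  83/153/386, published carrier rates and haplotype spectra) so that
  every stage is testable end to end without any download.

## Worked example

Replay the per-gene collapsing from the bundled carrier counts:

```r
library(transmodR)
tab <- replayCollapse()
tab[tab$gene %in% c("PROM1", "ROM1"), ]
#>  gene caseCarriers controlCarriers casePct controlPct        p   or ciLow ciHigh significant
#> PROM1            7              71    1.13      0.653 0.163361 1.73 0.793   3.78       FALSE
#>  ROM1            8              37    1.29      0.341 0.000241 3.81 1.768   8.22        TRUE
```

1.3% of 622 cases carry a rare (MAF < 0.005), predicted-deleterious
(CADD > 25) *ROM1* variant vs 0.3% of 10,865 controls: p = 0.000241,
OR 3.81 [1.77; 8.22], significant at the Bonferroni threshold 0.05/7.

Tag-SNP contrasts from the printed genotype percentages (counts
reconstructed to integers first):

```r
ct <- replayTagContrasts()
ct[ct$cohort == "discovery", c("contrast", "n1", "n2", "af1", "af2", "p", "or")]
#>      contrast  n1    n2   af1   af2        p    or
#>  all_patients 622 43029 0.248 0.210 0.001457 1.234
#>     hypomorph  83   539 0.163 0.261 0.006455 0.551
#>        g1961e 153   469 0.281 0.237 0.118384 1.261
#> hypomorph_ext  97   525 0.149 0.266 0.000569 0.486
```

The c.1013A minor allele is enriched in cases overall (MAF 0.25 vs 0.21
in the ethnicity-matched external controls) but *depleted* in the
hypomorph subgroup (0.15 vs 0.27 in the remaining cases, p = 0.00057,
OR 0.49) — the genotype-specific signature of a penetrance modifier.

The same functions run on genotype-level data; a synthetic discovery-scale
cohort exercises the full pipeline:

```r
sim <- generateCohort(simConfig(seed = 1))
res <- runAll(sim$cohort, popAF = sim$popAF,
              hapSiteKeys = sim$truth$hapSiteKeys,
              tagSiteKey = sim$truth$tagSiteKey)
res$spectra$all
#> HaplotypeSpectrum over 3 sites ( 6:42672325_C/G, 6:42672306_G/A, 6:42672222_A/G )
#> group: all_patients   n alleles: 1244   EM iterations: 10   logLik: -812.691
#>  haplotype frequency expected_count
#>      G-A-G    0.7508            934
#>      C-A-A    0.1262            157
#>      C-G-A    0.1013            126
#>      G-A-A    0.0217             27
#>      ...
```

The EM estimate recovers the generating spectrum (G-A-G configured at
0.753) from unphased genotypes at n = 622.

See `vignettes/transmod-methods.Rmd` for the model conventions, the
genotype-count reconstruction, the simulator's assumptions, and known
limitations.

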