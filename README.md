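# parentalASE

Parental haplotype-resolved allele-specific expression (ASE) analysis for
single-cell RNA-seq, aimed at the two allelic remodelling events of the
fetal human germ line: erasure of genomic imprints and reactivation of the
inactive X chromosome. It is written for analysts who have (or can
simulate) trio-style genotypes — a fetus and its mother — together with
single-cell libraries from that fetus, and who want per-cell,
parent-of-origin expression calls rather than anonymous monoallelic/
biallelic ones.

## What it computes

**Haplotyping.** A site that is heterozygous in the fetus and homozygous in
the mother is *informative*: the allele the mother does not carry must be
paternal. From paired VCFs the package selects exactly the PASS-filtered
biallelic SNPs with fetus 0/1 and mother 0/0 or 1/1, phases them
(mother 0/0 ⇒ ALT paternal; mother 1/1 ⇒ ALT maternal), counts every
discard category, and can substitute the phased alleles into a reference
sequence to produce individualized parental references.

**Allelic counting.** Reads mapped once against each parental reference are
assigned by edit distance (strictly smaller wins; ties ambiguous; reads not
uniquely mapped to *both* references unusable), giving an `AllelicCounts`
container (a `SummarizedExperiment` with `maternal` and `paternal` assays).
Cell QC: ≥ 7,500 expressed genes, then removal of cells in the lowest
quintile of allelic reads or of SNP-containing genes.

**Imprinting.** Per cell and confirmed imprinted gene, the ratio of reads
from the expected parental allele; aggregation per imprinted gene-cluster
(H19/IGF2, DLK1-DIO3/MEG3, KCNQ1/KCNQ1OT1, PEG3/ZIM, SNURF-SNRPN/UBE3A).
Monoallelic observations are tested against a random allelic-dropout null:
seeing the expected allele alone in *n* cells has probability (½)ⁿ, so
**n ≥ 5 cells is significant at α = 0.05**. Group contrasts use one-sided
Mann–Whitney–Wilcoxon (exact for small untied samples).

**X reactivation.** Per cell, maternal and paternal reads are summed per
chromosome (escapee genes excluded from the X), and the X's max-allele
fraction `b = max(M, P) / (M + P)` is placed in an empirical null built
from the autosomes of the same dataset: chromosome points are binned so
each bin holds an equal share of allelic reads, and per bin the interval
containing 95% of autosomal `b` values defines the biallelic range. An
assessable X (≥ 3 proper genes, ≥ 33 reads) strictly above its bin's upper
bound is **significantly non-reactivated (XiXa)**. A geometric-mean
variant (per-gene bias with +1 pseudocount, pooled autosomal 99% interval)
provides an outlier-robust cross-check, and a median-bias classifier
(≥ 95% median monoallelic bias ⇒ XCI) covers sparse datasets. XiXa-vs-XaXa
differential expression uses a negative-binomial Wald test (method-of-
moments dispersion, Poisson floor) with Benjamini–Hochberg correction.

**Staging and methylation.** Cells are staged PGC / LGC / MGC / somatic by
average-linkage clustering on Spearman correlation over a marker panel,
with tenfold stage-enrichment lists; CpG methylation is summarized over
1-based-inclusive ICR windows, with per-read pattern counts and SNP-allele
read splitting (> 5% allele frequency).

A synthetic-data module (`simulateTrio`, `simulateAllelicCounts`,
`simulateBiallelicCells`, `simulateStageExpression`,
`simulateMethylationReads`) generates every input with known ground truth;
all statistical claims in the test suite are parameter-recovery checks
against it.

## Worked example

```r
library(parentalASE)

## trio phasing round trip
trio   <- simulateTrio(trioSimConfig(n_snps = 5000, seed = 42))
phased <- selectInformativeSnps(trio$fetal, trio$maternal)
str(phased$summary)
#> List of 5
#>  $ n_paternal_informative   : int 505
#>  $ n_maternal_informative   : int 533
#>  $ n_discarded_maternal_het : int 439
#>  $ n_discarded_lowq_or_indel: int 0
#>  $ n_discarded_other        : int 0
phaseRecoveryCheck(trio$truth_phase, phased$phased)   # 1 (exact)

## 80 PGCs, 24 of them with a still-inactive X (XiXa), depth ~5000 reads
profiles   <- cellSimProfiles(80, stage = "PGC",
                              x_state = rep(c("XiXa", "XaXa"), c(24, 56)),
                              depth = 5000, dropout_rate = 0.2, seed = 1)
annotation <- simGeneAnnotation(n_autosomal = 220, n_x_proper = 10,
                                n_escapee = 4)
counts <- simulateAllelicCounts(profiles, annotation, seed = 2)

sums  <- chromosomeAllelicSums(counts)
null  <- buildBinnedNull(sums)            # 4 equal-read bins, 95% level
null
#> BinnedNull: 4 bin(s) at level 0.95 on bias
#>  bin lower_total upper_total     lower     upper n_points
#>    1          45         181 0.5030698 0.7510150      662
#>    2         181         231 0.5044212 0.7575432      459
#>    3         231         287 0.5038087 0.7641711      364
#>    4         287         571 0.5022797 0.7546162      275
calls <- classifyXState(sums, null)
table(calls$state)
#>  XaXa_range XiXa_biased
#>          55          25
```

The 24 planted XiXa cells are all recovered (plus one borderline autosomal
false positive), i.e. 31% of these PGCs carry a significantly
non-reactivated X. The per-bin `upper` column is the biallelic ceiling an
X chromosome must exceed, and `calls$active_x_parent` records which
parental X is the active one in each cell.

```r
## imprinting: one erased cluster among intact ones
states  <- imprintSimStates(c("H19/IGF2", "KCNQ1/KCNQ1OT1"), c(0.8, 0))
counts2 <- simulateAllelicCounts(profiles, annotation, states, seed = 3)
clusterBiasSummary(expectedAlleleRatio(counts2))
#>     imprint_cluster group    median      mean n_cells n_reads
#> 1    DLK1-DIO3/MEG3   all 1.0000000 1.0000000      80    4374
#> 2          H19/IGF2   all 0.5555556 0.5912487      80    5002
#> 3    KCNQ1/KCNQ1OT1   all 1.0000000 1.0000000      80    4760
#> 4          PEG3/ZIM   all 1.0000000 1.0000000      80    4793
#> 5 SNURF-SNRPN/UBE3A   all 1.0000000 1.0000000      80    4459

monoallelicDropoutTest(4:6)
#>   n  p_value significant
#> 1 4 0.062500       FALSE
#> 2 5 0.031250        TRUE
#> 3 6 0.015625        TRUE
```

The erased H19/IGF2 cluster sits at a biallelic median (~0.5) while intact
clusters stay fully monoallelic (1.0), and the dropout model shows why
five monoallelic cells — not four — are needed to call a gene imprinted.

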