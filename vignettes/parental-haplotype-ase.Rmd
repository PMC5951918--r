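---
title: "Parental haplotype-resolved allelic expression: models and methods"
author: "parentalASE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parental haplotype-resolved allelic expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parentalASE)
```

# Overview

`parentalASE` analyses parent-of-origin allele-specific expression (ASE) in
single cells from a fetus whose exome, together with the mother's, has been
genotyped. Its scientific targets are the two allelic remodelling events of
the female human germ line: the erasure of genomic imprints and the
reactivation of the inactive X chromosome. Both manifest as a shift from
monoallelic to biallelic expression, which is only observable when each read
can be assigned to a parental haplotype.

The pipeline has six analysis stages, each usable on its own:

1. **Haplotyping** — select *informative SNPs* (heterozygous in the fetus,
   homozygous in the mother) from paired VCFs and phase each fetal allele.
2. **Allelic counting** — assign reads to a parent by edit distance against
   the two individualized references, tabulate per-cell per-gene
   maternal/paternal counts in an `AllelicCounts` container, and apply the
   cell-level QC filters.
3. **Staging** — hierarchical clustering (Spearman correlation) on a
   marker-gene panel to label cells PGC / LGC / MGC / somatic.
4. **Imprinting** — expected-allele expression ratios per imprinted
   gene-cluster, with a dropout-aware significance model for monoallelic
   calls.
5. **X reactivation** — per-cell chromosome-summed counts classified
   against a binned autosomal empirical null, plus a geometric-mean (GM)
   variant, a median-bias classifier, and negative-binomial differential
   expression between reactivating (XiXa) and reactivated (XaXa) cells.
6. **Methylation** — CpG methylation summaries over imprinting control
   region (ICR) windows, per-read pattern counts and SNP-allele splits.

A synthetic-data module simulates every input with known ground truth, so
each stage is validated by parameter recovery rather than by eyeballing.

# Trio-lite haplotype construction

At a site where the fetus is heterozygous (alleles $R/A$) and the mother
homozygous, the parent of origin of each fetal allele is determined without
pedigree phasing: if the mother is $R/R$ she must have transmitted $R$, so
$A$ is paternal; if she is $A/A$, the fetal $A$ is maternal. Sites are used
only when they are PASS-filtered biallelic SNPs in both individuals;
indels, multi-allelic records, low-quality calls and maternally
heterozygous sites are discarded and counted. Sites called in only one
individual are treated as non-informative (the upstream variant caller, not
this package, is the right place to resolve them); they are tracked in a
separate discard counter so that every fetal-het site appears in exactly
one bookkeeping category. The rule is deterministic given genotypes, so on
simulated trios recovery of the true phase is exact — the round-trip test
asserts 100%, not approximately 100%.

`buildParentalSequences()` materializes the two haplotypes as single-base
substitutions into a reference (`Biostrings`), for use as alignment
references; coordinates are 1-based inclusive throughout the package,
matching VCF and the printed ICR windows.

# Allele assignment and cell QC

A read is usable only if it maps *uniquely* against **both** parental
references; among usable reads the strictly smaller edit distance decides
the allele, and ties are ambiguous. Ambiguous and unusable reads are
dropped, never fractionally split: with single-base haplotype differences
there is no defensible fractional assignment, and counts must stay integer
for the downstream binomial reasoning. Counting works on read counts, not
TPM, precisely so that sampling effects and allelic dropout can be modelled.

Two cell filters are applied in order:

* **Transcriptome size** — keep cells expressing at least 7,500 genes
  (inclusive). This bounds library quality before any allelic reasoning.
* **Allelic coverage quintile** — compute each cell's number of
  SNP-containing genes and total allelic reads, and remove cells lying in
  the lowest quintile of *either* metric (union of exclusions). The
  boundary is the interpolated 20th percentile; a cell is removed only when
  strictly below it, so ties at the boundary survive and a constant metric
  removes nobody. Because the boundary is data-derived, re-filtering a
  filtered subset would move it; the filter therefore returns its
  thresholds, and passing them back re-applies the filter as a fixed rule
  (the identity on its own output). Quintiles are computed on the pooled
  dataset by default; per-donor filtering is a matter of subsetting the
  container first.

# Staging from a marker panel

Cells are clustered with average-linkage hierarchical clustering on
$1 - \rho_s$ (Spearman). Rank correlation makes the distance invariant to
any monotone per-cell transformation, so the staging is insensitive to
normalization details; median normalization (each cell divided by its
median positive expression, rescaled by the global median of medians) is
still applied for the fold-change computations. Average linkage is the
conventional choice with correlation distances and is configurable. The
panel is a user input (gene, category); genes absent from the matrix are
dropped with a warning, mirroring how unexpressed panel genes are handled
in practice. Cluster labels are derived from the panel-category means
(z-scored across clusters) with greedy unique assignment — highest
pluripotency+early germ cluster becomes PGC, highest meiotic MGC, highest
somatic somatic, intermediate LGC — so labelling is reproducible rather
than manual. Stage-enriched genes are those with mean expression at least
tenfold the combined mean of the other groups; the boundary is inclusive
and a gene expressed in one group but silent elsewhere counts as enriched
(the fold is infinite).

# Imprinting and the dropout null

For each confirmed imprinted gene with at least one allelic read in a cell,
the *expected-allele ratio* is the fraction of reads from the parental
allele expected (by imprinting) to be expressed: 1 is faithful monoallelic
expression, 0.5 biallelic (erased). Only genes annotated `confirmed` enter;
predicted/provisional categories are excluded because they do not behave
imprinted even in somatic cells. Ratios are aggregated per imprinted
gene-cluster (H19/IGF2, DLK1-DIO3/MEG3, KCNQ1/KCNQ1OT1, PEG3/ZIM,
SNURF-SNRPN/UBE3A) — the ICR is the regulatory unit, so erasure is a
cluster-level property.

Monoallelic observations in single cells are confounded by allelic dropout.
The null model: dropout exposes either allele independently per cell with
probability $\tfrac12$, so the probability that $n$ cells all show the
specific expected allele is $(\tfrac12)^n$. The boundary for significance
at $\alpha = 0.05$ is therefore $n = 5$
($2^{-5} = 0.031 < 0.05 \le 0.0625 = 2^{-4}$); the one-sided direction
toward the expected allele is the only reading under which 5 cells is the
boundary. A cell counts as monoallelic when its ratio equals 1 with at
least `min_reads` reads (default 1; the threshold is configurable because
no minimum is canonical). Group comparisons of ratio distributions use the
one-sided Mann–Whitney–Wilcoxon test, exact when both groups have at most
8 untied observations and the tie-corrected normal approximation otherwise.

# X-reactivation classification

Per-gene X allelic ratios in single cells are dominated by dropout, so the
unit of analysis is the chromosome: per cell, all maternal and all paternal
reads of SNP-containing genes are summed per chromosome. X-linked genes
reported to escape XCI stay biallelic on the inactive X and are excluded
from every X computation (they are informative controls, analyzed
separately). Cells are assessable when their X has at least 3
SNP-containing proper genes and at least 33 allelic reads, both inclusive.

The scalar compared between chromosomes is the **max-allele fraction**
$b = \max(M, P) / (M + P) \in [0.5, 1]$. The choice is deliberate: it is
direction-free, so maternally and paternally biased X chromosomes are
treated symmetrically, and it makes the autosomal null one-sided — only
the upper tail can indicate monoallelic expression. The parental direction
is reported separately as the paternal read fraction, and the presumed
active X is simply the parent with more summed X reads.

Allelic bias of a chromosome depends strongly on its read total (fewer
reads, noisier fraction), so chromosome points are binned by total allelic
reads with **equal-read bins**: points are ordered by total and a point
joins bin $\lceil s \cdot K \rceil$ where $s$ is its cumulative read share
and $K$ the number of bins; a point exactly on a boundary stays in the
lower bin. This equalizes transcripts, not points, per bin. The default is
$K = 4$ bins for the chromosome-level null (configurable; a warning is
emitted when a bin holds fewer than 20 autosomal points, where the
empirical quantiles become unstable).

Within each bin the biallelic range is the empirical interval
$[q_{(1-\ell)/2},\, q_{1-(1-\ell)/2}]$ of the autosomal bias values at
level $\ell = 0.95$, computed with linear interpolation (`quantile`
type 7) — deterministic and faithful to "contains 95% of the autosomes"
on finite samples. X points never enter the null. A cell's X is
**significantly non-reactivated (XiXa)** when its bias lies strictly above
its bin's upper bound; at or below, it is within the biallelic (XaXa)
range. X totals outside the training range map to the nearest boundary
bin.

Because $b$ is bounded below at 0.5 with a probability atom there (totals
are small in the lowest bin, and exact 50:50 splits occur), the two-sided
empirical interval over-covers somewhat: held-out coverage on purely
biallelic simulations is near 97% rather than 95%. This is a property of
the metric, not a bug; it makes the upper-tail classifier conservative
(false-positive X calls well below 5%). The calibration tests and the
acceptance script report the measured coverage.

The **GM variant** replaces the chromosome sum with the geometric mean
over genes of the per-gene max-allele fraction computed with a +1
pseudocount on both alleles, $(\max(m,p)+1)/(m+p+2)$. The pseudocount
shrinks low-coverage genes toward 0.5 and the geometric mean is less
sensitive to a single outlier gene than the arithmetic mean. The GM null
is the pooled (unbinned) empirical interval of autosomal GM values at 99%:
the pseudocount already absorbs most depth dependence, and binning the GM
would leave too few autosomal points per bin. Both the GM formula and the
pooling are package choices — the metric's name fixes neither.

For datasets too sparse for a binned null, the **median-bias classifier**
calls a cell in XCI state when the median over proper X genes of the
per-gene monoallelic bias is at least 0.95 (inclusive).

**Differential expression** between XiXa and XaXa cells uses a negative
binomial two-group Wald test: gene-wise dispersion by method of moments
from the pooled within-group variances, floored at Poisson, and the
difference of group means tested with the NB mean–variance relation.
P-values are Benjamini–Hochberg adjusted; both raw and adjusted values are
reported, since a fixed 0.05 threshold can reasonably be applied to
either.

# The synthetic-data module

The generators emulate the statistical structure of haplotype-resolved
single-cell data, not its molecular detail:

* **Trios** — sites placed along hg19-length chromosomes; fetal
  heterozygosity and maternal homozygosity rates are free parameters
  (defaults 0.3 and 0.7); optional indel, low-quality and contradiction
  channels default to off so the noise-free round trip is exact.
* **Allelic counts** — per-gene read totals are negative binomial across
  genes (size 1 by default), scaled by the cell's depth: sparse,
  overdispersed counts of the kind the quintile filters assume. The
  maternal count of a gene is Binomial(total, $p$) with $p$ encoding the
  regime: 0.5 for autosomal and escapee genes, $1-\text{leak}$ toward the
  active X for X-proper genes in XiXa cells (leak default 0.02 —
  reactivation is ongoing, so the classifier is tested off the degenerate
  case), and the expected allele for non-erased imprinted genes. Imprint
  erasure fires per cell and cluster with a configurable probability.
  Dropout hits a gene with the profile's dropout probability and moves all
  of its reads onto one allele, *chosen with probability equal to its
  expression share*: for biallelic genes this is exactly the fair coin of
  the dropout null, while monoallelic genes keep their active allele (a
  silenced allele cannot be exposed at full depth by losing the other).
  Totals are conserved exactly, and all truth (per-gene $p$, dropout hits,
  erasure events, cell profiles) ships with the object.
* **Biallelic calibration cells** — per-chromosome totals NB(mean 200,
  dispersion 1) split multinomially over genes, maternal counts
  Binomial(total, 0.5); the summed chromosome maternal count is then
  exactly Binomial(total, 0.5) in distribution, which is what the null
  claims to describe.
* **Staged expression** — log-normal expression around per-stage archetype
  means over the marker categories. The archetype weights are graded so
  each stage has a distinct deterministic rank profile; with the default
  noise (SD 0.2 in log space) staging recovery is exact, which is the
  regime the panel-based staging claims to handle.
* **Methylation reads** — per-read, per-CpG independent Bernoulli calls at
  an allele-specific rate.

What the simulations do *not* emulate: alignment artifacts, reference
bias, gene-length and GC effects, bursty transcription kinetics,
cross-contamination, or developmental trajectories. Passing tests
demonstrate that the statistical machinery is correct under its own model
assumptions — they do not certify performance on real libraries, where
read assignment error and expression covariance add noise the null does
not see.

# Numerical choices and degenerate inputs

* Quantiles everywhere are type 7 (linear interpolation); intervals on
  identical values degenerate to a point, level 1 gives `[min, max]`, and
  an empty bin is an error rather than a silent `NA`.
* Bin ties: points sharing a total may split across bins only when their
  cumulative read share crosses a boundary; a point exactly on a boundary
  goes to the lower bin.
* `classifyXState` uses strict inequality at the upper bound, so a bias
  exactly on the boundary is within range (conservative).
* NB dispersion estimates are floored at 0 (Poisson); all-zero genes are
  skipped, not tested.
* Active-X assignment returns `tied` on exact equality instead of
  guessing.
* Multi-allelic VCF records are discarded with indels; phased genotype
  separators (`|`) are normalized to unphased before comparison.
* BED input is converted from 0-based half-open to the package's 1-based
  inclusive convention on read (via `rtracklayer`).

# Problem sizes

The test-suite simulations are sized to exercise the asymptotics they
invoke while staying small: calibration uses 200 + 200 cells × 22
autosomes per replicate (≈ 8,800 autosomal points), parameter recovery
100 cells × ~240 genes over three seeds, and the acceptance script runs
ten replicates of the 400-cell split design. These sizes put simulation
error well below the tolerances asserted.

# Known limitations

* The edit-distance assignment consumes precomputed alignment summaries;
  the package does not align reads.
* The dropout null treats cells as independent and dropout as symmetric
  between alleles; systematic capture bias violates it.
* The binned null assumes autosomes are biallelic; broad autosomal
  imbalance (e.g. aneuploidy) would contaminate it.
* The GM construction (pseudocount, pooling, 99% level) is one defensible
  parameterization of an outlier-robust statistic, not a canonical
  definition.
* Methylation analysis starts from extracted per-read CpG call tables;
  bisulfite alignment is out of scope.
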