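# X-reactivation module. Per-cell chromosome-summed allelic counts place
# each X chromosome inside an empirical null built from the biallelic
# autosomes of the same dataset: chromosome points are binned so that reads
# are equally distributed per bin (countering depth-related technical
# effects) and, per bin, the interval containing 95% of the autosomal bias
# values defines the biallelic range. An X falling above it is
# significantly non-reactivated (XiXa). The bias scalar is the max-allele
# fraction max(M,P)/(M+P), in [0.5, 1], so only the upper tail is
# informative and the parental direction is reported separately.

#' BinnedNull: binned autosomal empirical interval
#'
#' Holds the equal-read bin boundaries and the per-bin empirical interval
#' of autosomal allelic bias at a given confidence level.
#'
#' @slot bins a `data.frame` with columns `bin`, `lower_total`,
#'   `upper_total`, `lower`, `upper`, `n_points`.
#' @slot level confidence level of the per-bin interval.
#' @slot metric name of the bias scalar the interval is built on.
#' @export
setClass("BinnedNull", representation(bins = "data.frame",
                                      level = "numeric",
                                      metric = "character"))

setValidity("BinnedNull", function(object) {
  need <- c("bin", "lower_total", "upper_total", "lower", "upper",
            "n_points")
  if (!all(need %in% names(object@bins)))
    return("bins must have columns bin, lower_total, upper_total, lower, upper, n_points")
  if (object@level <= 0 || object@level > 1)
    return("level must be in (0, 1]")
  TRUE
})

setMethod("show", "BinnedNull", function(object) {
  cat("BinnedNull:", nrow(object@bins), "bin(s) at level",
      object@level, "on", object@metric, "\n")
  print(object@bins, row.names = FALSE)
})

#' Partition X-linked genes into XCI-proper and escapee sets
#'
#' Genes reported to escape X inactivation stay biallelically expressed on
#' the inactive X and are analyzed separately; every X-bias computation
#' excludes them.
#'
#' @param annotation gene annotation with `gene` and `chromosome` columns
#'   (and optionally a logical `escapee` column).
#' @param escapee_list optional character vector of escapee gene names,
#'   used in addition to the annotation flag.
#' @param x_chrom the X chromosome name (default `"chrX"`).
#' @return a list with character vectors `proper_genes` and
#'   `escapee_genes` (disjoint; union = all annotated X genes).
#' @export
partitionXGenes <- function(annotation, escapee_list = NULL,
                            x_chrom = "chrX") {
  stopifnot(all(c("gene", "chromosome") %in% names(annotation)))
  xg <- annotation$gene[annotation$chromosome == x_chrom]
  esc_flag <- if (!is.null(annotation$escapee))
    annotation$gene[annotation$chromosome == x_chrom &
                      annotation$escapee] else character(0)
  esc <- union(esc_flag, intersect(escapee_list, xg))
  list(proper_genes = setdiff(xg, esc), escapee_genes = esc)
}

#' Per-cell per-chromosome summed parental counts
#'
#' Adds up all maternal and all paternal reads of SNP-containing genes per
#' chromosome per cell; on the X, escapee genes are excluded. Chromosome
#' points with zero total reads are omitted.
#'
#' @param x an [AllelicCounts-class] object whose `rowData` carries
#'   `chromosome`.
#' @param partition optional result of [partitionXGenes()]; derived from
#'   `rowData(x)$escapee` when omitted.
#' @param x_chrom the X chromosome name.
#' @return a `data.frame` with `cell_id`, `chromosome`, `M`, `P`,
#'   `total`, `paternal_fraction`, `bias`, `n_snp_genes`.
#' @export
chromosomeAllelicSums <- function(x, partition = NULL, x_chrom = "chrX") {
  ann <- as.data.frame(rowData(x))
  if (is.null(ann$gene)) ann$gene <- rownames(x)
  stopifnot(!is.null(ann$chromosome))
  if (is.null(partition))
    partition <- partitionXGenes(ann, x_chrom = x_chrom)
  keep <- ann$chromosome != x_chrom |
    ann$gene %in% partition$proper_genes
  m <- maternalCounts(x)[keep, , drop = FALSE]
  p <- paternalCounts(x)[keep, , drop = FALSE]
  chrom <- ann$chromosome[keep]
  sumBy <- function(mat) {
    out <- rowsum(mat, chrom)
    out[order(rownames(out)), , drop = FALSE]
  }
  M <- sumBy(m); P <- sumBy(p); G <- sumBy((m + p > 0) * 1L)
  tot <- M + P
  out <- data.frame(
    cell_id = rep(colnames(M), each = nrow(M)),
    chromosome = rep(rownames(M), ncol(M)),
    M = as.vector(M), P = as.vector(P), total = as.vector(tot),
    n_snp_genes = as.vector(G),
    stringsAsFactors = FALSE
  )
  out <- out[out$total > 0, , drop = FALSE]
  out$paternal_fraction <- out$P / out$total
  out$bias <- pmax(out$M, out$P) / out$total
  rownames(out) <- NULL
  out
}

#' X-assessability filter
#'
#' Keeps cells whose X chromosome has at least `min_x_genes`
#' SNP-containing proper genes and at least `min_x_reads` allelic reads
#' (both inclusive).
#'
#' @param summaries output of [chromosomeAllelicSums()].
#' @param min_x_genes,min_x_reads thresholds (defaults 3 genes, 33 reads).
#' @param x_chrom the X chromosome name.
#' @return character vector of assessable cell ids.
#' @export
filterXCells <- function(summaries, min_x_genes = 3, min_x_reads = 33,
                         x_chrom = "chrX") {
  xs <- summaries[summaries$chromosome == x_chrom, , drop = FALSE]
  xs$cell_id[xs$n_snp_genes >= min_x_genes & xs$total >= min_x_reads]
}

#' Presumed active X per cell
#'
#' The parent contributing more summed X reads; equal counts give
#' `"tied"`.
#'
#' @param summaries chromosome summaries restricted (or restrictable) to
#'   the X; rows with other chromosomes are ignored.
#' @param x_chrom the X chromosome name.
#' @return named character vector cell_id -> `"maternal"`, `"paternal"` or
#'   `"tied"`.
#' @export
assignActiveX <- function(summaries, x_chrom = "chrX") {
  xs <- summaries[summaries$chromosome == x_chrom, , drop = FALSE]
  stopifnot(all(xs$total >= 1))
  setNames(ifelse(xs$M > xs$P, "maternal",
                  ifelse(xs$P > xs$M, "paternal", "tied")),
           xs$cell_id)
}

#' Equal-read binning of chromosome points
#'
#' Boundaries are chosen so each bin holds an (as near as possible) equal
#' share of the total allelic reads: points are ordered by total, the
#' cumulative read share is computed, and a point joins bin
#' `ceiling(share * n_bins)`. A point landing exactly on a boundary stays
#' in the lower bin.
#'
#' @param totals per-point total allelic read counts (all positive).
#' @param n_bins number of bins (>= 1; at most the number of points).
#' @return a list with `bin` (per-point bin index, input order) and
#'   `boundaries` (`data.frame` of per-bin total ranges).
#' @export
binByTotal <- function(totals, n_bins) {
  stopifnot(n_bins >= 1, all(totals > 0))
  if (length(totals) < n_bins)
    stop("fewer points than bins")
  ord <- order(totals)
  share <- cumsum(totals[ord]) / sum(totals)
  b <- pmin(n_bins, pmax(1L, ceiling(share * n_bins - 1e-9)))
  bin <- integer(length(totals))
  bin[ord] <- b
  boundaries <- do.call(rbind, lapply(seq_len(n_bins), function(i) {
    pts <- totals[bin == i]
    data.frame(bin = i,
               lower_total = if (length(pts)) min(pts) else NA_real_,
               upper_total = if (length(pts)) max(pts) else NA_real_)
  }))
  list(bin = bin, boundaries = boundaries)
}

# map new totals onto existing bin boundaries: first bin whose upper
# total covers the point; out-of-range points go to the nearest boundary
# bin
.assignBin <- function(totals, boundaries) {
  uppers <- boundaries$upper_total
  vapply(totals, function(t) {
    w <- which(!is.na(uppers) & t <= uppers)
    if (length(w)) w[1] else max(boundaries$bin[!is.na(uppers)])
  }, 0L)
}

#' Empirical quantile interval of autosomal bias values
#'
#' The interval `[(1-level)/2, 1-(1-level)/2]` empirical quantile range
#' (linear interpolation) containing `level` of the supplied autosomal
#' points.
#'
#' @param biases numeric vector of autosomal bias values (non-empty).
#' @param level confidence level (default 0.95; 1 gives `[min, max]`).
#' @return numeric vector `c(lower, upper)`.
#' @export
autosomalInterval <- function(biases, level = 0.95) {
  if (length(biases) == 0) stop("empty bin: no autosomal points")
  a <- (1 - level) / 2
  unname(quantile(biases, c(a, 1 - a), type = 7))
}

#' Build the binned autosomal null
#'
#' Bins the autosomal chromosome points by total allelic reads
#' (equal-read bins) and computes, per bin, the empirical interval
#' containing `level` of the autosomal bias values. X points never enter
#' the null construction.
#'
#' @param summaries output of [chromosomeAllelicSums()].
#' @param n_bins number of bins (default 4).
#' @param level interval level (default 0.95).
#' @param x_chrom the X chromosome name (excluded).
#' @param min_bin_points warn when a bin has fewer autosomal points
#'   (default 20).
#' @return a [BinnedNull-class] object.
#' @export
buildBinnedNull <- function(summaries, n_bins = 4, level = 0.95,
                            x_chrom = "chrX", min_bin_points = 20) {
  auto <- summaries[summaries$chromosome != x_chrom, , drop = FALSE]
  if (nrow(auto) == 0) stop("no autosomal points")
  bb <- binByTotal(auto$total, n_bins)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(i) {
    pts <- auto$bias[bb$bin == i]
    iv <- autosomalInterval(pts, level)
    data.frame(bin = i,
               lower_total = bb$boundaries$lower_total[i],
               upper_total = bb$boundaries$upper_total[i],
               lower = iv[1], upper = iv[2], n_points = length(pts))
  }))
  if (any(bins$n_points < min_bin_points))
    warning("bin(s) with fewer than ", min_bin_points,
            " autosomal points: ",
            paste(bins$bin[bins$n_points < min_bin_points],
                  collapse = ", "))
  new("BinnedNull", bins = bins, level = level, metric = "bias")
}

#' Classify per-cell X reactivation state against the binned null
#'
#' Each assessable cell's X point is placed in its read-count bin; an X
#' bias strictly above the bin's upper bound is significantly
#' non-reactivated (`XiXa_biased`), otherwise the X lies in the biallelic
#' autosomal range (`XaXa_range`). Cells failing the assessability filter
#' are `unassessable`. Since the bias metric is at least 0.5 by
#' construction, only the upper tail indicates monoallelic expression.
#'
#' @param summaries output of [chromosomeAllelicSums()].
#' @param null a [BinnedNull-class] from [buildBinnedNull()].
#' @param min_x_genes,min_x_reads assessability thresholds.
#' @param x_chrom the X chromosome name.
#' @return a `data.frame` with `cell_id`, `state`, `bin_id`, `x_bias`,
#'   `lower`, `upper`, `active_x_parent`, `total`.
#' @export
classifyXState <- function(summaries, null, min_x_genes = 3,
                           min_x_reads = 33, x_chrom = "chrX") {
  stopifnot(is(null, "BinnedNull"))
  xs <- summaries[summaries$chromosome == x_chrom, , drop = FALSE]
  if (nrow(xs) == 0)
    return(data.frame(cell_id = character(), state = character(),
                      bin_id = integer(), x_bias = numeric(),
                      lower = numeric(), upper = numeric(),
                      active_x_parent = character(), total = numeric(),
                      stringsAsFactors = FALSE))
  ok <- xs$cell_id %in% filterXCells(xs, min_x_genes, min_x_reads,
                                     x_chrom)
  bin_id <- .assignBin(xs$total, null@bins)
  lower <- null@bins$lower[bin_id]
  upper <- null@bins$upper[bin_id]
  state <- ifelse(!ok, "unassessable",
                  ifelse(xs$bias > upper, "XiXa_biased", "XaXa_range"))
  data.frame(
    cell_id = xs$cell_id, state = state, bin_id = bin_id,
    x_bias = xs$bias, lower = lower, upper = upper,
    active_x_parent = unname(assignActiveX(xs, x_chrom)),
    total = xs$total, stringsAsFactors = FALSE
  )
}

#' Held-out coverage of a binned null
#'
#' Fraction of (autosomal) points that fall inside their bin's interval —
#' the empirical calibration check of the biallelic range.
#'
#' @param null a [BinnedNull-class].
#' @param summaries chromosome summaries of independent points.
#' @param x_chrom X chromosome name (excluded).
#' @return the coverage fraction in `[0, 1]`.
#' @export
intervalCoverage <- function(null, summaries, x_chrom = "chrX") {
  auto <- summaries[summaries$chromosome != x_chrom, , drop = FALSE]
  bin_id <- .assignBin(auto$total, null@bins)
  inside <- auto$bias >= null@bins$lower[bin_id] &
    auto$bias <= null@bins$upper[bin_id]
  mean(inside)
}

#' Per-chromosome geometric-mean bias statistic
#'
#' For every (cell, chromosome), the geometric mean over its
#' SNP-containing genes of the per-gene max-allele fraction, computed with
#' a +1 pseudocount on both alleles: `(max(m, p) + pc) / (m + p + 2 pc)`.
#' The pseudocount shrinks low-coverage genes toward 0.5, making the
#' statistic robust to outlier genes.
#'
#' @param x an [AllelicCounts-class]; escapee X genes are excluded as in
#'   [chromosomeAllelicSums()].
#' @param pseudocount added to both alleles (default 1; 0 recovers the
#'   raw per-gene bias).
#' @param x_chrom the X chromosome name.
#' @return a `data.frame` with `cell_id`, `chromosome`, `gm`, `n_genes`,
#'   `total`.
#' @export
gmStatistics <- function(x, pseudocount = 1, x_chrom = "chrX") {
  ann <- as.data.frame(rowData(x))
  if (is.null(ann$gene)) ann$gene <- rownames(x)
  partition <- partitionXGenes(ann, x_chrom = x_chrom)
  keep <- ann$chromosome != x_chrom |
    ann$gene %in% partition$proper_genes
  m <- maternalCounts(x)[keep, , drop = FALSE]
  p <- paternalCounts(x)[keep, , drop = FALSE]
  chrom <- ann$chromosome[keep]
  tot <- m + p
  bias <- (pmax(m, p) + pseudocount) / (tot + 2 * pseudocount)
  logb <- ifelse(tot > 0, log(bias), 0)  # read-less genes contribute nothing
  n_g <- rowsum((tot > 0) * 1L, chrom)
  s_log <- rowsum(logb, chrom)
  t_sum <- rowsum(tot, chrom)
  o <- order(rownames(n_g))
  n_g <- n_g[o, , drop = FALSE]; s_log <- s_log[o, , drop = FALSE]
  t_sum <- t_sum[o, , drop = FALSE]
  out <- data.frame(
    cell_id = rep(colnames(m), each = nrow(n_g)),
    chromosome = rep(rownames(n_g), ncol(m)),
    gm = as.vector(exp(s_log / pmax(n_g, 1))),
    n_genes = as.vector(n_g), total = as.vector(t_sum),
    stringsAsFactors = FALSE
  )
  out <- out[out$n_genes > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Geometric-mean interval classifier
#'
#' The outlier-robust variant of [classifyXState()]: per-chromosome GM
#' bias statistics are compared against the pooled empirical interval of
#' autosomal GM values at `level` (default 99%). An X GM strictly above
#' the upper bound is called biased.
#'
#' @param x an [AllelicCounts-class], or a precomputed [gmStatistics()]
#'   table.
#' @param level interval level (default 0.99).
#' @param pseudocount forwarded to [gmStatistics()].
#' @param min_x_genes,min_x_reads assessability thresholds on the X
#'   (genes with reads, summed reads).
#' @param x_chrom the X chromosome name.
#' @return a list with `calls` (`cell_id`, `state`, `gm`, `lower`,
#'   `upper`) and `interval` (the autosomal GM interval).
#' @export
gmIntervalClassify <- function(x, level = 0.99, pseudocount = 1,
                               min_x_genes = 3, min_x_reads = 33,
                               x_chrom = "chrX") {
  gmst <- if (is(x, "AllelicCounts"))
    gmStatistics(x, pseudocount, x_chrom) else x
  auto <- gmst[gmst$chromosome != x_chrom, , drop = FALSE]
  if (nrow(auto) == 0) stop("no autosomal GM points")
  iv <- autosomalInterval(auto$gm, level)
  xs <- gmst[gmst$chromosome == x_chrom, , drop = FALSE]
  ok <- xs$n_genes >= min_x_genes & xs$total >= min_x_reads
  state <- ifelse(!ok, "unassessable",
                  ifelse(xs$gm > iv[2], "XiXa_biased", "XaXa_range"))
  list(calls = data.frame(cell_id = xs$cell_id, state = state,
                          gm = xs$gm, lower = iv[1], upper = iv[2],
                          stringsAsFactors = FALSE),
       interval = iv)
}

#' Paternal-X read-fraction summary per cell type
#'
#' @param summaries chromosome summaries; only X rows are used.
#' @param groups named vector cell_id -> cell type.
#' @param x_chrom the X chromosome name.
#' @return a list with `per_cell` (`cell_id`, `group`,
#'   `paternal_fraction`) and `quartiles` (per group 25/50/75%).
#' @export
paternalFractionSummary <- function(summaries, groups,
                                    x_chrom = "chrX") {
  xs <- summaries[summaries$chromosome == x_chrom, , drop = FALSE]
  per_cell <- data.frame(cell_id = xs$cell_id,
                         group = unname(groups[xs$cell_id]),
                         paternal_fraction = xs$paternal_fraction,
                         stringsAsFactors = FALSE)
  sp <- split(per_cell$paternal_fraction, per_cell$group)
  quartiles <- do.call(rbind, lapply(names(sp), function(g) {
    q <- quantile(sp[[g]], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, q25 = q[1], median = q[2], q75 = q[3],
               n = length(sp[[g]]), stringsAsFactors = FALSE)
  }))
  list(per_cell = per_cell, quartiles = quartiles)
}

#' Rank cells by X-chromosome allelic bias
#'
#' Descending bias; ties broken by total reads (descending) then cell id,
#' so the ranking is deterministic.
#'
#' @param summaries chromosome summaries; only X rows are used.
#' @param x_chrom the X chromosome name.
#' @return the X summaries reordered, with a `rank` column.
#' @export
rankCellsByXBias <- function(summaries, x_chrom = "chrX") {
  xs <- summaries[summaries$chromosome == x_chrom, , drop = FALSE]
  o <- order(-xs$bias, -xs$total, xs$cell_id)
  xs <- xs[o, , drop = FALSE]
  xs$rank <- seq_len(nrow(xs))
  rownames(xs) <- NULL
  xs
}

#' Median monoallelic-bias XCI classifier
#'
#' The per-cell classifier used when too few cells support a binned null:
#' a cell whose median per-gene monoallelic bias over proper X genes is at
#' least `threshold` (inclusive) is in XCI state.
#'
#' @param per_gene_biases numeric vector of per-gene max-allele fractions
#'   of one cell's proper X genes.
#' @param threshold median-bias threshold (default 0.95).
#' @return `"XCI"`, `"not_XCI"`, or `"unassessable"` when no gene has
#'   reads.
#' @export
medianBiasClassifier <- function(per_gene_biases, threshold = 0.95) {
  b <- per_gene_biases[!is.na(per_gene_biases)]
  if (length(b) == 0) return("unassessable")
  if (median(b) >= threshold) "XCI" else "not_XCI"
}

#' Apply the median-bias classifier to every cell
#'
#' @param x an [AllelicCounts-class].
#' @param threshold forwarded to [medianBiasClassifier()].
#' @param x_chrom the X chromosome name.
#' @return a `data.frame` with `cell_id`, `median_bias`, `call`.
#' @export
xMedianBiasCalls <- function(x, threshold = 0.95, x_chrom = "chrX") {
  ann <- as.data.frame(rowData(x))
  if (is.null(ann$gene)) ann$gene <- rownames(x)
  partition <- partitionXGenes(ann, x_chrom = x_chrom)
  keep <- ann$gene %in% partition$proper_genes
  m <- maternalCounts(x)[keep, , drop = FALSE]
  p <- paternalCounts(x)[keep, , drop = FALSE]
  tot <- m + p
  bias <- ifelse(tot > 0, pmax(m, p) / tot, NA_real_)
  do.call(rbind, lapply(seq_len(ncol(bias)), function(j) {
    b <- bias[, j]
    data.frame(cell_id = colnames(bias)[j],
               median_bias = if (all(is.na(b))) NA_real_
               else median(b, na.rm = TRUE),
               call = medianBiasClassifier(b, threshold),
               stringsAsFactors = FALSE)
  }))
}

#' Negative binomial two-group differential expression
#'
#' Per gene, a two-group test of equal means under a negative binomial
#' model: the gene-wise dispersion is estimated by method of moments from
#' the pooled within-group variances (floored at Poisson), and the
#' difference of group means is tested with a Wald statistic whose
#' variance follows the NB mean-variance relation. P-values are adjusted
#' across tested genes by Benjamini-Hochberg. Genes with no reads in
#' either group are skipped.
#'
#' @param counts genes x cells matrix of non-negative integer expression
#'   counts.
#' @param group_a,group_b character vectors of cell ids (>= 2 cells
#'   each).
#' @return a `data.frame` with `gene`, `mean_a`, `mean_b`, `log2fc`,
#'   `dispersion`, `p_value`, `q_value`, ordered by `p_value`.
#' @export
differentialExpressionNB <- function(counts, group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            all(c(group_a, group_b) %in% colnames(counts)))
  A <- counts[, group_a, drop = FALSE]
  B <- counts[, group_b, drop = FALSE]
  keep <- rowSums(A) + rowSums(B) > 0
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  mu_a <- rowMeans(A); mu_b <- rowMeans(B)
  s2_a <- apply(A, 1, var); s2_b <- apply(B, 1, var)
  s2_w <- ((na - 1) * s2_a + (nb - 1) * s2_b) / (na + nb - 2)
  mu_w <- (na * mu_a + nb * mu_b) / (na + nb)
  disp <- pmax(0, (s2_w - mu_w) / mu_w^2)   # Poisson floor
  v_a <- (mu_a + disp * mu_a^2) / na
  v_b <- (mu_b + disp * mu_b^2) / nb
  z <- (mu_a - mu_b) / sqrt(v_a + v_b)
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(
    gene = rownames(A), mean_a = mu_a, mean_b = mu_b,
    log2fc = log2((mu_a + 0.5) / (mu_b + 0.5)),
    dispersion = disp, p_value = p,
    q_value = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
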