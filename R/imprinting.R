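# Imprinting module: parent-of-origin expression of confirmed imprinted
# genes relative to the expected allele, aggregated per imprinted
# gene-cluster, with a fair-coin allelic-dropout significance model for
# monoallelic expression.

#' Per-cell expected-allele expression ratios of imprinted genes
#'
#' For each (cell, gene) entry of a confirmed imprinted gene with at least
#' one allelic read, the ratio of reads from the expected (by imprinting)
#' parental allele to all allelic reads. 1 means fully monoallelic from
#' the expected allele, 0.5 biallelic. Genes with status other than
#' `"confirmed"` (predicted, provisional, ...) never enter.
#'
#' @param x an [AllelicCounts-class] object.
#' @param annotation optional imprint annotation `data.frame` (`gene`,
#'   `imprint_cluster`, `expected_allele`, `imprint_status`); defaults to
#'   `rowData(x)`.
#' @return a `data.frame` with columns `cell_id`, `gene`,
#'   `imprint_cluster`, `ratio`, `total_reads`.
#' @export
expectedAlleleRatio <- function(x, annotation = NULL) {
  if (is.null(annotation))
    annotation <- as.data.frame(rowData(x))
  if (is.null(annotation$gene)) annotation$gene <- rownames(annotation)
  need <- c("gene", "expected_allele", "imprint_status")
  stopifnot(all(need %in% names(annotation)))
  ann <- annotation[annotation$imprint_status == "confirmed" &
                      !is.na(annotation$expected_allele), , drop = FALSE]
  genes <- intersect(ann$gene, rownames(x))
  if (length(genes) == 0)
    return(data.frame(cell_id = character(), gene = character(),
                      imprint_cluster = character(), ratio = numeric(),
                      total_reads = integer(), stringsAsFactors = FALSE))
  ann <- ann[match(genes, ann$gene), ]
  m <- maternalCounts(x)[genes, , drop = FALSE]
  p <- paternalCounts(x)[genes, , drop = FALSE]
  tot <- m + p
  expected <- ifelse(ann$expected_allele == "maternal", 1, 0)
  expReads <- sweep(m, 1, expected, "*") +
    sweep(p, 1, 1 - expected, "*")
  keep <- which(tot >= 1, arr.ind = TRUE)
  cluster <- if (is.null(ann$imprint_cluster)) NA_character_
  else ann$imprint_cluster
  out <- data.frame(
    cell_id = colnames(m)[keep[, 2]],
    gene = genes[keep[, 1]],
    imprint_cluster = cluster[keep[, 1]],
    ratio = expReads[keep] / tot[keep],
    total_reads = tot[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$cell_id, out$gene), , drop = FALSE]
}

#' Monoallelic expression significance under random allelic dropout
#'
#' Null model: in every cell, allelic dropout independently exposes either
#' parental allele with probability 1/2, so observing the specific expected
#' allele alone in all of n cells has probability (1/2)^n. Monoallelic
#' expression in 5 or more cells is significant at alpha = 0.05
#' ((1/2)^5 = 0.03125 < 0.05 <= (1/2)^4).
#'
#' @param n_cells_same_allele number(s) of cells observed monoallelic for
#'   the expected allele (vectorized).
#' @param alpha significance level (default 0.05).
#' @return a `data.frame` with columns `n`, `p_value`, `significant`.
#' @examples
#' monoallelicDropoutTest(4:6)
#' @export
monoallelicDropoutTest <- function(n_cells_same_allele, alpha = 0.05) {
  n <- n_cells_same_allele
  stopifnot(all(n >= 0), n == round(n))
  p <- 0.5^n
  data.frame(n = n, p_value = p, significant = p < alpha)
}

#' Count cells monoallelic for the expected allele, per gene
#'
#' Helper feeding [monoallelicDropoutTest()]: a cell counts as monoallelic
#' for a gene when its expected-allele ratio equals 1 with at least
#' `min_reads` allelic reads.
#'
#' @param ratios output of [expectedAlleleRatio()].
#' @param min_reads minimum allelic reads for a cell to count (default 1).
#' @param alpha significance level passed through.
#' @return per-gene `data.frame` with `gene`, `n_cells`,
#'   `n_monoallelic_expected`, `p_value`, `significant`.
#' @export
monoallelicGeneTest <- function(ratios, min_reads = 1, alpha = 0.05) {
  sp <- split(ratios, ratios$gene)
  out <- do.call(rbind, lapply(sp, function(d) {
    n_mono <- sum(d$ratio == 1 & d$total_reads >= min_reads)
    data.frame(gene = d$gene[1], n_cells = nrow(d),
               n_monoallelic_expected = n_mono,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  cbind(out, monoallelicDropoutTest(out$n_monoallelic_expected,
                                    alpha)[c("p_value", "significant")])
}

#' Summarize expected-allele ratios per imprinted cluster and cell group
#'
#' @param ratios output of [expectedAlleleRatio()] (must carry
#'   `imprint_cluster`).
#' @param groups optional named vector cell_id -> group (e.g. stage);
#'   omitted, all cells form one group.
#' @return a `data.frame` with `imprint_cluster`, `group`, `median`,
#'   `mean`, `n_cells`, `n_reads`. Empty clusters are omitted with a
#'   warning.
#' @export
clusterBiasSummary <- function(ratios, groups = NULL) {
  if (is.null(groups))
    groups <- setNames(rep("all", length(unique(ratios$cell_id))),
                       unique(ratios$cell_id))
  ratios$group <- unname(groups[ratios$cell_id])
  ratios <- ratios[!is.na(ratios$imprint_cluster) &
                     ratios$imprint_cluster != "none", , drop = FALSE]
  if (nrow(ratios) == 0) {
    warning("no ratios in any imprinted cluster")
    return(data.frame(imprint_cluster = character(), group = character(),
                      median = numeric(), mean = numeric(),
                      n_cells = integer(), n_reads = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(ratios, list(ratios$imprint_cluster, ratios$group),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    imprint_cluster = d$imprint_cluster[1], group = d$group[1],
    median = median(d$ratio), mean = mean(d$ratio),
    n_cells = length(unique(d$cell_id)), n_reads = sum(d$total_reads),
    stringsAsFactors = FALSE
  )))
  rownames(out) <- NULL
  out[order(out$imprint_cluster, out$group), , drop = FALSE]
}

#' Compare allelic-bias distributions between two cell groups
#'
#' One-sided Mann-Whitney-Wilcoxon test that group A's ratios are shifted
#' above group B's. Exact enumeration when both groups have at most
#' `exact_max` observations and no ties; the tie-corrected normal
#' approximation otherwise.
#'
#' @param group_a,group_b numeric vectors of ratios (non-empty).
#' @param alternative `"greater"` (a > b, default), `"less"` or
#'   `"two.sided"`.
#' @param exact_max maximum per-group size for the exact test (default 8).
#' @return the p-value.
#' @export
compareBiasDistributions <- function(group_a, group_b,
                                     alternative = "greater",
                                     exact_max = 8) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && length(group_a) <= exact_max &&
    length(group_b) <= exact_max
  suppressWarnings(
    wilcox.test(group_a, group_b, alternative = alternative,
                exact = exact, correct = !exact)$p.value
  )
}
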