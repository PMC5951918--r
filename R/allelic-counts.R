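# Allele-of-origin read assignment and cell-level QC. A read is usable only
# when it maps uniquely against BOTH parental references; among usable reads
# the strictly smaller edit distance decides the parental allele, and ties
# stay ambiguous (dropped, never fractionally split).

#' Assign reads to a parental allele by edit distance
#'
#' @param pairs a `data.frame` of alignment pairs with columns
#'   `unique_maternal`, `unique_paternal` (logical),
#'   `edit_distance_maternal`, `edit_distance_paternal` (non-negative).
#' @return a character vector over rows of `pairs`, each one of
#'   `"maternal"`, `"paternal"`, `"ambiguous"`, `"unusable"`.
#' @examples
#' assignReadOrigin(data.frame(unique_maternal = TRUE,
#'                             unique_paternal = TRUE,
#'                             edit_distance_maternal = 2,
#'                             edit_distance_paternal = 0))
#' @export
assignReadOrigin <- function(pairs) {
  stopifnot(all(c("unique_maternal", "unique_paternal",
                  "edit_distance_maternal",
                  "edit_distance_paternal") %in% names(pairs)))
  stopifnot(all(pairs$edit_distance_maternal >= 0),
            all(pairs$edit_distance_paternal >= 0))
  usable <- pairs$unique_maternal & pairs$unique_paternal
  out <- rep("unusable", nrow(pairs))
  em <- pairs$edit_distance_maternal
  ep <- pairs$edit_distance_paternal
  out[usable & em < ep] <- "maternal"
  out[usable & ep < em] <- "paternal"
  out[usable & em == ep] <- "ambiguous"
  out
}

#' Tabulate parental read counts per gene for one cell
#'
#' Counts maternal- and paternal-assigned reads per gene; ambiguous and
#' unusable reads are excluded. Genes with no assigned read are absent.
#'
#' @param pairs alignment-pair table with a `gene` column plus the columns
#'   [assignReadOrigin()] needs.
#' @param cell_id the cell the pairs belong to.
#' @return a `data.frame` with columns `cell_id`, `gene`,
#'   `maternal_reads`, `paternal_reads`, suitable for
#'   [readAllelicCounts()]-style assembly.
#' @export
countAlleles <- function(pairs, cell_id) {
  origin <- assignReadOrigin(pairs)
  keep <- origin %in% c("maternal", "paternal")
  if (!any(keep))
    return(data.frame(cell_id = character(), gene = character(),
                      maternal_reads = integer(),
                      paternal_reads = integer(),
                      stringsAsFactors = FALSE))
  g <- pairs$gene[keep]
  o <- origin[keep]
  genes <- sort(unique(g))
  m <- as.integer(table(factor(g[o == "maternal"], levels = genes)))
  p <- as.integer(table(factor(g[o == "paternal"], levels = genes)))
  data.frame(cell_id = cell_id, gene = genes, maternal_reads = m,
             paternal_reads = p, stringsAsFactors = FALSE)
}

#' Transcriptome-size cell filter
#'
#' Keeps cells expressing at least `min_genes` genes (expression strictly
#' positive); the boundary is inclusive.
#'
#' @param expression_matrix genes x cells matrix of non-negative values.
#' @param min_genes minimum number of expressed genes (default 7500).
#' @return character vector of kept cell ids.
#' @export
filterCellsExpression <- function(expression_matrix, min_genes = 7500) {
  if (length(expression_matrix) == 0 || ncol(expression_matrix) == 0)
    return(character(0))
  stopifnot(all(expression_matrix >= 0, na.rm = TRUE))
  n_expr <- colSums(expression_matrix > 0)
  colnames(expression_matrix)[n_expr >= min_genes]
}

#' Lowest-quintile allelic-coverage cell filter
#'
#' Excludes every cell lying in the lowest quintile of total allelic reads
#' OR of SNP-containing genes (union of the two exclusions). A cell is
#' removed when its metric falls strictly below the quintile boundary
#' (empirical 20th percentile, linear interpolation); ties at the boundary
#' are kept, so identical cells are never removed.
#'
#' The returned vector carries the two boundary values as a `thresholds`
#' attribute; passing them back via `thresholds` re-applies the filter with
#' fixed boundaries (the identity on an already-filtered set) instead of
#' recomputing quantiles on the subset.
#'
#' @param x an [AllelicCounts-class] object or a `data.frame` with columns
#'   `cell_id`, `n_snp_genes`, `n_allelic_reads`.
#' @param quintile_fraction the excluded lower fraction (default 0.2).
#' @param thresholds optional fixed boundaries
#'   `c(n_allelic_reads = ..., n_snp_genes = ...)`; when supplied the
#'   quantiles are not recomputed.
#' @return character vector of kept cell ids, with attribute `thresholds`.
#' @export
filterCellsAllelicQuintile <- function(x, quintile_fraction = 0.2,
                                       thresholds = NULL) {
  stats <- if (is(x, "AllelicCounts")) as.data.frame(cellAllelicStats(x))
  else as.data.frame(x)
  stopifnot(all(c("cell_id", "n_snp_genes", "n_allelic_reads") %in%
                  names(stats)))
  if (is.null(thresholds)) {
    if (nrow(stats) < 5)
      stop("quintiles undefined for fewer than 5 cells")
    thresholds <- c(
      n_allelic_reads = quantile(stats$n_allelic_reads,
                                 quintile_fraction, type = 7,
                                 names = FALSE),
      n_snp_genes = quantile(stats$n_snp_genes, quintile_fraction,
                             type = 7, names = FALSE)
    )
  }
  drop <- stats$n_allelic_reads < thresholds[["n_allelic_reads"]] |
    stats$n_snp_genes < thresholds[["n_snp_genes"]]
  structure(stats$cell_id[!drop], thresholds = thresholds)
}
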