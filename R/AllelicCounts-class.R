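#' AllelicCounts: per-cell, per-gene parental allele read counts
#'
#' `AllelicCounts` extends [SummarizedExperiment::SummarizedExperiment] with
#' two integer assays, `"maternal"` and `"paternal"`, holding the number of
#' reads assigned to each parental allele for every gene (rows) in every cell
#' (columns). Gene annotation (chromosome, imprinted-cluster membership,
#' expected imprinted allele, escapee flag) lives in `rowData`; per-cell
#' metadata (stage labels, simulation truth) lives in `colData`. All allelic
#' analyses in the package consume this container.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#'
#' @seealso [AllelicCounts()] the constructor, [maternalCounts()],
#'   [paternalCounts()], [cellAllelicStats()]
#' @export
setClass("AllelicCounts", contains = "SummarizedExperiment")

setValidity("AllelicCounts", function(object) {
  an <- assayNames(object)
  if (!all(c("maternal", "paternal") %in% an))
    return("assays must include 'maternal' and 'paternal'")
  m <- assay(object, "maternal")
  p <- assay(object, "paternal")
  if (any(m < 0, na.rm = TRUE) || any(p < 0, na.rm = TRUE))
    return("allelic counts must be non-negative")
  if (!identical(dim(m), dim(p)))
    return("maternal and paternal assays must have identical dimensions")
  TRUE
})

#' Construct an AllelicCounts object
#'
#' @param maternal,paternal gene-by-cell matrices of non-negative read counts
#'   assigned to the maternal and paternal allele. Dimnames are required
#'   (genes as rownames, cell ids as colnames).
#' @param geneAnnotation optional `data.frame`/`DataFrame` of per-gene
#'   annotation, one row per gene, with at least a `chromosome` column and
#'   optionally `imprint_cluster`, `expected_allele`
#'   (`"maternal"`/`"paternal"`), `imprint_status` and logical `escapee`.
#' @param cellData optional per-cell `data.frame`/`DataFrame`.
#'
#' @return an [AllelicCounts-class] object.
#' @examples
#' m <- matrix(c(3L, 2L), 2, 1, dimnames = list(c("g1", "g2"), "cellA"))
#' p <- matrix(c(1L, 2L), 2, 1, dimnames = list(c("g1", "g2"), "cellA"))
#' ac <- AllelicCounts(m, p)
#' cellAllelicStats(ac)
#' @export
AllelicCounts <- function(maternal, paternal, geneAnnotation = NULL,
                          cellData = NULL) {
  maternal <- as.matrix(maternal)
  paternal <- as.matrix(paternal)
  stopifnot(identical(dim(maternal), dim(paternal)))
  if (is.null(rownames(maternal)))
    stop("gene rownames are required")
  if (is.null(colnames(maternal)))
    stop("cell colnames are required")
  args <- list(assays = list(maternal = maternal, paternal = paternal))
  if (!is.null(geneAnnotation)) {
    geneAnnotation <- as(geneAnnotation, "DataFrame")
    if (!is.null(geneAnnotation$gene))
      rownames(geneAnnotation) <- geneAnnotation$gene
    geneAnnotation <- geneAnnotation[rownames(maternal), , drop = FALSE]
    args$rowData <- geneAnnotation
  }
  if (!is.null(cellData)) {
    cellData <- as(cellData, "DataFrame")
    if (!is.null(cellData$cell_id))
      rownames(cellData) <- cellData$cell_id
    cellData <- cellData[colnames(maternal), , drop = FALSE]
    args$colData <- cellData
  }
  se <- do.call(SummarizedExperiment, args)
  new("AllelicCounts", se)
}

#' @describeIn AllelicCounts maternal read-count assay
#' @param x an `AllelicCounts` object
#' @export
maternalCounts <- function(x) assay(x, "maternal")

#' @describeIn AllelicCounts paternal read-count assay
#' @export
paternalCounts <- function(x) assay(x, "paternal")

#' @describeIn AllelicCounts total allelic reads per gene and cell
#' @export
allelicTotals <- function(x) maternalCounts(x) + paternalCounts(x)

#' Per-cell allelic coverage statistics
#'
#' Recomputes, from the count assays, the two per-cell quantities the QC
#' filters act on: the number of SNP-containing genes (genes with at least
#' one allelic read) and the total number of allelic reads.
#'
#' @param x an [AllelicCounts-class] object
#' @return a `DataFrame` with columns `cell_id`, `n_snp_genes`,
#'   `n_allelic_reads`.
#' @export
cellAllelicStats <- function(x) {
  tot <- allelicTotals(x)
  DataFrame(
    cell_id = colnames(tot),
    n_snp_genes = unname(colSums(tot > 0)),
    n_allelic_reads = unname(colSums(tot)),
    row.names = colnames(tot)
  )
}

setMethod("show", "AllelicCounts", function(object) {
  cat("AllelicCounts:", nrow(object), "genes x", ncol(object), "cells\n")
  st <- cellAllelicStats(object)
  cat("  allelic reads/cell: median",
      stats::median(st$n_allelic_reads), "\n")
  cat("  SNP-containing genes/cell: median",
      stats::median(st$n_snp_genes), "\n")
  callNextMethod()
})

#' Read and write allelic count tables
#'
#' The on-disk interchange format is a long TSV with columns
#' `cell_id`, `gene`, `maternal_reads`, `paternal_reads`.
#'
#' @param path file path
#' @param geneAnnotation,cellData forwarded to [AllelicCounts()]
#' @return `readAllelicCounts` returns an [AllelicCounts-class];
#'   `writeAllelicCounts` invisibly returns `path`.
#' @export
readAllelicCounts <- function(path, geneAnnotation = NULL, cellData = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "gene", "maternal_reads", "paternal_reads")
  if (!all(need %in% names(tab)))
    stop("allelic count table must have columns: ",
         paste(need, collapse = ", "))
  genes <- sort(unique(tab$gene))
  cells <- unique(tab$cell_id)
  m <- matrix(0L, length(genes), length(cells),
              dimnames = list(genes, cells))
  p <- m
  idx <- cbind(match(tab$gene, genes), match(tab$cell_id, cells))
  m[idx] <- as.integer(tab$maternal_reads)
  p[idx] <- as.integer(tab$paternal_reads)
  AllelicCounts(m, p, geneAnnotation = geneAnnotation, cellData = cellData)
}

#' @rdname readAllelicCounts
#' @param x an [AllelicCounts-class] object
#' @export
writeAllelicCounts <- function(x, path) {
  m <- maternalCounts(x)
  p <- paternalCounts(x)
  keep <- which(m + p > 0, arr.ind = TRUE)
  tab <- data.frame(
    cell_id = colnames(m)[keep[, 2]],
    gene = rownames(m)[keep[, 1]],
    maternal_reads = m[keep],
    paternal_reads = p[keep],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$cell_id, tab$gene), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
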