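# Staging module: marker-panel based assignment of germ-cell developmental
# stage (PGC / LGC / MGC / somatic) via Spearman hierarchical clustering.

.STAGES <- c("PGC", "LGC", "MGC", "somatic")

#' Median-normalize an expression matrix
#'
#' Divides each cell's values by that cell's median over its positive
#' genes, then multiplies by the global median of those per-cell medians so
#' the overall scale is preserved.
#'
#' @param expression_matrix genes x cells matrix of non-negative values
#'   (FPKM-like); every cell must express at least one gene.
#' @return the normalized matrix, same dimensions.
#' @export
medianNormalize <- function(expression_matrix) {
  m <- as.matrix(expression_matrix)
  stopifnot(all(m >= 0, na.rm = TRUE))
  cell_med <- apply(m, 2, function(v) median(v[v > 0]))
  if (any(is.na(cell_med)))
    stop("all-zero cell(s): ",
         paste(colnames(m)[is.na(cell_med)], collapse = ", "))
  global <- median(cell_med)
  sweep(m, 2, cell_med, "/") * global
}

#' Cluster cells on a marker panel and label the clusters by stage
#'
#' Cells are clustered with average-linkage hierarchical clustering on
#' 1 - Spearman correlation over the panel genes, the tree is cut into `k`
#' clusters, and each cluster is labeled by its panel-category expression:
#' the cluster highest in somatic markers is `somatic`, the highest in
#' meiotic markers is `MGC`, the highest in pluripotency + early germ
#' markers is `PGC`, and intermediate clusters are `LGC`. Panel genes
#' absent from the matrix are dropped with a warning.
#'
#' @param normalized genes x cells matrix (see [medianNormalize()]).
#' @param panel marker panel `data.frame` (`gene`, `category` with
#'   categories among pluripotency, early_germ, late, meiotic, somatic).
#' @param k number of clusters to cut (default 4).
#' @param linkage linkage method for [stats::hclust] (default
#'   `"average"`).
#' @return a `data.frame` with columns `cell_id`, `stage`, `cluster_id`.
#' @export
clusterAndStage <- function(normalized, panel, k = 4,
                            linkage = "average") {
  stopifnot(nrow(panel) > 0, !anyDuplicated(panel$gene))
  if (k > ncol(normalized))
    stop("k exceeds the number of cells")
  present <- panel$gene %in% rownames(normalized)
  if (!all(present))
    warning("panel gene(s) not in expression matrix, dropped: ",
            paste(panel$gene[!present], collapse = ", "))
  panel <- panel[present, , drop = FALSE]
  if (nrow(panel) < 2)
    stop("fewer than 2 panel genes available")
  sub <- normalized[panel$gene, , drop = FALSE]
  rho <- cor(sub, method = "spearman")
  d <- as.dist(1 - rho)
  cl <- cutree(hclust(d, method = linkage), k = k)

  # per-cluster mean expression of each panel category, z-scored across
  # clusters so categories with different scales compare fairly
  cats <- c("pluripotency", "early_germ", "late", "meiotic", "somatic")
  score <- vapply(cats, function(cat) {
    g <- panel$gene[panel$category == cat]
    if (length(g) == 0) return(rep(0, k))
    vapply(seq_len(k), function(ci)
      mean(sub[g, cl == ci, drop = FALSE]), 0)
  }, numeric(k))
  score <- matrix(score, nrow = k, dimnames = list(NULL, cats))
  if (k > 1) score <- scale(score)
  score[is.na(score)] <- 0
  stage_score <- cbind(
    PGC = (score[, "pluripotency"] + score[, "early_germ"]) / 2,
    LGC = score[, "late"],
    MGC = score[, "meiotic"],
    somatic = score[, "somatic"]
  )
  lab <- .labelClusters(stage_score)
  data.frame(cell_id = colnames(normalized), stage = lab[cl],
             cluster_id = unname(cl), stringsAsFactors = FALSE)
}

# greedy unique stage assignment while unique labels are possible;
# remaining clusters (k > 4) take their argmax stage
.labelClusters <- function(stage_score) {
  k <- nrow(stage_score)
  lab <- rep(NA_character_, k)
  sc <- stage_score
  for (i in seq_len(min(k, ncol(sc)))) {
    best <- which(sc == max(sc), arr.ind = TRUE)[1, ]
    lab[best["row"]] <- colnames(sc)[best["col"]]
    sc[best["row"], ] <- -Inf
    sc[, best["col"]] <- -Inf
  }
  left <- is.na(lab)
  if (any(left))
    lab[left] <- colnames(stage_score)[
      apply(stage_score[left, , drop = FALSE], 1, which.max)]
  lab
}

#' Tenfold stage-enriched genes
#'
#' A gene is enriched in a group when its mean there is at least ten times
#' its mean over all other groups combined (and positive); genes silent
#' everywhere else but expressed in the group count as enriched.
#'
#' @param normalized genes x cells matrix.
#' @param groups character vector over cells giving each cell's group.
#' @param fold enrichment factor (default 10).
#' @return a named list, one character vector of enriched genes per group.
#' @export
tenfoldEnrichedGenes <- function(normalized, groups, fold = 10) {
  stopifnot(ncol(normalized) == length(groups))
  ug <- unique(groups)
  if (length(ug) < 2) stop("need at least 2 groups")
  setNames(lapply(ug, function(g) {
    in_g <- groups == g
    mean_in <- rowMeans(normalized[, in_g, drop = FALSE])
    mean_out <- rowMeans(normalized[, !in_g, drop = FALSE])
    enriched <- mean_in > 0 & (mean_out == 0 | mean_in >= fold * mean_out)
    rownames(normalized)[enriched]
  }), ug)
}
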