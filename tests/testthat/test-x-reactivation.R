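# chromosome sums, equal-read binning, empirical null, classifiers, NB DE

test_that("escapee partition is an exact set difference", {
  ann <- data.frame(gene = c(paste0("x", 1:10), "a1"),
                    chromosome = c(rep("chrX", 10), "chr1"),
                    escapee = c(rep(FALSE, 10), FALSE))
  part <- partitionXGenes(ann, escapee_list = paste0("x", 1:4))
  expect_setequal(part$proper_genes, paste0("x", 5:10))
  expect_setequal(part$escapee_genes, paste0("x", 1:4))
  expect_length(intersect(part$proper_genes, part$escapee_genes), 0)
  # no escapees: everything is proper; all escapees: proper set empty
  expect_length(partitionXGenes(ann)$escapee_genes, 0)
  all_esc <- partitionXGenes(ann, escapee_list = paste0("x", 1:10))
  expect_length(all_esc$proper_genes, 0)
})

test_that("chromosome sums add gene counts and exclude escapees on the X", {
  ac <- tinyCounts()
  s <- chromosomeAllelicSums(ac)
  chr1 <- s[s$cell_id == "cellA" & s$chromosome == "chr1", ]
  expect_equal(chr1$M, 5); expect_equal(chr1$P, 3)
  expect_equal(chr1$bias, 0.625)
  # X excludes the escapee e1 (5,5): proper x1 (0,10) + x2 (1,9)
  chrX <- s[s$cell_id == "cellA" & s$chromosome == "chrX", ]
  expect_equal(chrX$M, 1); expect_equal(chrX$P, 19)
  expect_equal(chrX$n_snp_genes, 2)
  # single monoallelic gene gives bias 1
  sB <- s[s$cell_id == "cellB" & s$chromosome == "chr11", ]
  expect_equal(sB$bias, 1.0)

  # brute-force tally oracle on a simulated cell
  pop <- plantedPopulation(n_xixa = 1, n_xaxa = 1, depth = 2000, seed = 4)
  s2 <- chromosomeAllelicSums(pop$counts)
  m <- maternalCounts(pop$counts); p <- paternalCounts(pop$counts)
  ann <- pop$annotation
  for (ch in c("chr1", "chr7")) {
    genes <- ann$gene[ann$chromosome == ch]
    row <- s2[s2$cell_id == "cell001" & s2$chromosome == ch, ]
    expect_equal(row$M, sum(m[genes, "cell001"]))
    expect_equal(row$P, sum(p[genes, "cell001"]))
  }
})

test_that("X assessability bounds are inclusive at 3 genes and 33 reads", {
  mk <- function(id, genes, total) data.frame(
    cell_id = id, chromosome = "chrX", M = total, P = 0, total = total,
    n_snp_genes = genes, paternal_fraction = 0, bias = 1)
  s <- rbind(mk("ok", 3, 33), mk("few_genes", 2, 100),
             mk("few_reads", 3, 32))
  expect_equal(filterXCells(s), "ok")
})

test_that("active X is the parent with more summed reads", {
  s <- data.frame(cell_id = c("m", "t", "p"), chromosome = "chrX",
                  M = c(40, 5, 2), P = c(2, 5, 40),
                  total = c(42, 10, 42), n_snp_genes = 3,
                  paternal_fraction = 0.5, bias = 0.9)
  expect_equal(unname(assignActiveX(s)), c("maternal", "tied", "paternal"))
  # at leak 0.02 and decent depth the truth parent is recovered nearly always
  prof <- cellSimProfiles(100, x_state = "XiXa", depth = 2500,
                          dropout_rate = 0, seed = 12)
  ann <- simGeneAnnotation(n_autosomal = 40, n_x_proper = 5, n_escapee = 0,
                           genes_per_cluster = 0)
  ac <- simulateAllelicCounts(prof, ann, seed = 13)
  sums <- chromosomeAllelicSums(ac)
  act <- assignActiveX(sums)
  expect_gte(mean(act[prof$cell_id] == prof$active_x_parent_truth), 0.95)
})

test_that("equal-read bins split cumulative read share, ties to the lower bin", {
  bb <- binByTotal(c(10, 10, 10, 10), 2)
  expect_equal(as.vector(table(bb$bin)), c(2L, 2L))
  expect_equal(binByTotal(c(5, 9, 2), 1)$bin, c(1, 1, 1))
  expect_error(binByTotal(c(5, 9), 3), "fewer points")
  # cumulative-share oracle: each bin's read share within one point of 25%
  set.seed(14)
  totals <- rnbinom(100, mu = 200, size = 1) + 1
  bb4 <- binByTotal(totals, 4)
  shares <- tapply(totals, bb4$bin, sum) / sum(totals)
  expect_true(all(abs(shares - 0.25) <= (max(totals) + 1) / sum(totals)))
  # every point maps to exactly one bin and bins are ordered by total
  expect_true(all(bb4$bin %in% 1:4))
  expect_true(all(diff(bb4$boundaries$upper_total) >= 0))
})

test_that("autosomal interval is the linear-interpolation quantile pair", {
  biases <- seq(0.5, 1.0, length.out = 101)
  expect_equal(autosomalInterval(biases, 0.95), c(0.5125, 0.9875))
  expect_equal(autosomalInterval(rep(0.7, 9)), c(0.7, 0.7))
  expect_equal(autosomalInterval(biases, 1.0), c(0.5, 1.0))
  expect_error(autosomalInterval(numeric(0)), "empty bin")
})

test_that("X state classification is strict at the upper bound and monotone", {
  null <- new("BinnedNull",
              bins = data.frame(bin = 1, lower_total = 1,
                                upper_total = 1000, lower = 0.50,
                                upper = 0.70, n_points = 100),
              level = 0.95, metric = "bias")
  mk <- function(id, bias) data.frame(
    cell_id = id, chromosome = "chrX", M = round(100 * bias),
    P = 100 - round(100 * bias), total = 100, n_snp_genes = 5,
    paternal_fraction = 1 - bias, bias = bias)
  s <- rbind(mk("hi", 0.99), mk("at", 0.70), mk("lo", 0.55))
  calls <- classifyXState(s, null)
  expect_equal(calls$state[calls$cell_id == "hi"], "XiXa_biased")
  expect_equal(calls$state[calls$cell_id == "at"], "XaXa_range")
  expect_equal(calls$state[calls$cell_id == "lo"], "XaXa_range")
  # monotonicity: raising a biased cell's bias never reverts the call
  grid <- seq(0.71, 1, by = 0.01)
  states <- classifyXState(do.call(rbind, lapply(seq_along(grid),
    function(i) mk(paste0("c", i), grid[i]))), null)$state
  expect_true(all(states == "XiXa_biased"))
  # unassessable cells are flagged, not classified
  shallow <- mk("shallow", 0.99); shallow$total <- 10; shallow$M <- 10
  expect_equal(classifyXState(rbind(s, shallow), null)$state[4],
               "unassessable")
})

test_that("GM statistic shrinks low-coverage genes and resists outliers", {
  ann <- data.frame(gene = paste0("g", 1:2), chromosome = "chr2")
  m <- matrix(c(10, 5), 2, 1, dimnames = list(ann$gene, "c1"))
  p <- matrix(c(0, 5), 2, 1, dimnames = list(ann$gene, "c1"))
  ac <- AllelicCounts(m, p, geneAnnotation = ann)
  # pseudocount off: per-gene biases {1, 0.5}, GM = sqrt(0.5)
  gm0 <- gmStatistics(ac, pseudocount = 0)
  expect_equal(gm0$gm, sqrt(0.5))
  # fully monoallelic, pseudocount off -> GM exactly 1
  ac1 <- AllelicCounts(m, p * 0, geneAnnotation = ann)
  expect_equal(gmStatistics(ac1, pseudocount = 0)$gm, 1)
  # both genes balanced -> GM 0.5
  ac5 <- AllelicCounts(m * 0 + 5, p * 0 + 5, geneAnnotation = ann)
  expect_equal(gmStatistics(ac5, pseudocount = 0)$gm, 0.5)
  # robustness: one outlier among 9 biallelic genes moves the GM less
  # than the arithmetic mean
  b <- c(rep(0.5, 9), 1.0)
  gm_shift <- exp(mean(log(b))) - 0.5
  mean_shift <- mean(b) - 0.5
  expect_lt(gm_shift, mean_shift)
})

test_that("interval and GM classifiers agree exactly on degenerate populations", {
  # deterministic fixtures: every gene exactly biallelic / exactly
  # monoallelic, so the empirical intervals degenerate and both
  # classifiers must return identical state vectors
  mkCounts <- function(m_per_gene, p_per_gene) {
    genes <- paste0(rep(c(paste0("chr", 1:4), "chrX"), each = 2),
                    "_g", 1:2)
    ann <- data.frame(gene = genes,
                      chromosome = rep(c(paste0("chr", 1:4), "chrX"),
                                       each = 2))
    m <- matrix(m_per_gene, 10, 30,
                dimnames = list(genes, paste0("c", 1:30)))
    p <- matrix(p_per_gene, 10, 30, dimnames = dimnames(m))
    AllelicCounts(m, p, geneAnnotation = ann)
  }
  for (counts in list(mkCounts(25, 25), mkCounts(50, 0))) {
    s <- chromosomeAllelicSums(counts)
    cB <- classifyXState(s, buildBinnedNull(s, n_bins = 2),
                         min_x_genes = 1, min_x_reads = 1)
    gB <- gmIntervalClassify(counts, min_x_genes = 1, min_x_reads = 1)
    expect_equal(cB$state,
                 gB$calls$state[match(cB$cell_id, gB$calls$cell_id)])
    expect_true(all(cB$state == "XaXa_range"))
  }
})

test_that("paternal-fraction summary reproduces brute-force quartiles", {
  set.seed(16)
  s <- data.frame(cell_id = paste0("c", 1:20), chromosome = "chrX",
                  M = 0, P = 0, total = 100, n_snp_genes = 5,
                  paternal_fraction = runif(20), bias = 0.6)
  groups <- setNames(rep(c("PGC", "somatic"), 10), s$cell_id)
  ps <- paternalFractionSummary(s, groups)
  for (g in c("PGC", "somatic")) {
    v <- sort(ps$per_cell$paternal_fraction[ps$per_cell$group == g])
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    row <- ps$quartiles[ps$quartiles$group == g, ]
    expect_equal(c(row$q25, row$median, row$q75), q)
  }
  one <- paternalFractionSummary(s[1, ], groups[1])
  expect_equal(one$quartiles$median, s$paternal_fraction[1])
})

test_that("bias ranking is descending and deterministic under ties", {
  s <- data.frame(cell_id = c("b", "a", "c"), chromosome = "chrX",
                  M = 0, P = 0, total = c(50, 100, 100),
                  n_snp_genes = 3, paternal_fraction = 0.5,
                  bias = c(0.9, 0.9, 0.6))
  r <- rankCellsByXBias(s)
  expect_equal(r$cell_id, c("a", "b", "c"))
  expect_equal(r$rank, 1:3)
  expect_equal(rankCellsByXBias(s[c(3, 1, 2), ])$cell_id, r$cell_id)
})

test_that("median-bias XCI call is inclusive at the threshold", {
  expect_equal(medianBiasClassifier(c(1.0, 0.96, 0.95)), "XCI")
  expect_equal(medianBiasClassifier(c(0.5, 0.5, 0.5)), "not_XCI")
  expect_equal(medianBiasClassifier(0.95), "XCI")
  expect_equal(medianBiasClassifier(numeric(0)), "unassessable")
  # per-cell wrapper on planted data: XiXa cells are called XCI
  pop <- plantedPopulation(n_xixa = 5, n_xaxa = 5, depth = 6000,
                           dropout = 0, seed = 18)
  calls <- xMedianBiasCalls(pop$counts)
  truth <- setNames(pop$profiles$x_state_truth, pop$profiles$cell_id)
  expect_true(all(calls$call[truth[calls$cell_id] == "XiXa"] == "XCI"))
  expect_true(all(calls$call[truth[calls$cell_id] == "XaXa"] == "not_XCI"))
})

test_that("NB differential expression is calibrated, powered, and BH-adjusted", {
  set.seed(9)
  cells <- paste0("c", 1:40)
  cnt <- matrix(rnbinom(200 * 40, mu = 50, size = 2), 200, 40,
                dimnames = list(paste0("g", 1:200), cells))
  de <- differentialExpressionNB(cnt, cells[1:20], cells[21:40])
  # null p-values are uniform
  expect_gt(stats::ks.test(de$p_value, "punif")$p.value, 0.01)
  expect_equal(de$q_value, p.adjust(de$p_value, "BH")[order(de$p_value)])
  # an 8-fold planted shift is detected in (at least) 19 of 20 seeds
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    cnt <- matrix(rnbinom(50 * 40, mu = 10, size = 2), 50, 40,
                  dimnames = list(paste0("g", 1:50), cells))
    cnt[1, 1:20] <- rnbinom(20, mu = 80, size = 2)
    de <- differentialExpressionNB(cnt, cells[1:20], cells[21:40])
    de$q_value[de$gene == "g1"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  # all-zero genes are skipped
  cnt0 <- rbind(cnt, dead = 0L)
  expect_false("dead" %in%
                 differentialExpressionNB(cnt0, cells[1:20],
                                          cells[21:40])$gene)
  expect_error(differentialExpressionNB(cnt, cells[1], cells[2:4]),
               ">= 2")
})

test_that("NB test agrees directionally with an independent exact test", {
  skip_if_not_installed("edgeR")
  set.seed(23)
  cells <- paste0("c", 1:30)
  cnt <- matrix(rnbinom(40 * 30, mu = 20, size = 2), 40, 30,
                dimnames = list(paste0("g", 1:40), cells))
  cnt[1:5, 1:15] <- rnbinom(5 * 15, mu = 120, size = 2)
  de <- differentialExpressionNB(cnt, cells[1:15], cells[16:30])
  y <- edgeR::DGEList(counts = cnt,
                      group = rep(c("A", "B"), each = 15))
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y)$table
  top_ours <- de$gene[de$q_value < 0.05]
  top_ref <- rownames(et)[p.adjust(et$PValue, "BH") < 0.05]
  expect_gte(sum(paste0("g", 1:5) %in% top_ours), 4)
  expect_gte(sum(paste0("g", 1:5) %in% top_ref), 4)
  # and neither route floods with false positives
  expect_lte(length(setdiff(top_ours, paste0("g", 1:5))), 2)
})
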