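# shared in-code fixtures; no data files

# tiny AllelicCounts with explicit numbers for arithmetic checks
tinyCounts <- function() {
  genes <- c("a1", "a2", "x1", "x2", "e1", "i1")
  m <- matrix(c(3, 2, 0, 1, 5, 7,
                4, 0, 10, 9, 4, 0), ncol = 2,
              dimnames = list(genes, c("cellA", "cellB")))
  p <- matrix(c(1, 2, 10, 9, 5, 0,
                4, 1, 0, 1, 6, 6), ncol = 2,
              dimnames = list(genes, c("cellA", "cellB")))
  ann <- data.frame(
    gene = genes,
    chromosome = c("chr1", "chr1", "chrX", "chrX", "chrX", "chr11"),
    imprint_cluster = c("none", "none", "none", "none", "none",
                        "H19/IGF2"),
    expected_allele = c(NA, NA, NA, NA, NA, "maternal"),
    imprint_status = c("none", "none", "none", "none", "none",
                       "confirmed"),
    escapee = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  AllelicCounts(m, p, geneAnnotation = ann)
}

# small simulated population with planted X states, shared across tests
plantedPopulation <- function(n_xixa = 40, n_xaxa = 60, depth = 5000,
                              dropout = 0.2, seed = 5) {
  prof <- cellSimProfiles(n_xixa + n_xaxa, stage = "PGC",
                          x_state = rep(c("XiXa", "XaXa"),
                                        c(n_xixa, n_xaxa)),
                          depth = depth, dropout_rate = dropout,
                          seed = seed)
  ann <- simGeneAnnotation(n_autosomal = 220, n_x_proper = 10,
                           n_escapee = 4)
  ac <- simulateAllelicCounts(prof, ann, seed = seed + 1, x_leak = 0.02)
  list(profiles = prof, annotation = ann, counts = ac)
}
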