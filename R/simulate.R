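# Synthetic-data module: trio genotypes, allele-tagged single-cell counts and
# methylation read tables with known ground truth. The generators define the
# statistical conditions the rest of the package is validated against:
# biallelic binomial allelic sampling on autosomes, per-cell XCI state with a
# random parental choice, per-cluster imprint erasure, gene-level allelic
# dropout (fair-coin allele loss) and overdispersed per-cell depth.

.HG19_CHROM_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560
)

.BASES <- c("A", "C", "G", "T")

#' Configuration for trio genotype simulation
#'
#' @param n_snps number of candidate SNP sites to generate (> 0).
#' @param het_rate_fetus probability a site is heterozygous (0/1) in the
#'   fetus.
#' @param maternal_hom_rate probability a site is homozygous in the mother;
#'   the remainder are maternal heterozygous (and hence uninformative).
#' @param chromosome_lengths named vector of chromosome lengths in bp; sites
#'   are placed proportionally to length.
#' @param seed integer RNG seed; a fixed seed yields byte-identical output.
#' @param indel_rate probability a site is emitted as a short insertion
#'   rather than a SNP (default 0: pure SNP tables).
#' @param lowq_rate probability a variant record carries a non-PASS filter
#'   tag (default 0).
#' @return a validated `TrioSimConfig` list.
#' @export
trioSimConfig <- function(n_snps, het_rate_fetus = 0.3,
                          maternal_hom_rate = 0.7,
                          chromosome_lengths = .HG19_CHROM_LENGTHS,
                          seed = 1L, indel_rate = 0, lowq_rate = 0) {
  probs <- c(het_rate_fetus = het_rate_fetus,
             maternal_hom_rate = maternal_hom_rate,
             indel_rate = indel_rate, lowq_rate = lowq_rate)
  if (any(probs < 0 | probs > 1))
    stop("rates must be probabilities in [0, 1]")
  if (length(n_snps) != 1L || is.na(n_snps) || n_snps <= 0)
    stop("n_snps must be a positive count (empty simulation requested)")
  if (is.null(names(chromosome_lengths)) || any(chromosome_lengths < 1))
    stop("chromosome_lengths must be a named vector of positive lengths")
  structure(list(
    n_snps = as.integer(n_snps), het_rate_fetus = het_rate_fetus,
    maternal_hom_rate = maternal_hom_rate,
    chromosome_lengths = chromosome_lengths,
    seed = as.integer(seed), indel_rate = indel_rate, lowq_rate = lowq_rate
  ), class = "TrioSimConfig")
}

#' Simulate fetal and maternal variant tables with a known phase
#'
#' Generates paired variant call tables for a fetus and its mother plus the
#' ground-truth parent-of-origin assignment at every informative site (fetal
#' heterozygous and maternal homozygous). When the mother is homozygous
#' reference the fetal ALT allele must be paternal; when homozygous
#' alternative, the ALT allele is maternal.
#'
#' @param config a [trioSimConfig()] object.
#' @return a list with `fetal` and `maternal` variant `data.frame`s
#'   (`chrom`, `pos`, `id`, `ref`, `alt`, `gt`, `filter`) and `truth_phase`
#'   (`chrom`, `pos`, `ref`, `alt`, `paternal_allele`, `maternal_allele`,
#'   `informative_class`).
#' @examples
#' trio <- simulateTrio(trioSimConfig(100, seed = 7))
#' head(trio$truth_phase)
#' @export
simulateTrio <- function(config) {
  stopifnot(inherits(config, "TrioSimConfig"))
  set.seed(config$seed)
  n <- config$n_snps
  lens <- config$chromosome_lengths
  chrom <- sample(names(lens), n, replace = TRUE,
                  prob = lens / sum(lens))
  pos <- floor(runif(n) * lens[chrom]) + 1L
  # resample clashes so (chrom, pos) is unique
  repeat {
    dup <- duplicated(paste(chrom, pos))
    if (!any(dup)) break
    pos[dup] <- floor(runif(sum(dup)) * lens[chrom[dup]]) + 1L
  }
  o <- order(factor(chrom, levels = names(lens)), pos)
  chrom <- chrom[o]; pos <- pos[o]

  ref <- sample(.BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1L), "")
  is_indel <- runif(n) < config$indel_rate
  alt[is_indel] <- paste0(alt[is_indel], sample(.BASES, sum(is_indel),
                                                replace = TRUE))

  fetal_het <- runif(n) < config$het_rate_fetus
  fetal_gt <- ifelse(fetal_het, "0/1",
                     ifelse(runif(n) < 0.5, "0/0", "1/1"))
  maternal_hom <- runif(n) < config$maternal_hom_rate
  hom_pick <- ifelse(runif(n) < 0.5, "0/0", "1/1")
  # at fetal hom sites a consistent homozygous mother shares the allele
  hom_pick[!fetal_het & fetal_gt == "0/0"] <- "0/0"
  hom_pick[!fetal_het & fetal_gt == "1/1"] <- "1/1"
  maternal_gt <- ifelse(maternal_hom, hom_pick, "0/1")

  fetal_filter <- ifelse(runif(n) < config$lowq_rate, "LowQual", "PASS")
  maternal_filter <- ifelse(runif(n) < config$lowq_rate, "LowQual", "PASS")

  ids <- paste0("snp", seq_len(n))
  fetal <- data.frame(chrom = chrom, pos = pos, id = ids, ref = ref,
                      alt = alt, gt = fetal_gt, filter = fetal_filter,
                      stringsAsFactors = FALSE)
  maternal <- data.frame(chrom = chrom, pos = pos, id = ids, ref = ref,
                         alt = alt, gt = maternal_gt,
                         filter = maternal_filter,
                         stringsAsFactors = FALSE)

  informative <- fetal_het & maternal_hom & !is_indel &
    fetal_filter == "PASS" & maternal_filter == "PASS"
  cls <- ifelse(maternal_gt == "0/0", "mother_hom_ref", "mother_hom_alt")
  truth <- data.frame(
    chrom = chrom[informative], pos = pos[informative],
    ref = ref[informative], alt = alt[informative],
    paternal_allele = ifelse(cls[informative] == "mother_hom_ref",
                             alt[informative], ref[informative]),
    maternal_allele = ifelse(cls[informative] == "mother_hom_ref",
                             ref[informative], alt[informative]),
    informative_class = cls[informative],
    stringsAsFactors = FALSE
  )
  list(fetal = fetal, maternal = maternal, truth_phase = truth)
}

#' Build a table of per-cell simulation profiles
#'
#' Each row is one cell with its ground-truth developmental stage, X
#' inactivation state, active-X parental choice, expected sequencing depth
#' (total allelic reads) and gene-level allelic dropout rate.
#'
#' @param n number of cells.
#' @param stage stage truth, recycled over cells
#'   (`"PGC"`, `"LGC"`, `"MGC"`, `"somatic"`).
#' @param x_state `"XaXa"` (both X active, biallelic) or `"XiXa"`
#'   (one X still inactive, monoallelically biased), recycled.
#' @param active_x active-X parent for XiXa cells; `NULL` draws
#'   maternal/paternal with equal probability per cell (the random nature of
#'   XCI).
#' @param depth expected total allelic reads per cell.
#' @param dropout_rate per-gene probability that dropout forces all of a
#'   gene's reads onto a single, fair-coin-chosen allele.
#' @param cell_prefix prefix for generated cell ids.
#' @param seed RNG seed used only when `active_x` is drawn.
#' @return a `data.frame` of cell profiles.
#' @export
cellSimProfiles <- function(n, stage = "PGC", x_state = "XaXa",
                            active_x = NULL, depth = 2000,
                            dropout_rate = 0.3, cell_prefix = "cell",
                            seed = NULL) {
  stopifnot(n >= 1, all(depth > 0),
            all(dropout_rate >= 0 & dropout_rate <= 1))
  stage <- rep_len(as.character(stage), n)
  x_state <- rep_len(as.character(x_state), n)
  stopifnot(all(stage %in% c("PGC", "LGC", "MGC", "somatic")),
            all(x_state %in% c("XaXa", "XiXa")))
  if (is.null(active_x)) {
    if (!is.null(seed)) set.seed(seed)
    active_x <- sample(c("maternal", "paternal"), n, replace = TRUE)
  } else {
    active_x <- rep_len(as.character(active_x), n)
  }
  data.frame(
    cell_id = sprintf("%s%03d", cell_prefix, seq_len(n)),
    stage_truth = stage, x_state_truth = x_state,
    active_x_parent_truth = active_x,
    depth = rep_len(depth, n),
    dropout_rate = rep_len(dropout_rate, n),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic gene annotation
#'
#' Genes spread round-robin over the 22 autosomes, X-linked genes split into
#' proper and escapee sets, and imprinted genes placed on their cluster's
#' chromosome with the cluster's canonically expressed parental allele.
#'
#' @param n_autosomal number of ordinary autosomal genes.
#' @param n_x_proper number of X-linked genes subject to XCI.
#' @param n_escapee number of X-linked genes escaping XCI.
#' @param genes_per_cluster imprinted genes per gene-cluster.
#' @return a `data.frame` with columns `gene`, `chromosome`,
#'   `imprint_cluster`, `expected_allele`, `imprint_status`, `escapee`.
#' @export
simGeneAnnotation <- function(n_autosomal = 200, n_x_proper = 10,
                              n_escapee = 4, genes_per_cluster = 3) {
  clusters <- data.frame(
    cluster = c("H19/IGF2", "DLK1-DIO3/MEG3", "KCNQ1/KCNQ1OT1",
                "PEG3/ZIM", "SNURF-SNRPN/UBE3A"),
    chromosome = c("chr11", "chr14", "chr11", "chr19", "chr15"),
    expected = c("maternal", "maternal", "paternal", "paternal",
                 "paternal"),
    stringsAsFactors = FALSE
  )
  auto <- if (n_autosomal == 0) NULL else data.frame(
    gene = sprintf("geneA%03d", seq_len(n_autosomal)),
    chromosome = paste0("chr", rep_len(1:22, n_autosomal)),
    imprint_cluster = "none", expected_allele = NA_character_,
    imprint_status = "none", escapee = FALSE,
    stringsAsFactors = FALSE
  )
  xp <- if (n_x_proper == 0) NULL else data.frame(
    gene = sprintf("geneX%03d", seq_len(n_x_proper)),
    chromosome = "chrX", imprint_cluster = "none",
    expected_allele = NA_character_, imprint_status = "none",
    escapee = FALSE, stringsAsFactors = FALSE
  )
  esc <- if (n_escapee > 0) data.frame(
    gene = sprintf("geneE%03d", seq_len(n_escapee)),
    chromosome = "chrX", imprint_cluster = "none",
    expected_allele = NA_character_, imprint_status = "none",
    escapee = TRUE, stringsAsFactors = FALSE
  ) else NULL
  imp <- if (genes_per_cluster == 0) NULL else
    do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
    data.frame(
      gene = sprintf("geneI_c%d_%d", i, seq_len(genes_per_cluster)),
      chromosome = clusters$chromosome[i],
      imprint_cluster = clusters$cluster[i],
      expected_allele = clusters$expected[i],
      imprint_status = "confirmed", escapee = FALSE,
      stringsAsFactors = FALSE
    )
  }))
  rbind(auto, imp, xp, esc)
}

#' Imprint-cluster erasure states
#'
#' @param cluster_id character vector of cluster names.
#' @param erasure_fraction per-cluster probability that a germ cell has
#'   erased the imprint and expresses the cluster biallelically.
#' @return a `data.frame` with one row per cluster.
#' @export
imprintSimStates <- function(cluster_id, erasure_fraction = 0) {
  stopifnot(all(erasure_fraction >= 0 & erasure_fraction <= 1))
  data.frame(cluster_id = as.character(cluster_id),
             erasure_fraction = rep_len(erasure_fraction,
                                        length(cluster_id)),
             stringsAsFactors = FALSE)
}

.ALLOWED_CHROMS <- c(paste0("chr", 1:22), "chrX", "chrY", "chrM")

#' Simulate an allele-tagged single-cell count matrix with ground truth
#'
#' Draws, for every cell, overdispersed per-gene read totals (negative
#' binomial across genes, scaled by the cell's depth) and splits each total
#' between the maternal and paternal allele by a binomial draw whose success
#' probability encodes the gene's allelic regime: 0.5 for ordinary autosomal
#' and escapee genes, near-monoallelic toward the expected allele for
#' non-erased imprinted genes, and near-monoallelic toward the cell's active
#' X for X-proper genes in XiXa cells. Gene-level allelic dropout then
#' forces all reads of a hit gene onto one allele, chosen with probability
#' equal to that allele's expression share (a fair coin for biallelic
#' genes, matching the dropout null; monoallelic genes keep their active
#' allele), so maternal + paternal always equals the drawn gene total.
#'
#' @param profiles cell profile table from [cellSimProfiles()].
#' @param annotation gene annotation as from [simGeneAnnotation()].
#' @param imprint_states cluster erasure table from [imprintSimStates()];
#'   clusters absent from it never erase.
#' @param seed integer RNG seed.
#' @param nb_size negative binomial size (inverse dispersion) of gene
#'   totals.
#' @param x_leak residual fraction of reads the inactive X still emits in
#'   XiXa cells (incomplete or ongoing reactivation); 0 makes XiXa strictly
#'   monoallelic.
#' @param imprint_leak residual expression of the silenced allele at
#'   non-erased imprinted genes.
#' @return an [AllelicCounts-class] whose `colData` carries the profile
#'   truth and whose `metadata()$truth` holds the per-gene maternal
#'   probability, dropout and erasure indicator matrices.
#' @export
simulateAllelicCounts <- function(profiles, annotation,
                                  imprint_states = NULL, seed = 1L,
                                  nb_size = 1, x_leak = 0.02,
                                  imprint_leak = 0) {
  need <- c("cell_id", "stage_truth", "x_state_truth",
            "active_x_parent_truth", "depth", "dropout_rate")
  stopifnot(all(need %in% names(profiles)),
            all(c("gene", "chromosome") %in% names(annotation)))
  bad <- setdiff(annotation$chromosome, .ALLOWED_CHROMS)
  if (length(bad) > 0)
    stop("unknown chromosome in annotation: ", paste(bad, collapse = ", "))
  if (is.null(annotation$escapee)) annotation$escapee <- FALSE
  if (is.null(annotation$imprint_cluster))
    annotation$imprint_cluster <- "none"
  if (is.null(annotation$imprint_status))
    annotation$imprint_status <- "none"
  set.seed(seed)

  genes <- annotation$gene
  cells <- profiles$cell_id
  ng <- length(genes); nc <- length(cells)
  er_frac <- setNames(rep(0, 0), character(0))
  if (!is.null(imprint_states))
    er_frac <- setNames(imprint_states$erasure_fraction,
                        imprint_states$cluster_id)
  clusters <- setdiff(unique(annotation$imprint_cluster), "none")

  M <- P <- matrix(0L, ng, nc, dimnames = list(genes, cells))
  T_truth <- matrix(0L, ng, nc, dimnames = list(genes, cells))
  p_truth <- matrix(NA_real_, ng, nc, dimnames = list(genes, cells))
  drop_truth <- matrix(FALSE, ng, nc, dimnames = list(genes, cells))
  erased <- matrix(FALSE, nc, length(clusters),
                   dimnames = list(cells, clusters))

  is_imprinted <- annotation$imprint_status == "confirmed" &
    annotation$imprint_cluster != "none"
  is_x <- annotation$chromosome == "chrX"

  for (j in seq_len(nc)) {
    pr <- profiles[j, ]
    totals <- rnbinom(ng, mu = pr$depth / ng, size = nb_size)
    p <- rep(0.5, ng)
    if (length(clusters) > 0) {
      fire <- runif(length(clusters)) <
        ifelse(clusters %in% names(er_frac), er_frac[clusters], 0)
      erased[j, ] <- fire
      for (ci in seq_along(clusters)) {
        gi <- which(is_imprinted & annotation$imprint_cluster ==
                      clusters[ci])
        if (fire[ci]) {
          p[gi] <- 0.5
        } else {
          p[gi] <- ifelse(annotation$expected_allele[gi] == "maternal",
                          1 - imprint_leak, imprint_leak)
        }
      }
    }
    if (pr$x_state_truth == "XiXa") {
      xi <- which(is_x & !annotation$escapee)
      p[xi] <- if (pr$active_x_parent_truth == "maternal")
        1 - x_leak else x_leak
    }
    m <- rbinom(ng, totals, p)
    # gene-level allelic dropout: all of a hit gene's reads land on one
    # allele, drawn with probability equal to its expression share -- the
    # fair coin of the dropout null for biallelic genes, while monoallelic
    # genes keep expressing their active allele
    hit <- runif(ng) < pr$dropout_rate
    keep_maternal <- runif(ng) < p
    m[hit & keep_maternal] <- totals[hit & keep_maternal]
    m[hit & !keep_maternal] <- 0L
    M[, j] <- as.integer(m)
    P[, j] <- as.integer(totals - m)
    T_truth[, j] <- as.integer(totals)
    p_truth[, j] <- p
    drop_truth[, j] <- hit
  }

  ac <- AllelicCounts(M, P, geneAnnotation = annotation,
                      cellData = profiles)
  metadata(ac)$truth <- list(totals = T_truth, p_maternal = p_truth,
                             dropout = drop_truth, erased = erased,
                             profiles = profiles)
  ac
}

#' Simulate purely biallelic autosomal cells
#'
#' The calibration workhorse for the X-reactivation null: every chromosome
#' total is drawn from a negative binomial and split between genes by an
#' equal-probability multinomial; each gene's maternal count is
#' Binomial(total, 0.5), so every chromosome summary is exactly biallelic in
#' expectation and its summed maternal count is Binomial(chromosome total,
#' 0.5) in distribution.
#'
#' @param n_cells number of cells.
#' @param n_chrom number of autosomes (chr1..chrN).
#' @param genes_per_chrom SNP-containing genes per chromosome.
#' @param total_mu,total_size negative binomial mean and size of the
#'   per-chromosome allelic read total.
#' @param seed RNG seed.
#' @param cell_prefix prefix for cell ids.
#' @return an [AllelicCounts-class] of biallelic cells.
#' @export
simulateBiallelicCells <- function(n_cells, n_chrom = 22,
                                   genes_per_chrom = 5, total_mu = 200,
                                   total_size = 1, seed = 1L,
                                   cell_prefix = "cell") {
  stopifnot(n_cells >= 1, n_chrom >= 1, genes_per_chrom >= 1)
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  genes <- as.vector(vapply(chroms, function(ch)
    paste0(ch, "_g", seq_len(genes_per_chrom)),
    character(genes_per_chrom)))
  anno <- data.frame(gene = genes,
                     chromosome = rep(chroms, each = genes_per_chrom),
                     escapee = FALSE, stringsAsFactors = FALSE)
  cells <- sprintf("%s%04d", cell_prefix, seq_len(n_cells))
  M <- P <- matrix(0L, length(genes), n_cells,
                   dimnames = list(genes, cells))
  for (j in seq_len(n_cells)) {
    for (ci in seq_len(n_chrom)) {
      tot <- rnbinom(1, mu = total_mu, size = total_size)
      split <- if (tot > 0)
        as.vector(rmultinom(1, tot, rep(1, genes_per_chrom)))
      else rep(0L, genes_per_chrom)
      m <- rbinom(genes_per_chrom, split, 0.5)
      rows <- (ci - 1L) * genes_per_chrom + seq_len(genes_per_chrom)
      M[rows, j] <- as.integer(m)
      P[rows, j] <- as.integer(split - m)
    }
  }
  AllelicCounts(M, P, geneAnnotation = anno)
}

#' Simulate read-level CpG methylation calls for one region
#'
#' Each simulated read carries an allele tag and an independent 0/1
#' methylation call at every CpG of the region, drawn at the allele's rate.
#'
#' @param cpg_positions 1-based genomic positions of the region's CpGs
#'   (at least one).
#' @param per_allele_rate named numeric vector, allele -> methylation
#'   probability.
#' @param n_reads reads per allele; scalar or named like
#'   `per_allele_rate`. Zero yields an empty table.
#' @param seed RNG seed.
#' @return a long `data.frame` with columns `read_id`, `allele`,
#'   `cpg_index`, `position`, `call`.
#' @export
simulateMethylationReads <- function(cpg_positions, per_allele_rate,
                                     n_reads, seed = 1L) {
  stopifnot(length(cpg_positions) >= 1,
            all(per_allele_rate >= 0 & per_allele_rate <= 1),
            !is.null(names(per_allele_rate)))
  if (any(n_reads < 0)) stop("n_reads must be non-negative")
  n_reads <- if (length(n_reads) == 1L)
    setNames(rep(n_reads, length(per_allele_rate)),
             names(per_allele_rate))
  else n_reads[names(per_allele_rate)]
  set.seed(seed)
  k <- length(cpg_positions)
  out <- lapply(names(per_allele_rate), function(a) {
    n <- n_reads[[a]]
    if (n == 0) return(NULL)
    data.frame(
      read_id = rep(sprintf("%s_read%04d", a, seq_len(n)), each = k),
      allele = a,
      cpg_index = rep(seq_len(k), n),
      position = rep(cpg_positions, n),
      call = as.integer(runif(n * k) < per_allele_rate[[a]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(read_id = character(), allele = character(),
                      cpg_index = integer(), position = integer(),
                      call = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Default germ-cell marker panel
#'
#' A compact stand-in for the larger curated marker panel used to stage
#' germ cells: pluripotency and early germ-cell markers high in PGCs, late
#' germ-cell markers in pre-meiotic LGCs, meiotic markers in MGCs and
#' somatic markers in gonadal somatic cells. Synthetic default; real
#' analyses supply their own panel (gene, category).
#'
#' @return a `data.frame` with columns `gene`, `category`.
#' @export
defaultMarkerPanel <- function() {
  data.frame(
    gene = c("POU5F1", "NANOG", "LIN28A", "TFAP2C",
             "PDPN", "KIT", "ALPL", "NANOS3",
             "DDX4", "DAZL", "MAEL", "PIWIL2",
             "SYCP3", "SYCP1", "HORMAD1", "STRA8", "SPO11",
             "WT1", "GATA4", "NR5A1", "KRT18"),
    category = rep(c("pluripotency", "early_germ", "late", "meiotic",
                     "somatic"), times = c(4, 4, 4, 5, 4)),
    stringsAsFactors = FALSE
  )
}

# per-stage log-scale expression multiplier of each marker category
.STAGE_ARCHETYPES <- rbind(
  PGC     = c(pluripotency = 1.0, early_germ = 0.8, late = 0.2,
              meiotic = 0.05, somatic = 0.0),
  LGC     = c(pluripotency = 0.1, early_germ = 0.4, late = 1.0,
              meiotic = 0.5, somatic = 0.0),
  MGC     = c(pluripotency = 0.0, early_germ = 0.1, late = 0.4,
              meiotic = 1.0, somatic = 0.05),
  somatic = c(pluripotency = 0.4, early_germ = 0.0, late = 0.1,
              meiotic = 0.25, somatic = 1.0)
)

#' Simulate staged expression profiles from stage archetypes
#'
#' Log-normal expression for panel genes whose log-mean follows the stage's
#' archetype (its marker categories up, others down), plus background genes
#' common to all stages. Used to validate marker-panel staging.
#'
#' @param n_per_stage named integer vector, stage -> number of cells
#'   (names among PGC, LGC, MGC, somatic).
#' @param panel marker panel (gene, category); see [defaultMarkerPanel()].
#' @param n_background number of stage-independent background genes.
#' @param separation log-fold separation between an "on" and "off"
#'   category.
#' @param noise_sd log-scale noise standard deviation (default 0.2, small
#'   against the archetype grading so stage rank profiles stay coherent).
#' @param seed RNG seed.
#' @return list with `expression` (genes x cells, FPKM-like), `stages`
#'   (cell_id, stage_truth), `panel`.
#' @export
simulateStageExpression <- function(n_per_stage = c(PGC = 10, LGC = 10,
                                                    MGC = 10, somatic = 10),
                                    panel = defaultMarkerPanel(),
                                    n_background = 100, separation = 4,
                                    noise_sd = 0.2, seed = 1L) {
  stopifnot(all(names(n_per_stage) %in% rownames(.STAGE_ARCHETYPES)))
  set.seed(seed)
  stages <- rep(names(n_per_stage), n_per_stage)
  cells <- sprintf("%s_%03d", stages, unlist(lapply(n_per_stage, seq_len)))
  bg <- sprintf("bg%03d", seq_len(n_background))
  genes <- c(panel$gene, bg)
  logmu <- matrix(1, length(genes), length(cells),
                  dimnames = list(genes, cells))
  for (j in seq_along(cells)) {
    w <- .STAGE_ARCHETYPES[stages[j], panel$category]
    logmu[seq_len(nrow(panel)), j] <- 0.5 + separation * w
  }
  expr <- exp(logmu + matrix(rnorm(length(logmu), 0, noise_sd),
                             nrow(logmu)))
  list(expression = expr,
       stages = data.frame(cell_id = cells, stage_truth = stages,
                           stringsAsFactors = FALSE),
       panel = panel)
}
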