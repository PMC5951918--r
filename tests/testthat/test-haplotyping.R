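# informative-SNP selection, parental sequence substitution, phase recovery

makeSite <- function(gt_f, gt_m, ref = "A", alt = "G", filt_f = "PASS",
                     filt_m = "PASS", pos = 100, in_mother = TRUE) {
  fet <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                    gt = gt_f, filter = filt_f, stringsAsFactors = FALSE)
  mot <- if (in_mother)
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
               gt = gt_m, filter = filt_m, stringsAsFactors = FALSE)
  else data.frame(chrom = "chr2", pos = 1, ref = "C", alt = "T",
                  gt = "0/0", filter = "PASS", stringsAsFactors = FALSE)
  selectInformativeSnps(fet, mot)
}

test_that("genotype combinations phase or discard as the trio rule dictates", {
  # mother hom-ref: the fetal ALT allele came from the father
  r <- makeSite("0/1", "0/0")
  expect_equal(r$phased$paternal_allele, "G")
  expect_equal(r$phased$informative_class, "mother_hom_ref")
  # mother hom-alt: the ALT allele is maternal
  r <- makeSite("0/1", "1/1")
  expect_equal(r$phased$maternal_allele, "G")
  expect_equal(r$phased$paternal_allele, "A")
  # maternal heterozygous sites are discarded
  r <- makeSite("0/1", "0/1")
  expect_equal(nrow(r$phased), 0)
  expect_equal(r$summary$n_discarded_maternal_het, 1)
  # indel alleles are discarded
  r <- makeSite("0/1", "0/0", alt = "GT")
  expect_equal(nrow(r$phased), 0)
  expect_equal(r$summary$n_discarded_lowq_or_indel, 1)
  # low-quality fetal calls are discarded
  r <- makeSite("0/1", "0/0", filt_f = "LowQual")
  expect_equal(r$summary$n_discarded_lowq_or_indel, 1)
  # sites absent in the mother are non-informative
  r <- makeSite("0/1", "0/0", in_mother = FALSE)
  expect_equal(nrow(r$phased), 0)
  expect_equal(r$summary$n_discarded_other, 1)
})

test_that("every fetal-het site lands in exactly one summary category", {
  trio <- simulateTrio(trioSimConfig(3000, seed = 13, indel_rate = 0.1,
                                     lowq_rate = 0.1,
                                     maternal_hom_rate = 0.6))
  res <- selectInformativeSnps(trio$fetal, trio$maternal)
  s <- res$summary
  n_het <- sum(trio$fetal$gt == "0/1")
  expect_equal(s$n_paternal_informative + s$n_maternal_informative +
                 s$n_discarded_maternal_het + s$n_discarded_lowq_or_indel +
                 s$n_discarded_other, n_het)
  expect_equal(nrow(res$phased),
               s$n_paternal_informative + s$n_maternal_informative)
})

test_that("trio round-trip recovers the simulated phase exactly", {
  trio <- simulateTrio(trioSimConfig(1000, seed = 7))
  res <- selectInformativeSnps(trio$fetal, trio$maternal)
  acc <- phaseRecoveryCheck(trio$truth_phase, res$phased)
  expect_equal(as.numeric(acc), 1.0)
  expect_equal(attr(acc, "n_compared"), nrow(trio$truth_phase))
})

test_that("phase recovery warns and flags on disjoint site sets", {
  truth <- data.frame(chrom = "chr1", pos = 1:3, paternal_allele = "A")
  phased <- data.frame(chromosome = "chr2", position = 1:3,
                       paternal_allele = "A")
  expect_warning(
    expect_warning(res <- phaseRecoveryCheck(truth, phased), "no overlap"),
    "absent from the phased table")
  expect_true(is.na(res))
})

test_that("parental sequences carry the assigned alleles and nothing else", {
  ph <- data.frame(chromosome = "chr1", position = 2, ref_allele = "C",
                   alt_allele = "T", paternal_allele = "T",
                   maternal_allele = "C",
                   informative_class = "mother_hom_ref")
  seqs <- buildParentalSequences("ACGT", ph)
  expect_equal(as.character(seqs[["paternal"]]), "ATGT")
  expect_equal(as.character(seqs[["maternal"]]), "ACGT")

  # empty phase list: both parents equal the reference
  seqs0 <- buildParentalSequences("ACGT", ph[0, ])
  expect_equal(as.character(seqs0[["paternal"]]), "ACGT")
  expect_equal(as.character(seqs0[["maternal"]]), "ACGT")

  # positionwise diff oracle on a 100 bp reference with 3 phased sites
  set.seed(42)
  ref <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  pos <- c(10, 55, 90)
  refb <- substring(ref, pos, pos)
  altb <- vapply(refb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  ph3 <- data.frame(chromosome = "chr1", position = pos,
                    ref_allele = refb, alt_allele = altb,
                    paternal_allele = altb, maternal_allele = refb,
                    informative_class = "mother_hom_ref")
  seqs <- buildParentalSequences(ref, ph3)
  pat <- strsplit(as.character(seqs[["paternal"]]), "")[[1]]
  refc <- strsplit(ref, "")[[1]]
  expect_equal(which(pat != refc), pos)
  expect_equal(pat[pos], unname(altb))
  expect_equal(as.character(seqs[["maternal"]]), ref)

  expect_error(buildParentalSequences("ACGT", transform(ph, position = 9)),
               "out of reference range")
  expect_error(buildParentalSequences("AAGT", ph), "mismatch at position 2")
})

test_that("minimal VCF writing round-trips through vcfR", {
  trio <- simulateTrio(trioSimConfig(50, seed = 3, lowq_rate = 0.2))
  path <- tempfile(fileext = ".vcf")
  writeMinimalVcf(trio$fetal, path, sample_name = "fetus")
  back <- readVariantTable(path)
  expect_equal(back$chrom, trio$fetal$chrom)
  expect_equal(back$pos, trio$fetal$pos)
  expect_equal(back$gt, trio$fetal$gt)
  expect_equal(back$filter, trio$fetal$filter)
  # phasing from files matches phasing from tables
  pm <- tempfile(fileext = ".vcf")
  writeMinimalVcf(trio$maternal, pm, sample_name = "mother")
  expect_equal(selectInformativeSnps(path, pm)$phased,
               selectInformativeSnps(trio$fetal, trio$maternal)$phased)
})
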