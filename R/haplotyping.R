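# Haplotyping module: trio-lite phasing. A site phases when the fetus is
# heterozygous and the mother homozygous: the allele the mother does not
# carry must have come from the father.

#' Select informative SNPs and assign parent of origin
#'
#' Keeps exactly the sites that are PASS-filtered biallelic SNPs,
#' heterozygous (0/1) in the fetus and homozygous in the mother. At a
#' mother-hom-ref site the fetal ALT allele is paternal; at a mother-hom-alt
#' site the ALT allele is maternal. Maternally heterozygous sites, indels,
#' multi-allelic records and low-quality calls are discarded and counted.
#' Fetal-het sites absent in the mother or with a genotype contradiction
#' are non-informative and counted under `n_discarded_other`.
#'
#' @param fetal_variants,maternal_variants variant tables
#'   (`chrom`, `pos`, `ref`, `alt`, `gt`, `filter`) or VCF file paths.
#' @return a list with `phased` — a `data.frame` of phased SNPs
#'   (`chromosome`, `position`, `ref_allele`, `alt_allele`,
#'   `paternal_allele`, `maternal_allele`, `informative_class`) — and
#'   `summary`, the discard/keep bookkeeping over all fetal-het sites
#'   (`n_paternal_informative`, `n_maternal_informative`,
#'   `n_discarded_maternal_het`, `n_discarded_lowq_or_indel`,
#'   `n_discarded_other`).
#' @examples
#' fet <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G",
#'                   gt = "0/1", filter = "PASS")
#' mot <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G",
#'                   gt = "0/0", filter = "PASS")
#' selectInformativeSnps(fet, mot)$phased
#' @export
selectInformativeSnps <- function(fetal_variants, maternal_variants) {
  fet <- .asVariantTable(fetal_variants)
  mot <- .asVariantTable(maternal_variants)

  fet <- fet[fet$gt == "0/1", , drop = FALSE]
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  mot_idx <- match(key(fet), key(mot))

  is_snp <- nchar(fet$ref) == 1L & nchar(fet$alt) == 1L &
    !grepl(",", fet$alt, fixed = TRUE)
  fet_pass <- fet$filter %in% c("PASS", ".")
  mot_gt <- ifelse(is.na(mot_idx), NA_character_, mot$gt[mot_idx])
  mot_pass <- !is.na(mot_idx) & mot$filter[mot_idx] %in% c("PASS", ".")
  mot_same_alleles <- !is.na(mot_idx) &
    mot$ref[mot_idx] == fet$ref & mot$alt[mot_idx] == fet$alt

  lowq_or_indel <- !is_snp | !fet_pass |
    (!is.na(mot_idx) & !mot_pass & is_snp & fet_pass)
  rest <- !lowq_or_indel
  missing_or_contra <- rest & (is.na(mot_idx) | !mot_same_alleles)
  rest <- rest & !missing_or_contra
  maternal_het <- rest & mot_gt == "0/1"
  informative <- rest & mot_gt %in% c("0/0", "1/1")
  other <- !(lowq_or_indel | missing_or_contra | maternal_het |
               informative)
  missing_or_contra <- missing_or_contra | other

  cls <- ifelse(mot_gt == "0/0", "mother_hom_ref", "mother_hom_alt")
  phased <- data.frame(
    chromosome = fet$chrom[informative],
    position = fet$pos[informative],
    ref_allele = fet$ref[informative],
    alt_allele = fet$alt[informative],
    paternal_allele = ifelse(cls[informative] == "mother_hom_ref",
                             fet$alt[informative], fet$ref[informative]),
    maternal_allele = ifelse(cls[informative] == "mother_hom_ref",
                             fet$ref[informative], fet$alt[informative]),
    informative_class = cls[informative],
    stringsAsFactors = FALSE
  )
  rownames(phased) <- NULL
  summary <- list(
    n_paternal_informative =
      sum(phased$informative_class == "mother_hom_ref"),
    n_maternal_informative =
      sum(phased$informative_class == "mother_hom_alt"),
    n_discarded_maternal_het = sum(maternal_het),
    n_discarded_lowq_or_indel = sum(lowq_or_indel),
    n_discarded_other = sum(missing_or_contra)
  )
  list(phased = phased, summary = summary)
}

#' Substitute phased alleles into a reference sequence
#'
#' Builds the individualized parental sequences: each output equals the
#' reference with single-base substitutions at the phased positions
#' carrying that parent's allele. Lengths are unchanged.
#'
#' @param reference_sequence a [Biostrings::DNAString], or a single
#'   character string.
#' @param phased phased SNP table from [selectInformativeSnps()]; positions
#'   are 1-based and must be unique and within the reference.
#' @return a [Biostrings::DNAStringSet] of length 2 named `paternal`,
#'   `maternal`.
#' @examples
#' ph <- data.frame(chromosome = "chr1", position = 2, ref_allele = "C",
#'                  alt_allele = "T", paternal_allele = "T",
#'                  maternal_allele = "C",
#'                  informative_class = "mother_hom_ref")
#' buildParentalSequences("ACGT", ph)
#' @export
buildParentalSequences <- function(reference_sequence, phased) {
  ref <- if (is(reference_sequence, "DNAString")) reference_sequence
  else DNAString(as.character(reference_sequence))
  if (nrow(phased) == 0)
    return(DNAStringSet(list(paternal = ref, maternal = ref)))
  pos <- phased$position
  if (anyDuplicated(pos))
    stop("phased positions must be unique")
  if (any(pos < 1 | pos > length(ref)))
    stop("phased position out of reference range")
  at <- as.character(ref)
  got <- substring(at, pos, pos)
  bad <- got != phased$ref_allele
  if (any(bad))
    stop("reference base mismatch at position ",
         paste(pos[bad], collapse = ", "),
         " (expected ", paste(phased$ref_allele[bad], collapse = ","),
         ", found ", paste(got[bad], collapse = ","), ")")
  sel <- rep(FALSE, length(ref))
  sel[pos] <- TRUE
  pat <- replaceLetterAt(ref, sel, phased$paternal_allele[order(pos)])
  mat <- replaceLetterAt(ref, sel, phased$maternal_allele[order(pos)])
  DNAStringSet(list(paternal = pat, maternal = mat))
}

#' Check phased output against a simulation truth table
#'
#' @param truth_phase truth table from [simulateTrio()] (columns `chrom`,
#'   `pos`, `paternal_allele`).
#' @param phased phased table from [selectInformativeSnps()].
#' @return the fraction of truth-informative sites, restricted to the
#'   intersection of the two site sets, whose paternal allele matches;
#'   `NA` (with a warning) when the intersection is empty. The result
#'   carries attributes `n_truth`, `n_compared`.
#' @export
phaseRecoveryCheck <- function(truth_phase, phased) {
  tk <- paste(truth_phase$chrom, truth_phase$pos, sep = ":")
  pk <- paste(phased$chromosome, phased$position, sep = ":")
  idx <- match(tk, pk)
  compared <- !is.na(idx)
  if (!all(compared))
    warning(sum(!compared),
            " truth site(s) absent from the phased table; ",
            "accuracy computed over the intersection")
  if (!any(compared)) {
    warning("no overlap between truth and phased sites; ",
            "accuracy undefined")
    res <- NA_real_
  } else {
    res <- mean(truth_phase$paternal_allele[compared] ==
                  phased$paternal_allele[idx[compared]])
  }
  structure(res, n_truth = length(tk), n_compared = sum(compared))
}

#' Write phased SNPs as TSV
#'
#' @param phased phased SNP table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhasedSnps <- function(phased, path) {
  write.table(phased, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
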