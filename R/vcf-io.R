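# Minimal VCF interchange for the trio tables. Writing emits plain-text
# VCF 4.2 with a single-sample GT column; reading goes through vcfR and is
# normalized to the internal variant table layout
# (chrom, pos, id, ref, alt, gt, filter).

#' Write a variant table as minimal VCF 4.2
#'
#' @param variants a `data.frame` with columns `chrom`, `pos`, `ref`,
#'   `alt`, `gt` and optionally `id`, `filter`.
#' @param path output file path.
#' @param sample_name sample column header.
#' @return `path`, invisibly.
#' @export
writeMinimalVcf <- function(variants, path, sample_name = "SAMPLE") {
  need <- c("chrom", "pos", "ref", "alt", "gt")
  stopifnot(all(need %in% names(variants)))
  id <- if (is.null(variants$id)) "." else variants$id
  filt <- if (is.null(variants$filter)) "PASS" else variants$filter
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  ), con)
  body <- paste(variants$chrom, variants$pos, id, variants$ref,
                variants$alt, ".", filt, ".", "GT", variants$gt,
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF file into the internal variant table layout
#'
#' Uses vcfR; only the first sample's GT is kept. Genotype separators are
#' normalized so phased calls (`0|1`) compare equal to unphased ones.
#'
#' @param path a VCF file path.
#' @return a `data.frame` with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `gt`, `filter`.
#' @export
readVariantTable <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt == "1/0"] <- "0/1"
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID), ".", fix$ID),
    ref = fix$REF, alt = fix$ALT,
    gt = unname(gt),
    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
    stringsAsFactors = FALSE
  )
}

.asVariantTable <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- readVariantTable(x)
  stopifnot(is.data.frame(x),
            all(c("chrom", "pos", "ref", "alt", "gt") %in% names(x)))
  if (is.null(x$filter)) x$filter <- "PASS"
  x$gt <- gsub("|", "/", x$gt, fixed = TRUE)
  x$gt[x$gt == "1/0"] <- "0/1"
  x
}
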