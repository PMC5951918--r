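# Methylation module: CpG methylation summarization over imprinting
# control region (ICR) and promoter windows, per-read pattern counting and
# SNP-allele read splitting. Windows are 1-based inclusive, matching the
# printed hg19 ICR coordinates; BED input (0-based half-open) is converted
# on read.

#' hg19 ICR and control promoter windows
#'
#' The differentially methylated imprinting control regions of the five
#' imprinted gene-clusters plus two germline promoter controls, as
#' 1-based inclusive hg19 coordinates.
#'
#' @return a [GenomicRanges::GRanges] with a `name` metadata column.
#' @export
icrWindows <- function() {
  GRanges(
    seqnames = c("chr11", "chr11", "chr14", "chr15", "chr19",
                 "chr5", "chr6"),
    ranges = IRanges(
      start = c(2021070, 2721173, 101292152, 25200010, 57351942,
                55029104, 74063525),
      end = c(2021302, 2721297, 101292376, 25200249, 57352097,
              55029220, 74063669)
    ),
    name = c("H19/IGF2", "KCNQ1/KCNQ1OT1", "DLK1-DIO3/MEG3",
             "SNURF-SNRPN/UBE3A", "PEG3/ZIM", "DDX4_promoter",
             "DPPA5_promoter")
  )
}

#' Read genomic windows from disk
#'
#' `.bed` files are parsed with rtracklayer (0-based half-open converted
#' to 1-based inclusive); any other extension is read as a TSV with
#' columns `name`, `chromosome`, `start`, `end` already 1-based
#' inclusive.
#'
#' @param path file path.
#' @return a [GenomicRanges::GRanges] with a `name` column.
#' @export
readWindows <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name)) gr$name <- paste0("window", seq_along(gr))
    return(gr)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "chromosome", "start", "end") %in% names(tab)))
  GRanges(tab$chromosome, IRanges(tab$start, tab$end), name = tab$name)
}

#' Average CpG methylation rate over a window
#'
#' Mean of the 0/1 CpG-context methylation calls whose position lies
#' inside the window (1-based inclusive at both edges). When the call
#' table carries a `sample` column, the across-sample standard deviation
#' of per-sample rates is reported; when it carries an `allele` column,
#' per-allele rates are reported too.
#'
#' @param calls `data.frame` with columns `position` and `call` (0/1) and
#'   optionally `chromosome`, `sample`, `allele`.
#' @param window a single-range [GenomicRanges::GRanges] (or a
#'   `data.frame` row with `chromosome`, `start`, `end`, `name`).
#' @return a one-row `data.frame`: `window`, `n_cpg_calls`, `mean_rate`,
#'   `sd` plus `rate_<allele>` columns when alleles are present;
#'   `mean_rate` is `NA` when no call falls inside the window.
#' @export
regionMethylationRate <- function(calls, window) {
  if (is(window, "GRanges")) {
    stopifnot(length(window) == 1)
    win <- data.frame(chromosome = as.character(seqnames(window)),
                      start = start(window), end = end(window),
                      name = if (!is.null(window$name)) window$name
                      else "window")
  } else win <- as.data.frame(window)
  stopifnot(all(c("position", "call") %in% names(calls)),
            win$start <= win$end)
  inside <- calls$position >= win$start & calls$position <= win$end
  if (!is.null(calls$chromosome))
    inside <- inside & calls$chromosome == win$chromosome
  sub <- calls[inside, , drop = FALSE]
  out <- data.frame(window = win$name, n_cpg_calls = nrow(sub),
                    mean_rate = if (nrow(sub)) mean(sub$call)
                    else NA_real_,
                    sd = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(sub$sample) && nrow(sub)) {
    per <- tapply(sub$call, sub$sample, mean)
    out$sd <- if (length(per) > 1) sd(per) else NA_real_
  }
  if (!is.null(sub$allele) && nrow(sub)) {
    per <- tapply(sub$call, sub$allele, mean)
    for (a in names(per)) out[[paste0("rate_", a)]] <- unname(per[a])
  }
  out
}

#' Count reads per methylation pattern
#'
#' Each read's calls over the window's CpG positions are concatenated
#' (ordered by CpG index) into a pattern string; positions a read does not
#' cover keep a `.` placeholder so counting stays total. The counts sum to
#' the number of reads.
#'
#' @param reads `data.frame` with columns `read_id`, `cpg_index`, `call`.
#' @param n_cpg number of CpG positions in the window; defaults to the
#'   largest observed index.
#' @return named integer vector, pattern string -> read count.
#' @examples
#' patternCounts(data.frame(read_id = c("r1", "r1", "r2", "r2"),
#'                          cpg_index = c(1, 2, 1, 2),
#'                          call = c(1, 1, 0, 0)))
#' @export
patternCounts <- function(reads, n_cpg = NULL) {
  if (nrow(reads) == 0) return(setNames(integer(0), character(0)))
  stopifnot(all(c("read_id", "cpg_index", "call") %in% names(reads)))
  if (is.null(n_cpg)) n_cpg <- max(reads$cpg_index)
  pats <- vapply(split(reads, reads$read_id), function(d) {
    v <- rep(".", n_cpg)
    v[d$cpg_index] <- as.character(d$call)
    paste(v, collapse = "")
  }, "")
  tab <- table(pats)
  setNames(as.integer(tab), names(tab))
}

#' Split reads by the allele observed at a SNP
#'
#' Reads covering the SNP are partitioned by observed allele; alleles at
#' frequency at or below `min_allele_freq` are pooled under `"other"`.
#' The subsets are disjoint and their union is the covering-read set.
#'
#' @param reads `data.frame` with one row per read carrying an `allele`
#'   column (the base observed at the SNP), e.g. the distinct
#'   (`read_id`, `allele`) pairs of a methylation read table.
#' @param min_allele_freq frequency above which an allele keeps its own
#'   subset (default 0.05).
#' @return a named list of `data.frame` subsets; empty (with a warning)
#'   when no read covers the SNP.
#' @export
splitBySnpAllele <- function(reads, min_allele_freq = 0.05) {
  stopifnot("allele" %in% names(reads))
  reads <- reads[!is.na(reads$allele), , drop = FALSE]
  if (nrow(reads) == 0) {
    warning("no read covers the SNP")
    return(list())
  }
  if (!is.null(reads$read_id)) {
    per_read <- reads[!duplicated(reads$read_id), , drop = FALSE]
  } else per_read <- reads
  freq <- table(per_read$allele) / nrow(per_read)
  label <- ifelse(freq[reads$allele] > min_allele_freq,
                  reads$allele, "other")
  split(reads, label)
}
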