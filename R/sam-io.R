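#' Read spliced alignments from SAM or BAM
#'
#' Loads primary mapped alignments; unmapped, secondary and supplementary
#' records are skipped and tallied in the QC counters. SAM text input is
#' converted on the fly.
#'
#' @param path SAM (`.sam`) or BAM file. SAM must carry `@SQ` header lines.
#' @param with_seq Load read sequence and base qualities (needed for
#'   editing analysis; off by default to save memory).
#' @param sample_id Sample label attached to downstream tables; defaults to
#'   the file base name.
#' @return An object of class `alignments` wrapping a `GAlignments` of
#'   primary mapped records plus QC counters (`n_unmapped`, `n_secondary`,
#'   `n_supplementary`).
#' @export
read_alignments <- function(path, with_seq = FALSE, sample_id = NULL) {
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", bam),
                     overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "mapq")
  if (with_seq) what <- c(what, "seq", "qual")
  param <- Rsamtools::ScanBamParam(what = what)
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  flag <- S4Vectors::mcols(gal)$flag
  sec <- bitwAnd(flag, 256L) != 0L
  sup <- bitwAnd(flag, 2048L) != 0L
  n_unmapped <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))$records
  structure(list(gal = gal[!(sec | sup)],
                 sample_id = sample_id %||% sub("\\.(sam|bam)$", "", basename(path)),
                 n_unmapped = n_unmapped,
                 n_secondary = sum(sec), n_supplementary = sum(sup)),
            class = "alignments")
}

#' @export
print.alignments <- function(x, ...) {
  cat(sprintf("alignments '%s': %d primary mapped (%d unmapped, %d secondary, %d supplementary skipped)\n",
              x$sample_id, length(x$gal), x$n_unmapped, x$n_secondary,
              x$n_supplementary))
  invisible(x)
}

n_mapped_fragments <- function(aln) {
  length(unique(S4Vectors::mcols(aln$gal)$qname))
}

# Expected read strand for a feature of strand `s` under a library type.
expected_strand <- function(s, library_strand) {
  switch(library_strand,
         forward = s,
         reverse = ifelse(s == "+", "-", "+"),
         unstranded = rep("*", length(s)),
         stopf("unknown library_strand: %s", library_strand))
}
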