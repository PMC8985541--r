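# Targeted A-to-I editing quantification. Inosine reads as G, so editing
# at a sense-strand A appears as A>G in sense reads (T>C on the reference
# strand for minus-strand genes). Counts are raw read tallies — no PCR
# amplification model.

#' Read an editing-site specification table
#'
#' BED-like TSV with columns `chrom`, `pos` (0-based base position),
#' `strand`, `label`. The reference base must be A on the sense strand.
#'
#' @param path TSV path (header optional; columns recognized by name or
#'   order).
#' @return Data.frame of class `editing_sites`.
#' @export
read_editing_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "strand", "label") %in% names(df))) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    names(df)[1:4] <- c("chrom", "pos", "strand", "label")
  }
  editing_sites(df$chrom, df$pos, df$strand, df$label)
}

#' Construct an editing-site specification
#'
#' @param chrom,pos,strand,label Site coordinates (0-based positions) and
#'   unique labels (e.g. A-E).
#' @return Data.frame of class `editing_sites`.
#' @export
editing_sites <- function(chrom, pos, strand, label) {
  if (anyDuplicated(label)) stopf("editing-site labels must be unique")
  structure(data.frame(chrom = chrom, pos = as.integer(pos),
                       strand = strand, label = as.character(label)),
            class = c("editing_sites", "data.frame"))
}

# Reference-space layout of read sequences and qualities: insertions
# removed, deletions filled with '-', splice gaps with '.', so the base at
# reference position P of read i is substring(seq[i], P - start[i] + 1).
layout_reads <- function(aln, min_mapq) {
  gal <- aln$gal
  mc <- S4Vectors::mcols(gal)
  if (is.null(mc$seq)) stopf("alignments were read without sequences; use read_alignments(with_seq = TRUE)")
  keep <- !is.na(mc$mapq) & mc$mapq >= min_mapq
  gal <- gal[keep]
  cig <- GenomicAlignments::cigar(gal)
  list(gal = gal,
       qname = S4Vectors::mcols(gal)$qname,
       seq = GenomicAlignments::sequenceLayer(mc$seq[keep], cig),
       qual = GenomicAlignments::sequenceLayer(
         Biostrings::BStringSet(mc$qual[keep]), cig))
}

# Per-read base call at each site: "ref", "edited", "other", or NA when
# the read does not cover the site with a passing base.
per_read_site_calls <- function(lay, sites, min_baseq) {
  starts <- GenomicAlignments::start(lay$gal)
  chroms <- as.character(GenomicAlignments::seqnames(lay$gal))
  widths <- Biostrings::width(lay$seq)
  n <- length(lay$gal)
  calls <- matrix(NA_character_, n, nrow(sites),
                  dimnames = list(NULL, sites$label))
  for (j in seq_len(nrow(sites))) {
    P <- sites$pos[j] + 1L
    off <- P - starts + 1L
    ok <- chroms == sites$chrom[j] & off >= 1L & off <= widths
    if (!any(ok)) next
    b <- substring(as.character(lay$seq[ok]), off[ok], off[ok])
    q <- as.integer(charToRaw(paste(
      substring(as.character(lay$qual[ok]), off[ok], off[ok]),
      collapse = ""))) - 33L
    pass <- b %in% c("A", "C", "G", "T") & q >= min_baseq
    ref_b <- if (sites$strand[j] == "-") "T" else "A"
    edit_b <- if (sites$strand[j] == "-") "C" else "G"
    call <- ifelse(b == ref_b, "ref", ifelse(b == edit_b, "edited", "other"))
    call[!pass] <- NA_character_
    calls[ok, j] <- call
  }
  calls
}

#' Per-site editing frequencies
#'
#' Pileup-style tally at each editing site over primary alignments passing
#' mapping- and base-quality filters. The editing fraction is
#' `n_edited / (n_ref + n_edited)`; other bases are counted but excluded
#' from the denominator.
#'
#' @param aln An `alignments` object loaded with `with_seq = TRUE`.
#' @param sites An `editing_sites` table.
#' @param min_baseq Minimum Phred base quality (default 20).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param read_ids Optional read-name subset (e.g. the informative reads
#'   of [haplotype_table()]) to tally over.
#' @return Data.frame of class `site_editing` with `sample_id`,
#'   `site_label`, `n_ref`, `n_edited`, `n_other`, `editing_fraction` (NA
#'   when no read passes: no-data, distinct from zero editing).
#' @export
site_editing <- function(aln, sites, min_baseq = 20L, min_mapq = 20L,
                         read_ids = NULL) {
  lay <- layout_reads(aln, min_mapq)
  calls <- per_read_site_calls(lay, sites, min_baseq)
  if (!is.null(read_ids)) calls <- calls[lay$qname %in% read_ids, , drop = FALSE]
  out <- data.frame(sample_id = aln$sample_id, site_label = sites$label,
                    n_ref = colSums(calls == "ref", na.rm = TRUE),
                    n_edited = colSums(calls == "edited", na.rm = TRUE),
                    n_other = colSums(calls == "other", na.rm = TRUE))
  denom <- out$n_ref + out$n_edited
  out$editing_fraction <- ifelse(denom > 0L, out$n_edited / denom, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("site_editing", "data.frame")
  out
}

#' Per-read editing-haplotype table
#'
#' Restricts to informative reads — those covering every site with a
#' passing ref-or-edited base call — and tabulates the combination of
#' edited site labels per read (empty string = fully unedited). Percents
#' are normalized over informative reads and sum to 100.
#'
#' @inheritParams site_editing
#' @return Object of class `editing_haplotypes`: `table` (data.frame
#'   `combination`, `count`, `percent`), `n_informative`, `n_ambiguous`
#'   (reads covering all sites but with an off-type base), `marginals`
#'   (per-site edited fraction over the informative reads), `read_ids`.
#' @export
haplotype_table <- function(aln, sites, min_baseq = 20L, min_mapq = 20L) {
  lay <- layout_reads(aln, min_mapq)
  calls <- per_read_site_calls(lay, sites, min_baseq)
  covered <- rowSums(!is.na(calls)) == ncol(calls)
  clean <- covered & rowSums(calls == "other", na.rm = TRUE) == 0L
  if (!any(covered))
    stopf("no read covers all %d editing sites; haplotype analysis needs long-read or amplicon input",
          nrow(sites))
  cm <- calls[clean, , drop = FALSE]
  combo <- apply(cm, 1L, function(r)
    paste(sites$label[r == "edited"], collapse = ""))
  tab <- as.data.frame(table(combo), stringsAsFactors = FALSE)
  names(tab) <- c("combination", "count")
  tab <- tab[order(-tab$count, tab$combination), , drop = FALSE]
  tab$percent <- 100 * tab$count / sum(tab$count)
  rownames(tab) <- NULL
  marg <- colMeans(cm == "edited")
  structure(list(sample_id = aln$sample_id, table = tab,
                 n_informative = nrow(cm),
                 n_ambiguous = sum(covered) - nrow(cm),
                 marginals = marg,
                 read_ids = lay$qname[clean]),
            class = "editing_haplotypes")
}

#' @export
print.editing_haplotypes <- function(x, ...) {
  cat(sprintf("editing_haplotypes '%s': %d informative reads, %d combinations\n",
              x$sample_id, x$n_informative, nrow(x$table)))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Alternative 5' splice-site (exon skipping) frequency
#'
#' Counts junction reads matching the inclusion (proximal splice site,
#' alternative exon included) versus skipping (distal splice site)
#' junctions, using the same exact gap-match rule as [count_junctions()].
#' The skipping fraction is `skip / (skip + inclusion)`.
#'
#' @param aln An `alignments` object.
#' @param inclusion_junctions List of `c(start, end)` 0-based half-open
#'   intron gaps whose use implies exon inclusion.
#' @param skipping_junction Single `c(start, end)` gap implying skipping.
#' @param min_overhang Minimum aligned nt flanking the gap (default 8).
#' @return Data.frame of class `skipping_result`: `sample_id`,
#'   `n_inclusion_junctions`, `n_skipping_junctions`, `skipping_fraction`
#'   (NA when no junction reads: no-data).
#' @export
exon_skipping <- function(aln, inclusion_junctions, skipping_junction,
                          min_overhang = 8L) {
  stopifnot(inherits(aln, "alignments"))
  if (!is.list(inclusion_junctions)) inclusion_junctions <- list(inclusion_junctions)
  chrom <- as.character(GenomicAlignments::seqnames(aln$gal))[1L]
  mk <- function(j) data.frame(chrom = chrom, start = j[1L], end = j[2L])
  juncs <- do.call(rbind, c(lapply(inclusion_junctions, mk),
                            list(mk(skipping_junction))))
  n_incl <- length(inclusion_junctions)
  gr <- gr0(juncs$chrom, juncs$start, juncs$end)
  ee <- ee_hits(aln$gal, juncs, gr, min_overhang)
  qn <- S4Vectors::mcols(aln$gal)$qname[ee$read]
  # distinct reads per class: a read matching several inclusion junctions
  # is one inclusion molecule
  n_inc <- length(unique(qn[ee$intron <= n_incl]))
  n_skip <- length(unique(qn[ee$intron > n_incl]))
  tot <- n_inc + n_skip
  out <- data.frame(sample_id = aln$sample_id,
                    n_inclusion_junctions = n_inc,
                    n_skipping_junctions = n_skip,
                    skipping_fraction = if (tot > 0) n_skip / tot else NA_real_)
  class(out) <- c("skipping_result", "data.frame")
  out
}

#' Compare per-site editing between two samples or conditions
#'
#' Two-proportion z-test (pooled) per site on edited vs ref counts, with
#' Benjamini-Hochberg correction across sites.
#'
#' @param res_a,res_b `site_editing` tables over the same sites.
#' @return Data.frame with `site_label`, `fraction_a`, `fraction_b`,
#'   `z`, `p_value`, `padj_bh`, `significant` (padj <= 0.05).
#' @export
compare_editing <- function(res_a, res_b) {
  b <- res_b[match(res_a$site_label, res_b$site_label), , drop = FALSE]
  x1 <- res_a$n_edited; n1 <- res_a$n_edited + res_a$n_ref
  x2 <- b$n_edited; n2 <- b$n_edited + b$n_ref
  p_pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (x1 / n1 - x2 / n2) / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(site_label = res_a$site_label,
             fraction_a = x1 / n1, fraction_b = x2 / n2,
             z = z, p_value = p, padj_bh = stats::p.adjust(p, "BH"),
             significant = stats::p.adjust(p, "BH") <= 0.05)
}
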