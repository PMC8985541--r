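# Junction-evidence counting: classify spliced short-read alignments into
# exon-exon (EE), exon-intron (EI5 donor / EI3 acceptor) and intron-body
# (IB) evidence per intron per sample.

#' Count junction evidence per intron
#'
#' For each intron, classifies primary mapped alignments into the four
#' evidence categories of the retention statistic:
#' * **EE** — a read whose alignment N-gap matches the intron's
#'   (start, end) exactly, with at least `min_overhang` aligned nt on both
#'   sides of the gap (the spliced isoform);
#' * **EI5 / EI3** — a read with one aligned block covering
#'   `[boundary - min_overhang, boundary + min_overhang)` contiguously at
#'   the donor / acceptor boundary (the retained isoform);
#' * **IB** — a read whose aligned span lies entirely inside the intron.
#'
#' Reads failing the library-strand expectation are excluded from the
#' counts but enter the denominator of `sense_fraction`, the per-intron
#' fraction of contributing reads on the expected strand. Mates of a pair
#' vote independently and the fragment takes the union of their categories,
#' with EE taking precedence over EI over IB on conflict.
#'
#' @param aln An `alignments` object from [read_alignments()].
#' @param introns An `intron_records` data.frame from [derive_introns()].
#' @param min_overhang Minimum aligned nt on each side of a junction or
#'   boundary (default 8).
#' @param library_strand `"forward"` (read strand = transcript strand),
#'   `"reverse"`, or `"unstranded"`.
#' @return A data.frame of class `junction_counts` with columns
#'   `sample_id`, `intron_id`, `EE`, `EI5`, `EI3`, `IB`, `sense_fraction`.
#' @export
count_junctions <- function(aln, introns, min_overhang = 8L,
                            library_strand = "forward") {
  stopifnot(inherits(aln, "alignments"))
  gal <- aln$gal
  qname <- S4Vectors::mcols(gal)$qname
  rstrand <- as.character(GenomicAlignments::strand(gal))
  intron_gr <- gr0(introns$chrom, introns$start, introns$end)

  hits <- rbind(ee_hits(gal, introns, intron_gr, min_overhang),
                ei_hits(gal, introns, min_overhang),
                ib_hits(gal, intron_gr))
  if (nrow(hits) == 0L)
    return(finish_junction_counts(aln$sample_id, introns, NULL))

  hits$qname <- qname[hits$read]
  exp_str <- expected_strand(introns$strand, library_strand)[hits$intron]
  hits$strand_ok <- exp_str == "*" | rstrand[hits$read] == exp_str
  finish_junction_counts(aln$sample_id, introns, hits)
}

# EE: N-gap equals the intron exactly, overhang on both sides.
ee_hits <- function(gal, introns, intron_gr, ov) {
  jnc <- GenomicAlignments::junctions(gal)
  k <- lengths(jnc)
  if (sum(k) == 0L) return(empty_hits())
  ugaps <- unlist(jnc, use.names = FALSE)
  gap_read <- rep(seq_along(jnc), k)
  # flanking block widths: for a read with blocks w[1..m], gap i sits
  # between blocks i and i+1
  bl <- GenomicAlignments::grglist(gal)
  uw <- IRanges::width(unlist(bl, use.names = FALSE))
  cnt <- lengths(bl)
  lastpos <- cumsum(cnt)
  firstpos <- lastpos - cnt + 1L
  left_w <- uw[-lastpos]
  right_w <- uw[-firstpos]
  fo <- GenomicRanges::findOverlaps(ugaps, intron_gr, type = "equal",
                                    ignore.strand = TRUE)
  q <- S4Vectors::queryHits(fo)
  keep <- left_w[q] >= ov & right_w[q] >= ov
  data.frame(read = gap_read[q[keep]],
             intron = S4Vectors::subjectHits(fo)[keep],
             cat = rep("EE", sum(keep)))
}

# EI: one aligned block contains the +-overhang window around a boundary.
ei_hits <- function(gal, introns, ov) {
  bl <- GenomicAlignments::grglist(gal)
  ub <- unlist(bl, use.names = FALSE)
  blk_read <- rep(seq_along(bl), lengths(bl))
  res <- list()
  for (side in c("EI5", "EI3")) {
    b <- if (side == "EI5") introns$donor_pos else introns$acceptor_pos
    win <- gr0(introns$chrom, b - ov, b + ov)
    fo <- GenomicRanges::findOverlaps(win, ub, type = "within",
                                      ignore.strand = TRUE)
    res[[side]] <- data.frame(read = blk_read[S4Vectors::subjectHits(fo)],
                              intron = S4Vectors::queryHits(fo),
                              cat = rep(side, length(fo)))
  }
  do.call(rbind, res)
}

# IB: the whole aligned span lies inside the intron.
ib_hits <- function(gal, intron_gr) {
  span <- GenomicRanges::granges(gal)
  fo <- GenomicRanges::findOverlaps(span, intron_gr, type = "within",
                                    ignore.strand = TRUE)
  data.frame(read = S4Vectors::queryHits(fo),
             intron = S4Vectors::subjectHits(fo),
             cat = rep("IB", length(fo)))
}

empty_hits <- function() {
  data.frame(read = integer(), intron = integer(), cat = character())
}

finish_junction_counts <- function(sample_id, introns, hits) {
  n <- nrow(introns)
  out <- data.frame(sample_id = rep(sample_id, n),
                    intron_id = introns$intron_id,
                    EE = 0L, EI5 = 0L, EI3 = 0L, IB = 0L,
                    sense_fraction = NA_real_)
  if (!is.null(hits) && nrow(hits) > 0L) {
    # fragment-level resolution: unique categories per (qname, intron),
    # EE beats EI beats IB
    key <- paste(hits$qname, hits$intron)
    hits <- hits[!duplicated(paste(key, hits$cat)), , drop = FALSE]
    has_ee <- tapply(hits$cat == "EE", key, any)[key]
    has_ei <- tapply(hits$cat %in% c("EI5", "EI3"), key, any)[key]
    keep <- (hits$cat == "EE") |
      (hits$cat %in% c("EI5", "EI3") & !has_ee) |
      (hits$cat == "IB" & !has_ee & !has_ei)
    hits <- hits[keep, , drop = FALSE]
    # sense fraction over distinct contributing fragments per intron
    frag <- hits[!duplicated(paste(hits$qname, hits$intron)), , drop = FALSE]
    denom <- tabulate(frag$intron, nbins = n)
    numer <- tabulate(frag$intron[frag$strand_ok], nbins = n)
    out$sense_fraction <- ifelse(denom > 0L, numer / denom, NA_real_)
    hits <- hits[hits$strand_ok, , drop = FALSE]
    for (cat in c("EE", "EI5", "EI3", "IB")) {
      h <- hits[hits$cat == cat, , drop = FALSE]
      out[[cat]] <- tabulate(h$intron, nbins = n)
    }
  }
  class(out) <- c("junction_counts", "data.frame")
  out
}

#' Gene-level read counts and fpkm
#'
#' Counts fragments whose alignment overlaps the gene's exonic union on the
#' expected strand and converts to fpkm (fragments per kilobase of exonic
#' model per million mapped fragments).
#'
#' @inheritParams count_junctions
#' @param models A `gene_models` object.
#' @return A data.frame of class `gene_expression` with columns
#'   `sample_id`, `gene_id`, `read_count`, `fpkm`.
#' @export
compute_fpkm <- function(aln, models, library_strand = "forward") {
  stopifnot(inherits(aln, "alignments"))
  total <- n_mapped_fragments(aln)
  if (total == 0L) stopf("sample '%s' has zero mapped reads", aln$sample_id)
  gal <- aln$gal
  qname <- S4Vectors::mcols(gal)$qname
  rstrand <- as.character(GenomicAlignments::strand(gal))
  exu <- lapply(models, function(g)
    GenomicRanges::reduce(gr0(g$chrom, g$exons$start, g$exons$end)))
  exon_kb <- vapply(exu, function(u) sum(IRanges::width(u)) / 1000, 0)
  span <- GenomicRanges::granges(gal)
  counts <- integer(length(models))
  for (i in seq_along(models)) {
    es <- expected_strand(models[[i]]$strand, library_strand)
    fo <- GenomicRanges::findOverlaps(span, exu[[i]], ignore.strand = TRUE)
    reads <- unique(S4Vectors::queryHits(fo))
    if (es != "*") reads <- reads[rstrand[reads] == es]
    counts[i] <- length(unique(qname[reads]))
  }
  out <- data.frame(sample_id = aln$sample_id,
                    gene_id = vapply(models, `[[`, "", "gene_id"),
                    read_count = counts,
                    fpkm = counts / (exon_kb * total / 1e6))
  rownames(out) <- NULL
  class(out) <- c("gene_expression", "data.frame")
  out
}

#' Intergenic background expression threshold
#'
#' Samples `n_regions` intervals of `region_length` nt uniformly from the
#' genome excluding gene spans plus a 1 kb buffer, computes each region's
#' fpkm, and returns the 95th percentile — the background a gene must
#' exceed to count as expressed. The percentile uses linear interpolation
#' between order statistics (R quantile type 7); the convention is recorded
#' in the returned object.
#'
#' @inheritParams compute_fpkm
#' @param n_regions Number of intergenic regions to sample (default 100).
#' @param region_length Length of each region in nt (default 1000).
#' @param seed Integer seed for region placement.
#' @param quantile_prob Percentile to report (default 0.95).
#' @param buffer Exclusion buffer around gene spans in nt (default 1000).
#' @return An object of class `background_model` with elements `sample_id`,
#'   `threshold` (fpkm), `region_fpkm`, and metadata (`quantile_prob`,
#'   `quantile_type`).
#' @export
background_threshold <- function(aln, models, n_regions = 100L,
                                 region_length = 1000L, seed = 1L,
                                 quantile_prob = 0.95, buffer = 1000L) {
  stopifnot(inherits(aln, "alignments"))
  total <- n_mapped_fragments(aln)
  if (total == 0L) stopf("sample '%s' has zero mapped reads", aln$sample_id)
  sl <- GenomeInfoDb::seqlengths(GenomicAlignments::seqinfo(aln$gal))
  if (anyNA(sl)) stopf("alignment header lacks sequence lengths (@SQ LN)")
  genome_gr <- GenomicRanges::GRanges(names(sl), IRanges::IRanges(1L, sl))
  gene_gr <- do.call(c, lapply(unname(models), function(g)
    gr0(g$chrom, max(0L, g$tx_start - buffer), g$tx_end + buffer)))
  GenomeInfoDb::seqlevels(gene_gr) <- GenomeInfoDb::seqlevels(genome_gr)
  allowed <- GenomicRanges::setdiff(genome_gr, gene_gr, ignore.strand = TRUE)
  allowed <- allowed[IRanges::width(allowed) >= region_length]
  if (length(allowed) == 0L)
    stopf("genome too gene-dense to place intergenic regions of %d nt; reduce n_regions or region_length",
          region_length)
  # uniform over valid start positions across all allowed intervals
  slots <- IRanges::width(allowed) - region_length + 1L
  set.seed(seed)
  iv <- sample.int(length(allowed), n_regions, replace = TRUE,
                   prob = slots / sum(slots))
  off <- floor(stats::runif(n_regions) * slots[iv])
  regions <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(allowed)[iv],
    IRanges::IRanges(GenomicRanges::start(allowed)[iv] + off,
                     width = region_length))
  span <- GenomicRanges::granges(aln$gal)
  qname <- S4Vectors::mcols(aln$gal)$qname
  fo <- GenomicRanges::findOverlaps(span, regions, ignore.strand = TRUE)
  cnt <- vapply(seq_len(n_regions), function(j)
    length(unique(qname[S4Vectors::queryHits(fo)[S4Vectors::subjectHits(fo) == j]])),
    0L)
  fpkm <- cnt / ((region_length / 1000) * total / 1e6)
  structure(list(sample_id = aln$sample_id,
                 threshold = unname(stats::quantile(fpkm, quantile_prob, type = 6)),
                 region_fpkm = fpkm, n_regions = n_regions,
                 region_length = region_length,
                 quantile_prob = quantile_prob,
                 quantile_type = "type6_linear_interpolation"),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model '%s': %.4f fpkm (p%.0f of %d intergenic regions, %s)\n",
              x$sample_id, x$threshold, 100 * x$quantile_prob, x$n_regions,
              x$quantile_type))
  invisible(x)
}
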