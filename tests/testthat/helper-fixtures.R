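# Shared fixtures, built in code at test time.

# Write a SAM file from alignment field lists.
# reads: data.frame with qname, flag, chrom, pos1 (1-based), cigar,
# optional seq, qual.
write_test_sam <- function(reads, seqlens, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  if (is.null(reads$seq)) reads$seq <- rep("*", nrow(reads))
  if (is.null(reads$qual)) reads$qual <- rep("*", nrow(reads))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$chrom, reads$pos1,
                  reads$cigar, reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  path
}

# Minimal GTF writer (1-based inclusive coordinates in `rows`).
write_test_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    rows$chrom, rows$start1, rows$end1, rows$strand, rows$gene_id,
    rows$transcript_id)
  writeLines(lines, path)
  path
}

# A deterministic two-gene toy annotation: gene A (+, 3 exons),
# gene B (-, 2 exons plus a retention transcript).
toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  rows <- data.frame(
    chrom = "chr1",
    start1 = c(101, 301, 501, 1001, 1301, 1001),
    end1 = c(200, 400, 600, 1100, 1400, 1400),
    strand = c("+", "+", "+", "-", "-", "-"),
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gB"),
    transcript_id = c("gA.t1", "gA.t1", "gA.t1", "gB.t1", "gB.t1", "gB.t2"))
  write_test_gtf(rows, path)
}

# Small locus set cached across tests in one session.
small_locus_env <- new.env()
small_locus <- function(seed = 11) {
  key <- paste0("locus", seed)
  if (is.null(small_locus_env[[key]])) {
    cfg <- synthetic_config(seed = seed, n_genes = 8, reads_per_gene = 300)
    small_locus_env[[key]] <- list(cfg = cfg, locus = make_locus_set(cfg))
  }
  small_locus_env[[key]]
}

# Independent brute-force stop-codon scanner: tests every single position.
brute_stop_frames <- function(seq) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  found <- logical(3)
  p <- 0L
  while (p + 3L <= n) {
    if (substr(seq, p + 1L, p + 3L) %in% stops) found[p %% 3L + 1L] <- TRUE
    p <- p + 1L
  }
  which(found) - 1L
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
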