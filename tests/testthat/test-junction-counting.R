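# Toy-alignment classification uses a single intron (200,300) in a
# plus-strand gene; reads are built by hand and expectations worked out
# from the category definitions.
toy_intron <- function() {
  structure(data.frame(intron_id = "gT.I1", gene_id = "gT", chrom = "chr1",
                       strand = "+", start = 200L, end = 300L,
                       donor_pos = 200L, acceptor_pos = 300L,
                       ordinal = 1L, n_introns = 1L, known_retained = FALSE,
                       flank_up = 100L, flank_down = 100L),
            class = c("intron_records", "data.frame"))
}

test_that("reads classify into EE, EI5, EI3, IB by the boundary definitions", {
  reads <- data.frame(
    qname = c("ee", "ei5", "ei3", "ib", "partial"),
    flag = 0L, chrom = "chr1",
    pos1 = c(151L, 193L, 251L, 211L, 151L),
    cigar = c("50M100N50M",   # gap (200,300) exact -> EE
              "50M",          # block (192,242) spans donor 200 -> EI5
              "100M",         # block (250,350) spans acceptor 300 -> EI3
              "80M",          # (210,290) inside intron -> IB
              "50M90N10M"))   # gap (200,290): alternative junction -> nothing
  sam <- write_test_sam(reads, c(chr1 = 1000L))
  jc <- count_junctions(read_alignments(sam), toy_intron(), min_overhang = 8)
  expect_equal(jc$EE, 1L)
  expect_equal(jc$EI5, 1L)
  expect_equal(jc$EI3, 1L)
  expect_equal(jc$IB, 1L)
  expect_equal(jc$sense_fraction, 1)
})

test_that("the exon-junction overhang requirement is enforced on both sides", {
  reads <- data.frame(
    qname = c("thin_left", "ok"),
    flag = 0L, chrom = "chr1",
    pos1 = c(196L, 151L),
    cigar = c("5M100N50M", "50M100N50M"))
  sam <- write_test_sam(reads, c(chr1 = 1000L))
  jc <- count_junctions(read_alignments(sam), toy_intron(), min_overhang = 8)
  expect_equal(jc$EE, 1L)
  jc2 <- count_junctions(read_alignments(sam), toy_intron(), min_overhang = 5)
  expect_equal(jc2$EE, 2L)
})

test_that("antisense reads are excluded from counts but enter sense_fraction", {
  reads <- data.frame(
    qname = c("s1", "s2", "s3", "anti"),
    flag = c(0L, 0L, 0L, 16L), chrom = "chr1",
    pos1 = 151L, cigar = "50M100N50M")
  sam <- write_test_sam(reads, c(chr1 = 1000L))
  jc <- count_junctions(read_alignments(sam), toy_intron())
  expect_equal(jc$EE, 3L)
  expect_equal(jc$sense_fraction, 0.75)
  # unstranded counts everything
  jcu <- count_junctions(read_alignments(sam), toy_intron(),
                         library_strand = "unstranded")
  expect_equal(jcu$EE, 4L)
})

test_that("mates vote independently and EE beats EI beats IB per fragment", {
  reads <- data.frame(
    qname = c("frag1", "frag1", "frag2", "frag2"),
    flag = 0L, chrom = "chr1",
    pos1 = c(151L, 211L,   # frag1: EE mate + IB mate -> EE only
             193L, 211L),  # frag2: EI5 mate + IB mate -> EI5 only
    cigar = c("50M100N50M", "80M", "50M", "80M"))
  sam <- write_test_sam(reads, c(chr1 = 1000L))
  jc <- count_junctions(read_alignments(sam), toy_intron())
  expect_equal(jc$EE, 1L)
  expect_equal(jc$EI5, 1L)
  expect_equal(jc$IB, 0L)
})

test_that("fpkm follows the fragments-per-exonic-kb-per-million definition", {
  gtf <- write_test_gtf(data.frame(
    chrom = "chr1", start1 = c(1001, 5001, 7001), end1 = c(2000, 6000, 9000),
    strand = "+", gene_id = c("g1k", "g2k", "g2k"),
    transcript_id = c("g1k.t", "g2k.t", "g2k.t")))
  models <- load_gene_models(gtf)
  # 10 reads on each gene; exonic lengths 1 kb and 3 kb -> fpkm ratio 3:1
  reads <- data.frame(
    qname = sprintf("r%02d", 1:20), flag = 0L, chrom = "chr1",
    pos1 = c(rep(1101L, 10), rep(5101L, 10)), cigar = "50M")
  sam <- write_test_sam(reads, c(chr1 = 10000L))
  expr <- compute_fpkm(read_alignments(sam), models)
  # 10 / (1 kb * 20/1e6 million) = 500000
  expect_equal(expr$fpkm[expr$gene_id == "g1k"], 5e5)
  expect_equal(expr$fpkm[expr$gene_id == "g1k"] /
                 expr$fpkm[expr$gene_id == "g2k"], 3)
  expect_true(all(expr$fpkm > 0 | expr$read_count == 0))
})

test_that("genes without reads get fpkm 0 and empty samples error", {
  gtf <- write_test_gtf(data.frame(
    chrom = "chr1", start1 = 1001, end1 = 2000, strand = "+",
    gene_id = "g0", transcript_id = "g0.t"))
  models <- load_gene_models(gtf)
  reads <- data.frame(qname = "far", flag = 0L, chrom = "chr1",
                      pos1 = 9000L, cigar = "50M")
  sam <- write_test_sam(reads, c(chr1 = 10000L))
  expr <- compute_fpkm(read_alignments(sam), models)
  expect_equal(expr$fpkm, 0)
  empty <- write_test_sam(reads[0, ], c(chr1 = 10000L))
  expect_error(compute_fpkm(read_alignments(empty), models), "zero mapped")
})

test_that("background threshold uses the declared percentile convention and is seed-stable", {
  sl <- small_locus()
  sam <- tempfile(fileext = ".sam")
  simulate_short_reads(sl$cfg, sl$locus, "AN", 1, sam)
  aln <- read_alignments(sam)
  bg1 <- background_threshold(aln, sl$locus$models, seed = 5)
  bg2 <- background_threshold(aln, sl$locus$models, seed = 5)
  expect_identical(bg1$threshold, bg2$threshold)
  expect_identical(bg1$region_fpkm, bg2$region_fpkm)
  expect_equal(bg1$quantile_type, "type6_linear_interpolation")
  # no intergenic reads in this generator -> threshold 0, all genes expressed
  expect_equal(bg1$threshold, 0)
  expr <- compute_fpkm(aln, sl$locus$models)
  expect_true(all(expr$fpkm > bg1$threshold))
  # the declared convention on the documented worked example:
  # 95 zeros and 1..5 -> between the 95th and 96th order statistics
  q <- unname(quantile(c(rep(0, 95), 1:5), 0.95, type = 6))
  expect_true(q >= 0.75 && q <= 1.0)
})

test_that("boundary retention evidence converges to the true retention fraction", {
  sl <- small_locus()
  sam <- tempfile(fileext = ".sam")
  simulate_short_reads(sl$cfg, sl$locus, "AN", 1, sam)
  jc <- count_junctions(read_alignments(sam), sl$locus$introns)
  rho <- sl$locus$truth$introns$rho[jc$intron_id, "AN"]
  for (i in seq_len(nrow(jc))) {
    n <- jc$EI5[i] + jc$EE[i]
    if (n < 20) next
    se <- sqrt(rho[i] * (1 - rho[i]) / n)
    expect_lt(abs(jc$EI5[i] / n - rho[i]), 3 * se + 1e-9)
  }
})

test_that("strand-specific libraries keep ~98% of evidence on the expected strand", {
  sl <- small_locus()
  sam <- tempfile(fileext = ".sam")
  simulate_short_reads(sl$cfg, sl$locus, "AI", 2, sam)
  jc <- count_junctions(read_alignments(sam), sl$locus$introns)
  w <- jc$EE + jc$EI5 + jc$EI3 + jc$IB
  overall <- weighted.mean(jc$sense_fraction, w, na.rm = TRUE)
  expect_gt(overall, 0.96)
  expect_lt(overall, 1.0)
})
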