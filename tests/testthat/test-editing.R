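# Editing analysis on hand-built amplicon reads over five sites at
# positions 20, 25, 32, 37, 44 (0-based) of a 100 nt reference.
ed_sites <- function(strand = "+") {
  editing_sites("chrE", c(20, 25, 32, 37, 44), strand, c("A", "B", "C", "D", "E"))
}

# build a read sequence of length 100 with site bases set per haplotype
ed_read <- function(qname, edited = character(0), strand = "+",
                    qual_char = "I") {
  s <- rep("C", 100)
  pos <- c(A = 21, B = 26, C = 33, D = 38, E = 45)
  s[pos] <- "A"
  s[pos[edited]] <- "G"
  data.frame(qname = qname, flag = if (strand == "-") 16L else 0L,
             chrom = "chrE", pos1 = 1L, cigar = "100M",
             seq = paste(s, collapse = ""), qual = strrep(qual_char, 100))
}

test_that("per-site editing fractions are edited/(ref+edited)", {
  reads <- do.call(rbind, c(
    lapply(1:8, function(i) ed_read(paste0("u", i))),
    lapply(1:2, function(i) ed_read(paste0("e", i), edited = c("A", "B")))))
  aln <- read_alignments(write_test_sam(reads, c(chrE = 200L)), with_seq = TRUE)
  se <- site_editing(aln, ed_sites())
  expect_equal(se$editing_fraction[se$site_label == "A"], 0.2)
  expect_equal(se$editing_fraction[se$site_label == "B"], 0.2)
  expect_equal(se$editing_fraction[se$site_label == "E"], 0)
  # all edited at one site
  all_e <- do.call(rbind, lapply(1:5, function(i)
    ed_read(paste0("x", i), edited = "C")))
  aln2 <- read_alignments(write_test_sam(all_e, c(chrE = 200L)), with_seq = TRUE)
  se2 <- site_editing(aln2, ed_sites())
  expect_equal(se2$editing_fraction[se2$site_label == "C"], 1)
})

test_that("quality filters gate base calls and uncovered sites give no-data", {
  reads <- rbind(ed_read("good"), ed_read("lowq", qual_char = "#"))
  aln <- read_alignments(write_test_sam(reads, c(chrE = 200L)), with_seq = TRUE)
  se <- site_editing(aln, ed_sites(), min_baseq = 20)
  expect_true(all(se$n_ref + se$n_edited == 1))
  # no read covers the site at all -> NA fraction
  off <- editing_sites("chrE", 150, "+", "Z")
  sez <- site_editing(aln, off)
  expect_true(is.na(sez$editing_fraction))
})

test_that("minus-strand sites classify complemented bases", {
  # sense-strand A on a minus-strand gene is reference T; edited G reads C.
  s <- rep("G", 100); s[21] <- "T"
  ref_read <- data.frame(qname = "r1", flag = 0L, chrom = "chrE", pos1 = 1L,
                         cigar = "100M", seq = paste(s, collapse = ""),
                         qual = strrep("I", 100))
  s2 <- rep("G", 100); s2[21] <- "C"
  ed_read2 <- data.frame(qname = "r2", flag = 0L, chrom = "chrE", pos1 = 1L,
                         cigar = "100M", seq = paste(s2, collapse = ""),
                         qual = strrep("I", 100))
  aln <- read_alignments(write_test_sam(rbind(ref_read, ed_read2),
                                        c(chrE = 200L)), with_seq = TRUE)
  se <- site_editing(aln, editing_sites("chrE", 20, "-", "A"))
  expect_equal(se$n_ref, 1L)
  expect_equal(se$n_edited, 1L)
  expect_equal(se$editing_fraction, 0.5)
})

test_that("haplotype table percents sum to 100 and recover hand-built combinations", {
  reads <- do.call(rbind, c(
    lapply(1:7, function(i) ed_read(paste0("abd", i), c("A", "B", "D"))),
    lapply(1:3, function(i) ed_read(paste0("u", i)))))
  aln <- read_alignments(write_test_sam(reads, c(chrE = 200L)), with_seq = TRUE)
  ht <- haplotype_table(aln, ed_sites())
  expect_equal(sum(ht$table$percent), 100)
  expect_equal(ht$table$percent[ht$table$combination == "ABD"], 70)
  expect_equal(ht$table$percent[ht$table$combination == ""], 30)
  expect_equal(ht$n_informative, 10)
  # single informative read -> one combination at 100%
  one <- read_alignments(write_test_sam(ed_read("solo", "E"), c(chrE = 200L)),
                         with_seq = TRUE)
  ht1 <- haplotype_table(one, ed_sites())
  expect_equal(ht1$table$combination, "E")
  expect_equal(ht1$table$percent, 100)
  # reads not covering every site -> error advising amplicon input
  part <- data.frame(qname = "short", flag = 0L, chrom = "chrE", pos1 = 1L,
                     cigar = "25M", seq = strrep("A", 25),
                     qual = strrep("I", 25))
  alnp <- read_alignments(write_test_sam(part, c(chrE = 200L)), with_seq = TRUE)
  expect_error(haplotype_table(alnp, ed_sites()), "covers all")
})

test_that("haplotype marginals equal site fractions on the informative subset exactly", {
  sl <- small_locus()
  sam <- tempfile(fileext = ".sam")
  simulate_editing_reads(sl$cfg, sl$locus, "BN", sam)
  aln <- read_alignments(sam, with_seq = TRUE)
  sites <- sl$locus$editing_locus$sites
  ht <- haplotype_table(aln, sites)
  se_sub <- site_editing(aln, sites, read_ids = ht$read_ids)
  expect_equal(unname(ht$marginals),
               se_sub$editing_fraction[match(sites$label, se_sub$site_label)])
})

test_that("generated haplotype and site frequencies are recovered within sampling error", {
  sl <- small_locus()
  sam <- tempfile(fileext = ".sam")
  simulate_editing_reads(sl$cfg, sl$locus, "AN", sam)
  aln <- read_alignments(sam, with_seq = TRUE)
  sites <- sl$locus$editing_locus$sites
  truth <- sl$locus$truth$editing
  se <- site_editing(aln, sites)
  n <- se$n_ref + se$n_edited
  for (j in seq_len(nrow(se))) {
    p <- truth$site_fractions[se$site_label[j]]
    se_j <- sqrt(p * (1 - p) / n[j])
    expect_lt(abs(se$editing_fraction[j] - p), 3 * se_j + 1e-9)
  }
  ht <- haplotype_table(aln, sites)
  for (ci in seq_along(truth$haplotypes)) {
    combo <- names(truth$haplotypes)[ci]
    p <- truth$haplotypes[[ci]]
    obs <- ht$table$percent[ht$table$combination == combo] / 100
    if (length(obs) == 0) obs <- 0
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / ht$n_informative))
  }
})

test_that("exon skipping fraction follows the junction-read definition and truth", {
  sl <- small_locus()
  sam <- tempfile(fileext = ".sam")
  simulate_editing_reads(sl$cfg, sl$locus, "BI", sam)
  aln <- read_alignments(sam, with_seq = TRUE)
  el <- sl$locus$editing_locus
  sk <- exon_skipping(aln, el$inclusion_junctions, el$skipping_junction)
  p <- sl$locus$truth$editing$skipping_fraction
  n <- sk$n_inclusion_junctions + sk$n_skipping_junctions
  expect_lt(abs(sk$skipping_fraction - p), 3 * sqrt(p * (1 - p) / n))
  # degenerate direct cases
  only_skip <- data.frame(qname = "s", flag = 0L, chrom = "chrE", pos1 = 1L,
                          cigar = "20M60N20M")
  alns <- read_alignments(write_test_sam(only_skip, c(chrE = 200L)))
  sk2 <- exon_skipping(alns, list(c(20, 40)), c(20, 80))
  expect_equal(sk2$skipping_fraction, 1)
})

test_that("the between-condition site comparison holds its size under the null", {
  set.seed(97)
  n_sim <- 500
  any_sig <- logical(n_sim)
  fractions <- c(A = 0.8, B = 0.6, C = 0.1, D = 0.4, E = 0.05)
  reject <- matrix(NA, n_sim, 5)
  for (k in seq_len(n_sim)) {
    mk <- function() {
      ed <- rbinom(5, 500, fractions)
      data.frame(site_label = names(fractions), n_ref = 500L - ed,
                 n_edited = ed)
    }
    cmp <- compare_editing(mk(), mk())
    reject[k, ] <- cmp$significant
  }
  # the module's decision rule (BH-corrected across sites) keeps the
  # per-site type-I error at or below the nominal level
  expect_lte(max(colMeans(reject)), 0.06)
  # and the raw z-test p-values are calibrated: rejection rate within
  # 3 Monte-Carlo SEs of alpha
  set.seed(98)
  raw <- replicate(500, {
    ed1 <- rbinom(1, 500, 0.4); ed2 <- rbinom(1, 500, 0.4)
    a <- data.frame(site_label = "D", n_ref = 500L - ed1, n_edited = ed1)
    b <- data.frame(site_label = "D", n_ref = 500L - ed2, n_edited = ed2)
    compare_editing(a, b)$p_value <= 0.05
  })
  expect_lt(abs(mean(raw) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("editing-site specs load from BED-like TSV", {
  p <- system.file("extdata", "editing_sites_synthetic.tsv",
                   package = "riquant")
  sites <- read_editing_sites(p)
  expect_s3_class(sites, "editing_sites")
  expect_equal(sites$label, c("A", "B", "C", "D", "E"))
  expect_equal(sites$pos[1], 420L)
  # headerless variant
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("chr9\t100\t-\tX", "chr9\t105\t-\tY"), tmp)
  s2 <- read_editing_sites(tmp)
  expect_equal(s2$label, c("X", "Y"))
  expect_error(editing_sites("c", c(1, 2), "+", c("A", "A")), "unique")
})
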