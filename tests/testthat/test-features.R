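test_that("relative position is the midpoint percent, strand-aware", {
  models <- structure(list(gP = list(
    gene_id = "gP", chrom = "c", strand = "+", tx_start = 1000L,
    tx_end = 11000L,
    exons = data.frame(start = c(1000L, 2200L), end = c(2000L, 11000L)),
    transcripts = list(t1 = c(1L, 2L)))), class = "gene_models")
  intr <- data.frame(intron_id = "gP.I1", gene_id = "gP", chrom = "c",
                     strand = "+", start = 2000L, end = 2200L)
  # first intron 10% into a 10 kb span, 200 nt long: 10 + 1 = 11%
  expect_equal(relative_position(intr, models), 11.0)
  # midpoint exactly at the gene midpoint -> 50
  intr50 <- transform(intr, start = 5900L, end = 6100L)
  expect_equal(relative_position(intr50, models), 50.0)
  # minus strand: an intron near the genomic end is near the 5' end
  mm <- models; mm$gP$strand <- "-"
  intr_end <- transform(intr, strand = "-", start = 10500L, end = 10700L)
  expect_equal(relative_position(intr_end, mm), 100 * (11000 - 10600) / 10000)
  expect_error(relative_position(transform(intr, start = 100L), models),
               "outside gene span")
})

test_that("relative position is invariant to coordinate translation and strand flip", {
  sl <- small_locus()
  introns <- sl$locus$introns
  models <- sl$locus$models
  rp <- relative_position(introns, models)
  expect_true(all(rp >= 0 & rp <= 100))
  # translate the whole locus by 5 kb
  shift_models <- models
  for (g in names(shift_models)) {
    shift_models[[g]]$tx_start <- shift_models[[g]]$tx_start + 5000L
    shift_models[[g]]$tx_end <- shift_models[[g]]$tx_end + 5000L
    shift_models[[g]]$exons <- shift_models[[g]]$exons + 5000L
  }
  shift_introns <- introns
  shift_introns$start <- shift_introns$start + 5000L
  shift_introns$end <- shift_introns$end + 5000L
  expect_equal(relative_position(shift_introns, shift_models), rp)
  # mirror the locus (strand flip): positions must be preserved
  L <- max(vapply(models, `[[`, 0, "tx_end")) + 1000L
  flip_models <- models
  for (g in names(flip_models)) {
    m <- flip_models[[g]]
    ex <- data.frame(start = L - m$exons$end, end = L - m$exons$start)
    ex <- ex[order(ex$start), ]
    flip_models[[g]]$exons <- ex
    flip_models[[g]]$tx_start <- L - m$tx_end
    flip_models[[g]]$tx_end <- L - m$tx_start
    flip_models[[g]]$strand <- ifelse(m$strand == "+", "-", "+")
  }
  flip_introns <- introns
  flip_introns$start <- L - introns$end
  flip_introns$end <- L - introns$start
  flip_introns$strand <- ifelse(introns$strand == "+", "-", "+")
  expect_equal(relative_position(flip_introns, flip_models), rp)
})

test_that("the PWM scorer ranks consensus above mismatches and background near zero", {
  set.seed(5)
  strength <- 0.9
  noisy <- function(consensus, n) {
    w <- strsplit(consensus, "")[[1]]
    vapply(seq_len(n), function(i) {
      b <- ifelse(runif(length(w)) < strength, w,
                  sample(c("A", "C", "G", "T"), length(w), TRUE))
      paste(b, collapse = "")
    }, "")
  }
  don <- noisy("CAGGTAAGT", 400)
  acc <- noisy("TTTTTTTTTTTTTCTTTCAGGTT", 400)
  comp <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  model <- train_splice_model(don, acc, comp)
  cons_score <- riquant:::score_window("CAGGTAAGT", model$donor)
  # every single-mismatch variant scores strictly below the consensus
  for (p in 1:9) for (b in setdiff(c("A", "C", "G", "T"),
                                   substr("CAGGTAAGT", p, p))) {
    v <- "CAGGTAAGT"
    substr(v, p, p) <- b
    expect_lt(riquant:::score_window(v, model$donor), cons_score)
  }
  # under an informative model, background sequence scores negative on
  # average (minus the KL divergence); near zero only for an
  # uninformative (background-trained) model
  rnd <- vapply(1:400, function(i) random_dna(9), "")
  sc <- vapply(rnd, riquant:::score_window, 0, mat = model$donor)
  expect_lt(mean(sc), 0)
  null_model <- train_splice_model(
    vapply(1:2000, function(i) random_dna(9), ""),
    vapply(1:2000, function(i) random_dna(23), ""), comp)
  sc0 <- vapply(rnd, riquant:::score_window, 0, mat = null_model$donor)
  expect_lt(abs(mean(sc0)), 3 * sd(sc0) / sqrt(length(sc0)) + 0.05)
  expect_error(train_splice_model(don[1:20], acc, comp), ">=50")
})

test_that("uniform-random training sites give near-zero weights that shrink with n", {
  # bounds from a multinomial simulation of max |log2 odds| over the
  # weight matrix: 99.9th percentile ~0.35 bits at n = 1000 and ~0.12 at
  # n = 8000 (pseudocount 0.5)
  set.seed(6)
  for (spec in list(list(n = 1000, bound = 0.36), list(n = 8000, bound = 0.15))) {
    don <- vapply(seq_len(spec$n), function(i) random_dna(9), "")
    acc <- vapply(seq_len(spec$n), function(i) random_dna(23), "")
    model <- train_splice_model(don, acc, c(A = .25, C = .25, G = .25, T = .25))
    expect_lt(max(abs(model$donor)), spec$bound)
    expect_lt(max(abs(model$acceptor)), spec$bound)
  }
})

test_that("trained on generated sites, held-out true windows separate from random (AUC > 0.9)", {
  train_locus <- make_locus_set(synthetic_config(seed = 31, n_genes = 25))
  zero_model <- structure(
    list(donor = matrix(0, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL)),
         acceptor = matrix(0, 4, 23, dimnames = list(c("A", "C", "G", "T"), NULL))),
    class = "splice_site_model")
  # window sequences of the training locus
  sc0 <- score_splice_sites(train_locus$introns, train_locus$genome, zero_model)
  model <- train_splice_model(sc0$donor_seq, sc0$acceptor_seq,
                              c(A = .25, C = .25, G = .25, T = .25))
  # held-out locus from an independent seed
  locus2 <- make_locus_set(synthetic_config(seed = 77, n_genes = 12))
  pos <- score_splice_sites(locus2$introns, locus2$genome, model)$donor_score
  set.seed(8)
  neg <- vapply(seq_along(pos), function(i)
    riquant:::score_window(random_dna(9), model$donor), 0)
  auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_gt(auc, 0.9)
})

test_that("stop-codon frames follow the positional definition and match brute force", {
  expect_equal(stop_codon_frames("TAATAGTGA"), 0L)
  expect_equal(stop_codon_frames("AAAAAA"), integer(0))
  expect_error(stop_codon_frames("AAXAA"), "outside")
  # exhaustive agreement with the all-positions scanner on short sequences
  bases <- c("A", "C", "G", "T")
  for (len in 3:6) {
    grid <- do.call(expand.grid, rep(list(bases), len))
    seqs <- do.call(paste0, grid)
    for (s in seqs)
      expect_identical(stop_codon_frames(s), brute_stop_frames(s))
  }
})

test_that("motif occurrences are overlapping, percent-positioned, and enrichment-tested", {
  mp <- motif_profile(c(i1 = "GGATAGAGG"), motif = "ATAGA")
  expect_equal(mp$per_intron$n_occurrences, 1L)
  expect_equal(mp$positions_percent, 100 * 2 / 9, tolerance = 1e-9)
  # overlapping occurrences both counted
  mp2 <- motif_profile(c(x = "ATAGATAGA"), motif = "ATAGA")
  expect_equal(mp2$per_intron$n_occurrences, 2L)
  expect_equal(sum(mp2$histogram), 2L)
  # absent motif with background: Haldane-corrected OR, p = 1
  mp3 <- motif_profile(c(a = "CCCCCCCC", b = "GGGGGGGG"), motif = "ATAGA",
                       background_seqs = c("CCCCCCCC", "GGGGGGGG"))
  expect_equal(mp3$fisher_p, 1)
  expect_true(is.finite(mp3$odds_ratio))
})

test_that("a 3'-planted motif is recovered as last-quintile clustering with enrichment", {
  set.seed(23)
  plant <- function(n, len) vapply(seq_len(n), function(i) {
    s <- random_dna(len)
    at <- sample(seq(round(0.82 * len), len - 5), 1)
    paste0(substr(s, 1, at - 1), "ATAGA", substr(s, at + 5, len))
  }, "")
  fg <- plant(100, 300)
  bg <- vapply(1:100, function(i) random_dna(300), "")
  mp <- motif_profile(fg, "ATAGA", bg)
  h <- mp$histogram
  expect_gt(h[5], 3 * max(h[1:4]))
  expect_lt(mp$fisher_p, 0.01)
  expect_gt(mp$odds_ratio, 1)
})

test_that("the combined feature table is consistent with its parts", {
  sl <- small_locus()
  ft <- intron_features(sl$locus$introns, sl$locus$models, sl$locus$genome)
  expect_equal(nrow(ft), nrow(sl$locus$introns))
  expect_equal(ft$intron_length, sl$locus$introns$end - sl$locus$introns$start)
  expect_true(all(ft$relative_position >= 0 & ft$relative_position <= 100))
  # stop-frame flags agree with the independent all-positions scanner
  for (i in seq_len(nrow(ft))) {
    s <- get_seq(sl$locus$genome, sl$locus$introns$chrom[i],
                 sl$locus$introns$start[i], sl$locus$introns$end[i],
                 sl$locus$introns$strand[i])
    expect_identical(ft$all_frames_stopped[i],
                     length(brute_stop_frames(s)) == 3L)
  }
})
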