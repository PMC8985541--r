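# Characterization of retained introns: position within the pre-mRNA,
# splice-site strength (position log-odds with donor 3+6 / acceptor 20+3
# window geometry), stop-codon reading frames, and positional profiling of
# a user-given motif.

#' Relative position of an intron within its pre-mRNA
#'
#' 100 x (distance from the transcription start to the intron midpoint) /
#' pre-mRNA length, measured 5' to 3' on the sense strand; for minus-strand
#' genes the distance is taken from the genomic end of the gene span.
#'
#' @param introns An `intron_records` data.frame.
#' @param models The `gene_models` the introns derive from.
#' @return Numeric vector of percents in `[0, 100]`, one per intron.
#' @export
relative_position <- function(introns, models) {
  vapply(seq_len(nrow(introns)), function(i) {
    g <- models[[introns$gene_id[i]]]
    if (is.null(g)) stopf("unknown gene: %s", introns$gene_id[i])
    if (introns$start[i] < g$tx_start || introns$end[i] > g$tx_end)
      stopf("intron %s outside gene span", introns$intron_id[i])
    mid <- (introns$start[i] + introns$end[i]) / 2
    len <- g$tx_end - g$tx_start
    d <- if (g$strand == "-") g$tx_end - mid else mid - g$tx_start
    100 * d / len
  }, 0)
}

#' Train a splice-site strength model
#'
#' Builds position-specific log2-odds matrices (true-site base frequencies
#' with a pseudocount against a background composition) for the donor
#' (9-mer: 3 exonic + 6 intronic nt) and acceptor (23-mer: 20 intronic +
#' 3 exonic nt) windows. The score of a window is the sum of per-position
#' log-odds, in bits; a window matching the training consensus scores
#' maximally and random background-composition sequence scores near zero
#' in expectation. Externally computed scores (e.g. maximum-entropy scores
#' from a published table) can be substituted downstream since scoring is
#' a plain per-window lookup.
#'
#' @param donor_sites,acceptor_sites Character vectors of true-site window
#'   sequences (9 nt and 23 nt respectively), at least 50 each.
#' @param background Either a named base-composition vector
#'   (`c(A=,C=,G=,T=)`) or a character vector of background sequences from
#'   which the composition is estimated.
#' @param pseudocount Per-base pseudocount (default 0.5).
#' @return Object of class `splice_site_model` with `donor` and `acceptor`
#'   log2-odds matrices (4 x window width).
#' @export
train_splice_model <- function(donor_sites, acceptor_sites, background,
                               pseudocount = 0.5) {
  comp <- background_composition(background)
  structure(list(donor = pwm_logodds(donor_sites, 9L, comp, pseudocount),
                 acceptor = pwm_logodds(acceptor_sites, 23L, comp, pseudocount),
                 background = comp),
            class = "splice_site_model")
}

background_composition <- function(background) {
  bases <- c("A", "C", "G", "T")
  if (is.numeric(background)) {
    if (!all(bases %in% names(background)))
      stopf("background composition must name A, C, G, T")
    p <- background[bases]
  } else {
    cnt <- colSums(Biostrings::letterFrequency(
      Biostrings::DNAStringSet(background), bases))
    p <- cnt
  }
  p / sum(p)
}

pwm_logodds <- function(sites, width, comp, pseudocount) {
  if (length(sites) < 50L)
    stopf("need >=50 training sites, got %d", length(sites))
  if (!all(nchar(sites) == width))
    stopf("training sites must all be %d nt", width)
  m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sites))
  bases <- c("A", "C", "G", "T")
  cm <- matrix(0, 4L, width, dimnames = list(bases, NULL))
  for (b in intersect(rownames(m), bases)) cm[b, ] <- m[b, ]
  freq <- sweep(cm + pseudocount, 2L, colSums(cm + pseudocount), "/")
  log2(freq / comp[bases])
}

score_window <- function(seq, mat) {
  b <- strsplit(seq, "")[[1L]]
  if (length(b) != ncol(mat)) stopf("window length %d, expected %d",
                                    length(b), ncol(mat))
  ri <- match(b, rownames(mat))
  if (anyNA(ri)) return(NA_real_)
  sum(mat[cbind(ri, seq_along(b))])
}

#' Score donor and acceptor splice sites of introns
#'
#' Extracts the strand-aware donor (3 exonic + 6 intronic nt) and acceptor
#' (20 intronic + 3 exonic nt) windows from the genome and scores them
#' under a trained [train_splice_model()]. Windows containing N (or
#' running off the chromosome) yield NA and are flagged.
#'
#' @param introns An `intron_records` data.frame.
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param model A `splice_site_model`.
#' @return Data.frame with `intron_id`, `donor_score`, `acceptor_score`
#'   (log2-odds bits), `donor_seq`, `acceptor_seq`, `flagged` (TRUE when a
#'   score is undefined).
#' @export
score_splice_sites <- function(introns, genome, model) {
  stopifnot(inherits(model, "splice_site_model"))
  n <- nrow(introns)
  ds <- as_ <- rep(NA_real_, n)
  dseq <- aseq <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    w <- splice_windows(introns[i, ], genome)
    dseq[i] <- w$donor; aseq[i] <- w$acceptor
    if (!is.na(w$donor)) ds[i] <- score_window(w$donor, model$donor)
    if (!is.na(w$acceptor)) as_[i] <- score_window(w$acceptor, model$acceptor)
  }
  data.frame(intron_id = introns$intron_id, donor_score = ds,
             acceptor_score = as_, donor_seq = dseq, acceptor_seq = aseq,
             flagged = is.na(ds) | is.na(as_))
}

# Strand-aware window extraction in sense orientation.
splice_windows <- function(intr, genome) {
  L <- length(genome[[intr$chrom]])
  grab <- function(s, e) {
    if (s < 0L || e > L) return(NA_character_)
    get_seq(genome, intr$chrom, s, e, intr$strand)
  }
  if (intr$strand == "+") {
    list(donor = grab(intr$start - 3L, intr$start + 6L),
         acceptor = grab(intr$end - 20L, intr$end + 3L))
  } else {
    list(donor = grab(intr$end - 6L, intr$end + 3L),
         acceptor = grab(intr$start - 3L, intr$start + 20L))
  }
}

#' Reading frames containing a stop codon
#'
#' Frame `f` (0, 1, 2, offsets from the intron's first sense-strand base)
#' is reported when any of TAA/TAG/TGA occurs at a position congruent to
#' `f` mod 3. Retained introns with stops in all three frames cannot
#' extend an open reading frame whatever the upstream phase.
#'
#' @param intron_seq Sense-strand nucleotide string over `{A,C,G,T,N}`.
#' @return Integer vector, a subset of `c(0, 1, 2)`.
#' @export
stop_codon_frames <- function(intron_seq) {
  if (grepl("[^ACGTN]", intron_seq))
    stopf("sequence contains characters outside {A,C,G,T,N}")
  hits <- gregexpr("(?=(TAA|TAG|TGA))", intron_seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  sort(unique((hits - 1L) %% 3L))
}

#' Positional motif profile across introns
#'
#' Exact sense-strand substring search (overlapping occurrences counted).
#' Occurrence positions are expressed as percent of intron length
#' (0-based start / length x 100) and binned into a histogram; presence/
#' absence against a background intron set gives a Haldane-corrected odds
#' ratio with a Fisher exact p-value.
#'
#' @param intron_seqs Named character vector of intron sequences (the
#'   foreground set, e.g. regulated retained introns).
#' @param motif Motif string (default `"ATAGA"`).
#' @param background_seqs Background intron sequences for the enrichment
#'   test (optional).
#' @param n_bins Number of positional bins (default 5, i.e. quintiles of
#'   intron length).
#' @return Object of class `motif_profile`: `motif`, `per_intron`
#'   (data.frame `intron_id`, `n_occurrences`), `positions_percent`,
#'   `histogram` (counts per bin; sums to total occurrences),
#'   `n_excluded` (introns shorter than the motif), and, with a
#'   background, `odds_ratio` (Haldane-corrected) and `fisher_p`.
#' @export
motif_profile <- function(intron_seqs, motif = "ATAGA",
                          background_seqs = NULL, n_bins = 5L) {
  if (is.null(names(intron_seqs)))
    names(intron_seqs) <- paste0("intron", seq_along(intron_seqs))
  usable <- nchar(intron_seqs) >= nchar(motif)
  n_excluded <- sum(!usable)
  seqs <- intron_seqs[usable]
  occ <- lapply(seqs, function(s) {
    h <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1L]]
    if (h[1L] == -1L) integer(0) else as.integer(h) - 1L
  })
  pos_pct <- unlist(Map(function(p, s) 100 * p / nchar(s), occ, seqs),
                    use.names = FALSE) %||% numeric(0)
  breaks <- seq(0, 100, length.out = n_bins + 1L)
  hist_counts <- if (length(pos_pct))
    table(cut(pos_pct, breaks, include.lowest = TRUE, right = FALSE,
              labels = sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1L])))
  else stats::setNames(rep(0L, n_bins),
                       sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1L]))
  res <- list(motif = motif,
              per_intron = data.frame(intron_id = names(seqs),
                                      n_occurrences = lengths(occ)),
              positions_percent = pos_pct,
              histogram = as.integer(hist_counts),
              bin_labels = names(hist_counts),
              n_excluded = n_excluded,
              odds_ratio = NA_real_, fisher_p = NA_real_)
  if (!is.null(background_seqs)) {
    bg_ok <- background_seqs[nchar(background_seqs) >= nchar(motif)]
    fg_pres <- sum(lengths(occ) > 0L)
    bg_pres <- sum(vapply(bg_ok, function(s)
      grepl(motif, s, fixed = TRUE), logical(1)))
    tab <- matrix(c(fg_pres, length(seqs) - fg_pres,
                    bg_pres, length(bg_ok) - bg_pres), 2L)
    res$odds_ratio <- (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
      ((tab[2, 1] + 0.5) * (tab[1, 2] + 0.5))
    res$fisher_p <- stats::fisher.test(tab)$p.value
  }
  structure(res, class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("motif_profile '%s': %d occurrences in %d introns",
              x$motif, sum(x$per_intron$n_occurrences),
              nrow(x$per_intron)))
  if (!is.na(x$odds_ratio))
    cat(sprintf("; enrichment OR %.2f (Fisher p %.3g)", x$odds_ratio,
                x$fisher_p))
  cat("\n")
  invisible(x)
}

#' Full feature table for a set of introns
#'
#' Convenience wrapper combining [relative_position()], intron and
#' flanking-exon lengths, [score_splice_sites()] and [stop_codon_frames()].
#'
#' @param introns An `intron_records` data.frame.
#' @param models The corresponding `gene_models`.
#' @param genome A `DNAStringSet`.
#' @param splice_model Optional `splice_site_model`; scores are NA without
#'   one.
#' @return Data.frame of class `intron_features` with one row per intron.
#' @export
intron_features <- function(introns, models, genome, splice_model = NULL) {
  seqs <- vapply(seq_len(nrow(introns)), function(i)
    get_seq(genome, introns$chrom[i], introns$start[i], introns$end[i],
            introns$strand[i]), "")
  frames <- lapply(seqs, stop_codon_frames)
  out <- data.frame(
    intron_id = introns$intron_id,
    gene_id = introns$gene_id,
    relative_position = relative_position(introns, models),
    intron_length = introns$end - introns$start,
    flank_up = introns$flank_up, flank_down = introns$flank_down,
    frames_with_stop = vapply(frames, paste, "", collapse = ","),
    all_frames_stopped = lengths(frames) == 3L,
    donor_score = NA_real_, acceptor_score = NA_real_)
  if (!is.null(splice_model)) {
    sc <- score_splice_sites(introns, genome, splice_model)
    out$donor_score <- sc$donor_score
    out$acceptor_score <- sc$acceptor_score
  }
  class(out) <- c("intron_features", "data.frame")
  out
}
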