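# Synthetic-data generator: seeded genome + gene models + truth tables.
# The generator emits already-aligned SAM (CIGARs constructed from the
# known molecule structure), so it exercises the counting and
# classification logic without an aligner dependency.

#' Configuration for the synthetic study
#'
#' Defaults emulate the study design the pipeline targets: four
#' experimental conditions (rostral/caudal x naive/injured), at least
#' three biological replicates each, 150 nt strand-specific short reads
#' with 98% strandedness fidelity, polyadenylated long reads with
#' per-molecule intron retention, and a targeted editing amplicon with
#' five clustered A-to-I sites plus an alternative 5' splice site.
#'
#' @param seed Integer master seed (mandatory); every downstream draw is
#'   derived from it, so an identical config yields byte-identical output.
#' @param n_genes Number of multi-exon genes (default 20).
#' @param exons_per_gene Range of exon counts per gene (default 3-6).
#' @param exon_length,intron_length Length ranges in nt.
#' @param conditions Condition labels (default `c("AN","AI","BN","BI")`).
#' @param replicates Replicates per condition (default 3).
#' @param read_length Short-read length in nt (default 150).
#' @param reads_per_gene Short reads per gene per replicate (default 300).
#' @param long_read_depth Long reads per gene per condition (default 20).
#' @param strandedness Probability a short read is emitted on the expected
#'   strand (default 0.98).
#' @param error_rate Short-read substitution error rate (default 0.001).
#' @param rho_background,rho_retained True retention fractions for
#'   non-retained and retained introns (defaults 0.02 and 0.5).
#' @param frac_retained_all Fraction of introns retained in every
#'   condition (default 0.2).
#' @param frac_condition_specific Fraction retained in a random proper
#'   subset of conditions (default 0.2); the rest are background.
#' @param frac_annotated_retained Fraction of introns additionally
#'   annotated as retained by a second transcript with a merged exon
#'   (default 0.1); calls on the remainder are "novel".
#' @param intergenic_spacer Minimum intergenic distance in nt
#'   (default 3000, leaving room for background-region sampling).
#' @param splice_consensus_strength Per-position probability of the
#'   consensus base in planted donor/acceptor windows (default 0.85;
#'   the GT/AG dinucleotides are always exact).
#' @param lr_truncation_prob Probability a long read is 5'-truncated
#'   (nanopore reads are 3'-anchored; default 0.15).
#' @param lr_jitter Max nt of block-boundary jitter emulating long-read
#'   indel noise (default 2).
#' @param editing_haplotypes Named probabilities of per-molecule edited
#'   site combinations (names over the site labels; `""` = unedited).
#' @param skipping_fraction True alternative-5'-splice-site (exon
#'   skipping) fraction (default 0.25).
#' @param n_editing_reads Amplicon reads per condition (default 1000).
#' @param de_frac,de_fold Fraction of genes differentially expressed in
#'   the injured conditions and their fold change (defaults 0 and 3).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_genes = 20L,
                             exons_per_gene = c(3L, 6L),
                             exon_length = c(80L, 200L),
                             intron_length = c(60L, 300L),
                             conditions = c("AN", "AI", "BN", "BI"),
                             replicates = 3L,
                             read_length = 150L,
                             reads_per_gene = 300L,
                             long_read_depth = 20L,
                             strandedness = 0.98,
                             error_rate = 0.001,
                             rho_background = 0.02,
                             rho_retained = 0.5,
                             frac_retained_all = 0.2,
                             frac_condition_specific = 0.2,
                             frac_annotated_retained = 0.1,
                             intergenic_spacer = 3000L,
                             splice_consensus_strength = 0.85,
                             lr_truncation_prob = 0.15,
                             lr_jitter = 2L,
                             editing_haplotypes = c("ABD" = 0.35, "AB" = 0.25,
                                                    "ABCD" = 0.20, " " = 0.20),
                             skipping_fraction = 0.25,
                             n_editing_reads = 1000L) {
  if (missing(seed)) stopf("seed is mandatory")
  names(editing_haplotypes)[names(editing_haplotypes) == " "] <- ""
  if (abs(sum(editing_haplotypes) - 1) > 1e-8)
    stopf("editing_haplotypes must sum to 1")
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              exons_per_gene = exons_per_gene, exon_length = exon_length,
              intron_length = intron_length, conditions = conditions,
              replicates = replicates, read_length = read_length,
              reads_per_gene = reads_per_gene,
              long_read_depth = long_read_depth,
              strandedness = strandedness, error_rate = error_rate,
              rho_background = rho_background, rho_retained = rho_retained,
              frac_retained_all = frac_retained_all,
              frac_condition_specific = frac_condition_specific,
              frac_annotated_retained = frac_annotated_retained,
              intergenic_spacer = intergenic_spacer,
              splice_consensus_strength = splice_consensus_strength,
              lr_truncation_prob = lr_truncation_prob,
              lr_jitter = lr_jitter,
              editing_haplotypes = editing_haplotypes,
              skipping_fraction = skipping_fraction,
              n_editing_reads = n_editing_reads,
              de_frac = 0, de_fold = 3)
  stopifnot(all(unlist(cfg[c("rho_background", "rho_retained")]) >= 0),
            all(unlist(cfg[c("rho_background", "rho_retained")]) <= 1))
  class(cfg) <- "synthetic_config"
  cfg
}

# Deterministic stream of sub-seeds, one per (purpose, condition,
# replicate) slot, all < 2^31.
sub_seed <- function(cfg, purpose, cond = NULL, rep = 1L) {
  purposes <- c("locus", "short", "long", "edit")
  ci <- if (is.null(cond)) 0L else match(cond, cfg$conditions)
  idx <- (match(purpose, purposes) - 1L) * 512L + ci * 32L + rep
  child_seeds(cfg$seed, 2048L)[idx]
}

# sample n integers uniformly from [lo, hi] (robust to lo == hi, unlike
# sample(lo:hi, ...))
sample_range <- function(range, n) {
  x <- range[1L]:range[2L]
  x[sample.int(length(x), n, replace = TRUE)]
}

DONOR_CONSENSUS <- "CAGGTAAGT"              # 3 exonic + 6 intronic
ACCEPTOR_CONSENSUS <- "TTTTTTTTTTTTTCTTTCAGGTT" # 20 intronic + 3 exonic

#' Generate a synthetic locus set
#'
#' Builds a random genome with non-overlapping multi-exon genes separated
#' by intergenic spacers (room for background-region sampling), plants
#' consensus-biased donor/acceptor windows (all introns begin GT and end
#' AG on the sense strand), adds a dedicated editing amplicon locus, and
#' fixes the ground truth: per-intron per-condition retention fractions,
#' expected retained calls and switches, per-gene expression multipliers,
#' and the editing haplotype distribution.
#'
#' @param cfg A [synthetic_config()].
#' @return Object of class `locus_set`: `genome` (DNAStringSet), `models`
#'   (`gene_models`), `introns` (`intron_records`), `truth` (list:
#'   `introns` with `rho` matrix and expected calls, `genes`,
#'   `editing`), and `editing_locus` (site table and junction
#'   coordinates).
#' @export
make_locus_set <- function(cfg) {
  set.seed(sub_seed(cfg, "locus"))
  n <- cfg$n_genes
  n_ex <- sample_range(cfg$exons_per_gene, n)
  strands <- sample(c("+", "-"), n, TRUE)
  gene_parts <- vector("list", n)
  pos <- cfg$intergenic_spacer
  for (i in seq_len(n)) {
    ex_len <- sample_range(cfg$exon_length, n_ex[i])
    in_len <- sample_range(cfg$intron_length, n_ex[i] - 1L)
    starts <- pos + c(0L, cumsum(ex_len[-n_ex[i]] + in_len))
    exons <- data.frame(start = starts, end = starts + ex_len)
    gene_parts[[i]] <- list(gene_id = sprintf("gene%03d", i),
                            strand = strands[i], exons = exons)
    pos <- max(exons$end) + cfg$intergenic_spacer
  }
  glen <- pos + cfg$intergenic_spacer
  if (glen > 5e7) stopf("requested genes do not fit a tractable genome; reduce n_genes")
  chars <- sample(c("A", "C", "G", "T"), glen, TRUE)

  # plant splice-site windows (sense orientation; GT/AG exact)
  for (g in gene_parts) {
    e <- g$exons
    for (j in seq_len(nrow(e) - 1L)) {
      s <- e$end[j]; t <- e$start[j + 1L]
      chars <- plant_window(chars, DONOR_CONSENSUS, cfg$splice_consensus_strength,
                            fixed = 4:5, start0 = if (g$strand == "+") s - 3L else t - 6L,
                            strand = g$strand)
      chars <- plant_window(chars, ACCEPTOR_CONSENSUS, cfg$splice_consensus_strength,
                            fixed = 19:20, start0 = if (g$strand == "+") t - 20L else s - 3L,
                            strand = g$strand)
    }
  }

  # annotation: transcript 1 = all exons; a fraction of introns get a
  # second transcript with the flanking exons merged (annotated retention)
  exon_rows <- list()
  for (g in gene_parts) {
    e <- g$exons
    exon_rows[[length(exon_rows) + 1L]] <-
      data.frame(chrom = "chr1", start = e$start, end = e$end,
                 strand = g$strand, gene_id = g$gene_id,
                 transcript_id = paste0(g$gene_id, ".t1"))
  }
  n_intr_per_gene <- n_ex - 1L
  all_intr <- data.frame(gene = rep(seq_len(n), n_intr_per_gene),
                         j = unlist(lapply(n_intr_per_gene, seq_len)))
  ann_ret <- stats::runif(nrow(all_intr)) < cfg$frac_annotated_retained
  for (k in which(ann_ret)) {
    g <- gene_parts[[all_intr$gene[k]]]
    e <- g$exons
    j <- all_intr$j[k]
    me <- e
    me$end[j] <- me$end[j + 1L]
    me <- me[-(j + 1L), , drop = FALSE]
    exon_rows[[length(exon_rows) + 1L]] <-
      data.frame(chrom = "chr1", start = me$start, end = me$end,
                 strand = g$strand, gene_id = g$gene_id,
                 transcript_id = sprintf("%s.tr%d", g$gene_id, j))
  }
  exon_df <- do.call(rbind, exon_rows)
  models <- lapply(split(exon_df, exon_df$gene_id), build_gene_model)
  ord <- order(vapply(models, `[[`, "", "chrom"),
               vapply(models, `[[`, 0, "tx_start"),
               vapply(models, `[[`, "", "gene_id"))
  models <- structure(models[ord], class = "gene_models")
  names(models) <- vapply(models, `[[`, "", "gene_id")

  # editing amplicon on its own sequence
  amp <- make_editing_locus(cfg)
  chars_amp <- amp$chars

  genome <- Biostrings::DNAStringSet(c(chr1 = paste(chars, collapse = ""),
                                       chrAmp = paste(chars_amp, collapse = "")))
  introns <- derive_introns(models)

  # truth: per-intron class and per-condition retention fraction
  nc <- length(cfg$conditions)
  ni <- nrow(introns)
  cls <- sample(c("retained_all", "condition_specific", "background"), ni, TRUE,
                prob = c(cfg$frac_retained_all, cfg$frac_condition_specific,
                         1 - cfg$frac_retained_all - cfg$frac_condition_specific))
  rho <- matrix(cfg$rho_background, ni, nc,
                dimnames = list(introns$intron_id, cfg$conditions))
  rho[cls == "retained_all", ] <- cfg$rho_retained
  for (i in which(cls == "condition_specific")) {
    k <- sample(seq_len(nc - 1L), 1L)
    rho[i, sample(nc, k)] <- cfg$rho_retained
  }
  expected_retained <- 100 * rho > 25

  genes_truth <- data.frame(gene_id = names(models),
                            expr_multiplier = exp(stats::rnorm(n, 0, 0.4)),
                            de_fold = 1)
  if (cfg$de_frac > 0) {
    de <- stats::runif(n) < cfg$de_frac
    genes_truth$de_fold[de] <- cfg$de_fold
  }

  truth <- list(
    introns = list(class = stats::setNames(cls, introns$intron_id),
                   rho = rho, expected_retained = expected_retained),
    genes = genes_truth,
    editing = list(haplotypes = cfg$editing_haplotypes,
                   site_fractions = editing_marginals(cfg$editing_haplotypes,
                                                     amp$sites$label),
                   skipping_fraction = cfg$skipping_fraction))
  structure(list(genome = genome, models = models, introns = introns,
                 truth = truth,
                 editing_locus = amp[c("sites", "exons", "inclusion_junctions",
                                       "skipping_junction", "read_span")],
                 cfg = cfg),
            class = "locus_set")
}

# Marginal per-site editing fraction implied by a haplotype distribution.
editing_marginals <- function(hap, labels) {
  vapply(labels, function(l)
    sum(hap[grepl(l, names(hap), fixed = TRUE)]), 0)
}

# Write a consensus-biased window into the genome character vector.
# start0 is 0-based; the window string is in sense orientation and is
# reverse-complemented for minus-strand genes. `fixed` positions (sense,
# 1-based) are planted exactly (the GT / AG dinucleotides).
plant_window <- function(chars, window, strength, fixed, start0, strand) {
  w <- strsplit(window, "")[[1L]]
  b <- ifelse(stats::runif(length(w)) < strength, w,
              sample(c("A", "C", "G", "T"), length(w), TRUE))
  b[fixed] <- w[fixed]
  if (strand == "-") b <- rev(c(A = "T", C = "G", G = "C", T = "A")[b])
  chars[(start0 + 1L):(start0 + length(b))] <- b
  chars
}

# The editing amplicon: exon IV - intron - exon Vb (with 5 A sites) -
# intron - exon VI; proximal splice sites include Vb, the distal site
# skips it.
make_editing_locus <- function(cfg) {
  len <- 1200L
  chars <- sample(c("A", "C", "G", "T"), len, TRUE)
  exIV <- c(100L, 250L); intr1 <- c(250L, 400L)
  exVb <- c(400L, 495L); intr2 <- c(495L, 650L)
  exVI <- c(650L, 900L)
  site_pos <- c(A = 420L, B = 425L, C = 432L, D = 437L, E = 444L)
  chars[site_pos + 1L] <- "A"
  for (b in list(intr1, intr2)) {
    chars[(b[1L] + 1L):(b[1L] + 2L)] <- c("G", "T")
    chars[(b[2L] - 1L):b[2L]] <- c("A", "G")
  }
  sites <- editing_sites("chrAmp", site_pos, "+", names(site_pos))
  # the alternative 5' splice-site decision shares the donor at the end of
  # exon IV: the proximal acceptor includes Vb, the distal one skips it;
  # only the shared-donor junction is diagnostic of inclusion
  list(chars = chars, sites = sites,
       exons = list(exIV = exIV, exVb = exVb, exVI = exVI),
       inclusion_junctions = list(intr1),
       skipping_junction = c(intr1[1L], intr2[2L]),
       read_span = c(150L, 750L))
}

#' Write the locus set to FASTA and GTF
#'
#' @param locus A `locus_set`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_locus_set <- function(locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "models.gtf")
  Biostrings::writeXStringSet(locus$genome, fa)
  write_gene_models(locus$models, gtf)
  truth_tsv <- file.path(dir, "truth_introns.tsv")
  tr <- data.frame(intron_id = rownames(locus$truth$introns$rho),
                   class = unname(locus$truth$introns$class),
                   locus$truth$introns$rho, check.names = FALSE)
  write_tsv6(tr, truth_tsv)
  c(fasta = fa, gtf = gtf, truth = truth_tsv)
}
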