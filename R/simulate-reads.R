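# Read simulators. Reads are emitted as already-aligned SAM text with
# CIGARs constructed from the known molecule structure; the truth tables
# of the locus set define every probability.

sam_header <- function(genome) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome)))
}

# Map a molecule interval [t0, t1) (molecule coordinates, genomic
# ascending) onto genomic blocks given the molecule's block table
# (genomic start/end per block, ascending). Returns list(pos, cigar_blocks).
molecule_to_blocks <- function(blocks, t0, t1) {
  mol_len <- cumsum(blocks$end - blocks$start)
  mol_off <- c(0L, mol_len[-length(mol_len)])
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(blocks))) {
    bs <- max(t0, mol_off[i]); be <- min(t1, mol_len[i])
    if (bs < be) {
      out_s <- c(out_s, blocks$start[i] + (bs - mol_off[i]))
      out_e <- c(out_e, blocks$start[i] + (be - mol_off[i]))
    }
  }
  list(start = out_s, end = out_e)
}

cigar_from_blocks <- function(bs, be) {
  bs <- as.integer(bs); be <- as.integer(be)
  m <- be - bs
  if (length(m) == 1L) return(sprintf("%dM", m))
  gaps <- bs[-1L] - be[-length(be)]
  paste0(paste0(m[-length(m)], "M", gaps, "N", collapse = ""),
         m[length(m)], "M")
}

# Molecule block table for a gene given a retention indicator per intron
# (introns in genomic order).
molecule_blocks <- function(exons, retained) {
  if (length(retained) == 0L || !any(retained))
    return(data.frame(start = exons$start, end = exons$end))
  s <- exons$start[1L]; out <- NULL; cur_s <- s; cur_e <- exons$end[1L]
  for (j in seq_len(length(retained))) {
    if (retained[j]) {
      cur_e <- exons$end[j + 1L]
    } else {
      out <- rbind(out, c(cur_s, cur_e))
      cur_s <- exons$start[j + 1L]; cur_e <- exons$end[j + 1L]
    }
  }
  out <- rbind(out, c(cur_s, cur_e))
  data.frame(start = out[, 1L], end = out[, 2L])
}

seq_with_errors <- function(chars, bs, be, error_rate) {
  s <- unlist(lapply(seq_along(bs), function(i) chars[(bs[i] + 1L):be[i]]))
  if (error_rate > 0) {
    err <- which(stats::runif(length(s)) < error_rate)
    if (length(err))
      s[err] <- sample(c("A", "C", "G", "T"), length(err), TRUE)
  }
  paste(s, collapse = "")
}

#' Simulate strand-specific spliced short reads for one sample
#'
#' Per gene, each read derives from an independent pre-mRNA molecule in
#' which every intron is retained independently with its true per-condition
#' probability; reads are sampled uniformly along the molecule. CIGARs
#' carry N-gaps exactly at spliced introns. The read strand matches the
#' gene strand with probability `strandedness` (flipped otherwise), and
#' substitution errors are applied at `error_rate`.
#'
#' @param cfg A [synthetic_config()].
#' @param locus A `locus_set` from [make_locus_set()].
#' @param condition Condition label (must be in `cfg$conditions`).
#' @param replicate Replicate number.
#' @param path Output SAM path.
#' @return The path, invisibly; attribute `n_skipped` counts molecules
#'   shorter than the read length.
#' @export
simulate_short_reads <- function(cfg, locus, condition, replicate, path) {
  set.seed(sub_seed(cfg, "short", condition, replicate))
  chars <- strsplit(as.character(locus$genome[["chr1"]]), "")[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sam_header(locus$genome), con)
  rho <- locus$truth$introns$rho[, condition]
  mult <- locus$truth$genes$expr_multiplier *
    ifelse(grepl("I$", condition), locus$truth$genes$de_fold, 1)
  n_skipped <- 0L
  rl <- cfg$read_length
  read_no <- 0L
  for (gi in seq_along(locus$models)) {
    g <- locus$models[[gi]]
    intr <- locus$introns[locus$introns$gene_id == g$gene_id, , drop = FALSE]
    intr <- intr[order(intr$start), , drop = FALSE]
    exons <- g$exons[g$transcripts[[paste0(g$gene_id, ".t1")]], , drop = FALSE]
    rho_g <- rho[intr$intron_id]
    n_reads <- round(cfg$reads_per_gene * mult[gi])
    if (n_reads == 0L) next
    # reads are drawn from the (molecule, start) pool: molecule patterns
    # are sampled proportional to their eligible start positions
    # (fragment yield scales with molecule length), starts uniformly
    max_len <- sum(exons$end - exons$start) +
      sum(intr$end - intr$start)
    if (sum(exons$end - exons$start) < rl) { n_skipped <- n_skipped + n_reads; next }
    lines <- character(n_reads)
    nl <- 0L
    for (r in seq_len(n_reads)) {
      repeat {
        retained <- stats::runif(length(rho_g)) < rho_g
        blocks <- molecule_blocks(exons, retained)
        mol_len <- sum(blocks$end - blocks$start)
        if (mol_len < rl) { n_skipped <- n_skipped + 1L; next }
        if (stats::runif(1L) <= (mol_len - rl + 1) / (max_len - rl + 1)) break
      }
      t0 <- floor(stats::runif(1L) * (mol_len - rl + 1L))
      bl <- molecule_to_blocks(blocks, t0, t0 + rl)
      flag <- if (stats::runif(1L) < cfg$strandedness) {
        if (g$strand == "-") 16L else 0L
      } else {
        if (g$strand == "-") 0L else 16L
      }
      read_no <- read_no + 1L
      nl <- nl + 1L
      lines[nl] <- paste(
        sprintf("%s_%d_r%07d", condition, replicate, read_no), flag, "chr1",
        as.integer(bl$start[1L] + 1L), 60L, cigar_from_blocks(bl$start, bl$end),
        "*", 0L, 0L, seq_with_errors(chars, bl$start, bl$end, cfg$error_rate),
        strrep("I", rl), sep = "\t")
    }
    if (nl > 0L) writeLines(lines[seq_len(nl)], con)
  }
  structure(invisible(path), n_skipped = n_skipped)
}

#' Simulate polyadenylated long reads for one condition
#'
#' Full-length molecules with per-molecule intron retention drawn from the
#' condition's true fractions; a configurable fraction of reads is
#' 5'-truncated at a uniform point (3'-anchored sequencing of
#' polyadenylated RNA), and block boundaries are jittered by up to
#' `lr_jitter` nt to emulate indel noise near splice junctions.
#'
#' @inheritParams simulate_short_reads
#' @return The path, invisibly.
#' @export
simulate_long_reads <- function(cfg, locus, condition, path) {
  set.seed(sub_seed(cfg, "long", condition))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sam_header(locus$genome), con)
  rho <- locus$truth$introns$rho[, condition]
  read_no <- 0L
  for (g in locus$models) {
    intr <- locus$introns[locus$introns$gene_id == g$gene_id, , drop = FALSE]
    intr <- intr[order(intr$start), , drop = FALSE]
    exons <- g$exons[g$transcripts[[paste0(g$gene_id, ".t1")]], , drop = FALSE]
    rho_g <- rho[intr$intron_id]
    lines <- character(cfg$long_read_depth)
    nl <- 0L
    for (r in seq_len(cfg$long_read_depth)) {
      retained <- stats::runif(length(rho_g)) < rho_g
      blocks <- molecule_blocks(exons, retained)
      mol_len <- sum(blocks$end - blocks$start)
      t0 <- 0L; t1 <- mol_len
      if (stats::runif(1L) < cfg$lr_truncation_prob) {
        cut <- floor(stats::runif(1L) * (mol_len - 50L))
        # 3'-anchored: truncation removes the transcript 5' end
        if (g$strand == "+") t0 <- cut else t1 <- mol_len - cut
      }
      bl <- molecule_to_blocks(blocks, t0, t1)
      bs <- bl$start; be <- bl$end
      if (cfg$lr_jitter > 0L && length(bs) > 1L) {
        k <- length(bs)
        be[-k] <- be[-k] + sample(-cfg$lr_jitter:cfg$lr_jitter, k - 1L, TRUE)
        bs[-1L] <- bs[-1L] + sample(-cfg$lr_jitter:cfg$lr_jitter, k - 1L, TRUE)
        bad <- be - bs < 10L | c(FALSE, bs[-1L] <= be[-k])
        if (any(bad)) { bs <- bl$start; be <- bl$end }
      }
      read_no <- read_no + 1L
      nl <- nl + 1L
      lines[nl] <- paste(
        sprintf("lr_%s_%07d", condition, read_no),
        if (g$strand == "-") 16L else 0L, "chr1", as.integer(bs[1L] + 1L), 60L,
        cigar_from_blocks(bs, be), "*", 0L, 0L, "*", "*", sep = "\t")
    }
    writeLines(lines[seq_len(nl)], con)
  }
  invisible(path)
}

#' Simulate edited amplicon reads for one condition
#'
#' Amplicon-like reads over the editing locus: a molecule skips the
#' alternative exon with the configured probability (distal splice site,
#' no site coverage) or includes it (proximal sites) with a per-molecule
#' editing haplotype drawn from the configured distribution; edited sites
#' read G, unedited A.
#'
#' @inheritParams simulate_short_reads
#' @return The path, invisibly.
#' @export
simulate_editing_reads <- function(cfg, locus, condition, path) {
  set.seed(sub_seed(cfg, "edit", condition))
  el <- locus$editing_locus
  chars <- strsplit(as.character(locus$genome[["chrAmp"]]), "")[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sam_header(locus$genome), con)
  span <- el$read_span
  hap <- cfg$editing_haplotypes
  incl_blocks <- data.frame(
    start = c(span[1L], el$exons$exVb[1L], el$exons$exVI[1L]),
    end = c(el$exons$exIV[2L], el$exons$exVb[2L], span[2L]))
  skip_blocks <- data.frame(start = c(span[1L], el$exons$exVI[1L]),
                            end = c(el$exons$exIV[2L], span[2L]))
  lines <- character(cfg$n_editing_reads)
  for (r in seq_len(cfg$n_editing_reads)) {
    skip <- stats::runif(1L) < cfg$skipping_fraction
    blocks <- if (skip) skip_blocks else incl_blocks
    s <- unlist(lapply(seq_len(nrow(blocks)), function(i)
      chars[(blocks$start[i] + 1L):blocks$end[i]]))
    if (!skip) {
      combo <- sample(names(hap), 1L, prob = hap)
      edited <- el$sites$label %in% strsplit(combo, "")[[1L]]
      # offset of each site within the read sequence
      off <- vapply(el$sites$pos, function(p) {
        cum <- 0L
        for (i in seq_len(nrow(blocks))) {
          if (p >= blocks$start[i] && p < blocks$end[i])
            return(cum + (p - blocks$start[i]) + 1L)
          cum <- cum + blocks$end[i] - blocks$start[i]
        }
        NA_integer_
      }, 0L)
      s[off[edited]] <- "G"
    }
    lines[r] <- paste(
      sprintf("amp_%s_%06d", condition, r), 0L, "chrAmp",
      as.integer(blocks$start[1L] + 1L), 60L,
      cigar_from_blocks(blocks$start, blocks$end), "*", 0L, 0L,
      paste(s, collapse = ""), strrep("I", length(s)), sep = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}

#' Simulate the complete synthetic dataset
#'
#' Writes genome FASTA, gene-model GTF, truth TSV, per-replicate
#' short-read SAMs, per-condition long-read and editing SAMs into `dir`.
#' Identical configs yield byte-identical files.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory.
#' @return A list: the `locus_set` and a `files` manifest.
#' @export
simulate_dataset <- function(cfg, dir) {
  locus <- make_locus_set(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- as.list(write_locus_set(locus, dir))
  files$short <- list()
  for (cond in cfg$conditions) {
    for (rep in seq_len(cfg$replicates)) {
      p <- file.path(dir, sprintf("short_%s_rep%d.sam", cond, rep))
      simulate_short_reads(cfg, locus, cond, rep, p)
      files$short[[paste(cond, rep, sep = "_")]] <- p
    }
    p <- file.path(dir, sprintf("long_%s.sam", cond))
    simulate_long_reads(cfg, locus, cond, p)
    files[[paste0("long_", cond)]] <- p
    p <- file.path(dir, sprintf("editing_%s.sam", cond))
    simulate_editing_reads(cfg, locus, cond, p)
    files[[paste0("editing_", cond)]] <- p
  }
  list(locus = locus, files = files)
}
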