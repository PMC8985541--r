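#' Load gene models from a GTF file
#'
#' Reads exon features from a GTF (Ensembl dialect) file and assembles one
#' gene model per `gene_id`. Coordinates are converted from GTF 1-based
#' inclusive to the package-internal 0-based half-open convention. Genes are
#' returned in deterministic order by (chrom, tx_start, gene_id).
#'
#' @param gtf_path Path to a GTF file whose exon features carry `gene_id`
#'   and `transcript_id` attributes.
#' @return An object of class `gene_models`: a named list of gene models,
#'   each a list with fields `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end` (pre-mRNA span), `exons` (data.frame of 0-based half-open
#'   `start`,`end`, sorted, deduplicated across transcripts) and
#'   `transcripts` (named list of integer indices into `exons`).
#' @export
load_gene_models <- function(gtf_path) {
  if (!file.exists(gtf_path)) stopf("GTF file not found: %s", gtf_path)
  validate_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  all_tx <- unique(stats::na.omit(
    data.frame(gene_id = as.character(gr$gene_id),
               transcript_id = as.character(gr$transcript_id))))
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stopf("GTF contains no exon features: %s", gtf_path)
  if (anyNA(ex$gene_id) || anyNA(ex$transcript_id))
    stopf("exon feature lacking gene_id/transcript_id attribute")
  exon_tx <- unique(as.character(ex$transcript_id))
  empty <- setdiff(all_tx$transcript_id, exon_tx)
  if (length(empty) > 0L) {
    g <- all_tx$gene_id[match(empty[1L], all_tx$transcript_id)]
    stopf("transcript '%s' of gene '%s' has zero exons", empty[1L], g)
  }
  df <- cbind(from_gr(ex),
              data.frame(gene_id = as.character(ex$gene_id),
                         transcript_id = as.character(ex$transcript_id)))
  models <- lapply(split(df, df$gene_id), build_gene_model)
  ord <- order(vapply(models, `[[`, "", "chrom"),
               vapply(models, `[[`, 0, "tx_start"),
               vapply(models, `[[`, "", "gene_id"))
  models <- models[ord]
  names(models) <- vapply(models, `[[`, "", "gene_id")
  structure(models, class = "gene_models")
}

# Line-level validation so malformed input is reported with its line number
# (rtracklayer's own errors do not carry one).
validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stopf("GTF parse error at line %d: expected 9 tab-separated fields, got %d",
            i, length(f))
    s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e))
      stopf("GTF parse error at line %d: non-numeric coordinates", i)
    if (e < s)
      stopf("GTF parse error at line %d: end (%d) < start (%d)", i, e, s)
  }
  invisible(TRUE)
}

build_gene_model <- function(df) {
  strand <- unique(df$strand)
  chrom <- unique(df$chrom)
  if (length(strand) != 1L || length(chrom) != 1L)
    stopf("gene '%s' spans multiple chromosomes or strands", df$gene_id[1L])
  exons <- unique(df[order(df$start, df$end), c("start", "end")])
  rownames(exons) <- NULL
  transcripts <- lapply(split(df, df$transcript_id), function(t) {
    t <- t[order(t$start), , drop = FALSE]
    if (any(t$start[-1L] < t$end[-nrow(t)]))
      stopf("overlapping exons within transcript '%s' of gene '%s'",
            t$transcript_id[1L], t$gene_id[1L])
    idx <- match(paste(t$start, t$end), paste(exons$start, exons$end))
    as.integer(idx)
  })
  list(gene_id = df$gene_id[1L], chrom = chrom, strand = strand,
       tx_start = min(exons$start), tx_end = max(exons$end),
       exons = exons, transcripts = transcripts)
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d sequence(s)\n", length(x),
              length(unique(vapply(x, `[[`, "", "chrom")))))
  invisible(x)
}

#' Write gene models back to GTF
#'
#' Inverse of [load_gene_models()]; exon features only, coordinates
#' converted back to 1-based inclusive. Reloading the written file yields
#' identical structures.
#'
#' @param models A `gene_models` object.
#' @param path Output GTF path.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(g) {
    do.call(rbind, lapply(names(g$transcripts), function(tx) {
      e <- g$exons[g$transcripts[[tx]], , drop = FALSE]
      data.frame(chrom = g$chrom, start = e$start, end = e$end,
                 strand = g$strand, gene_id = g$gene_id, transcript_id = tx)
    }))
  })
  df <- do.call(rbind, rows)
  gr <- gr0(df$chrom, df$start, df$end, df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "exon", gene_id = df$gene_id, transcript_id = df$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Derive introns from gene models
#'
#' Introns are the gaps between consecutive exons of each transcript,
#' deduplicated by (start, end) across transcripts of the gene. The ordinal
#' is assigned in transcription order (reversed for minus-strand genes) and
#' the donor position is the 5' splice site on the sense strand. An intron
#' wholly contained in another transcript's exon is flagged
#' `known_retained`: the annotation itself documents a transcript that
#' retains it.
#'
#' @param models A `gene_models` object (or a single gene model).
#' @param min_intron_length Gaps shorter than this (default 30 nt) are
#'   excluded and tallied in the `skipped` attribute of the result.
#' @return A data.frame of class `intron_records` with columns `intron_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end` (0-based half-open),
#'   `donor_pos`, `acceptor_pos`, `ordinal`, `n_introns`, `known_retained`,
#'   `flank_up`, `flank_down` (flanking exon lengths in transcript
#'   orientation). Attribute `skipped` reports sub-minimum gaps.
#' @export
derive_introns <- function(models, min_intron_length = 30L) {
  if (!inherits(models, "gene_models")) models <- structure(list(models),
                                                            class = "gene_models")
  per_gene <- lapply(models, derive_introns_one, min_intron_length)
  out <- do.call(rbind, lapply(per_gene, `[[`, "introns"))
  skipped <- do.call(rbind, lapply(per_gene, `[[`, "skipped"))
  if (is.null(out)) out <- empty_intron_records()
  rownames(out) <- NULL
  structure(out, skipped = skipped, class = c("intron_records", "data.frame"))
}

empty_intron_records <- function() {
  data.frame(intron_id = character(), gene_id = character(),
             chrom = character(), strand = character(),
             start = integer(), end = integer(),
             donor_pos = integer(), acceptor_pos = integer(),
             ordinal = integer(), n_introns = integer(),
             known_retained = logical(),
             flank_up = integer(), flank_down = integer())
}

derive_introns_one <- function(g, min_len) {
  gaps <- list()
  for (idx in g$transcripts) {
    e <- g$exons[idx, , drop = FALSE]
    if (nrow(e) < 2L) next
    for (i in seq_len(nrow(e) - 1L))
      gaps[[length(gaps) + 1L]] <- c(e$end[i], e$start[i + 1L],
                                     e$end[i] - e$start[i],
                                     e$end[i + 1L] - e$start[i + 1L])
  }
  if (length(gaps) == 0L)
    return(list(introns = NULL, skipped = NULL))
  m <- do.call(rbind, gaps)
  colnames(m) <- c("start", "end", "exon_left_len", "exon_right_len")
  m <- m[!duplicated(m[, c("start", "end"), drop = FALSE]), , drop = FALSE]
  m <- m[order(m[, "start"], m[, "end"]), , drop = FALSE]
  short <- (m[, "end"] - m[, "start"]) < min_len
  skipped <- NULL
  if (any(short))
    skipped <- data.frame(gene_id = g$gene_id,
                          start = m[short, "start"], end = m[short, "end"],
                          length = m[short, "end"] - m[short, "start"])
  m <- m[!short, , drop = FALSE]
  if (nrow(m) == 0L) return(list(introns = NULL, skipped = skipped))
  n <- nrow(m)
  ordinal <- if (g$strand == "-") rev(seq_len(n)) else seq_len(n)
  # retained in annotation if any exon of the gene covers the intron entirely
  kr <- vapply(seq_len(n), function(i)
    any(g$exons$start <= m[i, "start"] & g$exons$end >= m[i, "end"]),
    logical(1))
  minus <- g$strand == "-"
  out <- data.frame(
    intron_id = sprintf("%s.I%d", g$gene_id, ordinal),
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    start = as.integer(m[, "start"]), end = as.integer(m[, "end"]),
    donor_pos = as.integer(if (minus) m[, "end"] else m[, "start"]),
    acceptor_pos = as.integer(if (minus) m[, "start"] else m[, "end"]),
    ordinal = as.integer(ordinal), n_introns = n,
    known_retained = kr,
    flank_up = as.integer(if (minus) m[, "exon_right_len"] else m[, "exon_left_len"]),
    flank_down = as.integer(if (minus) m[, "exon_left_len"] else m[, "exon_right_len"]))
  out <- out[order(out$ordinal), , drop = FALSE]
  list(introns = out, skipped = skipped)
}

#' Read a genome FASTA
#'
#' @param fasta_path Path to a (possibly multi-sequence) FASTA file.
#' @return A `DNAStringSet` named by the first token of each header.
#' @export
read_genome <- function(fasta_path) {
  g <- Biostrings::readDNAStringSet(fasta_path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract genomic sequence, strand-aware
#'
#' Returns the sequence of `[start, end)` (0-based half-open) on `chrom`;
#' for `strand = "-"` the reverse complement is returned, so the result
#' always reads 5' to 3' on the requested strand.
#'
#' @param genome A `DNAStringSet` as from [read_genome()].
#' @param chrom,start,end Interval (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @return A character scalar over `{A,C,G,T,N}`.
#' @export
get_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stopf("unknown sequence: %s", chrom)
  L <- length(genome[[chrom]])
  if (start < 0L || end > L || start > end)
    stopf("interval [%d,%d) out of bounds for %s (length %d)", start, end, chrom, L)
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
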