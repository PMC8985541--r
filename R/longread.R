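# Single-molecule long-read validation of retained-intron candidates.
# A molecule retaining an intron must cover both exon/intron boundaries
# without a splice gap; a spliced molecule shows a gap matching the
# annotated boundaries. Classification tolerates nanopore indel noise by
# testing block-union coverage within a slack window instead of exact
# block matching.

#' Classify long reads against introns
#'
#' Per (read, intron) pair where the read overlaps the intron:
#' * **spliced** — some alignment N-gap has both endpoints within `slack`
#'   nt of the annotated intron boundaries;
#' * **retained** — the union of aligned blocks covers both boundary
#'   windows `[boundary - flank, boundary + flank)` without interruption
#'   and covers at least `body_cov_min` of the intron body;
#' * **uninformative** — anything else (e.g. 5'-truncated reads ending
#'   inside the intron).
#'
#' @param aln An `alignments` object of long-read (spliced) alignments.
#' @param introns An `intron_records` data.frame.
#' @param slack Max nt distance between an observed gap endpoint and the
#'   annotated boundary to count as spliced (default 10).
#' @param flank Half-width of the boundary coverage windows for the
#'   retained call (default 10).
#' @param body_cov_min Minimum fraction of the intron body covered by
#'   aligned blocks for the retained call (default 0.8).
#' @return A data.frame of class `long_read_calls`: `read_id`, `intron_id`,
#'   `verdict`, `intron_body_coverage`, `gap_match_slack` (nt distance of
#'   the best-matching gap, NA when no gap is near).
#' @export
classify_long_reads <- function(aln, introns, slack = 10L, flank = 10L,
                                body_cov_min = 0.8) {
  stopifnot(inherits(aln, "alignments"))
  gal <- aln$gal
  qname <- S4Vectors::mcols(gal)$qname
  intron_gr <- gr0(introns$chrom, introns$start, introns$end)
  span <- GenomicRanges::granges(gal)
  cand <- GenomicRanges::findOverlaps(span, intron_gr, ignore.strand = TRUE,
                                      maxgap = flank)
  if (length(cand) == 0L) return(empty_long_read_calls())
  bl <- GenomicAlignments::grglist(gal)
  jnc <- GenomicAlignments::junctions(gal)
  out <- vector("list", length(cand))
  q <- S4Vectors::queryHits(cand); s <- S4Vectors::subjectHits(cand)
  for (k in seq_along(cand)) {
    i <- s[k]
    out[[k]] <- classify_one_read(
      blocks = IRanges::ranges(bl[[q[k]]]),
      gaps = IRanges::ranges(jnc[[q[k]]]),
      start0 = introns$start[i], end0 = introns$end[i],
      slack = slack, flank = flank, body_cov_min = body_cov_min)
  }
  res <- do.call(rbind, out)
  res <- data.frame(read_id = qname[q], intron_id = introns$intron_id[s], res)
  class(res) <- c("long_read_calls", "data.frame")
  res
}

empty_long_read_calls <- function() {
  structure(data.frame(read_id = character(), intron_id = character(),
                       verdict = character(), intron_body_coverage = double(),
                       gap_match_slack = double()),
            class = c("long_read_calls", "data.frame"))
}

# blocks/gaps are IRanges in 1-based coordinates; intron is 0-based
# half-open [start0, end0).
classify_one_read <- function(blocks, gaps, start0, end0, slack, flank,
                              body_cov_min) {
  gap_dist <- NA_real_
  if (length(gaps) > 0L) {
    d5 <- abs((IRanges::start(gaps) - 1L) - start0)
    d3 <- abs(IRanges::end(gaps) - end0)
    gap_dist <- min(pmax(d5, d3))
    if (any(d5 <= slack & d3 <= slack))
      return(data.frame(verdict = "spliced", intron_body_coverage = 0,
                        gap_match_slack = gap_dist))
  }
  cov <- IRanges::reduce(blocks)
  win5 <- IRanges::IRanges(start0 - flank + 1L, start0 + flank)
  win3 <- IRanges::IRanges(end0 - flank + 1L, end0 + flank)
  covered_gapless <- function(win) {
    ov <- IRanges::findOverlaps(win, cov, type = "within")
    length(ov) > 0L
  }
  body <- IRanges::IRanges(start0 + 1L, end0)
  body_cov <- sum(IRanges::width(IRanges::intersect(cov, body))) /
    IRanges::width(body)
  if (covered_gapless(win5) && covered_gapless(win3) &&
      body_cov >= body_cov_min)
    return(data.frame(verdict = "retained", intron_body_coverage = body_cov,
                      gap_match_slack = gap_dist))
  data.frame(verdict = "uninformative", intron_body_coverage = body_cov,
             gap_match_slack = gap_dist)
}

#' Validate retained-intron candidates with long reads
#'
#' Summarizes long-read verdicts per candidate intron and computes the
#' validation rate: validated candidates (at least `min_support` retained
#' reads) over candidates with at least one informative read. Candidates
#' with zero informative reads are reported separately, not counted in the
#' rate's denominator.
#'
#' @param lr_calls A `long_read_calls` data.frame from
#'   [classify_long_reads()].
#' @param candidates An `ri_calls` data.frame (its retained introns are
#'   the candidates), or a character vector of intron ids.
#' @param min_support Minimum retained reads to validate (default 1).
#' @param condition_id Optional condition label.
#' @return A list of class `lr_validation`: `summary` (per-candidate
#'   data.frame with `intron_id`, `n_retained_reads`, `n_spliced_reads`,
#'   `validated`), `validation_rate`, `n_candidates`, `n_informative`,
#'   `n_no_reads`.
#' @export
validate_candidates <- function(lr_calls, candidates, min_support = 1L,
                                condition_id = NA_character_) {
  ids <- if (is.character(candidates)) candidates
         else candidates$intron_id[candidates$retained]
  if (length(ids) == 0L) stopf("empty candidate list")
  nret <- nspl <- integer(length(ids))
  for (i in seq_along(ids)) {
    v <- lr_calls$verdict[lr_calls$intron_id == ids[i]]
    nret[i] <- sum(v == "retained")
    nspl[i] <- sum(v == "spliced")
  }
  informative <- (nret + nspl) > 0L
  validated <- nret >= min_support
  summary <- data.frame(intron_id = ids, condition_id = condition_id,
                        n_retained_reads = nret, n_spliced_reads = nspl,
                        informative = informative,
                        validated = validated & informative)
  structure(list(summary = summary,
                 validation_rate = if (any(informative))
                   sum(validated & informative) / sum(informative) else NA_real_,
                 n_candidates = length(ids),
                 n_informative = sum(informative),
                 n_no_reads = sum(!informative)),
            class = "lr_validation")
}

#' @export
print.lr_validation <- function(x, ...) {
  cat(sprintf("lr_validation: %d/%d informative candidates validated (rate %.3f); %d with no informative reads\n",
              sum(x$summary$validated), x$n_informative, x$validation_rate,
              x$n_no_reads))
  invisible(x)
}
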