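# Differential retention: categorical switch calls between conditions,
# plus the splicing-index test and a simplified gene-level DE test.

#' Call retention switches between two conditions
#'
#' The switch rule is categorical, not magnitude-based: an intron switches
#' when its pooled intron usage is at most 25% in one condition and
#' strictly above 25% in the other. Both conditions must quantify the same
#' intron universe and the host gene must be expressed in both.
#'
#' @param calls_a,calls_b `ri_calls` data.frames for the two conditions
#'   (their `pooled_minPIR` and `gene_expressed` columns are used).
#' @param usage_threshold Percent boundary of the rule (default 25).
#' @return A data.frame of class `ri_switches` with columns `intron_id`,
#'   `condition_a`, `condition_b`, `pir_a`, `pir_b`, `switched`,
#'   `direction` (`"up_in_b"`/`"down_in_b"`). Introns with an undefined
#'   pooled PIR or an unexpressed gene in either condition are excluded;
#'   their number is in the `n_excluded` attribute.
#' @export
call_switches <- function(calls_a, calls_b, usage_threshold = 25) {
  if (!setequal(calls_a$intron_id, calls_b$intron_id))
    stopf("conditions quantify disjoint intron universes")
  b <- calls_b[match(calls_a$intron_id, calls_b$intron_id), , drop = FALSE]
  usable <- calls_a$pooled_defined & b$pooled_defined &
    calls_a$gene_expressed & b$gene_expressed
  n_excluded <- sum(!usable)
  a <- calls_a[usable, , drop = FALSE]
  b <- b[usable, , drop = FALSE]
  pa <- a$pooled_minPIR
  pb <- b$pooled_minPIR
  up <- pa <= usage_threshold & pb > usage_threshold
  down <- pa > usage_threshold & pb <= usage_threshold
  out <- data.frame(intron_id = a$intron_id,
                    condition_a = a$condition_id, condition_b = b$condition_id,
                    pir_a = pa, pir_b = pb,
                    switched = up | down,
                    direction = ifelse(up, "up_in_b",
                                       ifelse(down, "down_in_b", NA_character_)))
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("ri_switches", "data.frame")
  out
}

#' Splicing-index differential test
#'
#' Per replicate, a feature's inclusion is normalized to its gene
#' (`(feature + pseudocount) / (gene + pseudocount)`); the fold change is
#' the ratio of condition means of normalized inclusion, and the p-value
#' comes from a Welch two-sample test on log2 normalized inclusion with a
#' per-group variance floor that keeps the statistic defined for exact
#' replicates. Two significance flags are set: PATTERN
#' (|FC| >= 1.5 and p <= 0.05) and EXON (|FC| >= 2.0 and p <= 0.01), where
#' |FC| is the symmetric magnitude `max(FC, 1/FC)`.
#'
#' @param feature_a,feature_b Numeric vectors of feature read counts per
#'   replicate in conditions A and B.
#' @param gene_a,gene_b Matching gene read counts per replicate (must be
#'   positive in every used replicate).
#' @param feature_id Feature label.
#' @param pseudocount Added to feature and gene counts (default 0.5).
#' @param variance_floor_cv Per-group coefficient-of-variation floor for
#'   the Welch variance (default 0.05).
#' @return A one-row data.frame of class `splicing_index_result`:
#'   `feature_id`, `fold_change` (B relative to A), `p_value`,
#'   `significant_pattern`, `significant_exon`.
#' @export
splicing_index <- function(feature_a, feature_b, gene_a, gene_b,
                           feature_id = "feature", pseudocount = 0.5,
                           variance_floor_cv = 0.05) {
  if (length(feature_a) < 2L || length(feature_b) < 2L)
    stopf("need >=2 replicates per condition")
  if (any(gene_a <= 0) || any(gene_b <= 0))
    stopf("feature '%s' skipped: zero gene count in a replicate", feature_id)
  inc_a <- (feature_a + pseudocount) / (gene_a + pseudocount)
  inc_b <- (feature_b + pseudocount) / (gene_b + pseudocount)
  fc <- mean(inc_b) / mean(inc_a)
  tt <- welch_floor_test(log2(inc_a), log2(inc_b), variance_floor_cv)
  p <- tt$p_value
  out <- data.frame(feature_id = feature_id, fold_change = fc, p_value = p,
                    significant_pattern = fc_magnitude(fc) >= 1.5 & p <= 0.05,
                    significant_exon = fc_magnitude(fc) >= 2.0 & p <= 0.01)
  class(out) <- c("splicing_index_result", "data.frame")
  out
}

#' Simplified gene-level differential expression
#'
#' Library-size-normalized counts (counts per million), fold change of
#' condition means, and a Welch test on log2 normalized counts. This is a
#' deliberately simple self-contained test (flagged
#' `"welch_cpm_simplified"` in the `method` attribute) so synthetic
#' end-to-end runs need no external model; significance uses fold change
#' >= 1.5 at uncorrected p <= 0.05, plus a Benjamini-Hochberg column for
#' reference.
#'
#' @param counts_a,counts_b Matrices (genes x replicates) of raw counts.
#' @param lib_a,lib_b Library sizes (total mapped fragments) per replicate;
#'   default column sums.
#' @param gene_ids Gene labels (default rownames of `counts_a`).
#' @param pseudocount Added to normalized counts before log/ratio
#'   (default 0.5).
#' @return A data.frame of class `gene_de_result` with `gene_id`,
#'   `fold_change`, `p_value`, `padj_bh`, `significant`.
#' @export
gene_de <- function(counts_a, counts_b, lib_a = colSums(counts_a),
                    lib_b = colSums(counts_b),
                    gene_ids = rownames(counts_a), pseudocount = 0.5) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts_a)))
  keep <- rowSums(counts_a) + rowSums(counts_b) > 0
  cpm_a <- sweep(counts_a, 2L, lib_a / 1e6, "/") + pseudocount
  cpm_b <- sweep(counts_b, 2L, lib_b / 1e6, "/") + pseudocount
  fc <- rowMeans(cpm_b) / rowMeans(cpm_a)
  p <- vapply(seq_len(nrow(counts_a)), function(i)
    welch_floor_test(log2(cpm_a[i, ]), log2(cpm_b[i, ]))$p_value, 0)
  out <- data.frame(gene_id = gene_ids, fold_change = fc, p_value = p,
                    padj_bh = stats::p.adjust(p, "BH"),
                    significant = fc_magnitude(fc) >= 1.5 & p <= 0.05)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- "welch_cpm_simplified"
  class(out) <- c("gene_de_result", "data.frame")
  out
}
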