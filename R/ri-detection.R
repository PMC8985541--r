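# PIR / minPIR computation and condition-level retained-intron calling.

#' Percent intron retention per boundary and minPIR
#'
#' PIR at a boundary is the percentage of junction-informative reads
#' supporting retention: `PIR5 = 100 * EI5 / (EI5 + EE)` at the donor and
#' `PIR3 = 100 * EI3 / (EI3 + EE)` at the acceptor. minPIR is the minimum
#' of the two — the conservative summary, since one clean (well-spliced)
#' boundary vetoes retention evidence at the other.
#'
#' By default only junction reads enter the statistic. With
#' `pir_mode = "with_intronic"`, intron-body reads are added to both
#' numerators after normalization to junction-equivalent counts
#' (`IB * read_length / intron_length`, the expected number of boundary
#' reads a uniformly sampled retained molecule would yield).
#'
#' @param counts A `junction_counts` data.frame from [count_junctions()].
#' @param pir_mode `"junction"` (default) or `"with_intronic"`.
#' @param introns Required for `"with_intronic"`: the `intron_records`
#'   table (for intron lengths).
#' @param read_length Read length used for the IB normalization
#'   (default 150).
#' @return A data.frame of class `pir_estimate` with columns `sample_id`,
#'   `intron_id`, `PIR5`, `PIR3`, `minPIR` (percent), `coverage`
#'   (`EE + EI5 + EI3`), and `defined` (FALSE when either boundary has a
#'   zero denominator; such introns are excluded downstream).
#' @export
compute_pir <- function(counts, pir_mode = c("junction", "with_intronic"),
                        introns = NULL, read_length = 150L) {
  pir_mode <- match.arg(pir_mode)
  stopifnot(all(c("EE", "EI5", "EI3", "IB") %in% names(counts)))
  if (any(counts$EE < 0 | counts$EI5 < 0 | counts$EI3 < 0 | counts$IB < 0))
    stopf("negative junction counts")
  ei5 <- counts$EI5
  ei3 <- counts$EI3
  if (pir_mode == "with_intronic") {
    if (is.null(introns)) stopf("pir_mode='with_intronic' requires `introns`")
    len <- (introns$end - introns$start)[match(counts$intron_id, introns$intron_id)]
    ib_eq <- counts$IB * read_length / pmax(len, read_length)
    ei5 <- ei5 + ib_eq
    ei3 <- ei3 + ib_eq
  }
  d5 <- ei5 + counts$EE
  d3 <- ei3 + counts$EE
  pir5 <- ifelse(d5 > 0, 100 * ei5 / d5, NA_real_)
  pir3 <- ifelse(d3 > 0, 100 * ei3 / d3, NA_real_)
  out <- data.frame(sample_id = counts$sample_id,
                    intron_id = counts$intron_id,
                    PIR5 = pir5, PIR3 = pir3,
                    minPIR = pmin(pir5, pir3),
                    coverage = counts$EE + counts$EI5 + counts$EI3,
                    defined = d5 > 0 & d3 > 0)
  class(out) <- c("pir_estimate", "data.frame")
  out
}

#' Configuration of the retained-intron filter chain
#'
#' The three-part rule: an intron is retained in a condition when its
#' minPIR exceeds `pir_threshold` in strictly more than
#' `replicate_fraction` of the replicates (each passing replicate also
#' needing `min_coverage` junction reads and a defined minPIR), and the
#' hosting gene is expressed above the intergenic background.
#'
#' @param pir_threshold Percent; a replicate passes with minPIR strictly
#'   above it (default 25).
#' @param replicate_fraction Proportion of replicates that must pass,
#'   strict inequality (default 0.5).
#' @param min_coverage Minimum junction reads (`EE + EI5 + EI3`) for a
#'   replicate to be informative (default 10).
#' @param require_gene_expressed Gate calls on host-gene expression
#'   (default TRUE).
#' @param replicate_rule `"pir_filter"` (a replicate passes the minPIR and
#'   coverage filter) or `"any_evidence"` (a replicate passes with any
#'   retention evidence, `EI5 + EI3 + IB > 0`; the alternative reading of
#'   "intron expressed in" a replicate).
#' @return An object of class `ri_call_config`.
#' @export
ri_call_config <- function(pir_threshold = 25, replicate_fraction = 0.5,
                           min_coverage = 10L, require_gene_expressed = TRUE,
                           replicate_rule = c("pir_filter", "any_evidence")) {
  if (!(pir_threshold > 0 && pir_threshold < 100))
    stopf("pir_threshold must be in (0, 100)")
  structure(list(pir_threshold = pir_threshold,
                 replicate_fraction = replicate_fraction,
                 min_coverage = min_coverage,
                 require_gene_expressed = require_gene_expressed,
                 replicate_rule = match.arg(replicate_rule)),
            class = "ri_call_config")
}

#' Call retained introns for one condition
#'
#' Applies the filter chain of [ri_call_config()] to the replicates of one
#' condition. Gene expression is gated per replicate against that
#' replicate's intergenic background threshold; a gene counts as expressed
#' in the condition when it exceeds the background in a majority of
#' replicates. The condition-level PIR is computed from pooled counts
#' (sum, then ratio), which is robust to unequal sequencing depth.
#'
#' @param counts_list List of `junction_counts`, one per replicate.
#' @param expression_list List of `gene_expression`, one per replicate
#'   (same order).
#' @param background_list List of `background_model`, one per replicate
#'   (same order), or a single numeric fpkm threshold recycled across
#'   replicates.
#' @param introns The `intron_records` table (maps introns to host genes
#'   and marks annotated retention).
#' @param condition_id Label for the condition.
#' @param cfg An [ri_call_config()].
#' @return A data.frame of class `ri_calls` with columns `condition_id`,
#'   `intron_id`, `status` (`"retained"`, `"not_retained"`, or `"no_data"`
#'   when no replicate has a defined minPIR), `retained` (logical),
#'   `n_replicates_passing`, `n_replicates`, `pooled_minPIR` (from summed
#'   counts), `gene_expressed`, and `novel` (not flagged retained in the
#'   annotation).
#' @export
call_retained <- function(counts_list, expression_list, background_list,
                          introns, condition_id, cfg = ri_call_config()) {
  n_rep <- length(counts_list)
  if (n_rep < 2L) stopf("need >=2 replicates per condition, got %d", n_rep)
  if (length(expression_list) != n_rep)
    stopf("expression_list length mismatch")
  if (is.numeric(background_list))
    background_list <- rep(list(list(threshold = background_list)), n_rep)
  if (length(background_list) != n_rep)
    stopf("background_list length mismatch")

  ids <- counts_list[[1L]]$intron_id
  for (cc in counts_list) if (!identical(cc$intron_id, ids))
    stopf("replicates quantify different intron universes")

  pirs <- lapply(counts_list, compute_pir)
  pass <- defined <- matrix(FALSE, length(ids), n_rep)
  for (j in seq_len(n_rep)) {
    p <- pirs[[j]]
    defined[, j] <- p$defined
    pass[, j] <- if (cfg$replicate_rule == "any_evidence") {
      counts_list[[j]]$EI5 + counts_list[[j]]$EI3 + counts_list[[j]]$IB > 0
    } else {
      p$defined & p$coverage >= cfg$min_coverage &
        !is.na(p$minPIR) & p$minPIR > cfg$pir_threshold
    }
  }

  pooled <- Reduce(function(a, b) {
    a[c("EE", "EI5", "EI3", "IB")] <- a[c("EE", "EI5", "EI3", "IB")] +
      b[c("EE", "EI5", "EI3", "IB")]
    a
  }, counts_list)
  pooled$sample_id <- condition_id
  pooled_pir <- compute_pir(pooled)

  gene_expressed_tab <- gene_expressed_by_condition(expression_list,
                                                    background_list)
  gene_of <- introns$gene_id[match(ids, introns$intron_id)]
  gexp <- gene_expressed_tab$expressed[match(gene_of, gene_expressed_tab$gene_id)]
  gexp[is.na(gexp)] <- FALSE

  n_pass <- rowSums(pass)
  any_defined <- rowSums(defined) > 0L
  retained <- (n_pass / n_rep) > cfg$replicate_fraction &
    (!cfg$require_gene_expressed | gexp)
  status <- ifelse(!any_defined, "no_data",
                   ifelse(retained, "retained", "not_retained"))
  out <- data.frame(condition_id = condition_id, intron_id = ids,
                    status = status, retained = status == "retained",
                    n_replicates_passing = n_pass, n_replicates = n_rep,
                    pooled_minPIR = pooled_pir$minPIR,
                    pooled_defined = pooled_pir$defined,
                    gene_expressed = gexp,
                    novel = !introns$known_retained[match(ids, introns$intron_id)])
  class(out) <- c("ri_calls", "data.frame")
  out
}

# Gene expressed in a condition: fpkm above the replicate's background
# threshold in a strict majority of replicates.
gene_expressed_by_condition <- function(expression_list, background_list) {
  n_rep <- length(expression_list)
  gene_id <- expression_list[[1L]]$gene_id
  above <- matrix(FALSE, length(gene_id), n_rep)
  for (j in seq_len(n_rep)) {
    e <- expression_list[[j]]
    above[, j] <- e$fpkm[match(gene_id, e$gene_id)] > background_list[[j]]$threshold
  }
  data.frame(gene_id = gene_id,
             expressed = rowSums(above, na.rm = TRUE) > n_rep / 2)
}

#' Cross-condition census of retained-intron calls
#'
#' Builds the per-intron presence/absence matrix over conditions and the
#' counts per overlap (Venn) region, separating novel introns (absent from
#' the annotation as retained) from annotated ones.
#'
#' @param calls_list List of `ri_calls`, one per condition.
#' @return A list of class `ri_census`: `presence` (logical matrix, introns
#'   x conditions, restricted to introns retained somewhere), `regions`
#'   (data.frame of overlap-pattern counts), `n_retained_total`,
#'   `n_novel`, `n_common_all`.
#' @export
novel_ri_census <- function(calls_list) {
  if (length(calls_list) == 0L || any(vapply(calls_list, nrow, 0L) == 0L))
    stopf("every condition must carry calls")
  conds <- vapply(calls_list, function(x) x$condition_id[1L], "")
  ids <- calls_list[[1L]]$intron_id
  pres <- vapply(calls_list, function(x)
    x$retained[match(ids, x$intron_id)], logical(length(ids)))
  colnames(pres) <- conds
  rownames(pres) <- ids
  novel <- calls_list[[1L]]$novel[match(ids, calls_list[[1L]]$intron_id)]
  keep <- rowSums(pres) > 0L
  pres <- pres[keep, , drop = FALSE]
  novel <- novel[keep]
  pattern <- apply(pres, 1L, function(r) paste(conds[r], collapse = "+"))
  regions <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(regions) <- c("conditions", "n_introns")
  structure(list(presence = pres, regions = regions,
                 n_retained_total = nrow(pres),
                 n_novel = sum(novel),
                 n_common_all = sum(rowSums(pres) == ncol(pres))),
            class = "ri_census")
}

#' @export
print.ri_census <- function(x, ...) {
  cat(sprintf("ri_census: %d introns retained in >=1 condition (%d novel), %d common to all\n",
              x$n_retained_total, x$n_novel, x$n_common_all))
  invisible(x)
}
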