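# Internal coordinate helpers and small shared utilities.
#
# Internal convention: 0-based half-open [start, end) on the forward genomic
# strand. GRanges/GTF are 1-based inclusive; conversion happens only here.

# 0-based half-open -> GRanges (1-based inclusive)
gr0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand)
}

# GRanges -> 0-based half-open data.frame columns
from_gr <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Welch two-sample test on two numeric vectors with a per-group variance
# floor. The floor keeps the statistic defined when a group has zero
# within-group variance (exact replicates), without inventing a shrinkage
# model: each group's variance is bounded below by (floor_cv * |mean|)^2.
welch_floor_test <- function(x, y, floor_cv = 0.05) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) return(list(statistic = NA_real_, p_value = NA_real_))
  mx <- mean(x); my <- mean(y)
  vx <- max(stats::var(x), (floor_cv * abs(mx))^2)
  vy <- max(stats::var(y), (floor_cv * abs(my))^2)
  if (vx == 0 && vy == 0) {
    # both groups constant at 0: identical -> p = 1, else maximally distinct
    p <- if (isTRUE(all.equal(mx, my))) 1 else 0
    return(list(statistic = if (p == 1) 0 else Inf, p_value = p))
  }
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = tstat, p_value = 2 * stats::pt(-abs(tstat), df))
}

# Symmetric fold change magnitude: max(r, 1/r) for a positive ratio r.
fc_magnitude <- function(r) pmax(r, 1 / r)

# Deterministic TSV writer; floats rounded to 6 decimals so pipeline output
# is byte-stable across platforms.
write_tsv6 <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Derive a stream of child seeds from a master seed, each < 2^31.
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
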