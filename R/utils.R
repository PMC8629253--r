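# Internal numeric helpers shared across modules.

# Row-wise max without apply() overhead.
row_max <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx
}

# Row-wise log(sum(exp(x))) with the usual max shift.
logsumexp_rows <- function(m) {
  mx <- row_max(m)
  mx + log(rowSums(exp(m - mx)))
}

# rowsum() that always returns one row per level in `levels`,
# including levels absent from `group` (zero rows).
rowsum_all_levels <- function(x, group, levels) {
  f <- factor(group, levels = levels)
  out <- matrix(0, nrow = length(levels), ncol = ncol(x),
                dimnames = list(as.character(levels), colnames(x)))
  keep <- !is.na(f)
  if (any(keep)) {
    agg <- rowsum(x[keep, , drop = FALSE], f[keep], reorder = TRUE)
    out[rownames(agg), ] <- agg
  }
  out
}

# Derive a reproducible sub-seed for a named pipeline stage from a
# master seed; stays inside the 32-bit integer range.
stage_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + offs) %% 2147483587L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
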