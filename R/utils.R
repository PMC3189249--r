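
# Internal helpers shared across modules. All interval data.frames in this
# package use BED conventions: 0-based, half-open [start, end).

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what = "data frame") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

# interval df -> GRanges (shift to 1-based closed)
as_granges <- function(df) {
  assert_cols(df, c("chrom", "start", "end"), "interval set")
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# midpoint of a 0-based half-open interval
interval_mid <- function(start, end) floor((start + end) / 2)

# Deterministic sub-seed derivation; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483587L
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0
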