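# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals. base::round() rounds half to
# even, which makes reported percentages depend on binary representation;
# reported fractions must be stable.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Convert a (chrom, start, end) data frame to a GRanges. Internal coordinates
# are 0-based half-open; GRanges is 1-based closed, so shift start by one.
.as_granges <- function(df, levels = unique(df$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = levels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# findOverlaps on two coordinate data frames with shared seqlevels
.find_overlaps <- function(a, b) {
  lev <- union(unique(a$chrom), unique(b$chrom))
  GenomicRanges::findOverlaps(.as_granges(a, lev), .as_granges(b, lev))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Derive a stream-specific seed from a master seed. Offsets keep derived
# seeds distinct between generator stages while staying inside 32-bit range.
.derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
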