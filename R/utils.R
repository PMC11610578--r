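# Internal interval helpers. File formats carry 0-based half-open
# coordinates (BED, PAF, BedGraph); in memory everything is a GRanges
# (1-based closed). Conversion happens here and nowhere else.

# 0-based half-open -> GRanges
.gr0 <- function(seq_id, start0, end0) {
  GenomicRanges::GRanges(seq_id, IRanges::IRanges(start = start0 + 1L, end = end0))
}

# GRanges -> data.frame of 0-based half-open coordinates
.bed0 <- function(gr) {
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_granges <- function(x, what) {
  if (!methods::is(x, "GRanges")) {
    .stopf("%s must be a GRanges object", what)
  }
  invisible(x)
}

# Restrict a GRanges to a common sequence universe so that set operations
# (setdiff, intersect) do not drop or invent sequence levels.
.on_universe <- function(gr, seq_ids) {
  gr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(gr)),
    IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr))
  )
  GenomeInfoDb::seqlevels(gr) <- seq_ids
  gr
}

# Concatenate GRanges whose sequence levels may differ, without the
# seqlevel-merge warning; metadata columns must agree.
.cat_gr <- function(a, b) {
  levels <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- levels
  GenomeInfoDb::seqlevels(b) <- levels
  c(a, b)
}

# round() uses round-half-to-even; megabase sizes are reported with
# half-away-from-zero rounding instead.
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Lower-of-central-values median on integer sizes (even n picks the lower
# central element rather than averaging).
.lower_median <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  s <- sort(x)
  s[[ceiling(n / 2)]]
}

# sample() treats a scalar first argument as 1:x; draw uniformly from a
# closed integer range without that trap.
.sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq(as.integer(lo), as.integer(hi)), n, replace = TRUE)
}

.rand_bases <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}
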