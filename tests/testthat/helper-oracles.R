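# Independent per-base oracles used to cross-check the interval arithmetic
# and junction resolution. These deliberately use naive boolean arrays and
# ascending character scans rather than the package's interval algebra.

# Per-base DRR caller: mark covered bases, mark gaps, scan runs.
oracle_call_drrs <- function(blocks, seq_lengths, gaps = NULL,
                             min_size = 10000L, min_mapq = 0L) {
  out <- list()
  for (sq in names(seq_lengths)) {
    len <- seq_lengths[[sq]]
    covered <- logical(len)
    b <- blocks[blocks$target_id == sq & blocks$mapq >= min_mapq, , drop = FALSE]
    for (i in seq_len(nrow(b))) {
      covered[(b$target_start[i] + 1L):b$target_end[i]] <- TRUE
    }
    gap <- logical(len)
    if (!is.null(gaps)) {
      g <- gaps[as.character(GenomicRanges::seqnames(gaps)) == sq]
      for (i in seq_along(g)) {
        gap[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <- TRUE
      }
    }
    mask <- !covered & !gap
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths > min_size
    if (any(keep)) {
      out[[sq]] <- data.frame(seq_id = sq, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Per-base membership bitmask for multi-way shared-missing partitions.
oracle_shared_missing <- function(sets, seq_id, len) {
  members <- vapply(sets, function(g) {
    mask <- logical(len)
    g <- g[as.character(GenomicRanges::seqnames(g)) == seq_id]
    for (i in seq_along(g)) {
      mask[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <- TRUE
    }
    mask
  }, logical(len))
  keys <- apply(members, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  tab <- table(keys[keys != ""])
  setNames(as.numeric(tab), names(tab))
}

# Per-base repeat-class bitmask oracle for composition fractions.
oracle_repeat_fractions <- function(drr, repeats) {
  s <- GenomicRanges::start(drr); e <- GenomicRanges::end(drr)
  sq <- as.character(GenomicRanges::seqnames(drr))
  size <- e - s + 1L
  classes <- unique(S4Vectors::mcols(repeats)$repeat_class)
  any_mask <- logical(size)
  class_frac <- sapply(classes, function(k) {
    mask <- logical(size)
    feats <- repeats[S4Vectors::mcols(repeats)$repeat_class == k &
                       as.character(GenomicRanges::seqnames(repeats)) == sq]
    for (i in seq_along(feats)) {
      a <- max(GenomicRanges::start(feats)[i], s)
      b <- min(GenomicRanges::end(feats)[i], e)
      if (a <= b) mask[(a - s + 1L):(b - s + 1L)] <- TRUE
    }
    any_mask <<- any_mask | mask
    sum(mask) / size
  })
  list(class_fraction = class_frac, total = sum(any_mask) / size)
}

# Exhaustive ascending overlap scan for junction resolution (the package
# uses descending early-exit maximal extension).
oracle_junction <- function(der, fa, fb) {
  d <- strsplit(der, "")[[1]]
  a <- strsplit(fa, "")[[1]]
  b <- strsplit(fb, "")[[1]]
  n <- length(d)
  a_end <- 0L
  for (k in seq_len(min(n, length(a)))) {
    if (all(d[1:k] == a[(length(a) - k + 1L):length(a)])) a_end <- k
  }
  b_len <- 0L
  for (k in seq_len(min(n, length(b)))) {
    if (all(d[(n - k + 1L):n] == b[1:k])) b_len <- k
  }
  b_start <- n - b_len
  list(
    a_end = a_end, b_start = b_start,
    mh = max(0L, a_end - b_start),
    ins = max(0L, b_start - a_end)
  )
}

# Line-by-line text oracle for total aligned target bp in a PAF file.
oracle_paf_target_bp <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sum(vapply(strsplit(lines, "\t"), function(f) {
    as.numeric(f[9]) - as.numeric(f[8])
  }, numeric(1)))
}
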