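# Repeat composition and genomic context of DRRs. Fractions are computed
# with integer base-pair arithmetic against the union of (possibly
# overlapping) repeat annotations, so "100% repetitive" means exact full
# tiling, never a floating-point near-miss.

#' Repeat composition of a region
#'
#' Computes, for one DRR, the fraction of its bases covered by each repeat
#' class and by the union of all repeat features. Per-class fractions may
#' sum to more than the total when annotations of different classes
#' overlap; the union governs the total.
#'
#' @param drr A length-1 GRanges (one DRR).
#' @param repeats A GRanges of repeat features with a `repeat_class`
#'   metadata column, as returned by [read_repeatmasker_out()].
#' @return A list of class `repeat_composition` with elements
#'   `class_fraction` (named numeric over the closed class vocabulary),
#'   `total_repeat_fraction`, `unmasked_fraction`, `masked_bp` and `size`.
#' @examples
#' drr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' reps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500),
#'   repeat_class = "LINE", repeat_name = "L1PA3")
#' repeat_composition(drr, reps)$total_repeat_fraction
#' @export
repeat_composition <- function(drr, repeats) {
  .assert_granges(drr, "drr")
  if (length(drr) != 1L) .stopf("repeat_composition takes one DRR at a time")
  .assert_granges(repeats, "repeats")
  size <- GenomicRanges::width(drr)
  seq_ids <- unique(c(as.character(seqnames(drr)), as.character(seqnames(repeats))))
  drr_u <- .on_universe(drr, seq_ids)
  overlap_bp <- function(features) {
    if (length(features) == 0L) return(0)
    red <- GenomicRanges::reduce(.on_universe(features, seq_ids))
    sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(drr_u, red))))
  }
  cls <- mcols(repeats)$repeat_class
  class_fraction <- vapply(.REPEAT_CLASSES, function(k) {
    overlap_bp(repeats[cls == k]) / size
  }, numeric(1))
  masked_bp <- overlap_bp(repeats)
  structure(
    list(
      class_fraction = class_fraction,
      total_repeat_fraction = masked_bp / size,
      unmasked_fraction = (size - masked_bp) / size,
      masked_bp = masked_bp,
      size = size
    ),
    class = "repeat_composition"
  )
}

#' Genomic context flags of a DRR
#'
#' @param drr A length-1 GRanges (one DRR).
#' @param composition Its [repeat_composition()].
#' @param centromeres GRanges of centromere intervals on the same template.
#' @param segdups GRanges of segmental-duplication intervals.
#' @param cfg A [drr_config()]; `context_window` sets the centromere
#'   proximity window (default 10 kbp).
#' @return A list with logical flags `fully_repetitive` (every base covered
#'   by a repeat feature), `near_centromere` (overlapping or within the
#'   window of a centromere) and `in_segdup` (>= 1 bp overlap with an SD).
#' @export
context_flags <- function(drr, composition, centromeres, segdups,
                          cfg = drr_config()) {
  .assert_granges(drr, "drr")
  if (length(drr) != 1L) .stopf("context_flags takes one DRR at a time")
  near_cen <- FALSE
  if (!is.null(centromeres) && length(centromeres)) {
    seq_ids <- unique(c(as.character(seqnames(drr)), as.character(seqnames(centromeres))))
    hit <- GenomicRanges::distanceToNearest(.on_universe(drr, seq_ids),
                                            .on_universe(centromeres, seq_ids))
    near_cen <- length(hit) > 0 && mcols(hit)$distance <= cfg$context_window
  }
  in_sd <- FALSE
  if (!is.null(segdups) && length(segdups)) {
    seq_ids <- unique(c(as.character(seqnames(drr)), as.character(seqnames(segdups))))
    in_sd <- IRanges::overlapsAny(.on_universe(drr, seq_ids),
                                  .on_universe(segdups, seq_ids))
  }
  list(
    fully_repetitive = composition$masked_bp == composition$size,
    near_centromere = isTRUE(as.logical(near_cen)),
    in_segdup = isTRUE(as.logical(in_sd))
  )
}

#' Annotate a DRR set with repeat composition and context
#'
#' Convenience wrapper applying [repeat_composition()] and
#' [context_flags()] to every DRR of a set.
#'
#' @param drrs GRanges of DRRs from [call_drrs()].
#' @param repeats GRanges of repeat features.
#' @param centromeres,segdups Context annotation GRanges (may be `NULL`).
#' @param cfg A [drr_config()].
#' @return A data.frame with one row per DRR: identifiers, size, per-class
#'   repeat fractions, `total_repeat_fraction`, `unmasked_fraction`, and
#'   the three context flags.
#' @export
annotate_drrs <- function(drrs, repeats, centromeres = NULL, segdups = NULL,
                          cfg = drr_config()) {
  .assert_granges(drrs, "drrs")
  rows <- lapply(seq_along(drrs), function(i) {
    drr <- drrs[i]
    comp <- repeat_composition(drr, repeats)
    flags <- context_flags(drr, comp, centromeres, segdups, cfg)
    cbind(
      data.frame(
        drr_id = mcols(drr)$drr_id %||% sprintf("DRR_%s_%d",
          as.character(seqnames(drr)), GenomicRanges::start(drr) - 1L),
        seq_id = as.character(seqnames(drr)),
        start = GenomicRanges::start(drr) - 1L,
        end = GenomicRanges::end(drr),
        size = GenomicRanges::width(drr),
        stringsAsFactors = FALSE
      ),
      as.data.frame(as.list(comp$class_fraction)),
      data.frame(
        total_repeat_fraction = comp$total_repeat_fraction,
        unmasked_fraction = comp$unmasked_fraction,
        fully_repetitive = flags$fully_repetitive,
        near_centromere = flags$near_centromere,
        in_segdup = flags$in_segdup
      )
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort-level repeat and context report
#'
#' Summarizes an annotated DRR table into the shares of regions that are
#' fully repetitive, near a centromere or inside a segmental duplication,
#' together with a decile histogram of per-DRR repeat fraction.
#'
#' @param annotated A data.frame from [annotate_drrs()]; an optional
#'   `comparison` column groups rows into separate template/query
#'   comparisons.
#' @return A list with `shares` (one row per comparison: `n`,
#'   `frac_fully_repetitive`, `frac_near_centromere`, `frac_in_segdup`) and
#'   `repeat_deciles` (counts of DRRs per repeat-fraction decile; counts
#'   sum to `n` within each comparison).
#' @export
bucket_report <- function(annotated) {
  if (is.null(annotated) || nrow(annotated) == 0L) {
    return(list(
      shares = data.frame(comparison = character(), n = integer(),
                          frac_fully_repetitive = numeric(),
                          frac_near_centromere = numeric(),
                          frac_in_segdup = numeric()),
      repeat_deciles = data.frame(comparison = character(),
                                  decile = character(), n = integer())
    ))
  }
  comparison <- annotated$comparison %||% rep("all", nrow(annotated))
  breaks <- seq(0, 1, by = 0.1)
  labels <- sprintf("(%.0f%%,%.0f%%]", 100 * breaks[-11], 100 * breaks[-1])
  labels[1] <- "[0%,10%]"
  groups <- split(annotated, comparison)
  shares <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    data.frame(
      comparison = g,
      n = nrow(d),
      frac_fully_repetitive = mean(d$fully_repetitive),
      frac_near_centromere = mean(d$near_centromere),
      frac_in_segdup = mean(d$in_segdup),
      stringsAsFactors = FALSE
    )
  }))
  rownames(shares) <- NULL
  deciles <- do.call(rbind, lapply(names(groups), function(g) {
    d <- annotated[comparison == g, , drop = FALSE]
    bin <- cut(d$total_repeat_fraction, breaks = breaks,
               include.lowest = TRUE, labels = labels)
    data.frame(comparison = g, decile = labels,
               n = as.integer(table(bin)[labels]),
               stringsAsFactors = FALSE)
  }))
  rownames(deciles) <- NULL
  list(shares = shares, repeat_deciles = deciles)
}
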