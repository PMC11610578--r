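# Calling differential reference regions (DRRs) from whole-genome
# alignment coverage. A DRR is a segment of the template assembly, strictly
# larger than the configured size cutoff (default 10 kbp), that is not
# covered by any alignment block of the query assembly, after excluding
# known assembly gaps. Coverage is exact per-base interval arithmetic, not
# binned.

#' Template intervals covered by query alignments
#'
#' Unions the target-side intervals of all alignment blocks at or above a
#' mapping-quality cutoff into a disjoint, sorted interval set on the
#' template.
#'
#' @param blocks Alignment blocks as returned by [read_paf()].
#' @param min_mapq Minimum MAPQ for a block to count (default 0: every
#'   block counts).
#' @param seq_lengths Optional named vector of template sequence lengths;
#'   when supplied, blocks extending beyond a sequence end are an error.
#' @return A reduced (disjoint, sorted) GRanges of covered template bases.
#' @examples
#' paf <- data.frame(
#'   query_id = "q1", query_len = 100L, query_start = 0L, query_end = 90L,
#'   strand = "+", target_id = "t1", target_len = 200L,
#'   target_start = 10L, target_end = 100L, matches = 90L,
#'   block_len = 90L, mapq = 60L
#' )
#' covered_intervals(paf)
#' @export
covered_intervals <- function(blocks, min_mapq = 0L, seq_lengths = NULL) {
  blocks <- blocks[blocks$mapq >= min_mapq, , drop = FALSE]
  if (nrow(blocks) == 0L) return(GenomicRanges::GRanges())
  if (!is.null(seq_lengths)) {
    unknown <- setdiff(unique(blocks$target_id), names(seq_lengths))
    if (length(unknown)) {
      .stopf("alignment block on unknown template sequence: %s", unknown[1])
    }
    over <- blocks$target_end > seq_lengths[blocks$target_id]
    if (any(over)) {
      .stopf("alignment block beyond end of %s (%d > %d)",
             blocks$target_id[over][1], blocks$target_end[over][1],
             seq_lengths[blocks$target_id[over][1]])
    }
  }
  gr <- .gr0(blocks$target_id, blocks$target_start, blocks$target_end)
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Call differential reference regions
#'
#' Takes the complement of the covered set within each template sequence,
#' subtracts known assembly gaps (a gap may split an uncovered run into
#' pieces that individually fall below the size cutoff), and keeps segments
#' strictly larger than `cfg$min_drr_size`. Region identifiers are
#' deterministic: `DRR_<seq>_<0-based start>`.
#'
#' @param covered Covered template intervals from [covered_intervals()].
#' @param seq_lengths Named vector of template sequence lengths; must cover
#'   every sequence appearing in `covered` and `gaps`.
#' @param gaps Optional GRanges of known assembly gaps to exclude.
#' @param cfg A [drr_config()].
#' @param template_id,query_id Genome labels recorded on each call.
#' @return A sorted GRanges with metadata columns `drr_id`, `size`,
#'   `template_id` and `query_id`.
#' @examples
#' cov <- GenomicRanges::GRanges("t1", IRanges::IRanges(
#'   c(1, 45001), c(30000, 100000)))
#' call_drrs(cov, c(t1 = 100000))
#' @export
call_drrs <- function(covered, seq_lengths, gaps = NULL,
                      cfg = drr_config(),
                      template_id = "template", query_id = "query") {
  .assert_granges(covered, "covered")
  seq_ids <- names(seq_lengths)
  unknown <- setdiff(unique(as.character(seqnames(covered))), seq_ids)
  if (length(unknown)) .stopf("covered set on unknown sequence: %s", unknown[1])
  if (!is.null(gaps)) {
    .assert_granges(gaps, "gaps")
    unknown <- setdiff(unique(as.character(seqnames(gaps))), seq_ids)
    if (length(unknown)) .stopf("gap on unknown sequence: %s", unknown[1])
    out_of_bounds <- GenomicRanges::end(gaps) > seq_lengths[as.character(seqnames(gaps))] |
      GenomicRanges::start(gaps) < 1L
    if (any(out_of_bounds)) {
      .stopf("gap interval outside sequence bounds on %s",
             as.character(seqnames(gaps))[out_of_bounds][1])
    }
  }
  genome <- GenomicRanges::GRanges(seq_ids, IRanges::IRanges(1L, seq_lengths))
  GenomeInfoDb::seqlevels(genome) <- seq_ids
  uncovered <- GenomicRanges::setdiff(genome, .on_universe(covered, seq_ids))
  if (!is.null(gaps) && length(gaps)) {
    uncovered <- GenomicRanges::setdiff(uncovered, .on_universe(gaps, seq_ids))
  }
  drrs <- uncovered[GenomicRanges::width(uncovered) > cfg$min_drr_size]
  drrs <- GenomicRanges::sort(drrs)
  mcols(drrs)$drr_id <- sprintf("DRR_%s_%d",
                                as.character(seqnames(drrs)),
                                GenomicRanges::start(drrs) - 1L)
  mcols(drrs)$size <- GenomicRanges::width(drrs)
  mcols(drrs)$template_id <- rep(template_id, length(drrs))
  mcols(drrs)$query_id <- rep(query_id, length(drrs))
  drrs
}

#' Summarize a DRR set
#'
#' @param drrs A GRanges of DRRs from [call_drrs()].
#' @return A list with `n_regions`, `total_bp`, `min_bp`, `median_bp`
#'   (lower of the two central values for even counts) and `max_bp`. For an
#'   empty set the count and total are zero and the size statistics are
#'   `NA`.
#' @export
summarize_drrs <- function(drrs) {
  sizes <- if (length(drrs)) GenomicRanges::width(drrs) else integer(0)
  list(
    n_regions = length(sizes),
    total_bp = sum(as.numeric(sizes)),
    min_bp = if (length(sizes)) min(sizes) else NA_real_,
    median_bp = .lower_median(sizes),
    max_bp = if (length(sizes)) max(sizes) else NA_real_
  )
}

#' Multi-way shared-missing overlap of DRR sets
#'
#' Given DRR sets called against the same template from two or more query
#' genomes, computes (i) the intersection — template bases missing from
#' every query but present in the template — and (ii) the exclusive Venn
#' partition sizes in bp. Partition names join query labels with `&`; the
#' partition sizes sum to the size of the union of all sets.
#'
#' @param drr_sets Named list (length >= 2) of GRanges, one per query
#'   genome, all on the same template.
#' @return A list with elements `intersection` (GRanges) and `partitions`
#'   (named numeric vector of exclusive region sizes in bp).
#' @examples
#' sets <- list(
#'   q1 = GenomicRanges::GRanges("t1", IRanges::IRanges(1, 20000)),
#'   q2 = GenomicRanges::GRanges("t1", IRanges::IRanges(10001, 30000))
#' )
#' shared_missing(sets)
#' @export
shared_missing <- function(drr_sets) {
  if (!is.list(drr_sets) || length(drr_sets) < 2L) {
    .stopf("shared_missing needs at least 2 query DRR sets")
  }
  if (is.null(names(drr_sets)) || any(!nzchar(names(drr_sets)))) {
    names(drr_sets) <- paste0("Q", seq_along(drr_sets))
  }
  seq_ids <- sort(unique(unlist(lapply(drr_sets, function(g) {
    .assert_granges(g, "each DRR set")
    as.character(seqnames(g))
  }))))
  sets <- lapply(drr_sets, function(g) {
    GenomicRanges::reduce(.on_universe(g, seq_ids))
  })
  frags <- GenomicRanges::disjoin(unlist(GenomicRanges::GRangesList(sets)))
  membership <- vapply(sets, function(s) IRanges::overlapsAny(frags, s),
                       logical(length(frags)))
  membership <- matrix(membership, nrow = length(frags),
                       dimnames = list(NULL, names(sets)))
  key <- apply(membership, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  partitions <- tapply(as.numeric(GenomicRanges::width(frags)), key, sum)
  partitions <- setNames(as.numeric(partitions), names(partitions))
  intersection <- Reduce(GenomicRanges::intersect, sets)
  list(intersection = intersection, partitions = partitions)
}
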