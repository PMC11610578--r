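# Per-sample presence/absence of DRRs from short-read depth, cohort-level
# classification, and read mapping summaries. A DRR is present in a sample
# when its length-weighted mean depth lies strictly between the lower and
# upper bounds (defaults 8x and 100x); at or below the lower bound it is
# absent, and at or above the upper bound the region looks like a
# collapsed repeat and is not called. Boundary depths fall into the
# adjacent conservative class.

#' Length-weighted mean depth over a region
#'
#' Positions absent from the track count as depth 0.
#'
#' @param drr A length-1 GRanges (one DRR).
#' @param track A `depth_track` (see [read_depth_bedgraph()]).
#' @return Mean fold-coverage (x) over the region.
#' @examples
#' drr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' steps <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 501), c(500, 1000)), depth = c(10, 30))
#' mean_depth(drr, structure(list(sample_id = "s1", steps = steps),
#'                           class = "depth_track"))
#' @export
mean_depth <- function(drr, track) {
  .assert_granges(drr, "drr")
  if (length(drr) != 1L) .stopf("mean_depth takes one DRR at a time")
  steps <- track$steps
  if (is.null(steps) || length(steps) == 0L) return(0)
  seq_ids <- unique(c(as.character(seqnames(drr)), as.character(seqnames(steps))))
  depth <- mcols(steps)$depth
  steps_u <- .on_universe(steps, seq_ids)
  drr_u <- .on_universe(drr, seq_ids)
  hits <- GenomicRanges::findOverlaps(drr_u, steps_u)
  if (length(hits) == 0L) return(0)
  ov <- GenomicRanges::pintersect(steps_u[subjectHits(hits)],
                                  drr_u[queryHits(hits)])
  sum(as.numeric(GenomicRanges::width(ov)) * depth[subjectHits(hits)]) /
    GenomicRanges::width(drr)
}

#' Classify per-sample presence from mean depth
#'
#' @param depth Numeric vector of mean depths (x).
#' @param cfg A [drr_config()]; `presence_lo` and `presence_hi` set the
#'   open interval for a presence call.
#' @return Character vector: `"present"` (lo < depth < hi), `"absent"`
#'   (depth <= lo) or `"no_call"` (depth >= hi, collapsed repeat).
#' @examples
#' classify_presence(c(7.9, 30, 150, 8, 100))
#' @export
classify_presence <- function(depth, cfg = drr_config()) {
  if (any(depth < 0)) .stopf("mean depth must be non-negative")
  ifelse(depth >= cfg$presence_hi, "no_call",
         ifelse(depth <= cfg$presence_lo, "absent", "present"))
}

#' Cohort-level classification of one DRR
#'
#' The presence fraction counts presence calls over all samples (no-call
#' samples stay in the denominator, matching a fixed cohort size). Classes
#' partition DRRs: `not_detected` (no sample presents it), `rare` (present
#' in at most `common_frac` of the cohort) or `common` (more than
#' `common_frac`); `high_frequency` flags fractions above `high_frac`.
#'
#' @param status Character vector of per-sample presence statuses for one
#'   DRR (from [classify_presence()]).
#' @param cfg A [drr_config()].
#' @param drr_id Optional identifier carried through.
#' @return A list with `drr_id`, `n_present`, `n_total`, `presence_frac`,
#'   `class` and `high_frequency`.
#' @examples
#' population_class(rep(c("present", "absent"), c(6, 94)))$class
#' @export
population_class <- function(status, cfg = drr_config(), drr_id = NA_character_) {
  if (length(status) == 0L) .stopf("population_class needs at least one call")
  bad <- setdiff(unique(status), c("present", "absent", "no_call"))
  if (length(bad)) .stopf("unknown presence status: %s", bad[1])
  n_present <- sum(status == "present")
  n_total <- length(status)
  frac <- n_present / n_total
  cls <- if (n_present == 0L) "not_detected"
         else if (frac <= cfg$common_frac) "rare"
         else "common"
  list(
    drr_id = drr_id,
    n_present = n_present,
    n_total = n_total,
    presence_frac = frac,
    class = cls,
    high_frequency = frac > cfg$high_frac
  )
}

#' Per-sample presence calls over a DRR set
#'
#' @param drrs GRanges of DRRs with a `drr_id` metadata column.
#' @param tracks List of `depth_track` objects, one per sample.
#' @param cfg A [drr_config()].
#' @return A data.frame with columns `sample_id`, `drr_id`, `mean_depth`
#'   and `status`.
#' @export
call_presence <- function(drrs, tracks, cfg = drr_config()) {
  .assert_granges(drrs, "drrs")
  rows <- lapply(tracks, function(track) {
    depths <- vapply(seq_along(drrs), function(i) mean_depth(drrs[i], track),
                     numeric(1))
    data.frame(
      sample_id = track$sample_id,
      drr_id = mcols(drrs)$drr_id,
      mean_depth = depths,
      status = classify_presence(depths, cfg),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cohort table from per-sample presence calls
#'
#' @param presence A data.frame from [call_presence()].
#' @param cfg A [drr_config()].
#' @return One row per DRR with the [population_class()] fields.
#' @export
population_table <- function(presence, cfg = drr_config()) {
  rows <- lapply(split(presence, presence$drr_id), function(d) {
    as.data.frame(population_class(d$status, cfg, drr_id = d$drr_id[1]),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$drr_id), , drop = FALSE]
}

#' Mapping-quality and multimapping summary over a DRR
#'
#' Considers non-supplementary read records overlapping the DRR by at
#' least 1 bp and reports the fraction with mapping quality strictly above
#' the configured threshold and the fraction mapping to multiple genomic
#' locations.
#'
#' @param drr A length-1 GRanges (one DRR).
#' @param reads A GRanges of read records from [read_sam_reads()].
#' @param cfg A [drr_config()]; `mapq_threshold` defaults to 20.
#' @return A list with `n_reads`, `frac_mapq_gt_threshold`,
#'   `frac_multimapping` and `undefined` (`TRUE` with `NA` fractions when
#'   no read overlaps the region).
#' @export
mapping_summary <- function(drr, reads, cfg = drr_config()) {
  .assert_granges(drr, "drr")
  if (length(drr) != 1L) .stopf("mapping_summary takes one DRR at a time")
  .assert_granges(reads, "reads")
  keep <- !mcols(reads)$is_supplementary
  reads <- reads[keep]
  if (length(reads)) {
    seq_ids <- unique(c(as.character(seqnames(drr)), as.character(seqnames(reads))))
    ov <- IRanges::overlapsAny(.on_universe(reads, seq_ids),
                               .on_universe(drr, seq_ids))
    reads <- reads[ov]
  }
  if (length(reads) == 0L) {
    return(list(n_reads = 0L, frac_mapq_gt_threshold = NA_real_,
                frac_multimapping = NA_real_, undefined = TRUE))
  }
  list(
    n_reads = length(reads),
    frac_mapq_gt_threshold = mean(mcols(reads)$mapq > cfg$mapq_threshold),
    frac_multimapping = mean(mcols(reads)$n_alignments >= 2L),
    undefined = FALSE
  )
}
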