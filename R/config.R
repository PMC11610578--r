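#' Analysis configuration
#'
#' Collects every tunable threshold of the DRR and junction analysis in one
#' place. Defaults follow the published study conditions: DRRs must be
#' strictly larger than 10 kbp; a DRR counts as present in a sample when its
#' mean short-read depth lies strictly between 8x and 100x (above 100x the
#' region is treated as a collapsed repeat and not called); a DRR is common
#' in a cohort when present in more than 5% of samples and high-frequency
#' when present in more than 90%; read mapping quality is summarized against
#' a MAPQ 20 cutoff; genomic context uses a 10 kbp centromere proximity
#' window; junctions with >= 2 bp microhomology suggest MMEJ and junction
#' unbalances >= 100 bp (or >= 3 junctions) suggest replicative MMBIR.
#'
#' @param min_drr_size Minimum DRR size in bp (strictly greater than).
#' @param min_mapq_for_coverage Minimum alignment MAPQ for a block to count
#'   towards template coverage.
#' @param presence_lo Lower depth bound (x): mean depth must exceed this for
#'   a presence call; depth at or below it is an absence call.
#' @param presence_hi Upper depth bound (x): mean depth at or above it is a
#'   no-call (collapsed repeat).
#' @param common_frac Cohort presence fraction above which a DRR is common.
#' @param high_frac Cohort presence fraction above which a DRR is flagged
#'   high-frequency.
#' @param mapq_threshold MAPQ cutoff for the mapping-quality summary
#'   (fraction of reads with MAPQ strictly above it).
#' @param context_window Distance in bp within which a DRR counts as near a
#'   centromere.
#' @param mmej_min_mh Minimum microhomology (bp) for an MMEJ call.
#' @param mmbir_unbalance Minimum absolute junction indel (bp) for an MMBIR
#'   call.
#' @param complex_min_junctions Junction count at or above which a
#'   rearrangement is classified complex MMBIR.
#' @param nahr_min_identity Minimum paralog identity (fraction) between
#'   same-family repeats flanking both breakpoints for a NAHR call.
#' @param min_anchor Minimum exact anchor length (bp) required on each flank
#'   when resolving a breakpoint junction.
#' @param seed Integer seed recorded alongside the configuration.
#'
#' @return A list of class `drr_config`.
#' @examples
#' cfg <- drr_config()
#' cfg$min_drr_size
#' @export
drr_config <- function(min_drr_size = 10000L,
                       min_mapq_for_coverage = 0L,
                       presence_lo = 8,
                       presence_hi = 100,
                       common_frac = 0.05,
                       high_frac = 0.90,
                       mapq_threshold = 20L,
                       context_window = 10000L,
                       mmej_min_mh = 2L,
                       mmbir_unbalance = 100L,
                       complex_min_junctions = 3L,
                       nahr_min_identity = 0.95,
                       min_anchor = 15L,
                       seed = 1L) {
  if (!(presence_lo < presence_hi)) {
    .stopf("presence_lo (%s) must be below presence_hi (%s)", presence_lo, presence_hi)
  }
  if (!(common_frac > 0 && common_frac < high_frac && high_frac < 1)) {
    .stopf("need 0 < common_frac < high_frac < 1")
  }
  structure(
    list(
      min_drr_size = as.integer(min_drr_size),
      min_mapq_for_coverage = as.integer(min_mapq_for_coverage),
      presence_lo = presence_lo,
      presence_hi = presence_hi,
      common_frac = common_frac,
      high_frac = high_frac,
      mapq_threshold = as.integer(mapq_threshold),
      context_window = as.integer(context_window),
      mmej_min_mh = as.integer(mmej_min_mh),
      mmbir_unbalance = as.integer(mmbir_unbalance),
      complex_min_junctions = as.integer(complex_min_junctions),
      nahr_min_identity = nahr_min_identity,
      min_anchor = as.integer(min_anchor),
      seed = as.integer(seed)
    ),
    class = "drr_config"
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the study
#' conditions at desk scale: a template/query assembly pair differing by a
#' handful of implanted segments larger than 10 kbp of configurable repeat
#' content; a population depth panel of 100 samples sequenced to a 30x mean
#' (absent regions near 1x, collapsed repeats near 150x); and breakpoint
#' junction sequences with engineered microhomology (0-10 bp) or insertions
#' (0-50 bp).
#'
#' @param seed Integer seed; fixes every random stream of the generator.
#' @param n_chroms,chrom_len Number and length (bp) of template chromosomes.
#' @param n_drrs Total number of implanted differential segments.
#' @param drr_size_range Implant size range in bp (all above 10 kbp).
#' @param drr_repeat_fraction_range Range of the fraction of each implant
#'   covered by simple tandem-repeat arrays.
#' @param n_gaps_per_chrom,gap_len_range Assembly gaps (N runs) per
#'   chromosome and their length range in bp.
#' @param gc GC content of the random background sequence.
#' @param n_samples Population panel size.
#' @param depth_present_mean,depth_absent_mean,depth_collapsed_mean Poisson
#'   mean depth (x) of 100 bp steps over present, absent and collapsed-repeat
#'   DRRs respectively.
#' @param collapsed_prob Probability that a simulated DRR is a collapsed
#'   repeat (deep coverage in every sample).
#' @param presence_allele_freq_range Range of per-DRR population presence
#'   frequencies.
#' @param depth_step BedGraph step size in bp.
#' @param reads_per_drr Reads emitted per DRR in the per-sample SAM
#'   summaries.
#' @param n_mapq_samples Number of samples for which SAM read summaries are
#'   generated (mapping quality was assessed on a small subset of samples).
#' @param multimap_frac Fraction of simulated reads mapping to multiple
#'   locations.
#' @param mapq_gt_frac Fraction of simulated reads with MAPQ above 20.
#' @param mh_range,ins_range Junction microhomology and insertion length
#'   ranges in bp (one of the two is always zero for a given junction).
#' @param templated_prob Probability that a simulated insertion is copied
#'   from the breakpoint-proximal reference window rather than random.
#' @param flank_len,window_len Length (bp) of each junction flank and of the
#'   breakpoint-proximal reference windows.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 7, n_drrs = 2)
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_len = 500000L,
                       n_drrs = 3L,
                       drr_size_range = c(12000L, 20000L),
                       drr_repeat_fraction_range = c(0.3, 1),
                       n_gaps_per_chrom = 1L,
                       gap_len_range = c(2000L, 5000L),
                       gc = 0.41,
                       n_samples = 100L,
                       depth_present_mean = 30,
                       depth_absent_mean = 1,
                       depth_collapsed_mean = 150,
                       collapsed_prob = 0.05,
                       presence_allele_freq_range = c(0.05, 0.95),
                       depth_step = 100L,
                       reads_per_drr = 50L,
                       n_mapq_samples = 5L,
                       multimap_frac = 0.013,
                       mapq_gt_frac = 0.2,
                       mh_range = c(0L, 10L),
                       ins_range = c(0L, 50L),
                       templated_prob = 0.5,
                       flank_len = 200L,
                       window_len = 1000L) {
  stopifnot(
    n_chroms >= 1, chrom_len > 0, n_drrs >= 0,
    drr_size_range[1] <= drr_size_range[2],
    drr_repeat_fraction_range[1] >= 0, drr_repeat_fraction_range[2] <= 1,
    n_samples >= 1, depth_step >= 1,
    mh_range[1] >= 0, ins_range[1] >= 0,
    flank_len >= 30, window_len >= flank_len
  )
  structure(
    list(
      seed = as.integer(seed),
      n_chroms = as.integer(n_chroms),
      chrom_len = as.integer(chrom_len),
      n_drrs = as.integer(n_drrs),
      drr_size_range = as.integer(drr_size_range),
      drr_repeat_fraction_range = drr_repeat_fraction_range,
      n_gaps_per_chrom = as.integer(n_gaps_per_chrom),
      gap_len_range = as.integer(gap_len_range),
      gc = gc,
      n_samples = as.integer(n_samples),
      depth_present_mean = depth_present_mean,
      depth_absent_mean = depth_absent_mean,
      depth_collapsed_mean = depth_collapsed_mean,
      collapsed_prob = collapsed_prob,
      presence_allele_freq_range = presence_allele_freq_range,
      depth_step = as.integer(depth_step),
      reads_per_drr = as.integer(reads_per_drr),
      n_mapq_samples = as.integer(n_mapq_samples),
      multimap_frac = multimap_frac,
      mapq_gt_frac = mapq_gt_frac,
      mh_range = as.integer(mh_range),
      ins_range = as.integer(ins_range),
      templated_prob = templated_prob,
      flank_len = as.integer(flank_len),
      window_len = as.integer(window_len)
    ),
    class = "sim_config"
  )
}
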