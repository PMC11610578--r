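# Seeded synthetic inputs with matching truth: template/query assembly
# pairs differing by implanted segments, idealized alignment PAF, population
# depth panels, and engineered breakpoint junction sequences. Every stream
# is fixed by the configuration seed, so identical configurations give
# byte-identical outputs.

.MOTIF_ALPHABET <- c("A", "C", "G", "T")

# Random simple-repeat motif of length 2-6, e.g. "ATGG".
.rand_motif <- function() {
  len <- sample(2:6, 1L)
  repeat {
    m <- paste(sample(.MOTIF_ALPHABET, len, replace = TRUE), collapse = "")
    # avoid homopolymer-free degenerate motifs like "AAAA" collapsing into
    # longer accidental homology
    if (length(unique(strsplit(m, "")[[1]])) > 1L) return(m)
  }
}

.tandem_array <- function(motif, len) {
  full <- strrep(motif, ceiling(len / nchar(motif)))
  substr(full, 1L, len)
}

# Place n intervals of the given widths in [1, space_len] with at least
# `margin` bp between them and from both ends. Returns sorted starts or
# NULL when a placement attempt fails.
.place_intervals <- function(widths, space_len, margin, existing = NULL,
                             tries = 200L) {
  n <- length(widths)
  if (n == 0L) return(integer(0))
  for (t in seq_len(tries)) {
    starts <- sort(sample.int(space_len, n))
    cand <- IRanges::IRanges(start = starts, width = widths)
    ok <- max(IRanges::end(cand)) <= space_len - margin &&
      min(IRanges::start(cand)) > margin
    if (ok && n > 1L) {
      gaps_between <- IRanges::start(cand)[-1] - IRanges::end(cand)[-n]
      ok <- all(gaps_between > margin)
    }
    if (ok && !is.null(existing) && length(existing)) {
      padded <- IRanges::IRanges(pmax(IRanges::start(cand) - margin, 1L),
                                 IRanges::end(cand) + margin)
      ok <- !any(IRanges::overlapsAny(padded, existing))
    }
    if (ok) return(IRanges::start(cand))
  }
  NULL
}

#' Simulate a template/query reference assembly pair
#'
#' Generates a random template genome and a query genome equal to the
#' template with implanted segments removed; the implants are the truth
#' DRRs. Each implant carries simple tandem-repeat arrays covering a
#' configurable fraction of its bases, recorded as RepeatMasker-style
#' features; optional assembly gaps (runs of N) are placed in the shared
#' sequence and recorded in a gap set. Fully deterministic for a given
#' configuration seed.
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional directory; when given, writes `template.fa`,
#'   `query.fa`, `truth.bed`, `gaps.bed` and `repeats.out`.
#' @return A list of class `drr_sim`: `template` and `query`
#'   (DNAStringSet), `truth` (GRanges of implanted DRRs with `name` ids),
#'   `gaps` (GRanges), `repeats` (GRanges with `repeat_class`,
#'   `repeat_name`), `seq_lengths`, `query_lengths` and `cfg`.
#' @examples
#' sim <- simulate_reference_pair(sim_config(seed = 42, n_drrs = 2))
#' length(sim$truth)
#' @export
simulate_reference_pair <- function(cfg = sim_config(), outdir = NULL) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  margin <- 2000L
  # round-robin chromosome assignment keeps packing feasible
  drr_chrom <- if (cfg$n_drrs > 0) {
    chroms[(seq_len(cfg$n_drrs) - 1L) %% cfg$n_chroms + 1L]
  } else character(0)
  drr_sizes <- if (cfg$n_drrs > 0) {
    .sample_range(cfg$drr_size_range[1], cfg$drr_size_range[2], cfg$n_drrs)
  } else integer(0)
  for (ch in chroms) {
    if (sum(drr_sizes[drr_chrom == ch]) >= cfg$chrom_len / 2) {
      .stopf("infeasible packing: implants exceed half of %s", ch)
    }
  }
  template <- list(); query <- list()
  truth <- GenomicRanges::GRanges(); gaps <- GenomicRanges::GRanges()
  repeats <- GenomicRanges::GRanges()
  mcols(repeats)$repeat_class <- character(0)
  mcols(repeats)$repeat_name <- character(0)
  for (ch in chroms) {
    bases <- .rand_bases(cfg$chrom_len, cfg$gc)
    sizes <- drr_sizes[drr_chrom == ch]
    starts <- .place_intervals(sizes, cfg$chrom_len, margin)
    if (is.null(starts)) .stopf("infeasible packing of implants on %s", ch)
    implants <- IRanges::IRanges(start = starts, width = sizes)
    # fill implants with tandem-repeat arrays at the configured fraction
    for (i in seq_along(implants)) {
      s <- IRanges::start(implants)[i]; w <- IRanges::width(implants)[i]
      r <- runif(1, cfg$drr_repeat_fraction_range[1],
                 cfg$drr_repeat_fraction_range[2])
      rep_bp <- round(r * w)
      if (rep_bp > 0) {
        n_blocks <- if (rep_bp >= w) 1L else sample(1:3, 1L)
        cuts <- if (n_blocks > 1L) {
          sort(sample(seq_len(rep_bp - 1L), n_blocks - 1L))
        } else integer(0)
        block_lens <- diff(c(0L, cuts, rep_bp))
        block_lens <- block_lens[block_lens >= 2L]
        free <- w - sum(block_lens)
        # distribute non-repeat spacer around the blocks
        spacer <- if (length(block_lens) > 0L) {
          sp <- rep(free %/% (length(block_lens) + 1L), length(block_lens) + 1L)
          sp[1] <- sp[1] + free %% (length(block_lens) + 1L)
          sp
        } else free
        offset <- 0L
        for (b in seq_along(block_lens)) {
          offset <- offset + spacer[b]
          motif <- .rand_motif()
          arr <- .tandem_array(motif, block_lens[b])
          pos <- s + offset
          bases[pos:(pos + block_lens[b] - 1L)] <- strsplit(arr, "")[[1]]
          feat <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos, width = block_lens[b]))
          mcols(feat)$repeat_class <- "Simple_repeat"
          mcols(feat)$repeat_name <- sprintf("(%s)n", motif)
          repeats <- .cat_gr(repeats, feat)
          offset <- offset + block_lens[b]
        }
      }
    }
    # assembly gaps (N runs) in shared sequence, clear of the implants
    if (cfg$n_gaps_per_chrom > 0L) {
      glens <- .sample_range(cfg$gap_len_range[1], cfg$gap_len_range[2],
                             cfg$n_gaps_per_chrom)
      gstarts <- .place_intervals(glens, cfg$chrom_len, 1000L,
                                  existing = implants)
      if (is.null(gstarts)) .stopf("infeasible placement of gaps on %s", ch)
      for (g in seq_along(gstarts)) {
        bases[gstarts[g]:(gstarts[g] + glens[g] - 1L)] <- "N"
      }
      ggr <- GenomicRanges::GRanges(ch, IRanges::IRanges(gstarts, width = glens))
      gaps <- .cat_gr(gaps, GenomicRanges::sort(ggr))
    }
    template[[ch]] <- paste(bases, collapse = "")
    keep <- rep(TRUE, cfg$chrom_len)
    for (i in seq_along(implants)) {
      keep[IRanges::start(implants)[i]:IRanges::end(implants)[i]] <- FALSE
    }
    query[[ch]] <- paste(bases[keep], collapse = "")
    if (length(implants)) {
      tgr <- GenomicRanges::GRanges(ch, implants)
      mcols(tgr)$name <- sprintf("DRR_%s_%d", ch, IRanges::start(implants) - 1L)
      truth <- .cat_gr(truth, tgr)
    }
  }
  sim <- structure(
    list(
      template = Biostrings::DNAStringSet(unlist(template)),
      query = Biostrings::DNAStringSet(unlist(query)),
      truth = GenomicRanges::sort(truth),
      gaps = GenomicRanges::sort(gaps),
      repeats = GenomicRanges::sort(repeats),
      seq_lengths = setNames(rep(cfg$chrom_len, cfg$n_chroms), chroms),
      query_lengths = setNames(vapply(query, nchar, numeric(1))[chroms], chroms),
      cfg = cfg
    ),
    class = "drr_sim"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(sim$template, file.path(outdir, "template.fa"))
    Biostrings::writeXStringSet(sim$query, file.path(outdir, "query.fa"))
    write_bed(sim$truth, file.path(outdir, "truth.bed"))
    write_bed(sim$gaps, file.path(outdir, "gaps.bed"))
    write_repeatmasker_out(sim$repeats, file.path(outdir, "repeats.out"))
  }
  sim
}

#' Emit the idealized alignment of a simulated pair as PAF
#'
#' Stands in for the external whole-genome aligner: one exact alignment
#' block per maximal shared segment between template and query (split
#' around assembly gaps, which an aligner would not traverse), with
#' `matches = block_len` and MAPQ 60. Calling DRRs on this PAF recovers
#' the implanted truth intervals exactly.
#'
#' @param sim A `drr_sim` from [simulate_reference_pair()].
#' @param path Optional output path for the PAF file.
#' @return A data.frame of alignment blocks in [read_paf()] layout.
#' @export
emit_truth_paf <- function(sim, path = NULL) {
  if (!inherits(sim, "drr_sim")) .stopf("sim must come from simulate_reference_pair")
  chroms <- names(sim$seq_lengths)
  rows <- list()
  for (ch in chroms) {
    len <- sim$seq_lengths[[ch]]
    implants <- sim$truth[seqnames(sim$truth) == ch]
    chrom_gaps <- sim$gaps[seqnames(sim$gaps) == ch]
    excluded <- GenomicRanges::reduce(.on_universe(c(
      GenomicRanges::granges(implants), GenomicRanges::granges(chrom_gaps)
    ), ch))
    whole <- GenomicRanges::GRanges(ch, IRanges::IRanges(1L, len))
    GenomeInfoDb::seqlevels(whole) <- ch
    shared <- GenomicRanges::setdiff(whole, excluded)
    if (length(shared) == 0L) next
    imp_starts <- GenomicRanges::start(implants)
    imp_widths <- GenomicRanges::width(implants)
    implanted_before <- function(pos) {
      sum(imp_widths[imp_starts < pos])
    }
    qlen <- sim$query_lengths[[ch]]
    for (i in seq_along(shared)) {
      s <- GenomicRanges::start(shared)[i]; e <- GenomicRanges::end(shared)[i]
      qs0 <- (s - 1L) - implanted_before(s)
      w <- e - s + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = ch, query_len = qlen, query_start = qs0, query_end = qs0 + w,
        strand = "+", target_id = ch, target_len = len,
        target_start = s - 1L, target_end = e,
        matches = w, block_len = w, mapq = 60L,
        stringsAsFactors = FALSE
      )
    }
  }
  paf <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(paf)) {
    paf <- data.frame(
      query_id = character(), query_len = integer(), query_start = integer(),
      query_end = integer(), strand = character(), target_id = character(),
      target_len = integer(), target_start = integer(), target_end = integer(),
      matches = integer(), block_len = integer(), mapq = integer(),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(path)) write_paf(paf, path)
  paf
}

#' Simulate a population depth panel over the truth DRRs
#'
#' Draws, for each truth DRR, either a collapsed-repeat state (deep
#' coverage in every sample) or a population presence frequency, then a
#' per-sample genotype at that frequency. Depth over each DRR is emitted
#' as fixed-size BedGraph steps with Poisson counts around the present,
#' absent or collapsed mean. SAM-text read summaries (mapping quality and
#' hit counts) are generated for a small subset of samples.
#'
#' @param sim A `drr_sim` from [simulate_reference_pair()].
#' @param cfg A [sim_config()]; defaults to the one inside `sim`.
#' @param outdir Optional directory; when given, writes one
#'   `<sample>.bedgraph` per sample, one `<sample>.sam` per mapping-quality
#'   sample, and `genotypes.tsv`.
#' @return A list of class `depth_panel`: `genotypes` (samples x DRRs
#'   character matrix with values `present`, `absent`, `collapsed`),
#'   `allele_freq` (per-DRR presence frequency, `NA` for collapsed),
#'   `tracks` (list of `depth_track`), `reads` (per mapping-quality sample,
#'   a GRanges of read records) and `cfg`.
#' @export
simulate_depth_panel <- function(sim, cfg = sim$cfg, outdir = NULL) {
  if (!inherits(sim, "drr_sim")) .stopf("sim must come from simulate_reference_pair")
  drrs <- sim$truth
  if (length(drrs) == 0L) .stopf("simulated pair has no truth DRRs")
  set.seed(cfg$seed + 7919L)
  n_drr <- length(drrs)
  drr_ids <- mcols(drrs)$name
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  collapsed <- runif(n_drr) < cfg$collapsed_prob
  freq <- ifelse(collapsed, NA_real_,
                 runif(n_drr, cfg$presence_allele_freq_range[1],
                       cfg$presence_allele_freq_range[2]))
  genotypes <- matrix(NA_character_, cfg$n_samples, n_drr,
                      dimnames = list(samples, drr_ids))
  for (j in seq_len(n_drr)) {
    genotypes[, j] <- if (collapsed[j]) "collapsed"
    else ifelse(runif(cfg$n_samples) < freq[j], "present", "absent")
  }
  mean_of <- c(present = cfg$depth_present_mean,
               absent = cfg$depth_absent_mean,
               collapsed = cfg$depth_collapsed_mean)
  tracks <- lapply(seq_len(cfg$n_samples), function(s) {
    step_gr <- GenomicRanges::GRanges()
    for (j in seq_len(n_drr)) {
      s1 <- GenomicRanges::start(drrs)[j]; e1 <- GenomicRanges::end(drrs)[j]
      starts <- seq(s1, e1, by = cfg$depth_step)
      ends <- pmin(starts + cfg$depth_step - 1L, e1)
      depth <- rpois(length(starts), mean_of[[genotypes[s, j]]])
      g <- GenomicRanges::GRanges(as.character(seqnames(drrs))[j],
                                  IRanges::IRanges(starts, ends))
      mcols(g)$depth <- as.numeric(depth)
      step_gr <- .cat_gr(step_gr, g)
    }
    structure(list(sample_id = samples[s], steps = GenomicRanges::sort(step_gr)),
              class = "depth_track")
  })
  names(tracks) <- samples
  read_len <- 150L
  n_mapq <- min(cfg$n_mapq_samples, cfg$n_samples)
  reads <- lapply(seq_len(n_mapq), function(s) {
    gr <- GenomicRanges::GRanges()
    for (j in seq_len(n_drr)) {
      n <- cfg$reads_per_drr
      s1 <- GenomicRanges::start(drrs)[j]; e1 <- GenomicRanges::end(drrs)[j]
      starts <- sample(seq(s1, max(s1, e1 - read_len)), n, replace = TRUE)
      hi <- runif(n) < cfg$mapq_gt_frac
      mapq <- ifelse(hi, sample(21:60, n, replace = TRUE),
                     sample(0:20, n, replace = TRUE))
      multi <- runif(n) < cfg$multimap_frac
      n_aln <- ifelse(multi, sample(2:5, n, replace = TRUE), 1L)
      g <- GenomicRanges::GRanges(as.character(seqnames(drrs))[j],
                                  IRanges::IRanges(starts, width = read_len))
      mcols(g)$read_id <- sprintf("%s_%s_r%04d", samples[s], drr_ids[j], seq_len(n))
      mcols(g)$mapq <- as.integer(mapq)
      mcols(g)$n_alignments <- as.integer(n_aln)
      mcols(g)$is_supplementary <- FALSE
      gr <- .cat_gr(gr, g)
    }
    gr
  })
  names(reads) <- samples[seq_len(n_mapq)]
  panel <- structure(
    list(genotypes = genotypes, allele_freq = freq, collapsed = collapsed,
         tracks = tracks, reads = reads, cfg = cfg),
    class = "depth_panel"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (tr in tracks) {
      write_depth_bedgraph(tr, file.path(outdir, paste0(tr$sample_id, ".bedgraph")))
    }
    for (sid in names(reads)) {
      .write_sam(reads[[sid]], sim$seq_lengths,
                 file.path(outdir, paste0(sid, ".sam")))
    }
    geno <- data.frame(sample_id = rownames(genotypes), genotypes,
                       check.names = FALSE, stringsAsFactors = FALSE)
    write.table(geno, file.path(outdir, "genotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  panel
}

# Minimal SAM text writer for simulated read summaries.
.write_sam <- function(reads, seq_lengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths), seq_lengths))
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
                  mcols(reads)$read_id,
                  ifelse(mcols(reads)$is_supplementary, 2048L, 0L),
                  as.character(seqnames(reads)),
                  GenomicRanges::start(reads),
                  mcols(reads)$mapq,
                  GenomicRanges::width(reads),
                  mcols(reads)$n_alignments)
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Simulate a breakpoint junction with engineered features
#'
#' Builds two reference windows, takes flank A as the end of the first and
#' flank B as the start of the second, and joins them into a derivative
#' sequence with either an engineered microhomology (the flank ends are
#' made to share exactly `mh` bases) or an engineered insertion (copied
#' from a reference window for templated insertions, or random sequence
#' verified to have no window match). Microhomology and insertion are
#' mutually exclusive.
#'
#' @param cfg A [sim_config()]; supplies length ranges and the templated
#'   probability when `mh`/`ins_len`/`kind` are not given.
#' @param mh Microhomology length in bp, or `NULL` to draw from
#'   `cfg$mh_range`.
#' @param ins_len Insertion length in bp, or `NULL` to draw from
#'   `cfg$ins_range`. At most one of `mh` and `ins_len` may be positive.
#' @param kind `"templated"` or `"random"` for a positive insertion;
#'   insertions shorter than 6 bp are always templated (any such short
#'   sequence occurs in a kbp-scale reference window by chance, so a
#'   "random" label would be unverifiable).
#' @param seed Seed for this junction; defaults to `cfg$seed`.
#' @return A list of class `junction_sim`: `derivative`, `flank_a`,
#'   `flank_b`, `windows` (named character vector of the two reference
#'   windows) and `truth` (list with `mh`, `ins_len`, `kind`, `pos_a`,
#'   `pos_b`).
#' @examples
#' js <- simulate_junction(sim_config(), mh = 3, ins_len = 0, seed = 11)
#' resolve_junction(js$derivative, js$flank_a, js$flank_b)$microhomology_len
#' @export
simulate_junction <- function(cfg = sim_config(), mh = NULL, ins_len = NULL,
                              kind = NULL, seed = cfg$seed) {
  set.seed(seed)
  if (is.null(mh) && is.null(ins_len)) {
    if (runif(1) < 0.5) {
      mh <- .sample_range(cfg$mh_range[1], cfg$mh_range[2]); ins_len <- 0L
    } else {
      ins_len <- .sample_range(cfg$ins_range[1], cfg$ins_range[2]); mh <- 0L
    }
  }
  mh <- as.integer(mh %||% 0L); ins_len <- as.integer(ins_len %||% 0L)
  if (mh > 0L && ins_len > 0L) {
    .stopf("a junction cannot have both microhomology and an insertion")
  }
  if (ins_len > 0L) {
    if (is.null(kind)) {
      kind <- if (ins_len < 6L) "templated"
      else if (runif(1) < cfg$templated_prob) "templated" else "random"
    }
    if (kind == "random" && ins_len < 6L) {
      .stopf("random insertions shorter than 6 bp are not constructible")
    }
  } else {
    kind <- "none"
  }
  wl <- cfg$window_len; fl <- cfg$flank_len
  for (try in seq_len(500L)) {
    ref_a <- paste(.rand_bases(wl, cfg$gc), collapse = "")
    ref_b_chars <- .rand_bases(wl, cfg$gc)
    if (mh > 0L) {
      # engineer the microhomology: flank B starts with the last mh bases
      # of flank A
      tail_a <- strsplit(substr(ref_a, wl - mh + 1L, wl), "")[[1]]
      ref_b_chars[seq_len(mh)] <- tail_a
    }
    ref_b <- paste(ref_b_chars, collapse = "")
    flank_a <- substr(ref_a, wl - fl + 1L, wl)
    flank_b <- substr(ref_b, 1L, fl)
    if (ins_len > 0L) break
    # for microhomology/blunt junctions the engineered overlap must be the
    # maximal one, so the truth is the unique physical answer
    if (.max_suffix_prefix(flank_a, flank_b) == mh) break
    if (try == 500L) .stopf("could not engineer a junction with mh = %d", mh)
  }
  insertion <- ""
  if (ins_len > 0L) {
    if (kind == "templated") {
      src <- if (runif(1) < 0.5) ref_a else ref_b
      pos <- sample.int(wl - ins_len + 1L, 1L)
      insertion <- substr(src, pos, pos + ins_len - 1L)
      if (runif(1) < 0.5) {
        insertion <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(insertion)))
      }
    } else {
      ok <- FALSE
      for (try in seq_len(500L)) {
        insertion <- paste(sample(.MOTIF_ALPHABET, ins_len, replace = TRUE),
                           collapse = "")
        if (classify_insertion(insertion, c(ref_a, ref_b)) == "random") {
          ok <- TRUE; break
        }
      }
      if (!ok) .stopf("could not generate a %d bp random insertion", ins_len)
    }
  }
  derivative <- if (mh > 0L) {
    paste0(flank_a, substr(flank_b, mh + 1L, fl))
  } else {
    paste0(flank_a, insertion, flank_b)
  }
  structure(
    list(
      derivative = derivative,
      flank_a = flank_a,
      flank_b = flank_b,
      windows = c(a = ref_a, b = ref_b),
      truth = list(mh = mh, ins_len = ins_len, kind = kind,
                   pos_a = wl, pos_b = 1L)
    ),
    class = "junction_sim"
  )
}
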