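test_that("simulate_reference_pair implants sized segments with truth records", {
  cfg <- sim_config(seed = 4, n_drrs = 3, drr_size_range = c(12000, 20000))
  sim <- simulate_reference_pair(cfg)
  expect_equal(length(sim$truth), 3L)
  expect_true(all(GenomicRanges::width(sim$truth) > 10000))
  expect_true(all(GenomicRanges::width(sim$truth) >= 12000))
  expect_true(all(GenomicRanges::width(sim$truth) <= 20000))
  # query lengths shrink by exactly the implanted bp per chromosome
  for (ch in names(sim$seq_lengths)) {
    implanted <- sum(GenomicRanges::width(
      sim$truth[GenomicRanges::seqnames(sim$truth) == ch]))
    expect_equal(sim$query_lengths[[ch]], sim$seq_lengths[[ch]] - implanted)
  }
  # repeat features stay inside the implants
  expect_true(all(IRanges::overlapsAny(sim$repeats, sim$truth, type = "within")))
})

test_that("repeat fraction 1 tiles implants completely", {
  cfg <- sim_config(seed = 6, n_drrs = 2, drr_repeat_fraction_range = c(1, 1))
  sim <- simulate_reference_pair(cfg)
  for (i in seq_along(sim$truth)) {
    comp <- repeat_composition(sim$truth[i], sim$repeats)
    expect_equal(comp$total_repeat_fraction, 1)
  }
})

test_that("simulation is byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 77, n_drrs = 2, n_chroms = 1, chrom_len = 100000L)
  d1 <- file.path(tempdir(), "sim_rep1"); d2 <- file.path(tempdir(), "sim_rep2")
  simulate_reference_pair(cfg, outdir = d1)
  simulate_reference_pair(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("infeasible packing is a contract error", {
  cfg <- sim_config(seed = 1, n_chroms = 1, chrom_len = 60000L, n_drrs = 3,
                    drr_size_range = c(12000, 12000))
  expect_error(simulate_reference_pair(cfg), "packing")
})

test_that("emit_truth_paf reconstructs coverage that recovers the truth", {
  cfg <- sim_config(seed = 8, n_drrs = 3)
  sim <- simulate_reference_pair(cfg)
  paf_path <- tempfile(fileext = ".paf")
  paf <- emit_truth_paf(sim, path = paf_path)
  # blocks flank each implant: n_drrs + gaps split blocks further
  expect_true(all(paf$matches == paf$block_len))
  expect_true(all(paf$mapq == 60L))
  # round trip through the file format
  back <- read_paf(paf_path)
  expect_equal(back$target_start, paf$target_start)
  drrs <- call_drrs(covered_intervals(back), sim$seq_lengths, gaps = sim$gaps)
  expect_equal(GenomicRanges::start(drrs), GenomicRanges::start(sim$truth))
  expect_equal(GenomicRanges::end(drrs), GenomicRanges::end(sim$truth))
})

test_that("a pair without implants aligns end to end and yields no DRRs", {
  cfg <- sim_config(seed = 9, n_drrs = 0, n_gaps_per_chrom = 0)
  sim <- simulate_reference_pair(cfg)
  paf <- emit_truth_paf(sim)
  expect_equal(nrow(paf), cfg$n_chroms)
  expect_equal(paf$target_start, rep(0L, cfg$n_chroms))
  expect_equal(paf$target_end, unname(sim$seq_lengths))
  drrs <- call_drrs(covered_intervals(paf), sim$seq_lengths)
  expect_equal(length(drrs), 0L)
})

test_that("an implant at the chromosome start leaves a single flanking block", {
  truth <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 15000))
  S4Vectors::mcols(truth)$name <- "DRR_chr1_0"
  sim <- structure(list(
    truth = truth,
    gaps = GenomicRanges::GRanges(),
    seq_lengths = c(chr1 = 100000),
    query_lengths = c(chr1 = 85000),
    cfg = sim_config()
  ), class = "drr_sim")
  paf <- emit_truth_paf(sim)
  expect_equal(nrow(paf), 1L)
  expect_equal(paf$target_start, 15000L)
  expect_equal(paf$target_end, 100000L)
  expect_equal(paf$query_start, 0L)
})

test_that("depth panel genotypes drive depth classes as configured", {
  sim <- simulate_reference_pair(sim_config(seed = 21, n_drrs = 3))
  cfg <- sim_config(seed = 21, n_drrs = 3, n_samples = 25,
                    collapsed_prob = 0, depth_absent_mean = 1)
  panel <- simulate_depth_panel(sim, cfg)
  drrs <- sim$truth
  S4Vectors::mcols(drrs)$drr_id <- S4Vectors::mcols(drrs)$name
  # absent genotypes give mean depth below the 8x cutoff
  for (s in rownames(panel$genotypes)[1:5]) {
    for (j in seq_along(drrs)) {
      md <- mean_depth(drrs[j], panel$tracks[[s]])
      if (panel$genotypes[s, j] == "absent") expect_lt(md, 8)
      if (panel$genotypes[s, j] == "present") expect_gt(md, 8)
    }
  }
  # collapsed regions become no_call
  cfg2 <- sim_config(seed = 22, n_drrs = 3, n_samples = 5, collapsed_prob = 1)
  panel2 <- simulate_depth_panel(sim, cfg2)
  md <- mean_depth(drrs[1], panel2$tracks[[1]])
  expect_equal(classify_presence(md), "no_call")
})

test_that("cohort presence fraction tracks the configured allele frequency", {
  sim <- simulate_reference_pair(sim_config(seed = 31, n_drrs = 3))
  cfg <- sim_config(seed = 31, n_drrs = 3, n_samples = 60, collapsed_prob = 0,
                    presence_allele_freq_range = c(0.4, 0.4))
  panel <- simulate_depth_panel(sim, cfg)
  drrs <- sim$truth
  S4Vectors::mcols(drrs)$drr_id <- S4Vectors::mcols(drrs)$name
  tab <- population_table(call_presence(drrs, panel$tracks))
  se <- sqrt(0.4 * 0.6 / 60)
  expect_true(all(abs(tab$presence_frac - 0.4) <= 3 * se))
})

test_that("depth panel writes BedGraph and SAM files that read back", {
  sim <- simulate_reference_pair(sim_config(seed = 41, n_drrs = 2))
  cfg <- sim_config(seed = 41, n_drrs = 2, n_samples = 3, n_mapq_samples = 2)
  outdir <- file.path(tempdir(), "panel_out")
  panel <- simulate_depth_panel(sim, cfg, outdir = outdir)
  track <- read_depth_bedgraph(file.path(outdir, "S001.bedgraph"), "S001")
  expect_equal(length(track$steps), length(panel$tracks[["S001"]]$steps))
  reads <- read_sam_reads(file.path(outdir, "S001.sam"))
  expect_equal(length(reads), length(panel$reads[["S001"]]))
  expect_equal(sum(S4Vectors::mcols(reads)$n_alignments >= 2),
               sum(S4Vectors::mcols(panel$reads[["S001"]])$n_alignments >= 2))
})

test_that("simulate_junction engineers the requested junction structure", {
  cfg <- sim_config()
  js <- simulate_junction(cfg, mh = 3, ins_len = 0, seed = 51)
  expect_equal(substr(js$flank_a, nchar(js$flank_a) - 2, nchar(js$flank_a)),
               substr(js$flank_b, 1, 3))
  expect_equal(nchar(js$derivative), 2 * cfg$flank_len - 3)

  ji <- simulate_junction(cfg, mh = 0, ins_len = 17, kind = "templated", seed = 52)
  jc <- resolve_junction(ji$derivative, ji$flank_a, ji$flank_b)
  expect_equal(jc$insertion_len, 17L)
  expect_equal(classify_insertion(jc$insertion_seq, ji$windows), "templated")

  jr <- simulate_junction(cfg, mh = 0, ins_len = 23, kind = "random", seed = 53)
  jcr <- resolve_junction(jr$derivative, jr$flank_a, jr$flank_b)
  expect_equal(classify_insertion(jcr$insertion_seq, jr$windows), "random")

  jb <- simulate_junction(cfg, mh = 0, ins_len = 0, seed = 54)
  expect_equal(jb$derivative, paste0(jb$flank_a, jb$flank_b))

  expect_error(simulate_junction(cfg, mh = 2, ins_len = 5, seed = 55),
               "cannot have both")
})
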