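paf_row <- function(target_id, start0, end0, mapq = 60L, target_len = 200000L) {
  w <- end0 - start0
  data.frame(query_id = "q", query_len = w, query_start = 0L, query_end = w,
             strand = "+", target_id = target_id, target_len = target_len,
             target_start = start0, target_end = end0,
             matches = w, block_len = w, mapq = mapq,
             stringsAsFactors = FALSE)
}

test_that("covered_intervals unions blocks per sequence with a MAPQ filter", {
  blocks <- rbind(paf_row("t1", 10, 60), paf_row("t1", 50, 100),
                  paf_row("t2", 0, 40))
  cov <- covered_intervals(blocks)
  t1 <- cov[GenomicRanges::seqnames(cov) == "t1"]
  expect_equal(GenomicRanges::start(t1), 11L)
  expect_equal(GenomicRanges::end(t1), 100L)
  t2 <- cov[GenomicRanges::seqnames(cov) == "t2"]
  expect_equal(GenomicRanges::width(t2), 40L)

  low <- paf_row("t1", 0, 10, mapq = 0L)
  expect_equal(length(covered_intervals(low, min_mapq = 20L)), 0L)

  beyond <- paf_row("t1", 0, 300000)
  expect_error(covered_intervals(beyond, seq_lengths = c(t1 = 200000)),
               "beyond end")
})

test_that("call_drrs complements coverage, subtracts gaps and size-filters", {
  cov <- GenomicRanges::GRanges("t1", IRanges::IRanges(c(1, 45001), c(30000, 100000)))
  drrs <- call_drrs(cov, c(t1 = 100000))
  expect_equal(length(drrs), 1L)
  expect_equal(GenomicRanges::start(drrs), 30001L)
  expect_equal(GenomicRanges::end(drrs), 45000L)
  expect_equal(S4Vectors::mcols(drrs)$size, 15000L)
  expect_equal(S4Vectors::mcols(drrs)$drr_id, "DRR_t1_30000")

  # a gap splits the uncovered run and is excluded from the total
  cov2 <- GenomicRanges::GRanges("t1", IRanges::IRanges(1, 20000))
  gap <- GenomicRanges::GRanges("t1", IRanges::IRanges(50001, 60000))
  drrs2 <- call_drrs(cov2, c(t1 = 100000), gaps = gap)
  expect_equal(GenomicRanges::start(drrs2), c(20001L, 60001L))
  expect_equal(GenomicRanges::end(drrs2), c(50000L, 100000L))
  expect_equal(sum(S4Vectors::mcols(drrs2)$size), 70000L)

  expect_error(
    call_drrs(cov2, c(t1 = 100000),
              gaps = GenomicRanges::GRanges("t1", IRanges::IRanges(99001, 101000))),
    "outside sequence bounds")
})

test_that("the 10 kbp size cutoff is strict", {
  # uncovered runs of exactly 10000 and 10001 bp
  cov <- GenomicRanges::GRanges("t1", IRanges::IRanges(c(1, 20001, 40002),
                                                       c(10000, 30000, 100000)))
  drrs <- call_drrs(cov, c(t1 = 100000))
  expect_equal(length(drrs), 1L)
  expect_equal(S4Vectors::mcols(drrs)$size, 10001L)
})

test_that("self-comparison coverage yields zero DRRs", {
  cov <- GenomicRanges::GRanges(c("t1", "t2"), IRanges::IRanges(1, c(100000, 50000)))
  drrs <- call_drrs(cov, c(t1 = 100000, t2 = 50000))
  expect_equal(length(drrs), 0L)
  s <- summarize_drrs(drrs)
  expect_equal(s$n_regions, 0L)
  expect_equal(s$total_bp, 0)
})

test_that("summarize_drrs reports count, total and lower-median sizes", {
  gr <- GenomicRanges::GRanges("t1", IRanges::IRanges(1, 15000))
  expect_equal(summarize_drrs(gr)[c("n_regions", "total_bp", "median_bp")],
               list(n_regions = 1L, total_bp = 15000, median_bp = 15000L))

  gr3 <- GenomicRanges::GRanges("t1", IRanges::IRanges(c(1, 20001, 60001),
                                width = c(10001, 20000, 30000)))
  s <- summarize_drrs(gr3)
  expect_equal(s$n_regions, 3L)
  expect_equal(s$total_bp, 60001)
  expect_equal(s$median_bp, 20000L)

  # even count: lower of the two central values
  gr4 <- GenomicRanges::GRanges("t1", IRanges::IRanges(c(1, 2, 3, 4) * 100000,
                                width = c(11000, 12000, 13000, 14000)))
  expect_equal(summarize_drrs(gr4)$median_bp, 12000L)
})

test_that("shared_missing computes intersections and Venn partitions", {
  sets <- list(q1 = GenomicRanges::GRanges("t1", IRanges::IRanges(1, 20000)),
               q2 = GenomicRanges::GRanges("t1", IRanges::IRanges(10001, 30000)))
  sm <- shared_missing(sets)
  expect_equal(GenomicRanges::start(sm$intersection), 10001L)
  expect_equal(GenomicRanges::end(sm$intersection), 20000L)
  expect_equal(sm$partitions[["q1"]], 10000)
  expect_equal(sm$partitions[["q2"]], 10000)
  expect_equal(sm$partitions[["q1&q2"]], 10000)

  same <- shared_missing(list(a = sets$q1, b = sets$q1))
  expect_equal(names(same$partitions), "a&b")
  expect_equal(sum(same$partitions), 20000)

  disjoint <- shared_missing(list(
    a = GenomicRanges::GRanges("t1", IRanges::IRanges(1, 100)),
    b = GenomicRanges::GRanges("t1", IRanges::IRanges(201, 300))))
  expect_equal(length(disjoint$intersection), 0L)

  expect_error(shared_missing(list(only = sets$q1)), "at least 2")
})

test_that("three-way shared_missing matches the per-base bitmask oracle", {
  set.seed(7)
  mk <- function() {
    n <- sample(2:5, 1)
    starts <- sort(sample.int(900, n))
    GenomicRanges::reduce(GenomicRanges::GRanges("t1",
      IRanges::IRanges(starts, width = sample(20:120, n, replace = TRUE))))
  }
  for (rep in 1:10) {
    sets <- list(q1 = mk(), q2 = mk(), q3 = mk())
    sm <- shared_missing(sets)
    oracle <- oracle_shared_missing(sets, "t1", 1100)
    expect_equal(sm$partitions[sort(names(sm$partitions))],
                 oracle[sort(names(oracle))])
    # partitions sum to the union size
    union_bp <- sum(GenomicRanges::width(GenomicRanges::reduce(
      unlist(GenomicRanges::GRangesList(sets)))))
    expect_equal(sum(sm$partitions), union_bp)
  }
})

test_that("call_drrs matches the per-base oracle on random inputs", {
  set.seed(11)
  for (rep in 1:8) {
    len <- sample(50000:100000, 1)
    n <- sample(3:10, 1)
    starts <- sort(sample.int(len - 2000, n))
    blocks <- do.call(rbind, lapply(starts, function(s) {
      paf_row("t1", s, min(s + sample(500:20000, 1), len), target_len = len)
    }))
    gaps <- GenomicRanges::GRanges("t1",
      IRanges::IRanges(sample.int(len - 5000, 2), width = c(1500, 3000)))
    gaps <- GenomicRanges::reduce(gaps)
    cfg <- drr_config(min_drr_size = 5000L)
    drrs <- call_drrs(covered_intervals(blocks), c(t1 = len), gaps = gaps, cfg = cfg)
    oracle <- oracle_call_drrs(blocks, c(t1 = len), gaps, min_size = 5000L)
    expect_equal(GenomicRanges::start(drrs), oracle$start)
    expect_equal(GenomicRanges::end(drrs), oracle$end)
  }
})

test_that("coverage, gaps, DRRs and subthreshold pieces partition the genome", {
  set.seed(23)
  for (rep in 1:6) {
    len <- 80000
    blocks <- do.call(rbind, lapply(1:6, function(i) {
      s <- sample.int(len - 500, 1)
      paf_row("t1", s, min(s + sample(100:15000, 1), len), target_len = len)
    }))
    gaps <- GenomicRanges::reduce(GenomicRanges::GRanges("t1",
      IRanges::IRanges(sample.int(len - 3000, 2), width = c(800, 2000))))
    cov <- covered_intervals(blocks)
    cfg <- drr_config(min_drr_size = 4000L)
    drrs <- call_drrs(cov, c(t1 = len), gaps = gaps, cfg = cfg)
    # covered-or-gap bases counted once + kept DRRs + subthreshold uncovered
    genome <- GenomicRanges::GRanges("t1", IRanges::IRanges(1, len))
    GenomeInfoDb::seqlevels(genome) <- "t1"
    cov_or_gap <- GenomicRanges::reduce(c(cov, gaps))
    uncovered <- GenomicRanges::setdiff(genome, cov_or_gap)
    sub_bp <- sum(GenomicRanges::width(uncovered)[
      GenomicRanges::width(uncovered) <= cfg$min_drr_size])
    expect_equal(sum(GenomicRanges::width(cov_or_gap)) +
                   sum(GenomicRanges::width(drrs)) + sub_bp, len)
  }
})

test_that("DRR calling is invariant to block order and monotone in min size", {
  set.seed(31)
  len <- 60000
  blocks <- do.call(rbind, lapply(1:8, function(i) {
    s <- sample.int(len - 500, 1)
    paf_row("t1", s, min(s + sample(100:9000, 1), len), target_len = len)
  }))
  shuffled <- blocks[sample.int(nrow(blocks)), , drop = FALSE]
  a <- call_drrs(covered_intervals(blocks), c(t1 = len))
  b <- call_drrs(covered_intervals(shuffled), c(t1 = len))
  expect_identical(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_identical(GenomicRanges::end(a), GenomicRanges::end(b))

  sizes <- c(1000L, 4000L, 8000L, 12000L)
  counts <- vapply(sizes, function(ms) {
    length(call_drrs(covered_intervals(blocks), c(t1 = len),
                     cfg = drr_config(min_drr_size = ms)))
  }, integer(1))
  totals <- vapply(sizes, function(ms) {
    summarize_drrs(call_drrs(covered_intervals(blocks), c(t1 = len),
                             cfg = drr_config(min_drr_size = ms)))$total_bp
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(diff(totals) <= 0))
})
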