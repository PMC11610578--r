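# Readers and writers for the standard formats the pipeline touches. File
# formats with 0-based half-open coordinates (PAF, BED, BedGraph) are
# converted to/from GRanges at this boundary only; RepeatMasker .out is
# 1-based inclusive and maps to GRanges coordinates unchanged.

.REPEAT_CLASSES <- c("LINE", "SINE", "LTR", "DNA", "Simple_repeat",
                     "Satellite", "Low_complexity", "Other")

#' Read a PAF pairwise-alignment file
#'
#' Parses the 12 mandatory tab-separated PAF columns emitted by whole-genome
#' aligners such as minimap2. Optional SAM-style tags beyond column 12 are
#' ignored; no primary/secondary filtering happens at parse time (coverage
#' filtering is a downstream policy, see [covered_intervals()]).
#'
#' @param path Path to a PAF file.
#' @return A data.frame with one row per alignment block and columns
#'   `query_id`, `query_len`, `query_start`, `query_end` (0-based
#'   half-open), `strand`, `target_id`, `target_len`, `target_start`,
#'   `target_end` (0-based half-open), `matches`, `block_len`, `mapq`.
#' @examples
#' paf <- tempfile(fileext = ".paf")
#' writeLines("q1\t100\t0\t50\t+\tt1\t200\t10\t60\t48\t50\t60", paf)
#' read_paf(paf)
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) .stopf("PAF file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(
    query_id = character(), query_len = integer(), query_start = integer(),
    query_end = integer(), strand = character(), target_id = character(),
    target_len = integer(), target_start = integer(), target_end = integer(),
    matches = integer(), block_len = integer(), mapq = integer(),
    stringsAsFactors = FALSE
  )
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    .stopf("PAF parse error at line %d: %d fields (12 required)",
           which(nf < 12L)[1], nf[which(nf < 12L)[1]])
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  int_col <- function(i, name) {
    v <- suppressWarnings(as.integer(col(i)))
    if (anyNA(v)) {
      .stopf("PAF parse error at line %d: non-integer %s", which(is.na(v))[1], name)
    }
    v
  }
  out <- data.frame(
    query_id = col(1), query_len = int_col(2, "query length"),
    query_start = int_col(3, "query start"), query_end = int_col(4, "query end"),
    strand = col(5), target_id = col(6),
    target_len = int_col(7, "target length"),
    target_start = int_col(8, "target start"), target_end = int_col(9, "target end"),
    matches = int_col(10, "match count"), block_len = int_col(11, "block length"),
    mapq = int_col(12, "mapping quality"),
    stringsAsFactors = FALSE
  )
  bad <- which(out$query_start >= out$query_end | out$target_start >= out$target_end)
  if (length(bad)) .stopf("PAF validation error at line %d: start >= end", bad[1])
  if (any(out$strand != "+" & out$strand != "-")) {
    .stopf("PAF parse error at line %d: strand must be + or -",
           which(out$strand != "+" & out$strand != "-")[1])
  }
  if (any(out$matches > out$block_len)) {
    .stopf("PAF validation error at line %d: matches exceed block length",
           which(out$matches > out$block_len)[1])
  }
  if (any(out$mapq < 0L | out$mapq > 255L)) {
    .stopf("PAF validation error at line %d: mapq outside [0,255]",
           which(out$mapq < 0L | out$mapq > 255L)[1])
  }
  out
}

#' Write alignment blocks as PAF
#'
#' @param blocks A data.frame as returned by [read_paf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path) {
  cols <- c("query_id", "query_len", "query_start", "query_end", "strand",
            "target_id", "target_len", "target_start", "target_end",
            "matches", "block_len", "mapq")
  write.table(blocks[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file of genomic intervals
#'
#' Reads 0-based half-open BED intervals into a GRanges (1-based closed).
#' Lines starting with `#`, `track` or `browser` are skipped; columns beyond
#' the third are ignored, so ragged UCSC exports parse cleanly.
#'
#' @param path Path to a BED file.
#' @return A GRanges in file order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    .stopf("BED parse error at line %d: %d columns (3 required)",
           which(nf < 3L)[1], nf[which(nf < 3L)[1]])
  }
  seq_id <- vapply(fields, `[[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start0) || anyNA(end0)) {
    .stopf("BED parse error at line %d: non-numeric coordinate",
           which(is.na(start0) | is.na(end0))[1])
  }
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad)) {
    .stopf("BED validation error at line %d: empty or negative interval [%s, %s)",
           bad[1], start0[bad[1]], end0[bad[1]])
  }
  .gr0(seq_id, start0, end0)
}

#' Write genomic intervals as BED3 (+ optional name column)
#'
#' @param gr A GRanges. If a `name` metadata column (or `drr_id`) is
#'   present it is written as the fourth BED column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  .assert_granges(gr, "gr")
  df <- .bed0(gr)
  m <- GenomicRanges::mcols(gr)
  if ("name" %in% colnames(m)) {
    df$name <- m$name
  } else if ("drr_id" %in% colnames(m)) {
    df$name <- m$drr_id
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Map a RepeatMasker class/family string to the closed class vocabulary.
.repeat_class_of <- function(class_family) {
  prefix <- sub("/.*$", "", class_family)
  ifelse(prefix %in% .REPEAT_CLASSES[.REPEAT_CLASSES != "Other"], prefix, "Other")
}

#' Read RepeatMasker .out annotations
#'
#' Parses the standard whitespace-delimited RepeatMasker `.out` layout
#' (header lines skipped automatically). The 1-based inclusive `begin`
#' column is converted so interval widths equal `end - begin + 1`. The
#' repeat class is the class/family column prefix before `/`, mapped onto
#' the closed vocabulary LINE, SINE, LTR, DNA, Simple_repeat, Satellite,
#' Low_complexity; anything else becomes Other.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A GRanges with metadata columns `repeat_class` and `repeat_name`.
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) .stopf("RepeatMasker file not found: %s", path)
  lines <- readLines(path)
  trimmed <- trimws(lines)
  is_data <- grepl("^[0-9]", trimmed)
  lines <- trimmed[is_data & nzchar(trimmed)]
  gr <- GenomicRanges::GRanges()
  mcols(gr)$repeat_class <- character(0)
  mcols(gr)$repeat_name <- character(0)
  if (length(lines) == 0L) return(gr)
  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    .stopf("RepeatMasker parse error at data line %d: %d columns (11 required)",
           which(nf < 11L)[1], nf[which(nf < 11L)[1]])
  }
  seq_id <- vapply(fields, `[[`, character(1), 5)
  begin <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 6)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 7)))
  if (anyNA(begin) || anyNA(end)) {
    .stopf("RepeatMasker parse error at data line %d: non-numeric coordinate",
           which(is.na(begin) | is.na(end))[1])
  }
  name <- vapply(fields, `[[`, character(1), 10)
  fam <- vapply(fields, `[[`, character(1), 11)
  gr <- GenomicRanges::GRanges(seq_id, IRanges::IRanges(begin, end))
  mcols(gr)$repeat_class <- .repeat_class_of(fam)
  mcols(gr)$repeat_name <- name
  gr
}

#' Write repeat features in RepeatMasker .out layout
#'
#' Emits the standard three header lines followed by one whitespace-aligned
#' data row per feature (1-based inclusive coordinates). Used mainly to
#' serialize simulated repeat annotations.
#'
#' @param repeats A GRanges with `repeat_class` and `repeat_name` metadata
#'   columns, as returned by [read_repeatmasker_out()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  .assert_granges(repeats, "repeats")
  header <- c(
    "   SW   perc perc perc  query     position in query         matching          repeat            position in repeat",
    "score   div. del. ins.  sequence  begin  end      (left)    repeat            class/family    begin  end    (left)   ID",
    ""
  )
  rows <- sprintf(
    "%5d %6.1f %4.1f %4.1f  %s %8d %8d (%d) + %-16s %-15s 1 %d (0) %d",
    1000L, 0, 0, 0,
    as.character(GenomicRanges::seqnames(repeats)),
    GenomicRanges::start(repeats), GenomicRanges::end(repeats), 0L,
    mcols(repeats)$repeat_name, mcols(repeats)$repeat_class,
    GenomicRanges::width(repeats), seq_along(repeats)
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a per-sample depth track from BedGraph
#'
#' @param path Path to a 4-column BedGraph file (0-based half-open steps
#'   with a mean fold-coverage value).
#' @param sample_id Sample identifier attached to the track.
#' @return A list of class `depth_track` with elements `sample_id` and
#'   `steps` (a sorted GRanges with a `depth` metadata column).
#' @export
read_depth_bedgraph <- function(path, sample_id) {
  if (!file.exists(path)) .stopf("BedGraph file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  score <- mcols(gr)$score
  steps <- GenomicRanges::GRanges(
    as.character(seqnames(gr)),
    IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
    score = score
  )
  steps <- GenomicRanges::sort(steps)
  if (any(mcols(steps)$score < 0)) {
    .stopf("BedGraph validation error: negative depth in %s", path)
  }
  if (!IRanges::isDisjoint(steps)) {
    .stopf("BedGraph validation error: overlapping steps in %s", path)
  }
  names(mcols(steps)) <- sub("^score$", "depth", names(mcols(steps)))
  structure(list(sample_id = sample_id, steps = steps), class = "depth_track")
}

#' Write a depth track as BedGraph
#'
#' @param track A `depth_track` as returned by [read_depth_bedgraph()] or
#'   built by [simulate_depth_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_bedgraph <- function(track, path) {
  df <- .bed0(track$steps)
  df$depth <- mcols(track$steps)$depth
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sequence lengths from a FASTA or faidx index
#'
#' Accepts either a `samtools faidx`-style tab-separated index (sequence
#' name and length in the first two columns) or a FASTA file, which is
#' scanned directly.
#'
#' @param path Path to a `.fai` index or FASTA file.
#' @return A named numeric vector of sequence lengths.
#' @export
read_fasta_index <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    lens <- Biostrings::fasta.seqlengths(path)
    names(lens) <- sub("\\s.*$", "", names(lens))
  } else {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) .stopf("faidx parse error: fewer than 2 columns")
    lens <- setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  }
  if (anyDuplicated(names(lens))) {
    .stopf("duplicate sequence name: %s", names(lens)[duplicated(names(lens))][1])
  }
  if (any(lens <= 0)) .stopf("non-positive sequence length")
  lens
}

#' Read per-read alignment summaries from SAM text
#'
#' Parses the mandatory SAM columns of a text SAM file (header lines
#' skipped, unmapped records dropped). The reference span of each record is
#' computed from its CIGAR string. A read is multimapping when an `NH` tag
#' exceeds 1 or when more than one non-supplementary record shares its read
#' name.
#'
#' @param path Path to a SAM text file.
#' @return A GRanges with one range per mapped record and metadata columns
#'   `read_id`, `mapq`, `n_alignments` and `is_supplementary`.
#' @export
read_sam_reads <- function(path) {
  if (!file.exists(path)) .stopf("SAM file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  empty <- GenomicRanges::GRanges()
  mcols(empty)$read_id <- character(0)
  mcols(empty)$mapq <- integer(0)
  mcols(empty)$n_alignments <- integer(0)
  mcols(empty)$is_supplementary <- logical(0)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    .stopf("SAM parse error at record %d: %d fields (11 required)",
           which(nf < 11L)[1], nf[which(nf < 11L)[1]])
  }
  qname <- vapply(fields, `[[`, character(1), 1)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2))
  rname <- vapply(fields, `[[`, character(1), 3)
  pos <- as.integer(vapply(fields, `[[`, character(1), 4))
  mapq <- as.integer(vapply(fields, `[[`, character(1), 5))
  cigar <- vapply(fields, `[[`, character(1), 6)
  mapped <- !(bitwAnd(flag, 4L) > 0L) & rname != "*"
  # reference span from CIGAR: sum of M, D, N, =, X operation lengths
  ref_width <- vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  nh <- vapply(fields, function(f) {
    tag <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  keep <- mapped & ref_width > 0L
  qname <- qname[keep]; flag <- flag[keep]; rname <- rname[keep]
  pos <- pos[keep]; mapq <- mapq[keep]; ref_width <- ref_width[keep]
  nh <- nh[keep]
  is_supp <- bitwAnd(flag, 2048L) > 0L
  rec_per_name <- table(qname[!is_supp])
  cnt <- as.integer(rec_per_name[qname])
  cnt[is.na(cnt)] <- 0L
  n_aln <- pmax(ifelse(is.na(nh), 1L, nh), cnt, 1L)
  gr <- GenomicRanges::GRanges(rname, IRanges::IRanges(pos, width = ref_width))
  mcols(gr)$read_id <- qname
  mcols(gr)$mapq <- mapq
  mcols(gr)$n_alignments <- pmax(n_aln, 1L)
  mcols(gr)$is_supplementary <- is_supp
  gr
}
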