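# Breakpoint junction resolution and formation-mechanism inference.
#
# A junction derivative sequence anchors to two reference flanks: flank A
# ends at the A-side breakpoint and flank B begins at the B-side breakpoint,
# both supplied in the orientation in which they appear in the derivative
# (the caller reverse-complements flank B for inverted segments, keeping
# the core arithmetic strand-agnostic). The maximal exact extension of the
# derivative prefix along the end of flank A and of the derivative suffix
# along the start of flank B either overlap (microhomology), leave a gap
# (inserted bases) or meet exactly (blunt joint). Microhomology placement
# is inherently ambiguous by its length; the leftmost placement on the
# derivative is reported to keep outputs deterministic.

# Maximal k such that the first k bases of `der` equal the last k of
# `flank`.
.max_prefix_suffix <- function(der, flank) {
  n <- nchar(der); lf <- nchar(flank)
  for (k in seq(min(n, lf), 0L)) {
    if (k == 0L) return(0L)
    if (substr(der, 1L, k) == substr(flank, lf - k + 1L, lf)) return(k)
  }
  0L
}

# Maximal L such that the last L bases of `der` equal the first L of
# `flank`.
.max_suffix_prefix <- function(der, flank) {
  n <- nchar(der); lf <- nchar(flank)
  for (k in seq(min(n, lf), 0L)) {
    if (k == 0L) return(0L)
    if (substr(der, n - k + 1L, n) == substr(flank, 1L, k)) return(k)
  }
  0L
}

#' Resolve a breakpoint junction
#'
#' Aligns a derivative sequence spanning a breakpoint junction to its two
#' reference flanks by maximal exact extension and reports the
#' microhomology or inserted bases at the joint. Microhomology and
#' insertion are mutually exclusive: a junction has one or the other (or
#' neither, for a blunt joint), never both.
#'
#' @param derivative_seq Nucleotide string spanning the junction.
#' @param flank_a Reference sequence ending at the A-side breakpoint,
#'   oriented 5'->3' as it appears in the derivative.
#' @param flank_b Reference sequence beginning at the B-side breakpoint,
#'   oriented as in the derivative (reverse-complemented by the caller for
#'   inverted segments).
#' @param min_anchor Minimum exact match (bp) required between the
#'   derivative and each flank; anchoring failure is an error.
#' @return A list of class `junction_call`: `microhomology_len`,
#'   `microhomology_seq`, `insertion_len`, `insertion_seq`,
#'   `insertion_kind` (`"none"` until classified, see
#'   [classify_insertion()]), `anchor_a_len`, `anchor_b_len`.
#' @examples
#' resolve_junction("ACGTACGTAACCGGTT", "ACGTACGTAA", "AACCGGTT",
#'                  min_anchor = 4)
#' @export
resolve_junction <- function(derivative_seq, flank_a, flank_b,
                             min_anchor = 15L) {
  der <- toupper(as.character(derivative_seq))
  fa <- toupper(as.character(flank_a))
  fb <- toupper(as.character(flank_b))
  if (!nzchar(fa) || !nzchar(fb)) .stopf("junction flanks must be non-empty")
  if (grepl("[^ACGTN]", paste0(der, fa, fb))) {
    .stopf("junction sequences must be over the alphabet ACGTN")
  }
  if (nchar(der) < 2L * min_anchor) {
    .stopf("derivative too short (%d bp) for a %d bp anchor on each side",
           nchar(der), min_anchor)
  }
  n <- nchar(der)
  a_end <- .max_prefix_suffix(der, fa)
  if (a_end < min_anchor) {
    .stopf(paste0("unresolved junction: derivative start matches only %d bp ",
                  "of flank A (>= %d required)"), a_end, min_anchor)
  }
  b_match <- .max_suffix_prefix(der, fb)
  if (b_match < min_anchor) {
    .stopf(paste0("unresolved junction: derivative end matches only %d bp ",
                  "of flank B (>= %d required)"), b_match, min_anchor)
  }
  b_start <- n - b_match           # 0-based offset where the B anchor begins
  mh_len <- 0L; mh_seq <- ""
  ins_len <- 0L; ins_seq <- ""
  if (b_start < a_end) {
    mh_len <- a_end - b_start
    mh_seq <- substr(der, b_start + 1L, a_end)
  } else if (b_start > a_end) {
    ins_len <- b_start - a_end
    ins_seq <- substr(der, a_end + 1L, b_start)
  }
  stopifnot(mh_len == 0L || ins_len == 0L)
  structure(
    list(
      microhomology_len = mh_len,
      microhomology_seq = mh_seq,
      insertion_len = ins_len,
      insertion_seq = ins_seq,
      insertion_kind = "none",
      anchor_a_len = a_end,
      anchor_b_len = b_match
    ),
    class = "junction_call"
  )
}

#' Classify an insertion as templated or random
#'
#' An inserted junction sequence is templated when it (or its reverse
#' complement) matches breakpoint-proximal reference sequence — windows
#' around both breakpoints — at 90% identity or better over its full
#' length; otherwise it is random.
#'
#' @param insertion_seq Inserted bases (non-empty).
#' @param reference_windows Character vector of reference sequences around
#'   the breakpoints (typically within 1 kbp of each).
#' @param min_identity Minimum full-length identity for a templated call.
#' @return `"templated"` or `"random"`.
#' @export
classify_insertion <- function(insertion_seq, reference_windows,
                               min_identity = 0.9) {
  ins <- toupper(as.character(insertion_seq))
  if (!nzchar(ins)) .stopf("classify_insertion needs a non-empty insertion")
  windows <- toupper(as.character(reference_windows))
  windows <- windows[nzchar(windows)]
  if (length(windows) == 0L) .stopf("classify_insertion needs reference windows")
  len <- nchar(ins)
  max_mm <- floor((1 - min_identity) * len)
  subject <- Biostrings::DNAStringSet(windows)
  pat <- Biostrings::DNAString(ins)
  hits <- sum(Biostrings::vcountPattern(pat, subject, max.mismatch = max_mm)) +
    sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat), subject,
                                  max.mismatch = max_mm))
  if (hits > 0) "templated" else "random"
}

# Signed gap between the flank-end coordinate of one junction and the
# flank-resume coordinate of the other on the same reference side.
.signed_gap <- function(c_end, c_resume) {
  if (c_resume == c_end + 1L) 0L
  else if (c_resume > c_end) -(c_resume - c_end - 1L)
  else (c_end - c_resume + 1L)
}

#' Junction indels of a two-junction rearrangement
#'
#' For each reference side of an inversion, compares the coordinate where
#' the reference is last used by one junction with the coordinate where it
#' resumes at the other. Adjacent coordinates mean a clean joint (0);
#' skipped bases, present in neither derivative segment, are a deletion
#' (negative); re-used bases, present in both segments, are a duplication
#' (positive). Coordinates are 1-based and assumed left-aligned with
#' respect to any microhomology.
#'
#' @param j1_coords,j2_coords Numeric length-2 vectors `c(pos_a, pos_b)` of
#'   the two junctions' 1-based reference coordinates.
#' @param orientation Orientation of the B-side segment (`"+"` or `"-"`);
#'   recorded for provenance — the role convention above already makes the
#'   arithmetic orientation-independent.
#' @return Named numeric `c(side_a, side_b)` of signed indel lengths
#'   (negative = deletion, positive = duplication).
#' @examples
#' junction_indels(c(1000, 5000), c(1006, 5001))  # 5 bp deletion on side A
#' @export
junction_indels <- function(j1_coords, j2_coords, orientation = "-") {
  if (length(j1_coords) != 2L || length(j2_coords) != 2L) {
    .stopf("each junction needs c(pos_a, pos_b) coordinates")
  }
  if (!orientation %in% c("+", "-")) .stopf("orientation must be '+' or '-'")
  c(
    side_a = .signed_gap(j1_coords[[1]], j2_coords[[1]]),
    side_b = .signed_gap(j1_coords[[2]], j2_coords[[2]])
  )
}

#' Span and chromosome fraction of an inversion
#'
#' @param pos_a,pos_b 1-based breakpoint coordinates on one chromosome.
#' @param chrom_length Chromosome length in bp.
#' @return A list with `span_bp` (absolute coordinate difference),
#'   `span_mbp_rounded` (megabases, rounded half away from zero) and
#'   `chrom_fraction`.
#' @examples
#' inversion_span(42125501, 127429118, 181e6)$span_mbp_rounded  # 85
#' @export
inversion_span <- function(pos_a, pos_b, chrom_length) {
  if (chrom_length <= 0) .stopf("chrom_length must be positive")
  if (pos_a == pos_b) .stopf("breakpoints must differ")
  span <- abs(pos_b - pos_a)
  list(
    span_bp = span,
    span_mbp_rounded = .round_half_away(span / 1e6),
    chrom_fraction = span / chrom_length
  )
}

#' Infer the likely rearrangement formation mechanism
#'
#' Applies a rule cascade over resolved junction features:
#' \enumerate{
#'   \item NAHR when every junction lies between same-family repeats of
#'     sufficient paralog identity spanning the joint;
#'   \item complex MMBIR when the rearrangement has at least
#'     `cfg$complex_min_junctions` junctions;
#'   \item MMBIR when any junction side shows an unbalance (deletion or
#'     duplication) of at least `cfg$mmbir_unbalance` bp — the signature of
#'     a replicative repair process;
#'   \item MMEJ when the largest junction microhomology reaches
#'     `cfg$mmej_min_mh` bp;
#'   \item NHEJ otherwise (blunt or near-blunt joints, small indels, and
#'     insertions of any observed length do not by themselves indicate a
#'     replicative mechanism).
#' }
#'
#' @param microhomology Numeric vector of per-junction microhomology
#'   lengths (bp); use 0 for junctions without microhomology.
#' @param side_indels Numeric vector of signed junction indels (bp) across
#'   all junction sides (see [junction_indels()]).
#' @param n_junctions Number of breakpoint junctions in the rearrangement.
#' @param repeat_context Optional list with one element per junction, each
#'   a list `list(same_family = logical, identity = numeric)` describing
#'   the repeat pair flanking that junction; used only for the NAHR rule.
#' @param cfg A [drr_config()].
#' @return One of `"NAHR"`, `"complex_MMBIR"`, `"MMBIR"`, `"MMEJ"`,
#'   `"NHEJ"`.
#' @examples
#' infer_mechanism(c(2, 3), c(8, -2), 2)           # MMEJ
#' infer_mechanism(c(0, 0), c(-14), 2)             # NHEJ
#' infer_mechanism(c(0, 2), c(1, -335), 2)         # MMBIR
#' @export
infer_mechanism <- function(microhomology, side_indels = numeric(0),
                            n_junctions = length(microhomology),
                            repeat_context = NULL, cfg = drr_config()) {
  if (length(microhomology) == 0L) .stopf("need at least one resolved junction")
  if (anyNA(microhomology)) .stopf("unresolved junction: microhomology is NA")
  if (!is.null(repeat_context) && length(repeat_context) > 0L) {
    nahr <- all(vapply(repeat_context, function(rc) {
      isTRUE(rc$same_family) && isTRUE(rc$identity >= cfg$nahr_min_identity)
    }, logical(1)))
    if (nahr) return("NAHR")
  }
  if (n_junctions >= cfg$complex_min_junctions) return("complex_MMBIR")
  if (length(side_indels) && any(abs(side_indels) >= cfg$mmbir_unbalance, na.rm = TRUE)) {
    return("MMBIR")
  }
  if (max(microhomology) >= cfg$mmej_min_mh) return("MMEJ")
  "NHEJ"
}

#' Summarize a resolved rearrangement
#'
#' Bundles span, junction indels and mechanism inference for a
#' two-junction inversion (or a multi-junction complex event) into one
#' record.
#'
#' @param junctions List of `junction_call` objects from
#'   [resolve_junction()].
#' @param pos_a,pos_b 1-based breakpoint coordinates of the defining
#'   junction.
#' @param chrom_length Chromosome length in bp.
#' @param side_indels Signed junction indels (see [junction_indels()]).
#' @param repeat_context Optional NAHR context (see [infer_mechanism()]).
#' @param cfg A [drr_config()].
#' @return A list of class `rearrangement_call` with the junctions, span
#'   fields, indels and inferred `mechanism`.
#' @export
summarize_rearrangement <- function(junctions, pos_a, pos_b, chrom_length,
                                    side_indels = numeric(0),
                                    repeat_context = NULL,
                                    cfg = drr_config()) {
  if (!length(junctions)) .stopf("need at least one junction")
  mh <- vapply(junctions, function(j) j$microhomology_len, numeric(1))
  span <- inversion_span(pos_a, pos_b, chrom_length)
  structure(
    c(
      list(junctions = junctions, side_indels = side_indels),
      span,
      list(mechanism = infer_mechanism(mh, side_indels, length(junctions),
                                       repeat_context, cfg))
    ),
    class = "rearrangement_call"
  )
}
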