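# Fixture builders: small files written to tempdir() at test time, plus
# the published junction feature table used by the mechanism tests.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# RepeatMasker .out fixture with the standard two header lines + blank.
rmsk_fixture <- function(rows) {
  header <- c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score   div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    ""
  )
  write_lines_tmp(c(header, rows), ".out")
}

rmsk_row <- function(seq_id, begin, end, name, fam) {
  sprintf("  463   1.3  0.6  1.7  %s %d %d (0) + %s %s 1 %d (0) 1",
          seq_id, begin, end, name, fam, end - begin + 1L)
}

# Junction feature columns of the nine resolved inversions: per-junction
# microhomology (bp), signed junction indels (bp; negative = deletion),
# junction count, breakpoint coordinates, printed span (Mbp) and published
# mechanism. BH16643-1's A-side breakpoint spans a range; its upper bound
# gives the printed lower span bound. Spans marked NA have printed sizes
# that are not reproducible from the printed coordinates.
inversion_feature_table <- function() {
  list(
    RD_P525 = list(mh = c(1, 0), indels = c(-5, -8), n_junctions = 2,
                   pos_a = 42125501, pos_b = 127429118, size_mbp = 85,
                   mechanism = "NHEJ"),
    P4855_501 = list(mh = c(2, 3), indels = c(8, -2), n_junctions = 2,
                     pos_a = 51032755, pos_b = 94376921, size_mbp = 43,
                     mechanism = "MMEJ"),
    `BH16643-1` = list(mh = c(2, 3), indels = c(-4), n_junctions = 2,
                       pos_a = 77056693, pos_b = 150079672, size_mbp = 73,
                       mechanism = "MMEJ"),
    P4855_106 = list(mh = c(0, 0), indels = c(-14), n_junctions = 2,
                     pos_a = 42315905, pos_b = 96022615, size_mbp = NA,
                     mechanism = "NHEJ"),
    RD_P541 = list(mh = c(2, 1), indels = c(6, 6), n_junctions = 2,
                   pos_a = 32945545, pos_b = 58051150, size_mbp = 25,
                   mechanism = "MMEJ"),
    RD_P549 = list(mh = c(3, 1), indels = c(-8, 5), n_junctions = 2,
                   pos_a = 63951601, pos_b = 97962156, size_mbp = 34,
                   mechanism = "MMEJ"),
    RD_P526 = list(mh = c(2, 2), indels = c(2, 2), n_junctions = 2,
                   pos_a = 7340601, pos_b = 47883888, size_mbp = 41,
                   mechanism = "MMEJ"),
    RD_P542 = list(mh = c(0, 2), indels = c(1, -335), n_junctions = 2,
                   pos_a = 9982025, pos_b = 58312124, size_mbp = 48,
                   mechanism = "MMBIR"),
    RD_P546 = list(mh = c(0, 2, 0, 0, 0), indels = numeric(0), n_junctions = 5,
                   pos_a = 3256970, pos_b = 56644686, size_mbp = NA,
                   mechanism = "complex_MMBIR")
  )
}
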