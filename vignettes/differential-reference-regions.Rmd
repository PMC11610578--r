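---
title: "Calling differential reference regions and characterizing inversion breakpoint junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differential reference regions and characterizing inversion breakpoint junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drrscan)
```

## The problem

Human reference assemblies differ from one another by megabases of
sequence: segments present in one build (for instance the
telomere-to-telomere assembly) are simply absent from another (GRCh37 or
GRCh38). When a structural-variant breakpoint falls inside such a segment,
the variant is invisible against the incomplete reference. `drrscan`
formalizes and automates this comparison. It calls *differential reference
regions* (DRRs) — segments of a template assembly, strictly larger than
10 kbp, with no aligned counterpart in a query assembly — from a pairwise
whole-genome alignment, annotates their repeat content and genomic
context, classifies their presence across a short-read population panel
from read depth, and characterizes inversion breakpoint junctions at
base-pair resolution to infer the likely DNA double-strand-break repair
mechanism.

## The DRR model

The input is a PAF file from a whole-genome aligner (e.g. minimap2), with
the template assembly as the alignment target. The procedure is exact
per-base interval arithmetic throughout:

1. **Coverage.** `covered_intervals()` unions the target-side intervals of
   all alignment blocks. No strand filter and no MAPQ filter is applied by
   default (`min_mapq = 0`): a DRR is a region *not covered by the query
   genome*, so any alignment evidence counts. Secondary alignments are
   retained at parse time; filtering is a downstream policy exposed through
   `min_mapq`.
2. **Gap exclusion.** Known assembly gaps are subtracted *before* size
   filtering. Exclusion precedes identification, so a gap can split an
   uncovered run into two pieces that individually fall below the size
   cutoff — such pieces are dropped, not merged across the gap.
3. **Size filter.** Segments strictly larger than `min_drr_size`
   (default 10 000 bp) are kept. A 10 000 bp segment is excluded, a
   10 001 bp segment is kept; the cutoff is configurable.
4. **No merging.** Nearby DRRs are never proximity-merged; the calls are
   exactly the maximal uncovered, non-gap runs.

Coverage is computed exactly rather than in bins: binned coverage depends
on an arbitrary bin size, while interval arithmetic is deterministic and
can be verified against a per-base boolean-array oracle (the test suite
does exactly that on templates up to 100 kbp).

Multi-way comparisons use `shared_missing()`: given DRR sets from several
queries against one template, it reports the template bases missing from
*every* query (the intersection) and the exclusive Venn partition sizes in
bp, which sum to the union of all sets.

## Repeat and context annotation

`repeat_composition()` intersects a DRR with RepeatMasker features and
reports per-class and union coverage fractions. Classes come from the
class/family column prefix (LINE, SINE, LTR, DNA, Simple_repeat,
Satellite, Low_complexity; everything else is Other); low-complexity
annotations are reported as their own class, not folded into interspersed
repeats. Overlapping annotations are *not* resolved against each other —
per-class fractions may sum to more than the union fraction — because the
union is what determines masked versus unmasked sequence. All fractions
derive from integer bp counts, so `unmasked + total == 1` exactly and
"100% repetitive" means literal full tiling, never a floating-point
near-miss.

`context_flags()` marks a DRR as near-centromeric when it overlaps or
lies within `context_window` (default 10 000 bp, the conventional
proximity window for centromeric context) of a centromere interval, and
as inside a segmental duplication on any overlap of at least 1 bp — no
minimum overlap fraction is imposed, and the choice is configurable.

## Population presence from read depth

`mean_depth()` computes the length-weighted mean fold-coverage of a DRR
from a BedGraph depth track, counting positions absent from the track as
depth 0. `classify_presence()` then applies an open interval: a DRR is
**present** in a sample when 8× < depth < 100×, **absent** when depth is
below 8×, and a **no-call** above 100×, where coverage that deep over a
unique region indicates a collapsed repeat rather than extra copies of
the region in that individual. The published thresholds are strict
inequalities, which leaves the boundary depths unassigned; this package
assigns each boundary to the adjacent conservative class (exactly 8× is
absent, exactly 100× is a no-call) and exposes both bounds in
`drr_config()`.

At the cohort level (`population_class()`), the presence fraction is
computed over *all* samples — no-call samples stay in the denominator,
because the published fractions are quoted against the full cohort size.
A DRR is **not detected** when no sample presents it, **rare** when
present in at most 5% of samples, **common** above 5%, and flagged
high-frequency above 90%. The three classes partition any DRR set. The
"not detected" definition is the zero-presence reading (no sample above
the cutoff) rather than a cohort-average reading; only the former keeps
the classes a partition.

`mapping_summary()` reports, over non-supplementary reads overlapping a
DRR by at least 1 bp, the fraction with MAPQ strictly above 20 and the
fraction that are multimapping. A read counts as multimapping when an
explicit hit-count tag (`NH`) exceeds 1 or when several non-supplementary
records share its name — the common operational definition.

## Breakpoint junction resolution

`resolve_junction()` takes a derivative sequence spanning a junction plus
the two reference flanks, supplied in derivative orientation (the caller
reverse-complements flank B for inverted segments; the core arithmetic is
strand-agnostic). It computes the maximal exact extension of the
derivative prefix along the end of flank A (`a_end`) and of the
derivative suffix along the start of flank B (`b_start`). The joint is
then read off directly:

* `b_start < a_end` — **microhomology** of `a_end − b_start` bp;
* `b_start > a_end` — **insertion** of the intervening bases;
* equal — a **blunt** joint.

Microhomology and insertion are mutually exclusive by construction, and
the call asserts it. Because breakpoint placement under microhomology is
ambiguous by its length, the leftmost placement on the derivative is
reported — a fixed tie-break that makes outputs deterministic. Each flank
must anchor with at least `min_anchor` (default 15 bp) of exact match;
failure is an explicit unresolved-junction error rather than a guess.

`classify_insertion()` labels inserted bases **templated** when they (or
their reverse complement) match sequence within the breakpoint-proximal
reference windows at ≥90% identity over the full insertion length, and
**random** otherwise.

`junction_indels()` compares, per reference side, the coordinate where
one junction last uses the reference with the coordinate where the other
junction resumes it: adjacent coordinates are a clean joint (0), skipped
bases are a deletion (negative), re-used bases a duplication (positive).
This sequence-level definition is authoritative for the package;
published junction-indel magnitudes are not always reproducible from
printed coordinates by any single coordinate convention.

`inversion_span()` reports `|pos_b − pos_a|` in bp, in Mbp rounded half
away from zero, and as a fraction of the chromosome. Half-away-from-zero
is used (rather than R's round-half-to-even) because it matches the
printed megabase sizes of the published junction table.

## Mechanism inference

`infer_mechanism()` applies a fixed cascade over resolved junction
features:

1. **NAHR** — every junction flanked by same-family repeats with paralog
   identity ≥95% spanning the joint. The identity threshold is a
   configurable default; no resolved case in the motivating data
   exercised it.
2. **complex MMBIR** — at least 3 junctions.
3. **MMBIR** — any junction unbalance (deletion or duplication) of
   ≥100 bp, the signature of a replicative template-switching process.
4. **MMEJ** — maximal microhomology ≥2 bp.
5. **NHEJ** — otherwise. Blunt joints, ≤1 bp microhomology, small indels
   and insertions of any observed length (up to ~90 nt) remain NHEJ;
   insertions alone do not indicate a replicative mechanism.

The order matters: a junction with 2 bp microhomology *and* a 335 bp
deletion is MMBIR, not MMEJ. This cascade with thresholds (2 bp, 100 bp,
3 junctions) is the simplest rule set consistent with all nine resolved
inversions in the motivating study, and the test suite verifies that it
reproduces all nine published labels from their feature columns.

## What the simulator emulates — and what it does not

`simulate_reference_pair()` builds the study conditions at desk scale: a
random template genome (default 2 chromosomes × 500 kbp, GC 0.41), a
handful of implanted segments of 12–20 kbp (all above the 10 kbp cutoff)
whose removal produces the query, simple tandem-repeat arrays (2–6-mer
motifs, as in `(ATGG)n`) covering a configurable fraction of each
implant, and N-run assembly gaps recorded in a gap set.
`emit_truth_paf()` stands in for the aligner with idealized identity
blocks (MAPQ 60, `matches = block_len`) covering every shared segment,
split around gaps, so the whole calling path can be validated against
exact truth.

`simulate_depth_panel()` emulates the population analysis: 100 samples by
default (the size of the analyzed cohort), per-DRR presence frequencies
drawn uniformly, and per-100-bp-step depths drawn Poisson around 30×
(present — the cohort's sequencing depth), 1× (absent) and 150×
(collapsed repeat). Poisson noise is the simplest model that exercises
the 8×/100× thresholds; real short-read depth is overdispersed and
GC-biased, so passing recovery tests demonstrates correct threshold logic,
not robustness to real-world depth artifacts. Read summaries (for a
5-sample subset, mirroring the study's mapping-quality subset) carry MAPQ
and hit-count distributions at configurable rates.

`simulate_junction()` engineers derivative sequences with exact
microhomology (the flank ends are made to share exactly `mh` bases, and
candidate flanks are rejected until that overlap is *maximal*, so the
engineered value is the unique physical answer) or insertions copied from
the reference windows (templated) or verified absent from them (random).
Engineered "random" insertions shorter than 6 bp are not constructible —
any such short k-mer occurs in a kbp-scale window by chance, so the
simulator labels short insertions templated by definition.

What the synthetic data does **not** model: sequence divergence between
template and query in shared regions (alignment blocks are exact),
alignment ambiguity in repeats, real repeat families (only simple tandem
arrays are implanted), overdispersed or wavy depth, and read-level errors.
Truth-recovery results on this data validate the interval arithmetic, the
threshold logic and the junction algebra — not aligner behavior.

## Numerical and design choices

* Intervals are held as `GRanges` (1-based closed) internally — the
  canonical container in R genomics — with 0-based half-open conversion
  exactly once at every file boundary (PAF, BED, BedGraph). Widths are
  identical under both conventions, and all round-trips are tested.
* "Larger than 10 kbp" is read strictly (`> 10 000`); the edge case is
  tested and the cutoff configurable.
* `summarize_drrs()` reports the lower of the two central values as the
  median for even counts, keeping the statistic an observed region size.
* Degenerate inputs are explicit: empty DRR sets summarize to zero counts
  with `NA` size statistics; zero overlapping reads yield an `undefined`
  mapping summary rather than silent zeros; empty junction flanks,
  out-of-bounds gaps and overlapping depth steps are validation errors.
* Desk-scale problem sizes (500 kbp chromosomes, 3 implants, 20-seed
  truth-recovery sweeps, a 50-sample recovery panel, the full
  microhomology 0–10 × insertion 0–50 junction grid) were chosen so the
  entire validation suite runs in a couple of minutes while still
  exercising every rule boundary; all sizes scale through `sim_config()`.

## Limitations

* DRR calling takes the alignment as given; it does not chain, filter by
  identity, or lift over between references. Different aligner settings
  yield different coverage and therefore different DRR sets.
* Junction resolution requires exact anchors; highly diverged or
  error-containing derivative sequences should be polished before
  resolution.
* The mechanism cascade is a heuristic consistent with the nine resolved
  junctions that motivated it; it does not express uncertainty and will
  misclassify mechanisms whose signatures overlap (e.g. NHEJ with an
  undetected templated insertion).
* Population presence is a depth threshold call, not a genotype
  likelihood; partial presence (one haplotype) and mosaic states are not
  modeled.
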