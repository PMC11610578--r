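# drrscan

Reference genome assemblies are not interchangeable: megabase-scale
segments present in one human build are absent from another, and a
structural-variant breakpoint that falls inside such a segment is
invisible against the incomplete reference. `drrscan` is an R package for
clinical and population genomicists who need to quantify this effect. It

* calls **differential reference regions (DRRs)** — segments of a
  template assembly, strictly larger than 10 kbp, with no aligned
  counterpart in a query assembly — from pairwise whole-genome alignments
  (PAF), with assembly-gap exclusion and exact per-base interval
  arithmetic;
* annotates DRRs with **repeat composition** (RepeatMasker classes,
  union-based masked fraction) and **genomic context** (centromere
  proximity within 10 kbp, segmental-duplication overlap);
* classifies DRR **presence in a sequenced population** from read depth
  (present when 8× < depth < 100×, absent below 8×, no-call above 100×;
  cohort classes: not detected / rare ≤5% / common >5%, high-frequency
  >90%) and summarizes read mapping quality and multimapping;
* resolves **inversion breakpoint junctions** from derivative sequences
  and reference flanks — microhomology, insertions (templated vs
  random), junction indels, span — and infers the likely repair
  mechanism by a fixed cascade: NAHR → complex MMBIR (≥3 junctions) →
  MMBIR (unbalance ≥100 bp) → MMEJ (microhomology ≥2 bp) → NHEJ;
* ships a **seeded simulator** producing template/query assembly pairs,
  idealized alignment PAF, population depth panels and engineered
  junction sequences with matching truth, so the whole pipeline is
  validated end to end without downloads.

## The core definitions

For a template sequence $T$ with length $L$, covered set
$C = \bigcup_i [s_i, e_i)$ from the query's alignment blocks, and known
gap set $G$:

$$\mathrm{DRR}(T) = \{ r \subseteq [0, L) \setminus (C \cup G)
  \;:\; r \text{ maximal},\; |r| > 10\,\mathrm{kbp} \}$$

A junction derivative $d$ with flanks $f_A$ (ending at breakpoint A) and
$f_B$ (starting at breakpoint B) is resolved by the maximal exact
extensions $a$ (derivative prefix vs end of $f_A$) and $b$ (derivative
suffix vs start of $f_B$): $a > b$ is a microhomology of $a - b$ bp,
$a < b$ an insertion of the intervening bases, $a = b$ a blunt joint.

## Worked example

```r
library(drrscan)

cfg  <- sim_config(seed = 42, n_drrs = 3)        # 2 x 500 kbp chromosomes
sim  <- simulate_reference_pair(cfg)             # implant 3 segments > 10 kbp
paf  <- emit_truth_paf(sim)                      # idealized aligner output
drrs <- call_drrs(covered_intervals(paf), sim$seq_lengths, gaps = sim$gaps)
summarize_drrs(drrs)
#> $n_regions  3
#> $total_bp   45044
#> $min_bp     14368
#> $median_bp  14608
#> $max_bp     16068
```

Three regions totalling 45 kbp are called, matching the implanted truth
exactly (count and coordinates). Annotation and population classification:

```r
annotate_drrs(drrs, sim$repeats)[, c("drr_id", "total_repeat_fraction")]
#>            drr_id total_repeat_fraction
#> 1 DRR_chr1_214351             0.8457010
#> 2 DRR_chr1_301656             0.4264337
#> 3  DRR_chr2_35830             0.8388723

panel <- simulate_depth_panel(sim, cfg)          # 100 samples at 30x
population_table(call_presence(drrs, panel$tracks))
#>            drr_id n_present n_total presence_frac  class high_frequency
#> 1 DRR_chr1_214351        45     100          0.45 common          FALSE
#> 2 DRR_chr1_301656        71     100          0.71 common          FALSE
#> 3  DRR_chr2_35830        23     100          0.23 common          FALSE
```

Each DRR's tandem-repeat fraction reflects the simulation settings, and
the cohort presence fractions track the simulated allele frequencies; all
three regions exceed the 5% cutoff, so they are classified common.
Junction characterization:

```r
jc <- resolve_junction("ACGTACGTAACCGGTT", "ACGTACGTAA", "AACCGGTT",
                       min_anchor = 4)
jc$microhomology_seq                       # "AA" — 2 bp microhomology
inversion_span(42125501, 127429118, 181537261)
#> 85303617 bp = 85 Mbp, 47% of the chromosome
infer_mechanism(c(2, 3), c(8, -2), 2)      # "MMEJ"
```

A junction with 2–3 bp microhomology and only small indels is classified
as microhomology-mediated end joining; an unbalance of 100 bp or more
would reclassify it as replicative (MMBIR).

A command-line front end over the same functions is installed at
`inst/cli/drr.R` (subcommands `call`, `venn`, `annotate`, `junction`,
`simulate`).

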