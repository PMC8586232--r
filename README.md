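# circvalid

In-silico validation of circular RNAs (circRNAs) from a single gene locus.

A circRNA shares every base with the linear splice variants of its locus
except one: the back-splice junction (BSJ), the covalent joint between the
3' end of a downstream exon *b* and the 5' start of an upstream exon *a*.
Claims of circularity therefore rest on a chain of converging checks, each
of which has a computational core that this package implements over an
explicit locus model:

* **Divergent-primer PCR** — primers facing away from each other on the
  linear transcript amplify only when the template is circular (or a
  concatemer). `circvalid` models primer binding with an exact 3'-seed
  rule (default 10 nt, ≤ 2 mismatches 5' of it), classifies pair
  orientation geometrically, and enumerates amplicons on linear, circular,
  concatemeric and genomic templates, including the rolling-circle cDNA
  ladder *L, L + c, L + 2c, …* for a circle of length *c*.
* **Primer and asON design** — convergent pairs (spliced product 70–150 nt,
  T_m 57–63 °C by unified nearest-neighbor thermodynamics), divergent
  pairs inside one shared exon, BSJ-spanning primers with a ≥ 4 nt 3'
  overhang into the acceptor exon (the 3' end defines Taq specificity),
  and BSJ-directed antisense oligonucleotides for RNase H.
* **Clone classification** — sequenced amplicon clones are decomposed into
  exon paths (comma = canonical junction, slash = back-splice, e.g.
  `4,5,6/3,4`; reverse-complement clones appear as `4,3/6,5,4`), then
  called `linear`, `circ_consistent`, `artifact` (primer duplication,
  missing internal exon, inconsistent BSJ, sequence deviation) or
  `foreign`.
* **Flanking-intron complementarity** — Smith–Waterman alignment of the
  upstream flanking intron against the reverse complement of the
  downstream one (match +5, mismatch −4, gap −12/−4; Waterman–Eggert
  top-k; seeded permutation-null significance screen), the signal that
  inverse-complementary intron pairing may assist back-splicing.
* **Nuclease topology tests** — RNase H opens a circle at a BSJ-guided
  asON heteroduplex (divergent signal collapses, convergent signal stays);
  RNase R digestion gives lg10(*B*/*A*) copy ratios with threshold calls
  (≤ −1.0 linear-consistent, ≥ −0.3 circular-consistent).
* **Marker arithmetic** — lg10(fold change) = log10(case/control), rounded
  half-away-from-zero to 2 decimals; candidate pools are unweighted means
  of member abundances per group; only negative-fold-change species enter
  the pooled primer target set.

Everything runs offline on a bundled synthetic TRAM1-like fixture locus
(11 exons on the reverse strand; five linear variants of spliced lengths
542/3394/3056/872/535 nt; four predicted circles of 176/383/447/422 nt
spanning exons 4–5, 3–6, 2–6 and 1–5) plus seeded generators for random
loci, clone libraries with truth tables, and grouped expression tables.

## Worked example

```r
library(circvalid)
loc <- tram1_fixture_locus()

# divergent pair in exon 4 (shared by all four circles)
div <- design_divergent_pair("circTRAM1-58", loc, exon = 4L)
predict_amplicons(div, new_template("parent",
                  spliced_sequence("TRAM1-201", loc), "linear"))
#> [zero rows]  — divergent pairs see nothing on the linear parent
predict_amplicons(div, new_template("c56",
                  circ_sequence("circTRAM1-56", loc), "circular"))$length
#> [1] 380      — one monomer product: circle length 383 minus the 3 nt gap

# a clone read wrapping the BSJ of the exons-3..6 circle
cs <- circ_sequence("circTRAM1-56", loc)   # 383 nt, linearized from exon 3
read <- substr(strrep(cs, 2), 88, 560)     # exon 4 around the circle to exon 4
call <- classify(decompose(read, loc), div, loc)
call$path_string   #> "4,5,6/3,4"
call$category      #> "circ_consistent"
call$matched_circ  #> "circTRAM1-56"

# RNase R copy ratio from the packaged qPCR table
rnase_r_ratio(66353.49, 223.56)
#> $lg10_ratio [1] -2.47    $topology_call [1] "linear-consistent"

# pooled urine marker arithmetic
tab <- tram1_tables("urine_tpm")
rec <- data.frame(transcript_id = tab$transcript_id,
                  group = tab$group, value = tab$tpm)
pool_candidate(rec, tram1_pools()$circular, "HR", "C")$lg10_fc
#> [1] -1.26
```

The numbers mean: the divergent pair is circle-specific (0 products on the
linear parent, one 380 nt product on the 383 nt circle); the clone read is
a reverse-complement insert whose normalized exon path carries exactly one
back-splice (6→3) matching the exons-3–6 circle; linear transcripts drop
by ~2.5 orders of magnitude under RNase R while circles do not; and the
pooled circular candidate is ~18-fold down (lg10 fc −1.26) in the
high-risk urine pool.

## Analysis workflow

The `analysis/` directory holds numbered drivers that reproduce the whole
reasoning chain on the fixture locus and write tables under `results/`:

```sh
Rscript analysis/01_build_model.R          # locus model, JSON/FASTA/GFF3
Rscript analysis/02_pcr_simulation.R       # primers, amplicons, tandem-repeat control
Rscript analysis/03_clone_classification.R # worked clone paths + 400-clone library
Rscript analysis/04_intron_pairing.R       # flanking-intron alignments
Rscript analysis/05_nuclease.R             # RNase H readout, RNase R ratios
Rscript analysis/06_quantify.R             # marker fold-change tables
```

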