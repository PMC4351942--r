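---
title: "Detecting transposable element insertion sites from paired-end resequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transposable element insertion sites from paired-end resequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Insertional mutagenesis with transposable elements (TEs) such as the tobacco
retrotransposon Tnt1 produces lines carrying tens of new insertions. Forward
genetics needs all of them: every insertion is a candidate causal mutation.
Whole-genome paired-end resequencing contains the evidence, because any read
pair touching a new insertion junction links the TE sequence to its flanking
genomic sequence. `teloci` turns that evidence into a table of insertion
sites with exact breakpoints, target-site duplications (TSDs), element
orientation, and a heterozygous/homozygous call per site.

## The method

**Combined reference.** Reads are aligned once against the genome plus the TE
sequence appended as one extra reference record (`build_combined_reference()`,
`align_reads()`; `bwa mem -T 20`, so at least 20 bp of a read must align for a
record to be reported). Pairs bridging the two references then directly expose
junctions. Any coordinate-sorted or name-sorted SAM/BAM over this combined
reference is accepted in place of the built-in aligner call.

**Read-pair classification** (`classify_pairs()`). Every pair falls in exactly
one category:

* *background* — both mates on the same genome sequence, no TE evidence.
  Useless for locating insertions, but at an insertion locus they measure the
  allele without the insertion, which drives the zygosity call.
* *cross* — one mate completely on the genome (at most 5 bp incidental
  clipping), the other on the TE. Localizes a junction to within an insert
  length.
* *clipped* — at least one read spans the junction itself, recognized either
  through a supplementary alignment (in either direction: genome-primary with
  a TE supplementary, or TE-primary with a genome supplementary) or through a
  terminal soft clip whose sequence matches one of the two TE termini, in
  either orientation, with at most 10% mismatches. Clipped pairs give the
  junction at base-pair resolution and take precedence over cross.
* *uninformative* — everything else, including pairs whose TE-derived portion
  is shorter than 20 bp and pairs entirely inside the TE (no genome anchor).

A pair is *informative* (cross or clipped) only when at least
`min_te_overlap = 20` bp of it derive from the TE, mirroring the aligner's
minimum reportable alignment. Soft clips shorter than `min_clip_match = 8` bp
are treated as alignment noise and never matched against the TE.

**Evidence sides.** Evidence whose genome-side alignment points rightward
(toward increasing coordinates, with the TE beyond its 3' end) supports the
*left* junction of the insertion; leftward-pointing evidence supports the
*right* junction. For clipped reads the side follows from which end of the
alignment carries the clip.

**Clustering and filters** (`cluster_evidence()`, `apply_filters()`).
Evidence is single-linkage clustered along the genome with a window of
`insert_mean + 3 * insert_sd` (650 bp at the default 500 ± 50 bp library).
A cluster is reported only if all four filters hold: mean mapping quality of
the informative pairs at least 1 (placements in repetitive sequence carry
MAPQ 0 and are screened out), mean read depth in a ±`insert_mean` window
between 2 and 300, at least 3 supporting pairs, and at least one pair on each
junction. We read "both ends" as the two genome flanks (left and right
junction), not the two TE termini; with the side convention above these
coincide for cross pairs anyway. Rejected candidates are kept with their
failure reasons.

**Breakpoint and TSD** (`refine_breakpoint()`). During transposition the
target site is duplicated: for Tnt1 the 5-bp sequence at the integration
point appears on both sides of the element. Consequently the last reference
base before the TE approached from the left (`L`, the modal clip coordinate
of left-junction clipped reads) lies *after* the first reference base that
follows the TE approached from the right (`R`, the start of the duplicated
target site): `tsd = reference[R..L]`, `position = R`. Modal coordinates are
used because sequencing errors and microhomology occasionally shift a clip by
a base or two; ties break toward the smaller coordinate so output is
deterministic. Implied TSDs longer than `max_tsd = 20` bp indicate mis-paired
junctions and are flagged rather than reported. With clips on only one side
the position is that coordinate; with no clipped pairs at all the call falls
back to the midpoint of the innermost left/right anchors and is marked
interval-precision.

**Orientation** (`call_orientation()`). Each evidence pair votes for the
element strand: a cross pair votes `+` when its two mates align on opposite
strands of genome and TE, a split read votes `+` when its two partial
alignments share a strand, and a matched soft clip votes by which terminus
and orientation it matched. A cluster needs an 80:20 majority; anything
closer is reported `unknown`.

**Zygosity** (`zygosity_test()`). At a heterozygous locus the inserted allele
produces supportive pairs at *two* junctions while the intact allele produces
spanning background pairs at *one* site, so supportive:background is 2:1 in
expectation and a background pair occurs with probability 1/3. The site is
called homozygous when the exact one-sided binomial lower tail
`P(X <= n_background)`, `X ~ Binomial(n_support + n_background, 1/3)`, falls
below `alpha = 0.05`. Excess background beyond the heterozygous expectation is
still reported heterozygous (mosaicism is out of scope), and no
multiple-testing correction is applied, matching common practice for these
small per-line call sets. Background pairs are counted as pairs (not single
reads), symmetric with how supportive evidence is counted.

**Annotation and enrichment** (`classify_positions()`,
`enrichment_test()`). Calls are classified exon / intron / intergenic against
a GFF3. Genic enrichment is tested by permutation: `n_perm` (default 10,000)
random placements of the same number of insertions, with the add-one
estimator `(1 + #\{perm >= obs\}) / (n_perm + 1)` so the p-value is never
exactly zero. A permutation test was chosen over a 2×2 exact test because it
is self-contained and makes no marginal assumptions; with uniform placements
the two agree closely.

## The simulator

`generate_genome()`, `insert_te()`, `simulate_reads()`, `mix_heterozygous()`
and `project_truth_alignments()` reproduce the benchmark conditions the
caller is designed for: i.i.d. genomes (optionally with exact interspersed
repeats, to exercise the repeat-region failure mode), TE insertions with 5-bp
TSDs spaced at least 10 kb apart, 100-bp paired reads with insert size
500 ± 50 and per-base substitution rate 0.001 (the short-insert parameter
subset of the pIRS simulator: no indel errors, no GC bias), and heterozygous
libraries built by mixing equal read *amounts* from the mutant and unmodified
haplotypes. Base qualities are written as constant Q30; the caller never uses
them. Since the real Tnt1 sequence is not bundled, `synthesize_te()` generates
a synthetic element with Tnt1's geometry — 5,334 bp with identical 610-bp
terminal repeats — which reproduces the length and the LTR-induced mapping
ambiguity, though not the element's composition.

What the synthetic data do **not** emulate: divergence between the sequenced
line and the reference (the dominant error source on real data), indels and
quality-dependent errors, biased fragment sampling, and natural repeat
families more complex than exact copies. Passing the simulated benchmark
therefore demonstrates the pipeline's correctness and its behaviour under
coverage and zygosity changes, not its robustness to reference divergence.

`project_truth_alignments()` writes, for every simulated read, the alignment
it must have on the combined reference if alignment were perfect (junction
reads soft-clipped at the known splice point). This aligner-free oracle
separates caller errors from aligner errors and is what the exactness tests
run on.

```{r example}
library(teloci)
sim <- simulate_benchmark(n_seq = 1, seq_len = 5e5, n_insertions = 5,
                          coverage = 10, zygosity = "het", seed = 42)
dir <- tempfile(); dir.create(dir)
write_fasta(sim$genome, file.path(dir, "genome.fa"))
write_fasta(sim$te, file.path(dir, "te.fa"))
write_fastq(sim$reads, file.path(dir, "r1.fq"), file.path(dir, "r2.fq"))
calls <- detect_insertions(file.path(dir, "genome.fa"), file.path(dir, "te.fa"),
                           fastq1 = file.path(dir, "r1.fq"),
                           fastq2 = file.path(dir, "r2.fq"))
glance(evaluate_calls(calls, sim$truth))
autoplot(calls)
```

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere a user sees them (TSV, truth
  tables, `position`); only the BED export is 0-based half-open.
* The clustering window is not stated by the method's description; we derive
  it from the library geometry (`insert_mean + 3 * insert_sd`) so that two
  evidence pairs of one insertion can essentially never be split apart.
* Local depth is measured from all genome-side primary alignments in a
  ±`insert_mean` window around the cluster midpoint.
* `bwa mem` is assumed as the alignment algorithm (its `-T` option matches
  the documented minimum-score setting); any aligner producing soft clips
  and supplementary alignments over the combined reference works.
* Degenerate inputs: empty FASTA/FASTQ/BAM inputs produce empty outputs with
  warnings; a TE name colliding with a genome sequence, duplicate read names
  across libraries, and positions on unknown sequences are errors.
* Determinism: identical input yields byte-identical call tables (modal ties
  break to the smaller coordinate; no RNG in the caller), and every simulator
  function is seeded.

## Scale of the bundled checks

The test suite and the acceptance script run entirely on synthetic data
generated at run time: genomes of 0.05–5 Mb, 1–50 insertions, coverages of
3–50X — study conditions scaled so the whole suite runs on a laptop-class
single core. Recall-versus-coverage monotonicity is asserted on nested
downsamples of one read set, which makes the expected monotone behaviour
structural rather than a property of one lucky seed.

## Limitations

* Absence calling (detecting that a reference TE copy is gone) is out of
  scope, as are CRAM input and long single-end reads.
* Insertions inside repetitive sequence fail the mapping-quality filter by
  design; they are reported in the rejected-candidates table, not the calls.
* The binomial zygosity model assumes the 2:1 evidence geometry; shorter
  fragments relative to read length shave the supportive side slightly, so
  very unusual library geometries would need a recalibrated `p_background`.
* Two insertions closer than the clustering window merge into one candidate.
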