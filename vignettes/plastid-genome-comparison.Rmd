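---
title: "Comparative plastid genomics with plastidcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastid genomics with plastidcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidcomp)
```

## What the package computes

Red algal plastid genomes are compact circular chromosomes of roughly
150–192 kb that carry around 200 densely packed, single-exon genes with
9–18% intergenic space. Because their gene content is highly conserved while
their gene *order* is not, they are a natural setting for two complementary
comparisons: set-level comparison of gene repertoires (which genes does each
genome carry?) and order-level comparison of shared genes (how many
rearrangements separate two genomes?). `plastidcomp` implements both, along
with the per-genome composition statistics that conventionally accompany
them, and a synthetic-genome generator that plants known ground truth so the
whole pipeline can be verified without any downloads.

## Coordinates and the circle

All internal coordinates are 0-based half-open; GenBank's 1-based inclusive
convention is converted exactly once, at the I/O boundary. A feature that
crosses the replication origin is stored as a single interval with
`wraps = TRUE` even when the source file encodes it as a two-part
`join(x..L,1..y)`; this single canonical form keeps length and union
arithmetic branch-free. On writing, the wrapped form is re-expanded to the
standard `join`. Span unions (the basis of the intergenic statistic) are
computed with `IRanges::reduce()` after unrolling wrapped intervals into
their two arcs.

## ORF detection

`find_orfs()` scans both strands in all frames. Defaults are start codons
ATG and GTG, a 90 bp minimum, and the standard genetic code; TTG can be
admitted with `use_extended = TRUE`. Two conventions are deliberately
configurable, because annotation tools disagree and published ORF totals
rarely state them:

* `min_length` counts the full span *including* the stop codon by default
  (`include_stop_in_length = FALSE` applies it to the coding part only);
* `counting_mode = "longest_per_stop"` (default) reports one ORF per
  (strand, stop) anchored at the 5'-most qualifying start, which matches the
  magnitude of published plastid ORF counts; `"all_starts"` reports every
  qualifying start and is several-fold larger.

On circular sequences the scan continues across the origin; an ORF's length
is capped at the genome length, and a sequence consisting of a single
stop-free frame yields no call rather than an infinite one. Codons
containing IUPAC ambiguity codes never match a start or stop — a conservative
choice that can only lose borderline calls, never invent them. GTG/TTG
initiators are translated per the standard table (V/L), not recoded to M,
since the analyses here never consume the protein sequence beyond domain
checks.

## Composition statistics

`gc_content()` excludes ambiguity codes from numerator and denominator.
`intergenic_fraction()` treats the union of `gene`, `CDS`, `tRNA`, `rRNA`
and `tmRNA` spans as "annotated", the inclusive reading of the usual
intergenic-space footnote; the kind set is an argument, so the stricter
`gene`-only reading is one call away. rRNA operons are counted by clustering
rRNA features at a 5 kb gap (closing the circle), a threshold chosen to
be far above intra-operon spacing and far below inter-operon distances in
organelle genomes. Percentages are rounded half-away-from-zero to one
decimal only at reporting time.

## Gene-content partitioning

Gene repertoires are compared *by name after harmonization*, copy number
ignored. A shipped synonym table maps curated aliases (e.g. `sufB` →
`ycf24`, `pdhA` → `odpA`) to preferred symbols; alias groups without a
curated canonical fall back to majority election — the spelling used by the
most species wins, ties broken lexicographically, so the result is
deterministic. Sequence-similarity orthology is out of scope; names are the
unit of comparison.

`partition_sets()` computes each gene's exact presence signature across
species and reports disjoint blocks: present-in-all (`core`), present in
exactly a named clade and nowhere else, unique to one species, and a
residual block per remaining signature. "Exactly" matters: a gene present
in a clade *and* one outgroup genome lands in a residual block, which is
what makes the block sizes add up to the union exactly.

The package bundles two transcribed comparison tables for six red algal
plastid genomes: a 233-gene sharing classification (140 shared by all six,
21 by the four Eurhodophytina, 5 by the two florideophytes, 35 found in
*G. taiwanensis* only) and a tRNA isoacceptor copy-number matrix. In the
sharing table, flags whose published formatting did not survive
transcription were completed by curation so that the blocks match the
published totals; the per-gene flags beyond those counts should be treated
as curated rather than primary data, and the fixture header says so.
Typesetting duplicates in the source listing were removed. In the tRNA
matrix the anticodon strings are preserved exactly as printed (the source
gives them 3'–5', the reverse of the usual convention); one row sums to 31
where the source's own summary row says 30 — the transcription is kept
verbatim rather than silently corrected, and the analyses assert only the
row sums that transcribe cleanly.

## DCJ rearrangement distance

Two genomes are reduced to signed orders over their shared single-copy
harmonized genes (`shared_marker_orders()`): order from genomic coordinate,
sign from strand. This gene-order reduction stands in for alignment-derived
collinear blocks; it captures the same signal when gene content is largely
shared, but it is not the same marker definition, so distances computed this
way on real genomes should be read as estimates of the published
alignment-based values rather than exact reproductions.

The distance itself is the canonical adjacency-graph formula. Each marker
contributes a head and a tail extremity; each genome contributes adjacencies
(and telomeres, for linear chromosomes) between consecutive extremities; the
union multigraph decomposes into cycles and paths, and with $N$ markers,
$C$ cycles and $I$ odd-length paths,

$$d_{DCJ} = N - \left(C + \frac{I}{2}\right).$$

Because the formula is easy to get subtly wrong, the package also ships an
*independent* oracle: `dcj_distance_bruteforce()` runs breadth-first search
over the full DCJ move graph (every way to cut two adjacencies/telomeres
and rejoin) and returns the true shortest path. It refuses $N > 8$; the test
suite checks formula-vs-BFS equality on hundreds of random signed circular
orders with $N \le 6$, plus the metric axioms and invariance under rotation
and reflection of a circular chromosome. That oracle equivalence — not any
particular published distance value — is the primary correctness surface for
this module.

## The synthetic-genome generator

`simulate_ancestor()` builds a circular genome from explicit composition
targets (defaults: 180 kb, G+C 0.31, 200 genes from a pool of real plastid
symbols, 29 tRNAs, one rRNA operon, 15% intergenic). Coding sequences are a
planted start codon (88/6/6 ATG/GTG/TTG by default), random stop-free
interior codons, and a random stop; spacers are i.i.d. nucleotides. Because
stop-avoidance biases coding G+C slightly upward, the spacer composition is
tuned so the *whole genome* lands on the target (within ±0.01). Everything
is a pure function of the seed; the same seed gives byte-identical GenBank
output.

`evolve_genome()` applies segment inversions (order reversal plus strand
flip — exactly one DCJ operation each, which keeps the planted upper bound on
the DCJ distance exact), gene losses, and gene gains from the unused pool.
Transpositions are deliberately not generated: they would cost up to two
DCJ operations each and turn the clean bound `d ≤ k` into a looser one.
`make_clade()` evolves the ancestor down a nested tree with per-branch edit
counts and records, per leaf pair, the summed inversions along the
connecting path — the quantity the DCJ estimate must never exceed. For that
bound to be exact, gains are kept globally unique across branches (each
drawn from a shared, depleting pool of never-used names): if two lineages
could gain the same gene independently, or re-gain a gene lost upstream,
that gene would sit at unrelated positions in the two leaves and inflate
the distance beyond the planted inversion count.

What the generator does *not* emulate: nucleotide-level substitution or
indel processes, realistic intergenic motifs, gene family expansion, or
introns. Passing tests on synthetic clades therefore demonstrate the
correctness of the bookkeeping (coordinates, orders, sets, distances), not
robustness to annotation noise in real data — that is what the
accession-based checks, which require user-supplied GenBank records, are
for.

## Problem sizes and determinism

The test matrix exercises the generator at 15–40 kb with 12–60 genes for
module tests, and the full default scale (six leaves at 180 kb, 200 genes)
once, in the end-to-end acceptance check; the BFS oracle suite uses 200
random pairs at $N \le 6$. These sizes were chosen so the whole suite
verifies every stage on a single CPU in a few minutes while still touching
the generator's default (study-scale) conditions. All randomness flows from
explicit integer seeds; derived branch seeds are kept below $2^{31}$.

## Worked example

```{r example, eval = FALSE}
library(plastidcomp)

tree <- list(name = "root", children = list(
  list(name = "sp1", edits = c(inversions = 2, losses = 2, gains = 1)),
  list(name = "sp2", edits = c(inversions = 3, losses = 1, gains = 0))))
clade <- make_clade(sim_params(genome_length = 30000, n_genes = 30,
                               n_trna = 6, seed = 1), tree)

run_report(clade$genomes, "report_out")
read_tsv("report_out/dcj_matrix.tsv")
```

## Known limitations

* GenBank support covers the flat-file subset annotated genomes use
  (LOCUS/FEATURES/ORIGIN, `join`/`complement`, multi-line qualifiers);
  exotic location operators (`order(...)`, remote references) are not
  parsed.
* Marker extraction drops duplicated genes entirely rather than matching
  copies, so heavily duplicated genomes lose signal.
* The partition treats absence of a name as absence of the gene; an
  unannotated but present gene (the usual cause of spurious "losses" in
  real data) is invisible to it.
* DCJ distances are computed on gene orders, not alignment blocks; see
  above for how to read them.
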