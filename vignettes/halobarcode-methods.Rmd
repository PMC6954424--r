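---
title: "Counting barcoded protein molecules: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting barcoded protein molecules: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halobarcode)
```

## The assay and its computational problem

In a protein-barcoding assay each protein molecule is covalently coupled, at
1:1 stoichiometry, to a synthetic oligonucleotide. The oligo concatenates
four segments:

* a **protein identifier** — a fixed 8-bp sequence naming the protein,
* a **counting tag** — a 30-bp semi-random sequence (24 random + 6 fixed
  bases) that is unique per molecule with overwhelming probability,
* two **31-bp amplification arms** flanking the payload for PCR,

for a 100-bp oligo in the default design. After an assay step (a pulldown,
an immunoprecipitation), the surviving barcodes are PCR-amplified and
sequenced; each 76-bp read covers the 38-bp identifier+tag region. The
computational task is to turn those reads into (i) per-protein
unique-molecule counts and (ii) positive/negative assay decisions.

The difficulty is that PCR and sequencing introduce substitutions, so one
true molecule appears as a cloud of near-identical tags, and reads from
barcodes that were never in the tube appear at a low background rate. The
pipeline deals with both: an error-tolerant demultiplexer with a fixed-base
read filter, distance-based tag clustering, and a noise floor estimated from
deliberately unused barcodes.

## Demultiplexing and the fixed-base filter

Reads are assigned to proteins by Hamming distance between the 8-bp
identifier segment and the schema's identifier table. The default tolerance
is one mismatch with an unambiguous-best requirement (ties are unassigned).
A direct 8-mer comparison is exact and reproducible at this length; the
schema validator enforces a minimum pairwise identifier distance (default 3)
that makes 1-mismatch assignment provably unambiguous. An aligner adds no
power for 8-mer lookup, so none is used. Reads are processed in sequencing
orientation only; the amplicon design fixes the orientation.

The counting tag carries 6 invariant bases (A, C, T, G, A, C by default).
A read whose tag mismatches *any* fixed base betrays a synthesis, PCR or
sequencing error in the tag region and is excluded from counting entirely —
not rescued — because an error visible at the 6 monitored positions implies
a substantial chance of unseen errors among the 24 random positions, which
would inflate molecule counts. For a uniformly random 30-mer the expected
number of fixed-base mismatches is 6 × 3/4 = 4.5, so the filter also removes
essentially all foreign sequence.

Where the 6 fixed bases sit inside the 30-mer is a property of the oligo
design, not of the algorithm; the pattern is therefore configurable as a
string over `{A,C,G,T,N}`. The default interleaves one fixed base after
every four random bases. Downstream logic uses only the mask, so the choice
does not affect counting.

Quality strings are parsed and carried along but not used for filtering: the
assay's protocol defines no quality filter, and the fixed-base filter plays
that role.

## Molecule counting by tag clustering

Distinct tags within a small edit distance of each other almost surely
descend from the same true molecule, because the tag space (4^24 ≈ 2.8e14)
makes chance proximity negligible at assay scale, while PCR/sequencing
errors generate near neighbours constantly. The counter therefore clusters
each protein's filtered tags with **distance 2, 6 fixed bases, 24 random
bases** and reports the number of clusters as the molecule count.

The clustering rule is greedy and abundance-ordered, as is standard in the
unique-molecular-identifier literature: distinct tags are visited by
decreasing read count (ties broken lexicographically); a tag joins the
earliest-seeded cluster whose *representative* is within distance 2,
otherwise it seeds a new cluster. The rule is deterministic, independent of
read order, and O(n·k) with k clusters. A literal O(n²) re-implementation
(`brute_force_cluster()`) with an explicit pairwise distance matrix serves
as an independent oracle in the test suite; the two must agree exactly.
Single-linkage merging is available behind `cluster_params(linkage =
"single")` for sensitivity analysis — it merges chains that greedy
clustering keeps apart, and is deliberately not the default because
transitive chaining under-counts at high depth.

Distance is Hamming by default: tags are fixed-length and extracted at a
fixed offset, and substitutions dominate short-read errors; an indel would
shift the fixed-base register and be removed by the filter anyway.
Levenshtein distance (via `utils::adist`) is available by configuration.
Distance is computed over the full 30-mer, but since filtered tags agree at
all six fixed positions this provably equals the distance over the 24 random
bases — making an otherwise open layout question irrelevant post-filter.

## Noise floor and assay calls

Barcodes that were synthesized but never used in an assay still attract a
trickle of reads (index hopping, cross-contamination, demultiplexing error).
The read counts of these *unused* identifiers estimate the sequencing
background: the noise floor is their **mean + 3 SD**, with SD computed with
the sample (n−1) denominator so the threshold is reproducible at the small
number of unused barcodes typically available.

A prey protein is called **positive** only when three rules all hold, each
recorded individually in the output:

1. *minimum signal*: at least 10 reads (below 10 a pair is negative),
2. *control excess*: strictly more reads than the matched tag-only negative
   control ("exceeds" is read strictly, so ties are negative),
3. *noise floor*: signal at or above the unused-barcode mean + 3 SD.

The three rules overlap in intent; this package composes them as a
conjunction — the most conservative reading — and each is individually
toggleable (rule 3 by passing `floor = NULL`, rule 1 via `min_reads`).
A pair failing only the noise-floor rule is labelled `background_noise`
rather than plain `negative`, since the distinction is diagnostically
useful. The rules apply to read counts by default, with molecule counts one
flag away (`call_on = "molecules"`), because read counts are the quantity
the thresholds were defined on.

Reference-set screens (a positive reference set, PRS, of literature-
supported pairs against a random reference set, RRS) are compared with a
two-tailed Fisher's exact test computed by hypergeometric enumeration under
the point-probability rule: all tables with both margins fixed whose point
probability does not exceed the observed table's (within relative tolerance
1e-7, guarding against floating-point ties) contribute to p. This is the
convention of `stats::fisher.test` and of the common online calculators;
the test suite checks agreement with `stats::fisher.test` on random tables
and with explicit `choose()`-based enumeration on extreme tables.

Immunoprecipitation dilution series use the same comparison logic per
dilution step: replicate-barcode reads (the default design barcodes one
antigen with four oligos) are summed, a step is positive iff its sum
strictly exceeds the matched background-control sum, the specificity ratio
divides the signal by the reference-serum signal, and the detection limit is
the largest dilution factor still positive.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` generates reads with full ground truth:

1. each true molecule draws a distinct counting tag (collisions re-drawn, so
   truth is collision-free by construction; the birthday bound M²/(2·4^24)
   makes re-draws vanishingly rare),
2. each molecule is amplified by a **Galton–Watson branching process**: per
   cycle, every amplicon duplicates with probability `pcr_efficiency`, and
   every new copy acquires substitutions at `pcr_error_rate` per base —
   branching (rather than deterministic doubling) produces the realistic
   read-count skew across molecules that stresses the abundance-greedy
   clusterer,
3. `reads_out` amplicons are sampled uniformly with replacement, or every
   amplicon exactly once in *exhaustive* mode,
4. each read is assembled to 76 bases and acquires substitutions at
   `seq_error_rate` per base,
5. a fraction `unassigned_fraction` of reads has its identifier replaced by
   a random 8-mer, emulating foreign amplicons.

Defaults, chosen once as field-typical values: 8 effective cycles at
efficiency 0.8 (an amplicon pool ≈ 110× the molecule number — enough
branching for realistic skew while keeping simulation cheap; the real
protocol's ~29 cycles beyond pool saturation only rescale all counts),
`pcr_error_rate` 1e-5 per base per duplication (high-fidelity polymerase
order of magnitude), `seq_error_rate` 1e-3 per base (short-read platform
order of magnitude). Identical configurations yield byte-identical output.

The simulator models substitutions only (consistent with the Hamming
metric), constant quality strings, no chimeras, no sequencer-specific error
profiles, and no quality-dependent error rates. Passing tests on simulated
data therefore demonstrate correctness of the counting and calling logic
under a substitution-error generative model — not robustness to indels,
adapter artefacts or platform-specific biases in real data.

Exhaustive mode exists to make limit statements exact: with all error rates
zero and every amplicon emitted once, the counter must recover the
configured molecule numbers *exactly*, with no stochastic slack — the test
suite asserts this.

## Numerical and interface choices

* Coordinates are 1-based inclusive in all R interfaces, following base R
  and Bioconductor convention; `read_offset` alone is a 0-based *offset*
  (number of bases preceding the region), the natural parameterisation for
  "region starts at the beginning of the read" (`read_offset = 0`).
* Clustering tie-breaks are fully specified (read count descending, then
  lexicographic; clusters reported by total reads descending, then
  representative), so every table the package writes is reproducible
  byte-for-byte.
* The default amplification-arm sequences are placeholder 31-mer PCR
  handles; arms flank the counted region and never affect demultiplexing or
  counting, and real designs override them in the schema config.
* Validation problem sizes used by the acceptance checks: clustering oracle
  equivalence on 100 random instances of up to 200 distinct tags; counting
  recovery on 20 simulated experiments with true counts 100 and 50 at 20×
  read depth and substitution rates 0.001, summarised as the mean absolute
  relative error per protein across seeds (the per-seed error at true count
  50 is quantised to 2% steps, so the seed-averaged error is the meaningful
  resolution at this problem size).

## Known limitations

* The in-house clustering rule of the original assay software is not
  published; the greedy abundance-ordered rule implemented here is a stated
  design commitment, standard in the UMI literature, not a claim about the
  original implementation.
* Identifier demultiplexing tolerates one mismatch by default; whether the
  original pipeline tolerated any is unknown, and exact-only matching is one
  flag away (`max_mismatch = 0`).
* Whether the 10-read minimum applies before or after noise-floor
  subtraction is ambiguous in prose descriptions of such assays; it is
  implemented as an independent conjunct, and each rule's outcome is
  recorded per call so either reading can be audited.
* Counting accuracy degrades when per-read tag error rates approach the
  clustering distance (≥3 expected substitutions per tag), and molecule
  counts above ~10^4 begin to feel the tag-space collision bound.
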