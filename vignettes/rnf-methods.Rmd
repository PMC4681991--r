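---
title: "Encoding simulated-read truth in read names and evaluating mappers with it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding simulated-read truth in read names and evaluating mappers with it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnfr)
```

## The problem

Mapper benchmarking with simulated reads has three stages: simulate reads
whose true origin is known, map them, and classify every alignment as
correct or not. The weak link is the middle of the pipe: each simulator
records the truth in its own format, so evaluation tools must special-case
simulators. The Read Naming Format (RNF) removes the coupling by encoding
the truth in the read name itself, in a grammar any tool can parse.

## The name grammar and its assumptions

A *read tuple* is everything sequenced from one DNA fragment; its elements
are *reads*, and each read is a chain of *segments* — spatially distinct
origin intervals, each corresponding to one SAM line. A segment is
rendered `(genome_id,chromosome_id,direction,L,R)`: integer genome and
chromosome IDs, direction `F`/`R`, and 1-based *closed* coordinates.
Unknown values render as `0` (`N` for direction), which is how a random
contaminant read with no meaningful placement is expressed:
`(1,0,N,0,0)`.

The long read name (LRN) has exactly four `__`-delimited parts — prefix,
zero-padded lowercase hexadecimal tuple ID, comma-joined segment block,
extension suffix — and the segment block is sorted by (genome,
chromosome, left, right, direction). Because all segments of all reads are
sorted jointly, read membership is *not recoverable from the name*; this
is a property of the format, not a defect of the decoder. `decode_lrn()`
therefore returns a flat sorted segment list, and read membership travels
with FASTQ file pairing (mates share a tuple name across files). An
optional `[pair:i]` extension can carry it explicitly when files are not
available.

Several points of the grammar are fixed here by design decision because
the format description leaves them open:

- **Segment separator**: `,` between parenthesized segments — a
  single-character separator outside the segment alphabet.
- **Extension syntax**: `[tag:value]` units concatenated in the suffix;
  tags alphanumeric, values excluding `[`, `]`, `_` (so the four-part
  split stays unambiguous).
- **Hex ID case and padding**: lowercase, zero-padded to the number of
  hex digits of the batch's largest ID, so lexicographic order equals
  numeric order within one file; width 1 for single encodes.
- **Direction sort order**: `F < N < R`, plain character-code order (the
  sort keys list direction last without defining its order).
- **Empty prefix** is legal; the delimiters remain, so the name still
  splits into four parts.
- **Length fallback**: "exceeds 255" is read strictly — an LRN of exactly
  255 characters (the SAM name limit) is kept; at 256 the short name
  `#<hex id>` is emitted and a two-column tab-separated SRN–LRN
  correspondence file (suffix `.sl.tsv`, no header) is written next to
  the FASTQ.
- A chimeric read (fusion/long deletion/translocation) must have at least
  two segments; `rnf_read()` refuses `chimeric = TRUE` with fewer.
- Genome ID 0 together with known coordinates is tolerated by the
  validator (warn-level semantics): the format does not forbid it, and
  rejecting it would make partially-known truth inexpressible.

## Dialect conversion

Upstream simulators differ in one semantically important way: wgsim
records the **first nucleotide of each end** — for a reverse end that is
its *rightmost* base — while dwgsim and CuReSim record the **leftmost
nucleotide of each end** regardless of strand. Converters reconstruct the
missing endpoint from the read length (`left = pos − L + 1` for a
first-nucleotide reverse end). Upstream name formats drift across
versions, so the grammars ship as editable `key=value` pattern files
(`inst/extdata/dialects/`) with named-capture regular expressions, and
any file in the same format can be loaded with `load_dialect_file()`.
When a dialect does not encode strand (CuReSim single-end), the direction
becomes `N` and the right coordinate 0 — the converter never guesses.
SAM-truth conversion (Art/Mason style) computes
`right = POS + reference-consumed CIGAR length − 1` (M/D/N/=/X consume
reference; insertions and clips do not); secondary and supplementary
truth records become additional segments of the same read, so chimeric
truth is representable. Pirs's bespoke text format is not converted: its
structure is not documented well enough to implement without guessing.

## The built-in simulator: what it emulates, and what not

The generator exists so the whole toolchain is testable stand-alone, not
to model a sequencer. It samples a chromosome proportionally to length,
a start uniformly over valid positions, a strand uniformly, and applies
independent per-base substitutions at a configurable rate (default 0) to
a uniformly chosen different base; qualities are constant `I` (Q40).
Paired mode draws the fragment length from a normal distribution
(defaults: mean `3 × read_length`, coefficient of variation 10%), rounds
and clamps it to `[read_length, chromosome length]`, and emits an FR
pair with mate 2 on the reverse strand. There are no indels, no quality
model, no coverage or GC bias, and no genomic mutations — realism is the
province of the dedicated simulators whose output the converters ingest.
Consequently a green end-to-end test establishes that *bookkeeping* is
exact (names address the right substring, counts conserve, curves follow
their definitions), not that any mapper ranking would transfer to real
error profiles.

The central invariant the whole toolchain leans on: at substitution rate
0, every emitted sequence equals the reference substring addressed by its
own name (reverse-complemented for `R`). The mixer preserves the multiset
of sequences, rewrites each sample's genome ID (refusing duplicate IDs,
which would make provenance ambiguous), re-assigns tuple IDs to be unique
across the merged file, and interleaves round-robin by default —
deterministic — with a seeded shuffle available.

## LiftOver of truth coordinates

Chain files are parsed in their native 0-based half-open convention and
converted to RNF's 1-based closed coordinates at exactly one boundary,
avoiding off-by-one proliferation. A segment lifts only if both endpoints
map through the *same chain* and the lifted interval preserves the source
length; endpoints straddling an indel gap inside a chain therefore fail,
and the segment returns with coordinates zeroed and direction `N`. Truth
must never be approximate — a nearest-block rescue would silently turn
"correct" into "wrong by a few bases" downstream. When chains overlap,
the highest score wins, ties broken by file order. On a reverse-strand
chain the direction flips and endpoints swap. Already-unknown segments
pass through unchanged.

## Evaluation: categories, curves, conventions

The unit of evaluation is the individual read via its primary SAM record
(each segment corresponds to one SAM line); paired ends score
independently, and secondary records are ignored because multi-mapping
policy is mapper-specific. A read is *reported* at threshold `q` when it
is mapped with MAPQ ≥ `q`. Truth matching is by leftmost coordinate
within a tolerance (default 5 bases), same chromosome, same genome, and —
by default — agreeing strand (a truth direction of `N` matches either).
The tolerance default is deliberate looseness: mappers legitimately
differ by a few bases around homopolymers and clips, and the definition
of "correctly mapped" is known to vary between studies, so it is a
visible, documented knob rather than a hidden constant. A read whose
truth has *no* segment from the reference genome is a contaminant. The
six categories (CORRECT, WRONG_POSITION, CONTAMINANT_MAPPED,
SHOULD_MAP_UNMAPPED, CONTAMINANT_UNMAPPED, UNDER_THRESHOLD) are
exhaustive and mutually exclusive, so counts conserve the total at every
threshold. A chimeric read is CORRECT if its primary alignment matches
*any* of its true segments; requiring all segments would conflate the
primary-record convention with supplementary-alignment scoring, which is
out of scope.

Mapping qualities are not comparable across mappers at a fixed cutoff, so
curves are *parametrized* by the MAPQ threshold: at each `q`,
`sensitivity = CORRECT / (non-contaminant reads)` and
`precision = CORRECT / (CORRECT + WRONG_POSITION + CONTAMINANT_MAPPED)`,
with `FDR = 1 − precision` on the x-axis of the main figure. Numerical
conventions: precision is defined as 1 when the denominator is 0 (no
discoveries ⇒ no false discoveries); mapped contaminants count as false
discoveries by default (`contaminants_in_fdr = FALSE` excludes them —
defensible when contamination detection is not the question, but then the
blind and aware mappers above would look identical); the threshold sweep
uses the distinct observed MAPQ values plus a sentinel 0, which yields a
curve identical to a dense 0–255 sweep with fewer points, and an explicit
threshold vector can be supplied to compare mappers on a shared grid.

## The fixture world

`make_fixtures()` builds the deterministic toy world the heavier tests
consume: two 10-kb uniform-random genomes ("host", "contaminant"), 1000 +
1000 error-free reads mixed into one sample, and three scripted
pseudo-mappers written as SAM — *perfect* (truth positions, MAPQ 60,
contaminants unmapped), *blind* (corrupts each host read's position with
probability 0.2 and maps every contaminant at a random host position),
and *aware* (identical host records, contaminants unmapped). MAPQ
correlates with correctness (correct 40–60, corrupted 0–20, blind-mapped
contaminants 20–60) so the two noisy mappers share thresholds over the
whole range and the contamination penalty is visible at every shared
threshold. The 1000 + 1000 design is the full-genome contamination
experiment (reads from a host and a foreign genome mapped to the host)
reproduced at desk scale; a 10-kb uniform-random genome has essentially
no repeats, so position corruption must be injected by the scripted
mapper rather than arising from genuine ambiguity — another reason a
green fixture run validates the evaluator's arithmetic, not mapper
quality.

## Known limitations

- Read-boundary grouping is not recoverable from a decoded name (format
  property; see above).
- The built-in simulator has no indel or quality model; converted
  external reads are the intended source of realism.
- Liftover composes chains only pairwise by re-running; multi-step
  composition is not a feature.
- The evaluator does not score edit-operation-level correctness (CIGAR
  comparison) or interval-overlap sensitivity; correctness is
  leftmost-coordinate-within-tolerance only.
- The HTML report is static (tables mirror the TSVs cell for cell; SVG
  figures are hand-rendered polylines), trading interactivity for
  diffable, dependency-free output.
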