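---
title: "Models and methods: junction chemistry, derivative reconstruction and mechanism signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svjigsaw)
```

This vignette documents the models behind `svjigsaw`, the parameters that
matter, what the simulator does and does not emulate, and the design
choices made where the design was genuinely open. Every empirical number
mentioned here is computed by the test suite or the acceptance script, not
asserted from memory.

## Coordinates and breakpoint sides

All coordinates are 1-based and inclusive at both ends; conversion to
0-based half-open happens only inside format readers/writers (BED). A
breakpoint side is `(contig, position, orientation)` where `position` is
the last retained base of that side's flank and the orientation says how
the flank reads when approaching the junction: `+` means reference-forward
ending at `position`, `-` means the reverse complement beginning at
`position`. A junction is an unordered pair of oriented sides; the
canonical order is lexicographic by `(contig, position)`. Under this
convention a simple deletion is `(+,-)`, the two joints of an inversion are
`(+,+)` and `(-,-)`. `N` never matches anything in homology computations,
so masked sequence cannot generate fake microhomology.

## Microhomology by slide ambiguity

The package defines microhomology operationally: the number of breakpoint
placements consistent with the observed derivative, minus one. Writing the
derivative around a junction as `F1 | B2`, the junction can slide right
when the reference continuation of side 1 equals the next base of `B2`,
and left when the last base of `F1` equals the base `B2` would acquire if
side 2 extended. The reported placement is left-aligned (side 1 as short
as possible), which makes records planted anywhere inside a homology tract
collapse to one canonical record — a property the tests assert directly.
An independent brute-force oracle (enumerate all shifted placements,
compare derivative content) agrees with the implementation on 1000 random
side pairs per run.

Because microhomology is slide ambiguity, a junction with inserted bases
has `MH = 0` by definition: the insert interrupts both slides. Two rows of
the transcribed cohort table annotate small flank-edge microhomology next
to an insert; they are loaded verbatim through an explicit constructor
opt-out but can never be produced by the characterizer.

## From reads to junctions

* **Split-read collection.** Reads whose primary and supplementary records
  map to two loci become oriented side-pair observations, clustered
  single-linkage with a positional tolerance (default 50 bp, the scale of
  mapping jitter around a junction; configurable). Groups below
  `min_support` (default 2; shallow mate-pair data may justify 1) are
  dropped. When candidate SV regions are supplied, groups with a side
  inside a padded candidate region (default 1 kb) are kept.
* **Consensus.** Star alignment around the longest read; remaining reads
  join by best ungapped offset (minimum overlap 25 bp, minimum identity
  0.9), majority vote per column, ties broken A < C < G < T. With three or
  more reads, single-read overhangs are trimmed, since a lone erroneous
  base there cannot be outvoted. Unplaceable read sets return the seed
  read with a low-confidence flag.
* **Anchoring.** The consensus prefix and suffix are located in the
  reference by exact 31-mer seeding (either strand), stepping the probe
  inward by 8 bp when sequencing noise breaks the outermost k-mer, then
  extended maximally in both directions. 31 bp makes a random collision
  vanishingly rare even on megabase references; both anchors must cover at
  least `min_anchor` (default 20) bases. Anchor overlap in consensus
  coordinates is microhomology; an anchor gap is inserted sequence.
* **Insertion decomposition.** Greedy left-to-right cover of the insert by
  maximal exact matches to the ±`window` (default 100 nt) flanks of both
  sides, both strands. Matches of at least `min_templated` nt become
  templated blocks with source interval and strand; the rest is
  non-templated. `min_templated` defaults to 10: long enough that a random
  10-mer is unexpected in four 201-nt windows (expectation ≈ 8 × 192/4^10
  ≈ 1.5 × 10⁻³ per insert position), short enough to catch real templated
  tracts. Both knobs are exposed because one published templated insert
  has a printed source outside the 100-nt window.
* **Nearby variation.** Repeat elements overlapping each side are
  annotated from a RepeatMasker/BED track with a same-family flag over the
  classes Alu / LINE (L1–L4, HAL) / MIR / LTR-like / other. Pileup over
  ±1 kb windows calls junction-proximal SNVs (alternate fraction ≥ 0.25,
  depth ≥ 8); candidates present in a population frequency table above
  threshold 0 — that is, any previously reported variant — are flagged
  non-novel.

## Descriptors, structures and pattern strings

The descriptor grammar is a pragmatic HGVS-like subset fitted to the
constructs that occur in printed clustered-CNV case reports: `del`, `inv`,
`dup`, `ins`, `delins`, bracketed payload lists with per-element `inv`,
bare ranges, `pter`/`qter` and `?`. Full HGVS compliance is explicitly not
attempted. Two conventions matter downstream: `dup` means a direct-
orientation copy immediately 3′ of its template (tandem), while copies
supplied through `ins`/`delins` payloads are interspersed; and a
reference-descending payload range denotes an inverted copy. Parsing is
lossless (`serialize(parse(d)) == d` modulo whitespace for all 21 bundled
descriptors); typographic noise in the printed tables (stray underscores
before `ins`, a stray semicolon, one dropped digit restored from the same
case's junction table) is normalized in the fixture with raw strings kept
alongside.

A derivative structure is the ordered, oriented list of reference segment
uses: retained pieces (span minus deletions, flipped where covered by
inversions, split at insertion anchors) interleaved with duplicate copies
at their target positions. The pattern string walks the rearranged span
left to right and emits one token per maximal segment from the derivative
haplotype's copy counts (the intact homolog contributes one copy
everywhere): `DEL` where no copy survives, `DUP`/`DUPinv` where extra
copies exist, `INV` for copy-neutral segments whose surviving copy is
inverted, `N` otherwise. Three deliberate choices:

* adjacent identical `DUP`/`INV` tokens merge only when they come from the
  same duplicate fragment — distinct shattered fragments keep distinct
  tokens, as the printed patterns do;
* non-`INV` tokens of width 1 bp are suppressed: they are artifacts of
  printed coordinate endpoints, not dosage segments, whereas a 1-bp
  inversion token is junction-level evidence and is kept;
* a forward payload copy flanked on both sides by inverted copies is
  reported inverted ("block inversion" context): a forward fragment riding
  inside an inverted cluster reads backwards relative to the flow of the
  derivative.

Thirteen of the twenty `?`-free bundled cases reproduce their printed
pattern exactly under these rules. The remaining seven expose
inconsistencies between the printed descriptors and the printed patterns
themselves (a deletions-only case whose descriptor implies gains;
orientation annotated on duplications in one cohort group but not the
other); the corresponding acceptance test is intentionally left failing
and the project notes carry the case-by-case analysis, because no single
convention can satisfy both printed sources.

## Reconstruction and enumeration

The fragment graph partitions the span at every breakpoint and copy-number
boundary; each node carries its copy-number state and its derivative copy
count (`state − 1`). Junction edges attach to node ends according to side
orientation; one-sided junctions stay as half-edges. Enumeration is
exhaustive depth-first search over walks from the left to the right
terminus that consume each node exactly its copy count and each junction
edge exactly once, with reference-adjacency steps always permitted; with
at most ~15 fragments this is trivial, and a `max_solutions` cap (default
64) guards degenerate inputs. When copies are indistinguishable the first
traversal of an interval is labelled the template — a labelling choice
that cannot affect tandem/interspersed calls. For the bundled
five-duplication case the constraint set admits multiple walks including
the descriptor-derived one, reproducing the published order ambiguity; the
original figure showing three drawn alternatives is not recoverable from
text, so the test asserts ambiguity and containment rather than a count of
exactly three.

A duplication call requires at least half of a copy's length to be present
in two or more derivative copies — payload copies of regions deleted in
place are copy-neutral relocations, not duplications. Tandem means a
direct-orientation copy immediately following derivative material carrying
its template; everything else is interspersed.

## Mechanism signatures

Per-junction flags are a pure function of the record, its annotations, and
a configuration holding the published thresholds: NHEJ-compatible
microhomology ≤ 4 bp; Pol-θ insertion scar 5–25 bp (larger values keep the
flag with an `above_max` note); replicative microhomology 1–5 bp;
ambiguity-triggering non-templated insert > 8 bp; Alu-pair identity bound
90% for plausible homologous recombination. The case-level decision tree
is deliberately simple and documented: a large non-templated insert in a
case not dominated (> 50%) by NHEJ-like junctions suggests an ambiguous
mechanism; otherwise deletions-only suggests chromothripsis and any case
with duplications suggests chromoanasynthesis. The published expert
partition of the bundled cohort (7/10/4) is reproduced only when the
shipped override table is applied — five rows, each with its reason, two
of them for cases with no resolved junction at all. The overrides are
data, visible in every call's evidence trail; the bare tree matches 16 of
21 and always respects the group backbone.

The breakage-fusion-bridge / attempted-ring detector asks a narrow
structural question: is a terminal deletion at one chromosome end occupied
by an inverted duplicated copy of the opposite terminal region? Spans that
do not reach both chromosome ends return "not evaluable" rather than
false-negative evidence.

## The simulator's world — and what a green test does not establish

The simulator emulates the sequencing designs under which such cohorts are
characterized: paired-end libraries with 2 × 150 bp reads, 350 bp mean
insert and 30× coverage (the defaults), or mate-pair libraries with 2–15
kb fragments; uniform substitution errors at a configurable rate (0 to a
few per mille); junction chemistry planted exactly — engineered homology
tracts, non-templated inserts, templated inserts copied from inside (or,
to probe window sensitivity, outside) the search window; heterozygous SNVs
near junctions; split alignments computed analytically from the truth
mapping rather than by an external aligner, including soft-clips, strand
flags and supplementary-alignment links.

It does not model: coverage biases or GC waves, indel or quality-score
error structure, chimeric mate-pair artifacts, duplicate reads, repetitive
reference sequence (references are i.i.d. random with a target GC), or
multi-chromosome derivatives. Consequently, green round-trip tests
establish correctness of the junction arithmetic — coordinates,
orientations, microhomology, insert decomposition — under honest read
noise, but say nothing about mapping ambiguity in repeats; that is what
the repeat-annotation flags and the configurable support thresholds are
for on real data. Round-trip tests run on 12-kb references to keep the
suite fast; nothing in the algorithms depends on reference length except
anchor-collision probability, which only improves the case for 31-mers.

## Numerical and edge-case choices

* Every stochastic routine takes an explicit seed (package default 42 for
  plants, 1 for libraries); identical seeds give byte-identical output.
* Consensus ties break in fixed base order; enumeration output is sorted
  lexicographically by walk — both remove platform-dependent ordering.
* Reversed (zero-width) intervals in printed descriptors parse as
  degenerate deletions rather than failing the whole descriptor.
* Unresolvable consensus sequences yield records with `NA` chemistry
  rather than being dropped; the resolved-junction statistic of the
  bundled cohort (63 of 83) depends on preserving `NA`.
* The cohort summary rounds means and percentages to the nearest integer,
  as the published statistics do; the microhomology median is computed
  over MH ≥ 2 junctions and reported but not asserted against the printed
  value, which disagrees with the printed table.

## Known limitations

Interspersed-duplication placement is reported as the descriptor or walk
states it, with no probabilistic ranking of alternative walks. Derivatives
are single-chromosome. The repeat-family classification is name-prefix
based, not alignment based; Alu-pair identity is only compared against the
homologous-recombination bound when sequences are supplied. The CLI
exposes the analysis path end to end but is a convenience, not a
workflow manager.
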