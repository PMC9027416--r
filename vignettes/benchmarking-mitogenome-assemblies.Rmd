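---
title: "Benchmarking long-read mitogenome assemblies against a reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking long-read mitogenome assemblies against a reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitobench)
```

## The problem

Mitochondrial genomes assembled purely from nanopore long reads are
nearly — but not exactly — identical to a trusted short-read ("gold
standard") assembly of the same organism. The residual discordance is
dominated by 1–2 bp insertions and deletions at homopolymer runs, the
characteristic nanopore failure mode, with a minority of substitutions
and non-homopolymer indels. Quantifying that discordance precisely is
what this package does: given a circular reference and one or more
candidate assemblies, it reports each assembly's uncorrected
p-distance to the reference, a per-category error profile under a
homopolymer-aware taxonomy, and an audit of which protein-coding genes
(PCGs) the errors disrupt.

Because a candidate contig is a circle with an arbitrary origin and
strand, the pipeline has four stages, each of which this vignette
documents: circular normalization, global alignment with canonical gap
placement, error extraction and classification, and reporting/auditing.
A seeded simulator provides references and error-injected assemblies
with exact ground truth, so every stage is testable without any
sequencing data.

## Circular normalization

`normalize_assembly()` first decides strand by comparing circular
k-mer multisets (default `k = 15`): at mitogenome scale (~16.7 kb) the
two strands of an unrelated-orientation assembly share a negligible
number of 15-mers, so the decision is sharp; an exact tie (possible
only for near-perfect palindromes) raises a typed condition rather
than guessing.

Rotation then places the locus matching the reference's leading
`anchor_len = 31` bases at position 0. The search scans the anchor
against the doubled assembly string — the standard trick that turns
circular matching into linear matching — in O(n · anchor_len). A
subtlety matters here: when a sequencing error sits *inside* the
anchor window, the offset with the best exact-match score can be
displaced by the indel's length, and the true offset may score far
below it. The search therefore keeps the near-maximal offsets plus a
±8 bp neighbourhood (no category in the taxonomy is longer than 7 bp)
and adjudicates candidates by *anchored window alignments* at both
ends of the candidate rotation: the reference's leading
`refine_len = 300` bases aligned against the rotation's leading
window (both anchored at the start, the assembly's tail free) plus
the mirrored computation at the trailing end. A displaced origin pays
leading gap costs at one end or wraps bases into spurious indels at
the other, while an error inside either window penalizes all
candidates equally; ties resolve to the smallest offset, which also
settles the genuinely ambiguous case of an indel touching position 0
itself. Two designs that do *not* work motivated this one: a
fixed-width global window charges the correct offset a spurious
terminal gap whenever an insertion pushes reference content past the
window end, and a start-only anchored window cannot see bases that a
displaced origin wraps to the far end of the sequence.

Rotation requires the assembly length within 50% of the reference
length and at least `anchor_len / 2` matching anchor bases; violations
signal a failed assembly or wrong organism rather than proceeding to a
meaningless alignment. Linear-topology inputs are not rotated (offset
0, with a warning) since they have no origin to move.

## Alignment and canonical gap placement

`global_align()` computes an optimal end-to-end (Needleman–Wunsch/
Gotoh) alignment with affine gaps, implemented in C++ with a packed
one-byte-per-cell traceback (~290 MB transient for 17 kb × 17 kb;
a `max_cells = 1e9` guard refuses accidental genome-scale input). A
pairwise optimal alignment was chosen over a multiple-alignment
heuristic deliberately: only two sequences are ever compared per
benchmark, and optimality plus fixed tie-breaking makes results
bit-reproducible.

The default scoring (match +2, mismatch −3, gap open −5, gap extend
−2 per additional column) favors one contiguous indel over scattered
mismatches, matching the expected structure of discordance at ~99.9%
identity. Terminal gaps are charged like internal ones: after rotation
into a common circular frame, the sequence ends are not special.

The position of an indel inside a homopolymer run is alignment-
arbitrary, so `normalize_gaps()` canonicalizes placement before
classification: every gap run is shifted left while the base entering
the aligned column equals the one leaving it, which provably preserves
both sequences and every column's match state. The procedure is
idempotent, and the test suite verifies that classification is
invariant across all score-equivalent placements produced by a
brute-force shuffler.

## The error taxonomy

`extract_events()` emits one event per maximal gap run per row
(insertions in the reference row, deletions in the assembly row) and
one per mismatching column. Counting per *event* rather than per base
is deliberate: published per-assembly totals in this setting (65–110
for ~16.7 kb at p-distance ~1e-3) are only consistent with indel runs
counted once. Adjacent substitution columns remain separate events;
an insertion run adjacent to a deletion run remains two events
(the taxonomy has no replacement category).

`classify_events()` then applies, in order: substitution; homopolymer
indel (`HP_INS_k` / `HP_DEL_k`, k = 1..7); single indel (`INS_1` /
`DEL_1`); short indel of 2–4 bp (`INS_SHORT` / `DEL_SHORT`). The
classifier is total: ≥5 bp non-homopolymer indels and >7 bp
homopolymer indels land in extension categories (`*_LONG`,
`HP_*_GT7`) flagged "outside the published taxonomy" in reports.

The homopolymer criterion defaults to **reference-run**: an indel of
identical bases qualifies when the flanking reference run is ≥2 bp
*before* the edit — the reference is ground truth, so inserting an `A`
next to a lone `A` is a plain `INS_1`. The alternative reading
(**resulting-run**, selectable in `run_config()`) asks whether the run
in the corrected sequence reaches 2 bp; it differs only in that
boundary case for insertions. For deletions both readings demand a
reference run ≥2 bp — removing one base of a 2-run must remain a
homopolymer deletion under either. Published descriptions of this
taxonomy do not pin the choice down; both are implemented, one is the
default, and the switch is recorded in every report's configuration
fingerprint.

## p-distance

`p_distance()` is the uncorrected proportion of differing sites. The
default convention is **pairwise deletion**: columns with a gap or an
`N` in either row are excluded from both numerator and denominator,
mirroring desktop phylogenetics suites; identical sequences give
exactly 0. Under indel-dominated discordance this choice matters — an
assembly whose only errors are homopolymer indels has p-distance 0
under pairwise deletion and a positive one under
**gaps-as-difference** (also provided). Which convention produced any
given published table generally cannot be determined post hoc, which
is precisely why the switch is explicit rather than silent.

`N` handling is conservative by default: `N` columns are neither
comparable sites nor errors. Setting `count_ambiguous = TRUE` counts
N-mismatch columns as substitutions. The simulator never generates
`N`, so these paths are exercised only by constructed fixtures.

## The ORF audit

Rather than re-annotating each assembly with external servers, the
package projects the reference's gene coordinates through the
alignment (`project_annotations()`): insertions inside a gene extend
its projection, deletions shrink it, a fully deleted gene maps to an
empty interval. This is deterministic, offline, and measures exactly
the quantity of interest — whether assembly errors interrupt reading
frames — rather than any annotation heuristic. Insertions
immediately flanking a gene's outermost bases are not attributed
to it.

`audit_orfs()` reads each projected PCG in frame 0
(reverse-complementing minus-strand genes) and counts internal stop
codons under the vertebrate mitochondrial code (table 2: `TAA`,
`TAG`, `AGA`, `AGG` — hard-coded, unit-tested against the Biostrings
code table). A gene is *disrupted* if it has an internal stop or its
net intra-genic indel length is not a multiple of 3. A gene is *not
detected* when its projection is empty or shorter than
`min_detect_frac = 0.5` of its reference length — a parameterized
stand-in for annotation tools missing heavily damaged short genes;
0.5 is a design choice, not an empirical constant. Incomplete terminal
codons are ignored, and the final complete codon is excluded from the
internal-stop count (vertebrate mitochondrial PCGs legitimately end in
stops, sometimes completed only by polyadenylation).

Coordinates are 0-based half-open internally and 1-based in
human-readable output. Genes spanning the circular origin are not
representable in the annotation track; inputs must be rotated so no
gene wraps (the simulator guarantees this, and the reader rejects
wrap-around intervals with instructions).

## The simulator

`generate_reference()` builds a circular
vertebrate-mitogenome-like reference: default length 16,705 bp, GC
0.38, 13 PCGs + 22 tRNAs + 2 rRNAs in the canonical vertebrate order
(`nad6` on the minus strand) with a control region absorbing the
residual length. Intergenic and RNA sequence comes from a run-length
process (runs of length 1 with tuned probability, otherwise
2 + geometric) iteratively calibrated so the fraction of bases inside
homopolymer runs ≥2 lands within ±0.05 of the target (default 0.45,
about what a GC-0.38 random sequence realizes). PCGs are overwritten
with stop-free in-frame codons starting `ATG` and ending `TAA`, which
caps achievable homopolymer enrichment — an accepted limitation since
codon usage is not modeled.

`inject_errors()` is count-based, not rate-based: the acceptance
surface is exact recovery of requested per-category counts, so
determinism beats realism here. Placement respects each category's
context (homopolymer events draw a qualifying run length-weighted,
mirroring the empirical concentration of errors at longer runs;
single indels need isolated bases; short indels are constrained so
their placement cannot left-shift into a different representation),
a minimum spacing of 10 bp between events, and at most one event per
homopolymer run — two indels in one run would merge into a single
alignment event and make exact recovery ill-posed. These constraints
are deliberate idealizations relative to real nanopore error tracts,
where errors do cluster; passing round-trip tests therefore certifies
the pipeline's bookkeeping, not its behaviour on pathological error
clusters. Rotation and strand flips are applied after mutation, so
the truth set stays in reference coordinates.

What the simulator does *not* emulate: base quality, signal-level
artifacts, coverage variation, chimeras, and real run-length-dependent
error rates (no published per-run-length rates exist to calibrate
against).

## Validation strategy and problem sizes

Every stage is checked against an independent oracle: the aligner
against exhaustive scoring on strings ≤12 bp (100 cases) and against
Biostrings' `pairwiseAlignment` at realistic sizes; p-distance against
a literal column scan (1,000 cases); rotation against an exhaustive
all-rotations minimal-edit-distance oracle (20 cases on 2.4 kb
genomes); stop counting against Biostrings translation under code
table 2. The flagship property is the full-scale round trip: 100
seeded injections into a 16.7 kb reference, each rotated and possibly
strand-flipped, must recover the injected per-category counts exactly
in ≥99 runs — rare residual failures can arise when an injected event
interacts with the origin region in a way the rotation refinement
cannot disambiguate. Module-level tests use 2.4–8 kb genomes to keep
the suite fast; the full-scale suite and the aggregate statistics over
the packaged published accuracy table run in the acceptance tests.

## Known limitations

* The aligner is exact but quadratic; it is sized for organelle
  genomes (the cell guard refuses inputs beyond ~1e9 DP cells).
* Coverage is pass-through metadata, never computed (no read mapping).
* The error taxonomy judges homopolymer context on the reference; a
  criterion based on both sequences simultaneously is not offered.
* The ORF audit checks frame integrity and internal stops only — no
  start-codon curation, no tRNA/rRNA structural validation.
* Simulator idealizations listed above.
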