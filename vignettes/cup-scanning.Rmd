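---
title: "Identifying conversion-unstable positions between genome builds"
author: "cupScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying conversion-unstable positions between genome builds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupScan)
```

## The problem

Coordinate liftover converts genomic positions from one reference build to
another through a chain file: a set of scored pairwise alignments, each a
list of ungapped blocks separated by gaps on either genome. Tools such as
liftOver and CrossMap do nothing but evaluate this file, so whatever
instability exists in a conversion is a property of the chain files, not of
the tool. Most positions convert cleanly, but a small fraction misbehave in
ways that silently corrupt downstream annotation: they fail to convert, land
on a different chromosome, or convert somewhere that does not convert back
to where they started.

cupScan classifies every base of a source build by performing the round trip
— source to target, then target back to source — and assigning the first
failure in a fixed decision order:

| category     | meaning                                                     |
|--------------|-------------------------------------------------------------|
| `REJECT_1`   | the first conversion fails (chain gap, no chain, or an unresolvable tie between chains) |
| `CHR_JUMP_1` | the first conversion lands on a different chromosome        |
| `REJECT_2`   | the converted point fails the return conversion             |
| `CHR_JUMP_2` | the point returns to a different chromosome                 |
| `POS_JUMP`   | the point returns to a different position                   |
| `STABLE`     | the round trip is the identity                              |

Every category except `STABLE` is a conversion-unstable position (CUP); the
last four are the *novel* CUPs — the ones a conversion tool will not warn
about, because the first conversion succeeds. The practical payoff is the
pre-exclusion workflow: removing variants that sit on novel CUPs *before*
converting a VCF yields exactly the stable variant set that running the full
round-trip analysis would keep, so a published CUP track is all a user needs.

The decision order is deliberately sequential and mutually exclusive: a
position that returns to the wrong chromosome also returns to the wrong
position, but it is counted once, as `CHR_JUMP_2`. This keeps the category
totals a partition of the genome.

## Conventions and the lift engine

Chain files are read exactly as written (0-based half-open coordinates,
destination coordinates on the strand named in the header; every chain is
validated against the format's two block-sum identities). Internally all
interval sets live in `GRanges` objects — the 1-based closed convention of
the Bioconductor stack — and conversion between the two happens only at file
boundaries (chain, BED, VCF). We chose this over carrying 0-based intervals
internally because it lets the entire interval algebra (merge, intersect,
complement, overlap joins) run through IRanges/GenomicRanges instead of
hand-written code; the boundary conversions are three well-tested lines.

A single base lifts through the unique aligned block covering it:
`dest = dest_block_start + (pos - src_block_start)`, reflected through the
destination length on `-`-strand chains so that reported coordinates are
always forward-strand. Three details are worth stating:

* **Overlapping chains.** When blocks of several chains cover one base with
  conflicting destinations, the highest-scoring chain wins; an exact score
  tie is reported `ambiguous`, which the scanner folds into the reject
  categories — conversion tools likewise refuse multi-mapped features. Two
  covering chains that *agree* on the destination are not ambiguous.
* **Boundaries.** A base belongs to the block whose half-open span contains
  it; no double counting.
* **Unknown chromosomes** are unmapped, not an error; rejected records carry
  a reason code (`gap` / `no_chain` / `ambiguous`).

Destination contigs that are not among the scanned chromosomes (unplaced,
unlocalized, alternate haplotypes) are parsed and retained; a jump onto one
counts as a chromosome jump, so every scanned base keeps an accurate label
even though such contigs are never scanned as inputs.

## The two scan modes

`scanGenome()` offers two extensionally identical modes, and their equality
is one of the package's central tests.

**Per-base mode** applies the classifier to every single position. It is the
literal definition and serves as the reference oracle, feasible up to
a few hundred kilobases.

**Interval mode** computes the same partition exactly, without enumeration.
Each chain block defines an affine map `dest = intercept ± src`. The
forward blocks on a chromosome are cut into disjoint pieces (`disjoin`),
each piece resolved to a single affine map by the score policy; the piece's
image is intersected with the equally resolved reverse map; the two affine
maps compose, and the composition is compared with the identity piece by
piece. Category regions fall out as exact intervals — nothing is sampled —
which is what makes a 3-Gbp scan tractable in minutes rather than the
per-base mode's billions of classifications.

Two degenerate configurations need explicit care to keep the modes equal:

* two tied-score maps of opposite slope on the same destination chromosome
  agree at at most one integer position (`c1 + x = c2 - x`); that single
  base is mapped, the rest of the piece is ambiguous;
* a composed round trip of slope −1 fixes at most one integer position
  (`x = c/2`); that base is `STABLE`, its neighbours `POS_JUMP`.

Both are measure-zero cases that only arise from adversarial chain files,
but the interval scanner handles them so that equality with the per-base
definition is exact, not approximate.

Ambiguity on the *second* conversion is not defined by the published
workflow; we treat it as `REJECT_2` (the return conversion failed), the
same reading a conversion tool would give it.

## Synthetic build pairs as ground truth

Real chain files offer no ground truth, so the package carries a generator
(`rearrangementScript()` / `realizeScript()`) that manufactures it. A script
lists non-overlapping operations on a toy source genome — deletion,
insertion, inversion, duplication, translocation, and a deliberately
asymmetric back-mapping — and realization produces the two genomes, exact
chain files in both directions, and per-base truth labels derived by rule
(deletion ⇒ `REJECT_1`, translocation ⇒ `CHR_JUMP_1`, dropped back-map ⇒
`REJECT_2`, redirected back-map ⇒ `CHR_JUMP_2`/`POS_JUMP`, tied duplication
⇒ `REJECT_1` via ambiguity, everything else `STABLE`). Chain scores are
block-length sums, so a duplication exercises the score policy
controllably: the in-place copy outscores the appended copy unless the
script requests an exact tie. Chains are emitted through the package's own
serializer and re-parsed, so every fixture also exercises the format
validator. Sequences are uniform random bases with a fixed seed;
deterministic given `(script, seed)`.

What the generator emulates is the *coordinate* structure of real build
differences (gap closing, contig updates, duplications, strand flips) plus
the chain-file pathologies behind each category. What it does not emulate:
biological base composition, realistic rearrangement length spectra,
N-runs, or the sheer scale of a human chain file (thousands of chains,
many megabases). Passing tests therefore demonstrate algorithmic
correctness against the chain-file semantics, not performance claims or
biological realism. Test problem sizes — 2–100 kb genomes, 20 random
script seeds, ~100-variant VCFs — were chosen so the whole suite runs in a
few minutes while still covering every category and both duplicate-score
resolutions.

## VCF conversion and the two mismatch dialects

For variants the round trip gains reference-allele checks, mirroring the
two behaviours found in the common tools:

* `reject_on_mismatch` (the LiftoverVcf behaviour): after a successful
  lift, any disagreement between the (strand-adjusted) REF and the
  target-build base rejects the variant;
* `update_ref` (the CrossMap VCF behaviour): REF is updated to the target
  base, and the variant fails only if the source ALT equals the updated
  REF.

A target base that is an IUPAC ambiguity code is a mismatch under both
dialects. On `-`-strand chains REF and ALT are reverse-complemented before
comparison — the workflow description is silent here, but without this
every inversion-spanning variant would spuriously mismatch. Mismatch
failures are recorded as `MISMATCH_1` or `MISMATCH_2` depending on which
conversion they abort, and the check sits where the tool performs it:
after the lift of that conversion and before any chromosome or position
comparison, so a mismatching variant is reported as a mismatch, not as a
jump. For all non-mismatch records the VCF category equals the position
classifier's category at that locus, which the tests assert directly.

Genotype discordance is computed on unphased allele multisets (`0/1` and
`1|0` agree) over position-matched variants only, with the matched count as
denominator; multi-sample VCFs are out of scope — the first sample column
is used, and the tests exercise single-sample files only.

## Annotation overlaps

`overlapProportion(A, B) = |A ∩ B| / |A|` quantifies how much of a CUP
category an assembly annotation track explains; proportions are reported
raw and rounded to 0.1%, never for empty categories (undefined, not zero).
`partitionAnnotations()` splits the genome into bases unique to each of the
three standard tracks (assembly gaps, contig differences, segmental
duplications), bases in **more than one** track (`multiple`), and bases in
none (`other`). A figure legend in the source literature reads as "one or
more" for `multiple`; the methods text says "more than one", and we follow
the methods text — the five sets then partition the genome. Centromere
rows can be stripped from a gap table (GRCh37 carries them, GRCh38 does
not) and are returned separately so their contribution can be re-attributed.

## Numerical and design notes

* Coordinates are stored as doubles internally (chain spans exceed 2^31−1
  summed over a genome); all arithmetic is exact integer arithmetic within
  doubles' 2^53 range.
* Merging uses distance-0 semantics (bookended intervals merge), matching
  the default of the standard BED toolchain; total bp is conserved.
* Duplicate chain ids occur in real files; they warn and chains are keyed
  by ordinal.
* Determinism: all randomness (sequences, random scripts, simulated
  variants) is seeded, and the generators save and restore the caller's
  RNG state.
* Chromosome names are stored verbatim; a normalizer (strip `chr`,
  case-fold) applies only in comparisons, since chain files are
  chr-prefixed while user tables often are not.

## Limitations

Only single-base positions (and biallelic SNVs) are in scope: multi-base
regions interact with chain gaps in tool-specific ways and are refused, one
record at a time, rather than half-handled. Bit-exact parity with the UCSC
liftOver binary on pathological overlapping-chain inputs is not guaranteed
— the score-tie policy here is deterministic where the binary's choice is
unspecified — but on chains without score ties the lift engine agrees with
an independent chain implementation (rtracklayer's) on status and
coordinates, which the test suite checks on every synthetic fixture,
reverse-strand chains included.
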