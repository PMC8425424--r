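# cupScan

Liftover between genome reference builds (GRCh37 ↔ GRCh38, or any pair
related by UCSC chain files) is not a bijection. A small fraction of
base-pair positions fail to convert, change chromosome when converted, or
convert to a position that does not convert back to where it started —
and the second and third failure modes are silent: the conversion tool
reports success. cupScan identifies these **conversion-unstable positions
(CUPs)** from the chain files alone, by round-tripping every position of
the source build and classifying it into one of six mutually exclusive
categories:

```
source pos ──fwd──▶ target pos ──rev──▶ back pos

REJECT_1     first conversion fails (gap / no chain / ambiguous)
CHR_JUMP_1   first conversion changes chromosome
REJECT_2     return conversion fails
CHR_JUMP_2   returns to a different chromosome
POS_JUMP     returns to a different position
STABLE       round trip is the identity
```

All categories except `STABLE` are CUPs; the last four are *novel* CUPs —
the silent ones. For a category region set *A* and an assembly annotation
track *B* (gaps, contig differences, segmental duplications), the overlap
statistic |A ∩ B| / |A| attributes each category to its likely cause. For
variant data the package applies the same round trip to biallelic SNVs with
the two reference-allele dialects used by the common tools (reject on
mismatch, as in picard LiftoverVcf; update the REF and fail when ALT equals
it, as in CrossMap), and supports the pre-exclusion workflow: dropping
variants at novel CUPs *before* conversion provably leaves exactly the
stable variant set.

The scanner has two modes that compute identical output: a per-base mode
(the literal definition, used as a test oracle) and an exact interval-
algebra mode that composes the chain files' affine block maps piecewise,
making whole-genome scans feasible. A synthetic-build module generates toy
genome pairs with exact chain files and analytically known per-base truth
labels, so every category is testable without downloading anything.

Intended users: anyone converting SNV data or position-based annotation
between builds who needs to know which positions to distrust, and anyone
producing or validating CUP tracks for other chain-file pairs.

## Worked example

Scan a scripted toy build pair — a 50 bp deletion, a 100 bp translocation
onto another chromosome, and a 50 bp interval whose reverse chain points
200 bp downstream:

```r
library(cupScan)

sc <- rearrangementScript(
  c(chrA = 5000L, chrB = 4000L),
  list(opDelete("chrA", 100, 150),
       opTranslocate("chrA", 2000, 2100, "chrB"),
       opAsymmetricBackmap("chrA", 3000, 3050, "chrA", 4000)),
  seed = 1)
pair <- realizeScript(sc)

scanGenome(pair$fwd, pair$rev, pair$chromSizes)
#> CupScanResult (interval mode) over 2 chromosome(s), 9,000 bp
#>    category   bp     pct
#>      STABLE 8800 97.7778
#>    REJECT_1   50  0.5556
#>  CHR_JUMP_1  100  1.1111
#>    REJECT_2    0  0.0000
#>  CHR_JUMP_2    0  0.0000
#>    POS_JUMP   50  0.5556
```

Each scripted rearrangement appears as exactly its span in the expected
category: the deletion is 50 bp of `REJECT_1` (the position no longer
exists in the target build), the translocation 100 bp of `CHR_JUMP_1`, the
asymmetric interval 50 bp of `POS_JUMP`. Individual positions classify the
same way:

```r
classifyPositions(pair$fwd, pair$rev, "chrA", c(125, 2050, 3025, 4500))
#> [1] REJECT_1   CHR_JUMP_1 POS_JUMP   STABLE
```

The same round trip on a VCF adds the reference-allele checks; variants
placed at `POS_JUMP` loci surface as second-conversion failures (here as
allele mismatches at the wrong return locus):

```r
v  <- simulateVariants(pair, seed = 2, stratify = c(STABLE = 8, POS_JUMP = 2))
rt <- roundtripClassifyVcf(v, pair$fwd, pair$rev,
                           makeBaseLookup(pair$srcSeqs),
                           makeBaseLookup(pair$destSeqs),
                           dialect = "reject_on_mismatch")
rt$counts
#>     STABLE   REJECT_1 CHR_JUMP_1   REJECT_2 CHR_JUMP_2   POS_JUMP MISMATCH_1 MISMATCH_2
#>          8          0          0          0          0          0          0          2
```

Pre-excluding variants at the scan's novel CUPs keeps exactly the stable
ones:

```r
scan <- scanGenome(pair$fwd, pair$rev, pair$chromSizes)
nrow(filterAtCups(v, novelCupRegions(scan))$kept)
#> [1] 8
```

For real data, point `readChainFile()` at the two UCSC chain files (one per
direction), `readChromSizes()` at the assembled-chromosome sizes, and
`scanGenome(..., mode = "interval")` produces the per-category BED tracks
via `writeScanResult()`. A command-line front end covering the whole
workflow (`scan`, `lift`, `overlap`, `vcf-convert`, `vcf-filter`,
`concordance`, `simulate`) is installed at
`system.file("scripts", "cupscan.R", package = "cupScan")`.

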