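#' @import methods
#' @importFrom stats setNames
#' @importFrom utils head tail
#' @importFrom data.table data.table fread fwrite setkey := .N .SD rbindlist as.data.table
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList findOverlaps reduce disjoin
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths seqinfo Seqinfo
#'   seqlevels<- seqlengths<- keepSeqlevels
#' @importFrom Biostrings DNAStringSet subseq reverseComplement
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "ord", "score", "dchrom", "slope", "intercept", "pos0", "dpos0",
  "qidx", "bidx", "top", "chrom", "s0", "s1", "status", "size", "dt", "dq",
  "src_chrom", "dest_chrom", "strand", "piece", "n_maps", "key_"
))

## Canonical CUP category labels, in flow-chart decision order.
CUP_CATEGORIES <- c("STABLE", "REJECT_1", "CHR_JUMP_1", "REJECT_2",
                    "CHR_JUMP_2", "POS_JUMP")
VCF_CATEGORIES <- c(CUP_CATEGORIES, "MISMATCH_1", "MISMATCH_2")
NOVEL_CUP_CATEGORIES <- c("CHR_JUMP_1", "REJECT_2", "CHR_JUMP_2", "POS_JUMP")

#' CUP category labels
#'
#' Constants naming the round-trip classification categories. `STABLE` marks
#' positions that convert to the target build and back to their exact origin;
#' everything else is a conversion-unstable position (CUP). The four
#' categories beyond plain first-conversion failure (`REJECT_1`) are the
#' "novel" CUPs. VCF classification adds `MISMATCH_1`/`MISMATCH_2` for
#' reference-allele failures on the first/second conversion.
#'
#' @return A character vector of category labels.
#' @export
cupCategories <- function() CUP_CATEGORIES

#' @rdname cupCategories
#' @export
vcfCategories <- function() VCF_CATEGORIES

#' @rdname cupCategories
#' @export
novelCupCategories <- function() NOVEL_CUP_CATEGORIES

## Chromosome-name normalization used ONLY for comparisons: names are stored
## verbatim everywhere (chain files are chr-prefixed, user input may not be).
normChrom <- function(x) tolower(sub("^chr", "", x, ignore.case = TRUE))

sameChrom <- function(a, b) normChrom(a) == normChrom(b)

## GRanges from 0-based half-open coordinates.
granges0 <- function(chrom, start0, end0, seqlens = NULL, ...) {
  gr <- GRanges(seqnames = chrom, ranges = IRanges(start0 + 1L, end0), ...)
  if (!is.null(seqlens)) {
    seqlevels(gr) <- names(seqlens)
    seqlengths(gr) <- as.integer(seqlens)
  }
  gr
}

## data.frame (chrom, start0, end0) from a GRanges
bedFrame <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

## total bp of a GRanges
totalBp <- function(gr) sum(as.numeric(GenomicRanges::width(gr)))

## Collapse a set of single positions (0-based) into merged regions.
positionsToRegions <- function(chrom, pos0) {
  if (length(pos0) == 0L) return(GRanges())
  reduce(granges0(chrom, pos0, pos0 + 1L))
}

## complement of single bases (strings of single characters, vectorized);
## for 1-bp alleles complement == reverse complement.
complementBase <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

isUnambiguousBase <- function(x) x %in% c("A", "C", "G", "T", "a", "c", "g", "t")
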