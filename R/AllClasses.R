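#' ChainSet: an indexed collection of UCSC liftover chains
#'
#' A `ChainSet` holds the parsed content of one UCSC chain file (one
#' conversion direction) together with an interval index over source-build
#' coordinates. Header coordinates are stored exactly as written in the file
#' (0-based half-open; destination coordinates on the strand given by
#' `dest_strand`). The block index pre-computes, for every ungapped aligned
#' block, the affine map from a source position to the forward-strand
#' destination position: `dest = intercept + slope * src` with `slope` +1 on
#' '+' chains and -1 on '-' chains.
#'
#' @slot headers data.frame with one row per chain: `ord` (internal ordinal
#'   key), `score`, `src_chrom`, `src_size`, `src_start`, `src_end`,
#'   `dest_chrom`, `dest_size`, `dest_strand`, `dest_start`, `dest_end`,
#'   `chain_id` (verbatim from the file; duplicates allowed but warned).
#' @slot blocktab data.frame of raw body lines per chain: `ord`, `size`,
#'   `dt` (source gap after the block), `dq` (destination gap); used for
#'   faithful serialization.
#' @slot blocks [GenomicRanges::GRanges] over source coordinates, one range
#'   per aligned block, with metadata columns `ord`, `score`, `dchrom`,
#'   `dsize`, `strand_c`, `slope`, `intercept`.
#' @slot spans GRanges of whole-chain source spans (metadata `ord`), used to
#'   distinguish "in a chain gap" from "outside every chain".
#' @slot direction free-text label, e.g. `"toy37->toy38"`.
#'
#' @seealso [readChainFile()], [liftPositions()], [scanGenome()]
#' @export
setClass("ChainSet", representation(
  headers = "data.frame",
  blocktab = "data.frame",
  blocks = "GRanges",
  spans = "GRanges",
  direction = "character"
))

setValidity("ChainSet", function(object) {
  h <- object@headers
  msgs <- character()
  needed <- c("ord", "score", "src_chrom", "src_size", "src_start", "src_end",
              "dest_chrom", "dest_size", "dest_strand", "dest_start",
              "dest_end", "chain_id")
  if (!all(needed %in% names(h)))
    msgs <- c(msgs, "headers is missing required columns")
  else if (nrow(h)) {
    if (any(h$src_start < 0 | h$src_start >= h$src_end | h$src_end > h$src_size))
      msgs <- c(msgs, "chain source span outside [0, src_size)")
    if (any(h$dest_start < 0 | h$dest_start >= h$dest_end | h$dest_end > h$dest_size))
      msgs <- c(msgs, "chain dest span outside [0, dest_size)")
    if (!all(h$dest_strand %in% c("+", "-")))
      msgs <- c(msgs, "dest_strand must be '+' or '-'")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ChainSet number of chains
#' @param x,object a `ChainSet`
#' @export
chainCount <- function(x) nrow(x@headers)

#' @describeIn ChainSet the per-chain header table
#' @export
chainHeaders <- function(x) x@headers

#' @describeIn ChainSet the aligned-block index (GRanges on source coords)
#' @export
chainBlocks <- function(x) x@blocks

#' @describeIn ChainSet direction label
#' @export
chainDirection <- function(x) x@direction

setMethod("show", "ChainSet", function(object) {
  cat("ChainSet (", object@direction, "): ",
      chainCount(object), " chain(s), ",
      nrow(object@blocktab), " block(s) over ",
      length(unique(object@headers$src_chrom)),
      " source sequence(s)\n", sep = "")
})

#' CupScanResult: a genome-wide round-trip classification
#'
#' The result of [scanGenome()]: a partition of the scanned source build into
#' the six round-trip categories, held as sorted, merged region sets on
#' source-build coordinates.
#'
#' @slot regions named [GenomicRanges::GRangesList], one element per category
#'   in [cupCategories()]; elements are reduced (bookended/overlapping ranges
#'   merged) and pairwise disjoint; their union is the scanned genome.
#' @slot chromSizes named integer vector of scanned chromosome lengths (bp).
#' @slot mode `"interval"` or `"per_base"`.
#'
#' @seealso [scanGenome()], [scanSummary()], [cupRegions()]
#' @export
setClass("CupScanResult", representation(
  regions = "GRangesList",
  chromSizes = "numeric",
  mode = "character"
))

setValidity("CupScanResult", function(object) {
  if (!identical(names(object@regions), CUP_CATEGORIES))
    return("regions must be named by the six CUP categories, in order")
  TRUE
})

#' @describeIn CupScanResult region set for one category (or all, as a
#'   GRangesList, when `category` is missing)
#' @param x,object a `CupScanResult`
#' @param category a category name from [cupCategories()]
#' @export
cupRegions <- function(x, category) {
  if (missing(category)) return(x@regions)
  x@regions[[match.arg(category, CUP_CATEGORIES)]]
}

#' @describeIn CupScanResult the stable region set
#' @export
stableRegions <- function(x) x@regions[["STABLE"]]

#' @describeIn CupScanResult merged novel-CUP regions (all categories except
#'   STABLE and REJECT_1)
#' @export
novelCupRegions <- function(x) {
  reduce(unlist(x@regions[NOVEL_CUP_CATEGORIES], use.names = FALSE))
}

#' @describeIn CupScanResult summary table: bp and percent of the scanned
#'   build per category (the per-build totals table of the workflow)
#' @export
scanSummary <- function(x) {
  bp <- vapply(x@regions, totalBp, numeric(1))
  tot <- sum(as.numeric(x@chromSizes))
  data.frame(category = CUP_CATEGORIES,
             bp = unname(bp),
             pct = unname(100 * bp / tot),
             row.names = NULL, stringsAsFactors = FALSE)
}

setMethod("show", "CupScanResult", function(object) {
  s <- scanSummary(object)
  cat("CupScanResult (", object@mode, " mode) over ",
      length(object@chromSizes), " chromosome(s), ",
      format(sum(as.numeric(object@chromSizes)), big.mark = ","), " bp\n",
      sep = "")
  s$pct <- sprintf("%.4f", s$pct)
  print(s, row.names = FALSE)
})
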