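#' Read and write BED3+label files
#'
#' Plain BED (0-based half-open), with an optional fourth (name) column.
#' Intervals are converted to/from the package's [GenomicRanges::GRanges]
#' representation at this boundary.
#'
#' @param file path (BED, optionally gzipped for reading).
#' @return `readBedFile`: a `GRanges` (metadata column `name` when present).
#' @export
readBedFile <- function(file) {
  d <- fread(file, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(d) == 0L) return(GRanges())
  gr <- granges0(d[[1]], as.numeric(d[[2]]), as.numeric(d[[3]]))
  if (ncol(d) >= 4L) mcols(gr)$name <- as.character(d[[4]])
  gr
}

#' @rdname readBedFile
#' @param gr a `GRanges` (or data.frame with `chrom`, `start0`, `end0`).
#' @param name optional name column: a single label, a vector, or `NULL` to
#'   use the `name` metadata column / omit the column.
#' @export
writeBedFile <- function(gr, file, name = NULL) {
  if (is.data.frame(gr)) gr <- granges0(gr$chrom, gr$start0, gr$end0)
  gr <- sort(gr, ignore.strand = TRUE)
  d <- bedFrame(gr)
  if (is.null(name) && !is.null(mcols(gr)$name)) name <- mcols(gr)$name
  if (!is.null(name)) d$name <- rep_len(name, nrow(d))
  fwrite(d, file, sep = "\t", col.names = FALSE)
  invisible(file)
}

#' Overlap statistics between region sets
#'
#' `intersectBp(A, B)` is the exact number of base pairs shared by two region
#' sets (commutative). `overlapProportion(A, B)` is `|A intersect B| / |A|`,
#' the proportion of CUP category A explained by annotation set B; it is
#' undefined (returned as `NA` with a message) when A is empty, never 0.
#'
#' @param A,B [GenomicRanges::GRanges] on the same build.
#' @return `intersectBp`: numeric bp; `overlapProportion`: fraction in
#'   \[0, 1\] or `NA`.
#' @examples
#' A <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
#' B <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 8))
#' intersectBp(A, B)        # 3
#' overlapProportion(A, B)  # 0.3
#' @export
intersectBp <- function(A, B) {
  if (length(A) == 0L || length(B) == 0L) return(0)
  suppressWarnings(
    totalBp(GenomicRanges::intersect(A, B, ignore.strand = TRUE)))
}

#' @rdname intersectBp
#' @export
overlapProportion <- function(A, B) {
  if (length(A) == 0L || totalBp(A) == 0) {
    message("overlapProportion: empty query set; proportion not applicable")
    return(NA_real_)
  }
  intersectBp(A, B) / totalBp(reduce(A, ignore.strand = TRUE))
}

#' Partition the genome by assembly annotation membership
#'
#' Splits the scanned genome into five disjoint sets: bases unique to each of
#' the three annotation tracks (assembly gaps, contig differences, segmental
#' duplications), bases present in more than one track (`multiple`), and
#' bases in none (`other`). The first four sets union to the union of the
#' inputs; the five together cover the genome.
#'
#' @param gap,contigdiff,segdup annotation [GenomicRanges::GRanges] on the
#'   same build.
#' @param chromSizes named vector of scanned chromosome lengths (defines the
#'   genome extent for `other`).
#' @return Named list of `GRanges`: `gap_only`, `contigdiff_only`,
#'   `segdup_only`, `multiple`, `other`.
#' @export
partitionAnnotations <- function(gap, contigdiff, segdup, chromSizes) {
  genome <- granges0(names(chromSizes), rep(0, length(chromSizes)),
                     as.numeric(chromSizes))
  sets <- lapply(list(gap, contigdiff, segdup), function(g)
    suppressWarnings(reduce(g, ignore.strand = TRUE)))
  un2 <- function(a, b) suppressWarnings(
    GenomicRanges::union(a, b, ignore.strand = TRUE))
  int2 <- function(a, b) suppressWarnings(
    GenomicRanges::intersect(a, b, ignore.strand = TRUE))
  dif2 <- function(a, b) suppressWarnings(
    GenomicRanges::setdiff(a, b, ignore.strand = TRUE))
  allUnion <- Reduce(un2, sets)
  multiple <- reduce(c(int2(sets[[1]], sets[[2]]),
                       int2(sets[[1]], sets[[3]]),
                       int2(sets[[2]], sets[[3]])))
  only <- lapply(1:3, function(i)
    dif2(sets[[i]], Reduce(un2, sets[-i])))
  list(gap_only = only[[1]], contigdiff_only = only[[2]],
       segdup_only = only[[3]], multiple = sort(multiple),
       other = dif2(genome, allUnion))
}

#' Drop centromere rows from a UCSC gap table
#'
#' The GRCh37 gap track includes the centromeres (they were not assembled);
#' the GRCh38 track does not. For a like-for-like comparison the centromeres
#' are removed from the gap set before computing overlaps, and returned
#' separately so their contribution (they explain a sizeable share of
#' first-conversion failures on GRCh37) can be re-attributed.
#'
#' @param gapTable data.frame in UCSC gap-track layout: columns `chrom`,
#'   `chromStart`, `chromEnd` (0-based half-open) and `type`.
#' @return list with `gap` (non-centromere rows, `GRanges`) and
#'   `centromeres` (`GRanges`).
#' @export
removeCentromeres <- function(gapTable) {
  nm <- names(gapTable)
  if (!"type" %in% nm)
    stop("gap table has no 'type' column; cannot identify centromeres")
  startCol <- intersect(c("chromStart", "start0", "start"), nm)[1]
  endCol <- intersect(c("chromEnd", "end0", "end"), nm)[1]
  if (is.na(startCol) || is.na(endCol))
    stop("gap table must have chromStart/chromEnd (or start0/end0) columns")
  gr <- granges0(gapTable$chrom, as.numeric(gapTable[[startCol]]),
                 as.numeric(gapTable[[endCol]]))
  cen <- gapTable$type == "centromere"
  list(gap = sort(reduce(gr[!cen])), centromeres = sort(reduce(gr[cen])))
}

#' Read a UCSC Table Browser dump
#'
#' Tab-separated with a (possibly `#`-prefixed) header line; coordinates are
#' 0-based half-open as distributed. A column map renames the coordinate and
#' type columns into the package's convention.
#'
#' @param file path to the TSV.
#' @param colmap named character vector mapping file columns to
#'   `chrom`/`chromStart`/`chromEnd`/`type`; defaults cover the gap and
#'   genomicSuperDups schemas.
#' @return data.frame with the mapped columns (plus the rest untouched).
#' @export
readUcscTable <- function(file, colmap = c(chrom = "chrom",
                                           chromStart = "chromStart",
                                           chromEnd = "chromEnd",
                                           type = "type")) {
  d <- fread(file, header = TRUE, sep = "\t")
  names(d) <- sub("^#", "", names(d))
  for (target in names(colmap)) {
    src <- colmap[[target]]
    if (src %in% names(d) && target != src)
      data.table::setnames(d, src, target)
  }
  as.data.frame(d)
}

#' Overlap report between CUP categories and annotation sets
#'
#' For every scan category and every annotation set (the three tracks plus
#' the `multiple`/`other` partition pieces), reports the overlap in bp and as
#' a proportion of the category. Proportions are additionally given rounded
#' to 0.1% (`pct`), with exact bp alongside.
#'
#' @param scan a [CupScanResult-class].
#' @param annotations named list of [GenomicRanges::GRanges] annotation sets
#'   (e.g. the output of [partitionAnnotations()]).
#' @return data.frame: `category`, `annotation`, `category_bp`,
#'   `overlap_bp`, `proportion`, `pct`.
#' @export
annotationOverlapReport <- function(scan, annotations) {
  stopifnot(!is.null(names(annotations)))
  rows <- list()
  for (cat in CUP_CATEGORIES) {
    A <- cupRegions(scan, cat)
    for (an in names(annotations)) {
      ov <- intersectBp(A, annotations[[an]])
      prop <- if (totalBp(A) > 0) ov / totalBp(A) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, annotation = an, category_bp = totalBp(A),
        overlap_bp = ov, proportion = prop,
        pct = round(100 * prop, 1), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
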