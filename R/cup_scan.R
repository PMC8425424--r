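#' Classify positions by round-trip conversion stability
#'
#' Applies the round-trip decision flow to single positions: lift each source
#' position to the target build, then lift the mapped point back, and assign
#' the first failing category:
#'
#' 1. `REJECT_1` — first conversion fails (unmapped or ambiguous);
#' 2. `CHR_JUMP_1` — first conversion lands on a different chromosome
#'    (after name normalization; unplaced/unlocalized/alternate destination
#'    contigs count as different);
#' 3. `REJECT_2` — second conversion of the mapped point fails;
#' 4. `CHR_JUMP_2` — the point maps back to a different chromosome;
#' 5. `POS_JUMP` — the point maps back to a different position;
#' 6. `STABLE` otherwise.
#'
#' Positions in categories 1-2 never enter the second conversion. All
#' categories but `STABLE` are conversion-unstable positions (CUPs);
#' categories 2-5 are the novel CUPs.
#'
#' @param fwd [ChainSet-class] mapping source build to target build.
#' @param rev [ChainSet-class] mapping target build back to the source.
#' @param chrom,pos source chromosome names and 0-based positions.
#' @return factor of categories, levels [cupCategories()].
#' @examples
#' cs <- parseChainLines(c("chain 100 chrA 1000 + 0 1000 chrA 1000 + 0 1000 1",
#'                         "1000", ""))
#' classifyPositions(cs, cs, "chrA", 0:5)
#' @export
classifyPositions <- function(fwd, rev, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  cat <- rep(NA_character_, n)

  l1 <- liftPositions(fwd, chrom, pos)
  cat[l1$status != "mapped"] <- "REJECT_1"
  jump1 <- is.na(cat) & !sameChrom(l1$dest_chrom, chrom)
  cat[jump1] <- "CHR_JUMP_1"

  todo <- which(is.na(cat))
  if (length(todo)) {
    l2 <- liftPositions(rev, l1$dest_chrom[todo], l1$dest_pos[todo])
    cat2 <- rep(NA_character_, length(todo))
    cat2[l2$status != "mapped"] <- "REJECT_2"
    j2 <- is.na(cat2) & !sameChrom(l2$dest_chrom, chrom[todo])
    cat2[j2] <- "CHR_JUMP_2"
    pj <- is.na(cat2) & l2$dest_pos != pos[todo]
    cat2[pj] <- "POS_JUMP"
    cat2[is.na(cat2)] <- "STABLE"
    cat[todo] <- cat2
  }
  factor(cat, levels = CUP_CATEGORIES)
}

## ---------------------------------------------------------------------------
## Interval-mode machinery.
##
## resolveLiftMap() reduces a ChainSet to a "resolved map": per source
## chromosome, disjoint pieces each carrying either a single affine map to
## forward-strand destination coordinates (dest = intercept + slope * src)
## or the status "ambiguous". Positions outside all pieces are unmapped.
## The resolution applies the same policy as liftPositions (highest chain
## score wins; conflicting destinations at tied score are ambiguous), with
## one refinement needed for exactness: two tied maps of opposite slope on
## the same destination chromosome agree at (at most) one integer position,
## which is then mapped, not ambiguous.
## ---------------------------------------------------------------------------
resolveLiftMap <- function(chains, chromNames, chromLens = NULL) {
  empty <- data.table(chrom = character(), s0 = numeric(), s1 = numeric(),
                      status = character(), dchrom = character(),
                      slope = numeric(), intercept = numeric())
  blocks <- chains@blocks
  if (length(blocks) == 0L) return(empty)
  keep <- as.character(seqnames(blocks)) %in% chromNames
  blocks <- blocks[keep]
  if (length(blocks) == 0L) return(empty)

  out <- vector("list", length(chromNames))
  for (ci in seq_along(chromNames)) {
    cn <- chromNames[ci]
    b <- blocks[as.character(seqnames(blocks)) == cn]
    if (!is.null(chromLens))
      b <- IRanges::restrict(b, start = 1L, end = as.integer(chromLens[ci]))
    b <- b[GenomicRanges::width(b) > 0]
    if (length(b) == 0L) next
    pieces <- disjoin(b)
    hits <- findOverlaps(pieces, b)
    mc <- mcols(b)[subjectHits(hits), ]
    dtab <- data.table(piece = queryHits(hits), score = mc$score,
                       dchrom = mc$dchrom, slope = mc$slope,
                       intercept = mc$intercept)
    ps0 <- GenomicRanges::start(pieces) - 1
    ps1 <- as.numeric(GenomicRanges::end(pieces))
    res <- vector("list", length(pieces))
    maps <- dtab[, {
      top <- .SD[score == max(score)]
      unique(top[, .(dchrom, slope, intercept)])
    }, by = piece]
    nmaps <- maps[, .N, by = piece]
    simple <- nmaps[N == 1L, piece]
    if (length(simple)) {
      m1 <- maps[piece %in% simple]
      res[m1$piece] <- split(
        data.table(chrom = cn, s0 = ps0[m1$piece], s1 = ps1[m1$piece],
                   status = "mapped", dchrom = m1$dchrom, slope = m1$slope,
                   intercept = m1$intercept),
        seq_len(nrow(m1)))
    }
    for (p in nmaps[N > 1L, piece]) {
      mm <- maps[piece == p]
      res[[p]] <- resolveTiedMaps(cn, ps0[p], ps1[p], mm)
    }
    out[[ci]] <- rbindlist(res[!vapply(res, is.null, logical(1))])
  }
  r <- rbindlist(out)
  if (nrow(r) == 0L) empty else r[order(chrom, s0)]
}

## Tied-score conflicting maps over a piece [s0, s1). Exactly two maps of
## opposite slope on the same destination chromosome coincide at the integer
## solution of c1 + x == c2 - x (if any); there the destination is unique and
## the position is mapped. Every other position is ambiguous.
resolveTiedMaps <- function(cn, s0, s1, maps) {
  amb <- function(a0, a1) if (a1 > a0)
    data.table(chrom = cn, s0 = a0, s1 = a1, status = "ambiguous",
               dchrom = NA_character_, slope = NA_real_,
               intercept = NA_real_) else NULL
  if (nrow(maps) == 2L && length(unique(maps$dchrom)) == 1L &&
      all(sort(maps$slope) == c(-1, 1))) {
    c1 <- maps$intercept[maps$slope == 1][1]
    c2 <- maps$intercept[maps$slope == -1][1]
    xstar <- (c2 - c1) / 2
    if (xstar == floor(xstar) && xstar >= s0 && xstar < s1) {
      return(rbindlist(list(
        amb(s0, xstar),
        data.table(chrom = cn, s0 = xstar, s1 = xstar + 1,
                   status = "mapped", dchrom = maps$dchrom[1],
                   slope = 1, intercept = c1),
        amb(xstar + 1, s1)), use.names = TRUE))
    }
  }
  amb(s0, s1)
}

## forward image of a source piece [s0,s1) under an affine map
imageInterval <- function(s0, s1, slope, intercept) {
  if (slope > 0) c(intercept + s0, intercept + s1)
  else c(intercept - (s1 - 1), intercept - s0 + 1)
}

## pull a destination sub-interval [u0,u1) back through the same map
preimageInterval <- function(u0, u1, slope, intercept) {
  if (slope > 0) c(u0 - intercept, u1 - intercept)
  else c(intercept - (u1 - 1), intercept - u0 + 1)
}

#' Scan a genome for conversion-unstable positions
#'
#' Classifies every base of the listed chromosomes by round-trip conversion
#' stability (see [classifyPositions()]) and returns the per-category region
#' sets. Two modes compute extensionally identical output:
#'
#' * `"per_base"` applies [classifyPositions()] to every single position —
#'   the literal definition, feasible for toy genomes and used as the
#'   reference oracle;
#' * `"interval"` (default) computes the same partition exactly by interval
#'   algebra: forward chain blocks are resolved into disjoint affine pieces,
#'   their destination images are intersected with the resolved reverse map,
#'   the two affine maps are composed piecewise, and each composed piece is
#'   compared against the identity. No sampling is involved; the output
#'   regions are exact, which is what makes genome-scale scans tractable.
#'
#' Chromosomes listed in `chromSizes` but absent from the forward chains are
#' wholly `REJECT_1`: nothing in them can convert.
#'
#' @param fwd,rev forward and reverse [ChainSet-class] objects.
#' @param chromSizes named vector of source chromosome lengths; exactly the
#'   chromosomes to scan (standard assembled chromosomes only, in the
#'   canonical workflow).
#' @param mode `"interval"` or `"per_base"`.
#' @return A [CupScanResult-class].
#' @export
scanGenome <- function(fwd, rev, chromSizes,
                       mode = c("interval", "per_base")) {
  mode <- match.arg(mode)
  stopifnot(length(chromSizes) > 0, !is.null(names(chromSizes)))
  if (mode == "per_base") {
    acc <- lapply(names(chromSizes), function(cn) {
      p <- seq_len(chromSizes[[cn]]) - 1
      split(p, classifyPositions(fwd, rev, cn, p))
    })
    regions <- lapply(CUP_CATEGORIES, function(cat) {
      grl <- lapply(seq_along(acc), function(i) {
        p <- acc[[i]][[cat]]
        positionsToRegions(rep(names(chromSizes)[i], length(p)), p)
      })
      suppressWarnings(reduce(do.call(c, grl)))
    })
    names(regions) <- CUP_CATEGORIES
    return(newScanResult(regions, chromSizes, mode))
  }
  intervalScan(fwd, rev, chromSizes)
}

intervalScan <- function(fwd, rev, chromSizes) {
  chromNames <- names(chromSizes)
  fmap <- resolveLiftMap(fwd, chromNames, chromSizes)
  acc <- list(STABLE = list(), REJECT_1 = list(), CHR_JUMP_1 = list(),
              REJECT_2 = list(), CHR_JUMP_2 = list(), POS_JUMP = list())
  put <- function(cat, cn, a0, a1) {
    if (a1 > a0)
      acc[[cat]][[length(acc[[cat]]) + 1L]] <<-
        data.table(chrom = cn, s0 = a0, s1 = a1)
  }

  if (nrow(fmap)) {
    amb <- fmap[status == "ambiguous"]
    for (i in seq_len(nrow(amb))) put("REJECT_1", amb$chrom[i], amb$s0[i], amb$s1[i])
    mapped <- fmap[status == "mapped"]
    j1 <- !sameChrom(mapped$dchrom, mapped$chrom)
    cj <- mapped[j1]
    for (i in seq_len(nrow(cj))) put("CHR_JUMP_1", cj$chrom[i], cj$s0[i], cj$s1[i])
    mapped <- mapped[!j1]
  } else {
    mapped <- fmap
  }

  if (nrow(mapped)) {
    destChroms <- unique(mapped$dchrom)
    rmap <- resolveLiftMap(rev, destChroms)
    rsplit <- if (nrow(rmap)) split(rmap, rmap$chrom) else list()
    for (i in seq_len(nrow(mapped))) {
      cn <- mapped$chrom[i]; sf <- mapped$slope[i]; cf <- mapped$intercept[i]
      u <- imageInterval(mapped$s0[i], mapped$s1[i], sf, cf)
      rp <- rsplit[[mapped$dchrom[i]]]
      cursor <- u[1]
      if (!is.null(rp)) {
        rp <- rp[s1 > u[1] & s0 < u[2]]
        if (nrow(rp)) rp <- rp[order(s0)]
        for (k in seq_len(nrow(rp))) {
          v0 <- max(u[1], rp$s0[k]); v1 <- min(u[2], rp$s1[k])
          if (v0 > cursor) {  # uncovered image gap -> second conversion fails
            pre <- preimageInterval(cursor, v0, sf, cf)
            put("REJECT_2", cn, pre[1], pre[2])
          }
          pre <- preimageInterval(v0, v1, sf, cf)
          if (rp$status[k] == "ambiguous") {
            put("REJECT_2", cn, pre[1], pre[2])
          } else if (!sameChrom(rp$dchrom[k], cn)) {
            put("CHR_JUMP_2", cn, pre[1], pre[2])
          } else {
            sg <- rp$slope[k]; cg <- rp$intercept[k]
            sB <- sg * sf; cB <- cg + sg * cf
            if (sB == 1 && cB == 0) {
              put("STABLE", cn, pre[1], pre[2])
            } else if (sB == -1) {
              # back(x) = cB - x: identity only at the integer fixed point
              xstar <- cB / 2
              if (xstar == floor(xstar) && xstar >= pre[1] && xstar < pre[2]) {
                put("POS_JUMP", cn, pre[1], xstar)
                put("STABLE", cn, xstar, xstar + 1)
                put("POS_JUMP", cn, xstar + 1, pre[2])
              } else put("POS_JUMP", cn, pre[1], pre[2])
            } else put("POS_JUMP", cn, pre[1], pre[2])
          }
          cursor <- v1
        }
      }
      if (cursor < u[2]) {
        pre <- preimageInterval(cursor, u[2], sf, cf)
        put("REJECT_2", cn, pre[1], pre[2])
      }
    }
  }

  toGR <- function(lst) {
    if (!length(lst)) return(GRanges())
    d <- rbindlist(lst)
    reduce(granges0(d$chrom, d$s0, d$s1))
  }
  regions <- lapply(acc, toGR)
  genome <- granges0(chromNames, rep(0, length(chromSizes)),
                     as.numeric(chromSizes))
  assigned <- suppressWarnings(reduce(do.call(c, unname(regions))))
  # everything not reached by a resolvable forward map fails conversion 1
  regions$REJECT_1 <- reduce(c(regions$REJECT_1,
                               GenomicRanges::setdiff(genome, assigned,
                                                      ignore.strand = TRUE)))
  newScanResult(regions[CUP_CATEGORIES], chromSizes, "interval")
}

newScanResult <- function(regions, chromSizes, mode) {
  regions <- lapply(regions, function(g) {
    g <- granges0(as.character(seqnames(g)), GenomicRanges::start(g) - 1,
                  as.numeric(GenomicRanges::end(g)), seqlens = chromSizes)
    sort(reduce(g))
  })
  new("CupScanResult", regions = GRangesList(regions),
      chromSizes = setNames(as.numeric(chromSizes), names(chromSizes)),
      mode = mode)
}

#' Re-classify an arbitrary region set per base
#'
#' Enumerates every position of `regions` and classifies it with
#' [classifyPositions()]. Used to verify idempotence: re-scanning the STABLE
#' set of a [scanGenome()] result must put every position back in `STABLE`.
#'
#' @inheritParams classifyPositions
#' @param regions a [GenomicRanges::GRanges] of source-build regions.
#' @return Named numeric vector of base counts per category.
#' @export
classifyRegionsPerBase <- function(fwd, rev, regions) {
  if (length(regions) == 0L)
    return(setNames(numeric(length(CUP_CATEGORIES)), CUP_CATEGORIES))
  d <- bedFrame(regions)
  chrom <- rep(d$chrom, d$end0 - d$start0)
  pos <- unlist(lapply(seq_len(nrow(d)),
                       function(i) seq(d$start0[i], d$end0[i] - 1)))
  tab <- table(classifyPositions(fwd, rev, chrom, pos))
  out <- setNames(numeric(length(CUP_CATEGORIES)), CUP_CATEGORIES)
  out[names(tab)] <- as.numeric(tab)
  out
}

#' Merge positions or intervals into a canonical region set
#'
#' Collapses bookended and overlapping intervals (distance-0 merge, the
#' `bedtools merge` default) into sorted disjoint regions; total covered bp
#' is conserved.
#'
#' @param x a [GenomicRanges::GRanges], or a data.frame with columns
#'   `chrom`, `start0`, `end0` (0-based half-open).
#' @return A sorted, reduced `GRanges`.
#' @export
mergeRegions <- function(x) {
  if (is.data.frame(x)) x <- granges0(x$chrom, x$start0, x$end0)
  sort(reduce(x, ignore.strand = TRUE))
}

#' Write scan output as BED files and a summary table
#'
#' One sorted, merged BED file per category (source-build coordinates, the
#' category as the name column) plus `summary.tsv` (category, bp, percent of
#' build).
#'
#' @param scan a [CupScanResult-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeScanResult <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cat in CUP_CATEGORIES) {
    p <- file.path(dir, paste0(cat, ".bed"))
    writeBedFile(cupRegions(scan, cat), p, name = cat)
    paths <- c(paths, p)
  }
  sp <- file.path(dir, "summary.tsv")
  fwrite(scanSummary(scan), sp, sep = "\t")
  invisible(c(paths, sp))
}
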