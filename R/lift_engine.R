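#' Lift single base positions between builds
#'
#' Maps 0-based single-base positions through a [ChainSet-class]. A position
#' covered by exactly one aligned block (or by several blocks that agree on
#' the destination) maps to
#' `dest = dest_block_start + (pos - source_block_start)`, reported as a
#' forward-strand coordinate (on '-' chains the raw chain coordinate is
#' reflected through the destination sequence length). A position covered
#' only by inter-block gaps, or by no chain, is unmapped. When blocks of
#' several chains cover a position with conflicting destinations, the chain
#' with the highest score wins; an exact score tie between conflicting
#' destinations is reported as `ambiguous`.
#'
#' @param chains a [ChainSet-class].
#' @param chrom character vector of source chromosome names (recycled with
#'   `pos`).
#' @param pos integer vector of 0-based source positions.
#' @return A data.frame with one row per input position: `chrom`, `pos`,
#'   `status` (`mapped` / `unmapped` / `ambiguous`), `dest_chrom`,
#'   `dest_pos` (0-based forward strand), `dest_strand`, `chain_ord`, and
#'   `reason` (`gap` / `no_chain` / `ambiguous` for failures).
#' @examples
#' cs <- parseChainLines(c("chain 100 chrA 1000 + 0 100 chrA 1000 + 0 100 1",
#'                         "100", ""))
#' liftPositions(cs, "chrA", c(42L, 500L))
#' @export
liftPositions <- function(chains, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  stopifnot(all(pos >= 0))
  out <- data.frame(chrom = chrom, pos = pos,
                    status = rep("unmapped", n),
                    dest_chrom = NA_character_, dest_pos = NA_real_,
                    dest_strand = NA_character_, chain_ord = NA_integer_,
                    reason = rep("no_chain", n),
                    stringsAsFactors = FALSE)
  if (n == 0L || chainCount(chains) == 0L) return(out)

  blocks <- chains@blocks
  known <- chrom %in% seqlevels(blocks)
  if (any(!known)) {
    for (nm in unique(chrom[!known]))
      message("chromosome '", nm, "' not present in chain set; unmapped")
  }
  if (!any(known)) return(out)

  q <- GRanges(chrom[known], IRanges(pos[known] + 1L, pos[known] + 1L),
               seqinfo = seqinfo(blocks))
  hits <- findOverlaps(q, blocks)
  kidx <- which(known)
  if (length(hits)) {
    b <- as.data.table(mcols(blocks)[subjectHits(hits), ])
    dtab <- data.table(qidx = kidx[queryHits(hits)],
                       ord = b$ord, score = b$score, dchrom = b$dchrom,
                       strand_c = b$strand_c,
                       dpos0 = b$intercept + b$slope * pos[kidx[queryHits(hits)]])
    dtab <- dtab[dtab[, .I[score == max(score)], by = qidx]$V1]
    u <- unique(dtab, by = c("qidx", "dchrom", "dpos0"))
    ambq <- u[duplicated(qidx), unique(qidx)]
    mapped <- u[!qidx %in% ambq]
    out$status[mapped$qidx] <- "mapped"
    out$dest_chrom[mapped$qidx] <- mapped$dchrom
    out$dest_pos[mapped$qidx] <- mapped$dpos0
    out$dest_strand[mapped$qidx] <- mapped$strand_c
    out$chain_ord[mapped$qidx] <- as.integer(mapped$ord)
    out$reason[mapped$qidx] <- NA_character_
    out$status[ambq] <- "ambiguous"
    out$reason[ambq] <- "ambiguous"
  }
  # unmapped positions inside a chain span sit in an alignment gap
  un <- which(known & out$status == "unmapped")
  if (length(un)) {
    qs <- GRanges(chrom[un], IRanges(pos[un] + 1L, pos[un] + 1L),
                  seqinfo = seqinfo(chains@spans))
    inSpan <- IRanges::overlapsAny(qs, chains@spans)
    out$reason[un[inSpan]] <- "gap"
  }
  out
}

#' Lift 1-bp BED records
#'
#' Partitions a stream of single-base BED records (`chrom`, `start0`, `end0`,
#' `name`) into mapped records (with new coordinates, labels kept) and
#' rejected records annotated with a reason code (`gap`, `no_chain`,
#' `ambiguous`). Record counts are conserved: `nrow(mapped) +
#' nrow(rejected) == nrow(input)`.
#'
#' @param chains a [ChainSet-class].
#' @param bed data.frame with columns `chrom`, `start0`, `end0`, `name`
#'   (0-based half-open; every record must have `end0 == start0 + 1`).
#' @return list with elements `mapped` (columns `chrom`, `start0`, `end0`,
#'   `name`, `strand`) and `rejected` (input columns plus `reason`).
#' @export
liftBedRecords <- function(chains, bed) {
  stopifnot(all(c("chrom", "start0", "end0") %in% names(bed)))
  if (is.null(bed$name))
    bed$name <- paste0(bed$chrom, "_", bed$start0)
  if (any(bed$end0 != bed$start0 + 1))
    stop("multi-base records are not supported: every record must have ",
         "end0 == start0 + 1")
  r <- liftPositions(chains, bed$chrom, bed$start0)
  ok <- r$status == "mapped"
  list(
    mapped = data.frame(chrom = r$dest_chrom[ok], start0 = r$dest_pos[ok],
                        end0 = r$dest_pos[ok] + 1, name = bed$name[ok],
                        strand = r$dest_strand[ok], stringsAsFactors = FALSE),
    rejected = data.frame(chrom = bed$chrom[!ok], start0 = bed$start0[!ok],
                          end0 = bed$end0[!ok], name = bed$name[!ok],
                          reason = r$reason[!ok], stringsAsFactors = FALSE))
}
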