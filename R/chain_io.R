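#' Read a UCSC chain file
#'
#' Parses a UCSC-format chain file (header lines
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id`, body lines `size dt dq`, final line a bare `size`), validates
#' every chain's block-sum arithmetic against its header span, and builds an
#' interval index over source ("target" in UCSC parlance, `tName`)
#' coordinates. Gzip-compressed files are decompressed transparently.
#'
#' Coordinates are kept exactly as written: 0-based half-open, destination
#' coordinates on the strand named by `qStrand`. Chains whose destination is
#' an unplaced/unlocalized/alternate contig are parsed and retained like any
#' other. Duplicate chain ids are tolerated with a warning; chains are keyed
#' internally by ordinal.
#'
#' @param file path to a chain file (optionally gzipped) or a connection.
#' @param direction optional free-text direction label, e.g.
#'   `"GRCh37->GRCh38"`.
#' @return A [ChainSet-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("chain 100 chrA 1000 + 0 100 chrB 2000 + 50 150 1", "100", ""), f)
#' cs <- readChainFile(f, "toy")
#' chainCount(cs)
#' @export
readChainFile <- function(file, direction = "") {
  if (inherits(file, "connection")) {
    lines <- readLines(file)
  } else {
    con <- file(file)  # transparently gunzips
    on.exit(close(con))
    lines <- readLines(con)
  }
  parseChainLines(lines, direction = direction)
}

#' @rdname readChainFile
#' @param lines character vector of chain-format lines.
#' @export
parseChainLines <- function(lines, direction = "") {
  lines <- sub("\r$", "", lines)
  trimmed <- trimws(lines)
  nonEmpty <- nzchar(trimmed) & !startsWith(trimmed, "#")
  isHeader <- grepl("^chain\\s", trimmed)
  if (any(nonEmpty & !isHeader & cumsum(isHeader) == 0L)) {
    bad <- which(nonEmpty & cumsum(isHeader) == 0L)[1L]
    stop("malformed chain file: data before first header at line ", bad)
  }
  hidx <- which(isHeader)
  nchain <- length(hidx)
  if (nchain == 0L) {
    return(newChainSet(emptyHeaders(), emptyBlocktab(), direction))
  }

  headers <- vector("list", nchain)
  for (i in seq_len(nchain)) {
    tok <- strsplit(trimmed[hidx[i]], "\\s+")[[1]]
    if (length(tok) != 13L)
      stop("malformed chain header at line ", hidx[i],
           ": expected 13 fields, got ", length(tok))
    score <- suppressWarnings(as.numeric(tok[2]))
    nums <- suppressWarnings(as.numeric(tok[c(4, 6, 7, 9, 11, 12)]))
    if (is.na(score) || anyNA(nums))
      stop("malformed chain header at line ", hidx[i], ": non-numeric field")
    headers[[i]] <- data.frame(
      ord = i, score = score,
      src_chrom = tok[3], src_size = nums[1],
      src_strand = tok[5], src_start = nums[2], src_end = nums[3],
      dest_chrom = tok[8], dest_size = nums[4],
      dest_strand = tok[10], dest_start = nums[5], dest_end = nums[6],
      chain_id = tok[13], stringsAsFactors = FALSE)
  }
  headers <- do.call(rbind, headers)
  if (any(headers$src_strand != "+"))
    stop("chain ", headers$chain_id[headers$src_strand != "+"][1],
         ": source strand must be '+'")

  # body lines grouped by preceding header
  grp <- cumsum(isHeader)
  bodyIdx <- which(nonEmpty & !isHeader)
  btok <- strsplit(trimmed[bodyIdx], "\\s+")
  blen <- lengths(btok)
  if (any(!blen %in% c(1L, 3L)))
    stop("malformed chain block at line ", bodyIdx[which(!blen %in% c(1L, 3L))[1]])
  bvals <- suppressWarnings(lapply(btok, as.numeric))
  if (anyNA(unlist(bvals)))
    stop("non-numeric chain block at line ",
         bodyIdx[which(vapply(bvals, anyNA, logical(1)))[1]])
  bt <- data.table(
    ord = grp[bodyIdx],
    size = vapply(bvals, `[`, numeric(1), 1L),
    dt = vapply(bvals, function(v) if (length(v) == 3L) v[2] else 0, numeric(1)),
    dq = vapply(bvals, function(v) if (length(v) == 3L) v[3] else 0, numeric(1)))

  # per-chain validation
  sums <- bt[, .(nb = .N, s_src = sum(size + dt), s_dest = sum(size + dq),
                 last_dt = dt[.N], last_dq = dq[.N], minsize = min(size)),
             by = ord]
  miss <- setdiff(headers$ord, sums$ord)
  if (length(miss))
    stop("chain ", headers$chain_id[headers$ord == miss[1]], " has no blocks")
  m <- merge(as.data.table(headers), sums, by = "ord")
  bad <- m[s_src != src_end - src_start | s_dest != dest_end - dest_start]
  if (nrow(bad))
    stop("block sums do not match header span for chain id ",
         bad$chain_id[1], " (source ", bad$s_src[1], " vs ",
         bad$src_end[1] - bad$src_start[1], "; dest ", bad$s_dest[1],
         " vs ", bad$dest_end[1] - bad$dest_start[1], ")")
  bad <- m[last_dt != 0 | last_dq != 0]
  if (nrow(bad))
    stop("final block of chain id ", bad$chain_id[1], " has non-zero gaps")
  bad <- m[minsize <= 0]
  if (nrow(bad))
    stop("chain id ", bad$chain_id[1], " has a block of non-positive size")

  if (anyDuplicated(headers$chain_id))
    warning("duplicate chain id(s): ",
            paste(unique(headers$chain_id[duplicated(headers$chain_id)]),
                  collapse = ", "), "; chains are keyed by ordinal")

  headers$src_strand <- NULL
  newChainSet(headers, as.data.frame(bt), direction)
}

emptyHeaders <- function() {
  data.frame(ord = integer(), score = numeric(), src_chrom = character(),
             src_size = numeric(), src_start = numeric(), src_end = numeric(),
             dest_chrom = character(), dest_size = numeric(),
             dest_strand = character(), dest_start = numeric(),
             dest_end = numeric(), chain_id = character(),
             stringsAsFactors = FALSE)
}

emptyBlocktab <- function() {
  data.frame(ord = integer(), size = numeric(), dt = numeric(),
             dq = numeric())
}

## Assemble the ChainSet: compute per-block source intervals and the affine
## map to forward-strand destination coordinates.
newChainSet <- function(headers, blocktab, direction = "") {
  if (nrow(headers) == 0L) {
    return(new("ChainSet", headers = headers, blocktab = blocktab,
               blocks = GRanges(), spans = GRanges(),
               direction = as.character(direction)))
  }
  bt <- as.data.table(blocktab)
  hd <- as.data.table(headers)
  bt <- merge(bt, hd[, .(ord, score, src_chrom, src_start, dest_start,
                         dest_chrom, dest_size, dest_strand)],
              by = "ord", sort = FALSE)
  setkey(bt, ord)
  cum0 <- function(x) cumsum(c(0, head(x, -1)))
  bt[, `:=`(b_src0 = src_start + cum0(size + dt),
            b_q0 = dest_start + cum0(size + dq)), by = ord]
  # affine forward-strand map: dest = intercept + slope * src
  bt[, slope := ifelse(dest_strand == "+", 1, -1)]
  bt[, intercept := ifelse(dest_strand == "+",
                           b_q0 - b_src0,
                           (dest_size - 1 - b_q0) + b_src0)]
  blocks <- granges0(bt$src_chrom, bt$b_src0, bt$b_src0 + bt$size)
  mcols(blocks) <- S4Vectors::DataFrame(
    ord = bt$ord, score = bt$score, dchrom = bt$dest_chrom,
    dsize = bt$dest_size, strand_c = bt$dest_strand,
    slope = bt$slope, intercept = bt$intercept)
  spans <- granges0(headers$src_chrom, headers$src_start, headers$src_end)
  mcols(spans)$ord <- headers$ord
  new("ChainSet", headers = as.data.frame(headers),
      blocktab = as.data.frame(blocktab[, c("ord", "size", "dt", "dq")]),
      blocks = blocks, spans = spans, direction = as.character(direction))
}

#' Write a ChainSet back to chain format
#'
#' Serializes in chain ordinal order; output re-parses to an equal
#' `ChainSet` (round-trip identity). Scores and coordinates are written as
#' integers.
#'
#' @param x a [ChainSet-class].
#' @param file output path or connection.
#' @return Invisibly, the character vector of lines written.
#' @export
writeChainFile <- function(x, file) {
  lines <- chainLines(x)
  writeLines(lines, file)
  invisible(lines)
}

chainLines <- function(x) {
  h <- x@headers
  if (nrow(h) == 0L) return(character())
  bt <- as.data.table(x@blocktab)
  num <- function(v) sprintf("%.0f", v)
  out <- vector("list", nrow(h))
  for (i in seq_len(nrow(h))) {
    hi <- h[i, ]
    hdr <- paste("chain", num(hi$score), hi$src_chrom, num(hi$src_size), "+",
                 num(hi$src_start), num(hi$src_end), hi$dest_chrom,
                 num(hi$dest_size), hi$dest_strand, num(hi$dest_start),
                 num(hi$dest_end), hi$chain_id)
    b <- bt[ord == hi$ord]
    n <- nrow(b)
    body <- if (n > 1L)
      c(paste(num(b$size[-n]), num(b$dt[-n]), num(b$dq[-n])), num(b$size[n]))
    else num(b$size)
    out[[i]] <- c(hdr, body, "")
  }
  unlist(out)
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV (sequence name, length in bp), as distributed by UCSC
#' (`*.chrom.sizes`).
#'
#' @param file path to the table.
#' @return Named integer vector of sequence lengths.
#' @export
readChromSizes <- function(file) {
  d <- fread(file, header = FALSE, select = 1:2,
             col.names = c("chrom", "size"))
  setNames(as.integer(d$size), d$chrom)
}

#' @rdname readChromSizes
#' @param sizes named vector of lengths.
#' @export
writeChromSizes <- function(sizes, file) {
  fwrite(data.table(chrom = names(sizes), size = as.integer(sizes)),
         file, sep = "\t", col.names = FALSE)
  invisible(file)
}
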