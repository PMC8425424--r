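#' Read and write VCF files as record tables
#'
#' Variant records travel through the package as a plain data.frame with the
#' VCF 4.x fixed columns (`CHROM`, `POS` — 1-based, `ID`, `REF`, `ALT`,
#' `QUAL`, `FILTER`, `INFO`) plus `FORMAT` and a single sample column `GT`
#' (the full per-sample string). Header meta lines are carried in the
#' `"meta"` attribute and the sample name in `"sample"`. Parsing goes through
#' \pkg{vcfR}; writing emits plain-text VCF.
#'
#' @param file path to a VCF (plain or bgzip/gzip for reading).
#' @return `readVcfFile`: the records data.frame described above.
#' @export
readVcfFile <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  d <- data.frame(CHROM = fix$CHROM, POS = as.integer(fix$POS),
                  ID = fix$ID, REF = fix$REF, ALT = fix$ALT,
                  QUAL = fix$QUAL, FILTER = fix$FILTER, INFO = fix$INFO,
                  stringsAsFactors = FALSE)
  d$ID[is.na(d$ID)] <- "."
  d$QUAL[is.na(d$QUAL)] <- "."
  d$FILTER[is.na(d$FILTER)] <- "."
  d$INFO[is.na(d$INFO)] <- "."
  gt <- v@gt
  if (!is.null(gt) && ncol(gt) >= 2L) {
    d$FORMAT <- gt[, 1L]
    d$GT <- gt[, 2L]
    attr(d, "sample") <- colnames(gt)[2L]
  } else {
    d$FORMAT <- "GT"
    d$GT <- "./."
    attr(d, "sample") <- "SAMPLE"
  }
  attr(d, "meta") <- v@meta
  d
}

#' @rdname readVcfFile
#' @param records a records data.frame.
#' @param meta character vector of `##` header lines; defaults to the
#'   records' `"meta"` attribute or a minimal header.
#' @export
writeVcfFile <- function(records, file, meta = NULL) {
  if (is.null(meta)) meta <- attr(records, "meta")
  if (is.null(meta))
    meta <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  sample <- attr(records, "sample")
  if (is.null(sample)) sample <- "SAMPLE"
  hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample), collapse = "\t")
  body <- if (nrow(records)) {
    do.call(paste, c(records[c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO", "FORMAT", "GT")],
                     sep = "\t"))
  } else character()
  writeLines(c(meta, hdr, body), file)
  invisible(file)
}

## construct a records data.frame with the standard attributes
newVcfRecords <- function(CHROM, POS, REF, ALT, GT, ID = ".",
                          sample = "SAMPLE") {
  n <- length(POS)
  d <- data.frame(CHROM = CHROM, POS = as.integer(POS),
                  ID = rep_len(ID, n), REF = REF, ALT = ALT,
                  QUAL = rep_len(".", n), FILTER = rep_len(".", n),
                  INFO = rep_len(".", n), FORMAT = rep_len("GT", n),
                  GT = GT, stringsAsFactors = FALSE)
  attr(d, "meta") <- c("##fileformat=VCFv4.2",
                       '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  attr(d, "sample") <- sample
  d
}

#' Base lookup over a sequence set
#'
#' Wraps a [Biostrings::DNAStringSet] (e.g. a read FASTA) into a vectorized
#' lookup `f(chrom, pos0)` returning the uppercase base at each 0-based
#' position, or `NA` for unknown sequences / out-of-range positions. IUPAC
#' ambiguity codes are returned verbatim so callers can apply
#' mismatch-on-ambiguity rules.
#'
#' @param seqs a named `DNAStringSet`.
#' @return A function `(chrom, pos0) -> character`.
#' @export
makeBaseLookup <- function(seqs) {
  stopifnot(is(seqs, "DNAStringSet"), !is.null(names(seqs)))
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  function(chrom, pos0) {
    chrom <- as.character(chrom)
    out <- rep(NA_character_, length(chrom))
    ok <- !is.na(chrom) & chrom %in% names(lens) & !is.na(pos0) &
      pos0 >= 0 & pos0 < lens[chrom]
    if (any(ok)) {
      for (cn in unique(chrom[ok])) {
        idx <- which(ok & chrom == cn)
        s <- seqs[[cn]]
        out[idx] <- vapply(pos0[idx] + 1, function(p)
          toupper(as.character(subseq(s, p, p))), character(1))
      }
    }
    out
  }
}
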