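#' Extract biallelic SNVs from a record table
#'
#' Keeps records whose REF and ALT are each a single unambiguous base
#' (A/C/G/T) with exactly one alternate allele; drops indels, multiallelic
#' sites and symbolic alleles. Order is preserved. Records that cannot be
#' interpreted at all (missing coordinate or alleles) are skipped with a
#' warning and counted.
#'
#' @param records a VCF records data.frame (see [readVcfFile()]).
#' @return The filtered records; attributes `"n_removed"` (non-SNV records
#'   dropped) and `"n_malformed"` (uninterpretable records skipped).
#' @export
extractBiallelicSnvs <- function(records) {
  malformed <- is.na(records$POS) | is.na(records$REF) | is.na(records$ALT) |
    !nzchar(records$REF) | !nzchar(records$ALT)
  if (any(malformed))
    warning(sum(malformed), " malformed record(s) skipped")
  ok <- !malformed &
    nchar(records$REF) == 1L & isUnambiguousBase(records$REF) &
    nchar(records$ALT) == 1L & isUnambiguousBase(records$ALT)
  out <- records[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "meta") <- attr(records, "meta")
  attr(out, "sample") <- attr(records, "sample")
  attr(out, "n_removed") <- sum(!ok & !malformed)
  attr(out, "n_malformed") <- sum(malformed)
  out
}

## Reference-allele handling at one conversion step, vectorized over records.
## ref/alt are the alleles already on the destination strand (i.e. reverse
## complemented when the chain used is '-'). Returns a list:
##   mismatch  logical      TRUE where the dialect rejects the variant
##   ref, alt  character    post-dialect alleles (ref possibly updated)
##
## dialect "reject_on_mismatch" (picard LiftoverVcf): any disagreement
## between the target base and REF is a mismatch. dialect "update_ref"
## (CrossMap VCF mode): REF is updated to the target base and the variant
## fails only when ALT equals the updated REF. A target base that is an
## IUPAC ambiguity code (or unavailable) is a mismatch under both dialects.
applyMismatchDialect <- function(ref, alt, targetBase, dialect) {
  ambiguous <- is.na(targetBase) | !isUnambiguousBase(targetBase)
  targetBase <- toupper(targetBase)
  if (dialect == "reject_on_mismatch") {
    mm <- ambiguous | targetBase != ref
    list(mismatch = mm, ref = ref, alt = alt)
  } else {
    newRef <- ifelse(ambiguous, ref, targetBase)
    mm <- ambiguous | alt == newRef
    list(mismatch = mm, ref = newRef, alt = alt)
  }
}

#' Convert VCF variants to another build with reference-allele checking
#'
#' Lifts each biallelic SNV through `chains` and applies one of the two
#' reference-allele dialects used by the common conversion tools:
#' `"reject_on_mismatch"` removes any variant whose (strand-adjusted) REF
#' disagrees with the target-build base; `"update_ref"` replaces REF with
#' the target base and fails only when the source ALT equals the updated
#' REF. A target base that is an IUPAC ambiguity code is a mismatch under
#' both dialects. On '-'-strand chains REF and ALT are reverse-complemented
#' before comparison.
#'
#' @param records biallelic SNV records (see [extractBiallelicSnvs()]).
#' @param chains [ChainSet-class] source -> target.
#' @param targetLookup base lookup on the target build
#'   (see [makeBaseLookup()]).
#' @param dialect `"reject_on_mismatch"` or `"update_ref"`.
#' @return list: `converted` (records on target coordinates, alleles
#'   strand-adjusted and possibly REF-updated, with a `strand` column) and
#'   `failed` (input records plus a `category` column: `REJECT_1` or
#'   `MISMATCH_1`).
#' @export
convertVariants <- function(records, chains, targetLookup,
                            dialect = c("reject_on_mismatch", "update_ref")) {
  dialect <- match.arg(dialect)
  l1 <- liftPositions(chains, records$CHROM, records$POS - 1)
  mapped <- l1$status == "mapped"
  ref1 <- ifelse(mapped & l1$dest_strand == "-",
                 complementBase(records$REF), records$REF)
  alt1 <- ifelse(mapped & l1$dest_strand == "-",
                 complementBase(records$ALT), records$ALT)
  tgt <- rep(NA_character_, nrow(records))
  tgt[mapped] <- targetLookup(l1$dest_chrom[mapped], l1$dest_pos[mapped])
  dd <- applyMismatchDialect(ref1, alt1, tgt, dialect)

  category <- rep(NA_character_, nrow(records))
  category[!mapped] <- "REJECT_1"
  category[mapped & dd$mismatch] <- "MISMATCH_1"
  ok <- is.na(category)

  converted <- records[ok, , drop = FALSE]
  if (nrow(converted)) {
    converted$CHROM <- l1$dest_chrom[ok]
    converted$POS <- as.integer(l1$dest_pos[ok] + 1)
    converted$REF <- dd$ref[ok]
    converted$ALT <- dd$alt[ok]
    converted$strand <- l1$dest_strand[ok]
  }
  failed <- records[!ok, , drop = FALSE]
  if (nrow(failed)) failed$category <- category[!ok]
  rownames(converted) <- rownames(failed) <- NULL
  attr(converted, "meta") <- attr(records, "meta")
  attr(converted, "sample") <- attr(records, "sample")
  list(converted = converted, failed = failed)
}

#' Round-trip classification of VCF variants
#'
#' Applies the full round-trip flow of [classifyPositions()] to each
#' biallelic SNV, with reference-allele mismatch checks inserted at each
#' conversion: after a successful first lift the target base is checked
#' under the chosen dialect (`MISMATCH_1`), after a successful second lift
#' the source base at the returned locus is checked the same way
#' (`MISMATCH_2`). The decision order per record is `REJECT_1`,
#' `MISMATCH_1`, `CHR_JUMP_1`, `REJECT_2`, `MISMATCH_2`, `CHR_JUMP_2`,
#' `POS_JUMP`, `STABLE`: a mismatch aborts the conversion the way the tools
#' abort it, before any chromosome or position comparison at that step.
#'
#' @inheritParams convertVariants
#' @param fwd,rev forward and reverse [ChainSet-class] objects.
#' @param sourceLookup,targetLookup base lookups for the source and target
#'   builds ([makeBaseLookup()]).
#' @return list: `category` (factor over [vcfCategories()], one per input
#'   record), `converted` (first-conversion output for every record that
#'   passed lift + mismatch checks), `perCategory` (input records split by
#'   category), `counts` (named vector over all categories; sums to
#'   `nrow(records)`).
#' @export
roundtripClassifyVcf <- function(records, fwd, rev, sourceLookup,
                                 targetLookup,
                                 dialect = c("reject_on_mismatch",
                                             "update_ref")) {
  dialect <- match.arg(dialect)
  n <- nrow(records)
  category <- rep(NA_character_, n)

  l1 <- liftPositions(fwd, records$CHROM, records$POS - 1)
  mapped1 <- l1$status == "mapped"
  category[!mapped1] <- "REJECT_1"
  flip1 <- mapped1 & l1$dest_strand == "-"
  ref1 <- ifelse(flip1, complementBase(records$REF), records$REF)
  alt1 <- ifelse(flip1, complementBase(records$ALT), records$ALT)
  tgt <- rep(NA_character_, n)
  tgt[mapped1] <- targetLookup(l1$dest_chrom[mapped1], l1$dest_pos[mapped1])
  d1 <- applyMismatchDialect(ref1, alt1, tgt, dialect)
  category[is.na(category) & d1$mismatch] <- "MISMATCH_1"
  category[is.na(category) & !sameChrom(l1$dest_chrom, records$CHROM)] <-
    "CHR_JUMP_1"

  todo <- which(is.na(category))
  if (length(todo)) {
    l2 <- liftPositions(rev, l1$dest_chrom[todo], l1$dest_pos[todo])
    mapped2 <- l2$status == "mapped"
    cat2 <- rep(NA_character_, length(todo))
    cat2[!mapped2] <- "REJECT_2"
    flip2 <- mapped2 & l2$dest_strand == "-"
    ref2 <- ifelse(flip2, complementBase(d1$ref[todo]), d1$ref[todo])
    alt2 <- ifelse(flip2, complementBase(d1$alt[todo]), d1$alt[todo])
    src <- rep(NA_character_, length(todo))
    src[mapped2] <- sourceLookup(l2$dest_chrom[mapped2], l2$dest_pos[mapped2])
    d2 <- applyMismatchDialect(ref2, alt2, src, dialect)
    cat2[is.na(cat2) & d2$mismatch] <- "MISMATCH_2"
    cat2[is.na(cat2) & !sameChrom(l2$dest_chrom, records$CHROM[todo])] <-
      "CHR_JUMP_2"
    cat2[is.na(cat2) & l2$dest_pos != records$POS[todo] - 1] <- "POS_JUMP"
    cat2[is.na(cat2)] <- "STABLE"
    category[todo] <- cat2
  }
  category <- factor(category, levels = VCF_CATEGORIES)

  ok1 <- !category %in% c("REJECT_1", "MISMATCH_1")
  converted <- records[ok1, , drop = FALSE]
  if (nrow(converted)) {
    converted$CHROM <- l1$dest_chrom[ok1]
    converted$POS <- as.integer(l1$dest_pos[ok1] + 1)
    converted$REF <- d1$ref[ok1]
    converted$ALT <- d1$alt[ok1]
    converted$strand <- l1$dest_strand[ok1]
    rownames(converted) <- NULL
  }
  attr(converted, "meta") <- attr(records, "meta")
  attr(converted, "sample") <- attr(records, "sample")
  counts <- setNames(as.numeric(table(category)), VCF_CATEGORIES)
  list(category = category, converted = converted,
       perCategory = split(records, category), counts = counts)
}

#' Pre-exclude variants at conversion-unstable positions
#'
#' Splits a record table by whether each variant's position (0-based) lies
#' inside a region set of CUPs on the same build. Pre-excluding variants at
#' the novel CUPs before conversion yields exactly the stable variant set
#' that running the full round-trip algorithm would keep.
#'
#' @param records VCF records data.frame.
#' @param cupRegions [GenomicRanges::GRanges] of CUPs on the records' build.
#' @return list: `kept`, `excluded` (both record tables;
#'   `nrow(kept) + nrow(excluded) == nrow(records)`).
#' @export
filterAtCups <- function(records, cupRegions) {
  if (nrow(records) == 0L || length(cupRegions) == 0L) {
    return(list(kept = records, excluded = records[0, , drop = FALSE]))
  }
  q <- granges0(records$CHROM, records$POS - 1, records$POS,
                seqlens = NULL)
  seqlevels(q) <- union(seqlevels(q), seqlevels(cupRegions))
  hit <- IRanges::overlapsAny(q, cupRegions, ignore.strand = TRUE)
  kept <- records[!hit, , drop = FALSE]
  excluded <- records[hit, , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  for (a in c("meta", "sample")) {
    attr(kept, a) <- attr(records, a)
    attr(excluded, a) <- attr(records, a)
  }
  list(kept = kept, excluded = excluded)
}

## allele multiset of an unphased genotype, e.g. "0|1" + REF=A, ALT=G -> "A/G"
genotypeKey <- function(gt, ref, alt) {
  gtf <- sub(":.*", "", gt)
  vapply(seq_along(gtf), function(i) {
    idx <- strsplit(gtf[i], "[/|]")[[1]]
    al <- ifelse(idx == "0", ref[i], ifelse(idx == "1", alt[i], NA))
    paste(sort(al), collapse = "/")
  }, character(1))
}

#' Position and genotype discordance between two variant sets
#'
#' Compares converted variants against natively aligned calls on the same
#' build. Position discordance is the fraction of converted variants with no
#' aligned variant at the same (chromosome, position). Genotype discordance
#' is computed only over position matches, comparing unphased allele
#' multisets (so `0/1` and `1|0` agree), its denominator being the number of
#' position-matched variants. Both are `NA` when their denominator is zero.
#'
#' @param converted,aligned VCF records data.frames on the same build.
#' @return list of class `"DiscordanceReport"`: `position_discordance`,
#'   `genotype_discordance`, `n_converted`, `n_position_matched`,
#'   `n_genotype_discordant`.
#' @export
discordance <- function(converted, aligned) {
  n <- nrow(converted)
  if (n == 0L) {
    out <- list(position_discordance = NA_real_,
                genotype_discordance = NA_real_, n_converted = 0L,
                n_position_matched = 0L, n_genotype_discordant = 0L)
    class(out) <- "DiscordanceReport"
    return(out)
  }
  keyC <- paste(normChrom(converted$CHROM), converted$POS)
  keyA <- paste(normChrom(aligned$CHROM), aligned$POS)
  m <- match(keyC, keyA)
  matched <- !is.na(m)
  nGenoDisc <- 0L
  if (any(matched)) {
    gC <- genotypeKey(converted$GT[matched], converted$REF[matched],
                      converted$ALT[matched])
    gA <- genotypeKey(aligned$GT[m[matched]], aligned$REF[m[matched]],
                      aligned$ALT[m[matched]])
    nGenoDisc <- sum(gC != gA)
  }
  out <- list(
    position_discordance = sum(!matched) / n,
    genotype_discordance = if (any(matched))
      nGenoDisc / sum(matched) else NA_real_,
    n_converted = n,
    n_position_matched = sum(matched),
    n_genotype_discordant = nGenoDisc)
  class(out) <- "DiscordanceReport"
  out
}

#' @export
print.DiscordanceReport <- function(x, ...) {
  cat("DiscordanceReport\n")
  cat(sprintf("  position discordance: %s (%d / %d converted)\n",
              format(x$position_discordance),
              x$n_converted - x$n_position_matched, x$n_converted))
  cat(sprintf("  genotype discordance: %s (%d / %d position-matched)\n",
              format(x$genotype_discordance), x$n_genotype_discordant,
              x$n_position_matched))
  invisible(x)
}
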