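#' Rearrangement scripts for paired toy builds
#'
#' A rearrangement script declares how a toy "target" build differs from a
#' toy "source" build as an ordered set of non-overlapping operations on
#' source coordinates (0-based half-open). [realizeScript()] turns a script
#' into sequences for both builds, exact chain files in both directions, and
#' per-base truth labels, so that every conversion-stability category is
#' manufactured analytically:
#'
#' * `opDelete(chrom, start0, end0)` — interval absent from the target build
#'   (truth `REJECT_1`: first conversion falls in a chain gap);
#' * `opInsert(chrom, at0, length)` — novel sequence in the target build
#'   (shifts coordinates; all source bases stay `STABLE`);
#' * `opInvert(chrom, start0, end0)` — interval reverse-complemented in the
#'   target build, mapped by a '-'-strand chain (`STABLE`: the round trip
#'   returns);
#' * `opDuplicate(chrom, start0, end0, tie = FALSE)` — interval present
#'   twice in the target build. With `tie = FALSE` the in-place copy's chain
#'   scores twice the appended copy's, the score policy resolves the
#'   ambiguity, and the interval is `STABLE`; with `tie = TRUE` both chains
#'   score equally and the interval is unresolvably ambiguous, hence
#'   `REJECT_1`;
#' * `opTranslocate(chrom, start0, end0, destChrom)` — interval moved to a
#'   different target chromosome (`CHR_JUMP_1`);
#' * `opAsymmetricBackmap(chrom, start0, end0, altChrom, altStart0)` — the
#'   interval maps forward normally but the reverse chain sends the
#'   corresponding target interval elsewhere. `altChrom = NULL` drops it
#'   from the reverse chains (`REJECT_2`); another chromosome gives
#'   `CHR_JUMP_2`; the same chromosome at a different offset gives
#'   `POS_JUMP`. This deliberate asymmetry is how the no-return categories
#'   are manufactured; without such operations the two chain files are exact
#'   mutual inverses.
#'
#' @param chromLengths named vector of source chromosome lengths (bp).
#' @param ops list of operations built with the `op*()` constructors.
#' @param seed integer seed controlling sequence generation.
#' @return An object of class `"rearrangement_script"`.
#' @examples
#' sc <- rearrangementScript(c(chrA = 2000, chrB = 1500),
#'                           list(opDelete("chrA", 100, 150)), seed = 1)
#' pair <- realizeScript(sc)
#' scanSummary(scanGenome(pair$fwd, pair$rev, pair$chromSizes))
#' @export
rearrangementScript <- function(chromLengths, ops = list(), seed = 1L) {
  stopifnot(length(chromLengths) > 0, !is.null(names(chromLengths)),
            all(chromLengths > 0))
  for (op in ops) validateOp(op, chromLengths)
  # ops must not overlap on source coordinates (keeps truth derivable)
  iv <- opIntervals(ops)
  if (nrow(iv) > 1L) {
    iv <- iv[order(iv$chrom, iv$s0), ]
    same <- iv$chrom[-1] == iv$chrom[-nrow(iv)]
    if (any(same & iv$s0[-1] < iv$s1[-nrow(iv)]))
      stop("script error: overlapping operations on source coordinates")
  }
  for (op in ops) {
    if (op$kind == "insert" && nrow(iv)) {
      inside <- iv$chrom == op$chrom & iv$s0 < op$at0 & op$at0 < iv$s1
      if (any(inside))
        stop("script error: insertion point inside another operation")
    }
  }
  structure(list(chromLengths = setNames(as.integer(chromLengths),
                                         names(chromLengths)),
                 ops = ops, seed = as.integer(seed)),
            class = "rearrangement_script")
}

opIntervals <- function(ops) {
  rows <- lapply(ops, function(op) {
    if (op$kind == "insert") NULL
    else data.frame(chrom = op$chrom, s0 = op$s0, s1 = op$s1,
                    stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(chrom = character(), s0 = numeric(),
                               s1 = numeric()) else out
}

validateOp <- function(op, lens) {
  chk <- function(chrom, s0, s1) {
    if (!chrom %in% names(lens))
      stop("script error: unknown chromosome '", chrom, "'")
    if (s0 < 0 || s1 <= s0 || s1 > lens[[chrom]])
      stop("script error: interval [", s0, ",", s1, ") out of bounds on ",
           chrom)
  }
  switch(op$kind,
    insert = {
      if (!op$chrom %in% names(lens))
        stop("script error: unknown chromosome '", op$chrom, "'")
      if (op$at0 < 0 || op$at0 > lens[[op$chrom]] || op$len <= 0)
        stop("script error: bad insert")
    },
    translocate = {
      chk(op$chrom, op$s0, op$s1)
      if (!op$destChrom %in% names(lens) || op$destChrom == op$chrom)
        stop("script error: translocation needs a different existing ",
             "destination chromosome")
    },
    asymmetric_backmap = {
      chk(op$chrom, op$s0, op$s1)
      if (!is.null(op$altChrom)) {
        chk(op$altChrom, op$altStart0, op$altStart0 + (op$s1 - op$s0))
        if (op$altChrom == op$chrom && op$altStart0 == op$s0)
          stop("script error: asymmetric backmap must not be the identity")
      }
    },
    chk(op$chrom, op$s0, op$s1))
  invisible(TRUE)
}

#' @rdname rearrangementScript
#' @param chrom,start0,end0 source interval (0-based half-open).
#' @export
opDelete <- function(chrom, start0, end0)
  list(kind = "delete", chrom = chrom, s0 = start0, s1 = end0)

#' @rdname rearrangementScript
#' @param at0 insertion point on the source (0-based).
#' @param length length of the novel inserted sequence.
#' @export
opInsert <- function(chrom, at0, length)
  list(kind = "insert", chrom = chrom, at0 = at0, len = length)

#' @rdname rearrangementScript
#' @export
opInvert <- function(chrom, start0, end0)
  list(kind = "invert", chrom = chrom, s0 = start0, s1 = end0)

#' @rdname rearrangementScript
#' @param tie if `TRUE` the two copies' chains score equally (unresolvable
#'   ambiguity, `REJECT_1`); if `FALSE` the in-place copy wins (`STABLE`).
#' @export
opDuplicate <- function(chrom, start0, end0, tie = FALSE)
  list(kind = "duplicate", chrom = chrom, s0 = start0, s1 = end0, tie = tie)

#' @rdname rearrangementScript
#' @param destChrom target-build chromosome receiving the interval.
#' @export
opTranslocate <- function(chrom, start0, end0, destChrom)
  list(kind = "translocate", chrom = chrom, s0 = start0, s1 = end0,
       destChrom = destChrom)

#' @rdname rearrangementScript
#' @param altChrom,altStart0 where the reverse chains send the interval
#'   back to (`NULL` altChrom: nowhere).
#' @export
opAsymmetricBackmap <- function(chrom, start0, end0, altChrom = NULL,
                                altStart0 = NULL)
  list(kind = "asymmetric_backmap", chrom = chrom, s0 = start0, s1 = end0,
       altChrom = altChrom, altStart0 = altStart0)

opTruthCategory <- function(op) {
  switch(op$kind,
         delete = "REJECT_1",
         translocate = "CHR_JUMP_1",
         duplicate = if (isTRUE(op$tie)) "REJECT_1" else "STABLE",
         asymmetric_backmap =
           if (is.null(op$altChrom)) "REJECT_2"
           else if (op$altChrom == op$chrom) "POS_JUMP" else "CHR_JUMP_2",
         "STABLE")
}

#' Realize a rearrangement script
#'
#' Builds the paired toy genomes and their exact chain files. The forward
#' map is assembled from the target-build layout; the reverse map is its
#' inverse, except where `opAsymmetricBackmap` deliberately redirects or
#' drops the back-mapping. Chain scores are block-length sums, so the
#' highest-score ambiguity policy is exercised controllably by duplications.
#' Both chain sets are produced by serializing to chain format and
#' re-parsing, so they always satisfy the format's arithmetic invariants.
#'
#' @param script a [rearrangementScript()].
#' @return list of class `"synthetic_build_pair"`: `srcSeqs`, `destSeqs`
#'   ([Biostrings::DNAStringSet]), `fwd`, `rev` ([ChainSet-class]), `truth`
#'   ([GenomicRanges::GRangesList] over [cupCategories()], partitioning the
#'   source genome), `chromSizes` (source), `destSizes` (target), `script`.
#' @export
realizeScript <- function(script) {
  stopifnot(inherits(script, "rearrangement_script"))
  lens <- script$chromLengths
  chroms <- names(lens)

  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(script$seed)

  srcSeqs <- DNAStringSet(vapply(chroms, function(cn)
    paste(sample(c("A", "C", "G", "T"), lens[[cn]], replace = TRUE),
          collapse = ""), character(1)))
  names(srcSeqs) <- chroms

  # source pieces per chromosome: script ops + identity fillers
  pieces <- list()
  for (cn in chroms) {
    opsHere <- Filter(function(op) op$chrom == cn, script$ops)
    iv <- lapply(opsHere, function(op) {
      if (op$kind == "insert") list(s0 = op$at0, s1 = op$at0, op = op)
      else list(s0 = op$s0, s1 = op$s1, op = op)
    })
    iv <- iv[order(vapply(iv, `[[`, numeric(1), "s0"))]
    cursor <- 0
    for (p in iv) {
      if (p$s0 > cursor)
        pieces[[length(pieces) + 1L]] <- list(kind = "identity", chrom = cn,
                                              s0 = cursor, s1 = p$s0)
      if (p$op$kind == "insert") {
        pieces[[length(pieces) + 1L]] <- c(p$op, list(s0 = p$s0, s1 = p$s1))
      } else {
        pieces[[length(pieces) + 1L]] <- p$op
      }
      cursor <- max(cursor, p$s1)
    }
    if (cursor < lens[[cn]])
      pieces[[length(pieces) + 1L]] <- list(kind = "identity", chrom = cn,
                                            s0 = cursor, s1 = lens[[cn]])
  }

  # target-build layout: native pieces in order, then appended pieces
  # (translocations, duplicate extra copies) in op order
  layout <- setNames(vector("list", length(chroms)), chroms)
  for (p in pieces) {
    if (p$kind == "delete") next
    dest <- if (p$kind == "translocate") p$destChrom else p$chrom
    if (p$kind == "translocate") next  # appended below, after native pieces
    layout[[dest]] <- c(layout[[dest]], list(p))
  }
  for (p in pieces) {
    if (p$kind == "translocate")
      layout[[p$destChrom]] <- c(layout[[p$destChrom]], list(p))
    if (p$kind == "duplicate")
      layout[[p$chrom]] <- c(layout[[p$chrom]],
                             list(c(p, list(copy = TRUE))))
  }

  destParts <- setNames(vector("list", length(chroms)), chroms)
  entries <- list()   # forward map entries
  addEntry <- function(aCh, a0, a1, bCh, b0, strand, standalone = FALSE,
                       score = NA_real_, tag = "") {
    entries[[length(entries) + 1L]] <<- data.frame(
      a_chrom = aCh, a0 = a0, a1 = a1, b_chrom = bCh, b0 = b0,
      strand = strand, standalone = standalone, score = score, tag = tag,
      stringsAsFactors = FALSE)
  }
  for (cn in chroms) {
    d0 <- 0
    for (p in layout[[cn]]) {
      plen <- if (p$kind == "insert") p$len else p$s1 - p$s0
      seqpart <- switch(p$kind,
        insert = paste(sample(c("A", "C", "G", "T"), p$len, replace = TRUE),
                       collapse = ""),
        invert = as.character(reverseComplement(
          subseq(srcSeqs[[p$chrom]], p$s0 + 1, p$s1))),
        as.character(subseq(srcSeqs[[p$chrom]], p$s0 + 1, p$s1)))
      destParts[[cn]] <- c(destParts[[cn]], seqpart)
      if (p$kind != "insert") {
        strand <- if (p$kind == "invert") "-" else "+"
        if (p$kind == "duplicate") {
          len <- p$s1 - p$s0
          if (isTRUE(p$copy)) {
            addEntry(p$chrom, p$s0, p$s1, cn, d0, "+", standalone = TRUE,
                     score = len, tag = "dup_copy")
          } else {
            addEntry(p$chrom, p$s0, p$s1, cn, d0, "+", standalone = TRUE,
                     score = if (isTRUE(p$tie)) len else 2 * len,
                     tag = "dup_inplace")
          }
        } else {
          addEntry(p$chrom, p$s0, p$s1, cn, d0, strand,
                   tag = p$kind)
        }
      }
      d0 <- d0 + plen
    }
  }
  destSeqs <- DNAStringSet(vapply(chroms, function(cn)
    paste(unlist(destParts[[cn]]), collapse = ""), character(1)))
  names(destSeqs) <- chroms
  destSizes <- setNames(Biostrings::width(destSeqs), chroms)
  fwdEntries <- do.call(rbind, entries)

  # reverse entries: the inverse map, with asymmetric redirections applied
  asymKey <- function(op) paste(op$chrom, op$s0, op$s1)
  asymOps <- Filter(function(op) op$kind == "asymmetric_backmap", script$ops)
  names(asymOps) <- vapply(asymOps, asymKey, character(1))
  revRows <- list()
  for (i in seq_len(nrow(fwdEntries))) {
    e <- fwdEntries[i, ]
    key <- paste(e$a_chrom, e$a0, e$a1)
    if (e$tag == "asymmetric_backmap" ||
        (key %in% names(asymOps) && e$tag %in% c("identity",
                                                 "asymmetric_backmap"))) {
      op <- asymOps[[key]]
      if (is.null(op$altChrom)) next  # dropped: REJECT_2
      revRows[[length(revRows) + 1L]] <- data.frame(
        a_chrom = e$b_chrom, a0 = e$b0, a1 = e$b0 + (e$a1 - e$a0),
        b_chrom = op$altChrom, b0 = op$altStart0, strand = "+",
        standalone = TRUE, score = NA_real_, tag = "asym_redirect",
        stringsAsFactors = FALSE)
    } else {
      revRows[[length(revRows) + 1L]] <- data.frame(
        a_chrom = e$b_chrom, a0 = e$b0, a1 = e$b0 + (e$a1 - e$a0),
        b_chrom = e$a_chrom, b0 = e$a0, strand = e$strand,
        standalone = e$standalone, score = e$score, tag = e$tag,
        stringsAsFactors = FALSE)
    }
  }
  revEntries <- do.call(rbind, revRows)

  fwd <- parseChainLines(entriesToChainLines(fwdEntries, lens, destSizes),
                         direction = "source->target")
  rev <- parseChainLines(entriesToChainLines(revEntries, destSizes, lens),
                         direction = "target->source")

  # truth labels on source coordinates
  truthAcc <- setNames(vector("list", length(CUP_CATEGORIES)), CUP_CATEGORIES)
  for (op in script$ops) {
    cat <- opTruthCategory(op)
    if (cat == "STABLE" || op$kind == "insert") next
    truthAcc[[cat]] <- c(truthAcc[[cat]],
                         list(granges0(op$chrom, op$s0, op$s1)))
  }
  truth <- lapply(truthAcc, function(l)
    if (is.null(l)) GRanges() else suppressWarnings(sort(reduce(do.call(c, l)))))
  genome <- granges0(chroms, rep(0, length(lens)), as.numeric(lens))
  nonStable <- suppressWarnings(
    reduce(do.call(c, unname(truth[CUP_CATEGORIES != "STABLE"]))))
  truth$STABLE <- sort(GenomicRanges::setdiff(genome, nonStable,
                                              ignore.strand = TRUE))
  structure(list(srcSeqs = srcSeqs, destSeqs = destSeqs, fwd = fwd,
                 rev = rev, truth = GRangesList(truth[CUP_CATEGORIES]),
                 chromSizes = lens, destSizes = destSizes, script = script),
            class = "synthetic_build_pair")
}

## Assemble map entries (a -> b, slope from strand) into chain-format lines.
## '+' entries that are compatible (a and b both advancing, not standalone)
## merge into multi-block chains with dt/dq gaps; everything else becomes a
## single-block chain. Score defaults to the sum of block sizes.
entriesToChainLines <- function(entries, aSizes, bSizes) {
  if (is.null(entries) || nrow(entries) == 0L) return(character())
  lines <- character()
  chainId <- 0L
  emit <- function(run) {
    chainId <<- chainId + 1L
    n <- nrow(run)
    sizes <- run$a1 - run$a0
    score <- if (n == 1L && !is.na(run$score[1])) run$score[1] else sum(sizes)
    aCh <- run$a_chrom[1]; bCh <- run$b_chrom[1]; strand <- run$strand[1]
    tStart <- run$a0[1]; tEnd <- run$a1[n]
    if (strand == "+") {
      qStart <- run$b0[1]; qEnd <- run$b0[n] + sizes[n]
    } else {
      stopifnot(n == 1L)
      qStart <- bSizes[[bCh]] - (run$b0[1] + sizes[1])
      qEnd <- bSizes[[bCh]] - run$b0[1]
    }
    hdr <- paste("chain", sprintf("%.0f", score), aCh,
                 sprintf("%.0f", aSizes[[aCh]]), "+",
                 sprintf("%.0f", tStart), sprintf("%.0f", tEnd), bCh,
                 sprintf("%.0f", bSizes[[bCh]]), strand,
                 sprintf("%.0f", qStart), sprintf("%.0f", qEnd), chainId)
    body <- if (n > 1L) {
      dt <- run$a0[-1] - run$a1[-n]
      dq <- run$b0[-1] - (run$b0[-n] + sizes[-n])
      c(paste(sprintf("%.0f", sizes[-n]), sprintf("%.0f", dt),
              sprintf("%.0f", dq)), sprintf("%.0f", sizes[n]))
    } else sprintf("%.0f", sizes)
    lines <<- c(lines, hdr, body, "")
  }
  mergeable <- entries$strand == "+" & !entries$standalone
  solo <- entries[!mergeable, , drop = FALSE]
  for (i in seq_len(nrow(solo))) emit(solo[i, ])
  m <- entries[mergeable, , drop = FALSE]
  if (nrow(m)) {
    m <- m[order(m$a_chrom, m$b_chrom, m$a0), ]
    grp <- paste(m$a_chrom, m$b_chrom)
    for (g in unique(grp)) {
      sub <- m[grp == g, , drop = FALSE]
      runStart <- 1L
      for (i in seq_len(nrow(sub))) {
        if (i == nrow(sub)) { emit(sub[runStart:i, ]); break }
        okNext <- sub$a0[i + 1] >= sub$a1[i] &&
          sub$b0[i + 1] >= sub$b0[i] + (sub$a1[i] - sub$a0[i])
        if (!okNext) { emit(sub[runStart:i, ]); runStart <- i + 1L }
      }
    }
  }
  lines
}

#' Build a rearrangement script from a plain list
#'
#' Deserializes the declarative script schema used by the command-line
#' `simulate` subcommand (e.g. parsed from YAML): a list with
#' `chrom_lengths` (named lengths), `seed`, and `ops`, each op a list with a
#' `kind` field (`delete`, `insert`, `invert`, `duplicate`, `translocate`,
#' `asymmetric_backmap`) and that kind's arguments (`chrom`, `start0`,
#' `end0`, `at0`, `length`, `tie`, `dest_chrom`, `alt_chrom`, `alt_start0`).
#'
#' @param x the list.
#' @return A [rearrangementScript()].
#' @export
scriptFromList <- function(x) {
  stopifnot(!is.null(x$chrom_lengths))
  ops <- lapply(x$ops, function(o) {
    switch(o$kind,
      delete = opDelete(o$chrom, o$start0, o$end0),
      insert = opInsert(o$chrom, o$at0, o$length),
      invert = opInvert(o$chrom, o$start0, o$end0),
      duplicate = opDuplicate(o$chrom, o$start0, o$end0,
                              tie = isTRUE(o$tie)),
      translocate = opTranslocate(o$chrom, o$start0, o$end0, o$dest_chrom),
      asymmetric_backmap = opAsymmetricBackmap(
        o$chrom, o$start0, o$end0,
        altChrom = o$alt_chrom,
        altStart0 = o$alt_start0),
      stop("unknown op kind '", o$kind, "'"))
  })
  rearrangementScript(unlist(x$chrom_lengths), ops,
                      seed = if (is.null(x$seed)) 1L else x$seed)
}

#' Generate a random rearrangement script
#'
#' Samples `nOps` operations of random kinds with non-overlapping source
#' intervals, guaranteeing (given enough room) that scripts exercise the
#' spectrum of categories. Deterministic per seed.
#'
#' @param chromLengths named source chromosome lengths; needs at least two
#'   chromosomes for translocations/cross-chromosome backmaps.
#' @param nOps number of operations to attempt.
#' @param seed integer seed.
#' @param kinds operation kinds to sample from.
#' @return A [rearrangementScript()].
#' @export
randomScript <- function(chromLengths, nOps = 6L, seed = 1L,
                         kinds = c("delete", "insert", "invert", "duplicate",
                                   "duplicate_tie", "translocate",
                                   "backmap_pos", "backmap_chr",
                                   "backmap_drop")) {
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(seed)
  chroms <- names(chromLengths)
  used <- lapply(chromLengths, function(...) cbind(s0 = numeric(),
                                                   s1 = numeric()))
  pickInterval <- function(cn, len) {
    L <- chromLengths[[cn]]
    for (i in 1:50) {
      s0 <- sample.int(L - len, 1L) - 1L
      s1 <- s0 + len
      u <- used[[cn]]
      if (!nrow(u) || all(s1 <= u[, "s0"] | s0 >= u[, "s1"])) {
        used[[cn]] <<- rbind(u, cbind(s0 = s0, s1 = s1))
        return(c(s0, s1))
      }
    }
    NULL
  }
  ops <- list()
  for (k in sample(rep_len(kinds, nOps))) {
    cn <- sample(chroms, 1L)
    len <- sample(20:200, 1L)
    iv <- pickInterval(cn, len)
    if (is.null(iv)) next
    other <- if (length(chroms) > 1L) sample(setdiff(chroms, cn), 1L) else cn
    op <- switch(k,
      delete = opDelete(cn, iv[1], iv[2]),
      insert = opInsert(cn, iv[1], len),
      invert = opInvert(cn, iv[1], iv[2]),
      duplicate = opDuplicate(cn, iv[1], iv[2], tie = FALSE),
      duplicate_tie = opDuplicate(cn, iv[1], iv[2], tie = TRUE),
      translocate = if (other != cn) opTranslocate(cn, iv[1], iv[2], other)
                    else NULL,
      backmap_pos = {
        alt <- pickInterval(cn, len)
        if (is.null(alt)) NULL
        else opAsymmetricBackmap(cn, iv[1], iv[2], cn, alt[1])
      },
      backmap_chr = if (other != cn && chromLengths[[other]] > len) {
        alt <- pickInterval(other, len)
        if (is.null(alt)) NULL
        else opAsymmetricBackmap(cn, iv[1], iv[2], other, alt[1])
      } else NULL,
      backmap_drop = opAsymmetricBackmap(cn, iv[1], iv[2]))
    if (!is.null(op)) ops[[length(ops) + 1L]] <- op
  }
  rearrangementScript(chromLengths, ops, seed = seed)
}

#' Simulate biallelic SNVs on a synthetic build
#'
#' Draws `n` distinct variant positions on the source build, with REF taken
#' from the source sequence, a random ALT among the other three bases, and
#' random diploid genotypes (a mix of phased and unphased heterozygotes and
#' homozygotes). With `stratify`, the requested number of variants is placed
#' inside each truth category's regions, guaranteeing category coverage; the
#' per-record intended category is recorded in the `"truth_category"`
#' attribute.
#'
#' @param pair a `"synthetic_build_pair"` from [realizeScript()].
#' @param n total number of variants (ignored when `stratify` is given).
#' @param seed integer seed.
#' @param stratify optional named vector of per-category counts (names from
#'   [cupCategories()]).
#' @return A VCF records data.frame (see [readVcfFile()]), sorted by
#'   position.
#' @export
simulateVariants <- function(pair, n = 100L, seed = 1L, stratify = NULL) {
  stopifnot(inherits(pair, "synthetic_build_pair"))
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(seed)

  samplePositions <- function(regions, k) {
    d <- bedFrame(regions)
    if (nrow(d) == 0L || sum(d$end0 - d$start0) < k)
      stop("not enough positions available to place ", k, " variants")
    all <- data.table(chrom = rep(d$chrom, d$end0 - d$start0),
                      pos0 = unlist(lapply(seq_len(nrow(d)), function(i)
                        seq(d$start0[i], d$end0[i] - 1))))
    all[sample(nrow(all), k)]
  }
  if (is.null(stratify)) {
    genome <- granges0(names(pair$chromSizes),
                       rep(0, length(pair$chromSizes)),
                       as.numeric(pair$chromSizes))
    picks <- samplePositions(genome, n)
    picks[, truth := NA_character_]
  } else {
    stopifnot(all(names(stratify) %in% CUP_CATEGORIES))
    picks <- rbindlist(lapply(names(stratify), function(cat) {
      if (stratify[[cat]] == 0L) return(NULL)
      p <- samplePositions(pair$truth[[cat]], stratify[[cat]])
      p[, truth := cat]
    }))
  }
  picks <- picks[order(chrom, pos0)]
  lookup <- makeBaseLookup(pair$srcSeqs)
  ref <- lookup(picks$chrom, picks$pos0)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  gt <- sample(c("0/1", "1/1", "0|1", "1|0"), nrow(picks), replace = TRUE)
  rec <- newVcfRecords(CHROM = picks$chrom, POS = picks$pos0 + 1,
                       REF = ref, ALT = unname(alt), GT = gt)
  attr(rec, "truth_category") <- picks$truth
  rec
}

#' Write a synthetic build pair to disk
#'
#' Emits FASTA for both builds, both chain files, chrom.sizes tables and
#' truth-label BED files — everything the scan/convert commands consume.
#'
#' @param pair a `"synthetic_build_pair"`.
#' @param dir output directory.
#' @return Invisibly, the named list of paths.
#' @export
writeBuildPair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    src_fasta = file.path(dir, "source.fa"),
    dest_fasta = file.path(dir, "target.fa"),
    fwd_chain = file.path(dir, "source_to_target.chain"),
    rev_chain = file.path(dir, "target_to_source.chain"),
    src_sizes = file.path(dir, "source.chrom.sizes"),
    dest_sizes = file.path(dir, "target.chrom.sizes"))
  Biostrings::writeXStringSet(pair$srcSeqs, p$src_fasta)
  Biostrings::writeXStringSet(pair$destSeqs, p$dest_fasta)
  writeChainFile(pair$fwd, p$fwd_chain)
  writeChainFile(pair$rev, p$rev_chain)
  writeChromSizes(pair$chromSizes, p$src_sizes)
  writeChromSizes(pair$destSizes, p$dest_sizes)
  for (cat in CUP_CATEGORIES) {
    bp <- file.path(dir, paste0("truth_", cat, ".bed"))
    writeBedFile(pair$truth[[cat]], bp, name = cat)
    p[[paste0("truth_", cat)]] <- bp
  }
  invisible(p)
}
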