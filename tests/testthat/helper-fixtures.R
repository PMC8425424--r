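# Shared fixtures: scripted build pairs with analytically known labels.

`%||%` <- function(a, b) if (is.null(a)) b else a

# one operation of every kind; exercises all six categories plus both
# duplicate resolutions
mixedScript <- function(seed = 7) {
  rearrangementScript(
    c(chrA = 5000L, chrB = 4000L),
    list(opDelete("chrA", 100, 150),
         opInvert("chrA", 300, 400),
         opInsert("chrA", 600, 50),
         opDuplicate("chrA", 1000, 1100),
         opDuplicate("chrB", 3000, 3080, tie = TRUE),
         opTranslocate("chrA", 2000, 2100, "chrB"),
         opAsymmetricBackmap("chrA", 3000, 3050, "chrA", 4000),
         opAsymmetricBackmap("chrA", 3500, 3550, "chrB", 100),
         opAsymmetricBackmap("chrB", 500, 560)),
    seed = seed)
}

identityScript <- function(lens = c(chrA = 1000L), seed = 1)
  rearrangementScript(lens, list(), seed = seed)

# a single-block minimal chain file, optionally tweaked
minimalChainLines <- function() {
  c("chain 100 chrA 1000 + 0 100 chrB 2000 + 50 150 1", "100", "")
}

# identity ChainSet over one chromosome
identityChain <- function(chrom = "chrA", len = 1000) {
  parseChainLines(c(sprintf("chain %d %s %d + 0 %d %s %d + 0 %d 1",
                            len, chrom, len, len, chrom, len, len),
                    as.character(len), ""))
}

regionsAsFrame <- function(x) lapply(x, function(g) {
  g <- sort(GenomicRanges::reduce(g))
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g))
})

expect_same_regions <- function(a, b) {
  expect_identical(regionsAsFrame(a), regionsAsFrame(b))
}

# integer-set oracle for interval algebra on small coordinates
asIntegerSet <- function(gr) {
  d <- as.data.frame(gr)
  unlist(lapply(seq_len(nrow(d)), function(i)
    paste0(d$seqnames[i], ":", seq(d$start[i], d$end[i]))))
}
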