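mkRecords <- function(CHROM, POS, REF, ALT, GT = "0/1") {
  cupScan:::newVcfRecords(CHROM = CHROM, POS = POS, REF = REF, ALT = ALT,
                          GT = rep_len(GT, length(POS)))
}

test_that("biallelic SNV extraction keeps SNVs and drops everything else", {
  rec <- mkRecords(rep("chrA", 5), 1:5,
                   REF = c("A", "A", "A", "AT", "A"),
                   ALT = c("G", "AT", "G,T", "A", "<DEL>"))
  out <- extractBiallelicSnvs(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$POS, 1L)
  expect_equal(attr(out, "n_removed"), 4L)

  # independent per-record predicate on a mixed synthetic VCF
  set.seed(21)
  n <- 100
  ref <- sample(c("A", "C", "G", "T", "AT", "N"), n, replace = TRUE)
  alt <- sample(c("A", "C", "G", "T", "TG", "G,T", "<INS>"), n,
                replace = TRUE)
  rec <- mkRecords(rep("chrA", n), seq_len(n), ref, alt)
  keep <- nchar(ref) == 1 & ref %in% c("A", "C", "G", "T") &
    nchar(alt) == 1 & alt %in% c("A", "C", "G", "T")
  expect_equal(nrow(extractBiallelicSnvs(rec)), sum(keep))
})

test_that("the two mismatch dialects reproduce their rules, including IUPAC", {
  # enumerated truth table: variant A>G against each possible target base
  cases <- data.frame(
    target = c("A", "G", "C", "R", "N"),
    reject_fails = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    update_fails = c(FALSE, TRUE, FALSE, TRUE, TRUE),
    update_ref = c("A", "G", "C", "A", "A"))
  pair <- realizeScript(identityScript(c(chrA = 100L)))
  for (i in seq_len(nrow(cases))) {
    lookup <- local({
      tb <- cases$target[i]
      function(chrom, pos0) rep(tb, length(pos0))
    })
    rec <- mkRecords("chrA", 11L, "A", "G")
    rej <- convertVariants(rec, pair$fwd, lookup, "reject_on_mismatch")
    expect_equal(nrow(rej$failed) == 1L, cases$reject_fails[i],
                 info = paste("reject, target", cases$target[i]))
    if (nrow(rej$failed)) expect_equal(rej$failed$category, "MISMATCH_1")
    upd <- convertVariants(rec, pair$fwd, lookup, "update_ref")
    expect_equal(nrow(upd$failed) == 1L, cases$update_fails[i],
                 info = paste("update, target", cases$target[i]))
    if (nrow(upd$converted))
      expect_equal(upd$converted$REF, cases$update_ref[i])
  }
})

test_that("alleles are reverse-complemented through '-'-strand chains", {
  pair <- realizeScript(rearrangementScript(
    c(chrA = 500L), list(opInvert("chrA", 100, 200)), seed = 2))
  lookup <- makeBaseLookup(pair$destSeqs)
  srcLookup <- makeBaseLookup(pair$srcSeqs)
  ref <- srcLookup("chrA", 150)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  rec <- mkRecords("chrA", 151L, ref, alt)
  out <- convertVariants(rec, pair$fwd, lookup, "reject_on_mismatch")
  expect_equal(nrow(out$failed), 0L)
  expect_equal(out$converted$strand, "-")
  expect_equal(out$converted$REF, cupScan:::complementBase(ref))
  expect_equal(out$converted$ALT, cupScan:::complementBase(alt))
  # and the full round trip through the inversion is STABLE
  rt <- roundtripClassifyVcf(rec, pair$fwd, pair$rev, srcLookup, lookup,
                             "reject_on_mismatch")
  expect_equal(as.character(rt$category), "STABLE")
})

test_that("round-trip VCF categories match the position classifier and truth", {
  pair <- realizeScript(mixedScript())
  strat <- c(STABLE = 40, REJECT_1 = 6, CHR_JUMP_1 = 6, REJECT_2 = 6,
             CHR_JUMP_2 = 6, POS_JUMP = 6)
  v <- simulateVariants(pair, seed = 31, stratify = strat)
  rt <- roundtripClassifyVcf(v, pair$fwd, pair$rev,
                             makeBaseLookup(pair$srcSeqs),
                             makeBaseLookup(pair$destSeqs), "update_ref")
  expect_equal(sum(rt$counts), nrow(v))
  truth <- attr(v, "truth_category")
  got <- as.character(rt$category)
  mism <- got %in% c("MISMATCH_1", "MISMATCH_2")
  # non-mismatch records agree exactly with the per-position classifier ...
  posCat <- as.character(classifyPositions(pair$fwd, pair$rev, v$CHROM,
                                           v$POS - 1))
  expect_equal(got[!mism], posCat[!mism])
  # ... and with the generator's intended labels
  expect_equal(got[!mism], truth[!mism])
  # mismatches only arise where the return locus differs from the origin
  expect_true(all(truth[mism] %in% c("CHR_JUMP_2", "POS_JUMP")))
})

test_that("an all-stable VCF survives the round trip byte-identically", {
  pair <- realizeScript(mixedScript())
  v <- simulateVariants(pair, seed = 17, stratify = c(STABLE = 30))
  for (dialect in c("reject_on_mismatch", "update_ref")) {
    rt <- roundtripClassifyVcf(v, pair$fwd, pair$rev,
                               makeBaseLookup(pair$srcSeqs),
                               makeBaseLookup(pair$destSeqs), dialect)
    expect_true(all(rt$category == "STABLE"))
    back <- roundtripClassifyVcf(rt$converted, pair$rev, pair$fwd,
                                 makeBaseLookup(pair$destSeqs),
                                 makeBaseLookup(pair$srcSeqs), dialect)
    expect_equal(back$converted$POS, v$POS)
    expect_equal(back$converted$REF, v$REF)
    expect_equal(back$converted$ALT, v$ALT)
  }
})

test_that("pre-excluding variants at CUPs equals scan-then-remove exactly", {
  pair <- realizeScript(mixedScript())
  strat <- c(STABLE = 40, REJECT_1 = 5, CHR_JUMP_1 = 5, REJECT_2 = 5,
             CHR_JUMP_2 = 5, POS_JUMP = 5)
  v <- simulateVariants(pair, seed = 41, stratify = strat)
  scan <- scanGenome(pair$fwd, pair$rev, pair$chromSizes)
  srcL <- makeBaseLookup(pair$srcSeqs); tgtL <- makeBaseLookup(pair$destSeqs)

  filt <- filterAtCups(v, novelCupRegions(scan))
  expect_equal(nrow(filt$kept) + nrow(filt$excluded), nrow(v))
  rtF <- roundtripClassifyVcf(filt$kept, pair$fwd, pair$rev, srcL, tgtL,
                              "reject_on_mismatch")
  rtO <- roundtripClassifyVcf(v, pair$fwd, pair$rev, srcL, tgtL,
                              "reject_on_mismatch")
  expect_equal(sum(rtF$counts[novelCupCategories()]), 0)
  keyF <- with(rtF$perCategory$STABLE, paste(CHROM, POS, REF, ALT))
  keyO <- with(rtO$perCategory$STABLE, paste(CHROM, POS, REF, ALT))
  expect_identical(keyF, keyO)
})

test_that("filterAtCups trivial cases behave", {
  v <- mkRecords(rep("chrA", 3), c(5L, 10L, 15L), "A", "G")
  none <- filterAtCups(v, GenomicRanges::GRanges())
  expect_equal(nrow(none$kept), 3L)
  all <- filterAtCups(v, GenomicRanges::GRanges("chrA",
                                                IRanges::IRanges(1, 100)))
  expect_equal(nrow(all$excluded), 3L)
})

test_that("discordance counts positions then genotypes among matches", {
  a <- mkRecords(rep("chrA", 10), seq(10, 100, 10), "A", "G",
                 GT = c("0/1", "0/1", "1/1", "0/1", "0/1", "0/1", "0/1",
                        "0/1", "0/1", "0/1"))
  expect_equal(discordance(a, a)$position_discordance, 0)
  expect_equal(discordance(a, a)$genotype_discordance, 0)

  b <- a
  b$POS <- b$POS + 1000L   # all positions miss
  d <- discordance(a, b)
  expect_equal(d$position_discordance, 1)
  expect_true(is.na(d$genotype_discordance))

  # 2 position misses, 1 genotype flip among the 8 matches
  b <- a
  b$POS[1:2] <- b$POS[1:2] + 500L
  b$GT[3] <- "0/1"
  d <- discordance(a, b)
  expect_equal(d$position_discordance, 0.2)
  expect_equal(d$genotype_discordance, 0.125)

  # unphased comparison: 0/1 matches 1|0
  c1 <- mkRecords("chrA", 5L, "A", "G", GT = "0/1")
  c2 <- mkRecords("chrA", 5L, "A", "G", GT = "1|0")
  expect_equal(discordance(c1, c2)$genotype_discordance, 0)

  expect_true(is.na(discordance(a[0, ], a)$position_discordance))
})

test_that("VCF files round-trip through write and vcfR-backed read", {
  pair <- realizeScript(mixedScript())
  v <- simulateVariants(pair, n = 25, seed = 5)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVcfFile(v, f)
  back <- readVcfFile(f)
  expect_equal(back$CHROM, v$CHROM)
  expect_equal(back$POS, v$POS)
  expect_equal(back$REF, v$REF)
  expect_equal(back$ALT, v$ALT)
  expect_equal(back$GT, v$GT)
  expect_equal(attr(back, "sample"), "SAMPLE")
})
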