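test_that("identity chains in both directions give STABLE everywhere", {
  pair <- realizeScript(identityScript(c(chrA = 1000L)))
  expect_equal(as.character(classifyPositions(pair$fwd, pair$rev, "chrA",
                                              c(0, 1, 500, 999))),
               rep("STABLE", 4))
  s <- scanGenome(pair$fwd, pair$rev, pair$chromSizes)
  expect_equal(scanSummary(s)$pct[scanSummary(s)$category == "STABLE"], 100)
})

test_that("a deletion turns into exactly its span of REJECT_1", {
  pair <- realizeScript(rearrangementScript(
    c(chrA = 2000L), list(opDelete("chrA", 100, 150)), seed = 3))
  s <- scanGenome(pair$fwd, pair$rev, pair$chromSizes)
  sm <- scanSummary(s)
  expect_equal(sm$bp[sm$category == "REJECT_1"], 50)
  expect_equal(sm$bp[sm$category == "STABLE"], 1950)
  expect_equal(sum(sm$bp), 2000)
  r1 <- as.data.frame(cupRegions(s, "REJECT_1"))
  expect_equal(r1$start, 101)  # 1-based closed view of [100,150)
  expect_equal(r1$end, 150)
})

test_that("an asymmetric back-mapping produces POS_JUMP with the traced round trip", {
  # forward maps [100,200) in place; reverse sends the image to [300,400)
  pair <- realizeScript(rearrangementScript(
    c(chrA = 1000L),
    list(opAsymmetricBackmap("chrA", 100, 200, "chrA", 300)), seed = 5))
  expect_equal(as.character(classifyPositions(pair$fwd, pair$rev,
                                              "chrA", 150)), "POS_JUMP")
  fwdHit <- liftPositions(pair$fwd, "chrA", 150)
  expect_equal(fwdHit$dest_pos, 150)
  back <- liftPositions(pair$rev, fwdHit$dest_chrom, fwdHit$dest_pos)
  expect_equal(back$dest_pos, 350)  # round trip lands 200 bp downstream
})

test_that("category regions partition the genome and match the truth labels", {
  pair <- realizeScript(mixedScript())
  s <- scanGenome(pair$fwd, pair$rev, pair$chromSizes, mode = "interval")
  sm <- scanSummary(s)
  expect_equal(sum(sm$bp), sum(pair$chromSizes))
  # pairwise disjoint
  all <- unlist(cupRegions(s), use.names = FALSE)
  expect_equal(sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(all)))),
               sum(sm$bp))
  expect_same_regions(as.list(cupRegions(s)), as.list(pair$truth))
})

test_that("interval mode equals the per-base oracle on scripted and random builds", {
  fixtures <- list(
    identityScript(c(chrA = 800L)),
    mixedScript(),
    randomScript(c(chrA = 3000L, chrB = 2500L), nOps = 8L, seed = 101),
    randomScript(c(chrA = 3000L, chrB = 2500L), nOps = 8L, seed = 102))
  for (sc in fixtures) {
    pair <- realizeScript(sc)
    si <- scanGenome(pair$fwd, pair$rev, pair$chromSizes, mode = "interval")
    sp <- scanGenome(pair$fwd, pair$rev, pair$chromSizes, mode = "per_base")
    expect_same_regions(as.list(cupRegions(si)), as.list(cupRegions(sp)))
  }
})

test_that("a chromosome absent from the chains is wholly REJECT_1", {
  pair <- realizeScript(identityScript(c(chrA = 500L)))
  sizes <- c(chrA = 500L, chrM = 100L)
  s <- scanGenome(pair$fwd, pair$rev, sizes)
  sm <- scanSummary(s)
  expect_equal(sm$bp[sm$category == "REJECT_1"], 100)
  expect_equal(sm$bp[sm$category == "STABLE"], 500)
})

test_that("re-scanning the stable set finds no new CUPs (idempotence)", {
  pair <- realizeScript(mixedScript())
  s <- scanGenome(pair$fwd, pair$rev, pair$chromSizes)
  counts <- classifyRegionsPerBase(pair$fwd, pair$rev, stableRegions(s))
  expect_equal(sum(counts[names(counts) != "STABLE"]), 0)
  expect_equal(counts[["STABLE"]], sum(GenomicRanges::width(stableRegions(s))))
})

test_that("stable source bases land on bases stable in the opposite scan", {
  # symmetric script: chains are exact mutual inverses
  sc <- rearrangementScript(
    c(chrA = 2000L, chrB = 1500L),
    list(opDelete("chrA", 100, 150), opInvert("chrA", 300, 400),
         opInsert("chrB", 700, 30), opDuplicate("chrA", 900, 950),
         opTranslocate("chrA", 1200, 1300, "chrB")), seed = 9)
  pair <- realizeScript(sc)
  fwdScan <- scanGenome(pair$fwd, pair$rev, pair$chromSizes)
  revScan <- scanGenome(pair$rev, pair$fwd, pair$destSizes)
  sm <- scanSummary(fwdScan)
  expect_equal(sm$bp[sm$category %in% c("POS_JUMP", "CHR_JUMP_2")],
               c(0, 0))
  d <- as.data.frame(stableRegions(fwdScan))
  set.seed(1)
  idx <- sample(nrow(d), 40, replace = TRUE)
  pos <- mapply(function(a, b) sample(seq(a, b), 1), d$start[idx], d$end[idx]) - 1
  cn <- as.character(d$seqnames[idx])
  img <- liftPositions(pair$fwd, cn, pos)
  expect_true(all(img$status == "mapped"))
  hitStable <- IRanges::overlapsAny(
    GenomicRanges::GRanges(img$dest_chrom,
                           IRanges::IRanges(img$dest_pos + 1, img$dest_pos + 1)),
    stableRegions(revScan))
  expect_true(all(hitStable))
})

test_that("mergeRegions collapses bookended runs and conserves bp", {
  m <- mergeRegions(data.frame(chrom = "c", start0 = c(5, 6, 7),
                               end0 = c(6, 7, 8)))
  expect_equal(as.data.frame(m)$start, 6)
  expect_equal(as.data.frame(m)$end, 8)   # [5,8) in 0-based terms
  m2 <- mergeRegions(data.frame(chrom = "c", start0 = c(5, 7), end0 = c(6, 8)))
  expect_equal(length(m2), 2L)
  set.seed(4)
  p <- sample.int(1e5, 1e4)
  m3 <- mergeRegions(data.frame(chrom = "c", start0 = p, end0 = p + 1))
  expect_equal(sum(GenomicRanges::width(m3)), length(unique(p)))
})

test_that("scan results write sorted BEDs and a summary table", {
  pair <- realizeScript(mixedScript())
  s <- scanGenome(pair$fwd, pair$rev, pair$chromSizes)
  d <- withr::local_tempdir()
  writeScanResult(s, d)
  expect_true(all(file.exists(file.path(d, paste0(cupCategories(), ".bed")))))
  back <- readBedFile(file.path(d, "REJECT_1.bed"))
  expect_same_regions(list(back), list(cupRegions(s, "REJECT_1")))
  sm <- read.delim(file.path(d, "summary.tsv"))
  expect_equal(sum(sm$bp), sum(pair$chromSizes))
})
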