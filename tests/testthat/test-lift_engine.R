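test_that("identity chain maps positions to themselves", {
  cs <- identityChain("chrA", 1000)
  r <- liftPositions(cs, "chrA", c(0, 42, 999))
  expect_equal(r$status, rep("mapped", 3))
  expect_equal(r$dest_pos, c(0, 42, 999))
  expect_equal(r$dest_chrom, rep("chrA", 3))
  expect_equal(r$dest_strand, rep("+", 3))
})

test_that("gap, no-chain and unknown-chromosome failures are distinguished", {
  # two blocks with a 20 bp source gap between them
  cs <- parseChainLines(c("chain 80 chrA 1000 + 0 100 chrB 2000 + 0 80 1",
                          "40 20 0", "40", ""))
  r <- liftPositions(cs, "chrA", c(10, 45, 70, 500))
  expect_equal(r$status, c("mapped", "unmapped", "mapped", "unmapped"))
  expect_equal(r$reason[2], "gap")
  expect_equal(r$reason[4], "no_chain")
  expect_equal(r$dest_pos[c(1, 3)], c(10, 50))  # second block shifts by -20
  expect_message(r2 <- liftPositions(cs, "chrZ", 5), "chrZ")
  expect_equal(r2$status, "unmapped")
})

test_that("reverse-strand chains report forward-strand coordinates", {
  # source [0,100) aligned to the reversed first 100 bases of a 1000 bp dest
  cs <- parseChainLines(c("chain 100 chrA 1000 + 0 100 chrB 1000 - 0 100 1",
                          "100", ""))
  r <- liftPositions(cs, "chrA", 10)
  expect_equal(r$status, "mapped")
  expect_equal(r$dest_pos, 989)
  expect_equal(r$dest_strand, "-")
})

test_that("lifts are deterministic and block-locally linear", {
  pair <- realizeScript(mixedScript())
  pos <- seq(0, 4999, by = 7)
  r1 <- liftPositions(pair$fwd, "chrA", pos)
  r2 <- liftPositions(pair$fwd, "chrA", pos)
  expect_identical(r1, r2)
  # within a block, lift(pos+1) - lift(pos) == slope of the chain strand
  r <- liftPositions(pair$fwd, "chrA", 300:399)  # inverted interval, '-'
  expect_true(all(r$status == "mapped" & r$dest_strand == "-"))
  expect_true(all(diff(r$dest_pos) == -1))
  r <- liftPositions(pair$fwd, "chrA", 4000:4099) # untouched tail, '+'
  expect_true(all(r$status == "mapped" & r$dest_strand == "+"))
  expect_true(all(diff(r$dest_pos) == 1))
})

test_that("conflicting equal-score chains are ambiguous; higher score wins", {
  tie <- parseChainLines(c(
    "chain 50 chrA 1000 + 0 50 chrB 2000 + 0 50 1", "50", "",
    "chain 50 chrA 1000 + 0 50 chrB 2000 + 500 550 2", "50", ""))
  r <- liftPositions(tie, "chrA", 10)
  expect_equal(r$status, "ambiguous")
  expect_equal(r$reason, "ambiguous")

  scored <- parseChainLines(c(
    "chain 99 chrA 1000 + 0 50 chrB 2000 + 0 50 1", "50", "",
    "chain 100 chrA 1000 + 0 50 chrB 2000 + 500 550 2", "50", ""))
  r <- liftPositions(scored, "chrA", 10)
  expect_equal(r$status, "mapped")
  expect_equal(r$dest_pos, 510)

  # equal scores but agreeing destinations are not ambiguous
  agree <- parseChainLines(c(
    "chain 50 chrA 1000 + 0 50 chrB 2000 + 0 50 1", "50", "",
    "chain 50 chrA 1000 + 0 50 chrB 2000 + 0 50 2", "50", ""))
  r <- liftPositions(agree, "chrA", 10)
  expect_equal(r$status, "mapped")
})

test_that("liftBedRecords partitions input and matches per-position lifts", {
  pair <- realizeScript(mixedScript())
  set.seed(11)
  bed <- data.frame(chrom = sample(c("chrA", "chrB"), 100, replace = TRUE),
                    start0 = NA, end0 = NA, name = paste0("v", 1:100))
  bed$start0 <- ifelse(bed$chrom == "chrA",
                       sample.int(5000, 100, replace = TRUE),
                       sample.int(4000, 100, replace = TRUE)) - 1L
  bed$end0 <- bed$start0 + 1L
  out <- liftBedRecords(pair$fwd, bed)
  expect_equal(nrow(out$mapped) + nrow(out$rejected), 100L)
  per <- liftPositions(pair$fwd, bed$chrom, bed$start0)
  expect_setequal(out$mapped$name, bed$name[per$status == "mapped"])
  expect_equal(sort(out$mapped$start0),
               sort(per$dest_pos[per$status == "mapped"]))
  expect_error(liftBedRecords(pair$fwd,
                              data.frame(chrom = "chrA", start0 = 0,
                                         end0 = 5, name = "bad")),
               "end0 == start0 \\+ 1")
})

test_that("lift engine agrees with rtracklayer's liftOver on synthetic chains", {
  skip_if_not_installed("rtracklayer")
  pair <- realizeScript(mixedScript())
  f <- withr::local_tempfile(fileext = ".chain")
  writeChainFile(pair$fwd, f)
  ch <- rtracklayer::import.chain(f)
  for (cn in c("chrA", "chrB")) {
    len <- pair$chromSizes[[cn]]
    pos <- seq(0, len - 1, by = 13)
    mine <- liftPositions(pair$fwd, cn, pos)
    lo <- rtracklayer::liftOver(
      GenomicRanges::GRanges(cn, IRanges::IRanges(pos + 1, pos + 1)), ch)
    n <- S4Vectors::elementNROWS(lo)
    # multi-hits only at the duplications, where the score policy picks one
    expect_identical(n == 0, mine$status == "unmapped")
    single <- which(n == 1 & mine$status == "mapped")
    hit <- unlist(lo[single])
    expect_identical(as.character(GenomeInfoDb::seqnames(hit)),
                     mine$dest_chrom[single])
    expect_identical(GenomicRanges::start(hit) - 1L,
                     as.integer(mine$dest_pos[single]))
  }
  # reverse-strand parity on the dedicated toy chain
  lines <- c("chain 100 chrA 1000 + 0 100 chrB 1000 - 0 100 1", "100", "")
  f2 <- withr::local_tempfile(fileext = ".chain")
  writeLines(lines, f2)
  ch2 <- rtracklayer::import.chain(f2)
  mine <- liftPositions(parseChainLines(lines), "chrA", 0:99)
  lo <- unlist(rtracklayer::liftOver(
    GenomicRanges::GRanges("chrA", IRanges::IRanges(1:100, 1:100)), ch2))
  expect_identical(GenomicRanges::start(lo) - 1L, as.integer(mine$dest_pos))
})
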