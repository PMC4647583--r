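# Spliced-leader prefix matching, trimming, exact placement and TSS
# clustering.

slBody <- function(n = 77) strrep("A", n)

test_that("the SL prefix accepts the degenerate first base T/A/G and rejects C", {
  core <- substring(slConsensus(), 2)
  for (b in c("T", "A", "G")) {
    r <- matchSLPrefix(paste0(b, core, slBody()))
    expect_true(r$match)
    expect_equal(r$sl_first_base, b)
  }
  expect_false(matchSLPrefix(paste0("C", core, slBody()))$match)
  # non-degenerate mismatch consumes the budget; degenerate never does
  mism <- paste0("T", sub("CCGT", "CCGA", core), slBody())
  expect_false(matchSLPrefix(mism, maxMismatch = 0L)$match)
  expect_true(matchSLPrefix(mism, maxMismatch = 1L)$match)
  # reads shorter than the consensus never match
  expect_false(matchSLPrefix("ACGTACGTAC")$match)
})

test_that("trimming removes exactly the 22-nt leader: 99-nt reads become 77-nt", {
  read99 <- paste0("T", substring(slConsensus(), 2), slBody(77))
  expect_equal(nchar(read99), 99L)
  tr <- trimSLReads(c(r1 = read99))
  expect_equal(width(tr$trimmed), 77L)
  expect_equal(unname(tr$slFirstBase), "T")

  # a read equal to the consensus leaves an empty residual: discarded, flagged
  bare <- paste0("A", substring(slConsensus(), 2))
  tr2 <- trimSLReads(c(r1 = bare))
  expect_equal(length(tr2$trimmed), 0L)
  expect_equal(tr2$counts$empty_discarded, 1L)
})

test_that("residuals are exact suffixes of their reads (slicing oracle)", {
  set.seed(42)
  for (rep in 1:25) {
    body <- paste(sample(c("A", "C", "G", "T"), sample(30:90, 1),
                         replace = TRUE), collapse = "")
    fb <- sample(c("T", "A", "G"), 1)
    read <- paste0(fb, substring(slConsensus(), 2), body)
    tr <- trimSLReads(setNames(read, "r"))
    expect_identical(as.character(tr$trimmed[["r"]]),
                     substring(read, 23L))
  }
})

test_that("trimmed + untrimmed + too-short read counts conserve the input", {
  set.seed(7)
  n <- 2000
  mk <- function(i) {
    kind <- sample(c("sl", "plain", "short"), 1)
    if (kind == "sl")
      paste0(sample(c("T", "A", "G"), 1), substring(slConsensus(), 2),
             paste(sample(c("A", "C", "G", "T"), 77, TRUE), collapse = ""))
    else if (kind == "plain")
      paste(sample(c("A", "C", "G", "T"), 99, TRUE), collapse = "")
    else
      paste(sample(c("A", "C", "G", "T"), sample(5:21, 1), TRUE),
            collapse = "")
  }
  reads <- vapply(seq_len(n), mk, "")
  tr <- trimSLReads(reads)
  expect_equal(tr$counts$trimmed + tr$counts$untrimmed +
                 tr$counts$too_short, n)
  expect_equal(tr$counts$input, n)
})

test_that("exact placement finds planted reads on both strands with unique flags", {
  set.seed(19)
  scaffold <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  scaff <- DNAStringSet(setNames(scaffold, "sc1"))

  # planted forward read at 101..177 (the 0-based 100:177 slice)
  fwd <- substring(scaffold, 101, 177)
  mp <- mapReadsExact(c(rf = fwd), scaff)
  expect_equal(mp$placements$start, 101L)
  expect_equal(mp$placements$strand, "+")
  expect_true(mp$placements$unique)

  # reverse-complemented planted read: strand -, leftmost coordinate kept
  rc <- as.character(reverseComplement(DNAString(substring(scaffold, 501, 560))))
  mp2 <- mapReadsExact(c(rr = rc), scaff)
  expect_equal(mp2$placements$strand, "-")
  expect_equal(mp2$placements$start, 501L)

  # duplicated locus -> two placements, unique = FALSE
  dupScaffold <- paste0(scaffold, substring(scaffold, 101, 177))
  mp3 <- mapReadsExact(c(rf = fwd), DNAStringSet(setNames(dupScaffold, "sc1")))
  expect_equal(nrow(mp3$placements), 2L)
  expect_true(all(!mp3$placements$unique))

  # absent read counted unmapped
  mp4 <- mapReadsExact(c(rx = strrep("ACGT", 20)), scaff)
  expect_equal(mp4$unmapped, "rx")
})

test_that("TSS clustering recovers planted sites and matches a brute-force oracle", {
  sim <- simulateSLReadSet(c(800, 1300), readsPerTSS = 5, seed = 11)
  tr <- trimSLReads(sim$reads)
  mp <- mapReadsExact(tr$trimmed, sim$scaffold)
  det <- detectTransSpliceSites(mp$placements, sim$geneModel,
                                clusterGap = 50L, minSupport = 2L)
  expect_equal(det$transcripts$transcript_count, 2L)
  expect_setequal(det$clusters$representative_position, c(800L, 1300L))

  # all reads at one position -> one cluster
  sim1 <- simulateSLReadSet(600, readsPerTSS = 6, seed = 3)
  tr1 <- trimSLReads(sim1$reads)
  mp1 <- mapReadsExact(tr1$trimmed, sim1$scaffold)
  det1 <- detectTransSpliceSites(mp1$placements, sim1$geneModel)
  expect_equal(det1$transcripts$transcript_count, 1L)

  # single-linkage clustering equals the all-pairs union-find oracle
  set.seed(88)
  for (rep in 1:20) {
    pos <- sample(1:2000, sample(3:40, 1), replace = TRUE)
    gap <- sample(c(5L, 25L, 100L), 1)
    got <- dinoPKS:::.clusterPositions(pos, gap)
    want <- naiveSingleLinkage(pos, gap)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("support and gap parameters act monotonically", {
  sim <- simulateSLReadSet(c(500, 560, 1500), readsPerTSS = c(2, 3, 4),
                           seed = 23)
  tr <- trimSLReads(sim$reads)
  mp <- mapReadsExact(tr$trimmed, sim$scaffold)
  countsAt <- function(minSupport, gap)
    detectTransSpliceSites(mp$placements, sim$geneModel,
                           clusterGap = gap,
                           minSupport = minSupport)$transcripts$transcript_count
  # raising min_support never increases the transcript count
  prev <- Inf
  for (ms in 1:5) {
    cur <- countsAt(ms, 50L)
    expect_lte(cur, prev)
    prev <- cur
  }
  # raising cluster_gap never increases the cluster count (support 1)
  prev <- Inf
  for (gap in c(10L, 50L, 100L, 1000L)) {
    cur <- countsAt(1L, gap)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("multi-mapping and antisense placements are excluded from clustering", {
  sim <- simulateSLReadSet(700, readsPerTSS = 4, seed = 5)
  tr <- trimSLReads(sim$reads)
  mp <- mapReadsExact(tr$trimmed, sim$scaffold)
  pl <- mp$placements
  pl$unique <- FALSE
  det <- detectTransSpliceSites(pl, sim$geneModel)
  expect_equal(det$transcripts$transcript_count, 0L)
  pl2 <- mp$placements
  pl2$strand <- "-"
  det2 <- detectTransSpliceSites(pl2, sim$geneModel)
  expect_equal(det2$transcripts$transcript_count, 0L)
})

test_that("gene models read from BED convert to 1-based inclusive coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines("sc1\t99\t200\tgeneA\t0\t+", bed)
  gm <- readGeneModels(bed, format = "bed")
  expect_equal(gm$start, 100L)
  expect_equal(gm$end, 200L)
  expect_equal(gm$gene_id, "geneA")
})
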