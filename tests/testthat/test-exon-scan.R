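test_that("a single planted AG..CAC interval is found with exact bounds", {
  s <- paste0("AG", strrep("A", 300L), "CAC")
  iv <- enumerateMotifIntervals(s)
  fwd <- iv[iv$strand == "+", ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$start, 2L)
  expect_identical(fwd$end, 302L)

  ## below the length window: nothing
  short <- paste0("AG", strrep("A", 10L), "CAC")
  expect_identical(nrow(enumerateMotifIntervals(short)), 0L)
})

test_that("enumeration matches the quadratic brute-force oracle", {
  set.seed(31)
  for (rep in 1:4) {
    s <- randomDNA(5000L)
    got <- enumerateMotifIntervals(s)
    want <- bruteForceIntervals(s)
    expect_identical(intervalKey(got), intervalKey(want))
  }
})

test_that("translation anchors the frame at the RSS end and filters stops", {
  ## 300 bp, no in-frame stop: frame_trim 0, 100 residues
  aa100 <- strrep("GCT", 100L)  # Ala x 100
  iv <- data.frame(start = 0L, end = 300L, strand = "+")
  tr <- translateCandidates(iv, aa100)
  expect_identical(tr$frame_trim, 0L)
  expect_identical(nchar(tr$aa), 100L)

  ## 301 bp: one base trimmed at the 5' end
  s301 <- paste0("T", aa100)
  tr301 <- translateCandidates(data.frame(start = 0L, end = 301L, strand = "+"), s301)
  expect_identical(tr301$frame_trim, 1L)
  expect_identical(tr301$aa, strrep("A", 100L))

  ## in-frame stop codon: candidate discarded
  withStop <- paste0(strrep("GCT", 50L), "TAA", strrep("GCT", 49L))
  expect_identical(
    nrow(translateCandidates(data.frame(start = 0L, end = 300L, strand = "+"), withStop)),
    0L)

  ## ambiguity code: discarded
  withN <- paste0(strrep("GCT", 50L), "NCT", strrep("GCT", 49L))
  expect_identical(
    nrow(translateCandidates(data.frame(start = 0L, end = 300L, strand = "+"), withN)),
    0L)
})

test_that("minus-strand candidates report forward coordinates and oriented sequence", {
  inner <- strrep("GCT", 100L)
  plus <- paste0(strrep("T", 20L), "AG", inner, "CACAGTG", strrep("T", 20L))
  minus <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus)))
  grP <- scanSequence(plus, "c")
  grM <- scanSequence(minus, "c")
  ## mirror image: same number of candidates, strands flipped
  expect_identical(length(grP), length(grM))
  expect_identical(sort(as.vector(table(GenomicRanges::strand(grP))[c("+", "-")])),
                   sort(as.vector(table(GenomicRanges::strand(grM))[c("+", "-")])))
  ## the planted exon appears on - in the flipped contig with the same translation
  aaP <- S4Vectors::mcols(grP)$aa
  aaM <- S4Vectors::mcols(grM)$aa
  expect_true(strrep("A", 100L) %in% aaP)
  expect_true(strrep("A", 100L) %in% aaM)
})

test_that("overlap grouping equals the union-find oracle and respects half-open bounds", {
  ## touching intervals do not overlap
  gr <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1L, 301L), c(300L, 600L)), "+")
  gid <- S4Vectors::mcols(groupOverlaps(gr))$group_id
  expect_false(gid[1L] == gid[2L])

  ## chained overlap joins transitively
  gr2 <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1L, 101L), c(300L, 400L)), "+")
  gid2 <- S4Vectors::mcols(groupOverlaps(gr2))$group_id
  expect_identical(gid2[1L], gid2[2L])

  ## 200 random intervals vs brute-force transitive closure
  set.seed(13)
  st <- sample.int(5000L, 200L)
  en <- st + sample(50:400, 200L, replace = TRUE)
  grR <- GenomicRanges::GRanges("c", IRanges::IRanges(st, en), "+")
  gidR <- S4Vectors::mcols(groupOverlaps(grR))$group_id
  ## union-find oracle
  parent <- seq_len(200L)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in 1:199) for (b in (a + 1):200) {
    if (st[a] <= en[b] && st[b] <= en[a]) {       # closed-interval overlap
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(1:200, find, integer(1))
  ## same partition: group ids agree up to relabeling
  expect_identical(as.vector(table(table(roots))), as.vector(table(table(gidR))))
  expect_true(all(tapply(roots, gidR, function(x) length(unique(x))) == 1L))
})

test_that("overlap resolution keeps the arg-max candidate and applies tie-breaks", {
  gr <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1L, 50L, 100L), c(300L, 350L, 400L)),
                               "+", aa = c("a", "b", "c"))
  gr <- groupOverlaps(gr)
  ps <- makeProfileSet(matrix(0, 3L, 0L))
  ps@assigned <- rep("IGHV", 3L)
  ps@accepted <- rep(TRUE, 3L)
  ps@combined[, "IGHV"] <- c(0.4, 0.9, 0.7)
  ps@mrScore <- rep(0, 3L)
  res <- resolveOverlaps(gr, ps)
  expect_length(res, 1L)
  expect_identical(S4Vectors::mcols(res)$aa, "b")
  expect_equal(S4Vectors::mcols(res)$score, 0.9)

  ## tie at maximal score: smaller start wins, then longer interval
  ps@combined[, "IGHV"] <- c(0.9, 0.9, 0.7)
  res2 <- resolveOverlaps(gr, ps)
  expect_identical(S4Vectors::mcols(res2)$aa, "a")

  ## rejected best candidate: the whole group yields nothing
  ps@combined[, "IGHV"] <- c(0.4, 0.9, 0.7)
  ps@accepted <- c(TRUE, FALSE, TRUE)
  expect_length(resolveOverlaps(gr, ps), 0L)

  ## singleton group passing thresholds survives
  g1 <- groupOverlaps(GenomicRanges::GRanges("c", IRanges::IRanges(1L, 300L), "+", aa = "z"))
  p1 <- makeProfileSet(matrix(0, 1L, 0L))
  p1@assigned <- "TRBV"; p1@accepted <- TRUE
  p1@combined[, "TRBV"] <- 0.8; p1@mrScore <- 0
  expect_length(resolveOverlaps(g1, p1), 1L)
})

test_that("chunked genome scan equals the unchunked scan", {
  set.seed(47)
  s <- randomDNA(30000L)
  dna <- Biostrings::DNAStringSet(s)
  names(dna) <- "c1"
  cfg <- vexConfig(chunkSize = 5000L, overlap = 1000L, seed = 1L)
  chunked <- scanGenome(dna, cfg)
  whole <- groupOverlaps(scanSequence(s, "c1", cfg))
  expect_identical(candidateKey(chunked), candidateKey(whole))
  ## grouping identical too
  expect_identical(
    as.vector(table(table(S4Vectors::mcols(chunked)$group_id))),
    as.vector(table(table(S4Vectors::mcols(whole)$group_id))))
})
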