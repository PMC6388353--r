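## Shared fixtures, built once per test run and cached.  Everything is
## generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixConfig <- function() vexConfig(seed = 11L)

fixProfiles <- function() {
  if (is.null(.fixtures$profiles)) {
    .fixtures$profiles <- makeLocusProfiles(seed = 11L)
  }
  .fixtures$profiles
}

## Tier-0 training families, 12 sequences per locus.
fixTraining <- function() {
  if (is.null(.fixtures$training)) {
    prof <- fixProfiles()
    .fixtures$training <- list(
      aa = unlist(lapply(names(prof), function(k) {
        sampleFamily(prof[[k]], 12L, tier = 0L, seed = 101L)
      })),
      locus = rep(names(prof), each = 12L))
  }
  .fixtures$training
}

## Trained model set over the fixture training families.
fixModels <- function() {
  if (is.null(.fixtures$models)) {
    tr <- fixTraining()
    mats <- buildTrainingMatrices(tr$aa, tr$locus, fixConfig())
    .fixtures$models <- trainLocusModels(mats, fixConfig())
  }
  .fixtures$models
}

## Small planted benchmark shared by pipeline-level tests.
fixBenchmark <- function() {
  if (is.null(.fixtures$benchmark)) {
    .fixtures$benchmark <- buildBenchmark(
      fixProfiles(), exonCounts = c("0" = 2L), nDecoys = 12L,
      nContigs = 4L, contigLength = 12000L, seed = 42L)
  }
  .fixtures$benchmark
}

randomAA <- function(n, len = 100L) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, character(1))
}

randomDNA <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## Independent quadratic oracle for the motif scan: regex with lookahead on
## one strand (finds overlapping occurrences), explicit double loop over all
## AG x CAC pairs, repeated on the reverse complement and mapped back.
bruteForceIntervals <- function(seq, lenMin = 275L, lenMax = 330L) {
  one <- function(s) {
    ag <- as.integer(gregexpr("(?=AG)", s, perl = TRUE)[[1L]])
    cac <- as.integer(gregexpr("(?=CAC)", s, perl = TRUE)[[1L]])
    ag <- ag[ag > 0]; cac <- cac[cac > 0]
    out <- list()
    for (a in ag) for (cc in cac) {
      len <- cc - a - 2L
      if (len >= lenMin && len <= lenMax) {
        out[[length(out) + 1L]] <- c(a + 1L, cc - 1L)  # 0-based half-open
      }
    }
    if (length(out) == 0L) return(data.frame(start = integer(0), end = integer(0)))
    m <- do.call(rbind, out)
    data.frame(start = m[, 1L], end = m[, 2L])
  }
  fwd <- one(seq); fwd$strand <- rep("+", nrow(fwd))
  rcmap <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(rcmap[strsplit(seq, "")[[1L]]]), collapse = "")
  L <- nchar(seq)
  rev <- one(rc)
  if (nrow(rev)) {
    rev <- data.frame(start = L - rev$end, end = L - rev$start, strand = "-")
  } else rev$strand <- character(0)
  rbind(fwd, rev)
}

intervalKey <- function(df) {
  sort(paste(df$start, df$end, df$strand))
}

candidateKey <- function(gr) {
  sort(paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr) - 1L,
             GenomicRanges::end(gr), GenomicRanges::strand(gr)))
}

## Hand-built prediction profile set (for criterion-style unit tests of the
## consistency / terminal / score machinery without training a model).
makeProfileSet <- function(probsByNode, loci = lociLabels(), depth = 2L) {
  nodes <- unlist(lapply(0:depth, function(i) paste0(i, ".", 0:(2^i - 1L))))
  cols <- as.vector(t(outer(loci, nodes, function(k, n) paste0(k, "|", n))))
  n <- nrow(probsByNode)
  probs <- matrix(0, nrow = n, ncol = length(cols),
                  dimnames = list(NULL, cols))
  for (nm in colnames(probsByNode)) probs[, nm] <- probsByNode[, nm]
  combined <- matrix(NA_real_, n, length(loci), dimnames = list(NULL, loci))
  for (k in loci) combined[, k] <- rowMeans(probs[, paste0(k, "|", nodes), drop = FALSE])
  methods::new("PredictionProfileSet",
               probs = probs, combined = combined,
               assigned = rep(NA_character_, n), accepted = rep(FALSE, n),
               mrScore = rep(NA_real_, n), ambiguous = rep(FALSE, n),
               loci = loci, nodes = nodes)
}
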