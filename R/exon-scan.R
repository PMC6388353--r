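## Candidate V-exon enumeration between the AG splice-acceptor motif and the
## CAC prefix of the recombination signal sequence.

## All AG/CAC motif occurrences on one oriented strand, paired so the inner
## span (AG-exclusive, CAC-exclusive) lies within [lenMin, lenMax].
## Returns 0-based half-open coordinates on that oriented string.
.scanStrandIntervals <- function(s, lenMin, lenMax) {
  subj <- Biostrings::DNAString(s)
  ## matchPattern reports every occurrence, including overlapping CACAC.
  ag1 <- Biostrings::start(Biostrings::matchPattern("AG", subj))
  cac1 <- Biostrings::start(Biostrings::matchPattern("CAC", subj))
  empty <- data.frame(start = integer(0), end = integer(0))
  if (length(ag1) == 0L || length(cac1) == 0L) return(empty)
  cac1 <- sort(cac1)
  ## inner span = cac1 - ag1 - 2 must lie in [lenMin, lenMax]
  lo <- findInterval(ag1 + lenMin + 2L - 1L, cac1) + 1L
  hi <- findInterval(ag1 + lenMax + 2L, cac1)
  n <- pmax(hi - lo + 1L, 0L)
  if (sum(n) == 0L) return(empty)
  agRep <- rep.int(ag1, n)
  cacIdx <- sequence(n, from = pmax(lo, 1L))
  cacSel <- cac1[cacIdx]
  data.frame(start = agRep + 1L, end = cacSel - 1L)  # 0-based half-open
}

#' Enumerate AG--CAC bounded intervals on both strands
#'
#' Every pairing of an AG occurrence with a downstream CAC occurrence whose
#' enclosed (motif-exclusive) interval length is within `[lenMin, lenMax]`
#' is reported, including nested and overlapping pairings.  The reverse
#' complement is scanned the same way and its intervals mapped back to
#' forward-strand coordinates.
#'
#' @param seq DNA sequence: character string, `DNAString` or one-element
#'   `DNAStringSet`.
#' @param lenMin,lenMax Inclusive bounds on the inner interval length in bp.
#' @return `data.frame` with columns `start`, `end` (0-based half-open,
#'   forward-strand coordinates of the inner interval) and `strand`.
#' @export
#' @examples
#' enumerateMotifIntervals(paste0("AG", strrep("A", 300), "CAC"))
enumerateMotifIntervals <- function(seq, lenMin = 275L, lenMax = 330L) {
  s <- .asSequenceString(seq)
  if (!nzchar(s)) stop("sequence must be non-empty")
  L <- nchar(s)
  fwd <- .scanStrandIntervals(s, lenMin, lenMax)
  fwd$strand <- rep("+", nrow(fwd))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev <- .scanStrandIntervals(rc, lenMin, lenMax)
  if (nrow(rev)) {
    rev <- data.frame(start = L - rev$end, end = L - rev$start,
                      strand = "-")
  } else {
    rev$strand <- character(0)
  }
  out <- rbind(fwd, rev)
  rownames(out) <- NULL
  out
}

#' Translate motif-bounded intervals into candidate exons
#'
#' The reading frame is anchored at the 3' (RSS) end: `len %% 3` bases are
#' trimmed from the 5' end so the 3' boundary sits on a codon boundary
#' (recorded as `frame_trim`).  Intervals whose in-frame translation contains
#' a stop codon, or whose nucleotide sequence contains a base outside
#' `{A, C, G, T}`, are discarded.
#'
#' @param intervals Output of [enumerateMotifIntervals()] on the same `seq`.
#' @param seq The forward-strand DNA sequence the intervals refer to.
#' @return `data.frame` with columns `start`, `end`, `strand`, `nt`
#'   (reading-orientation nucleotide sequence), `frame_trim` and `aa`.
#' @export
translateCandidates <- function(intervals, seq) {
  s <- .asSequenceString(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), nt = character(0),
                      frame_trim = integer(0), aa = character(0))
  if (nrow(intervals) == 0L) return(empty)
  nt <- substring(s, intervals$start + 1L, intervals$end)
  minus <- intervals$strand == "-"
  if (any(minus)) {
    nt[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(nt[minus])))
  }
  ok <- !grepl("[^ACGT]", nt)
  intervals <- intervals[ok, , drop = FALSE]
  nt <- nt[ok]
  if (length(nt) == 0L) return(empty)
  len <- nchar(nt)
  trim <- len %% 3L
  coding <- substring(nt, trim + 1L)
  ## no.init.codon: the frame is RSS-anchored, the first codon is not a start
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(coding),
                                           no.init.codon = TRUE))
  keep <- !grepl("*", aa, fixed = TRUE)
  out <- data.frame(start = intervals$start, end = intervals$end,
                    strand = intervals$strand, nt = nt,
                    frame_trim = trim, aa = aa,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(nchar(out$aa) == (nchar(out$nt) - out$frame_trim) / 3L))
  out
}

#' Scan one DNA sequence for candidate V-exons
#'
#' Combines [enumerateMotifIntervals()] and [translateCandidates()] and
#' packages the result as a `GRanges` (1-based closed internally; exported
#' tables use 0-based half-open coordinates).
#'
#' @param seq DNA sequence (character, `DNAString` or 1-element set).
#' @param contigId Sequence name for the returned ranges.
#' @param config A [vexConfig()]; uses `lenMin`/`lenMax`.
#' @return `GRanges` with metadata columns `nt`, `frame_trim`, `aa`.
#' @export
scanSequence <- function(seq, contigId = "seq", config = vexConfig()) {
  cand <- translateCandidates(
    enumerateMotifIntervals(seq, config$lenMin, config$lenMax), seq)
  GenomicRanges::GRanges(
    seqnames = rep(contigId, nrow(cand)),
    ranges = IRanges::IRanges(start = cand$start + 1L, end = cand$end),
    strand = cand$strand,
    nt = cand$nt, frame_trim = cand$frame_trim, aa = cand$aa
  )
}

#' Scan a genome (chunked) for candidate V-exons
#'
#' Each contig is split into overlapping chunks ([chunkContig()]), each chunk
#' is scanned independently (chunk processing is order-independent and
#' side-effect-free), per-chunk candidates are lifted to absolute contig
#' coordinates and deduplicated ([mergeCandidates()]), and overlapping
#' candidates are grouped ([groupOverlaps()]).
#'
#' @param genome FASTA path or a named [Biostrings::DNAStringSet].
#' @param config A [vexConfig()].
#' @return `GRanges` of candidates with metadata columns `nt`, `frame_trim`,
#'   `aa` and `group_id`.
#' @export
scanGenome <- function(genome, config = vexConfig()) {
  dna <- if (is.character(genome)) readGenome(genome) else genome
  stopifnot(is(dna, "DNAStringSet"))
  perContig <- lapply(seq_along(dna), function(ci) {
    cid <- names(dna)[ci]
    chunks <- chunkContig(dna[ci], config$chunkSize, config$overlap)
    hits <- lapply(seq_len(nrow(chunks)), function(k) {
      gr <- scanSequence(chunks$sequence[k], cid, config)
      GenomicRanges::shift(gr, chunks$chunk_start[k])
    })
    mergeCandidates(hits)
  })
  gr <- mergeCandidates(perContig)
  groupOverlaps(gr)
}

#' Group transitively-overlapping candidates
#'
#' Two candidates on the same contig and strand share a `group_id` iff their
#' half-open intervals are connected through a chain of pairwise overlaps
#' (touching intervals do not overlap).  Computed with `IRanges::reduce`
#' (interval-tree backed, `O((n+k) log n)`).
#'
#' @param gr Candidate `GRanges` (as from [scanSequence()]).
#' @return The same `GRanges` with an integer `group_id` metadata column.
#' @export
groupOverlaps <- function(gr) {
  n <- length(gr)
  gid <- integer(n)
  if (n > 0L) {
    key <- paste(GenomicRanges::seqnames(gr), GenomicRanges::strand(gr))
    offset <- 0L
    for (k in unique(key)) {
      idx <- which(key == k)
      r <- GenomicRanges::ranges(gr[idx])
      red <- IRanges::reduce(r, min.gapwidth = 0L)  # merge only true overlaps
      hit <- IRanges::findOverlaps(r, red, minoverlap = 1L)
      stopifnot(length(hit) == length(idx))
      gid[idx] <- S4Vectors::subjectHits(hit) + offset
      offset <- offset + length(red)
    }
  }
  S4Vectors::mcols(gr)$group_id <- gid
  gr
}

#' Resolve overlap groups by maximum likelihood
#'
#' Within each overlap group exactly one candidate survives: the one whose
#' combined probability for its assigned locus is maximal (tie-break: score
#' desc, start asc, length desc, strand + before -).  Groups whose best
#' candidate fails the acceptance criteria yield nothing.
#'
#' @param gr Grouped candidate `GRanges` (with `group_id`), parallel to
#'   `profiles`.
#' @param profiles A [PredictionProfileSet-class] for the same candidates,
#'   after [assignLoci()].
#' @return `GRanges` of surviving candidates with `locus`, `score` and
#'   `mr_score` metadata columns.
#' @export
resolveOverlaps <- function(gr, profiles) {
  stopifnot(is(profiles, "PredictionProfileSet"),
            length(gr) == nrow(profiles@probs))
  if (length(gr) == 0L) {
    S4Vectors::mcols(gr)$locus <- character(0)
    S4Vectors::mcols(gr)$score <- numeric(0)
    S4Vectors::mcols(gr)$mr_score <- numeric(0)
    return(gr)
  }
  if (all(is.na(profiles@assigned))) stop("run assignLoci() before resolveOverlaps()")
  score <- profiles@combined[cbind(seq_along(gr),
                                   match(profiles@assigned, profiles@loci))]
  ord <- order(S4Vectors::mcols(gr)$group_id, -score,
               GenomicRanges::start(gr), -GenomicRanges::width(gr),
               as.integer(GenomicRanges::strand(gr)))
  winner <- ord[!duplicated(S4Vectors::mcols(gr)$group_id[ord])]
  winner <- winner[profiles@accepted[winner]]
  out <- gr[winner]
  S4Vectors::mcols(out)$locus <- profiles@assigned[winner]
  S4Vectors::mcols(out)$score <- score[winner]
  S4Vectors::mcols(out)$mr_score <- profiles@mrScore[winner]
  ord2 <- order(as.character(GenomicRanges::seqnames(out)),
                GenomicRanges::start(out))
  out[ord2]
}
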