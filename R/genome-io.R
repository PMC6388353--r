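#' Read a genome assembly from FASTA
#'
#' Reads a multi-record (plain or gzipped) FASTA of contigs, scaffolds or
#' chromosomes.  Sequences are upper-cased and contig identifiers are taken
#' from the header up to the first whitespace.  Characters outside
#' `{A, C, G, T, N}` are preserved (intervals containing them are discarded
#' later at scan time) but counted in a warning.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig id.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 some description", "acgtACGT"), fa)
#' readGenome(fa)
readGenome <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) {
    warning("FASTA file contains no records: ", path)
    return(dna)
  }
  names(dna) <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(names(dna))) {
    stop("duplicate contig ids in ", path, ": ",
         paste(unique(names(dna)[duplicated(names(dna))]), collapse = ", "))
  }
  if (any(!nzchar(as.character(dna)))) stop("empty sequence record in ", path)
  freq <- Biostrings::alphabetFrequency(dna, collapse = TRUE)
  odd <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
  if (odd > 0) {
    warning(odd, " characters outside {A,C,G,T,N} in ", path,
            "; intervals containing them will be discarded at scan time")
  }
  dna
}

#' Split a contig into overlapping chunks
#'
#' Chunk `i` starts at `i * (chunkSize - overlap)`; the last chunk may be
#' shorter.  Because the overlap exceeds the maximum candidate span, every
#' candidate interval is wholly contained in at least one chunk, making the
#' chunked scan equivalent to an unchunked scan after duplicate removal.
#'
#' @param contig A single [Biostrings::DNAString], one-element `DNAStringSet`
#'   or character string.
#' @param chunkSize,overlap Chunk length and inter-chunk overlap in bp;
#'   `overlap < chunkSize` required.  Defaults 20000 and 1000.
#' @return A `data.frame` with columns `chunk_start` (0-based offset of the
#'   chunk within the contig) and `sequence`.
#' @export
#' @examples
#' chunkContig(paste(rep("ACGT", 10000), collapse = ""))[, "chunk_start"]
chunkContig <- function(contig, chunkSize = 20000L, overlap = 1000L) {
  if (overlap >= chunkSize) stop("overlap must be smaller than chunkSize")
  if (chunkSize < 1L || overlap < 1L) stop("chunkSize and overlap must be positive")
  s <- .asSequenceString(contig)
  L <- nchar(s)
  if (L == 0L) stop("contig sequence is empty")
  step <- chunkSize - overlap
  starts <- seq.int(0L, L - 1L, by = step)
  data.frame(
    chunk_start = starts,
    sequence = substring(s, starts + 1L, pmin(starts + chunkSize, L)),
    stringsAsFactors = FALSE
  )
}

.asSequenceString <- function(x) {
  if (is(x, "DNAStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence")
    as.character(x[[1L]])
  } else if (is(x, "DNAString")) {
    as.character(x)
  } else if (is.character(x) && length(x) == 1L) {
    toupper(x)
  } else {
    stop("unsupported sequence type: ", class(x)[1L])
  }
}

#' Merge per-chunk candidate sets, removing overlap duplicates
#'
#' Candidates found independently in overlapping chunks are identical in
#' `(contig, strand, start, end)` once chunk offsets have been applied;
#' duplicates collapse to one record and the result is sorted by
#' `(contig, start, end, strand)`.
#'
#' @param ... [GenomicRanges::GRanges] of candidates in absolute contig
#'   coordinates (or a single list of them).
#' @return A deduplicated, sorted `GRanges`.
#' @export
mergeCandidates <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !is(parts[[1L]], "GRanges")) {
    parts <- parts[[1L]]
  }
  parts <- parts[vapply(parts, length, integer(1)) > 0L]
  if (length(parts) == 0L) return(GenomicRanges::GRanges())
  gr <- suppressWarnings(do.call(c, unname(parts)))
  key <- paste(GenomicRanges::seqnames(gr), GenomicRanges::strand(gr),
               GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr <- gr[!duplicated(key)]
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr),
               as.integer(GenomicRanges::strand(gr)))
  gr[ord]
}
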