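## Seeded synthetic benchmark: V-exon-like families at controlled divergence
## tiers, planted into random contigs next to AG / CACAGTG context, plus
## structure-free decoy intervals.  Everything is reproducible from one seed.

## Sense codons per amino acid (stop codons excluded by construction).
.codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[.AA20]
}

#' Reverse-translate an amino-acid sequence
#'
#' Chooses uniformly at random among synonymous sense codons, so the result
#' is always stop-free in frame.  Randomness comes from the current RNG
#' state (seed it with `set.seed` for reproducibility).
#'
#' @param aaSeq Amino-acid sequence.
#' @return Nucleotide string of length `3 * nchar(aaSeq)`.
#' @export
reverseTranslate <- function(aaSeq) {
  ct <- .codonTable()
  chars <- .splitChars(aaSeq)
  if (!all(chars %in% .AA20)) stop("non-standard residue in sequence")
  paste(vapply(chars, function(a) {
    cs <- ct[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

#' Generate six divergent locus consensus profiles
#'
#' Each profile is a random amino-acid consensus of length 92--110 carrying
#' the conserved features of real V-exons: a cysteine near position 22, a
#' tryptophan near position 36 and a Y-Y-C motif within the final 15
#' residues.  Profiles are mutually divergent (pairwise identity < 0.6,
#' asserted).  These conserved elements are generator realism only -- the
#' classifier never uses them as rules.
#'
#' @param seed Integer seed.
#' @return Named list of 6 profiles (one per [lociLabels()] entry), each a
#'   list with `locus`, `length`, `consensus` and `conserved` (positions).
#' @export
makeLocusProfiles <- function(seed = 1L) {
  loci <- lociLabels()
  profiles <- list()
  for (ki in seq_along(loci)) {
    set.seed(.deriveSeed(seed, "profile", ki))
    L <- sample(92:110, 1L)
    cons <- sample(.AA20, L, replace = TRUE)
    yycStart <- L - 10L
    cons[22L] <- "C"
    cons[36L] <- "W"
    cons[yycStart + 0:2] <- c("Y", "Y", "C")
    profiles[[loci[ki]]] <- list(
      locus = loci[ki], length = L,
      consensus = paste(cons, collapse = ""),
      conserved = c(22L, 36L, yycStart + 0:2))
  }
  idm <- .pairwiseIdentity(vapply(profiles, `[[`, character(1), "consensus"))
  stopifnot("profiles are not mutually divergent enough" =
              max(idm[upper.tri(idm)]) < 0.6)
  profiles
}

.pairwiseIdentity <- function(seqs) {
  n <- length(seqs)
  m <- diag(1, n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    ca <- .splitChars(seqs[a]); cb <- .splitChars(seqs[b])
    k <- min(length(ca), length(cb))
    m[a, b] <- m[b, a] <- mean(ca[seq_len(k)] == cb[seq_len(k)])
  }
  m
}

## Divergence tiers: expected amino-acid substitution rate from consensus.
.tierRates <- c("0" = 0.05, "1" = 0.15, "2" = 0.30)

#' Sample a family of sequences from a locus profile
#'
#' Each family member is the consensus with positions substituted
#' independently at the tier's rate; conserved positions mutate at one
#' tenth of the global rate.  Substitutions are uniform over the other 19
#' residues.
#'
#' @param profile One profile from [makeLocusProfiles()].
#' @param n Number of sequences (>= 1).
#' @param tier Divergence tier 0, 1 or 2 (substitution rates 0.05, 0.15,
#'   0.30).
#' @param seed Integer seed.
#' @param rates Optional named vector overriding the tier rates.
#' @return Character vector of `n` amino-acid sequences.
#' @export
sampleFamily <- function(profile, n, tier = 0L, seed = 1L,
                         rates = .tierRates) {
  if (n < 1L) stop("n must be >= 1")
  rate <- rates[[as.character(tier)]]
  if (is.null(rate)) stop("unknown tier: ", tier)
  set.seed(.deriveSeed(seed, "family", profile$locus, tier))
  cons <- .splitChars(profile$consensus)
  pos_rate <- rep(rate, length(cons))
  pos_rate[profile$conserved] <- rate / 10
  vapply(seq_len(n), function(i) {
    mut <- stats::runif(length(cons)) < pos_rate
    out <- cons
    if (any(mut)) {
      out[mut] <- vapply(out[mut], function(a) {
        sample(setdiff(.AA20, a), 1L)
      }, character(1))
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Build a synthetic benchmark genome with ground truth
#'
#' Plants exon-like elements (`AG` + 0--2 frame-padding bases + reverse
#' translated family member + `CACAGTG`) and structure-free decoys (same
#' wrapping around uniform-random sense codons) at non-overlapping random
#' positions and strands inside uniform-random background contigs.  Planted
#' inner intervals always satisfy the scanner's motif, length, frame and
#' stop-codon constraints, so scan-stage recall on the truth set is 100% by
#' construction (asserted for every element at generation).
#'
#' @param profiles Output of [makeLocusProfiles()].
#' @param exonCounts Named list or vector: for each tier (`"0"`, `"1"`,
#'   `"2"`) the number of exons planted per locus.  E.g.
#'   `c("0" = 4, "1" = 4, "2" = 4)`.
#' @param nDecoys Total number of decoy elements.
#' @param nContigs,contigLength Number and length (bp) of background
#'   contigs.
#' @param seed Integer seed.
#' @param rates Tier substitution rates (see [sampleFamily()]).
#' @return List with `contigs` (named `DNAStringSet`) and `truth`
#'   (`data.frame`: `contig`, `start`, `end` (0-based half-open inner
#'   interval), `strand`, `locus`, `tier`, `kind` (exon/decoy), `aa`).
#' @export
buildBenchmark <- function(profiles, exonCounts = c("0" = 4L),
                           nDecoys = 30L, nContigs = 8L,
                           contigLength = 20000L, seed = 1L,
                           rates = .tierRates) {
  elements <- list()
  for (tier in names(exonCounts)) {
    nPer <- exonCounts[[tier]]
    if (nPer == 0L) next
    for (k in names(profiles)) {
      fam <- sampleFamily(profiles[[k]], nPer, tier = as.integer(tier),
                          seed = seed, rates = rates)
      for (ii in seq_along(fam)) {
        elements[[length(elements) + 1L]] <-
          list(aa = fam[ii], locus = k, tier = as.integer(tier), kind = "exon")
      }
    }
  }
  set.seed(.deriveSeed(seed, "decoys"))
  for (ii in seq_len(nDecoys)) {
    L <- sample(92:110, 1L)
    elements[[length(elements) + 1L]] <-
      list(aa = paste(sample(.AA20, L, replace = TRUE), collapse = ""),
           locus = NA_character_, tier = NA_integer_, kind = "decoy")
  }

  ## Encode each element: AG + pad + codons + CACAGTG, pad chosen so the
  ## inner span (pad + 3L) stays within the 275-330 window and exercises
  ## frame_trim in {0, 1, 2}.
  set.seed(.deriveSeed(seed, "encode"))
  for (ii in seq_along(elements)) {
    el <- elements[[ii]]
    nt <- reverseTranslate(el$aa)
    maxPad <- min(2L, 330L - nchar(nt))
    pad <- sample(0:maxPad, 1L)
    padNt <- if (pad > 0L) paste(sample(c("A", "C", "G", "T"), pad,
                                        replace = TRUE), collapse = "") else ""
    inner <- paste0(padNt, nt)
    stopifnot(nchar(inner) >= 275L, nchar(inner) <= 330L)
    elements[[ii]]$inner <- inner
    elements[[ii]]$element <- paste0("AG", inner, "CACAGTG")
    elements[[ii]]$strand <- sample(c("+", "-"), 1L)
  }

  ## Random background contigs, then overwrite with elements at
  ## non-overlapping positions (margin 10 bp from ends and between elements).
  set.seed(.deriveSeed(seed, "contigs"))
  contigs <- vapply(seq_len(nContigs), function(ci) {
    paste(sample(c("A", "C", "G", "T"), contigLength, replace = TRUE),
          collapse = "")
  }, character(1))
  names(contigs) <- sprintf("synth_contig_%02d", seq_len(nContigs))

  occupied <- rep(list(IRanges::IRanges()), nContigs)
  truth <- list()
  set.seed(.deriveSeed(seed, "place"))
  assignment <- sample(rep_len(seq_len(nContigs), length(elements)))
  for (ii in seq_along(elements)) {
    el <- elements[[ii]]
    ci <- assignment[ii]
    elen <- nchar(el$element)
    placed <- FALSE
    for (try in seq_len(1000L)) {
      q <- sample.int(contigLength - elen - 20L, 1L) + 10L  # 1-based start
      cand <- IRanges::IRanges(q - 10L, q + elen + 9L)       # margin buffer
      if (length(IRanges::findOverlaps(cand, occupied[[ci]])) == 0L) {
        occupied[[ci]] <- c(occupied[[ci]], cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place element ", ii,
                      " without overlap; increase contigLength or nContigs")
    emitted <- if (el$strand == "+") el$element else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(el$element)))
    substr(contigs[ci], q, q + elen - 1L) <- emitted
    q0 <- q - 1L  # 0-based element start
    ilen <- nchar(el$inner)
    if (el$strand == "+") {
      s0 <- q0 + 2L; e0 <- s0 + ilen
    } else {
      s0 <- q0 + 7L; e0 <- s0 + ilen
    }
    truth[[length(truth) + 1L]] <- data.frame(
      contig = names(contigs)[ci], start = s0, end = e0,
      strand = el$strand, locus = el$locus, tier = el$tier,
      kind = el$kind, aa = el$aa, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$contig, truth$start), , drop = FALSE]
  rownames(truth) <- NULL

  ## By-construction check: every planted inner interval translates back to
  ## its amino-acid sequence under the scanner's 3'-anchored frame.
  for (r in seq_len(nrow(truth))) {
    nt <- substring(contigs[truth$contig[r]], truth$start[r] + 1L, truth$end[r])
    if (truth$strand[r] == "-") {
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    }
    trim <- nchar(nt) %% 3L
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substring(nt, trim + 1L)), no.init.codon = TRUE))
    stopifnot(identical(aa, truth$aa[r]))
  }

  list(contigs = Biostrings::DNAStringSet(contigs), truth = truth)
}

#' Write a benchmark to FASTA + truth TSV
#'
#' @param benchmark Output of [buildBenchmark()].
#' @param prefix Output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>_truth.tsv` (BED-compatible first three columns).
#' @return Named character vector of the two paths, invisibly.
#' @export
writeBenchmark <- function(benchmark, prefix) {
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, "_truth.tsv")
  Biostrings::writeXStringSet(benchmark$contigs, fa)
  utils::write.table(benchmark$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, truth = tsv))
}
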