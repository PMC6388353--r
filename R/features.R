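## Multiresolution decomposition and alignment-free feature transforms.
## Feature length never depends on sequence length, and no transform ever
## compares two sequences -- classification stays alignment-free.

#' Multiresolution decomposition of an amino-acid sequence
#'
#' Recursively halves the sequence `depth` times.  Odd-length nodes split
#' with the left child one residue longer (frozen convention).  Level `i`
#' has `2^i` nodes and concatenating the two children of any node restores
#' the parent.
#'
#' @param aaSeq Amino-acid sequence (single string).
#' @param depth Number of subdivision levels; requires
#'   `nchar(aaSeq) >= 2^depth` so every terminal node is non-empty.
#' @return An [MRDecomposition-class] object.
#' @export
#' @examples
#' mrNodes(mrDecompose("ABCDEFGH", 2))
mrDecompose <- function(aaSeq, depth = 2L) {
  stopifnot(is.character(aaSeq), length(aaSeq) == 1L)
  depth <- as.integer(depth)
  if (depth < 0L) stop("depth must be non-negative")
  if (nchar(aaSeq) < 2^depth) {
    stop("sequence of length ", nchar(aaSeq),
         " is too short for depth ", depth, " (need >= ", 2^depth, ")")
  }
  nodes <- list("0.0" = aaSeq)
  if (depth > 0L) {
    for (i in seq_len(depth)) {
      for (j in 0:(2^(i - 1L) - 1L)) {
        parent <- nodes[[.nodeName(i - 1L, j)]]
        n <- nchar(parent)
        cut <- ceiling(n / 2)  # left child longer on odd lengths
        nodes[[.nodeName(i, 2L * j)]] <- substring(parent, 1L, cut)
        nodes[[.nodeName(i, 2L * j + 1L)]] <- substring(parent, cut + 1L, n)
      }
    }
  }
  nodes <- nodes[.nodeNames(depth)]
  new("MRDecomposition", sequence = aaSeq, depth = depth, nodes = nodes)
}

#' Amino-acid and consecutive-pair histogram transform (440 dimensions)
#'
#' Concatenates the 20-bin standard-residue histogram with a 420-bin
#' histogram of ordered consecutive residue pairs, for 440 integer entries
#' total.  Residues are indexed in fixed alphabetical one-letter order
#' (A, C, D, ..., Y); the pair block is laid out row-major by first residue
#' over a 21-symbol second position (the 20 residues plus the ambiguity
#' symbol `X`, which is structurally zero for the stop-free, unambiguous
#' exon translations this pipeline produces but keeps the layout closed
#' under deduced-sequence alphabets).  The first 20 entries always sum to
#' the sequence length and the pair block to length - 1.
#'
#' @param aaSeq Amino-acid sequence over the 20 standard residues.
#' @return Named integer vector of length 440.
#' @export
#' @examples
#' v <- aaPairTransform("ACD")
#' v[v != 0]
aaPairTransform <- function(aaSeq) {
  stopifnot(is.character(aaSeq), length(aaSeq) == 1L, nchar(aaSeq) >= 1L)
  idx <- match(.splitChars(aaSeq), .AA20)
  if (anyNA(idx)) {
    stop("non-standard residue in sequence: ",
         paste(setdiff(.splitChars(aaSeq), .AA20), collapse = ""))
  }
  mono <- tabulate(idx, nbins = 20L)
  n <- length(idx)
  pair <- if (n >= 2L) {
    tabulate(21L * (idx[-n] - 1L) + idx[-1L], nbins = 420L)
  } else {
    integer(420L)
  }
  v <- c(mono, pair)
  names(v) <- c(.AA20, as.vector(t(outer(.AA20, c(.AA20, "X"), paste0))))
  v
}

#' Standardized AAindex1 physicochemical property table
#'
#' Loads the AAindex1 collection of amino-acid property scales, drops
#' entries with missing values or zero variance, orders the remainder by
#' accession identifier and keeps the first 500.  Each retained scale is
#' standardized to zero mean and unit standard deviation over the 20
#' residues.  The selection is deterministic and its accession manifest is
#' stored with trained models.
#'
#' @param n Number of property scales to keep (default 500).
#' @return List with `values` (20 x `n` numeric matrix, rows named by
#'   one-letter residue code, standardized columns) and `accessions`
#'   (character vector of the retained AAindex accession numbers).
#' @export
defaultPropertyTable <- function(n = 500L) {
  cached <- .propertyCache[[as.character(n)]]
  if (!is.null(cached)) return(cached)
  e <- new.env()
  utils::data("aaindex", package = "seqinr", envir = e)
  aai <- e$aaindex
  keep <- vapply(aai, function(x) !anyNA(x$I) && stats::sd(x$I) > 0, logical(1))
  aai <- aai[keep]
  acc <- vapply(aai, function(x) x$H, character(1))
  aai <- aai[order(acc)]
  acc <- sort(acc)
  if (length(aai) < n) stop("only ", length(aai), " complete AAindex entries available")
  aai <- aai[seq_len(n)]
  acc <- acc[seq_len(n)]
  vals <- vapply(aai, function(x) {
    v <- x$I
    (v - mean(v)) / stats::sd(v)
  }, numeric(20L))
  ## seqinr names the 20 values by three-letter code, in a fixed order
  rownames(vals) <- vapply(rownames(vals), function(a3) {
    seqinr::a(a3)
  }, character(1))
  vals <- vals[.AA20, , drop = FALSE]
  colnames(vals) <- acc
  out <- list(values = vals, accessions = acc)
  .propertyCache[[as.character(n)]] <- out
  out
}

.propertyCache <- new.env(parent = emptyenv())

#' Physicochemical distance transform (PDT, 500 dimensions)
#'
#' For each standardized property scale `P`, computes the mean squared
#' difference between residues at lag `lam`:
#' \deqn{d_P = \frac{1}{L-\lambda}\sum_{i=1}^{L-\lambda}
#'       (P(a_i) - P(a_{i+\lambda}))^2}
#' over the sequence, then scales the 500-entry vector to unit Euclidean
#' norm (a zero vector, e.g. from a homopolymer, is left as zeros).
#'
#' @param aaSeq Amino-acid sequence; must be longer than `lam`.
#' @param lam Correlation lag (default 1 = immediate neighbours).
#' @param table Property table from [defaultPropertyTable()].
#' @return Named numeric vector of length `ncol(table$values)` (500 by
#'   default).
#' @export
#' @examples
#' sum(pdtTransform("ACDEFGHIKL")^2)  # unit norm
pdtTransform <- function(aaSeq, lam = 1L, table = defaultPropertyTable()) {
  stopifnot(is.character(aaSeq), length(aaSeq) == 1L)
  lam <- as.integer(lam)
  if (lam < 1L) stop("lam must be a positive integer")
  chars <- .splitChars(aaSeq)
  L <- length(chars)
  if (lam >= L) stop("lam (", lam, ") must be smaller than sequence length (", L, ")")
  idx <- match(chars, rownames(table$values))
  if (anyNA(idx)) {
    stop("non-standard residue in sequence: ",
         paste(setdiff(chars, rownames(table$values)), collapse = ""))
  }
  P <- table$values[idx, , drop = FALSE]
  d <- P[seq_len(L - lam), , drop = FALSE] - P[seq_len(L - lam) + lam, , drop = FALSE]
  raw <- colSums(d * d) / (L - lam)
  nrm <- sqrt(sum(raw * raw))
  if (nrm > 0) raw <- raw / nrm
  raw
}

#' Featurize every node of a multiresolution decomposition
#'
#' Applies the transform configured for each level to every node of that
#' level; all vectors within one level share a transform and length.
#'
#' @param mr An [MRDecomposition-class].
#' @param levelMap Named list mapping level (`"0"`, `"1"`, ...) to
#'   `list(kind = "aa_pairs")` or `list(kind = "pdt", lam = <lag>)`.  Must
#'   cover all levels `0:depth`.
#' @param table Property table for PDT levels.
#' @return Named list (by node) of numeric feature vectors.
#' @export
hybridTransform <- function(mr, levelMap, table = defaultPropertyTable()) {
  stopifnot(is(mr, "MRDecomposition"))
  need <- as.character(0:mr@depth)
  if (!all(need %in% names(levelMap))) {
    stop("levelMap must cover levels ", paste(need, collapse = ", "))
  }
  out <- lapply(names(mr@nodes), function(nm) {
    lv <- as.character(.nodeLevel(nm))
    spec <- levelMap[[lv]]
    if (spec$kind == "aa_pairs") {
      aaPairTransform(mr@nodes[[nm]])
    } else {
      pdtTransform(mr@nodes[[nm]], lam = spec$lam, table = table)
    }
  })
  names(out) <- names(mr@nodes)
  out
}

## Featurize a vector of sequences into one matrix per node:
## list over nodes of (n x d) matrices, using the config's level map.
.featurizeSet <- function(aaSeqs, config, table = NULL) {
  lm <- .levelMap(config)
  needsPdt <- any(vapply(lm, function(x) x$kind == "pdt", logical(1)))
  if (needsPdt && is.null(table)) table <- defaultPropertyTable()
  nodeNms <- .nodeNames(config$depth)
  perSeq <- lapply(aaSeqs, function(aa) {
    hybridTransform(mrDecompose(aa, config$depth), lm, table = table)
  })
  out <- lapply(nodeNms, function(nm) {
    do.call(rbind, lapply(perSeq, `[[`, nm))
  })
  names(out) <- nodeNms
  out
}
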