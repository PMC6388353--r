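#' @import methods
#' @importClassesFrom Biostrings AAStringSet
NULL

#' Multiresolution decomposition of an amino-acid sequence
#'
#' A recursive binary subdivision of one amino-acid sequence.  Node
#' \eqn{(i, j)} holds the j-th subsequence at hierarchical level i; node
#' (0,0) is the full sequence, level i has \eqn{2^i} nodes, and the two
#' children of a node concatenate back to their parent (odd lengths split
#' with the left child one residue longer).  The terminal left-most and
#' right-most nodes guard the exon boundaries during classification.
#'
#' @slot sequence The full amino-acid sequence (node 0.0).
#' @slot depth Number of subdivision levels.
#' @slot nodes Named list of subsequences; names are `"<level>.<index>"`.
#'
#' @seealso [mrDecompose()], [mrNode()], [mrNodes()]
#' @export
setClass("MRDecomposition",
  representation(sequence = "character", depth = "integer", nodes = "list"))

setValidity("MRDecomposition", function(object) {
  msg <- character(0)
  if (length(object@sequence) != 1L) msg <- c(msg, "sequence must be length 1")
  d <- object@depth
  expected <- .nodeNames(d)
  if (!identical(names(object@nodes), expected)) {
    msg <- c(msg, "nodes must be named 0.0, 1.0, 1.1, ... in level order")
  } else {
    if (!identical(object@nodes[["0.0"]], object@sequence)) {
      msg <- c(msg, "node 0.0 must equal the full sequence")
    }
    if (any(!nzchar(unlist(object@nodes)))) msg <- c(msg, "all nodes must be non-empty")
    if (d > 0) {
      for (i in 0:(d - 1L)) for (j in 0:(2^i - 1L)) {
        parent <- object@nodes[[.nodeName(i, j)]]
        kids <- paste0(object@nodes[[.nodeName(i + 1L, 2L * j)]],
                       object@nodes[[.nodeName(i + 1L, 2L * j + 1L)]])
        if (!identical(parent, kids)) {
          msg <- c(msg, sprintf("children of node %s do not concatenate to it", .nodeName(i, j)))
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Trained per-locus, per-node classifier ensembles
#'
#' One binary Random Forest per (locus, multiresolution node) pair, together
#' with everything needed to re-featurize candidates identically at predict
#' time: the transform configuration, the AAindex property selection
#' manifest, the locus order and the training seed.
#'
#' @slot models Named list of `ranger` ensembles, names `"<locus>|<node>"`.
#' @slot config The [vexConfig()] used for training (drives featurization).
#' @slot manifest List with `loci`, `nodes`, `featureLengths` and
#'   `propertyAccessions` (AAindex accessions backing the PDT, if used).
#' @slot seed Master seed the training run derived its randomness from.
#'
#' @seealso [trainLocusModels()], [predictProfiles()]
#' @export
setClass("LocusModelSet",
  representation(models = "list", config = "list", manifest = "list",
                 seed = "integer"))

setValidity("LocusModelSet", function(object) {
  msg <- character(0)
  want <- as.vector(outer(object@manifest$loci, object@manifest$nodes,
                          function(k, n) paste0(k, "|", n)))
  if (!setequal(names(object@models), want)) {
    msg <- c(msg, "models must hold exactly one ensemble per (locus, node) pair")
  }
  if (length(msg)) msg else TRUE
})

#' Per-candidate prediction profiles
#'
#' Signal-class probabilities for every (locus, node) pair of a set of
#' candidate sequences, the per-locus combined probabilities, the
#' multiresolution consistency score, and the acceptance decision.
#'
#' @slot probs Numeric matrix, candidates x (locus|node) columns; each entry
#'   is the ensemble's signal-class probability in \[0, 1\].
#' @slot combined Numeric matrix, candidates x loci: per-locus aggregate of
#'   the node probabilities (arithmetic mean by default).
#' @slot assigned Character vector of assigned loci (`NA` until
#'   [assignLoci()] has run).
#' @slot accepted Logical vector: passed the probability, consistency and
#'   terminal criteria for the assigned locus.
#' @slot mrScore Numeric vector of multiresolution consistency scores for the
#'   assigned locus (0 is perfect agreement across levels; more negative is
#'   worse under the default score form).
#' @slot ambiguous Logical vector flagging exact ties at the argmax.
#' @slot loci,nodes Character vectors giving the locus and node order.
#'
#' @seealso [predictProfiles()], [assignLoci()]
#' @export
setClass("PredictionProfileSet",
  representation(probs = "matrix", combined = "matrix",
                 assigned = "character", accepted = "logical",
                 mrScore = "numeric", ambiguous = "logical",
                 loci = "character", nodes = "character"))

setValidity("PredictionProfileSet", function(object) {
  msg <- character(0)
  n <- nrow(object@probs)
  if (any(object@probs < 0 | object@probs > 1, na.rm = TRUE)) {
    msg <- c(msg, "probabilities must lie in [0, 1]")
  }
  if (!identical(colnames(object@combined), object@loci)) {
    msg <- c(msg, "combined columns must match loci")
  }
  if (nrow(object@combined) != n || length(object@assigned) != n ||
      length(object@accepted) != n || length(object@mrScore) != n) {
    msg <- c(msg, "all per-candidate slots must have equal length")
  }
  if (any(object@accepted & is.na(object@assigned))) {
    msg <- c(msg, "accepted candidates must carry an assigned locus")
  }
  if (length(msg)) msg else TRUE
})

#' State of one bootstrap iteration
#'
#' The training set after iteration `t`, the discoveries made during it, and
#' bookkeeping used by the convergence rule and the iteration report.  The
#' training set only ever grows, and discoveries are deduplicated against it
#' by exact amino-acid sequence before augmentation.
#'
#' @slot t Iteration index (0 = state before any iteration).
#' @slot training `AAStringSet` of training sequences (uniquely named).
#' @slot locus Character vector parallel to `training`: locus label per
#'   training sequence.
#' @slot discoveries `data.frame` of the candidates newly accepted this
#'   iteration (aa, locus, score, contig, start, end, strand).
#' @slot nAccepted,nRejected Candidate counts for this iteration: accepted
#'   after overlap resolution, and scanned-but-not-accepted.
#' @slot scoreSamples Named list (per locus) of combined scores of accepted
#'   candidates, for score-distribution diagnostics.
#'
#' @seealso [newIterationState()], [runIteration()], [isConverged()]
#' @export
setClass("IterationState",
  representation(t = "integer", training = "AAStringSet", locus = "character",
                 discoveries = "data.frame", nAccepted = "integer",
                 nRejected = "integer", scoreSamples = "list"))

setValidity("IterationState", function(object) {
  msg <- character(0)
  if (length(object@training) != length(object@locus)) {
    msg <- c(msg, "locus must be parallel to training")
  }
  if (!all(object@locus %in% lociLabels())) {
    msg <- c(msg, "locus labels must be among lociLabels()")
  }
  if (anyDuplicated(names(object@training))) {
    msg <- c(msg, "training sequence names must be unique")
  }
  if (length(msg)) msg else TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "MRDecomposition", function(object) {
  cat("MRDecomposition: depth", object@depth, "|",
      length(object@nodes), "nodes |",
      nchar(object@sequence), "residues\n")
  lens <- vapply(object@nodes, nchar, integer(1))
  cat("  node lengths:", paste(names(lens), lens, sep = "=", collapse = " "), "\n")
})

setMethod("show", "LocusModelSet", function(object) {
  cat("LocusModelSet:", length(object@models), "ensembles (",
      length(object@manifest$loci), "loci x",
      length(object@manifest$nodes), "nodes ),",
      object@config$nTrees, "trees each\n")
  cat("  transform:", object@config$transform,
      "| depth:", object@config$depth, "| seed:", object@seed, "\n")
})

setMethod("show", "PredictionProfileSet", function(object) {
  n <- nrow(object@probs)
  cat("PredictionProfileSet:", n, "candidates,",
      length(object@loci), "loci x", length(object@nodes), "nodes\n")
  if (!all(is.na(object@assigned))) {
    cat("  accepted:", sum(object@accepted), "/", n, "\n")
  }
})

setMethod("show", "IterationState", function(object) {
  cat("IterationState: t =", object@t, "|",
      length(object@training), "training sequences |",
      nrow(object@discoveries), "new discoveries\n")
  tab <- table(factor(object@locus, levels = lociLabels()))
  cat("  per locus:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})
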